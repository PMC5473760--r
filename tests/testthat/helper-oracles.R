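# Shared fixtures and independent brute-force oracles used across tests.

img_of <- function(px, bit_depth = 16L, modality = "darkfield", ...) {
  worm_image(px, bit_depth = bit_depth, modality = modality, ...)
}

mask_of <- function(m) worm_mask(m)

# double-loop densitometry oracle
oracle_density <- function(px, m) {
  total <- 0; n <- 0L
  for (r in seq_len(nrow(px))) for (c in seq_len(ncol(px))) {
    if (m[r, c]) { total <- total + px[r, c]; n <- n + 1L }
  }
  total / n
}

# pixel-enumeration oracle for the phantom annulus mean (0-based center)
oracle_annulus_mean <- function(px, center, inner, outer) {
  total <- 0; n <- 0L
  for (r in seq_len(nrow(px))) for (c in seq_len(ncol(px))) {
    d <- sqrt((r - 1 - center[1])^2 + (c - 1 - center[2])^2)
    if (d >= inner && d <= outer) { total <- total + px[r, c]; n <- n + 1L }
  }
  total / n
}

# winding-angle point-in-polygon oracle (simple polygons, points off the
# boundary)
oracle_inside <- function(r, c, poly) {
  ang <- 0
  n <- nrow(poly)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    v1 <- c(poly[i, 1] - r, poly[i, 2] - c)
    v2 <- c(poly[j, 1] - r, poly[j, 2] - c)
    a <- atan2(v1[1] * v2[2] - v1[2] * v2[1], sum(v1 * v2))
    ang <- ang + a
  }
  abs(ang) > pi
}

# scalar even-odd crossing-number oracle (classic pnpoly), shares the
# boundary convention of the standard algorithm
oracle_inside_eo <- function(r, c, poly) {
  n <- nrow(poly); inside <- FALSE; j <- n
  for (i in seq_len(n)) {
    if (((poly[i, 2] > c) != (poly[j, 2] > c)) &&
        (r < (poly[j, 1] - poly[i, 1]) * (c - poly[i, 2]) /
           (poly[j, 2] - poly[i, 2]) + poly[i, 1]))
      inside <- !inside
    j <- i
  }
  inside
}

# random logical mask with exactly n true pixels
random_mask <- function(nr, nc, n) {
  m <- matrix(FALSE, nr, nc)
  m[sample(nr * nc, n)] <- TRUE
  m
}
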