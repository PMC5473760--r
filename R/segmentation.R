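#' Worm body mask
#'
#' Binary region congruent with its source frame, representing one worm.
#' Produced either by [segment_worms()] (intensity threshold) or
#' [manual_mask()] (hand-drawn outline).
#'
#' @param mask Logical matrix, a single connected component.
#' @param label Worm identifier string.
#' @param source `"auto_threshold"` or `"manual_polygon"`.
#' @param threshold_used Threshold that produced the mask (absent for
#'   manual outlines).
#' @return A `worm_mask` object with computed `area_px`.
#' @export
worm_mask <- function(mask, label = "worm_1",
                      source = c("auto_threshold", "manual_polygon"),
                      threshold_used = NULL) {
  source <- match.arg(source)
  stopifnot(is.matrix(mask), is.logical(mask))
  structure(list(mask = mask, label = label, area_px = sum(mask),
                 source = source, threshold_used = threshold_used),
            class = "worm_mask")
}

#' @export
print.worm_mask <- function(x, ...) {
  cat(sprintf("<worm_mask> '%s': %d px, %s%s\n", x$label, x$area_px, x$source,
              if (!is.null(x$threshold_used))
                sprintf(" (threshold %.4g)", x$threshold_used) else ""))
  invisible(x)
}

# 8-connected component labels of a logical matrix, via the pixel adjacency
# graph (EBImage::bwlabel is 4-connected). Returns an integer matrix, 0 for
# background.
label_components8 <- function(fg) {
  n <- sum(fg)
  lab <- matrix(0L, nrow(fg), ncol(fg))
  if (n == 0L) return(lab)
  idx <- which(fg)                      # column-major linear indices
  id <- matrix(0L, nrow(fg), ncol(fg))
  id[idx] <- seq_len(n)
  r <- ((idx - 1L) %% nrow(fg)) + 1L
  c <- ((idx - 1L) %/% nrow(fg)) + 1L
  edges <- list()
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- r + off[1]; c2 <- c + off[2]
    ok <- r2 >= 1L & r2 <= nrow(fg) & c2 >= 1L & c2 <= ncol(fg)
    ok[ok] <- fg[cbind(r2[ok], c2[ok])]
    if (any(ok))
      edges[[length(edges) + 1L]] <-
        cbind(id[cbind(r[ok], c[ok])], id[cbind(r2[ok], c2[ok])])
  }
  g <- igraph::graph_from_edgelist(do.call(rbind, c(edges, list(cbind(seq_len(n), seq_len(n))))),
                                   directed = FALSE)
  lab[idx] <- igraph::components(g)$membership
  lab
}

# fill interior holes of a logical mask (background regions not reachable
# from the frame border)
fill_holes <- function(mask) {
  filled <- EBImage::fillHull(mask * 1L)
  matrix(as.integer(filled) > 0L, nrow(mask), ncol(mask))
}

#' Threshold-based worm segmentation
#'
#' Pixels strictly above `threshold` are foreground; connected components
#' are taken under 8-connectivity, components smaller than `min_area_px`
#' are discarded, and interior holes are filled so that densities integrate
#' the whole body -- worm interiors (notably the head) can scatter weakly
#' and would otherwise be excluded. The threshold is supplied per condition
#' rather than auto-derived, since worm brightness varies between strains;
#' [suggest_threshold()] offers an Otsu starting point but is never applied
#' silently.
#'
#' Masks are returned sorted by area (descending; ties broken by the
#' smaller top-left pixel index) and labelled `worm_1`, `worm_2`, ... in
#' that order.
#'
#' @param image A [worm_image()].
#' @param threshold Intensity threshold (a.u.); pixels equal to the
#'   threshold are background.
#' @param min_area_px Minimum component area in pixels (default 1).
#' @param max_worms Keep at most this many largest components (`NULL` for
#'   all).
#' @return List of [worm_mask()] objects (possibly empty).
#' @export
segment_worms <- function(image, threshold, min_area_px = 1L,
                          max_worms = NULL) {
  stopifnot(is_worm_image(image))
  if (min_area_px < 1L) stop("`min_area_px` must be >= 1", call. = FALSE)
  fg <- image$pixels > threshold
  lab <- label_components8(fg)
  if (max(lab) == 0L) return(list())
  areas <- tabulate(lab)
  keep <- which(areas >= min_area_px)
  if (!length(keep)) return(list())
  # deterministic order: area desc, ties by first (top-left, row-major) pixel
  first_px <- vapply(keep, function(k) {
    idx <- which(lab == k)
    r <- ((idx - 1L) %% nrow(lab)); c <- ((idx - 1L) %/% nrow(lab))
    min(r * ncol(lab) + c)
  }, numeric(1))
  ord <- keep[order(-areas[keep], first_px)]
  if (!is.null(max_worms)) ord <- utils::head(ord, max_worms)
  lapply(seq_along(ord), function(i) {
    m <- fill_holes(lab == ord[i])
    worm_mask(m, label = sprintf("worm_%d", i), source = "auto_threshold",
              threshold_used = threshold)
  })
}

#' Otsu threshold suggestion
#'
#' A starting point for choosing the per-condition threshold; never applied
#' automatically.
#'
#' @param image A [worm_image()].
#' @return Suggested threshold on the image's native scale.
#' @export
suggest_threshold <- function(image) {
  stopifnot(is_worm_image(image))
  mx <- max(scale_max(image), max(image$pixels))
  EBImage::otsu(EBImage::Image(image$pixels / mx), range = c(0, 1)) * mx
}

# even-odd (crossing-number) point-in-polygon test for pixel centers;
# pts is an n x 2 matrix of (row, col), poly a k x 2 matrix of vertices
points_in_polygon <- function(pts, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, nrow(pts))
  x <- pts[, 1]; y <- pts[, 2]
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# proper-intersection test between all non-adjacent edge pairs of a polygon
polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  seg <- cbind(poly, poly[c(2:n, 1), ])
  orient <- function(p, q, r)
    sign((q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1]))
  for (i in seq_len(n - 2L)) {
    for (j in seq.int(i + 2L, n)) {
      if (i == 1L && j == n) next   # adjacent through the closing edge
      p1 <- seg[i, 1:2]; p2 <- seg[i, 3:4]
      q1 <- seg[j, 1:2]; q2 <- seg[j, 3:4]
      if (orient(p1, p2, q1) * orient(p1, p2, q2) < 0 &&
          orient(q1, q2, p1) * orient(q1, q2, p2) < 0)
        return(TRUE)
    }
  }
  FALSE
}

#' Rasterize a manually drawn worm outline
#'
#' For high-magnification frames the worm boundary is drawn by hand
#' (excluding head and cuticle). A pixel belongs to the mask iff its center
#' lies inside the outline under the even-odd fill rule; exclusion polygons
#' (e.g. the head) are subtracted. Vertices are 0-based `(row, col)`
#' pixel-center coordinates.
#'
#' @param image A [worm_image()] giving the frame geometry.
#' @param polygon Matrix (or list of `c(row, col)`) of >= 3 vertices.
#' @param exclusions Optional list of polygons to subtract.
#' @param label Worm identifier.
#' @return A [worm_mask()] with `source = "manual_polygon"`.
#' @export
manual_mask <- function(image, polygon, exclusions = list(),
                        label = "worm_1") {
  stopifnot(is_worm_image(image))
  as_poly <- function(p) {
    p <- if (is.matrix(p)) p else do.call(rbind, p)
    storage.mode(p) <- "double"
    p
  }
  polygon <- as_poly(polygon)
  if (nrow(polygon) < 3L)
    stop("outline polygon needs at least 3 vertices", call. = FALSE)
  if (polygon_self_intersects(polygon))
    stop("outline polygon is self-intersecting", call. = FALSE)
  nr <- nrow(image$pixels); nc <- ncol(image$pixels)
  pts <- cbind(rep(0:(nr - 1L), times = nc), rep(0:(nc - 1L), each = nr))
  inside <- points_in_polygon(pts, polygon)
  for (ex in exclusions)
    inside <- inside & !points_in_polygon(pts, as_poly(ex))
  worm_mask(matrix(inside, nr, nc), label = label, source = "manual_polygon")
}

# one pass of Zhang-Suen thinning; sub = 1 or 2
zhang_suen_pass <- function(m, sub) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  sh <- function(dr, dc) p[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)]
  p2 <- sh(-1, 0); p3 <- sh(-1, 1); p4 <- sh(0, 1); p5 <- sh(1, 1)
  p6 <- sh(1, 0); p7 <- sh(1, -1); p8 <- sh(0, -1); p9 <- sh(-1, -1)
  b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
  seq9 <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
  a <- matrix(0L, nr, nc)
  for (i in 1:8) a <- a + (seq9[[i]] == 0L & seq9[[i + 1L]] == 1L)
  if (sub == 1L) {
    cond <- m == 1L & b >= 2L & b <= 6L & a == 1L &
      (p2 * p4 * p6 == 0L) & (p4 * p6 * p8 == 0L)
  } else {
    cond <- m == 1L & b >= 2L & b <= 6L & a == 1L &
      (p2 * p4 * p8 == 0L) & (p2 * p6 * p8 == 0L)
  }
  m[cond] <- 0L
  m
}

# Zhang-Suen skeleton of a logical mask
skeletonize <- function(mask) {
  m <- mask * 1L
  repeat {
    m1 <- zhang_suen_pass(m, 1L)
    m2 <- zhang_suen_pass(m1, 2L)
    if (identical(m2, m)) break
    m <- m2
  }
  m > 0L
}

#' Worm length from the mask skeleton
#'
#' The mask is thinned to its morphological skeleton (Zhang-Suen) and the
#' length is the longest geodesic path along the skeleton's 8-neighbour
#' graph, with diagonal steps weighted `sqrt(2)`, times the pixel size.
#' Thinning erodes 1-3 px at each end of an elongated body, so lengths are
#' accurate to a few pixels.
#'
#' @param mask A [worm_mask()] (or logical matrix).
#' @param pixel_size_um Pixel edge length in micrometers, > 0.
#' @return Length in micrometers.
#' @export
worm_length <- function(mask, pixel_size_um) {
  m <- if (inherits(mask, "worm_mask")) mask$mask else mask
  if (!any(m)) stop("mask has zero area", call. = FALSE)
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be > 0", call. = FALSE)
  sk <- skeletonize(m)
  idx <- which(sk)
  n <- length(idx)
  if (n == 1L) return(0)
  id <- matrix(0L, nrow(sk), ncol(sk)); id[idx] <- seq_len(n)
  r <- ((idx - 1L) %% nrow(sk)) + 1L
  c <- ((idx - 1L) %/% nrow(sk)) + 1L
  el <- list(); w <- list()
  offs <- list(c(1L, 0L, 1), c(0L, 1L, 1), c(1L, 1L, sqrt(2)), c(-1L, 1L, sqrt(2)))
  for (off in offs) {
    r2 <- r + off[1]; c2 <- c + off[2]
    ok <- r2 >= 1L & r2 <= nrow(sk) & c2 >= 1L & c2 <= ncol(sk)
    ok[ok] <- sk[cbind(r2[ok], c2[ok])]
    if (any(ok)) {
      el[[length(el) + 1L]] <- cbind(id[cbind(r[ok], c[ok])],
                                     id[cbind(r2[ok], c2[ok])])
      w[[length(w) + 1L]] <- rep(off[3], sum(ok))
    }
  }
  if (!length(el)) return(0)
  g <- igraph::graph_from_edgelist(do.call(rbind, el), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::E(g)$weight <- unlist(w)
  deg <- igraph::degree(g)
  ends <- which(deg == 1L)
  if (length(ends) >= 2L) {
    d <- igraph::distances(g, v = ends, to = ends)
  } else {
    # closed or degenerate skeleton: double-sweep approximation
    d1 <- igraph::distances(g, v = 1L)
    far <- which.max(ifelse(is.finite(d1), d1, -1))
    d <- igraph::distances(g, v = far)
  }
  d[!is.finite(d)] <- 0
  max(d) * pixel_size_um
}
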