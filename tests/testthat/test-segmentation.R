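test_that("threshold segmentation recovers components above the size floor", {
  expect_identical(segment_worms(img_of(matrix(0, 30, 30)), 10), list())

  # one 500-px rectangle of value 100 on zero background
  px <- matrix(0, 60, 60)
  px[11:35, 11:30] <- 100
  out <- segment_worms(img_of(px), 50, min_area_px = 50)
  expect_length(out, 1L)
  expect_identical(out[[1]]$area_px, 500L)
  expect_identical(out[[1]]$threshold_used, 50)

  # size filter: keep the 800-px blob, drop the 300-px one
  px2 <- matrix(0, 80, 80)
  px2[3:42, 3:22] <- 100      # 800 px
  px2[61:75, 51:70] <- 100    # 300 px
  out2 <- segment_worms(img_of(px2), 50, min_area_px = 400)
  expect_length(out2, 1L)
  expect_identical(out2[[1]]$area_px, 800L)

  # both kept: sorted by area descending, deterministic labels
  out3 <- segment_worms(img_of(px2), 50, min_area_px = 100)
  expect_identical(vapply(out3, function(m) m$area_px, integer(1)),
                   c(800L, 300L))
  expect_identical(vapply(out3, function(m) m$label, ""),
                   c("worm_1", "worm_2"))

  # threshold above the image maximum finds nothing
  expect_identical(segment_worms(img_of(px2), 200), list())
})

test_that("components use 8-connectivity and have holes filled", {
  px <- matrix(0, 10, 10)
  px[3, 3] <- 10; px[4, 4] <- 10; px[5, 5] <- 10   # diagonal chain
  out <- segment_worms(img_of(px), 5)
  expect_length(out, 1L)
  expect_identical(out[[1]]$area_px, 3L)

  ring <- matrix(0, 20, 20)
  ring[5:15, 5:15] <- 100
  ring[8:12, 8:12] <- 0     # interior hole, below threshold
  out2 <- segment_worms(img_of(ring), 50)
  expect_identical(out2[[1]]$area_px, 11L * 11L)  # hole filled
})

test_that("pixels equal to the threshold are background", {
  px <- matrix(0, 5, 5); px[2:4, 2:4] <- 7
  expect_identical(segment_worms(img_of(px), 7), list())
  expect_length(segment_worms(img_of(px), 6.999), 1L)
})

test_that("raising the threshold never grows the segmented area", {
  for (seed in 1:5) {
    sp <- scene_spec(droplet_count = 6L, puncta_count = 8L,
                     shot_noise_gain = 0.5, read_noise_sd = 1, seed = seed)
    sc <- render_scene(sp)
    areas <- vapply(c(8, 15, 25, 35), function(thr) {
      out <- segment_worms(sc$image, thr, min_area_px = 50)
      if (length(out)) sum(vapply(out, function(m) m$area_px, integer(1))) else 0L
    }, integer(1))
    expect_true(all(diff(areas) <= 0))
  }
})

test_that("manual outlines rasterize by pixel-center even-odd rule", {
  img <- img_of(matrix(0, 20, 20))
  sq <- rbind(c(-0.5, -0.5), c(-0.5, 9.5), c(9.5, 9.5), c(9.5, -0.5))
  m <- manual_mask(img, sq)
  expect_identical(m$area_px, 100L)
  expect_identical(m$source, "manual_polygon")

  inner <- rbind(c(2.5, 2.5), c(2.5, 6.5), c(6.5, 6.5), c(6.5, 2.5))
  m2 <- manual_mask(img, sq, exclusions = list(inner))
  expect_identical(m2$area_px, 100L - 16L)

  # off-lattice triangle: winding-number oracle is unambiguous
  tri <- rbind(c(0.2, 0.1), c(0.2, 4.3), c(4.4, 0.1))
  m3 <- manual_mask(img, tri)
  expected <- matrix(FALSE, 20, 20)
  for (r in 1:20) for (c in 1:20)
    expected[r, c] <- oracle_inside(r - 1, c - 1, tri)
  expect_identical(m3$mask, expected)

  # lattice-aligned triangle: same even-odd boundary convention as the
  # scalar crossing-number enumeration
  tri2 <- rbind(c(0, 0), c(0, 4), c(4, 0))
  m4 <- manual_mask(img, tri2)
  expected2 <- matrix(FALSE, 20, 20)
  for (r in 1:20) for (c in 1:20)
    expected2[r, c] <- oracle_inside_eo(r - 1, c - 1, tri2)
  expect_identical(m4$mask, expected2)

  bowtie <- rbind(c(0, 0), c(10, 10), c(0, 10), c(10, 0))
  expect_error(manual_mask(img, bowtie), "self-intersecting")
  expect_error(manual_mask(img, sq[1:2, ]), "3 vertices")
})

test_that("worm length follows the skeleton's longest geodesic path", {
  bar <- matrix(FALSE, 20, 220)
  bar[8:13, 11:210] <- TRUE   # 200 x 6 horizontal bar
  len <- worm_length(mask_of(bar), 1)
  expect_gte(len, 193); expect_lte(len, 205)

  len_v <- worm_length(mask_of(t(bar)), 1)
  expect_lt(abs(len_v - len) / len, 0.01)

  # gently curved capsule with analytically known centerline arc length
  sp <- scene_spec(frame = c(160L, 170L), amplitude_px = 6,
                   wavelength_px = 120, half_width_px = 6, seed = 5L)
  sc <- render_scene(sp)
  measured <- worm_length(mask_of(sc$truth$body_mask), 1)
  expect_lt(abs(measured - sc$truth$arc_length_um) / sc$truth$arc_length_um,
            0.05)

  expect_error(worm_length(mask_of(matrix(FALSE, 3, 3)), 1), "zero area")
  expect_error(worm_length(mask_of(bar), 0), "> 0")
})
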