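test_that("scene rendering is deterministic under seed", {
  sp <- scene_spec(droplet_count = 8L, puncta_count = 10L,
                   shot_noise_gain = 0.5, read_noise_sd = 1,
                   vignette = 0.1, seed = 77L)
  s1 <- render_scene(sp); s2 <- render_scene(sp)
  expect_identical(s1$image$pixels, s2$image$pixels)
  expect_identical(s1$truth$droplet_centers, s2$truth$droplet_centers)
  sp2 <- sp; sp2$seed <- 78L
  expect_false(identical(render_scene(sp2)$image$pixels, s1$image$pixels))
})

test_that("a clean scene has exactly the programmed body density", {
  sp <- scene_spec(body_base_intensity = 40, background_mean = 0,
                   background_sd = 0, seed = 1L)
  sc <- render_scene(sp)
  d <- scattering_density(sc$image, mask_of(sc$truth$body_mask))
  expect_identical(d$density, 40)
  expect_identical(sc$truth$noiseless_density, 40)
})

test_that("droplet bookkeeping records disjoint in-body centers", {
  sp <- scene_spec(frame = c(220L, 220L), half_width_px = 14,
                   droplet_count = 30L, seed = 9L)
  sc <- render_scene(sp)
  ctr <- sc$truth$droplet_centers
  expect_identical(nrow(ctr), 30L)
  expect_length(sc$truth$droplet_radii, 30L)
  expect_true(all(sc$truth$body_mask[ctr]))
  dmat <- as.matrix(dist(ctr))
  rr <- sc$truth$droplet_radii
  off <- upper.tri(dmat)
  expect_true(all(dmat[off] >= (outer(rr, rr, `+`))[off]))  # interiors disjoint

  tiny <- scene_spec(frame = c(60L, 60L), half_width_px = 4,
                     droplet_count = 500L, seed = 9L)
  expect_error(render_scene(tiny), "place")
})

test_that("droplet density targeting hits the requested level on average", {
  got <- vapply(1:12, function(s) {
    sp <- scene_spec(background_sd = 0, droplet_density_target = 70,
                     droplet_radius_range = c(1.5, 2), droplet_min_sep = 0,
                     droplet_interior_gain = 100, seed = s)
    render_scene(sp)$truth$noiseless_density
  }, numeric(1))
  expect_lt(abs(mean(got) - 70) / 70, 0.04)
})

test_that("phantom frames calibrate to their mean level", {
  ph <- render_phantom(100, session_id = "s1", seed = 5L)
  expect_gte(ph$record$mean_intensity, 99)
  expect_lte(ph$record$mean_intensity, 101)

  exact <- render_phantom(250, noise_sd = 0, seed = 5L)
  expect_identical(exact$record$mean_intensity, 250)

  ph2 <- render_phantom(150, session_id = "s2", seed = 6L)
  cf <- correction_factor(ph$record$mean_intensity, ph2$record$mean_intensity)
  expect_lt(abs(cf$factor - 100 / 150) / (100 / 150), 0.01)
})

test_that("validation studies span disjoint worm sets and expected noise", {
  st <- generate_validation_study(seed = 100L)
  expect_identical(nrow(st$truth), 23L)
  expect_identical(nrow(st$scatter), 23L * 15L)
  expect_length(intersect(st$scatter$worm_id, st$oro$worm_id), 0L)
  expect_identical(generate_validation_study(seed = 100L)$scatter, st$scatter)

  noiseless <- generate_validation_study(n_conditions = 8L,
                                         worms_per_condition = 5L,
                                         noise_cv = 0, seed = 2L)
  fit <- fit_validation_study(noiseless$scatter, noiseless$oro)
  expect_gt(fit$r2, 1 - 1e-12)

  # swapping the two gains leaves r2 unchanged (scale invariance)
  a <- generate_validation_study(scatter_gain = 1, oro_gain = 3, seed = 7L)
  b <- generate_validation_study(scatter_gain = 3, oro_gain = 1, seed = 7L)
  expect_equal(fit_validation_study(a$scatter, a$oro)$r2,
               fit_validation_study(b$scatter, b$oro)$r2, tolerance = 1e-12)

  expect_error(generate_validation_study(noise_cv = -0.1, seed = 1L), ">= 0")
})

test_that("fasting cohorts lose density when loss dominates noise", {
  fc <- generate_fasting_cohort(seed = 3L)
  pc <- paired_change(fc$before, fc$after)
  expect_equal(pc$fraction_decreased, 1)
  expect_identical(pc$n, 55L)

  null <- generate_fasting_cohort(loss_range = c(0, 0), seed = 4L)
  pcn <- paired_change(null$before, null$after)
  expect_gt(pcn$fraction_decreased, 0.25)
  expect_lt(pcn$fraction_decreased, 0.75)
})
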