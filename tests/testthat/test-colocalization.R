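make_body_scene <- function(seed, puncta = 0L, coincident = TRUE) {
  sp <- scene_spec(puncta_count = puncta, puncta_radius = 1.5,
                   puncta_intensity = 120, shot_noise_gain = 0.3,
                   read_noise_sd = 2, seed = seed)
  sc <- render_scene(sp)
  list(scene = sc, spec = sp, mask = mask_of(sc$truth$body_mask))
}

test_that("mask-aware high-pass removes flat content and matches convolution", {
  m <- matrix(FALSE, 16, 16); m[4:13, 3:14] <- TRUE
  flat <- img_of(matrix(37, 16, 16), ingest = FALSE)
  expect_true(all(abs(highpass(flat, mask_of(m), 2)) < 1e-9))

  # impulse: maximal positive response at the bright pixel, negative ring
  px <- matrix(10, 16, 16); px[8, 8] <- 200
  hp <- highpass(img_of(px, ingest = FALSE), mask_of(m), 1.5)
  expect_identical(which.max(hp), which(seq_len(256) == (8 - 1) * 16 + 8))
  expect_lt(hp[8, 9], 0)
  expect_lt(hp[9, 8], 0)

  # brute-force mask-renormalized Gaussian convolution oracle
  withr::with_seed(31, rpx <- matrix(sample(0:255, 256, TRUE), 16, 16))
  sig <- 1.5; half <- ceiling(3 * sig)
  K <- outer(exp(-(-half:half)^2 / (2 * sig^2)),
             exp(-(-half:half)^2 / (2 * sig^2)))
  K <- K / sum(K)
  out <- matrix(0, 16, 16)
  for (r in 1:16) for (c in 1:16) {
    if (!m[r, c]) next
    num <- 0; den <- 0
    for (dr in -half:half) for (dc in -half:half) {
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= 16 && cc >= 1 && cc <= 16 && m[rr, cc]) {
        w <- K[dr + half + 1, dc + half + 1]
        num <- num + w * rpx[rr, cc]; den <- den + w
      }
    }
    out[r, c] <- rpx[r, c] - num / den
  }
  got <- highpass(img_of(rpx, 8L), mask_of(m), sig)
  expect_lt(max(abs(got - out)), 1e-9)
  # flat content is fully removed, so the in-mask response is near-centred
  expect_lt(abs(sum(got)) / sum(rpx[m]), 0.05)

  expect_error(highpass(img_of(rpx, 8L), mask_of(m), 10), "kernel")
  expect_error(highpass(img_of(rpx, 8L), mask_of(m), 0), "> 0")
})

test_that("percentile selection keeps strictly-above in-mask pixels", {
  m <- matrix(FALSE, 10, 12); m[1:10, 1:10] <- TRUE
  vals <- matrix(0, 10, 12)
  withr::with_seed(8, vals[m] <- sample(seq(1, 100)))   # distinct
  sel <- top_percentile_mask(vals, mask_of(m), 80)
  expect_identical(sum(sel), 20L)
  expect_identical(sort(vals[sel]), as.numeric(81:100))  # sort-based oracle

  ties <- matrix(5, 10, 12)
  expect_identical(sum(top_percentile_mask(ties, mask_of(m), 80)), 0L)

  m2 <- matrix(TRUE, 2, 5)
  v2 <- matrix(as.numeric(1:10), 2, 5)
  sel2 <- top_percentile_mask(v2, mask_of(m2), 50)
  expect_identical(sort(v2[sel2]), as.numeric(6:10))   # threshold 5.5

  expect_error(top_percentile_mask(v2, mask_of(m2), 100), "pct")
  expect_error(top_percentile_mask(v2, mask_of(matrix(FALSE, 2, 5)), 50),
               "empty")
})

test_that("Dice matches the set formula on every realizable overlap triple", {
  # qs depends only on (|A|, |B|, |A n B|); enumerate every triple that
  # occurs among subsets of a 4x4 grid with sizes <= 6 and verify dice()
  # on explicit masks realizing it
  for (na in 0:6) for (nb in 0:6) for (nov in 0:min(na, nb)) {
    if (na + nb - nov > 16) next
    a <- matrix(FALSE, 4, 4); b <- matrix(FALSE, 4, 4)
    a[seq_len(na)] <- TRUE
    if (nov > 0) b[seq_len(nov)] <- TRUE
    if (nb > nov) b[na + seq_len(nb - nov)] <- TRUE
    stopifnot(sum(a) == na, sum(b) == nb, sum(a & b) == nov)
    expected <- if (na + nb == 0) 1 else 2 * nov / (na + nb)
    expect_identical(dice(a, b)$qs, expected)
    expect_identical(dice(b, a)$qs, expected)   # symmetry
  }
  a <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  expect_identical(dice(a, a)$qs, 1)
  expect_identical(dice(a, !a)$qs, 0)
  expect_error(dice(a, matrix(TRUE, 3, 3)), "dimensions")
})

test_that("identical channels give perfect overlap", {
  s <- make_body_scene(41, puncta = 30L)
  res <- coloc_pipeline(s$scene$image, s$scene$image, s$mask)
  expect_equal(res$qs, 1)
  expect_identical(res$n_selected_a, res$n_selected_b)
  expect_equal(res$percentile, 80)
})

test_that("overlap is invariant to monotone intensity transforms", {
  s <- make_body_scene(42, puncta = 25L)
  fl <- render_fluorescence(s$scene, s$spec, coincident = TRUE, seed = 99L)
  base <- coloc_pipeline(s$scene$image, fl, s$mask)
  # strictly monotone transform of the dark-field channel after filtering:
  # selection is rank-based, so QS of the filtered selections is unchanged
  f1 <- highpass(s$scene$image, s$mask, 2)
  f2 <- highpass(fl, s$mask, 2)
  qs_monotone <- dice(top_percentile_mask(2 * f1 + 7, s$mask, 80),
                      top_percentile_mask(f2, s$mask, 80))$qs
  expect_equal(qs_monotone, base$qs)
})

test_that("co-placed puncta colocalize; independent puncta approach the null", {
  qs_co <- vapply(1:5, function(seed) {
    s <- make_body_scene(seed, puncta = 60L)
    fl <- render_fluorescence(s$scene, s$spec, coincident = TRUE,
                              seed = seed + 500L)
    coloc_pipeline(s$scene$image, fl, s$mask)$qs
  }, numeric(1))
  expect_true(all(qs_co >= 0.7))

  qs_null <- vapply(1:25, function(seed) {
    s <- make_body_scene(seed + 100L, puncta = 60L)
    fl <- render_fluorescence(s$scene, s$spec, coincident = FALSE,
                              seed = seed + 600L)
    coloc_pipeline(s$scene$image, fl, s$mask)$qs
  }, numeric(1))
  expect_lt(abs(mean(qs_null) - 0.2), 0.05)
  expect_true(all(qs_null < qs_co[1]))
})
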