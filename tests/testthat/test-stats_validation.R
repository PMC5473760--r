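test_that("cohort summaries match the textbook formulas", {
  s <- cohort_summary(c(4, 4, 4, 4), "flat")
  expect_equal(s$mean, 4); expect_equal(s$sem, 0)
  expect_equal(s$ci95, c(4, 4))

  s2 <- cohort_summary(c(1, 3))   # SD = sqrt(2), sem = 1
  expect_equal(s2$mean, 2); expect_equal(s2$sem, 1)

  withr::with_seed(4, v <- runif(50, 10, 60))
  s3 <- cohort_summary(v)
  n <- 50; m <- sum(v) / n
  sdv <- sqrt(sum((v - m)^2) / (n - 1)); sem <- sdv / sqrt(n)
  expect_equal(s3$mean, m); expect_equal(s3$sem, sem)
  expect_equal(s3$ci95, m + c(-1, 1) * qt(0.975, n - 1) * sem)

  expect_error(cohort_summary(5), "n < 2")
})

test_that("two-group ANOVA reduces to the pooled t-test (F = t^2)", {
  withr::with_seed(17, {
    g <- list(N2 = rnorm(12, 10, 2), mut = rnorm(9, 12, 3))
  })
  res <- anova_bonferroni(g, "N2")
  tt <- t.test(g$N2, g$mut, var.equal = TRUE)
  expect_lt(abs(attr(res, "anova_F") - tt$statistic^2), 1e-9)
  expect_lt(abs(attr(res, "anova_p") - tt$p.value), 1e-9)
})

test_that("Bonferroni adjustment is conservative, capped, and calibrated", {
  g0 <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  res0 <- anova_bonferroni(g0, "a")
  expect_equal(res0$p_adjusted, 1)
  expect_false(res0$significant)

  withr::with_seed(6, {
    g1 <- list(ref = rnorm(5, 0, 0.01), hi = rnorm(5, 10, 0.01),
               mid = rnorm(5, 5, 0.01))
  })
  res1 <- anova_bonferroni(g1, "ref")
  expect_true(all(res1$significant))
  expect_true(all(res1$p_adjusted >= res1$p_raw))
  expect_true(all(res1$p_adjusted <= 1))

  # all observations identical: degenerate no-effect path
  gd <- list(a = c(2, 2), b = c(2, 2))
  resd <- anova_bonferroni(gd, "a")
  expect_equal(attr(resd, "anova_F"), 0)
  expect_equal(attr(resd, "anova_p"), 1)
  expect_equal(resd$p_adjusted, 1)

  expect_error(anova_bonferroni(list(a = 1:3), "a"), "2 groups")
  expect_error(anova_bonferroni(g0, "zz"), "reference")
})

test_that("validation fit recovers exact linear cohort relationships", {
  x <- c(1, 2, 3, 4, 5)
  sc <- lapply(seq_along(x), function(i)
    cohort_summary(c(x[i] - 0.1, x[i] + 0.1), sprintf("c%d", i)))
  oro <- lapply(seq_along(x), function(i)
    cohort_summary(c(2 * x[i] + 1 - 0.1, 2 * x[i] + 1 + 0.1),
                   sprintf("c%d", i)))
  fit <- validation_fit(sc, oro)
  expect_equal(fit$slope, 2); expect_equal(fit$intercept, 1)
  expect_equal(fit$r2, 1)
  expect_lt(fit$p_slope, 1e-4)
  expect_equal(nrow(fit$points), 5L)

  # r2 is invariant to affine rescaling of either axis
  oro_scaled <- lapply(oro, function(s) {
    s$mean <- 100 * s$mean - 40; s
  })
  expect_equal(validation_fit(sc, oro_scaled)$r2, fit$r2)

  flat <- lapply(seq_along(x), function(i)
    cohort_summary(c(6.9, 7.1), sprintf("c%d", i)))
  fit0 <- validation_fit(sc, flat)
  expect_equal(fit0$slope, 0); expect_equal(fit0$r2, 0)

  expect_error(validation_fit(sc[1:2], oro[1:2]), "3 cohorts")
})

test_that("paired changes count strict decreases only", {
  pc <- paired_change(data.frame(worm_id = "w1", density = 10),
                      data.frame(worm_id = "w1", density = 8))
  expect_equal(pc$table$delta, -2)
  expect_equal(pc$fraction_decreased, 1)

  same <- data.frame(worm_id = c("a", "b"), density = c(5, 7))
  expect_equal(paired_change(same, same)$fraction_decreased, 0)

  before <- data.frame(worm_id = c("a", "b", "c"), density = c(5, 7, 9))
  after <- data.frame(worm_id = c("a", "b", "d"), density = c(4, 8, 1))
  expect_warning(pc2 <- paired_change(before, after), "unmatched")
  expect_equal(pc2$n, 2L)
  expect_setequal(pc2$unmatched, c("c", "d"))
  expect_equal(pc2$fraction_decreased, 0.5)
})

test_that("activity correlation handles exact and degenerate cases", {
  d <- data.frame(worm_id = letters[1:5], delta = c(-1, -2, -3, -4, -5))
  act <- data.frame(worm_id = letters[1:5], activity = c(-1, -2, -3, -4, -5))
  expect_equal(activity_correlation(d, act)$r, 1)

  act2 <- data.frame(worm_id = letters[1:5], activity = c(1, 2, 3, 4, 5))
  r2 <- activity_correlation(d, act2)
  expect_equal(r2$r, -1)

  actz <- data.frame(worm_id = letters[1:5], activity = rep(3, 5))
  rz <- activity_correlation(d, actz)
  expect_false(rz$defined)
  expect_true(is.na(rz$r))

  expect_error(activity_correlation(d[1:2, ], act[1:2, ]), "3 matched")
})
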