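#' Cohort summary: mean, SEM, 95% CI
#'
#' Standard per-condition summary of per-worm densities. SEM is the sample
#' standard deviation over `sqrt(n)`; the 95% confidence interval is
#' symmetric about the mean using the t quantile with `n - 1` degrees of
#' freedom.
#'
#' @param values Numeric vector of per-worm densities, `n >= 2`.
#' @param condition Condition label.
#' @return A `cohort_summary` list: `condition`, `n`, `mean`, `sem`,
#'   `ci95` (length-2 `c(lo, hi)`).
#' @export
cohort_summary <- function(values, condition = "cohort") {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stop("SEM undefined for n < 2", call. = FALSE)
  m <- mean(values)
  sem <- stats::sd(values) / sqrt(n)
  half <- stats::qt(0.975, df = n - 1L) * sem
  structure(list(condition = condition, n = n, mean = m, sem = sem,
                 ci95 = c(m - half, m + half)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %s: n=%d, mean=%.4g, sem=%.4g, 95%% CI [%.4g, %.4g]\n",
              x$condition, x$n, x$mean, x$sem, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' One-way ANOVA with Bonferroni pairwise tests against a reference
#'
#' The cohort comparison used for dark-field measurements: a one-way ANOVA
#' F test across all groups, followed by pairwise two-sample t tests of
#' each condition against the reference condition (by default unpooled
#' Welch tests, robust to the unequal strain variances typical of these
#' cohorts), Bonferroni-corrected by the number of pairwise tests
#' performed and capped at 1.
#'
#' @param groups Named list of numeric vectors (condition -> per-worm
#'   densities), each of length >= 2.
#' @param reference Name of the reference condition (e.g. `"N2"`).
#' @param alpha Significance level for the `significant` flag; default
#'   0.05.
#' @param all_pairs If `TRUE`, test every pair of conditions instead of
#'   reference-vs-each (the Bonferroni multiplier grows accordingly).
#' @param pool_variance If `TRUE` use pooled-variance t tests.
#' @return Data frame with columns `condition` (or `condition_a`/`_b` in
#'   all-pairs mode), `p_raw`, `p_adjusted`, `significant`; the ANOVA F
#'   statistic and p-value are attached as attributes `anova_F` and
#'   `anova_p`.
#' @export
anova_bonferroni <- function(groups, reference, alpha = 0.05,
                             all_pairs = FALSE, pool_variance = FALSE) {
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(lengths(groups) < 2L)) stop("each group needs n >= 2", call. = FALSE)
  if (!all_pairs && !reference %in% names(groups))
    stop(sprintf("reference condition '%s' not among groups", reference),
         call. = FALSE)
  vals <- unlist(groups, use.names = FALSE)
  cond <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (stats::var(vals) == 0) {
    f_stat <- 0; f_p <- 1      # all observations identical: no effect
  } else {
    fit <- stats::aov(vals ~ cond)
    s <- summary(fit)[[1]]
    f_stat <- s[["F value"]][1]; f_p <- s[["Pr(>F)"]][1]
  }
  pairs <- if (all_pairs) {
    utils::combn(names(groups), 2, simplify = FALSE)
  } else {
    lapply(setdiff(names(groups), reference), function(x) c(reference, x))
  }
  n_tests <- length(pairs)
  safe_t <- function(x, y) {
    if (stats::var(x) == 0 && stats::var(y) == 0)
      return(if (mean(x) == mean(y)) 1 else 0)
    stats::t.test(x, y, var.equal = pool_variance)$p.value
  }
  p_raw <- vapply(pairs, function(pr) safe_t(groups[[pr[1]]], groups[[pr[2]]]),
                  numeric(1))
  p_adj <- pmin(1, p_raw * n_tests)
  out <- if (all_pairs) {
    data.frame(condition_a = vapply(pairs, `[`, "", 1),
               condition_b = vapply(pairs, `[`, "", 2),
               p_raw = p_raw, p_adjusted = p_adj,
               significant = p_adj < alpha, stringsAsFactors = FALSE)
  } else {
    data.frame(condition = vapply(pairs, `[`, "", 2),
               p_raw = p_raw, p_adjusted = p_adj,
               significant = p_adj < alpha, stringsAsFactors = FALSE)
  }
  attr(out, "anova_F") <- f_stat
  attr(out, "anova_p") <- f_p
  out
}

#' Cohort-mean validation fit of ORO density on scattering density
#'
#' Ordinary least squares of mean ORO staining density (y) on mean
#' dark-field scattering density (x), one point per cohort. The fit is on
#' cohort means rather than individual worms because the two measurements
#' come from disjoint sets of worms drawn from the same cohort (ORO
#' staining requires fixation). SEMs of both axes are carried along for
#' plotting (SEM ellipses) but the fit is unweighted.
#'
#' @param scatter,oro Lists of [cohort_summary()] objects, matched by
#'   position (same cohort order), length >= 3.
#' @return A `validation_fit` list: `slope`, `intercept`, `r2`, `p_slope`,
#'   and a `points` data frame (`condition`, `x_mean`, `x_sem`, `y_mean`,
#'   `y_sem`).
#' @export
validation_fit <- function(scatter, oro) {
  if (length(scatter) != length(oro))
    stop("scatter and oro cohort lists differ in length", call. = FALSE)
  if (length(scatter) < 3L)
    stop("need at least 3 cohorts for the fit", call. = FALSE)
  pts <- data.frame(
    condition = vapply(scatter, function(s) s$condition, ""),
    x_mean = vapply(scatter, function(s) s$mean, numeric(1)),
    x_sem = vapply(scatter, function(s) s$sem, numeric(1)),
    y_mean = vapply(oro, function(s) s$mean, numeric(1)),
    y_sem = vapply(oro, function(s) s$sem, numeric(1)),
    stringsAsFactors = FALSE)
  if (stats::var(pts$x_mean) == 0)
    stop("cohort scattering means are constant; slope undefined", call. = FALSE)
  fit <- stats::lm(y_mean ~ x_mean, data = pts)
  sm <- suppressWarnings(summary(fit))   # exact collinearity is legitimate
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r2 = if (stats::var(pts$y_mean) == 0) 0 else sm$r.squared,
    p_slope = if (stats::var(pts$y_mean) == 0) 1 else sm$coefficients[2, 4],
    points = pts), class = "validation_fit")
}

#' @export
print.validation_fit <- function(x, ...) {
  cat(sprintf(
    "<validation_fit> %d cohorts: y = %.4g x + %.4g, r2 = %.3f, p(slope=0) = %.3g\n",
    nrow(x$points), x$slope, x$intercept, x$r2, x$p_slope))
  invisible(x)
}

#' Per-worm change between paired measurements
#'
#' Dark-field imaging is non-destructive, so the same worm can be measured
#' before and after an intervention (e.g. 18 hr of fasting). Computes the
#' per-worm change `after - before` and summarizes how many worms
#' decreased; a delta of exactly 0 is not a decrease.
#'
#' @param before,after Data frames with columns `worm_id`, `density`.
#' @return A list: `table` (data frame `worm_id`, `before`, `after`,
#'   `delta`, `decreased`), `n`, `n_decreased`, `fraction_decreased`,
#'   `unmatched` (ids present in only one of the two sets).
#' @export
paired_change <- function(before, after) {
  stopifnot(all(c("worm_id", "density") %in% names(before)),
            all(c("worm_id", "density") %in% names(after)))
  ids <- intersect(before$worm_id, after$worm_id)
  unmatched <- union(setdiff(before$worm_id, after$worm_id),
                     setdiff(after$worm_id, before$worm_id))
  if (length(unmatched))
    warning(sprintf("%d worm id(s) unmatched and excluded: %s",
                    length(unmatched),
                    paste(utils::head(unmatched, 5), collapse = ", ")),
            call. = FALSE)
  if (!length(ids)) stop("no matching worm ids", call. = FALSE)
  b <- before$density[match(ids, before$worm_id)]
  a <- after$density[match(ids, after$worm_id)]
  tab <- data.frame(worm_id = ids, before = b, after = a, delta = a - b,
                    decreased = (a - b) < 0, stringsAsFactors = FALSE)
  list(table = tab, n = nrow(tab), n_decreased = sum(tab$decreased),
       fraction_decreased = mean(tab$decreased), unmatched = unmatched)
}

#' Correlation between fat loss and activity
#'
#' Pearson correlation (with two-sided p-value) between per-worm density
#' change and an activity score, matched by worm id. Used to ask whether
#' worms that moved more lost more fat.
#'
#' @param deltas Data frame with `worm_id`, `delta`.
#' @param activity Data frame with `worm_id`, `activity`.
#' @return List: `r`, `p`, `n`, `defined` (`FALSE` when either variable
#'   has zero variance, in which case `r` and `p` are `NA`).
#' @export
activity_correlation <- function(deltas, activity) {
  ids <- intersect(deltas$worm_id, activity$worm_id)
  if (length(ids) < 3L) stop("need >= 3 matched pairs", call. = FALSE)
  d <- deltas$delta[match(ids, deltas$worm_id)]
  a <- activity$activity[match(ids, activity$worm_id)]
  if (stats::var(d) == 0 || stats::var(a) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(ids), defined = FALSE))
  ct <- stats::cor.test(d, a, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(ids),
       defined = TRUE)
}
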