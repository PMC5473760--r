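#' Normalize a density time series to its baseline timepoint
#'
#' Divides every per-worm density by the mean density at the baseline
#' timepoint `t0`, so the cohort mean at `t0` becomes exactly 1.
#' Developmental trajectories are reported this way (e.g. normalized to
#' the density at 4 hr post-refeeding) because absolute densities are only
#' comparable within one calibration reference.
#'
#' A series is a long data frame with columns `timepoint_hr`, `density`
#' and optionally `objective` and `worm_id`; each row is one worm at one
#' timepoint (different worms are culled at each time, so there is no
#' per-worm tracking).
#'
#' @param series Series data frame.
#' @param t0 Baseline timepoint (must be present in the series).
#' @return The series with densities rescaled.
#' @export
normalize_to_baseline <- function(series, t0) {
  stopifnot(all(c("timepoint_hr", "density") %in% names(series)))
  at0 <- abs(series$timepoint_hr - t0) < 1e-9
  if (!any(at0))
    stop(sprintf("no measurements at baseline t0 = %g hr", t0), call. = FALSE)
  series$density <- series$density / mean(series$density[at0])
  series
}

#' Stitch series acquired through two objectives
#'
#' Small larvae are imaged at high magnification and older ones at lower
#' magnification; one shared timepoint, imaged through both objectives,
#' provides the basis for combining the two series. The second series is
#' rescaled by `k = mean_a(shared_t) / mean_b(shared_t)` so the cohort
#' means at the shared timepoint agree by construction; both rescaled
#' cohorts at the shared timepoint are retained. `series_a` is the
#' reference scale (conventionally the high-magnification series covering
#' the early timepoints).
#'
#' @param series_a Reference series data frame.
#' @param series_b Series to rescale onto the reference.
#' @param shared_t Timepoint present in both series with >= 2 worms each.
#' @return The merged series, sorted by `timepoint_hr`, with a
#'   `stitch_factor` attribute.
#' @export
stitch_objectives <- function(series_a, series_b, shared_t) {
  for (s in list(series_a, series_b))
    stopifnot(all(c("timepoint_hr", "density") %in% names(s)))
  ia <- abs(series_a$timepoint_hr - shared_t) < 1e-9
  ib <- abs(series_b$timepoint_hr - shared_t) < 1e-9
  if (sum(ia) < 2L || sum(ib) < 2L)
    stop(sprintf("shared timepoint %g hr needs >= 2 worms in both series",
                 shared_t), call. = FALSE)
  k <- mean(series_a$density[ia]) / mean(series_b$density[ib])
  series_b$density <- series_b$density * k
  common <- intersect(names(series_a), names(series_b))
  merged <- rbind(series_a[common], series_b[common])
  merged <- merged[order(merged$timepoint_hr), , drop = FALSE]
  rownames(merged) <- NULL
  attr(merged, "stitch_factor") <- k
  merged
}

#' Per-timepoint summary of a series
#'
#' @param series Series data frame.
#' @return Data frame `timepoint_hr`, `n`, `mean`, `sem`, sorted by time.
#' @export
series_summary <- function(series) {
  ts <- sort(unique(series$timepoint_hr))
  do.call(rbind, lapply(ts, function(t) {
    v <- series$density[abs(series$timepoint_hr - t) < 1e-9]
    data.frame(timepoint_hr = t, n = length(v), mean = mean(v),
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_)
  }))
}

#' Larval-transition times from worm length
#'
#' Larval stage transitions are estimated from mean body length: the
#' transition time for each length cutoff is where the mean-length curve
#' first crosses that cutoff upward, located by linear interpolation
#' between the bracketing timepoints. The curve is 3-point median-smoothed
#' first to tolerate cohort noise. Cutoffs are user-supplied -- there are
#' no authoritative stage/length values; any defaults used upstream are
#' placeholders.
#'
#' @param lengths Data frame with `timepoint_hr` and `mean_length_um`.
#' @param cutoffs Named numeric vector of increasing length cutoffs (um),
#'   e.g. `c("L1-L2" = 360, "L2-L3" = 500)`.
#' @return Data frame `transition`, `cutoff_um`, `time_hr`, `status`
#'   (`"crossed"`, `"before_series"` when the series starts above the
#'   cutoff, `"absent"` when it never crosses).
#' @export
annotate_transitions <- function(lengths, cutoffs) {
  stopifnot(all(c("timepoint_hr", "mean_length_um") %in% names(lengths)))
  if (is.unsorted(cutoffs)) stop("cutoffs must be ordered", call. = FALSE)
  o <- order(lengths$timepoint_hr)
  t <- lengths$timepoint_hr[o]
  y <- lengths$mean_length_um[o]
  sm <- if (length(y) >= 3L) stats::runmed(y, 3L) else y
  nm <- if (!is.null(names(cutoffs))) names(cutoffs)
        else paste0("cutoff_", seq_along(cutoffs))
  do.call(rbind, lapply(seq_along(cutoffs), function(i) {
    cu <- cutoffs[i]
    row <- data.frame(transition = nm[i], cutoff_um = unname(cu),
                      time_hr = NA_real_, status = "absent",
                      stringsAsFactors = FALSE)
    if (sm[1] >= cu) {
      row$time_hr <- t[1]; row$status <- "before_series"
      return(row)
    }
    up <- which(sm[-length(sm)] < cu & sm[-1] >= cu)
    if (length(up)) {
      j <- up[1]
      row$time_hr <- t[j] + (cu - sm[j]) / (sm[j + 1] - sm[j]) * (t[j + 1] - t[j])
      row$status <- "crossed"
    }
    row
  }))
}
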