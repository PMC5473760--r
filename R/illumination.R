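#' Phantom calibration record
#'
#' A scattering phantom (a stable target such as BaSO4 in PDMS) is imaged at
#' the start of each session; the mean intensity in an annulus around a
#' surface scratch tracks the illumination level. The annulus excludes the
#' scratch itself (it is a registration landmark, not representative
#' scatter): a pixel belongs to the ROI when the Euclidean distance from its
#' center to `mark_center` lies in `[roi_inner_px, roi_outer_px]`, both ends
#' inclusive.
#'
#' @param frame A [worm_image()] of the phantom.
#' @param mark_center Numeric `(row, col)` of the scratch, 0-based.
#' @param roi_inner_px,roi_outer_px Annulus radii in pixels,
#'   `0 < inner < outer`. Defaults 5 and 25.
#' @param session_id Session the phantom calibrates.
#'
#' @return A `phantom_record` with computed `mean_intensity`.
#' @export
phantom_record <- function(frame, mark_center, roi_inner_px = 5,
                           roi_outer_px = 25, session_id = NULL) {
  stopifnot(is_worm_image(frame))
  if (!(roi_inner_px > 0 && roi_inner_px < roi_outer_px))
    stop("require 0 < roi_inner_px < roi_outer_px", call. = FALSE)
  rec <- structure(
    list(frame = frame, mark_center = as.numeric(mark_center),
         roi_inner_px = roi_inner_px, roi_outer_px = roi_outer_px,
         session_id = session_id, mean_intensity = NA_real_),
    class = "phantom_record")
  rec$mean_intensity <- phantom_mean(rec)
  rec
}

#' Mean phantom intensity around the mark
#'
#' Arithmetic mean of frame pixels whose centers fall inside the annulus of
#' the record. This is the per-session illumination readout that both the
#' lighting check and the correction factor are built on.
#'
#' @param record A [phantom_record()].
#' @return Mean intensity in arbitrary units.
#' @export
phantom_mean <- function(record) {
  stopifnot(inherits(record, "phantom_record"))
  px <- record$frame$pixels
  nr <- nrow(px); nc <- ncol(px)
  # 0-based pixel-center coordinates
  dr <- (seq_len(nr) - 1) - record$mark_center[1]
  dc <- (seq_len(nc) - 1) - record$mark_center[2]
  d2 <- outer(dr^2, dc^2, `+`)
  sel <- d2 >= record$roi_inner_px^2 & d2 <= record$roi_outer_px^2
  if (!any(sel))
    stop("annulus contains no pixels inside the frame", call. = FALSE)
  mean(px[sel])
}

#' Session lighting check against the fixed target
#'
#' Lighting is adjusted at the bench so that the phantom mean stays within a
#' fractional tolerance (default 10%) of a fixed target value; this check
#' reproduces that criterion in software. The boundary is inclusive, and a
#' failure is advisory -- residual differences are removed by
#' [apply_correction()] anyway.
#'
#' @param session_mean Phantom mean of the session (a.u.).
#' @param fixed_target The fixed target value (a.u.), > 0.
#' @param tol_frac Fractional tolerance, default 0.10.
#'
#' @return List with `pass` (logical) and `deviation` (signed relative
#'   deviation `(session - target) / target`).
#' @export
check_lighting <- function(session_mean, fixed_target, tol_frac = 0.10) {
  if (!is.numeric(fixed_target) || fixed_target <= 0)
    stop("`fixed_target` must be > 0", call. = FALSE)
  if (!is.numeric(tol_frac) || tol_frac <= 0)
    stop("`tol_frac` must be > 0", call. = FALSE)
  deviation <- (session_mean - fixed_target) / fixed_target
  list(pass = abs(deviation) <= tol_frac, deviation = deviation)
}

#' Multiplicative correction factor from phantom means
#'
#' The factor that puts a session onto the common reference scale:
#' `reference_mean / session_mean`. Scaling every pixel of a session's
#' frames by this ratio makes densities comparable across sessions, because
#' the phantom's scatter is constant and any change in its mean reflects
#' lighting alone.
#'
#' @param reference_mean Phantom mean of the common reference session.
#' @param session_mean Phantom mean of the session being corrected.
#' @param session_id,reference_id Optional identifiers recorded for audit.
#'
#' @return A `correction_factor` object with field `factor`.
#' @export
correction_factor <- function(reference_mean, session_mean,
                              session_id = NULL, reference_id = NULL) {
  if (!is.numeric(reference_mean) || reference_mean <= 0 ||
      !is.numeric(session_mean) || session_mean <= 0)
    stop("phantom means must be > 0", call. = FALSE)
  structure(list(factor = reference_mean / session_mean,
                 session_id = session_id, reference_id = reference_id),
            class = "correction_factor")
}

#' Apply a lighting correction to an experimental frame
#'
#' Multiplies every pixel by the correction factor. No clipping is
#' performed, so corrected values may exceed the native scale. The applied
#' factor is recorded in the image metadata, and a second application is a
#' guarded error rather than a silent no-op: accidental double correction
#' would silently bias every density downstream.
#'
#' @param image A [worm_image()] from the factor's session.
#' @param cf A [correction_factor()].
#' @return The corrected [worm_image()].
#' @export
apply_correction <- function(image, cf) {
  stopifnot(is_worm_image(image), inherits(cf, "correction_factor"))
  if (isTRUE(image$meta$corrected))
    stop("image already carries a lighting correction; refusing to correct twice",
         call. = FALSE)
  if (!is.null(cf$session_id) && !is.null(image$meta$session_id) &&
      !identical(cf$session_id, image$meta$session_id))
    stop(sprintf("correction factor is for session '%s' but image is from '%s'",
                 cf$session_id, image$meta$session_id), call. = FALSE)
  image$pixels <- image$pixels * cf$factor
  image$meta$corrected <- TRUE
  image$meta$correction_factor <- cf$factor
  if (!is.null(cf$reference_id)) image$meta$correction_reference <- cf$reference_id
  image
}
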