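#' Scattering density of a worm
#'
#' The core fat-proxy metric: the grayscale intensities of all pixels
#' inside the worm mask are summed and divided by the mask area in pixels,
#' giving an intensity per pixel (a.u./px). Under dark-field illumination
#' this tracks how strongly the body scatters light, which correlates with
#' lipid content. No background subtraction is applied by default -- the
#' method sums raw, lighting-corrected intensities.
#'
#' @param image A [worm_image()], normally lighting-corrected.
#' @param mask A [worm_mask()] congruent with the image.
#' @param background Constant background level subtracted from each in-mask
#'   pixel before summation; default 0 (off).
#' @return One-row data frame with columns `worm_id`, `condition`,
#'   `timepoint_hr`, `density`, `area_px`, `modality`, `corrected`.
#' @export
scattering_density <- function(image, mask, background = 0) {
  stopifnot(is_worm_image(image), inherits(mask, "worm_mask"))
  if (!identical(dim(image$pixels), dim(mask$mask)))
    stop("mask and image dimensions differ", call. = FALSE)
  if (mask$area_px < 1L) stop("mask has zero area", call. = FALSE)
  total <- sum(image$pixels[mask$mask] - background)
  data.frame(
    worm_id = mask$label,
    condition = if (!is.null(image$meta$condition)) image$meta$condition else NA_character_,
    timepoint_hr = if (!is.null(image$meta$timepoint_hr))
      as.numeric(image$meta$timepoint_hr) else NA_real_,
    density = total / mask$area_px,
    area_px = mask$area_px,
    modality = image$modality,
    corrected = isTRUE(image$meta$corrected),
    stringsAsFactors = FALSE)
}

#' Invert a 510 nm bright-field frame to pseudodark field
#'
#' Oil Red O absorbs strongly near 510 nm, so heavily stained regions are
#' dark in the bright-field frame. Inverting each pixel on the native scale
#' (`p -> 2^bit_depth - 1 - p`) makes stained regions bright, so the same
#' sum/area densitometry applies: weakly or intensely stained animals
#' produce low or high staining densities respectively.
#'
#' Inversion must happen on the native integer scale, before any
#' multiplicative lighting correction (the two operations do not commute);
#' the pipeline order is invert, then correct, then measure, and is
#' enforced through the modality and corrected flags.
#'
#' @param image A [worm_image()] with modality `"brightfield510"`.
#' @return A [worm_image()] with modality `"oro_pseudo"`.
#' @export
invert_to_pseudodarkfield <- function(image) {
  stopifnot(is_worm_image(image))
  if (image$modality != "brightfield510")
    stop("inversion applies to 510 nm bright-field frames only", call. = FALSE)
  mx <- scale_max(image)
  if (isTRUE(image$meta$corrected) || any(image$pixels > mx))
    stop("pixels exceed the native scale; invert before applying the ",
         "lighting correction", call. = FALSE)
  image$pixels <- mx - image$pixels
  image$modality <- "oro_pseudo"
  image
}

#' ORO staining density
#'
#' Pseudoscattering density of the inverted 510 nm frame:
#' `scattering_density(invert_to_pseudodarkfield(image510), mask)`.
#'
#' @param image510 A [worm_image()] with modality `"brightfield510"`.
#' @param mask A [worm_mask()].
#' @inheritParams scattering_density
#' @return One-row measurement data frame with modality `"oro_pseudo"`.
#' @export
staining_density <- function(image510, mask, background = 0) {
  scattering_density(invert_to_pseudodarkfield(image510), mask,
                     background = background)
}
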