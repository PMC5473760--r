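#' Grayscale micrograph with acquisition metadata
#'
#' The raster container shared by every stage of the pipeline. Pixels are
#' carried as non-negative real numbers on the native integer scale of the
#' camera (no \[0,1\] normalization): all downstream quantities -- the
#' phantom correction factor and the scattering/staining densities -- are
#' ratios, so the absolute scale is irrelevant, and keeping native values
#' makes round-trips through TIFF bit-exact. After multiplicative lighting
#' correction, values may exceed `2^bit_depth - 1`; only ingest enforces the
#' upper bound.
#'
#' Coordinates are 0-based `(row, col)`, row-major, throughout the package;
#' pixel `(0, 0)` is the top-left pixel and coordinates refer to pixel
#' centers.
#'
#' @param pixels Numeric matrix of intensities (arbitrary units), all >= 0.
#' @param bit_depth Integer, 8 or 16: the source scale of the frame.
#' @param modality One of `"darkfield"`, `"brightfield510"`, `"fluor_red"`,
#'   or `"oro_pseudo"` (the last only arises from inversion).
#' @param pixel_size_um Physical edge length of one pixel in micrometers,
#'   or `NULL` when unknown.
#' @param meta Named list of free-form acquisition metadata (e.g.
#'   `condition`, `timepoint_hr`, `objective`, `session_id`).
#' @param ingest Logical; when `TRUE` (the default for freshly read frames)
#'   pixel values must not exceed `2^bit_depth - 1`.
#'
#' @return An object of class `worm_image`.
#' @export
worm_image <- function(pixels, bit_depth = 16L,
                       modality = c("darkfield", "brightfield510",
                                    "fluor_red", "oro_pseudo"),
                       pixel_size_um = NULL, meta = list(), ingest = TRUE) {
  modality <- match.arg(modality)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("raster must have at least one row and one column", call. = FALSE)
  if (anyNA(pixels) || any(pixels < 0))
    stop("pixel values must be finite and >= 0", call. = FALSE)
  if (!bit_depth %in% c(8L, 16L))
    stop("`bit_depth` must be 8 or 16", call. = FALSE)
  if (ingest && any(pixels > 2^bit_depth - 1))
    stop("pixel values exceed 2^bit_depth - 1 on ingest", call. = FALSE)
  if (!is.null(pixel_size_um) && (!is.numeric(pixel_size_um) || pixel_size_um <= 0))
    stop("`pixel_size_um` must be a positive number", call. = FALSE)
  structure(
    list(pixels = unname(pixels), bit_depth = as.integer(bit_depth),
         modality = modality, pixel_size_um = pixel_size_um, meta = meta),
    class = "worm_image")
}

#' @export
print.worm_image <- function(x, ...) {
  cat(sprintf("<worm_image> %d x %d, %d-bit, modality=%s\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth, x$modality))
  cat(sprintf("  intensity range [%.4g, %.4g]", min(x$pixels), max(x$pixels)))
  if (!is.null(x$pixel_size_um))
    cat(sprintf(", pixel %.4g um", x$pixel_size_um))
  cat("\n")
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.worm_image <- function(x) dim(x$pixels)

is_worm_image <- function(x) inherits(x, "worm_image")

# max representable value on the frame's native scale
scale_max <- function(image) 2^image$bit_depth - 1
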