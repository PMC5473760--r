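#' Read a grayscale micrograph from TIFF or PNG
#'
#' Reads a single-plane image and returns it on its native integer scale:
#' an 8-bit frame spans 0..255, a 16-bit frame 0..65535. No rescaling or
#' background subtraction is ever applied on ingest.
#'
#' RGB frames (e.g. from a color CMOS camera) are rejected for
#' quantification by default. Passing `rgb_channel = "green"` extracts the
#' green channel, which is the sensible projection for Oil Red O work: ORO
#' absorbs strongly around 510 nm, so its contrast lives in the green
#' channel.
#'
#' @param path Path to a TIFF file, or a PNG (8-bit only).
#' @param modality Modality tag recorded on the image; see [worm_image()].
#' @param pixel_size_um Optional pixel edge length in micrometers.
#' @param meta Named list of acquisition metadata.
#' @param rgb_channel `NA` (reject RGB input, the default) or `"green"`.
#'
#' @return A [worm_image()].
#' @export
read_image <- function(path, modality = "darkfield", pixel_size_um = NULL,
                       meta = list(), rgb_channel = NA) {
  if (!file.exists(path))
    stop(sprintf("cannot read image: no such file '%s'", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    raw <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    bps <- attr(raw, "bits.per.sample")
    bit_depth <- if (!is.null(bps) && bps >= 16) 16L else 8L
  } else if (ext == "png") {
    raw <- png::readPNG(path)
    raw <- raw * 255      # readPNG returns [0,1]; restore the 8-bit scale
    bit_depth <- 8L
  } else {
    stop(sprintf("unsupported image format '.%s' (TIFF or PNG)", ext),
         call. = FALSE)
  }
  d <- dim(raw)
  if (length(d) == 3L) {
    if (d[3] == 1L) {
      raw <- raw[, , 1L]
    } else if (is.na(rgb_channel)) {
      stop("RGB input rejected for quantification; pass rgb_channel = \"green\" ",
           "to extract the 510 nm-relevant channel explicitly", call. = FALSE)
    } else if (identical(rgb_channel, "green")) {
      raw <- raw[, , 2L]
    } else {
      stop("`rgb_channel` must be NA or \"green\"", call. = FALSE)
    }
  } else if (length(d) != 2L) {
    stop("image has more than 2 spatial dimensions", call. = FALSE)
  }
  pixels <- matrix(as.numeric(round(raw)), nrow(raw), ncol(raw))
  worm_image(pixels, bit_depth = bit_depth, modality = modality,
             pixel_size_um = pixel_size_um, meta = meta)
}

#' Write an image to TIFF (or 8-bit PNG)
#'
#' Integer-valued rasters on the native scale round-trip bit-exactly through
#' `write_image()` / [read_image()]. Corrected frames whose values exceed the
#' native scale cannot be written losslessly and are rejected.
#'
#' @param image A [worm_image()].
#' @param path Destination path; format chosen by extension.
#' @export
write_image <- function(image, path) {
  stopifnot(is_worm_image(image))
  mx <- scale_max(image)
  if (any(image$pixels > mx))
    stop("pixels exceed the native scale; corrected frames cannot be written ",
         "losslessly", call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(image$pixels / mx, path,
                    bits.per.sample = image$bit_depth, compression = "none")
  } else if (ext == "png") {
    if (image$bit_depth != 8L)
      stop("PNG output supports 8-bit frames only", call. = FALSE)
    png::writePNG(image$pixels / mx, path)
  } else {
    stop(sprintf("unsupported image format '.%s'", ext), call. = FALSE)
  }
  invisible(path)
}

#' Write per-worm measurements to CSV
#'
#' One row per worm with columns `worm_id`, `condition`, `timepoint_hr`,
#' `density`, `area_px`, `modality`. Missing timepoints are written as empty
#' fields (not the text "NA"/"NaN"), so the file re-reads to the same table.
#'
#' @param rows Data frame of measurements (see [scattering_density()]).
#' @param path Destination CSV path.
#' @export
write_results <- function(rows, path) {
  cols <- c("worm_id", "condition", "timepoint_hr", "density", "area_px",
            "modality")
  if (!is.data.frame(rows) || nrow(rows) == 0L)
    stop("`rows` must be a non-empty data frame", call. = FALSE)
  missing_cols <- setdiff(cols, names(rows))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  utils::write.csv(rows[cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a measurement CSV written by [write_results()]
#' @param path CSV path.
#' @return Data frame with the standard measurement columns.
#' @export
read_results <- function(path) {
  if (!file.exists(path))
    stop(sprintf("no such file '%s'", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        colClasses = c(worm_id = "character",
                                       condition = "character",
                                       modality = "character"))
  df$timepoint_hr <- as.numeric(df$timepoint_hr)
  df$area_px <- as.integer(df$area_px)
  df
}
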