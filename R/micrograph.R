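#' Calibrated micrograph region of interest
#'
#' A `micrograph` bundles an RGB pixel array with its spatial calibration and
#' study metadata (subject, cortical region, hemisphere, antero-posterior
#' level, between-subject group labels). Intensities are carried as real
#' numbers on a 0-255 scale regardless of the bit depth of the source file;
#' nothing in the analysis path clips them.
#'
#' @param pixels numeric H x W x 3 array; the third dimension must carry
#'   channel names among `"red"`, `"green"`, `"blue"` (any order). All values
#'   must be finite and within \[0, 255\].
#' @param pixel_size_um microns per pixel, a single positive number. The
#'   study convention is a 300 x 300 um^2 window sampled at 1320 x 1320 px,
#'   i.e. 300/1320 um/px, but any positive calibration is accepted.
#' @param subject_id opaque subject identifier.
#' @param region region label; one of `"VO"`, `"LO"`, `"A32d"`, `"A32v"`,
#'   `"MO"`, `"M2"`, `"insula"`, `"other"`.
#' @param hemisphere `"left"` or `"right"`.
#' @param ap_mm antero-posterior level in mm from Bregma.
#' @param group_labels named character vector mapping each between-subject
#'   factor to this subject's level (may be empty).
#'
#' @return An object of class `micrograph`.
#' @export
micrograph <- function(pixels, pixel_size_um,
                       subject_id = NA_character_, region = "other",
                       hemisphere = "left", ap_mm = NA_real_,
                       group_labels = character()) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array", call. = FALSE)
  ch <- dimnames(pixels)[[3]]
  if (is.null(ch) || !setequal(ch, c("red", "green", "blue")))
    stop("third dimension of `pixels` must be named red/green/blue", call. = FALSE)
  if (!all(is.finite(pixels)))
    stop("all pixel intensities must be finite", call. = FALSE)
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("pixel intensities must lie within [0, 255]", call. = FALSE)
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number", call. = FALSE)
  region <- match.arg(region, c("VO", "LO", "A32d", "A32v", "MO", "M2",
                                "insula", "other"))
  hemisphere <- match.arg(hemisphere, c("left", "right"))
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um,
         subject_id = as.character(subject_id), region = region,
         hemisphere = hemisphere, ap_mm = as.numeric(ap_mm),
         group_labels = group_labels),
    class = "micrograph")
}

#' @export
print.micrograph <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<micrograph> %d x %d px, %.4f um/px, subject %s, region %s (%s, AP %+.1f mm)\n",
              d[1], d[2], x$pixel_size_um, x$subject_id, x$region,
              x$hemisphere, x$ap_mm))
  invisible(x)
}

#' Extract a named channel as a matrix
#' @param img a [micrograph()].
#' @param name `"red"`, `"green"` or `"blue"`.
#' @return numeric H x W matrix.
#' @export
channel <- function(img, name) {
  stopifnot(inherits(img, "micrograph"))
  name <- match.arg(name, c("red", "green", "blue"))
  d <- dim(img$pixels)
  matrix(img$pixels[, , name], d[1], d[2])
}

#' Read a calibrated RGB micrograph ROI
#'
#' Reads a 3-channel TIFF or PNG and attaches the calibration and study
#' metadata from a manifest record. Intensities are rescaled to the 0-255
#' real-valued convention used throughout the pipeline (a 16-bit image with
#' maximum representable value 65535 maps to 255). Files are assumed to be
#' stored RGB; channels are named, and every downstream operation addresses
#' channels by name, never by position.
#'
#' @param path path to a 3-channel TIFF (8- or 16-bit) or PNG file.
#' @param meta a one-row data frame or named list with at least
#'   `pixel_size_um`; optionally `subject`, `region`, `hemisphere`, `ap_mm`
#'   and any between-subject factor columns (all remaining columns are kept
#'   as group labels).
#' @return A [micrograph()].
#' @export
read_micrograph <- function(path, meta = list(pixel_size_um = 300 / 1320)) {
  if (!file.exists(path))
    stop(sprintf("cannot read micrograph: file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    tif = , tiff = tiff::readTIFF(path, convert = FALSE),
    png = png::readPNG(path),
    stop(sprintf("unsupported image format '%s' for %s", ext, path), call. = FALSE))
  if (length(dim(arr)) != 3L)
    stop(sprintf("%s: expected a 3-channel image, got %d dimension(s)",
                 path, length(dim(arr))), call. = FALSE)
  nch <- dim(arr)[3]
  if (nch == 4L) arr <- arr[, , 1:3, drop = FALSE]  # drop alpha
  else if (nch != 3L)
    stop(sprintf("%s: expected 3 channels, found %d", path, nch), call. = FALSE)
  # readTIFF/readPNG return values on [0, 1] whatever the bit depth
  arr <- arr * 255
  dimnames(arr) <- list(NULL, NULL, c("red", "green", "blue"))
  meta <- as.list(meta)
  ps <- meta$pixel_size_um
  if (is.null(ps) || !is.finite(ps) || ps <= 0)
    stop("manifest record must supply a positive pixel_size_um", call. = FALSE)
  known <- c("path", "subject", "region", "hemisphere", "ap_mm", "pixel_size_um")
  gl <- unlist(meta[setdiff(names(meta), known)])
  micrograph(arr, pixel_size_um = ps,
             subject_id = if (is.null(meta$subject)) NA_character_ else meta$subject,
             region = if (is.null(meta$region)) "other" else meta$region,
             hemisphere = if (is.null(meta$hemisphere)) "left" else meta$hemisphere,
             ap_mm = if (is.null(meta$ap_mm)) NA_real_ else meta$ap_mm,
             group_labels = if (length(gl)) gl else character())
}

#' Write a micrograph to an 8-bit TIFF
#'
#' Intensities are divided by 255 and written as 8-bit samples; for images
#' holding integer-valued 0-255 data the read/write round trip is exact.
#'
#' @param img a [micrograph()].
#' @param path output path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_micrograph <- function(img, path) {
  stopifnot(inherits(img, "micrograph"))
  arr <- img$pixels[, , c("red", "green", "blue")] / 255
  tiff::writeTIFF(arr, path, bits.per.sample = 8L)
  invisible(path)
}

#' Load and validate a study manifest
#'
#' The manifest is a CSV with one row per micrograph ROI and columns
#' `path`, `subject`, `region`, `hemisphere`, `ap_mm`, `pixel_size_um`,
#' plus one column per between-subject factor. The key tuple
#' (subject, region, hemisphere, ap_mm) must be unique.
#'
#' @param path path to the manifest CSV.
#' @param check_files if `TRUE` (default), every referenced image file must
#'   exist (relative paths are resolved against the manifest's directory).
#' @return A data frame of class `fiber_manifest`, row order preserved, with
#'   image paths resolved.
#' @export
load_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path))
    stop(sprintf("manifest not found: %s", path), call. = FALSE)
  man <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("path", "subject", "region", "hemisphere", "ap_mm", "pixel_size_um")
  missing <- setdiff(required, names(man))
  if (length(missing))
    stop(sprintf("manifest is missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (nrow(man) == 0L) {
    warning("manifest contains headers but no records", call. = FALSE)
  } else {
    key <- paste(man$subject, man$region, man$hemisphere, man$ap_mm, sep = "\r")
    dup <- duplicated(key)
    if (any(dup))
      stop(sprintf("duplicate manifest key(s): %s",
                   paste(unique(gsub("\r", "/", key[dup])), collapse = "; ")),
           call. = FALSE)
    rel <- !file.exists(man$path)
    man$path[rel] <- file.path(dirname(path), man$path[rel])
    if (check_files && !all(file.exists(man$path)))
      stop(sprintf("manifest references missing file(s): %s",
                   paste(man$path[!file.exists(man$path)], collapse = ", ")),
           call. = FALSE)
  }
  class(man) <- c("fiber_manifest", "data.frame")
  man
}
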