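#' Detect large stain artifacts
#'
#' Large dark blots (precipitates, blood vessels, tissue folds) would be
#' counted as stained signal by the fixed threshold, so they are located on
#' the pre-high-pass combined plane and excluded from detection. A pixel is
#' a stain candidate when its intensity falls more than
#' `stain_detect_level` grey levels below the plane's median (the median of
#' a sparse-fiber ROI is background, which makes the criterion invariant to
#' global offsets); candidate pixels are grouped into 8-connected
#' components, components of area `>= stain_min_area_px` are kept (thin
#' fibers never reach that area), and the result is dilated by a disk of
#' radius `stain_dilate_px` to absorb the blurred rim of each stain.
#'
#' @param combined numeric matrix: the combined (optionally median-denoised)
#'   plane, not the high-pass plane.
#' @param params a [quant_params()].
#' @return logical matrix, `TRUE` on excluded (stain) pixels; all-`FALSE`
#'   when no component reaches the area cutoff.
#' @export
detect_large_stains <- function(combined, params = quant_params()) {
  stopifnot(is.matrix(combined), inherits(params, "quant_params"))
  ref <- stats::median(combined)
  dark <- if (params$polarity == "stain_dark") ref - combined else combined - ref
  cand <- dark >= params$stain_detect_level
  if (!any(cand)) return(matrix(FALSE, nrow(combined), ncol(combined)))
  lab <- EBImage::bwlabel(cand * 1)
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= params$stain_min_area_px)
  if (!length(keep)) return(matrix(FALSE, nrow(combined), ncol(combined)))
  mask <- matrix(lab %in% keep, nrow(combined), ncol(combined))
  if (params$stain_dilate_px > 0) {
    brush <- EBImage::makeBrush(2L * params$stain_dilate_px + 1L, shape = "disc")
    mask <- EBImage::dilate(mask * 1, brush) > 0
  }
  mask
}

#' Threshold the high-pass plane into a fiber mask
#'
#' A pixel is detected when its polarity-corrected high-pass value is
#' greater than or equal to `level` (detected at exactly `level`) and it is
#' not covered by the stain mask. Negative high-pass values are never
#' detected.
#'
#' @param hp numeric matrix: polarity-corrected high-pass plane.
#' @param stain_mask logical matrix of excluded pixels (same size), or
#'   `NULL` for no exclusion.
#' @param level detection threshold on the 0-255 grey scale.
#' @return logical matrix of detected pixels.
#' @export
threshold_fibers <- function(hp, stain_mask = NULL, level = 11) {
  stopifnot(is.matrix(hp))
  if (is.null(stain_mask)) stain_mask <- matrix(FALSE, nrow(hp), ncol(hp))
  if (!identical(dim(hp), dim(stain_mask)))
    stop("`hp` and `stain_mask` dimensions differ", call. = FALSE)
  hp >= level & !stain_mask
}

#' Proportion of detected pixels in the ROI
#'
#' @param mask logical matrix of detected pixels.
#' @return a number in \[0, 1\]: detected pixels over all ROI pixels.
#' @export
volume_fraction <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (length(mask) == 0L)
    stop("cannot compute a fraction of a zero-size mask", call. = FALSE)
  sum(mask) / length(mask)
}

#' Focus quality control by dual-scale detection ratio
#'
#' Out-of-focus images lose fine-scale contrast, so the fraction detected
#' through the fine high-pass (`sigma = hp_sigma_px`) collapses relative to
#' the fraction detected when lower spatial frequencies are allowed
#' (`sigma = hp_sigma_lowfreq_px`). The ratio of the two fractions is the
#' focus criterion: images with `qc_ratio < cutoff` are flagged blurry.
#'
#' @param fraction_hp detected fraction at the fine scale, in \[0, 1\].
#' @param fraction_lowfreq detected fraction at the coarse scale, in \[0, 1\].
#' @param cutoff minimum acceptable ratio, in (0, 1\].
#' @return list with `qc_ratio` (NA when `fraction_lowfreq` is 0, with a
#'   warning) and logical `qc_pass`.
#' @export
focus_qc <- function(fraction_hp, fraction_lowfreq, cutoff = 0.5) {
  if (cutoff <= 0 || cutoff > 1)
    stop("`cutoff` must lie in (0, 1]", call. = FALSE)
  if (fraction_hp < 0 || fraction_hp > 1 || fraction_lowfreq < 0 || fraction_lowfreq > 1)
    stop("fractions must lie in [0, 1]", call. = FALSE)
  if (fraction_lowfreq == 0) {
    warning("no pixels detected at the low-frequency pass; QC ratio undefined, ROI fails QC",
            call. = FALSE)
    return(list(qc_ratio = NA_real_, qc_pass = FALSE))
  }
  ratio <- fraction_hp / fraction_lowfreq
  list(qc_ratio = ratio, qc_pass = ratio >= cutoff)
}
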