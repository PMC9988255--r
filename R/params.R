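#' Detection parameters for fiber quantification
#'
#' Collects every tunable constant of the fiber-detection algorithm. The
#' defaults are the published operating point of the method: the channel
#' combination weights (blue 1, red -0.25, green -0.25), the 3 px disk
#' median filter, the Gaussian smoothing scale of 8 px for the detection
#' pass and 20 px for the focus-control pass, and the fixed detection
#' threshold at grey level 11 on the 0-255 scale.
#'
#' @param channel_weights named numeric vector with exactly the entries
#'   `blue`, `red`, `green`: weights of the linear channel combination.
#' @param median_radius_px radius (px) of the disk median filter.
#' @param hp_sigma_px Gaussian sigma (px) of the high-pass detection pass.
#' @param hp_sigma_lowfreq_px Gaussian sigma (px) of the second,
#'   lower-frequency pass used only for the focus criterion.
#' @param threshold_level fixed detection threshold on the 0-255 grey
#'   scale, applied to the polarity-corrected high-pass plane; a pixel is
#'   detected when its value is `>= threshold_level`.
#' @param polarity `"stain_dark"` (default; DAB-stained structures are
#'   darker than the background after the channel combination, so the
#'   high-pass sign is flipped to make them positive) or `"stain_bright"`.
#' @param stain_detect_level intensity drop (grey levels below the ROI's
#'   median background of the combined plane) beyond which a pixel is a
#'   large-stain candidate. Referencing the ROI's own median makes stain
#'   detection invariant to a global intensity offset.
#' @param stain_min_area_px minimum connected-component area (px) for a
#'   candidate cluster to count as a large stain; thin fibers never reach it.
#' @param stain_dilate_px safety margin (px) dilated around detected stains.
#' @param blur_ratio_cutoff minimum acceptable ratio of the detected
#'   fraction at `hp_sigma_px` over the fraction at `hp_sigma_lowfreq_px`;
#'   images below the cutoff are flagged as out of focus.
#'
#' @return An object of class `quant_params`.
#' @export
quant_params <- function(channel_weights = c(blue = 1, red = -0.25, green = -0.25),
                         median_radius_px = 3L,
                         hp_sigma_px = 8,
                         hp_sigma_lowfreq_px = 20,
                         threshold_level = 11,
                         polarity = c("stain_dark", "stain_bright"),
                         stain_detect_level = 60,
                         stain_min_area_px = 2000,
                         stain_dilate_px = 5L,
                         blur_ratio_cutoff = 0.5) {
  polarity <- match.arg(polarity)
  if (!setequal(names(channel_weights), c("blue", "red", "green")))
    stop("`channel_weights` must name exactly blue, red and green", call. = FALSE)
  if (median_radius_px < 1)
    stop("`median_radius_px` must be >= 1", call. = FALSE)
  if (hp_sigma_px <= 0 || hp_sigma_lowfreq_px <= 0)
    stop("Gaussian sigmas must be positive", call. = FALSE)
  if (threshold_level <= 0 || threshold_level >= 255)
    stop("`threshold_level` must lie in (0, 255)", call. = FALSE)
  if (blur_ratio_cutoff <= 0 || blur_ratio_cutoff > 1)
    stop("`blur_ratio_cutoff` must lie in (0, 1]", call. = FALSE)
  if (stain_min_area_px < 1 || stain_dilate_px < 0)
    stop("invalid stain-elimination parameters", call. = FALSE)
  structure(
    list(channel_weights = channel_weights[c("blue", "red", "green")],
         median_radius_px = as.integer(median_radius_px),
         hp_sigma_px = hp_sigma_px,
         hp_sigma_lowfreq_px = hp_sigma_lowfreq_px,
         threshold_level = threshold_level,
         polarity = polarity,
         stain_detect_level = stain_detect_level,
         stain_min_area_px = stain_min_area_px,
         stain_dilate_px = as.integer(stain_dilate_px),
         blur_ratio_cutoff = blur_ratio_cutoff),
    class = "quant_params")
}

#' @export
print.quant_params <- function(x, ...) {
  cat("<quant_params>\n")
  cat(sprintf("  weights: blue %g, red %g, green %g | median r=%d px | sigma %g / %g px\n",
              x$channel_weights["blue"], x$channel_weights["red"],
              x$channel_weights["green"], x$median_radius_px,
              x$hp_sigma_px, x$hp_sigma_lowfreq_px))
  cat(sprintf("  threshold %g (%s) | stains: level %g, area >= %g px, dilate %d px | blur cutoff %g\n",
              x$threshold_level, x$polarity, x$stain_detect_level,
              x$stain_min_area_px, x$stain_dilate_px, x$blur_ratio_cutoff))
  invisible(x)
}

#' Read detection parameters from a YAML file
#'
#' The file mirrors [quant_params()] field for field; absent fields keep
#' their defaults.
#' @param path YAML file path.
#' @return A `quant_params` object.
#' @export
read_quant_params <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$channel_weights)) y$channel_weights <- unlist(y$channel_weights)
  do.call(quant_params, y)
}
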