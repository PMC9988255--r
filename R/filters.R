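#' Combine RGB channels into a stain-contrast plane
#'
#' Forms the per-pixel weighted sum of the named channels. With the default
#' weights (blue 1, red -0.25, green -0.25) brown DAB-stained structures,
#' which are strong in red and weak in blue, come out darker than the
#' bright, near-neutral background. Values are signed reals and are never
#' clipped: the downstream high-pass stage relies on signed arithmetic.
#'
#' @param img a [micrograph()].
#' @param weights named numeric vector with entries `blue`, `red`, `green`.
#' @return numeric H x W matrix (the "combined" grey plane).
#' @export
combine_channels <- function(img, weights = c(blue = 1, red = -0.25, green = -0.25)) {
  stopifnot(inherits(img, "micrograph"))
  missing <- setdiff(c("blue", "red", "green"), names(weights))
  if (length(missing))
    stop(sprintf("`weights` is missing channel(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  out <- weights[["blue"]]  * channel(img, "blue") +
         weights[["red"]]   * channel(img, "red") +
         weights[["green"]] * channel(img, "green")
  attr(out, "scale_note") <- "raw-combined"
  out
}

#' Disk median filter
#'
#' Replaces each pixel by the median over a disk-shaped neighborhood
#' (offsets with dx^2 + dy^2 <= radius^2, 29 pixels at the default radius
#' 3), the rank-filter neighborhood convention of common image-analysis
#' software. Borders are handled by whole-sample reflection (mirroring
#' about the edge pixel). Removes shot-like impulse noise while preserving
#' fiber edges.
#'
#' @param plane numeric matrix (typically the combined plane).
#' @param radius_px neighborhood radius in pixels, >= 1.
#' @return filtered matrix of the same size.
#' @export
median_denoise <- function(plane, radius_px = 3L) {
  stopifnot(is.matrix(plane), is.numeric(plane))
  radius_px <- as.integer(radius_px)
  if (radius_px < 1)
    stop("`radius_px` must be >= 1", call. = FALSE)
  if (radius_px >= min(dim(plane)))
    stop("median radius must be smaller than the image", call. = FALSE)
  out <- median_disk_cpp(plane, radius_px)
  attr(out, "scale_note") <- attr(plane, "scale_note")
  out
}

#' Gaussian smoothing with mirrored borders
#'
#' Separable Gaussian convolution; the kernel is truncated at
#' `ceiling(3.5 * sigma)` and renormalized to unit sum, and borders are
#' mirrored (whole-sample reflection), so constants are preserved.
#'
#' @param plane numeric matrix.
#' @param sigma_px Gaussian standard deviation in pixels, > 0.
#' @return smoothed matrix of the same size.
#' @export
gaussian_smooth <- function(plane, sigma_px) {
  stopifnot(is.matrix(plane), is.numeric(plane))
  if (!is.finite(sigma_px) || sigma_px <= 0)
    stop("`sigma_px` must be positive", call. = FALSE)
  h <- as.integer(ceiling(3.5 * sigma_px))
  k <- exp(-((-h:h)^2) / (2 * sigma_px^2))
  k <- k / sum(k)
  sep_conv_cpp(plane, k)
}

#' High-pass (difference-of-smoothing) transform
#'
#' Subtracts a Gaussian-smoothed copy from the plane, isolating spatial
#' frequencies finer than `sigma_px`. Under the default `"stain_dark"`
#' polarity the sign of the difference is flipped so that locally dark
#' (stained) elements come out positive and the fixed grey-level threshold
#' can be applied to positive deviations. Uniform offsets cancel exactly.
#'
#' @param plane numeric matrix, typically the median-denoised combined plane.
#' @param sigma_px Gaussian sigma in pixels.
#' @param polarity `"stain_dark"` (default) or `"stain_bright"`.
#' @return high-pass matrix of the same size (signed values).
#' @export
highpass <- function(plane, sigma_px, polarity = c("stain_dark", "stain_bright")) {
  polarity <- match.arg(polarity)
  d <- plane - gaussian_smooth(plane, sigma_px)
  out <- if (polarity == "stain_dark") -d else d
  attr(out, "scale_note") <- "high-pass"
  out
}
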