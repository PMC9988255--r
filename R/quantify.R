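#' Quantify fiber volume in one ROI
#'
#' Runs the full detection chain on a calibrated RGB micrograph:
#' channel combination (blue 1, red -0.25, green -0.25) -> disk median
#' filter -> high-pass by subtraction of a Gaussian-smoothed copy (sigma 8
#' px) -> exclusion of large stain artifacts -> fixed threshold (grey
#' level 11) -> detected-pixel fraction. The same chain is run a second
#' time with the coarser Gaussian (sigma 20 px) and the ratio of the two
#' detected fractions gives the focus criterion. The relative volume
#' occupied by fibers is reported as the fine-scale detected fraction
#' times 100. The computation is deterministic for a fixed input.
#'
#' @param img a [micrograph()].
#' @param params a [quant_params()].
#' @return An object of class `fiber_measurement`: a list with
#'   `fraction_hp`, `fraction_lowfreq`, `qc_ratio`, `qc_pass`,
#'   `volume_percent` (= 100 * `fraction_hp`), `n_stain_pixels_excluded`,
#'   and the provenance fields `subject_id`, `region`, `hemisphere`,
#'   `ap_mm`, `group_labels`.
#' @export
quantify_roi <- function(img, params = quant_params()) {
  stopifnot(inherits(img, "micrograph"), inherits(params, "quant_params"))
  step <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", what, conditionMessage(e)), call. = FALSE))
  }
  combined <- step("combine_channels", combine_channels(img, params$channel_weights))
  den <- step("median_denoise", median_denoise(combined, params$median_radius_px))
  stain <- step("detect_large_stains", detect_large_stains(den, params))
  hp_fine <- step("highpass", highpass(den, params$hp_sigma_px, params$polarity))
  hp_low  <- step("highpass", highpass(den, params$hp_sigma_lowfreq_px, params$polarity))
  det_fine <- threshold_fibers(hp_fine, stain, params$threshold_level)
  det_low  <- threshold_fibers(hp_low,  stain, params$threshold_level)
  f_fine <- volume_fraction(det_fine)
  f_low  <- volume_fraction(det_low)
  qc <- withCallingHandlers(
    focus_qc(f_fine, f_low, params$blur_ratio_cutoff),
    warning = function(w) invokeRestart("muffleWarning"))
  structure(
    list(fraction_hp = f_fine, fraction_lowfreq = f_low,
         qc_ratio = qc$qc_ratio, qc_pass = qc$qc_pass,
         volume_percent = 100 * f_fine,
         n_stain_pixels_excluded = sum(stain),
         subject_id = img$subject_id, region = img$region,
         hemisphere = img$hemisphere, ap_mm = img$ap_mm,
         group_labels = img$group_labels),
    class = "fiber_measurement")
}

#' @export
print.fiber_measurement <- function(x, ...) {
  cat(sprintf("<fiber_measurement> subject %s, %s (%s, AP %+.1f): volume %.3f%% | QC ratio %s -> %s\n",
              x$subject_id, x$region, x$hemisphere, x$ap_mm, x$volume_percent,
              ifelse(is.na(x$qc_ratio), "undefined", sprintf("%.2f", x$qc_ratio)),
              ifelse(x$qc_pass, "pass", "FAIL")))
  invisible(x)
}

#' @export
as.data.frame.fiber_measurement <- function(x, ...) {
  df <- data.frame(subject = x$subject_id, region = x$region,
                   hemisphere = x$hemisphere, ap_mm = x$ap_mm,
                   fraction_hp = x$fraction_hp,
                   fraction_lowfreq = x$fraction_lowfreq,
                   qc_ratio = x$qc_ratio, qc_pass = x$qc_pass,
                   volume_percent = x$volume_percent,
                   n_stain_pixels_excluded = x$n_stain_pixels_excluded,
                   stringsAsFactors = FALSE)
  for (g in names(x$group_labels)) df[[g]] <- x$group_labels[[g]]
  df
}

#' Bind fiber measurements into one table
#' @param measurements list of `fiber_measurement` objects.
#' @return data frame, one row per measurement.
#' @export
measurements_table <- function(measurements) {
  stopifnot(length(measurements) >= 1L)
  do.call(rbind, lapply(measurements, as.data.frame))
}

#' Aggregate ROI measurements per subject and region
#'
#' Averages `volume_percent` over hemispheres/sections for each subject x
#' region cell, after (by default) dropping ROIs that failed the focus
#' criterion. Cells in which every ROI failed QC are reported with `NA`
#' volume and a warning -- never silently imputed.
#'
#' @param measurements a list of `fiber_measurement` objects or the data
#'   frame from [measurements_table()].
#' @param drop_failed_qc drop ROIs with `qc_pass == FALSE` before averaging.
#' @return data frame with columns `subject`, `region`, any between-subject
#'   factor columns, `volume_percent` (cell mean), `n_used`, `n_excluded`.
#' @export
summarize_by_region <- function(measurements, drop_failed_qc = TRUE) {
  df <- if (is.data.frame(measurements)) measurements
        else measurements_table(measurements)
  extra <- setdiff(names(df), c("subject", "region", "hemisphere", "ap_mm",
                                "fraction_hp", "fraction_lowfreq", "qc_ratio",
                                "qc_pass", "volume_percent",
                                "n_stain_pixels_excluded"))
  key <- df[c("subject", "region", extra)]
  groups <- unique(key)
  rownames(groups) <- NULL
  res <- groups
  res$volume_percent <- NA_real_
  res$n_used <- 0L
  res$n_excluded <- 0L
  for (i in seq_len(nrow(groups))) {
    sel <- df$subject == groups$subject[i] & df$region == groups$region[i]
    use <- sel & (!drop_failed_qc | df$qc_pass)
    res$n_used[i] <- sum(use)
    res$n_excluded[i] <- sum(sel) - sum(use)
    if (any(use)) res$volume_percent[i] <- mean(df$volume_percent[use])
  }
  if (anyNA(res$volume_percent))
    warning(sprintf("%d subject x region cell(s) have no ROI surviving QC; reported as NA",
                    sum(is.na(res$volume_percent))), call. = FALSE)
  res
}
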