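#' Quantify every ROI listed in a manifest
#'
#' @param manifest a `fiber_manifest` from [load_manifest()].
#' @param params a [quant_params()].
#' @return data frame of per-ROI measurements (one row per manifest row).
#' @export
quantify_manifest <- function(manifest, params = quant_params()) {
  stopifnot(inherits(manifest, "fiber_manifest"))
  if (nrow(manifest) == 0L)
    stop("manifest contains no records", call. = FALSE)
  meas <- lapply(seq_len(nrow(manifest)), function(i)
    quantify_roi(read_micrograph(manifest$path[i], manifest[i, ]), params))
  measurements_table(meas)
}

#' Simulate a depletion-style cohort of micrographs
#'
#' Generates one synthetic ROI per subject x region x section, with
#' ground-truth fiber density set per treatment group and region (e.g.
#' control animals dense in VO, depleted animals sparse everywhere).
#' Subject-level biological variability is modelled as a multiplicative
#' Gaussian jitter on the target density (`density_cv`).
#'
#' @param densities named list: one entry per group, each a named numeric
#'   vector of target densities per region, e.g.
#'   `list(CTL = c(VO = 0.05, LO = 0.04), SAP = c(VO = 0.01, LO = 0.01))`.
#' @param n_per_group subjects per group.
#' @param scene_template a [fiber_scene_params()] whose density and seed
#'   are overridden per scene.
#' @param density_cv coefficient of variation of the per-subject density.
#' @param n_sections ROIs per subject x region.
#' @param seed master seed; per-scene seeds are drawn from it.
#' @return list of [micrograph()] objects carrying a `group` label, plus
#'   attribute `truth`: data frame of subject, group, region, section and
#'   realized ground-truth density.
#' @export
simulate_depletion_cohort <- function(densities = list(CTL = c(VO = 0.05, LO = 0.04),
                                                       SAP = c(VO = 0.01, LO = 0.01)),
                                      n_per_group = 10L,
                                      scene_template = fiber_scene_params(),
                                      density_cv = 0.05,
                                      n_sections = 1L,
                                      seed = 1L) {
  groups <- names(densities)
  regions <- names(densities[[1]])
  n_scenes <- length(groups) * n_per_group * length(regions) * n_sections
  plan <- with_seed(seed, {
    seeds <- sample.int(.Machine$integer.max, n_scenes)
    jitter <- rnorm(length(groups) * n_per_group, 1, density_cv)
    list(seeds = seeds, jitter = pmax(jitter, 0.1))
  })
  imgs <- list()
  truth <- list()
  k <- 0L
  subj <- 0L
  for (g in groups) for (s in seq_len(n_per_group)) {
    subj <- subj + 1L
    sid <- sprintf("%s%02d", g, s)
    for (r in regions) for (sec in seq_len(n_sections)) {
      k <- k + 1L
      dens <- min(densities[[g]][[r]] * plan$jitter[subj], 0.199)
      p <- scene_template
      p$target_density <- dens
      p$seed <- plan$seeds[k]
      scene <- generate_fiber_scene(p, subject_id = sid, region = r,
                                    hemisphere = if (sec %% 2) "left" else "right",
                                    ap_mm = 3.7,
                                    group_labels = c(group = g))
      imgs[[k]] <- scene$image
      truth[[k]] <- data.frame(subject = sid, group = g, region = r,
                               section = sec,
                               true_density = scene$realized_density,
                               stringsAsFactors = FALSE)
    }
  }
  attr(imgs, "truth") <- do.call(rbind, truth)
  imgs
}

#' Run a depletion study end to end
#'
#' Quantifies every ROI, aggregates fiber volume per subject x region, and
#' runs the planned group x region contrast analysis (region as the
#' within-subject factor) with simple effects for significant
#' interactions. QC exclusions are reported, never silent.
#'
#' @param images list of [micrograph()] objects (each carrying a `group`
#'   label and a region from `regions`), or a `fiber_manifest`.
#' @param params a [quant_params()].
#' @param group_factor name of the between-subject factor column.
#' @param regions within-subject region pair, default `c("VO", "LO")`.
#' @param alpha per-contrast error rate.
#' @param drop_failed_qc drop ROIs failing the focus criterion.
#' @param out_dir optional directory; when given, the measurement table,
#'   region summary (CSV) and contrast report (JSON) are written there.
#' @return list with `measurements`, `summary`, `table` (the factorial
#'   table analysed) and `report` (a `contrast_report`).
#' @export
run_depletion_study <- function(images, params = quant_params(),
                                group_factor = "group",
                                regions = c("VO", "LO"),
                                alpha = 0.05, drop_failed_qc = TRUE,
                                out_dir = NULL) {
  meas <- if (inherits(images, "fiber_manifest")) {
    quantify_manifest(images, params)
  } else {
    if (!length(images)) stop("no images supplied", call. = FALSE)
    measurements_table(lapply(images, quantify_roi, params = params))
  }
  smry <- summarize_by_region(meas, drop_failed_qc = drop_failed_qc)
  tab <- smry[smry$region %in% regions & !is.na(smry$volume_percent),
              c("subject", group_factor, "region", "volume_percent")]
  names(tab)[names(tab) == "volume_percent"] <- "response"
  # the contrast engine needs complete within-subject data: drop subjects
  # that lost a region cell to QC (reported, never silent)
  cnt <- table(tab$subject)
  incomplete <- names(cnt)[cnt < length(regions)]
  if (length(incomplete)) {
    warning(sprintf("dropping %d subject(s) with incomplete region data after QC: %s",
                    length(incomplete), paste(incomplete, collapse = ", ")),
            call. = FALSE)
    tab <- tab[!tab$subject %in% incomplete, ]
  }
  glev <- unique(tab[[group_factor]])
  bf <- stats::setNames(list(glev), group_factor)
  wf <- list(region = regions)
  report <- analyze_design(tab, bf, wf, alpha = alpha,
                           simple_effects_on = group_factor)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(meas, file.path(out_dir, "measurements.csv"), row.names = FALSE)
    write.csv(smry, file.path(out_dir, "region_summary.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(parameters = unclass(params), alpha = alpha,
           contrasts = report$contrasts, simple_effects = report$simple_effects,
           version = as.character(utils::packageVersion("fiberdens"))),
      file.path(out_dir, "contrast_report.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  list(measurements = meas, summary = smry, table = tab, report = report)
}

#' Run a devaluation-test contrast analysis
#'
#' Analyses a long-format behavioral table (responses per subject x
#' devaluation level) with the full planned contrast set and simple
#' effects of devaluation within each level of the designated treatment
#' factor for significant interactions.
#'
#' @param table long-format data frame (`subject`, between factor columns,
#'   within factor column, `response`).
#' @param between_factors,within_factors named lists of 2-level factors.
#' @param alpha per-contrast error rate.
#' @param simple_effects_on factor to condition simple effects on.
#' @param out_dir optional output directory for the JSON report.
#' @return a `contrast_report`.
#' @export
run_devaluation_analysis <- function(table,
                                     between_factors = list(group = c("Pre", "Post"),
                                                            treatment = c("CTL", "SAP")),
                                     within_factors = list(devaluation = c("Ndev", "Dev")),
                                     alpha = 0.05,
                                     simple_effects_on = "treatment",
                                     out_dir = NULL) {
  report <- analyze_design(table, between_factors, within_factors,
                           alpha = alpha, simple_effects_on = simple_effects_on)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      list(alpha = alpha, contrasts = report$contrasts,
           simple_effects = report$simple_effects,
           version = as.character(utils::packageVersion("fiberdens"))),
      file.path(out_dir, "devaluation_report.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  report
}
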