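cell_key <- function(df, factors) {
  if (!length(factors)) return(rep("(all)", nrow(df)))
  do.call(paste, c(unname(as.list(df[, factors, drop = FALSE])), sep = ":"))
}

grid_keys <- function(factor_list) {
  if (!length(factor_list)) return("(all)")
  g <- expand.grid(factor_list, stringsAsFactors = FALSE)
  do.call(paste, c(unname(g), sep = ":"))
}

#' Build the full orthogonal contrast set of a mixed factorial design
#'
#' For a design with two-level between-subject and within-subject factors,
#' returns one planned one-degree-of-freedom contrast per main effect and
#' per interaction (2^k - 1 contrasts for k factors): each factor is coded
#' -1/+1 in level order and interaction weights are products of the codes.
#' Any two contrasts in the set are orthogonal under equal-n cell
#' weighting. Each contrast is tested on its own, controlling the
#' per-contrast error rate at `alpha` (no familywise correction).
#'
#' @param between_factors named list of between-subject factors (each a
#'   character vector of exactly 2 levels); may be empty.
#' @param within_factors named list of within-subject factors (each exactly
#'   2 levels); may be empty.
#' @param alpha per-contrast error rate.
#' @return A list of `contrast_spec` objects.
#' @export
build_contrast_set <- function(between_factors = list(), within_factors = list(),
                               alpha = 0.05) {
  all_f <- c(between_factors, within_factors)
  if (!length(all_f))
    stop("at least one factor is required", call. = FALSE)
  bad <- names(all_f)[vapply(all_f, length, 1L) != 2L]
  if (length(bad))
    stop(sprintf("only 2-level factors are supported in contrast sets; factor(s) %s have another number of levels",
                 paste(bad, collapse = ", ")), call. = FALSE)
  bkeys <- grid_keys(between_factors)
  wkeys <- grid_keys(within_factors)
  bgrid <- if (length(between_factors))
    expand.grid(between_factors, stringsAsFactors = FALSE) else NULL
  wgrid <- if (length(within_factors))
    expand.grid(within_factors, stringsAsFactors = FALSE) else NULL
  code <- function(grid, keys, fac, levels) {
    if (is.null(grid)) return(stats::setNames(1, keys))
    stats::setNames(ifelse(grid[[fac]] == levels[2], 1, -1), keys)
  }
  fnames <- names(all_f)
  specs <- list()
  for (m in seq_len(2^length(fnames) - 1L)) {
    sel <- fnames[bitwAnd(m, 2^(seq_along(fnames) - 1L)) > 0]
    bw <- stats::setNames(rep(1, length(bkeys)), bkeys)
    for (f in intersect(sel, names(between_factors)))
      bw <- bw * code(bgrid, bkeys, f, between_factors[[f]])
    ww <- stats::setNames(rep(1, length(wkeys)), wkeys)
    for (f in intersect(sel, names(within_factors)))
      ww <- ww * code(wgrid, wkeys, f, within_factors[[f]])
    if (!length(intersect(sel, names(within_factors))))
      ww <- ww / length(ww)  # subject mean for pure-between contrasts
    specs[[length(specs) + 1L]] <- structure(
      list(name = paste(sel, collapse = " x "), factors = sel,
           between_factors = between_factors, within_factors = within_factors,
           between_weights = bw, within_weights = ww, alpha = alpha),
      class = "contrast_spec")
  }
  specs
}

#' Linear-trend within-subject contrast
#'
#' One-degree-of-freedom contrast testing a linear trend across the
#' ordered levels of a within-subject factor (e.g. training day), using
#' centred integer trend weights. Used for acquisition-curve analyses
#' where the reported statistic has one numerator degree of freedom.
#'
#' @param within_factor named list of length 1: the ordered within factor.
#' @param between_factors named list of between factors of the design (may
#'   be empty); the trend is averaged over them.
#' @param alpha per-contrast error rate.
#' @return A `contrast_spec`.
#' @export
linear_trend_contrast <- function(within_factor, between_factors = list(),
                                  alpha = 0.05) {
  stopifnot(length(within_factor) == 1L)
  lev <- within_factor[[1]]
  k <- length(lev)
  if (k < 2) stop("trend needs at least 2 levels", call. = FALSE)
  w <- stats::setNames(seq_len(k) - (k + 1) / 2, lev)
  structure(
    list(name = paste0("linear trend over ", names(within_factor)),
         factors = names(within_factor),
         between_factors = between_factors, within_factors = within_factor,
         between_weights = stats::setNames(rep(1, length(grid_keys(between_factors))),
                                           grid_keys(between_factors)),
         within_weights = w, alpha = alpha),
    class = "contrast_spec")
}

validate_factorial <- function(table, spec) {
  need <- c("subject", "response", names(spec$between_factors),
            names(spec$within_factors))
  missing <- setdiff(need, names(table))
  if (length(missing))
    stop(sprintf("table is missing column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  if (!all(is.finite(table$response)))
    stop("responses must be finite", call. = FALSE)
  bk <- cell_key(table, names(spec$between_factors))
  if (any(tapply(bk, table$subject, function(x) length(unique(x))) != 1L))
    stop("each subject must appear in exactly one between-subject cell", call. = FALSE)
  invisible(TRUE)
}

#' Test one planned contrast
#'
#' Implements the univariate contrast-score approach: the within-subject
#' weights are applied to each subject's responses to form one score per
#' subject, and the between-subject weighted combination of the cell means
#' of those scores is tested against the pooled within-cell variance of
#' the scores, with `df2 = N - (number of between cells)`. Pure
#' between-subject contrasts use the subject means as scores. Cell means
#' are unweighted (cell-mean weighting), so unbalanced groups are handled
#' without reweighting the hypothesis.
#'
#' @param table long-format data frame with columns `subject`, one per
#'   factor, and `response`; complete within-subject data required.
#' @param spec a `contrast_spec` (from [build_contrast_set()],
#'   [linear_trend_contrast()] or built by hand).
#' @return An object of class `contrast_result`: `name`, `estimate` (the
#'   contrast value on cell means of scores), `ss_contrast`, `df1` (= 1),
#'   `df2`, `F`, `p`, `significant`.
#' @export
test_contrast <- function(table, spec) {
  stopifnot(inherits(spec, "contrast_spec"))
  validate_factorial(table, spec)
  scores <- contrast_scores(table, spec)
  contrast_f_test(scores$score, scores$cell, spec$between_weights,
                  spec$name, spec$alpha)
}

contrast_scores <- function(table, spec) {
  wnames <- names(spec$within_factors)
  wkey <- cell_key(table, wnames)
  ww <- spec$within_weights
  unknown <- setdiff(unique(wkey), names(ww))
  if (length(unknown))
    stop(sprintf("within cell(s) %s not covered by the contrast's weights",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  subjects <- unique(table$subject)
  bkey <- cell_key(table, names(spec$between_factors))
  score <- numeric(length(subjects))
  cell <- character(length(subjects))
  for (i in seq_along(subjects)) {
    rows <- table$subject == subjects[i]
    k <- wkey[rows]
    if (anyDuplicated(k) || length(k) != length(ww))
      stop(sprintf("subject %s does not have exactly one response per within cell",
                   subjects[i]), call. = FALSE)
    score[i] <- sum(ww[k] * table$response[rows])
    cell[i] <- bkey[rows][1]
  }
  list(subject = subjects, score = score, cell = cell)
}

contrast_f_test <- function(score, cell, bw, name, alpha) {
  cells <- names(bw)
  missing <- setdiff(cells[bw != 0], unique(cell))
  if (length(missing))
    stop(sprintf("empty between cell(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  n_j <- tapply(score, cell, length)[cells]
  m_j <- tapply(score, cell, mean)[cells]
  N <- length(score)
  J <- length(unique(cell))
  df2 <- N - J
  if (df2 < 1)
    stop("error degrees of freedom < 1 (need more than one subject per cell)",
         call. = FALSE)
  use <- bw != 0
  L <- sum(bw[use] * m_j[use])
  denom <- sum(bw[use]^2 / n_j[use])
  ss <- L^2 / denom
  mse <- sum((score - stats::ave(score, cell))^2) / df2
  if (mse == 0) {
    warning(sprintf("contrast '%s': zero error variance; F degenerate", name),
            call. = FALSE)
    f <- if (ss == 0) 0 else Inf
    p <- if (ss == 0) 1 else 0
  } else {
    f <- ss / mse
    p <- pf(f, 1, df2, lower.tail = FALSE)
  }
  structure(list(name = name, estimate = L, ss_contrast = ss, df1 = 1L,
                 df2 = df2, F = f, p = p, alpha = alpha,
                 significant = p < alpha),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("%-40s F(1,%d) = %.3f, p = %.4g%s\n", x$name, x$df2, x$F, x$p,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Simple-effects decomposition of an interaction
#'
#' Tests the remaining factor(s) of an interaction within each level of the
#' conditioning factor, against the pooled error term of the full design
#' (so `df2 = N - cells` is constant across simple effects). Conditioning
#' on a between-subject factor tests the within (or other between)
#' contrast inside each group; conditioning on a within-subject factor
#' tests the between contrast on the responses at each within level.
#'
#' @param table long-format factorial data frame.
#' @param interaction a `contrast_spec` whose `factors` include
#'   `condition_on` plus at least one other factor.
#' @param condition_on name of the factor whose levels define the strata.
#' @return A list of `contrast_result` objects, one per level.
#' @export
simple_effects <- function(table, interaction, condition_on) {
  stopifnot(inherits(interaction, "contrast_spec"))
  if (!(condition_on %in% interaction$factors))
    stop(sprintf("interaction '%s' does not involve factor '%s'",
                 interaction$name, condition_on), call. = FALSE)
  others <- setdiff(interaction$factors, condition_on)
  if (!length(others))
    stop("the interaction has no other factor to test", call. = FALSE)
  bf <- interaction$between_factors
  wf <- interaction$within_factors
  is_between <- condition_on %in% names(bf)
  levels <- if (is_between) bf[[condition_on]] else wf[[condition_on]]
  bgrid <- if (length(bf)) expand.grid(bf, stringsAsFactors = FALSE) else NULL
  wgrid <- if (length(wf)) expand.grid(wf, stringsAsFactors = FALSE) else NULL
  bkeys <- grid_keys(bf)
  wkeys <- grid_keys(wf)
  pm_code <- function(grid, keys, fac, levs)
    stats::setNames(ifelse(grid[[fac]] == levs[2], 1, -1), keys)
  lapply(levels, function(lv) {
    bw <- stats::setNames(rep(1, length(bkeys)), bkeys)
    ww <- stats::setNames(rep(1, length(wkeys)), wkeys)
    if (is_between) {
      bw[bgrid[[condition_on]] != lv] <- 0
    } else {
      ww[wgrid[[condition_on]] != lv] <- 0
    }
    for (f in others) {
      if (f %in% names(bf)) bw <- bw * pm_code(bgrid, bkeys, f, bf[[f]])
      else ww <- ww * pm_code(wgrid, wkeys, f, wf[[f]])
    }
    # collapse (average over) within factors not in the interaction / stratum
    nz <- ww != 0
    if (!any(vapply(others, function(f) f %in% names(wf), logical(1))) ) {
      ww[nz] <- ww[nz] / sum(nz)
    }
    spec <- structure(
      list(name = sprintf("%s at %s = %s", paste(others, collapse = " x "),
                          condition_on, lv),
           factors = others, between_factors = bf, within_factors = wf,
           between_weights = bw, within_weights = ww,
           alpha = interaction$alpha),
      class = "contrast_spec")
    test_contrast(table, spec)
  })
}

#' Run the full planned-contrast analysis of a mixed factorial design
#'
#' Tests every contrast of the orthogonal set; for each significant
#' interaction, runs the simple-effects decomposition. The conditioning
#' factor for each interaction is the first between-subject factor it
#' involves (falling back to its first factor), unless overridden.
#'
#' @param table long-format data frame (`subject`, factor columns,
#'   `response`).
#' @param between_factors,within_factors named lists of 2-level factors.
#' @param alpha per-contrast error rate.
#' @param simple_effects_on optional factor name to condition simple
#'   effects on (used for interactions that involve it).
#' @return An object of class `contrast_report`: `contrasts` (data frame
#'   with name, estimate, ss, df, F, p, significant), `simple_effects`
#'   (same shape, possibly empty), and the design description.
#' @export
analyze_design <- function(table, between_factors, within_factors,
                           alpha = 0.05, simple_effects_on = NULL) {
  specs <- build_contrast_set(between_factors, within_factors, alpha)
  results <- lapply(specs, function(s) test_contrast(table, s))
  as_row <- function(r) data.frame(name = r$name, estimate = r$estimate,
                                   ss = r$ss_contrast, df1 = r$df1, df2 = r$df2,
                                   F = r$F, p = r$p, significant = r$significant,
                                   stringsAsFactors = FALSE)
  ctab <- do.call(rbind, lapply(results, as_row))
  simples <- list()
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    if (length(s$factors) < 2 || !results[[i]]$significant) next
    cond <- if (!is.null(simple_effects_on) && simple_effects_on %in% s$factors)
      simple_effects_on
    else {
      bf_in <- intersect(s$factors, names(between_factors))
      if (length(bf_in)) bf_in[1] else s$factors[1]
    }
    simples <- c(simples, simple_effects(table, s, cond))
  }
  stab <- if (length(simples)) do.call(rbind, lapply(simples, as_row))
          else ctab[0, ]
  structure(list(contrasts = ctab, simple_effects = stab,
                 between_factors = between_factors,
                 within_factors = within_factors, alpha = alpha),
            class = "contrast_report")
}

#' @export
print.contrast_report <- function(x, ...) {
  cat(sprintf("Planned orthogonal contrasts (per-contrast alpha = %g)\n", x$alpha))
  for (i in seq_len(nrow(x$contrasts)))
    cat(sprintf("  %-40s F(1,%d) = %.3f, p = %.4g%s\n",
                x$contrasts$name[i], x$contrasts$df2[i], x$contrasts$F[i],
                x$contrasts$p[i], if (x$contrasts$significant[i]) " *" else ""))
  if (nrow(x$simple_effects)) {
    cat("Simple effects (pooled error term):\n")
    for (i in seq_len(nrow(x$simple_effects)))
      cat(sprintf("  %-40s F(1,%d) = %.3f, p = %.4g%s\n",
                  x$simple_effects$name[i], x$simple_effects$df2[i],
                  x$simple_effects$F[i], x$simple_effects$p[i],
                  if (x$simple_effects$significant[i]) " *" else ""))
  }
  invisible(x)
}
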