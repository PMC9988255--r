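#' Parameters of the factorial behavioral-data generator
#'
#' Emulates an outcome-devaluation test table: a mixed factorial design
#' with between-subject factors (e.g. group: Pre/Post; treatment: CTL/SAP)
#' and one within-subject factor (e.g. devaluation: Ndev/Dev), response in
#' lever presses per minute. Responses follow a Gaussian cell-means model:
#' baseline + subject random effect + cell effect + residual, matching the
#' assumptions of the contrast analysis. A devaluation effect (a reduction
#' of responding on the devalued lever) can be injected into designated
#' between-subject cells only, producing the interaction patterns seen in
#' devaluation experiments.
#'
#' @param n_per_cell subjects per between-subject cell, >= 2.
#' @param between_factors named list of between-subject factors, each a
#'   character vector of levels.
#' @param within_factor named list of length 1: the within-subject factor
#'   and its levels.
#' @param baseline_rate grand mean response (presses/min).
#' @param devaluation_effect reduction (presses/min) applied to
#'   `effect_level` of the within factor.
#' @param effect_level within level receiving the effect; default the last
#'   level (conventionally "Dev").
#' @param effect_in `NULL` to apply the effect in all cells, or a named
#'   list restricting it, e.g. `list(treatment = "CTL")`.
#' @param subject_sd SD of the subject random effect.
#' @param residual_sd SD of the residual noise per observation.
#' @param seed integer; fixes the table exactly.
#' @return An object of class `behavior_sim_params`.
#' @export
behavior_sim_params <- function(n_per_cell = 14L,
                                between_factors = list(group = c("Pre", "Post"),
                                                       treatment = c("CTL", "SAP")),
                                within_factor = list(devaluation = c("Ndev", "Dev")),
                                baseline_rate = 10,
                                devaluation_effect = 0,
                                effect_level = NULL,
                                effect_in = NULL,
                                subject_sd = 2,
                                residual_sd = 2.5,
                                seed = 1L) {
  if (n_per_cell < 2)
    stop("`n_per_cell` must be >= 2 (no within-cell variance otherwise)", call. = FALSE)
  if (subject_sd < 0 || residual_sd < 0)
    stop("standard deviations must be >= 0", call. = FALSE)
  if (length(within_factor) != 1L || is.null(names(within_factor)))
    stop("`within_factor` must be a named list of length 1", call. = FALSE)
  if (is.null(effect_level)) effect_level <- utils::tail(within_factor[[1]], 1)
  if (!effect_level %in% within_factor[[1]])
    stop("`effect_level` is not a level of the within factor", call. = FALSE)
  structure(as.list(environment()), class = "behavior_sim_params")
}

#' Generate a factorial behavioral table
#'
#' One response per subject x within-level; negative draws are truncated
#' at 0 (rates are non-negative) and the number of truncations is recorded
#' in the `n_truncated` attribute.
#'
#' @param params a [behavior_sim_params()].
#' @return Long-format data frame with columns `subject`, one column per
#'   between factor, the within factor column, and `response`.
#' @export
generate_behavior_table <- function(params = behavior_sim_params()) {
  stopifnot(inherits(params, "behavior_sim_params"))
  with_seed(params$seed, {
    cells <- expand.grid(params$between_factors, stringsAsFactors = FALSE)
    wname <- names(params$within_factor)
    wlev <- params$within_factor[[1]]
    rows <- list()
    sid <- 0L
    for (ci in seq_len(nrow(cells))) {
      in_effect <- is.null(params$effect_in) ||
        all(vapply(names(params$effect_in), function(f)
          cells[ci, f] %in% params$effect_in[[f]], logical(1)))
      for (s in seq_len(params$n_per_cell)) {
        sid <- sid + 1L
        subj_eff <- rnorm(1, 0, params$subject_sd)
        mu <- params$baseline_rate + subj_eff -
          ifelse(wlev == params$effect_level & in_effect,
                 params$devaluation_effect, 0)
        resp <- mu + rnorm(length(wlev), 0, params$residual_sd)
        row <- cells[rep(ci, length(wlev)), , drop = FALSE]
        row$subject <- sprintf("S%03d", sid)
        row[[wname]] <- wlev
        row$response <- resp
        rows[[length(rows) + 1L]] <- row
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out <- out[c("subject", names(params$between_factors), wname, "response")]
    n_trunc <- sum(out$response < 0)
    out$response <- pmax(out$response, 0)
    attr(out, "n_truncated") <- n_trunc
    out
  })
}

#' Session schedule for operant training
#'
#' Encodes one daily instrumental session: each of the two levers is
#' presented twice in alternation; a presentation ends after
#' `presentation_cap_min` minutes or `outcome_cap` earned outcomes,
#' whichever comes first, with a fixed inter-trial interval. Reinforcement
#' probability per press is 1 (FR1), 1/5 (RR5), 1/10 (RR10) or 1/20 (RR20).
#'
#' @param stage `"FR1"`, `"RR5"`, `"RR10"` or `"RR20"`.
#' @return An object of class `session_schedule`.
#' @export
session_schedule <- function(stage = c("FR1", "RR5", "RR10", "RR20")) {
  stage <- match.arg(stage)
  ratio <- c(FR1 = 1, RR5 = 5, RR10 = 10, RR20 = 20)[[stage]]
  structure(list(stage = stage, ratio = ratio,
                 presentations_per_lever = 2L, levers = c("A1", "A2"),
                 presentation_cap_min = 10, outcome_cap = 20L, iti_min = 2.5),
            class = "session_schedule")
}

#' Simulate one operant training session
#'
#' Presses arrive as a Poisson process at `press_rate`; each press is
#' reinforced with the stage's ratio probability; a presentation ends at
#' the time or outcome cap, whichever comes first.
#'
#' @param schedule a [session_schedule()].
#' @param press_rate presses per minute, > 0.
#' @param seed integer seed.
#' @return Data frame with one row per lever presentation: `presentation`,
#'   `lever`, `presses`, `outcomes`, `duration_min`.
#' @export
simulate_training_session <- function(schedule = session_schedule("RR20"),
                                      press_rate, seed = 1L) {
  stopifnot(inherits(schedule, "session_schedule"))
  if (!is.finite(press_rate) || press_rate <= 0)
    stop("`press_rate` must be positive", call. = FALSE)
  with_seed(seed, {
    n_pres <- schedule$presentations_per_lever * length(schedule$levers)
    lever_seq <- rep(schedule$levers, schedule$presentations_per_lever)
    out <- data.frame(presentation = seq_len(n_pres), lever = lever_seq,
                      presses = 0L, outcomes = 0L,
                      duration_min = schedule$presentation_cap_min)
    for (p in seq_len(n_pres)) {
      t_press <- numeric(0)
      t_last <- 0
      # draw press times in chunks until past the time cap
      while (t_last < schedule$presentation_cap_min) {
        gaps <- rexp(64, rate = press_rate)
        t_press <- c(t_press, t_last + cumsum(gaps))
        t_last <- t_press[length(t_press)]
      }
      t_press <- t_press[t_press <= schedule$presentation_cap_min]
      rewarded <- rbinom(length(t_press), 1L, 1 / schedule$ratio) == 1L
      n_out <- cumsum(rewarded)
      hit_cap <- which(n_out >= schedule$outcome_cap)
      if (length(hit_cap)) {
        end_t <- t_press[hit_cap[1]]
        keep <- t_press <= end_t
        out$duration_min[p] <- end_t
        out$presses[p] <- sum(keep)
        out$outcomes[p] <- schedule$outcome_cap
      } else {
        out$presses[p] <- length(t_press)
        out$outcomes[p] <- if (length(n_out)) n_out[length(n_out)] else 0L
      }
    }
    out
  })
}
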