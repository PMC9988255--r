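bf2 <- list(group = c("Pre", "Post"), treatment = c("CTL", "SAP"))
wf1 <- list(devaluation = c("Ndev", "Dev"))

random_table <- function(n_per_cell, seed, effect = 0) {
  generate_behavior_table(behavior_sim_params(
    n_per_cell = n_per_cell, between_factors = bf2, within_factor = wf1,
    devaluation_effect = effect, seed = seed))
}

cell_weight_vector <- function(spec) {
  as.vector(outer(spec$between_weights, spec$within_weights))
}

test_that("contrast sets enumerate main effects and interactions", {
  s1 <- build_contrast_set(list(treatment = c("CTL", "SAP")), wf1)
  expect_length(s1, 3L)
  expect_setequal(sapply(s1, `[[`, "name"),
                  c("treatment", "devaluation", "treatment x devaluation"))
  s2 <- build_contrast_set(bf2, wf1)
  expect_length(s2, 7L)
  expect_error(build_contrast_set(list(g = c("a", "b", "c")), wf1), "2-level")
})

test_that("every pair of contrasts in a set is orthogonal", {
  specs <- build_contrast_set(bf2, wf1)
  for (i in seq_along(specs)) for (j in seq_along(specs)) {
    if (i >= j) next
    dot <- sum(cell_weight_vector(specs[[i]]) * cell_weight_vector(specs[[j]]))
    expect_equal(dot, 0, tolerance = 1e-12)
  }
})

test_that("all-equal responses give F = 0", {
  tab <- generate_behavior_table(behavior_sim_params(
    n_per_cell = 3, between_factors = bf2, within_factor = wf1,
    subject_sd = 1, residual_sd = 0, seed = 2))
  spec <- build_contrast_set(bf2, wf1)[[1]]  # a between contrast
  # subject_sd > 0 gives a nonzero error term; group means differ only by
  # sampling noise of the subject effects -- use truly equal data instead
  tab$response <- 10
  r <- suppressWarnings(test_contrast(tab, spec))
  expect_equal(r$F, 0)
})

test_that("2-group between contrasts reproduce the pooled t-test (F = t^2)", {
  for (seed in 1:8) {
    tab <- random_table(n_per_cell = 5 + seed %% 3, seed = seed)
    spec <- build_contrast_set(list(treatment = c("CTL", "SAP")), wf1)[[1]]
    tab$group <- NULL
    r <- test_contrast(tab, spec)
    sm <- aggregate(response ~ subject + treatment, tab, mean)
    tt <- t.test(response ~ treatment, sm, var.equal = TRUE)
    expect_equal(r$F, unname(tt$statistic)^2, tolerance = 1e-8)
    expect_equal(r$df2, unname(tt$parameter), tolerance = 1e-12)
  }
})

test_that("between-contrast sums of squares partition the between-cells SS", {
  for (seed in 1:5) {
    tab <- random_table(n_per_cell = 6, seed = 100 + seed)
    specs <- build_contrast_set(bf2, wf1)
    between <- specs[sapply(specs, function(s)
      all(s$factors %in% names(bf2)))]
    ss <- sum(sapply(between, function(s) test_contrast(tab, s)$ss_contrast))
    # oracle: between-cells SS of the subject means
    sm <- aggregate(response ~ subject + group + treatment, tab, mean)
    cellmean <- ave(sm$response, sm$group, sm$treatment)
    ss_cells <- sum((cellmean - mean(sm$response))^2)
    expect_equal(ss, ss_cells, tolerance = 1e-8)
  }
})

test_that("the full mixed analysis agrees with aov on balanced data", {
  tab <- random_table(n_per_cell = 6, seed = 77, effect = 3)
  rep <- analyze_design(tab, bf2, wf1)
  a <- summary(aov(response ~ group * treatment * devaluation +
                     Error(subject / devaluation), tab))
  af <- c(a[["Error: subject"]][[1]]$`F value`[1:3],
          a[["Error: subject:devaluation"]][[1]]$`F value`[1:4])
  names(af) <- c("group", "treatment", "group x treatment", "devaluation",
                 "group x devaluation", "treatment x devaluation",
                 "group x treatment x devaluation")
  for (nm in names(af))
    expect_equal(rep$contrasts$F[rep$contrasts$name == nm], unname(af[nm]),
                 tolerance = 1e-8)
})

test_that("F statistics are invariant to shifting and positive scaling", {
  tab <- random_table(n_per_cell = 5, seed = 9, effect = 2)
  specs <- build_contrast_set(bf2, wf1)
  f0 <- sapply(specs, function(s) test_contrast(tab, s)$F)
  t1 <- tab; t1$response <- t1$response + 137
  t2 <- tab; t2$response <- t2$response * 3.71
  expect_equal(sapply(specs, function(s) test_contrast(t1, s)$F), f0,
               tolerance = 1e-8)
  expect_equal(sapply(specs, function(s) test_contrast(t2, s)$F), f0,
               tolerance = 1e-8)
})

test_that("degenerate inputs are flagged, not silently analysed", {
  tab <- random_table(n_per_cell = 2, seed = 4)
  spec <- build_contrast_set(bf2, wf1)[[1]]
  # zero error variance -> infinite F with a warning
  t0 <- tab; t0$response <- ifelse(t0$treatment == "CTL", 1, 2)
  expect_warning(r <- test_contrast(t0, spec), "zero error variance")
  expect_true(is.infinite(r$F) || r$F == 0)
  # missing cell -> error
  t1 <- tab[tab$treatment == "CTL", ]
  expect_error(test_contrast(t1, spec), "empty between cell")
  # single subject per cell -> no error df
  t2 <- tab[tab$subject %in% sprintf("S%03d", c(1, 3, 5, 7)), ]
  expect_error(test_contrast(t2, spec), "degrees of freedom")
  # incomplete within data -> error
  t3 <- tab[-1, ]
  expect_error(test_contrast(t3, spec), "within cell")
})

test_that("simple effects localize an interaction with the pooled error term", {
  # effect delta in CTL only, zero noise apart from a seeded residual
  tab <- generate_behavior_table(behavior_sim_params(
    n_per_cell = 6, between_factors = list(treatment = c("CTL", "SAP")),
    within_factor = wf1, devaluation_effect = 6,
    effect_in = list(treatment = "CTL"), subject_sd = 0, residual_sd = 0,
    seed = 1))
  specs <- build_contrast_set(list(treatment = c("CTL", "SAP")), wf1)
  inter <- specs[[3]]
  se <- suppressWarnings(simple_effects(tab, inter, "treatment"))
  names(se) <- sapply(se, `[[`, "name")
  f_ctl <- se[["devaluation at treatment = CTL"]]
  f_sap <- se[["devaluation at treatment = SAP"]]
  expect_gt(f_ctl$F, 0)
  expect_equal(f_sap$F, 0)
  expect_equal(f_ctl$df2, f_sap$df2)  # pooled error: constant df2

  # with noise: each simple effect equals a hand-built contrast spec
  tabn <- generate_behavior_table(behavior_sim_params(
    n_per_cell = 6, between_factors = list(treatment = c("CTL", "SAP")),
    within_factor = wf1, devaluation_effect = 4,
    effect_in = list(treatment = "CTL"), seed = 8))
  sen <- simple_effects(tabn, specs[[3]], "treatment")
  hand <- structure(list(
    name = "hand", factors = "devaluation",
    between_factors = list(treatment = c("CTL", "SAP")), within_factors = wf1,
    between_weights = c(CTL = 1, SAP = 0),
    within_weights = c(Ndev = -1, Dev = 1), alpha = 0.05),
    class = "contrast_spec")
  expect_equal(sen[[1]]$F, test_contrast(tabn, hand)$F, tolerance = 1e-10)
  expect_equal(sen[[1]]$df2, test_contrast(tabn, hand)$df2)

  expect_error(simple_effects(tab, specs[[1]], "treatment"), "no other factor")
  expect_error(simple_effects(tab, inter, "region"), "does not involve")
})

test_that("symmetric noiseless interactions yield identical simple effects", {
  tab <- generate_behavior_table(behavior_sim_params(
    n_per_cell = 4, between_factors = list(treatment = c("CTL", "SAP")),
    within_factor = wf1, devaluation_effect = 3, subject_sd = 1,
    residual_sd = 0, seed = 12))  # same effect in every cell: no interaction
  specs <- build_contrast_set(list(treatment = c("CTL", "SAP")), wf1)
  se <- suppressWarnings(simple_effects(tab, specs[[3]], "treatment"))
  expect_equal(se[[1]]$F, se[[2]]$F, tolerance = 1e-10)
})

test_that("linear-trend contrasts recover a trend across ordered levels", {
  days <- sprintf("d%02d", 1:6)
  set.seed(5)
  subj <- sprintf("S%02d", 1:10)
  tab <- expand.grid(subject = subj, day = days, stringsAsFactors = FALSE)
  tab$response <- 2 + 0.8 * as.integer(substring(tab$day, 2)) +
    rnorm(nrow(tab), 0, 0.5)
  spec <- linear_trend_contrast(list(day = days))
  r <- test_contrast(tab, spec)
  expect_equal(r$df1, 1L)
  expect_equal(r$df2, length(subj) - 1L)
  expect_lt(r$p, 0.001)
  # no trend -> rarely significant
  tab$response <- rnorm(nrow(tab))
  expect_gt(test_contrast(tab, spec)$p, 1e-4)
})
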