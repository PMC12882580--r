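# Participant feature tables, discriminatory-feature selection and the
# KNN / random-forest / linear-SVM grid.

# minimal per-trial feature + covariate fixture for table building
make_trial_features <- function(n_per_group = 6, seed = 30) {
  set.seed(seed)
  shapes <- c("clover", "petals", "ellipse", "rounded_square")
  dvs <- c("speed", "acceleration", "jerk", "min_speed", "max_speed",
           "submovement_pct", "speed_modulation", "sparc", "error_px")
  grid <- tidyr::expand_grid(
    group = c("ASD", "PD", "CTRL"),
    idx = seq_len(n_per_group),
    day = 1:2, shape = shapes, trial = 1:2
  ) |>
    dplyr::mutate(participant_id = paste0(group, idx))
  for (dv in dvs) grid[[dv]] <- rnorm(nrow(grid))
  covars <- grid |>
    dplyr::distinct(participant_id, group) |>
    dplyr::mutate(age = rnorm(dplyr::n(), 59, 9),
                  gender = "F",
                  aq = rnorm(dplyr::n(), 20, 8),
                  raads = rnorm(dplyr::n(), 15, 8),
                  updrs = abs(rnorm(dplyr::n(), 5, 4)),
                  phq = abs(rnorm(dplyr::n(), 6, 4)),
                  gad = abs(rnorm(dplyr::n(), 6, 4)))
  rt <- covars |>
    dplyr::select(participant_id, group) |>
    tidyr::expand_grid(day = 1:2) |>
    dplyr::mutate(reaction_time = 0.5 + abs(rnorm(dplyr::n(), 0.1, 0.05)))
  list(features = grid, covariates = covars, rt = rt)
}

test_that("the participant table carries a 37-column kinematic block", {
  fx <- make_trial_features()
  tab <- build_feature_table(fx$features, fx$covariates, fx$rt)
  kin <- attr(tab, "kinematic_columns")
  expect_length(kin, 37)
  expect_true("reaction_time" %in% kin)
  expect_equal(nrow(tab), 18)
  # residualized columns are orthogonal to the covariates
  for (cl in c(kin[1], "aq", "updrs")) {
    expect_lt(abs(cor(tab[[cl]], tab$age)), 1e-9)
    expect_lt(abs(cor(tab[[cl]], tab$depression)), 1e-9)
  }
  expect_identical(tab$label_clinical,
                   as.integer(tab$group %in% c("ASD", "PD")))
})

test_that("participant-shape averages match a hand computation", {
  fx <- make_trial_features(seed = 31)
  tab <- build_feature_table(fx$features, fx$covariates, fx$rt)
  # oracle: average of that participant's clover speed over trials and days,
  # then residualize the whole column the same way
  manual_means <- fx$features |>
    dplyr::filter(shape == "clover") |>
    dplyr::group_by(participant_id) |>
    dplyr::summarise(m = mean(speed), .groups = "drop")
  joined <- tibble::tibble(participant_id = tab$participant_id) |>
    dplyr::left_join(manual_means, by = "participant_id") |>
    dplyr::left_join(
      dplyr::select(fx$covariates, participant_id, age, phq, gad),
      by = "participant_id")
  manual_resid <- resid(lm(m ~ age + phq + gad, joined))
  expect_equal(tab$speed__clover, unname(manual_resid), tolerance = 1e-9)
})

test_that("missing whole-shape cells are imputed with the pooled mean", {
  fx <- make_trial_features(seed = 32)
  fx$features <- fx$features |>
    dplyr::filter(!(participant_id == "ASD1" & shape == "petals"))
  tab <- build_feature_table(fx$features, fx$covariates, fx$rt)
  expect_true(all(is.finite(tab$speed__petals)))
  expect_true("speed__petals" %in% names(attr(tab, "imputed_cells")))
})

test_that("the selection rule reproduces the reported discriminatory pattern", {
  shapes <- c("clover", "petals", "ellipse", "rounded_square")
  contrasts <- dplyr::bind_rows(
    # sub-movements: pairwise main effect between ASD and PD
    tibble::tibble(dv = "submovement_pct", group1 = "ASD", group2 = "PD",
                   level = "pairwise_main", shape = NA, p.value = 0.035),
    # speed modulation: interaction, rounded square only
    tibble::tibble(dv = "speed_modulation", group1 = "ASD", group2 = "PD",
                   level = c("pairwise_main", "pairwise_interaction",
                             "per_shape"),
                   shape = c(NA, NA, "rounded_square"),
                   p.value = c(0.4, 0.001, 0.02)),
    # reaction time: group effect
    tibble::tibble(dv = "reaction_time", group1 = "ASD", group2 = "PD",
                   level = "pairwise_main", shape = NA, p.value = 0.009)
  )
  sel <- select_discriminatory_features(contrasts, "ASD_vs_PD")
  expect_setequal(sel, c(paste("submovement_pct", shapes, sep = "__"),
                         "speed_modulation__rounded_square",
                         "reaction_time"))
  # all-null report selects nothing
  null_rep <- dplyr::mutate(contrasts, p.value = 0.9)
  expect_length(select_discriminatory_features(null_rep, "ASD_vs_PD"), 0)
  # an interaction-only effect on one shape selects exactly one column
  one <- tibble::tibble(dv = "sparc", group1 = "ASD", group2 = "PD",
                        level = c("pairwise_main", "pairwise_interaction",
                                  "per_shape"),
                        shape = c(NA, NA, "petals"),
                        p.value = c(0.6, 0.01, 0.03))
  expect_equal(select_discriminatory_features(one, "ASD_vs_PD"),
               "sparc__petals")
  # clinical task unions the two control contrasts, not ASD-vs-PD
  clin <- dplyr::bind_rows(
    tibble::tibble(dv = "speed", group1 = "ASD", group2 = "CTRL",
                   level = "pairwise_main", shape = NA, p.value = 0.01),
    tibble::tibble(dv = "jerk", group1 = "CTRL", group2 = "PD",
                   level = "pairwise_main", shape = NA, p.value = 0.04),
    tibble::tibble(dv = "sparc", group1 = "ASD", group2 = "PD",
                   level = "pairwise_main", shape = NA, p.value = 0.001)
  )
  sel_clin <- select_discriminatory_features(clin, "clinical_vs_nonclinical")
  expect_setequal(sel_clin, c(paste("speed", shapes, sep = "__"),
                              paste("jerk", shapes, sep = "__")))
  # pure function of the report
  expect_identical(select_discriminatory_features(clin,
                                                  "clinical_vs_nonclinical"),
                   sel_clin)
})

# participant table with a controllable class separation
make_sep_table <- function(sep, n = 12, seed = 33, n_noise = 0) {
  set.seed(seed)
  tab <- tibble::tibble(
    participant_id = c(paste0("ASD", 1:n), paste0("PD", 1:n),
                       paste0("CTRL", 1:n)),
    group = rep(c("ASD", "PD", "CTRL"), each = n),
    f1 = rnorm(3 * n) + rep(c(sep, 0, 0), each = n),
    f2 = rnorm(3 * n) + rep(c(0, sep, 0), each = n)
  )
  for (k in seq_len(n_noise)) tab[[paste0("noise", k)]] <- rnorm(3 * n)
  tab$label_clinical <- as.integer(tab$group %in% c("ASD", "PD"))
  tab
}

test_that("widely separated classes are classified perfectly", {
  tab <- make_sep_table(10)
  res <- run_classifiers(tab, c("f1", "f2"), task = "ASD_vs_PD",
                         split_seed = 1)
  expect_equal(res$accuracy_knn, 1)
  expect_equal(res$accuracy_rf, 1)
  expect_equal(res$accuracy_svm, 1)
  expect_equal(res$mean_accuracy, 1)
})

test_that("results are deterministic for a fixed split seed", {
  tab <- make_sep_table(1.5)
  r1 <- run_classifiers(tab, c("f1", "f2"), task = "clinical_vs_nonclinical",
                        split_seed = 7)
  r2 <- run_classifiers(tab, c("f1", "f2"), task = "clinical_vs_nonclinical",
                        split_seed = 7)
  expect_identical(r1, r2)
})

test_that("permuted labels perform at chance", {
  accs <- vapply(1:50, function(i) {
    tab <- make_sep_table(8, seed = 400 + i)
    set.seed(500 + i)
    tab$group <- sample(tab$group)          # break the signal
    tab$label_clinical <- as.integer(tab$group %in% c("ASD", "PD"))
    run_classifiers(tab, c("f1", "f2"), task = "ASD_vs_PD",
                    split_seed = i)$mean_accuracy
  }, numeric(1))
  # chance = majority-class rate of the 2/2 or 3/2 test split
  chance <- 0.5
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - chance), 3 * se + 0.02)
})

test_that("pure-noise columns do not break a separable problem", {
  tab <- make_sep_table(10, n_noise = 5)
  clean <- run_classifiers(tab, c("f1", "f2"), task = "ASD_vs_PD",
                           split_seed = 3)
  noisy <- run_classifiers(tab, c("f1", "f2", paste0("noise", 1:5)),
                           task = "ASD_vs_PD", split_seed = 3)
  expect_lte(abs(noisy$accuracy_svm - clean$accuracy_svm), 0.25)
  expect_true(all(unlist(noisy[, c("accuracy_knn", "accuracy_rf",
                                   "accuracy_svm")]) <= 1))
})

test_that("the standard grid produces 22 ordered results", {
  fx <- make_trial_features(seed = 34)
  tab <- build_feature_table(fx$features, fx$covariates, fx$rt)
  disc <- list(
    clinical_vs_nonclinical = c("speed__clover", "reaction_time"),
    ASD_vs_PD = c("submovement_pct__petals")
  )
  grid <- run_model_grid(tab, disc, split_seed = 2,
                         rf_grid = c(100, 200))
  expect_equal(nrow(grid), 22)
  expect_equal(length(unique(grid$feature_set)), 11)
  expect_equal(length(unique(grid$task)), 2)
  expect_true(all(grid$mean_accuracy >= 0 & grid$mean_accuracy <= 1,
                  na.rm = TRUE))
  # within each task, rows are ordered by descending mean accuracy
  for (tk in unique(grid$task)) {
    m <- grid$mean_accuracy[grid$task == tk]
    expect_true(all(diff(m[!is.na(m)]) <= 1e-12))
  }
  # empty discriminatory set is skipped with a warning, not an error
  expect_warning(
    g2 <- run_model_grid(tab, list(clinical_vs_nonclinical = character(),
                                   ASD_vs_PD = "speed__clover"),
                         split_seed = 2, rf_grid = 100),
    "empty discriminatory"
  )
  expect_equal(nrow(g2), 22)
  expect_true(any(is.na(g2$mean_accuracy)))
})
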