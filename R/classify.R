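# Two-stage classification: participant-level feature tables residualized
# on age/depression/anxiety, filter-based discriminatory-feature selection
# from the mixed-model contrasts, and a KNN / random-forest / linear-SVM
# grid over eleven feature sets and two tasks (clinical vs non-clinical,
# ASD vs PD).

#' Build the participant-level feature table
#'
#' Per participant, shape and kinematic feature: the mean over retained
#' trials and days; reaction time averaged across days. Cells missing a
#' whole shape are imputed with the pooled column mean (logged). Every
#' kinematic and questionnaire column is then residualized by ordinary
#' least squares on age, depression and anxiety over the pooled sample.
#'
#' @param features Per-trial feature table (after outlier removal).
#' @param covariates Covariate table (`participant_id`, `group`, `age`,
#'   `aq`, `raads`, `updrs`, `phq`, `gad`).
#' @param rt_scores Per-participant-day reaction-time scores
#'   ([score_reaction_times()] output).
#' @return A `participant_features` tibble: one row per participant with the
#'   37-column kinematic block (attribute `"kinematic_columns"`), residualized
#'   questionnaire columns, and class labels `label_clinical` (ASD/PD = 1,
#'   CTRL = 0) and `group`. Attribute `"imputed_cells"` logs imputations.
#' @export
build_feature_table <- function(features, covariates, rt_scores) {
  dvs <- intersect(.kinematic_dvs, names(features))
  wide <- features |>
    dplyr::group_by(.data$participant_id, .data$shape) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(dvs),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop") |>
    tidyr::pivot_longer(dplyr::all_of(dvs), names_to = "feature") |>
    dplyr::mutate(column = paste(.data$feature, .data$shape, sep = "__")) |>
    dplyr::select("participant_id", "column", "value") |>
    tidyr::pivot_wider(names_from = "column", values_from = "value")
  rt <- rt_scores |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(reaction_time = mean(.data$reaction_time),
                     .groups = "drop")
  tab <- covariates |>
    dplyr::select("participant_id", "group", "age", "gender",
                  "aq", "raads", "updrs", "phq", "gad") |>
    dplyr::rename(depression = "phq", anxiety = "gad") |>
    dplyr::left_join(wide, by = "participant_id") |>
    dplyr::left_join(rt, by = "participant_id")
  kin_cols <- c(setdiff(names(wide), "participant_id"), "reaction_time")
  q_cols <- c("aq", "raads", "updrs")

  imputed <- list()
  for (cl in c(kin_cols, q_cols)) {
    miss <- !is.finite(tab[[cl]])
    if (any(miss)) {
      imputed[[cl]] <- tab$participant_id[miss]
      tab[[cl]][miss] <- mean(tab[[cl]][!miss])
    }
  }
  for (cl in c(kin_cols, q_cols)) {
    tab[[cl]] <- as.numeric(resid(lm(tab[[cl]] ~ age + depression + anxiety,
                                     data = tab)))
  }
  tab$label_clinical <- as.integer(tab$group %in% c("ASD", "PD"))
  structure(
    tab,
    kinematic_columns = kin_cols,
    questionnaire_columns = q_cols,
    imputed_cells = imputed,
    class = c("participant_features", class(tab))
  )
}

#' Select discriminatory kinematic features from mixed-model reports
#'
#' Applies the filter rule: for a pairwise comparison, a DV with a
#' significant pairwise group main effect contributes its columns for all
#' four shapes; a DV with only a significant group-by-shape interaction
#' contributes the columns of the specific shapes whose per-shape contrast
#' is significant; reaction time is included when its pairwise group effect
#' is significant. For the clinical-vs-non-clinical task the selection is
#' the union of the ASD-vs-CTRL and PD-vs-CTRL selections (ASD-vs-PD-only
#' differences are excluded since those groups share a class).
#'
#' @param contrasts Contrast report: tibble with columns `dv`, `group1`,
#'   `group2`, `level` (`pairwise_main`, `pairwise_interaction`,
#'   `per_shape`), `shape`, `p.value` (e.g. rows of [followup_contrasts()]
#'   results bound over DVs, plus `pairwise_main` rows for
#'   `dv = "reaction_time"`).
#' @param comparison `"ASD_vs_PD"` or `"clinical_vs_nonclinical"`.
#' @param shapes Shape names making up "all shapes".
#' @param alpha Significance threshold.
#' @return Character vector of selected feature-table columns
#'   (`feature__shape`, possibly `reaction_time`); empty when no DV
#'   discriminates.
#' @export
select_discriminatory_features <- function(contrasts,
                                           comparison = c("ASD_vs_PD",
                                                          "clinical_vs_nonclinical"),
                                           shapes = c("clover", "petals",
                                                      "ellipse",
                                                      "rounded_square"),
                                           alpha = 0.05) {
  comparison <- match.arg(comparison)
  pairs <- if (comparison == "ASD_vs_PD") {
    list(c("ASD", "PD"))
  } else {
    list(c("ASD", "CTRL"), c("CTRL", "PD"))
  }
  sel <- character()
  for (pr in pairs) {
    cc <- contrasts[(contrasts$group1 %in% pr) & (contrasts$group2 %in% pr) &
                      contrasts$group1 != contrasts$group2, ]
    for (dv in unique(cc$dv)) {
      d <- cc[cc$dv == dv, ]
      if (dv == "reaction_time") {
        if (any(d$level == "pairwise_main" & d$p.value < alpha, na.rm = TRUE)) {
          sel <- union(sel, "reaction_time")
        }
        next
      }
      main_sig <- any(d$level == "pairwise_main" & d$p.value < alpha,
                      na.rm = TRUE)
      if (main_sig) {
        sel <- union(sel, paste(dv, shapes, sep = "__"))
      } else {
        int_sig <- any(d$level == "pairwise_interaction" & d$p.value < alpha,
                       na.rm = TRUE)
        if (int_sig) {
          sh <- d$shape[d$level == "per_shape" & d$p.value < alpha]
          sh <- sh[!is.na(sh)]
          if (length(sh)) sel <- union(sel, paste(dv, sh, sep = "__"))
        }
      }
    }
  }
  sel
}

.stratified_split <- function(labels, test_frac, seed) {
  set.seed(seed)
  test <- integer(0)
  for (lv in unique(labels)) {
    ii <- which(labels == lv)
    n_test <- max(1L, round(test_frac * length(ii)))
    test <- c(test, sample(ii, n_test))
  }
  sort(test)
}

.tune_knn <- function(x, y, grid, folds, seed) {
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), nrow(x)))
  acc <- vapply(grid, function(k) {
    mean(vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      if (length(unique(y[tr])) < 2 || k > sum(tr)) return(NA_real_)
      pred <- class::knn(x[tr, , drop = FALSE], x[!tr, , drop = FALSE],
                         y[tr], k = k)
      mean(pred == y[!tr])
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  grid[which.max(acc)]
}

.tune_rf <- function(x, y, grid, seed) {
  set.seed(seed)
  oob <- vapply(grid, function(nt) {
    fit <- randomForest::randomForest(x, y, ntree = nt)
    mean(fit$predicted == y)
  }, numeric(1))
  grid[which.max(oob)]
}

#' Run the three classifiers on one feature set
#'
#' Stratified 80/20 split of participants; predictors standardized on
#' training statistics; KNN with the neighbour count tuned on the training
#' portion by cross-validation (grid 1..10), random forest with the tree
#' count tuned on its out-of-bag accuracy (grid 100..500), and a
#' linear-kernel SVM. Per-method test accuracy and their mean are reported.
#'
#' @param table A `participant_features` table.
#' @param feature_set Character vector of predictor columns.
#' @param task `"clinical_vs_nonclinical"` or `"ASD_vs_PD"`.
#' @param split_seed Seed controlling the split and tuning.
#' @param knn_grid,rf_grid Hyperparameter grids.
#' @param cv_folds Folds for KNN tuning.
#' @param test_frac Held-out fraction.
#' @return One-row tibble: task, feature-set size, per-method accuracies,
#'   mean accuracy, tuned hyperparameters, split seed.
#' @export
run_classifiers <- function(table, feature_set,
                            task = c("clinical_vs_nonclinical", "ASD_vs_PD"),
                            split_seed = 1L,
                            knn_grid = 1:10,
                            rf_grid = seq(100, 500, by = 100),
                            cv_folds = 5,
                            test_frac = 0.2) {
  task <- match.arg(task)
  stopifnot(length(feature_set) > 0, all(feature_set %in% names(table)))
  if (task == "ASD_vs_PD") {
    table <- table[table$group %in% c("ASD", "PD"), ]
    y <- factor(table$group, levels = c("ASD", "PD"))
  } else {
    y <- factor(table$label_clinical, levels = c(0, 1))
  }
  if (min(table(y)) < 5) abort("need at least 5 participants per class")
  x <- as.matrix(table[, feature_set, drop = FALSE])

  seed <- split_seed
  for (try in 1:25) {
    test_ix <- .stratified_split(as.character(y), test_frac, seed)
    tr_ix <- setdiff(seq_len(nrow(x)), test_ix)
    if (length(unique(y[tr_ix])) == 2 && length(unique(y[test_ix])) == 2) break
    seed <- seed + 1L
  }
  mu <- colMeans(x[tr_ix, , drop = FALSE])
  sg <- apply(x[tr_ix, , drop = FALSE], 2, sd)
  sg[!is.finite(sg) | sg == 0] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sg, "/")
  xtr <- xs[tr_ix, , drop = FALSE]; xte <- xs[test_ix, , drop = FALSE]
  ytr <- droplevels(y[tr_ix]); yte <- droplevels(y[test_ix])

  k_best <- .tune_knn(xtr, ytr, knn_grid[knn_grid < length(ytr)],
                      cv_folds, seed)
  set.seed(seed)
  acc_knn <- mean(class::knn(xtr, xte, ytr, k = k_best) == yte)
  nt_best <- .tune_rf(xtr, ytr, rf_grid, seed)
  set.seed(seed)
  rf <- randomForest::randomForest(xtr, ytr, ntree = nt_best)
  acc_rf <- mean(predict(rf, xte) == yte)
  set.seed(seed)
  sv <- e1071::svm(xtr, ytr, kernel = "linear", scale = FALSE)
  acc_svm <- mean(predict(sv, xte) == yte)

  tibble::tibble(
    task = task, n_features = length(feature_set),
    accuracy_knn = acc_knn, accuracy_rf = acc_rf, accuracy_svm = acc_svm,
    mean_accuracy = mean(c(acc_knn, acc_rf, acc_svm)),
    k_selected = k_best, ntree_selected = nt_best,
    split_seed = seed
  )
}

#' Feature-set definitions of the standard classification grid
#'
#' @param table A `participant_features` table.
#' @param disc_sets Named list with elements `clinical_vs_nonclinical` and
#'   `ASD_vs_PD`: the discriminatory column selections (see
#'   [select_discriminatory_features()]).
#' @return Named list of 11 feature sets; discriminatory sets are
#'   task-dependent, so their entries are functions of the task.
#' @export
standard_feature_sets <- function(table, disc_sets) {
  all_kf <- attr(table, "kinematic_columns")
  asd_q <- c("aq", "raads"); pd_q <- "updrs"; asdpd_q <- c(asd_q, pd_q)
  disc <- function(task) disc_sets[[task]]
  list(
    all_KF = function(task) all_kf,
    disc_KF = disc,
    ASD_Q = function(task) asd_q,
    PD_Q = function(task) pd_q,
    ASDPD_Q = function(task) asdpd_q,
    all_KF_ASD_Q = function(task) c(all_kf, asd_q),
    all_KF_PD_Q = function(task) c(all_kf, pd_q),
    all_KF_ASDPD_Q = function(task) c(all_kf, asdpd_q),
    disc_KF_ASD_Q = function(task) union(disc(task), asd_q),
    disc_KF_PD_Q = function(task) union(disc(task), pd_q),
    disc_KF_ASDPD_Q = function(task) union(disc(task), asdpd_q)
  )
}

#' Run the full 2 x 11 classification grid
#'
#' Eleven feature sets (all / discriminatory kinematic features, the three
#' questionnaire sets, and their six combinations) by two tasks.
#'
#' @param table A `participant_features` table.
#' @param disc_sets Named list of discriminatory selections per task.
#' @param split_seed Seed for splits and tuning.
#' @param ... Passed to [run_classifiers()].
#' @return A `classification_grid` tibble of 22 rows (feature sets with an
#'   empty discriminatory selection are skipped with a warning and reported
#'   as `NA` accuracies), ordered within task by descending mean accuracy.
#' @export
run_model_grid <- function(table, disc_sets, split_seed = 1L, ...) {
  sets <- standard_feature_sets(table, disc_sets)
  tasks <- c("clinical_vs_nonclinical", "ASD_vs_PD")
  rows <- list()
  for (task in tasks) {
    for (nm in names(sets)) {
      cols <- sets[[nm]](task)
      if (length(cols) == 0) {
        warn(sprintf("empty discriminatory selection for %s / %s; skipped",
                     task, nm))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          task = task, feature_set = nm, n_features = 0L,
          accuracy_knn = NA_real_, accuracy_rf = NA_real_,
          accuracy_svm = NA_real_, mean_accuracy = NA_real_,
          k_selected = NA_integer_, ntree_selected = NA_real_,
          split_seed = split_seed
        )
        next
      }
      res <- run_classifiers(table, cols, task = task,
                             split_seed = split_seed, ...)
      res$feature_set <- nm
      rows[[length(rows) + 1L]] <- dplyr::relocate(res, "feature_set",
                                                   .after = "task")
    }
  }
  out <- dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$task, dplyr::desc(.data$mean_accuracy))
  class(out) <- c("classification_grid", class(out))
  out
}

#' Heat-map of the classification grid
#'
#' Rows are KNN/RF/SVM and their mean; columns the feature sets ordered by
#' descending mean accuracy; one panel per task.
#'
#' @param object A `classification_grid`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.classification_grid <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(c("accuracy_knn", "accuracy_rf", "accuracy_svm",
                          "mean_accuracy"),
                        names_to = "method", values_to = "accuracy") |>
    dplyr::mutate(
      method = factor(.data$method,
                      levels = c("accuracy_knn", "accuracy_svm",
                                 "accuracy_rf", "mean_accuracy"),
                      labels = c("KNN", "SVM", "RF", "Mean")),
      feature_set = factor(.data$feature_set,
                           levels = unique(.data$feature_set))
    )
  ggplot2::ggplot(long, ggplot2::aes(.data$feature_set, .data$method,
                                     fill = .data$accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$accuracy), "",
                     sprintf("%.2f", .data$accuracy))), size = 3) +
    ggplot2::facet_wrap(~ .data$task, ncol = 1) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2166ac",
                                 limits = c(0, 1), na.value = "grey90") +
    ggplot2::labs(x = "feature set", y = NULL, fill = "test accuracy") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
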