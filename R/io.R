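# File schemas, configuration and the end-to-end pipeline driver. All
# interchange formats are plain delimited text: desk-scale data, diff-able
# fixtures.

.trajectory_schema <- c(
  participant_id = "character", group = "character", day = "numeric",
  block = "numeric", shape = "character", trial = "numeric",
  attempt = "numeric", success = "logical", t_s = "numeric",
  x_px = "numeric", y_px = "numeric"
)

#' Write / read a simulated cohort dataset
#'
#' Writes `trajectories.tsv`, `covariates.tsv`, `schedule.tsv`,
#' `reaction_times.tsv`, one shape file per target curve, and a JSON
#' manifest with the seed and per-file MD5 checksums.
#'
#' @param dataset A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `write_cohort()` returns the manifest invisibly; `read_cohort()`
#'   returns the dataset list.
#' @export
write_cohort <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(trajectories = "trajectories.tsv", covariates = "covariates.tsv",
             schedule = "schedule.tsv", reaction_times = "reaction_times.tsv")
  for (nm in names(files)) {
    readr::write_tsv(dataset[[nm]], file.path(dir, files[[nm]]))
  }
  for (nm in names(dataset$curves)) {
    write_shape(dataset$curves[[nm]], file.path(dir, paste0("shape_", nm, ".tsv")))
  }
  manifest <- dataset$manifest
  all_files <- c(unname(files), paste0("shape_", names(dataset$curves), ".tsv"))
  manifest$checksums <- as.list(tools::md5sum(file.path(dir, all_files)))
  names(manifest$checksums) <- all_files
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  rd <- function(f) readr::read_tsv(file.path(dir, f), show_col_types = FALSE)
  shape_files <- list.files(dir, pattern = "^shape_.*\\.tsv$")
  curves <- lapply(file.path(dir, shape_files), read_shape)
  names(curves) <- sub("^shape_(.*)\\.tsv$", "\\1", shape_files)
  list(
    trajectories = rd("trajectories.tsv"),
    covariates = rd("covariates.tsv"),
    schedule = rd("schedule.tsv"),
    reaction_times = rd("reaction_times.tsv"),
    curves = curves,
    manifest = jsonlite::read_json(file.path(dir, "manifest.json"))
  )
}

#' Validate a trajectory table against the interchange schema
#'
#' Checks column presence (order-insensitive), types, and per-trial
#' timestamp monotonicity. Report-based: never raises.
#'
#' @param x A data frame or a path to a delimited text file.
#' @return List: `pass` (logical) and `problems` (tibble with `check`,
#'   `detail`, `row` of the first offence per check).
#' @export
validate_trajectory_schema <- function(x) {
  if (is.character(x)) {
    x <- tryCatch(readr::read_tsv(x, show_col_types = FALSE),
                  error = function(e) NULL)
    if (is.null(x)) {
      return(list(pass = FALSE, problems = tibble::tibble(
        check = "readable", detail = "file could not be parsed",
        row = NA_integer_)))
    }
  }
  probs <- list()
  missing_cols <- setdiff(names(.trajectory_schema), names(x))
  if (length(missing_cols)) {
    probs[[length(probs) + 1L]] <- tibble::tibble(
      check = "columns",
      detail = paste("missing:", paste(missing_cols, collapse = ", ")),
      row = NA_integer_)
  } else {
    for (cl in names(.trajectory_schema)) {
      want <- .trajectory_schema[[cl]]
      ok <- switch(want,
                   character = is.character(x[[cl]]),
                   numeric = is.numeric(x[[cl]]),
                   logical = is.logical(x[[cl]]))
      if (!ok) {
        probs[[length(probs) + 1L]] <- tibble::tibble(
          check = "type", detail = sprintf("%s is not %s", cl, want),
          row = NA_integer_)
      }
    }
    if (is.numeric(x$t_s)) {
      bad <- x |>
        dplyr::mutate(.row = dplyr::row_number()) |>
        dplyr::group_by(.data$participant_id, .data$day, .data$shape,
                        .data$trial) |>
        dplyr::filter(dplyr::row_number() > 1 &
                        .data$t_s < dplyr::lag(.data$t_s)) |>
        dplyr::ungroup()
      if (nrow(bad)) {
        probs[[length(probs) + 1L]] <- tibble::tibble(
          check = "monotone_t", detail = "t_s decreases within a trial",
          row = bad$.row[1])
      }
    }
  }
  list(pass = length(probs) == 0,
       problems = if (length(probs)) dplyr::bind_rows(probs) else
         tibble::tibble(check = character(), detail = character(),
                        row = integer()))
}

#' Analysis run configuration
#'
#' Every tunable of the analysis chain in one validated list. Unknown keys
#' are rejected; the effective configuration is echoed into every report.
#'
#' @param ... Overrides of the defaults (see the returned list's names).
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  defaults <- list(
    rate_hz = 60,
    sg_window = 11,
    sg_polyorder = 3,
    sparc_omega_c = 20,
    sparc_amp_threshold = 0.05,
    sparc_pad_level = 4,
    sparc_min_element_s = 0.25,
    outlier_k = 2,
    rt_outlier_k = 2,
    min_traces = 2.5,
    min_speed_px_s = 200,
    grace_s = 5,
    timeout_s = 90,
    deviation_frac = 0.15,
    device_px_per_mm = device_scale_px_per_mm(),
    single_day = FALSE,
    alpha = 0.05,
    split_seed = 1L,
    knn_grid = 1:10,
    rf_grid = seq(100, 500, by = 100),
    cv_folds = 5,
    dvs = .kinematic_dvs
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown)) {
    abort(paste("unknown config keys:", paste(unknown, collapse = ", ")))
  }
  structure(modifyList(defaults, dots), class = "run_config")
}

#' Run the full analysis pipeline on a cohort dataset
#'
#' Preprocessing, per-trial feature extraction, outlier removal and
#' transforms, the omnibus and follow-up mixed models per dependent
#' variable, BIC-approximated Bayes factors for null group effects, the
#' discriminatory-feature selection, and the 2 x 11 classification grid.
#'
#' @param dataset A [simulate_cohort()] result or a directory written by
#'   [write_cohort()].
#' @param config A [run_config()].
#' @param out_dir Optional directory for the tabular report files.
#' @return List of reports: `qc`, `features`, `removal_fractions`,
#'   `lmm` (per-DV `kin_lmm`s), `contrasts`, `bayes_factors`,
#'   `participant_table`, `disc_sets`, `grid`, and the echoed `config`.
#' @export
analyze_cohort <- function(dataset, config = run_config(), out_dir = NULL) {
  if (is.character(dataset)) dataset <- read_cohort(dataset)
  curves <- dataset$curves

  pre <- preprocess_trials(dataset$trajectories, curves,
                           rate_hz = config$rate_hz,
                           min_traces = config$min_traces,
                           min_speed_px_s = config$min_speed_px_s,
                           grace_s = config$grace_s,
                           timeout_s = config$timeout_s)
  feats <- extract_cohort_features(pre$clean, curves,
                                   window = config$sg_window,
                                   polyorder = config$sg_polyorder,
                                   sparc_cfg = list(
                                     omega_c = config$sparc_omega_c,
                                     amp_threshold = config$sparc_amp_threshold,
                                     pad_level = config$sparc_pad_level,
                                     min_element_s = config$sparc_min_element_s),
                                   features = config$dvs)
  feats <- feats |>
    dplyr::left_join(dplyr::select(dataset$covariates, "participant_id",
                                   "age", depression = "phq",
                                   anxiety = "gad"),
                     by = "participant_id") |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(trial_number = dplyr::row_number()) |>
    dplyr::ungroup()

  screened <- remove_outliers(feats, features = config$dvs,
                              k = config$outlier_k)
  removal <- attr(screened, "removal_fractions")
  analysis <- transform_features(screened, features = config$dvs)

  rt_scores <- score_reaction_times(dataset$reaction_times,
                                    k = config$rt_outlier_k)
  rt_tab <- rt_scores |>
    dplyr::left_join(dplyr::select(dataset$covariates, "participant_id",
                                   "age", depression = "phq",
                                   anxiety = "gad"),
                     by = "participant_id")

  lmms <- list(); contrasts <- list(); bfs <- list()
  for (dv in config$dvs) {
    fit <- fit_lmm(analysis, dv, "kinematic", single_day = config$single_day)
    lmms[[dv]] <- fit
    ctr <- followup_contrasts(analysis, dv, fit, alpha = config$alpha,
                              single_day = config$single_day)
    if (nrow(ctr)) ctr$dv <- dv
    contrasts[[dv]] <- ctr
    if (!isTRUE(.term_p(fit, "group") < config$alpha)) {
      bfs[[dv]] <- tibble::tibble(
        dv = dv, bf01 = bayes_factor_group(analysis, dv, "kinematic",
                                           single_day = config$single_day)$bf01,
        method = "BIC-approximation")
    }
  }
  rt_fit <- fit_lmm(rt_tab, "reaction_time", "reaction_time",
                    single_day = config$single_day)
  lmms$reaction_time <- rt_fit
  rt_ctr <- followup_contrasts(rt_tab, "reaction_time", rt_fit,
                               alpha = config$alpha,
                               single_day = config$single_day)
  if (nrow(rt_ctr)) rt_ctr$dv <- "reaction_time"
  contrasts$reaction_time <- rt_ctr
  contrast_tbl <- dplyr::bind_rows(contrasts)

  ptab <- build_feature_table(screened, dataset$covariates, rt_scores)
  disc_sets <- list(
    clinical_vs_nonclinical = select_discriminatory_features(
      contrast_tbl, "clinical_vs_nonclinical", alpha = config$alpha),
    ASD_vs_PD = select_discriminatory_features(
      contrast_tbl, "ASD_vs_PD", alpha = config$alpha)
  )
  grid <- run_model_grid(ptab, disc_sets, split_seed = config$split_seed,
                         knn_grid = config$knn_grid,
                         rf_grid = config$rf_grid,
                         cv_folds = config$cv_folds)

  reports <- list(
    qc = pre$qc, features = feats, removal_fractions = removal,
    lmm = lmms, contrasts = contrast_tbl,
    bayes_factors = dplyr::bind_rows(bfs),
    participant_table = ptab, disc_sets = disc_sets, grid = grid,
    config = unclass(config)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(reports$qc, file.path(out_dir, "qc_report.tsv"))
    readr::write_tsv(reports$features, file.path(out_dir, "features.tsv"))
    readr::write_tsv(reports$removal_fractions,
                     file.path(out_dir, "outlier_removal.tsv"))
    readr::write_tsv(dplyr::bind_rows(
      purrr::imap(lmms, ~ dplyr::mutate(tidy(.x), dv = .y, .before = 1))),
      file.path(out_dir, "lmm_anova.tsv"))
    readr::write_tsv(reports$contrasts, file.path(out_dir, "contrasts.tsv"))
    readr::write_tsv(reports$bayes_factors,
                     file.path(out_dir, "bayes_factors.tsv"))
    readr::write_tsv(as.data.frame(reports$grid),
                     file.path(out_dir, "classification_grid.tsv"))
    jsonlite::write_json(
      list(config = reports$config,
           disc_sets = reports$disc_sets,
           seed = dataset$manifest$seed),
      file.path(out_dir, "run_config.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  reports
}
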