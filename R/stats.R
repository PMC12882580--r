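# Statistical chain: pooled-SD outlier removal, normalizing transforms and
# z-scoring, cohort-matching tests (raw data or printed summaries),
# effects-coded linear mixed models with Type-III term tests, follow-up
# group contrasts, and BIC-approximated Bayes factors for the group effect.

.kinematic_dvs <- c("speed", "acceleration", "jerk", "min_speed",
                    "max_speed", "submovement_pct", "speed_modulation",
                    "sparc", "error_px")

#' Remove outliers beyond k pooled standard deviations
#'
#' For each feature, the mean and SD are pooled once over all trials of all
#' participants; values further than `k` SDs from the pooled mean are set to
#' missing for that feature (other features of the same trial are kept).
#'
#' @param table Feature table (one row per trial).
#' @param features Feature columns to screen.
#' @param k SD multiplier (default 2).
#' @param reference Optional tibble (`feature`, `mean`, `sd`) fixing the
#'   pooled statistics; by default they are computed from `table`. Removal
#'   is idempotent at a fixed reference.
#' @return `table` with outlying cells set `NA`; attribute
#'   `"removal_fractions"` holds a tibble of per-feature removal fractions.
#' @export
remove_outliers <- function(table, features = intersect(.kinematic_dvs,
                                                        names(table)),
                            k = 2, reference = NULL) {
  fracs <- purrr::map_dbl(features, function(f) {
    x <- table[[f]]
    if (!is.null(reference)) {
      i <- match(f, reference$feature)
      m <- reference$mean[i]
      s <- reference$sd[i]
    } else {
      m <- mean(x, na.rm = TRUE)
      # population SD: the screening rule is a fixed-threshold filter, not
      # an inference, so no n-1 correction is applied
      s <- sqrt(mean((x[!is.na(x)] - m)^2))
    }
    if (!is.finite(s) || s == 0) return(0)
    out <- !is.na(x) & abs(x - m) > k * s
    table[[f]][out] <<- NA_real_
    mean(out[!is.na(x)])
  })
  attr(table, "removal_fractions") <-
    tibble::tibble(feature = features, fraction_removed = fracs)
  table
}

#' Normalizing transforms and z-scoring
#'
#' Applies a natural-log transform to speed, acceleration and jerk, a
#' reciprocal transform to minimum speed, then z-scores every feature
#' column over its retained (non-missing) values. Rows with non-positive
#' values where a log is required get `NA` for that feature.
#'
#' @param table Feature table.
#' @param features Feature columns to z-score.
#' @return Transformed table; attribute `"transform_log"` records the
#'   transform applied per feature and any rows dropped by the log guard.
#' @export
transform_features <- function(table, features = intersect(.kinematic_dvs,
                                                           names(table))) {
  log_vars <- intersect(c("speed", "acceleration", "jerk"), features)
  recip_vars <- intersect("min_speed", features)
  log_rows <- list()
  for (f in log_vars) {
    bad <- !is.na(table[[f]]) & table[[f]] <= 0
    log_rows[[f]] <- sum(bad)
    table[[f]][bad] <- NA_real_
    table[[f]] <- log(table[[f]])
  }
  for (f in recip_vars) {
    bad <- !is.na(table[[f]]) & table[[f]] == 0
    table[[f]][bad] <- NA_real_
    table[[f]] <- 1 / table[[f]]
  }
  for (f in features) {
    x <- table[[f]]
    table[[f]] <- (x - mean(x, na.rm = TRUE)) / sd(x, na.rm = TRUE)
  }
  attr(table, "transform_log") <- tibble::tibble(
    feature = features,
    transform = dplyr::case_when(
      features %in% log_vars ~ "log",
      features %in% recip_vars ~ "reciprocal",
      TRUE ~ "none"
    ),
    rows_dropped = vapply(features, function(f) log_rows[[f]] %||% 0L,
                          numeric(1))
  )
  table
}

# Welch t-test from group summaries (mean, sd, n)
.welch_t <- function(m1, s1, n1, m2, s2, n2) {
  se2 <- s1^2 / n1 + s2^2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  c(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# one-way ANOVA F from group summaries
.anova_f <- function(means, sds, ns) {
  k <- length(means)
  gm <- sum(ns * means) / sum(ns)
  msb <- sum(ns * (means - gm)^2) / (k - 1)
  msw <- sum((ns - 1) * sds^2) / (sum(ns) - k)
  f <- msb / msw
  c(F = f, df1 = k - 1, df2 = sum(ns) - k,
    p = pf(f, k - 1, sum(ns) - k, lower.tail = FALSE))
}

#' Cohort-matching tests
#'
#' One-way ANOVA per continuous covariate with group as a between-participant
#' factor, pairwise Welch t-tests (Welch-Satterthwaite df), and a chi-square
#' test of gender counts. Accepts either raw covariate data or published
#' summary statistics; the summary path computes the identical tests in
#' closed form.
#'
#' @param covariates Either a tibble of raw data (with a `group` column and
#'   the covariates in `vars`), or a summary tibble with columns `group`,
#'   `var`, `mean`, `sd`, `n`.
#' @param vars Covariate columns (raw interface only).
#' @param gender Optional: raw interface, name of the gender column;
#'   summary interface, a groups x categories count matrix.
#' @return List of tibbles `anova`, `pairwise`, and (when gender is given)
#'   `gender`.
#' @export
cohort_compare <- function(covariates, vars = NULL, gender = NULL) {
  if (all(c("var", "mean", "sd", "n") %in% names(covariates))) {
    summ <- covariates
  } else {
    stopifnot(!is.null(vars))
    summ <- covariates |>
      tidyr::pivot_longer(dplyr::all_of(vars), names_to = "var") |>
      dplyr::group_by(.data$group, .data$var) |>
      dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                       sd = sd(.data$value, na.rm = TRUE),
                       n = sum(!is.na(.data$value)), .groups = "drop")
    if (is.character(gender)) {
      gender <- table(covariates$group, covariates[[gender]])
    }
  }
  small <- summ$n < 2
  if (any(small)) {
    warn(paste("excluding groups with n < 2:",
               paste(unique(summ$group[small]), collapse = ", ")))
    summ <- summ[!small, ]
  }
  anova_tbl <- summ |>
    dplyr::group_by(.data$var) |>
    dplyr::group_modify(function(d, key) {
      r <- .anova_f(d$mean, d$sd, d$n)
      tibble::tibble(statistic = r[["F"]], df1 = r[["df1"]],
                     df2 = r[["df2"]], p.value = r[["p"]])
    }) |>
    dplyr::ungroup()
  pairwise_tbl <- summ |>
    dplyr::group_by(.data$var) |>
    dplyr::group_modify(function(d, key) {
      prs <- utils::combn(seq_len(nrow(d)), 2)
      purrr::map_dfr(seq_len(ncol(prs)), function(ci) {
        i <- prs[1, ci]; jj <- prs[2, ci]
        r <- .welch_t(d$mean[i], d$sd[i], d$n[i],
                      d$mean[jj], d$sd[jj], d$n[jj])
        tibble::tibble(group1 = d$group[i], group2 = d$group[jj],
                       statistic = r[["t"]], df = r[["df"]],
                       p.value = r[["p"]])
      })
    }) |>
    dplyr::ungroup()
  out <- list(anova = anova_tbl, pairwise = pairwise_tbl)
  if (!is.null(gender)) {
    ct <- suppressWarnings(stats::chisq.test(as.matrix(gender)))
    out$gender <- tibble::tibble(statistic = unname(ct$statistic),
                                 df = unname(ct$parameter),
                                 p.value = ct$p.value)
  }
  out
}

.as_factors <- function(table, cols) {
  for (cl in intersect(cols, names(table))) {
    if (!is.factor(table[[cl]])) table[[cl]] <- factor(table[[cl]])
  }
  table
}

#' Fit the effects-coded linear mixed model for one dependent variable
#'
#' The kinematic variant fits
#' `dv ~ group * shape + age + depression + anxiety +
#' (1|day) + (1|trial_number) + (1|participant_id)`;
#' the reaction-time variant drops shape and the trial-number intercept.
#' Group and shape use sum-to-zero (effects) coding; estimation is REML and
#' per-term tests are Type-III F tests with Satterthwaite denominator
#' degrees of freedom. Singular random-effect variances are retained at the
#' boundary with a warning flag.
#'
#' @param table Analysis table: the DV plus `group`, `shape`, `age`,
#'   `depression`, `anxiety`, `day`, `trial_number`, `participant_id`.
#' @param dv Name of the dependent-variable column (expected z-scored).
#' @param formula_variant `"kinematic"` or `"reaction_time"`.
#' @param single_day Drop the day random intercept (single-day datasets).
#' @return A `kin_lmm` object: the fitted model, the Type-III `anova` table,
#'   fixed effects with 95% Wald CIs, random-effect variances, and flags.
#' @export
fit_lmm <- function(table, dv,
                    formula_variant = c("kinematic", "reaction_time"),
                    single_day = FALSE) {
  formula_variant <- match.arg(formula_variant)
  table <- .as_factors(table, c("group", "shape", "day", "trial_number",
                                "participant_id"))
  fixed <- if (formula_variant == "kinematic") {
    "group * shape + age + depression + anxiety"
  } else {
    "group + age + depression + anxiety"
  }
  dat <- table[!is.na(table[[dv]]), ]
  rand_grp <- c(if (!single_day && nlevels(droplevels(dat$day)) > 1) "day",
                if (formula_variant == "kinematic") "trial_number",
                "participant_id")
  # random intercepts are only identifiable with fewer levels than rows
  rand_grp <- rand_grp[vapply(rand_grp, function(g) {
    nlevels(droplevels(dat[[g]])) < nrow(dat)
  }, logical(1))]
  n_fac <- if (formula_variant == "kinematic") {
    list(group = stats::contr.sum, shape = stats::contr.sum)
  } else {
    list(group = stats::contr.sum)
  }
  if (length(rand_grp)) {
    rand <- paste0("(1 | ", rand_grp, ")")
    fml <- as.formula(paste(dv, "~", fixed, "+",
                            paste(rand, collapse = " + ")))
    fit <- suppressMessages(suppressWarnings(
      lmerTest::lmer(fml, data = dat, REML = TRUE, contrasts = n_fac)
    ))
    singular <- lme4::isSingular(fit)
    an <- suppressMessages(
      stats::anova(fit, type = 3, ddf = "Satterthwaite"))
    an_tbl <- tibble::tibble(
      term = rownames(an),
      statistic = an[["F value"]],
      df1 = an[["NumDF"]], df2 = an[["DenDF"]],
      p.value = an[["Pr(>F)"]]
    )
    est <- lme4::fixef(fit)
    ci <- suppressMessages(confint(fit, parm = "beta_", method = "Wald"))
    vc <- as.data.frame(lme4::VarCorr(fit))
    ranef_var <- tibble::tibble(grp = vc$grp, variance = vc$vcov)
  } else {
    # no identifiable random term (e.g. single-day reaction times with one
    # score per participant): ordinary least squares with marginal F tests
    fml <- as.formula(paste(dv, "~", fixed))
    fit <- lm(fml, data = dat, contrasts = n_fac)
    singular <- FALSE
    dr <- stats::drop1(fit, test = "F")
    dr <- dr[-1, , drop = FALSE]
    an_tbl <- tibble::tibble(
      term = rownames(dr),
      statistic = dr[["F value"]],
      df1 = dr[["Df"]], df2 = stats::df.residual(fit),
      p.value = dr[["Pr(>F)"]]
    )
    est <- coef(fit)
    ci <- confint(fit)
    ranef_var <- tibble::tibble(grp = character(), variance = numeric())
  }
  fixed_tbl <- tibble::tibble(
    term = names(est), estimate = unname(est),
    conf.low = ci[, 1], conf.high = ci[, 2]
  )
  structure(
    list(model = fit, anova = an_tbl, fixed = fixed_tbl,
         ranef_var = ranef_var,
         dv = dv, formula = fml, variant = formula_variant,
         n = nrow(dat), singular = singular),
    class = "kin_lmm"
  )
}

#' @export
print.kin_lmm <- function(x, ...) {
  cat(sprintf("<kin_lmm> %s (%s variant, n = %d%s)\n", x$dv, x$variant, x$n,
              if (x$singular) ", singular random effects" else ""))
  print(x$anova)
  invisible(x)
}

#' @rdname fit_lmm
#' @param x A `kin_lmm` object.
#' @param effects `"anova"` (Type-III term tests) or `"fixed"` (estimates
#'   with 95% CIs).
#' @param ... Unused.
#' @export
tidy.kin_lmm <- function(x, effects = c("anova", "fixed"), ...) {
  effects <- match.arg(effects)
  if (effects == "anova") x$anova else x$fixed
}

#' @rdname fit_lmm
#' @export
glance.kin_lmm <- function(x, ...) {
  tibble::tibble(
    nobs = x$n,
    sigma = stats::sigma(x$model),
    logLik = as.numeric(logLik(x$model)),
    singular = x$singular
  )
}

.term_p <- function(lmm, term) {
  i <- match(term, lmm$anova$term)
  if (is.na(i)) NA_real_ else lmm$anova$p.value[i]
}

#' Follow-up group contrasts
#'
#' When the omnibus model shows a significant group main effect or
#' group-by-shape interaction (alpha = .05, uncorrected), each group pair is
#' refit as a two-group model; where the pairwise interaction is significant,
#' per-shape two-group models localize the effect. Group coefficients from
#' the two-group effects-coded fits are reported with 95% CIs.
#'
#' @param table Analysis table (as for [fit_lmm()]).
#' @param dv Dependent-variable column.
#' @param lmm The omnibus `kin_lmm` for this DV.
#' @param alpha Significance threshold.
#' @param single_day Passed to the refits.
#' @return Tibble of contrasts: `level` (`pairwise_main`,
#'   `pairwise_interaction`, `per_shape`), `group1`, `group2`, `shape`,
#'   `statistic`, `df1`, `df2`, `p.value`, `estimate`, `conf.low`,
#'   `conf.high`. Empty when nothing to unpack.
#' @export
followup_contrasts <- function(table, dv, lmm, alpha = 0.05,
                               single_day = FALSE) {
  empty <- tibble::tibble(
    level = character(), group1 = character(), group2 = character(),
    shape = character(), statistic = numeric(), df1 = numeric(),
    df2 = numeric(), p.value = numeric(), estimate = numeric(),
    conf.low = numeric(), conf.high = numeric()
  )
  is_rt <- lmm$variant == "reaction_time"
  p_main <- .term_p(lmm, "group")
  p_int <- if (is_rt) NA_real_ else .term_p(lmm, "group:shape")
  if (!(isTRUE(p_main < alpha) || isTRUE(p_int < alpha))) return(empty)

  groups <- sort(unique(as.character(table$group)))
  prs <- utils::combn(groups, 2)
  out <- list()
  grp_row <- function(fit, level, g1, g2, shape, term) {
    i <- match(term, fit$anova$term)
    est_i <- grep("^group", fit$fixed$term)[1]
    tibble::tibble(
      level = level, group1 = g1, group2 = g2, shape = shape,
      statistic = fit$anova$statistic[i], df1 = fit$anova$df1[i],
      df2 = fit$anova$df2[i], p.value = fit$anova$p.value[i],
      estimate = fit$fixed$estimate[est_i],
      conf.low = fit$fixed$conf.low[est_i],
      conf.high = fit$fixed$conf.high[est_i]
    )
  }
  for (ci in seq_len(ncol(prs))) {
    g1 <- prs[1, ci]; g2 <- prs[2, ci]
    sub <- table[table$group %in% c(g1, g2), ]
    sub$group <- droplevels(factor(sub$group))
    pf <- fit_lmm(sub, dv, formula_variant = lmm$variant,
                  single_day = single_day)
    out[[length(out) + 1L]] <- grp_row(pf, "pairwise_main", g1, g2,
                                       NA_character_, "group")
    if (!is_rt) {
      out[[length(out) + 1L]] <- grp_row(pf, "pairwise_interaction", g1, g2,
                                         NA_character_, "group:shape")
      if (isTRUE(.term_p(pf, "group:shape") < alpha)) {
        for (sh in sort(unique(as.character(sub$shape)))) {
          ssub <- sub[sub$shape == sh, ]
          sfit <- fit_lmm(ssub, dv, formula_variant = "reaction_time",
                          single_day = single_day)
          out[[length(out) + 1L]] <- grp_row(sfit, "per_shape", g1, g2, sh,
                                             "group")
        }
      }
    }
  }
  dplyr::bind_rows(out)
}

#' BIC-approximated Bayes factor for the group effect
#'
#' The DV is residualized on age, depression and anxiety by ordinary least
#' squares, then two mixed models (with and without the group term, both
#' retaining shape where applicable and the random intercepts) are fit by
#' maximum likelihood; `BF01 = exp((BIC_with_group - BIC_without) / 2)`
#' quantifies evidence for the no-group-effect null.
#'
#' @param table Analysis table (as for [fit_lmm()]).
#' @param dv Dependent-variable column.
#' @param formula_variant `"kinematic"` or `"reaction_time"`.
#' @param single_day Drop the day random intercept.
#' @return List: `bf01`, `bic_with`, `bic_without`, and
#'   `method = "BIC-approximation"`.
#' @export
bayes_factor_group <- function(table, dv,
                               formula_variant = c("kinematic",
                                                   "reaction_time"),
                               single_day = FALSE) {
  formula_variant <- match.arg(formula_variant)
  table <- .as_factors(table, c("group", "shape", "day", "trial_number",
                                "participant_id"))
  dat <- table[!is.na(table[[dv]]), ]
  rfml <- as.formula(paste(dv, "~ age + depression + anxiety"))
  dat$.resid <- resid(lm(rfml, data = dat))
  rand_grp <- c(if (!single_day && nlevels(droplevels(dat$day)) > 1) "day",
                if (formula_variant == "kinematic") "trial_number",
                "participant_id")
  rand_grp <- rand_grp[vapply(rand_grp, function(g) {
    nlevels(droplevels(dat[[g]])) < nrow(dat)
  }, logical(1))]
  rhs1 <- if (formula_variant == "kinematic") "group + shape" else "group"
  rhs0 <- if (formula_variant == "kinematic") "shape" else "1"
  mk <- function(rhs) {
    as.formula(paste(".resid ~", rhs,
                     if (length(rand_grp)) {
                       paste("+", paste0("(1 | ", rand_grp, ")",
                                         collapse = " + "))
                     } else ""))
  }
  f1 <- mk(rhs1); f0 <- mk(rhs0)
  fit_one <- function(f) {
    tryCatch(suppressMessages(suppressWarnings(
      if (length(rand_grp)) lme4::lmer(f, data = dat, REML = FALSE)
      else lm(f, data = dat))), error = function(e) NULL)
  }
  fit1 <- fit_one(f1)
  fit0 <- fit_one(f0)
  if (is.null(fit1) || is.null(fit0)) {
    return(list(bf01 = NA_real_, bic_with = NA_real_, bic_without = NA_real_,
                method = "BIC-approximation"))
  }
  b1 <- BIC(fit1); b0 <- BIC(fit0)
  list(bf01 = exp((b1 - b0) / 2), bic_with = b1, bic_without = b0,
       method = "BIC-approximation")
}

#' Score the reaction-time task
#'
#' Per participant and day: trials beyond `k` SDs of the participant-level
#' mean are removed, and the mean reaction time of the remaining
#' experimental trials is returned.
#'
#' @param rt Reaction-time table (`participant_id`, `group`, `day`,
#'   `practice`, `rt_s`).
#' @param k Outlier SD multiplier.
#' @return Tibble: one row per participant and day with `reaction_time` (s).
#' @export
score_reaction_times <- function(rt, k = 2) {
  rt |>
    dplyr::filter(!.data$practice) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(.keep_rt = abs(.data$rt_s - mean(.data$rt_s)) <=
                    k * sd(.data$rt_s)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$.keep_rt) |>
    dplyr::group_by(.data$participant_id, .data$group, .data$day) |>
    dplyr::summarise(reaction_time = mean(.data$rt_s), .groups = "drop")
}
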