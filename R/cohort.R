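# Synthetic study generator: three groups (ASD, PD, CTRL) tracing the four
# pure-frequency shapes over two days, plus reaction times and questionnaire
# covariates. The generative kinematic model is the speed-curvature power law
# v = c * kappa^(-beta) with multiplicative band-limited perturbations, the
# minimal model under which the downstream estimators are unbiased.

#' Group-level generative profile
#'
#' @param group Group label: `"ASD"`, `"PD"` or `"CTRL"`.
#' @param beta_gen Speed-modulation exponent of the generative power law
#'   (dimensionless, >= 0).
#' @param base_speed Time-averaged tracing speed in px/s.
#' @param submovement_gain Amplitude multiplier for the band-limited
#'   tangential speed perturbation that produces sub-movements.
#' @param rt_shift Reaction-time shift parameter in seconds.
#' @param rt_sigma Log-scale SD of the lognormal reaction-time component.
#' @param rt_meanlog Log-mean of the lognormal reaction-time component.
#' @param questionnaire_params Named list of `c(mean, sd)` for `aq`, `raads`,
#'   `updrs`, `phq`, `gad`.
#' @param age_params `c(mean, sd)` of age in years.
#' @param gender_counts Named integer vector of gender counts used to set
#'   sampling proportions (e.g. `c(M = 14, F = 16, O = 1)`).
#'
#' @return A `group_profile` list.
#' @export
group_profile <- function(group,
                          beta_gen,
                          base_speed,
                          submovement_gain,
                          rt_shift,
                          rt_sigma = 0.35,
                          rt_meanlog = log(0.12),
                          questionnaire_params,
                          age_params,
                          gender_counts) {
  stopifnot(beta_gen >= 0, base_speed > 0, submovement_gain >= 0,
            rt_sigma >= 0)
  sds <- c(vapply(questionnaire_params, `[`, numeric(1), 2), age_params[2])
  stopifnot(all(sds >= 0))
  structure(
    list(group = group, beta_gen = beta_gen, base_speed = base_speed,
         submovement_gain = submovement_gain, rt_shift = rt_shift,
         rt_sigma = rt_sigma, rt_meanlog = rt_meanlog,
         questionnaire_params = questionnaire_params,
         age_params = age_params, gender_counts = gender_counts),
    class = "group_profile"
  )
}

#' Default group profiles
#'
#' Questionnaire, age and gender parameters follow the study's descriptive
#' statistics for the three groups. Kinematic and reaction-time parameters
#' are generator calibration choices: the autistic profile carries a higher
#' speed-modulation exponent and sub-movement gain, the parkinsonian profile
#' a slower base speed and longer reaction-time shift.
#'
#' @return Named list of three [group_profile()] objects.
#' @export
default_profiles <- function() {
  list(
    ASD = group_profile(
      "ASD", beta_gen = 0.40, base_speed = 440, submovement_gain = 1.3,
      rt_shift = 0.44,
      questionnaire_params = list(
        aq = c(37.61, 7.06), raads = c(32.97, 8.05), updrs = c(3.7, 3.76),
        phq = c(8.2, 5.59), gad = c(9.9, 5.89)
      ),
      age_params = c(55.52, 8.01),
      gender_counts = c(M = 14, F = 16, O = 1)
    ),
    PD = group_profile(
      "PD", beta_gen = 0.30, base_speed = 380, submovement_gain = 1.0,
      rt_shift = 0.50,
      questionnaire_params = list(
        aq = c(19.19, 7.72), raads = c(10.7, 9.43), updrs = c(11.91, 6.93),
        phq = c(7.87, 4.56), gad = c(5.1, 4.39)
      ),
      age_params = c(63.16, 7.60),
      gender_counts = c(M = 19, F = 13)
    ),
    CTRL = group_profile(
      "CTRL", beta_gen = 0.30, base_speed = 450, submovement_gain = 0.9,
      rt_shift = 0.45,
      questionnaire_params = list(
        aq = c(16.03, 5.95), raads = c(6.32, 6.46), updrs = c(0.94, 1.69),
        phq = c(3.0, 2.58), gad = c(3.6, 4.90)
      ),
      age_params = c(59.00, 9.96),
      gender_counts = c(M = 15, F = 16)
    )
  )
}

#' Cohort simulation configuration
#'
#' @param n_per_group Named counts for ASD, PD, CTRL (defaults 31/32/31).
#' @param n_days Number of testing days (1 or 2).
#' @param seed Integer seed; a fixed seed yields a byte-identical dataset.
#' @param sampling_rate_hz Device sampling rate (Hz).
#' @param timestamp_jitter_sd SD of timestamp jitter (s).
#' @param shapes List of [shape_spec()]s (defaults to the four task shapes).
#' @param n_cycles Full traversals of the shape per trial.
#' @param failure_prob Per-attempt probability of an unsuccessful trial.
#' @param n_rt_trials Experimental reaction-time trials per day.
#' @param n_rt_practice Practice reaction-time trials (flagged, unscored).
#' @param slow_noise_sd Log-scale SD of the slow multiplicative speed noise.
#' @param slow_noise_corr_s Correlation time of the slow speed noise (s).
#' @param submovement_corr_s Correlation time of the sub-movement
#'   perturbation (s); an Ornstein-Uhlenbeck-style band-limited process.
#' @param submovement_sd Base log-scale SD of the sub-movement perturbation
#'   (multiplied by the group's `submovement_gain`).
#' @param error_sd_px SD of the low-frequency normal tracing offset (px).
#' @param error_corr_px Correlation length of the tracing offset (px);
#'   slow drift along the shape (short correlation lengths inject offset
#'   curvature that biases the speed-modulation exponent downward).
#' @param deviation_frac Deviation boundary as a fraction of the shape's
#'   larger dimension; exceeding it marks the trial unsuccessful.
#' @param timeout_s Trial timeout (s).
#'
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_per_group = c(ASD = 31, PD = 32, CTRL = 31),
                          n_days = 2,
                          seed = 1L,
                          sampling_rate_hz = 60,
                          timestamp_jitter_sd = 0.002,
                          shapes = NULL,
                          n_cycles = 10,
                          failure_prob = 0.05,
                          n_rt_trials = 40,
                          n_rt_practice = 8,
                          slow_noise_sd = 0.08,
                          slow_noise_corr_s = 1.0,
                          submovement_corr_s = 0.15,
                          submovement_sd = 0.06,
                          error_sd_px = 4,
                          error_corr_px = 150,
                          deviation_frac = 0.15,
                          timeout_s = 90) {
  stopifnot(n_days %in% c(1, 2), failure_prob >= 0, failure_prob < 1,
            n_cycles >= 1, sampling_rate_hz > 0)
  if (is.null(shapes)) {
    shapes <- lapply(c("clover", "petals", "ellipse", "rounded_square"),
                     shape_spec)
    names(shapes) <- vapply(shapes, `[[`, character(1), "name")
  }
  structure(
    list(n_per_group = n_per_group, n_days = as.integer(n_days),
         seed = as.integer(seed), sampling_rate_hz = sampling_rate_hz,
         timestamp_jitter_sd = timestamp_jitter_sd, shapes = shapes,
         n_cycles = n_cycles, failure_prob = failure_prob,
         n_rt_trials = n_rt_trials, n_rt_practice = n_rt_practice,
         slow_noise_sd = slow_noise_sd,
         slow_noise_corr_s = slow_noise_corr_s,
         submovement_corr_s = submovement_corr_s,
         submovement_sd = submovement_sd,
         error_sd_px = error_sd_px, error_corr_px = error_corr_px,
         deviation_frac = deviation_frac, timeout_s = timeout_s),
    class = "cohort_config"
  )
}

#' Simulate the block/attempt schedule of the tracing task
#'
#' Each day comprises eight blocks, two per shape, in random order. Within a
#' block, attempts are made until four successes or seven attempts, so a
#' maximum of eight successful trials is possible per shape across a day's
#' two blocks.
#'
#' @param config A [cohort_config()].
#' @param failure_prob Per-attempt failure probability.
#' @return Tibble with columns `day`, `block`, `shape`, `attempt`, `success`.
#'   Uses the current RNG state; seed externally for reproducibility.
#' @export
simulate_task_schedule <- function(config, failure_prob = config$failure_prob) {
  stopifnot(failure_prob >= 0, failure_prob < 1)
  shape_names <- names(config$shapes)
  out <- vector("list", config$n_days * 8L)
  k <- 0L
  for (day in seq_len(config$n_days)) {
    block_shapes <- sample(rep(shape_names, each = 2L))
    for (b in seq_along(block_shapes)) {
      succ <- 0L; att <- 0L
      rows <- list()
      while (succ < 4L && att < 7L) {
        att <- att + 1L
        ok <- runif(1) >= failure_prob
        if (ok) succ <- succ + 1L
        rows[[att]] <- tibble::tibble(
          day = day, block = b, shape = block_shapes[b],
          attempt = att, success = ok
        )
      }
      k <- k + 1L
      out[[k]] <- dplyr::bind_rows(rows)
    }
  }
  dplyr::bind_rows(out)
}

# Gaussian-kernel-smoothed white noise over a (near-uniform) grid; unit
# variance. Smooth at fine scales, so it adds negligible curvature of its
# own when used as a spatial offset.
.smooth_noise <- function(delta, corr_len) {
  n <- length(delta) + 1L
  sd_samp <- max(1, corr_len / mean(delta))
  half <- ceiling(3 * sd_samp)
  w <- stats::dnorm(seq(-half, half), sd = sd_samp)
  w <- w / sum(w)
  z <- rnorm(n + 2 * half)
  sm <- stats::filter(z, w, sides = 2)
  as.numeric(sm[(half + 1):(half + n)]) / sqrt(sum(w^2))
}

# AR(1) (discretized Ornstein-Uhlenbeck) noise over a possibly non-uniform
# grid; unit stationary variance
.ou_noise <- function(delta, corr_len) {
  n <- length(delta) + 1L
  z <- numeric(n)
  z[1] <- rnorm(1)
  phi <- exp(-delta / corr_len)
  innov_sd <- sqrt(pmax(0, 1 - phi^2))
  eps <- rnorm(n - 1L)
  for (i in 2:n) z[i] <- phi[i - 1L] * z[i - 1L] + innov_sd[i - 1L] * eps[i - 1L]
  z
}

#' Simulate one tracing-trial trajectory
#'
#' Target speed follows the power law `v(s) = c * kappa(s)^(-beta)` with
#' smooth multiplicative noise; sub-movements are injected as band-limited
#' zero-mean tangential perturbations scaled by the group's gain; spatial
#' tracing error is a low-frequency offset along the curve normal. The
#' normalization constant `c` is chosen so the time-averaged speed equals the
#' profile's `base_speed`. The trace is sampled near the device rate with
#' timestamp jitter.
#'
#' @param curve An `ideal_curve`.
#' @param profile A [group_profile()].
#' @param n_cycles Number of full traversals.
#' @param config A [cohort_config()].
#' @param noise Logical; `FALSE` disables all stochastic perturbations
#'   (pure power-law trace).
#' @return Tibble with columns `t_s`, `x_px`, `y_px` and attribute `success`
#'   (`FALSE` when the trace crossed the deviation boundary or timed out).
#' @export
simulate_trial_trajectory <- function(curve, profile, n_cycles = config$n_cycles,
                                      config = cohort_config(), noise = TRUE) {
  stopifnot(n_cycles >= 1)
  base <- curve[-nrow(curve), ]            # drop duplicated closure point
  L <- attr(curve, "perimeter")
  n0 <- nrow(base)
  lap <- rep(seq_len(n_cycles) - 1L, each = n0)
  s_grid <- rep(base$s, n_cycles) + lap * L
  kap <- rep(base$kappa, n_cycles)
  xg <- rep(base$x, n_cycles)
  yg <- rep(base$y, n_cycles)
  # close the final lap
  s_grid <- c(s_grid, n_cycles * L)
  kap <- c(kap, base$kappa[1]); xg <- c(xg, base$x[1]); yg <- c(yg, base$y[1])
  ds <- diff(s_grid)

  w <- kap^(-profile$beta_gen)
  if (noise) {
    v_ref <- profile$base_speed
    eta_slow <- config$slow_noise_sd *
      .ou_noise(ds, config$slow_noise_corr_s * v_ref)
    eta_sub <- (config$submovement_sd * profile$submovement_gain) *
      .ou_noise(ds, config$submovement_corr_s * v_ref)
    w <- w * exp(eta_slow + eta_sub)
  }
  # c such that total length / total time = base_speed
  wm <- (w[-1] + w[-length(w)]) / 2
  tt <- cumsum(c(0, ds / wm))
  c0 <- profile$base_speed * tt[length(tt)] / s_grid[length(s_grid)]
  v <- c0 * w
  t_grid <- tt / c0

  if (noise && config$error_sd_px > 0) {
    dirs <- cbind(diff(c(xg, xg[2])), diff(c(yg, yg[2])))
    nrm <- sqrt(rowSums(dirs^2)); nrm[nrm == 0] <- 1
    offs <- config$error_sd_px * .smooth_noise(ds, config$error_corr_px)
    xg <- xg + offs * (-dirs[, 2] / nrm)
    yg <- yg + offs * (dirs[, 1] / nrm)
  } else {
    offs <- 0
  }

  spec <- attr(curve, "spec")
  success <- max(abs(offs)) <= config$deviation_frac * spec$max_dim_px &&
    t_grid[length(t_grid)] <= config$timeout_s

  # sample near the device rate with jitter, preserving monotone timestamps
  dt <- 1 / config$sampling_rate_hz
  t_samp <- seq(0, t_grid[length(t_grid)], by = dt)
  if (noise && config$timestamp_jitter_sd > 0) {
    t_samp <- t_samp + rnorm(length(t_samp), 0, config$timestamp_jitter_sd)
    t_samp <- sort(pmax(0, pmin(t_samp, t_grid[length(t_grid)])))
    t_samp <- t_samp[c(TRUE, diff(t_samp) > 1e-6)]
  }
  fx <- splinefun(t_grid, xg, method = "natural")
  fy <- splinefun(t_grid, yg, method = "natural")
  out <- tibble::tibble(t_s = t_samp, x_px = fx(t_samp), y_px = fy(t_samp))
  attr(out, "success") <- success
  out
}

#' Simulate reaction times
#'
#' Per-trial reaction time is `rt_shift + lognormal(rt_meanlog, rt_sigma)`
#' seconds.
#'
#' @param profile A [group_profile()].
#' @param n_trials Number of experimental trials (default 40).
#' @return Numeric vector of length `n_trials` (seconds).
#' @export
simulate_reaction_times <- function(profile, n_trials = 40) {
  stopifnot(n_trials >= 1)
  profile$rt_shift + rlnorm(n_trials, profile$rt_meanlog, profile$rt_sigma)
}

# truncated-at-zero normal via rejection
.rtruncnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- rnorm(n, mean, sd)
  bad <- which(out < 0)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < 0]
  }
  out
}

#' Simulate questionnaire and demographic covariates
#'
#' Questionnaire scores and age are drawn from zero-truncated normals with
#' the group profiles' mean/SD parameters; gender labels are assigned to
#' match the profile counts as closely as the group size allows.
#'
#' @param profiles Named list of [group_profile()]s.
#' @param n_per_group Named counts per group.
#' @return Tibble with `participant_id`, `group`, `age`, `gender`, `aq`,
#'   `raads`, `updrs`, `phq` (depression), `gad` (anxiety).
#' @export
simulate_questionnaires <- function(profiles, n_per_group) {
  rows <- purrr::imap(profiles, function(pr, g) {
    n <- n_per_group[[g]]
    gc <- pr$gender_counts
    gn <- floor(gc / sum(gc) * n)
    rem <- n - sum(gn)
    if (rem > 0) {
      frac <- gc / sum(gc) * n - gn
      add <- order(frac, decreasing = TRUE)[seq_len(rem)]
      gn[add] <- gn[add] + 1L
    }
    qs <- purrr::map(pr$questionnaire_params,
                     ~ .rtruncnorm0(n, .x[1], .x[2]))
    tibble::tibble(
      participant_id = paste0(g, sprintf("%03d", seq_len(n))),
      group = g,
      age = .rtruncnorm0(n, pr$age_params[1], pr$age_params[2]),
      gender = sample(rep(names(gn), times = gn)),
      aq = qs$aq, raads = qs$raads, updrs = qs$updrs,
      phq = qs$phq, gad = qs$gad
    )
  })
  dplyr::bind_rows(rows)
}

#' Simulate a full synthetic cohort
#'
#' Generates covariates, task schedules, tracing trajectories and reaction
#' times for every participant and day. Deterministic for a fixed
#' `config$seed`.
#'
#' @param config A [cohort_config()].
#' @param profiles Named list of [group_profile()]s.
#' @param dir Output directory; when `NULL` the dataset is returned in
#'   memory only.
#' @param noise Passed through to [simulate_trial_trajectory()].
#' @return (Invisibly when written) list with `trajectories`, `covariates`,
#'   `schedule`, `reaction_times` tibbles, `curves`, and `manifest`.
#' @export
simulate_cohort <- function(config = cohort_config(),
                            profiles = default_profiles(),
                            dir = NULL,
                            noise = TRUE) {
  set.seed(config$seed)
  curves <- lapply(config$shapes, generate_shape)
  n_per_group <- config$n_per_group[names(profiles)]
  covars <- simulate_questionnaires(profiles, n_per_group)

  traj_list <- list(); sched_list <- list(); rt_list <- list()
  for (i in seq_len(nrow(covars))) {
    pid <- covars$participant_id[i]
    g <- covars$group[i]
    pr <- profiles[[g]]
    sched <- simulate_task_schedule(config)
    sched$participant_id <- pid
    sched_list[[i]] <- sched
    trial_no <- 0L
    keep <- which(sched$success)
    trials <- vector("list", length(keep))
    for (j in seq_along(keep)) {
      row <- sched[keep[j], ]
      trial_no <- trial_no + 1L
      tr <- simulate_trial_trajectory(curves[[row$shape]], pr,
                                      n_cycles = config$n_cycles,
                                      config = config, noise = noise)
      trials[[j]] <- dplyr::mutate(
        tr,
        participant_id = pid, group = g, day = row$day, block = row$block,
        shape = row$shape, trial = trial_no, attempt = row$attempt,
        success = attr(tr, "success"),
        .before = 1
      )
    }
    traj_list[[i]] <- dplyr::bind_rows(trials)
    for (day in seq_len(config$n_days)) {
      n_all <- config$n_rt_practice + config$n_rt_trials
      rts <- simulate_reaction_times(pr, n_all)
      rt_list[[length(rt_list) + 1L]] <- tibble::tibble(
        participant_id = pid, group = g, day = day,
        trial = seq_len(n_all),
        practice = seq_len(n_all) <= config$n_rt_practice,
        rt_s = rts
      )
    }
  }
  dataset <- list(
    trajectories = dplyr::bind_rows(traj_list),
    covariates = covars,
    schedule = dplyr::bind_rows(sched_list),
    reaction_times = dplyr::bind_rows(rt_list),
    curves = curves
  )
  dataset$manifest <- list(
    seed = config$seed,
    n_participants = nrow(covars),
    n_per_group = as.list(n_per_group),
    n_days = config$n_days,
    shapes = names(config$shapes)
  )
  if (!is.null(dir)) {
    write_cohort(dataset, dir)
    invisible(dataset)
  } else {
    dataset
  }
}
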