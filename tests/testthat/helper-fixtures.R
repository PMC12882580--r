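# Shared fixtures, built once per test run. Curves are cached because the
# generator is deterministic; cohorts are small so the suite stays fast.

.fixture_env <- new.env(parent = emptyenv())

# moderately sampled ideal curve for a named task shape
tk_curve <- function(name, samples_per_cycle = 256) {
  key <- paste0(name, "_", samples_per_cycle)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <-
      generate_shape(shape_spec(name, samples_per_cycle = samples_per_cycle))
  }
  .fixture_env[[key]]
}

tk_curves <- function(samples_per_cycle = 256) {
  nms <- c("clover", "petals", "ellipse", "rounded_square")
  out <- lapply(nms, tk_curve, samples_per_cycle = samples_per_cycle)
  names(out) <- nms
  out
}

# near-circular curve (tiny curvature oscillation)
tk_circle <- function(max_dim_px = 200) {
  key <- paste0("circle_", max_dim_px)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_shape(
      shape_spec("circle", nu = c(1, 1), epsilon = 1e-4,
                 max_dim_px = max_dim_px, samples_per_cycle = 512))
  }
  .fixture_env[[key]]
}

# small cohort configuration used across tests: one day, three cycles,
# reduced sampling density
tk_small_config <- function(seed = 11, n = c(ASD = 6, PD = 6, CTRL = 6),
                            n_cycles = 3, n_days = 1, ...) {
  shapes <- lapply(c("clover", "petals", "ellipse", "rounded_square"),
                   shape_spec, samples_per_cycle = 256)
  names(shapes) <- vapply(shapes, function(s) s$name, character(1))
  cohort_config(n_per_group = n, n_days = n_days, seed = seed,
                n_cycles = n_cycles, shapes = shapes, ...)
}

# cached small simulated cohort (default noise, seed 11)
tk_small_cohort <- function() {
  if (is.null(.fixture_env$small_cohort)) {
    .fixture_env$small_cohort <- simulate_cohort(tk_small_config())
  }
  .fixture_env$small_cohort
}

# one clean (validated, trimmed, resampled) simulated trial
tk_clean_trial <- function(shape = "ellipse", beta = 1/3, noise = TRUE,
                           n_cycles = 3, seed = 4, profile = NULL,
                           config = NULL) {
  cv <- tk_curve(shape)
  pr <- profile %||% default_profiles()$CTRL
  pr$beta_gen <- beta
  cfg <- config %||% tk_small_config()
  set.seed(seed)
  tr <- simulate_trial_trajectory(cv, pr, n_cycles = n_cycles, config = cfg,
                                  noise = noise)
  resample_uniform(trim_initial_theta(compute_angular_displacement(tr, cv)))
}

# synthetic analysis table at the feature level (bypasses trajectory
# simulation) for mixed-model tests: random participant/day/trial-number
# intercepts plus unit residual noise, optional fixed effects
tk_lmm_data <- function(n_per_group = 10, n_trials = 2, n_days = 2,
                        group_shift = c(ASD = 0, PD = 0, CTRL = 0),
                        shape_shift = NULL, age_slope = 0,
                        sd_participant = 0.5, sd_day = 0.1,
                        sd_trial = 0.1, sd_eps = 1) {
  shapes <- c("clover", "petals", "ellipse", "rounded_square")
  groups <- c("ASD", "PD", "CTRL")
  rows <- list()
  n_trial_ids <- n_trials * length(shapes) * n_days
  b_trial <- rnorm(n_trial_ids, 0, sd_trial)
  for (g in groups) {
    for (p in seq_len(n_per_group)) {
      pid <- paste0(g, p)
      b_p <- rnorm(1, 0, sd_participant)
      age <- rnorm(1, 59, 9)
      dep <- abs(rnorm(1, 6, 4)); anx <- abs(rnorm(1, 6, 5))
      b_day <- rnorm(n_days, 0, sd_day)
      tn <- 0L
      for (d in seq_len(n_days)) {
        for (sh in shapes) {
          for (k in seq_len(n_trials)) {
            tn <- tn + 1L
            eff <- unname(group_shift[g])
            if (!is.null(shape_shift) && sh == shape_shift$shape) {
              eff <- eff + ifelse(g == shape_shift$group, shape_shift$delta, 0)
            }
            rows[[length(rows) + 1L]] <- tibble::tibble(
              participant_id = pid, group = g, day = d, shape = sh,
              trial_number = tn,
              age = age, depression = dep, anxiety = anx,
              dv = eff + age_slope * (age - 59) + b_p + b_day[d] +
                b_trial[tn] + rnorm(1, 0, sd_eps)
            )
          }
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
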