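# Per-trial kinematic features: derivative stacks via Savitzky-Golay
# differentiation, sub-movement percentage from tangential-acceleration sign
# changes, the speed-curvature power-law exponent (speed modulation),
# decile-mean log speeds, spectral arc length (SPARC) smoothness per
# repeated sub-element, and normal-distance tracing error.

#' Differentiate a clean trajectory
#'
#' Applies a least-squares local-polynomial (Savitzky-Golay) derivative
#' filter stage-wise: velocity components from position, signed tangential
#' acceleration from speed, jerk from acceleration, and component
#' accelerations (for curvature) from the velocity components. Curvature is
#' `|vx*ay - vy*ax| / v^3`.
#'
#' @param traj Uniformly sampled trajectory (`t_s`, `x_px`, `y_px`).
#' @param window Filter window length in samples (odd, > `polyorder`).
#' @param polyorder Local polynomial order.
#' @return A `kinematic_series` tibble: `t_s`, `x_px`, `y_px`, `vx`, `vy`,
#'   `v` (speed, px/s), `a` (signed tangential acceleration, px/s^2), `j`
#'   (jerk, px/s^3), `kappa` (1/px), and `interior` marking samples clear of
#'   filter edge effects (three half-windows at each end).
#' @export
differentiate <- function(traj, window = 11, polyorder = 3) {
  n <- nrow(traj)
  if (window %% 2 == 0 || window <= polyorder || window > n) {
    abort("window must be odd, greater than polyorder, and at most the series length")
  }
  dt <- median(diff(traj$t_s))
  d1 <- function(z) signal::sgolayfilt(z, p = polyorder, n = window, m = 1, ts = dt)
  vx <- d1(traj$x_px); vy <- d1(traj$y_px)
  v <- sqrt(vx^2 + vy^2)
  a <- d1(v)
  j <- d1(a)
  ax <- d1(vx); ay <- d1(vy)
  kappa <- abs(vx * ay - vy * ax) / pmax(v, 1e-12)^3
  hw <- (window - 1) / 2
  edge <- 3 * hw
  interior <- seq_len(n) > edge & seq_len(n) <= n - edge
  out <- tibble::tibble(
    t_s = traj$t_s, x_px = traj$x_px, y_px = traj$y_px,
    vx = vx, vy = vy, v = v, a = a, j = j, kappa = kappa,
    interior = interior
  )
  class(out) <- c("kinematic_series", class(out))
  out
}

#' Sub-movement percentage
#'
#' Percentage of time samples at which the sign of the tangential
#' acceleration changes; zero accelerations inherit the preceding sign.
#' Accelerations within a small deadband are treated as zero so that a
#' constant-speed trace scores 0% instead of counting numerical ripple;
#' the deadband is relative to the trial's mean speed (so the measure is
#' invariant to uniform spatial scaling) and sits orders of magnitude
#' below physiological accelerations.
#'
#' @param series A `kinematic_series` (interior samples are used).
#' @param zero_rel_tol Deadband as a fraction of mean speed per second.
#' @return Percentage in `[0, 100]`.
#' @export
submovement_percentage <- function(series, zero_rel_tol = 1e-3) {
  a <- series$a[series$interior]
  if (length(a) < 3) abort("need at least 2 interior samples of acceleration")
  tol <- zero_rel_tol * mean(series$v[series$interior])
  a[abs(a) < tol] <- 0
  s <- sign(a)
  for (i in seq_along(s)[-1]) if (s[i] == 0) s[i] <- s[i - 1]
  s <- s[s != 0]
  if (length(s) < 2) return(0)
  100 * sum(s[-1] != s[-length(s)]) / (length(series$a[series$interior]) - 1)
}

#' Speed-curvature power-law exponent (speed modulation)
#'
#' Fits the power law `v = c * kappa^(-beta)` by ordinary least squares of
#' `log v` on `log kappa` after Savitzky-Golay smoothing of both series,
#' discarding samples with speed below its 1st percentile or curvature
#' outside configurable bounds (guarding the log transform). The reported
#' exponent is the absolute slope.
#'
#' @param series A `kinematic_series`.
#' @param filter_cfg List with `window`, `polyorder`, `kappa_lo`, `kappa_hi`.
#' @return A `speed_modulation` list: `beta`, `intercept`, `r_squared`,
#'   `n_points`, `reliable` (`FALSE` with fewer than 50 retained points).
#' @export
speed_modulation <- function(series,
                             filter_cfg = list(window = 11, polyorder = 3,
                                               kappa_lo = 1e-4, kappa_hi = 1)) {
  v <- series$v[series$interior]
  kap <- series$kappa[series$interior]
  sm <- function(z) signal::sgolayfilt(z, p = filter_cfg$polyorder,
                                       n = filter_cfg$window, m = 0)
  v <- sm(v); kap <- sm(kap)
  ok <- v > 0 & v >= quantile(v[v > 0], 0.01) &
    kap >= filter_cfg$kappa_lo & kap <= filter_cfg$kappa_hi
  v <- v[ok]; kap <- kap[ok]
  reliable <- length(v) >= 50
  if (length(v) < 3) {
    return(structure(list(beta = NA_real_, intercept = NA_real_,
                          r_squared = NA_real_, n_points = length(v),
                          reliable = FALSE),
                     class = "speed_modulation"))
  }
  fit <- lm(log(v) ~ log(kap))
  structure(
    list(beta = abs(unname(coef(fit)[2])),
         intercept = unname(coef(fit)[1]),
         r_squared = summary(fit)$r.squared,
         n_points = length(v),
         reliable = reliable),
    class = "speed_modulation"
  )
}

#' @export
print.speed_modulation <- function(x, ...) {
  cat(sprintf("<speed_modulation> beta = %.4f (r2 = %.3f, n = %d%s)\n",
              x$beta, x$r_squared, x$n_points,
              if (x$reliable) "" else ", unreliable"))
  invisible(x)
}

#' Minimum and maximum speed (decile means of log speed)
#'
#' Averages of the bottom and top 10% of log speed values within a trial
#' (decile size `ceiling(0.1 * N)`); non-positive speeds are excluded before
#' the log.
#'
#' @param series A `kinematic_series`.
#' @return Named numeric `c(min_speed, max_speed)`, in log px/s.
#' @export
min_max_speed <- function(series) {
  v <- series$v[series$interior]
  v <- v[v > 0]
  if (length(v) < 10) abort("need at least 10 positive speed samples")
  lv <- sort(log(v))
  k <- ceiling(0.1 * length(lv))
  c(min_speed = mean(lv[seq_len(k)]),
    max_speed = mean(lv[seq(length(lv) - k + 1, length(lv))]))
}

# spectral arc length of one speed profile segment
.sparc_element <- function(v, fs, omega_c = 20, amp_threshold = 0.05,
                           pad_level = 4) {
  nfft <- 2^(ceiling(log2(length(v))) + pad_level)
  spec <- abs(fft(c(v, rep(0, nfft - length(v)))))
  f <- (seq_len(nfft) - 1) * fs / nfft
  half <- f <= fs / 2
  f <- f[half]; spec <- spec[half]
  vn <- spec / spec[1]
  sel <- which(f <= omega_c)
  f <- f[sel]; vn <- vn[sel]
  above <- which(vn >= amp_threshold)
  cut <- seq(above[1], above[length(above)])
  f <- f[cut]; vn <- vn[cut]
  if (length(f) < 2) return(0)
  -sum(sqrt((diff(f) / (f[length(f)] - f[1]))^2 + diff(vn)^2))
}

#' Spectral arc length (SPARC) smoothness, per repeated sub-element
#'
#' SPARC values are only comparable across identical trajectories, so the
#' trial is split into its repeated identical sub-elements: the segments
#' between successive curvature maxima of the ideal curve (p per traversal
#' for angular frequency p/q), located on the trace via the nearest point on
#' the curve. Per element, the speed profile is zero-padded, its magnitude
#' spectrum normalized by the DC value and truncated at an adaptive cutoff
#' (amplitude threshold within the frequency cap), and the negative arc
#' length of the normalized spectrum returned; element values are averaged.
#'
#' @param series A `kinematic_series`.
#' @param curve The `ideal_curve` being traced.
#' @param cfg List: `omega_c` (Hz, frequency cap), `amp_threshold`
#'   (normalized amplitude cutoff), `pad_level` (zero-padding factor
#'   exponent), `min_element_s` (elements shorter than this are skipped).
#' @param frames Optional precomputed [nearest_point_frame()] result for the
#'   series samples.
#' @return A `smoothness_result` list: `sparc_per_element`, `sparc` (mean),
#'   `n_elements`.
#' @export
sparc <- function(series, curve,
                  cfg = list(omega_c = 20, amp_threshold = 0.05,
                             pad_level = 4, min_element_s = 0.25),
                  frames = NULL) {
  if (is.null(frames)) {
    frames <- nearest_point_frame(
      curve, tibble::tibble(x = series$x_px, y = series$y_px))
  }
  L <- attr(curve, "perimeter")
  # unwrap arc position across laps
  s_raw <- frames$s
  dsr <- diff(s_raw)
  dsr <- dsr + L * (dsr < -L / 2) - L * (dsr > L / 2)
  s_cum <- cumsum(c(s_raw[1], dsr))
  # a running median suppresses transient flips of the nearest-point
  # mapping between overlapping windings of the curve
  if (length(s_cum) > 31) s_cum <- stats::runmed(s_cum, 31)
  # element boundaries: curvature maxima of the ideal curve, every lap
  kap <- curve$kappa[-nrow(curve)]
  n <- length(kap)
  prv <- kap[c(n, seq_len(n - 1))]; nxt <- kap[c(seq_len(n - 1) + 1, 1)]
  s_max <- curve$s[-nrow(curve)][kap > prv & kap > nxt]
  if (length(s_max) == 0) abort("ideal curve has no curvature maxima")
  laps <- floor(min(s_cum) / L):ceiling(max(s_cum) / L)
  bounds <- sort(as.vector(outer(s_max, laps * L, "+")))
  # per-sample element id; elements are runs of a constant id, so brief
  # flips of the nearest-point mapping between overlapping windings only
  # shed short (skipped) fragments instead of corrupting the split
  seg_id <- findInterval(s_cum, bounds)
  runs <- rle(seg_id)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  fs <- 1 / median(diff(series$t_s))
  vals <- c()
  for (ri in seq_along(runs$lengths)) {
    ii <- run_start[ri]:run_end[ri]
    ii <- ii[series$interior[ii]]
    if (length(ii) < cfg$min_element_s * fs) next
    vals <- c(vals, .sparc_element(series$v[ii], fs,
                                   omega_c = cfg$omega_c,
                                   amp_threshold = cfg$amp_threshold,
                                   pad_level = cfg$pad_level))
  }
  if (length(vals) == 0) abort("no sub-element long enough to score")
  structure(list(sparc_per_element = vals, sparc = mean(vals),
                 n_elements = length(vals)),
            class = "smoothness_result")
}

#' Tracing error
#'
#' Mean absolute normal distance of the trace samples to the tangent of the
#' nearest point on the ideal curve.
#'
#' @param traj Trajectory tibble (`x_px`, `y_px`).
#' @param curve The `ideal_curve`.
#' @param frames Optional precomputed [nearest_point_frame()] result.
#' @return Error in px.
#' @export
tracing_error <- function(traj, curve, frames = NULL) {
  if (is.null(frames)) {
    frames <- nearest_point_frame(
      curve, tibble::tibble(x = traj$x_px, y = traj$y_px))
  }
  mean(abs(frames$distance))
}

#' Extract the nine kinematic features of one trial
#'
#' @param traj A clean (validated, trimmed, resampled) trajectory.
#' @param curve The `ideal_curve` for the trial's shape.
#' @param window,polyorder Savitzky-Golay differentiation parameters.
#' @param sparc_cfg SPARC configuration (see [sparc()]).
#' @param features Character vector of features to compute (default all
#'   nine); skipping the nearest-point-based features (`sparc`, `error_px`)
#'   speeds up large simulation studies.
#' @return One-row tibble: trial metadata plus `speed`, `acceleration`,
#'   `jerk` (trial means of `v`, `|a|`, `|j|`), `min_speed`, `max_speed`,
#'   `submovement_pct`, `speed_modulation`, `sparc`, `error_px`. Features
#'   whose sub-result is flagged unreliable are set to `NA`.
#' @export
extract_features <- function(traj, curve,
                             window = 11, polyorder = 3,
                             sparc_cfg = list(omega_c = 20,
                                              amp_threshold = 0.05,
                                              pad_level = 4,
                                              min_element_s = 0.25),
                             features = c("speed", "acceleration", "jerk",
                                          "min_speed", "max_speed",
                                          "submovement_pct",
                                          "speed_modulation", "sparc",
                                          "error_px")) {
  ser <- differentiate(traj, window = window, polyorder = polyorder)
  ii <- ser$interior
  meta_cols <- intersect(c("participant_id", "group", "day", "block",
                           "shape", "trial", "attempt"), names(traj))
  out <- tibble::as_tibble(traj[1, meta_cols])
  if ("speed" %in% features) out$speed <- mean(ser$v[ii])
  if ("acceleration" %in% features) out$acceleration <- mean(abs(ser$a[ii]))
  if ("jerk" %in% features) out$jerk <- mean(abs(ser$j[ii]))
  if (any(c("min_speed", "max_speed") %in% features)) {
    mm <- min_max_speed(ser)
    if ("min_speed" %in% features) out$min_speed <- mm[["min_speed"]]
    if ("max_speed" %in% features) out$max_speed <- mm[["max_speed"]]
  }
  if ("submovement_pct" %in% features) {
    out$submovement_pct <- submovement_percentage(ser)
  }
  if ("speed_modulation" %in% features) {
    smod <- speed_modulation(ser, filter_cfg = list(window = window,
                                                    polyorder = polyorder,
                                                    kappa_lo = 1e-4,
                                                    kappa_hi = 1))
    out$speed_modulation <- if (smod$reliable) smod$beta else NA_real_
  }
  need_frames <- any(c("sparc", "error_px") %in% features)
  if (need_frames) {
    frames <- nearest_point_frame(
      curve, tibble::tibble(x = traj$x_px, y = traj$y_px))
    if ("sparc" %in% features) {
      out$sparc <- tryCatch(sparc(ser, curve, cfg = sparc_cfg,
                                  frames = frames)$sparc,
                            error = function(e) NA_real_)
    }
    if ("error_px" %in% features) {
      out$error_px <- tracing_error(traj, curve, frames = frames)
    }
  }
  out
}

#' Extract features for every clean trial of a cohort
#'
#' @param clean Clean trajectory table ([preprocess_trials()] output).
#' @param curves Named list of `ideal_curve`s.
#' @param ... Passed to [extract_features()].
#' @return Feature table: one row per trial.
#' @export
extract_cohort_features <- function(clean, curves, ...) {
  ids <- c("participant_id", "day", "shape", "trial")
  if (nrow(clean) == 0) {
    abort("no clean trials: every trial was dropped during preprocessing")
  }
  clean |>
    dplyr::group_by(dplyr::across(dplyr::all_of(ids))) |>
    dplyr::group_split() |>
    purrr::map(function(tr) extract_features(tr, curves[[tr$shape[1]]], ...)) |>
    dplyr::bind_rows()
}
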