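# Preprocessing of raw stylus logs: trace counting via angular displacement
# about the target shape's centroid, trial validation, removal of the first
# half-pi of angular displacement, and cubic-spline resampling to a uniform
# device rate.

#' Angular displacement of a trace about the shape centroid
#'
#' Computes the unwrapped polar angle of each sample about the ideal curve's
#' centroid, normalized by the curve's winding number so that one full trace
#' of the shape corresponds to 2*pi regardless of how many times the curve
#' wraps its centre. Adds a `theta_traced` column (radians, increasing for a
#' trace that follows the task direction).
#'
#' @param traj Raw trajectory tibble with `x_px`, `y_px`.
#' @param curve The `ideal_curve` being traced.
#' @return `traj` with `theta_traced` added.
#' @export
compute_angular_displacement <- function(traj, curve) {
  stopifnot(nrow(traj) >= 10)
  ctr <- attr(curve, "centroid")
  winding <- attr(curve, "winding")
  dx <- traj$x_px - ctr["x"]
  dy <- traj$y_px - ctr["y"]
  if (all(sqrt(dx^2 + dy^2) < 1e-9)) {
    abort("all samples coincide with the shape centroid; angle undefined")
  }
  ang <- .unwrap(atan2(dy, dx))
  theta <- (ang - ang[1]) / winding
  dplyr::mutate(traj, theta_traced = theta)
}

#' Number of completed traces
#'
#' @param traj Trajectory with a `theta_traced` column (see
#'   [compute_angular_displacement()]).
#' @return Completed traces of the shape (angular span / 2*pi).
#' @export
traces_completed <- function(traj) {
  th <- traj$theta_traced
  (th[length(th)] - th[1]) / (2 * pi)
}

#' Validate a trial against the task rules
#'
#' A trial is dropped when it completes fewer than 2.5 traces of the shape,
#' when no sample within the first 5-second grace period reaches the minimal
#' speed of 200 px/s, when it exceeds the trial timeout, or when the
#' acquisition marked it unsuccessful (stylus lift / boundary deviation).
#' Validation reports reasons and never raises.
#'
#' @param traj Trajectory tibble with `t_s`, `x_px`, `y_px`, `theta_traced`
#'   (and optionally a `success` flag from acquisition).
#' @param curve The `ideal_curve` (unused by the current rules; kept so
#'   boundary re-checks can be added without changing call sites).
#' @param min_traces,min_speed_px_s,grace_s,timeout_s Rule thresholds.
#' @return One-row tibble: `keep` (logical), `reason` (`NA` when kept, else
#'   one of `"too_few_traces"`, `"too_slow"`, `"timeout"`, `"lifted"`),
#'   `traces_completed`.
#' @export
validate_trial <- function(traj, curve = NULL,
                           min_traces = 2.5,
                           min_speed_px_s = 200,
                           grace_s = 5,
                           timeout_s = 90) {
  tc <- traces_completed(traj)
  reason <- NA_character_
  if (!is.null(traj[["success"]]) && !all(traj[["success"]])) {
    reason <- "lifted"
  } else if (tc < min_traces) {
    reason <- "too_few_traces"
  } else {
    t0 <- traj$t_s - traj$t_s[1]
    if (t0[length(t0)] > timeout_s) {
      reason <- "timeout"
    } else {
      early <- which(t0 <= grace_s)
      if (length(early) >= 2) {
        i <- early[-length(early)]
        sp <- sqrt(diff(traj$x_px)[i]^2 + diff(traj$y_px)[i]^2) /
          pmax(diff(traj$t_s)[i], 1e-9)
        if (!any(sp >= min_speed_px_s)) reason <- "too_slow"
      } else {
        reason <- "too_slow"
      }
    }
  }
  tibble::tibble(keep = is.na(reason), reason = reason,
                 traces_completed = tc)
}

#' Discount the first half-pi of angular displacement
#'
#' Removes the initial run of samples up to the first sample at which the
#' trial's angular displacement reaches pi/2 (a time-prefix: later samples
#' are never touched, even when loops of the shape make the angle dip
#' transiently).
#'
#' @param traj Trajectory with `theta_traced`.
#' @return The trimmed trajectory; zero rows when the angular span never
#'   exceeds pi/2 (the trial is then dropped as `too_few_traces`).
#' @export
trim_initial_theta <- function(traj) {
  th <- traj$theta_traced
  first <- which(th - th[1] >= pi / 2)[1]
  if (is.na(first) || first >= nrow(traj)) {
    return(traj[0, ])
  }
  traj[first:nrow(traj), ]
}

#' Resample a trajectory to a uniform rate
#'
#' Duplicate timestamps are collapsed by averaging; `x(t)` and `y(t)` are
#' then interpolated with natural cubic splines onto a uniform grid spanning
#' the recorded time range.
#'
#' @param traj Trajectory tibble with `t_s`, `x_px`, `y_px`.
#' @param rate_hz Target sampling rate (default 60 Hz).
#' @return Tibble with uniform `t_s` spacing; metadata columns (constant
#'   within the trial) are carried over.
#' @export
resample_uniform <- function(traj, rate_hz = 60) {
  keep_cols <- setdiff(names(traj), c("t_s", "x_px", "y_px", "theta_traced"))
  if (any(diff(traj$t_s) < 0)) abort("timestamps must be strictly increasing")
  agg <- traj |>
    dplyr::group_by(.data$t_s) |>
    dplyr::summarise(x_px = mean(.data$x_px), y_px = mean(.data$y_px),
                     .groups = "drop") |>
    dplyr::arrange(.data$t_s)
  if (nrow(agg) < 4) abort("need at least 4 distinct timestamps to resample")
  tg <- seq(agg$t_s[1], agg$t_s[nrow(agg)], by = 1 / rate_hz)
  out <- tibble::tibble(
    t_s = tg,
    x_px = splinefun(agg$t_s, agg$x_px, method = "natural")(tg),
    y_px = splinefun(agg$t_s, agg$y_px, method = "natural")(tg)
  )
  for (cl in keep_cols) out[[cl]] <- traj[[cl]][1]
  dplyr::relocate(out, dplyr::all_of(keep_cols), .before = 1)
}

#' Preprocess all trials of a raw trajectory table
#'
#' Applies, per trial: angular-displacement computation, validation,
#' removal of the first half-pi of angular displacement, and uniform
#' resampling. Trace counting runs on the raw samples, before the trim.
#'
#' @param trajectories Raw trajectory table (schema of
#'   [validate_trajectory_schema()]).
#' @param curves Named list of `ideal_curve`s keyed by shape.
#' @param rate_hz Resampling rate.
#' @param ... Rule thresholds passed to [validate_trial()].
#' @return List with `clean` (resampled kept trials, with `theta_traced`
#'   recomputed on the resampled samples) and `qc` (one row per trial:
#'   kept/dropped, reason, traces completed).
#' @export
preprocess_trials <- function(trajectories, curves, rate_hz = 60, ...) {
  ids <- c("participant_id", "day", "shape", "trial")
  split_tbl <- trajectories |>
    dplyr::group_by(dplyr::across(dplyr::all_of(ids))) |>
    dplyr::group_split()
  clean <- list(); qc <- list()
  for (tr in split_tbl) {
    curve <- curves[[tr$shape[1]]]
    tr <- compute_angular_displacement(tr, curve)
    v <- validate_trial(tr, curve, ...)
    meta <- tibble::as_tibble(tr[1, intersect(ids, names(tr))])
    if (v$keep) {
      trimmed <- trim_initial_theta(tr)
      if (nrow(trimmed) < 4) {
        v$keep <- FALSE
        v$reason <- "too_few_traces"
      } else {
        rs <- resample_uniform(trimmed, rate_hz = rate_hz)
        clean[[length(clean) + 1L]] <-
          compute_angular_displacement(rs, curve)
      }
    }
    qc[[length(qc) + 1L]] <- dplyr::bind_cols(meta, v)
  }
  list(clean = dplyr::bind_rows(clean), qc = dplyr::bind_rows(qc))
}
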