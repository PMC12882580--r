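# Kinematic feature extraction: derivative stacks, sub-movements,
# speed modulation, decile speeds, SPARC, tracing error.

make_series <- function(t, x, y) {
  differentiate(tibble::tibble(t_s = t, x_px = x, y_px = y))
}

test_that("derivative filter is exact on polynomials", {
  t <- seq(0, 5, by = 1 / 60)
  lin <- make_series(t, 40 * t + 3, -30 * t)
  ii <- lin$interior
  expect_equal(lin$v[ii], rep(50, sum(ii)), tolerance = 1e-6)
  expect_lt(max(abs(lin$a[ii])), 1e-6)
  expect_lt(max(abs(lin$j[ii])), 1e-6)
  # x = t^2: tangential acceleration is 2 for t > 0
  t2 <- seq(1, 4, by = 1 / 60)
  quad <- make_series(t2, t2^2, 0 * t2)
  ii <- quad$interior
  expect_equal(quad$v[ii], 2 * t2[ii], tolerance = 1e-6)
  expect_equal(quad$a[ii], rep(2, sum(ii)), tolerance = 1e-6)
})

test_that("derivatives track a dense central-difference oracle", {
  set.seed(14)
  # random band-limited path (freqs <= 0.5 Hz) with a dominant drift so the
  # speed stays away from zero; smooth everywhere, inside the filter band
  freqs <- c(0.15, 0.3, 0.5)
  ax <- rnorm(3, 0, 15); px <- runif(3, 0, 2 * pi)
  ay <- rnorm(3, 0, 15); py <- runif(3, 0, 2 * pi)
  fx <- function(u) {
    250 * u + colSums(ax * sin(outer(2 * pi * freqs, u) + px))
  }
  fy <- function(u) {
    colSums(ay * sin(outer(2 * pi * freqs, u) + py))
  }
  t <- seq(0.5, 3.5, by = 1 / 60)
  ser <- make_series(t, fx(t), fy(t))
  # oracle on a 10x supersampled grid
  h <- 1 / 600
  vfun <- function(u) {
    sqrt(((fx(u + h) - fx(u - h)) / (2 * h))^2 +
           ((fy(u + h) - fy(u - h)) / (2 * h))^2)
  }
  v_o <- vfun(t)
  a_o <- (vfun(t + h) - vfun(t - h)) / (2 * h)
  ii <- ser$interior
  expect_lt(max(abs(ser$v[ii] - v_o[ii])) / mean(v_o), 0.01)
  expect_lt(max(abs(ser$a[ii] - a_o[ii])) / max(abs(a_o)), 0.01)
})

test_that("sub-movement percentage matches analytic sign-change counts", {
  t <- seq(0, 10, by = 1 / 60)
  # monotone speed ramp: no sign change
  ramp <- make_series(t, 10 * t + 0.5 * t^2, 0 * t)
  expect_equal(submovement_percentage(ramp), 0)
  # sinusoidally modulated speed: 2 f T sign changes over T seconds
  f <- 2
  x <- t + (0.1 / (2 * pi * f)) * (1 - cos(2 * pi * f * t))  # v = 1 + 0.1 sin
  sinser <- make_series(t, x, 0 * t)
  t_int <- t[sinser$interior]
  k <- 0:ceiling(4 * f * max(t))
  crossings <- (2 * k + 1) / (4 * f)   # zeros of cos(2*pi*f*t)
  n_cross <- sum(crossings > min(t_int) & crossings < max(t_int))
  expected_pct <- 100 * n_cross / (sum(sinser$interior) - 1)
  expect_equal(submovement_percentage(sinser), expected_pct,
               tolerance = 1e-9)
  # i.i.d. symmetric acceleration signs alternate about half the time
  set.seed(15)
  fake <- tibble::tibble(a = rnorm(1e5), v = 1,
                         interior = TRUE)
  expect_equal(submovement_percentage(fake), 50, tolerance = 1)
})

test_that("sub-movement percentage is invariant to time shift and spatial scale", {
  cl <- tk_clean_trial(seed = 16)
  s0 <- submovement_percentage(differentiate(cl))
  shifted <- dplyr::mutate(cl, t_s = t_s + 100)
  scaled <- dplyr::mutate(cl, x_px = 3.7 * x_px, y_px = 3.7 * y_px)
  expect_equal(submovement_percentage(differentiate(shifted)), s0)
  expect_equal(submovement_percentage(differentiate(scaled)), s0)
})

test_that("speed modulation recovers exact and noisy power laws", {
  cv <- tk_curve("ellipse")
  cl <- tk_clean_trial("ellipse", beta = 1 / 3, noise = FALSE)
  ser <- differentiate(cl)
  sm <- speed_modulation(ser)
  expect_equal(sm$beta, 1 / 3, tolerance = 0.015)
  expect_gt(sm$r_squared, 0.99)
  expect_true(sm$reliable)
  # constant speed over varying curvature: flat regression
  pr0 <- default_profiles()$CTRL; pr0$beta_gen <- 0; pr0$submovement_gain <- 0
  cl0 <- tk_clean_trial("ellipse", beta = 0, noise = FALSE, profile = pr0)
  expect_lte(speed_modulation(differentiate(cl0))$beta, 0.01)
  # small multiplicative noise: within 5%, r^2 still high
  set.seed(17)
  ser_n <- ser
  ser_n$v <- ser$v * exp(rnorm(nrow(ser), 0, 0.02))
  sm_n <- speed_modulation(ser_n)
  expect_equal(sm_n$beta, 1 / 3, tolerance = 0.05 / 3)
  expect_gt(sm_n$r_squared, 0.9)
  # fewer than 50 retained points flags the fit
  short <- ser[ser$interior, ][1:30, ]
  short$interior <- TRUE
  expect_false(speed_modulation(short)$reliable)
})

test_that("decile speeds use log speed with ceiling-sized deciles", {
  const <- tibble::tibble(v = rep(7, 100), interior = TRUE)
  mm <- min_max_speed(const)
  expect_equal(unname(mm), rep(log(7), 2))
  # N = 10 distinct values: decile of one
  ten <- tibble::tibble(v = 1:10, interior = TRUE)
  mm10 <- min_max_speed(ten)
  expect_equal(mm10[["min_speed"]], log(1))
  expect_equal(mm10[["max_speed"]], log(10))
  # dense uniform grid on [1, 2]: bottom decile mean matches the integral
  # 10 * int_1^1.1 log(x) dx
  v <- seq(1, 2, length.out = 1e5)
  mmu <- min_max_speed(tibble::tibble(v = v, interior = TRUE))
  oracle_lo <- 10 * integrate(log, 1, 1.1)$value
  oracle_hi <- 10 * integrate(log, 1.9, 2)$value
  expect_equal(mmu[["min_speed"]], oracle_lo, tolerance = 1e-4)
  expect_equal(mmu[["max_speed"]], oracle_hi, tolerance = 1e-4)
})

test_that("spectral arc length matches a direct-quadrature oracle", {
  fs <- 60
  t <- seq(0, 2, by = 1 / fs)
  v <- exp(-((t - 1) / 0.25)^2)  # single-peak Gaussian speed profile
  got <- tracekin:::.sparc_element(v, fs)
  # oracle: continuous-frequency spectrum by direct summation on a fine
  # grid, arc length by trapezoid segments over the same adaptive band
  f_fine <- seq(0, 20, by = 0.002)
  spec <- vapply(f_fine, function(f) Mod(sum(v * exp(-2i * pi * f * t))),
                 numeric(1))
  vn <- spec / spec[1]
  above <- which(vn >= 0.05)
  band <- seq(above[1], above[length(above)])
  fb <- f_fine[band]; vb <- vn[band]
  oracle <- -sum(sqrt((diff(fb) / (fb[length(fb)] - fb[1]))^2 + diff(vb)^2))
  expect_equal(got, oracle, tolerance = 1e-3)
  expect_lte(got, 0)
})

test_that("SPARC is invariant to amplitude and time scaling of the profile", {
  fs <- 60
  t <- seq(0, 2, by = 1 / fs)
  v <- exp(-((t - 1) / 0.25)^2) + 0.2
  s1 <- tracekin:::.sparc_element(v, fs)
  expect_equal(tracekin:::.sparc_element(5.3 * v, fs), s1, tolerance = 1e-12)
  # time-scaled by two: same shape, half the bandwidth, same arc length
  t2 <- seq(0, 4, by = 1 / fs)
  v2 <- exp(-((t2 - 2) / 0.5)^2) + 0.2
  expect_equal(tracekin:::.sparc_element(v2, fs), s1, tolerance = 0.02)
})

test_that("whole-trajectory SPARC is no smoother than its sub-elements", {
  fs <- 60
  t <- seq(0, 1, by = 1 / fs)
  el <- exp(-((t - 0.5) / 0.12)^2) + 0.1
  two <- c(el, el)
  expect_gte(abs(tracekin:::.sparc_element(two, fs)),
             abs(tracekin:::.sparc_element(el, fs)))
})

test_that("per-element SPARC on a trial counts the right number of elements", {
  cv <- tk_curve("ellipse")
  cl <- tk_clean_trial("ellipse", seed = 18)
  res <- sparc(differentiate(cl), cv)
  # 2 curvature oscillations per cycle x 3 cycles, minus the trimmed start
  expect_gte(res$n_elements, 4)
  expect_lte(res$n_elements, 7)
  expect_true(all(res$sparc_per_element <= 0))
  expect_equal(res$sparc, mean(res$sparc_per_element))
})

test_that("tracing error recovers analytic offsets", {
  cv <- tk_circle()
  ctr <- attr(cv, "centroid")
  ang <- seq(0, 2 * pi, length.out = 200)
  r <- mean(sqrt((cv$x - ctr["x"])^2 + (cv$y - ctr["y"])^2))
  off <- tibble::tibble(x_px = ctr["x"] + (r + 3) * cos(ang),
                        y_px = ctr["y"] + (r + 3) * sin(ang))
  expect_equal(tracing_error(off, cv), 3, tolerance = 0.02)
  on_curve <- tibble::tibble(x_px = cv$x, y_px = cv$y)
  expect_lt(tracing_error(on_curve, cv), 1e-9)
})

test_that("acceleration and jerk scale as k^2 and k^3 under time rescaling", {
  t <- seq(0, 6, by = 1 / 60)
  path_x <- function(u) 300 * cos(u) + 40 * cos(3 * u)
  path_y <- function(u) 300 * sin(u) + 40 * sin(2 * u)
  k <- 2
  s_slow <- make_series(t, path_x(t), path_y(t))
  s_fast <- make_series(t[t <= 3], path_x(k * t[t <= 3]),
                        path_y(k * t[t <= 3]))
  # compare over a common window of the path parameter u
  m <- function(z, s, u) mean(abs(z[s$interior & u >= 1 & u <= 5]))
  u_slow <- t; u_fast <- k * t[t <= 3]
  expect_equal(m(s_fast$a, s_fast, u_fast) / m(s_slow$a, s_slow, u_slow),
               k^2, tolerance = 0.01)
  expect_equal(m(s_fast$j, s_fast, u_fast) / m(s_slow$j, s_slow, u_slow),
               k^3, tolerance = 0.01)
})

test_that("feature extraction yields nine finite features deterministically", {
  cv <- tk_curve("rounded_square")
  set.seed(19)
  tr <- simulate_trial_trajectory(cv, default_profiles()$ASD, n_cycles = 3,
                                  config = tk_small_config())
  tr$participant_id <- "ASD001"; tr$shape <- "rounded_square"
  cl <- resample_uniform(trim_initial_theta(
    compute_angular_displacement(tr, cv)))
  f1 <- extract_features(cl, cv)
  dvs <- c("speed", "acceleration", "jerk", "min_speed", "max_speed",
           "submovement_pct", "speed_modulation", "sparc", "error_px")
  expect_true(all(dvs %in% names(f1)))
  expect_true(all(is.finite(unlist(f1[dvs]))))
  expect_true(f1$min_speed <= f1$max_speed)
  expect_gte(f1$submovement_pct, 0)
  expect_lte(f1$submovement_pct, 100)
  expect_identical(extract_features(cl, cv), f1)
})

test_that("generating exponents are recovered across shapes (noiseless)", {
  # spot-check two shapes here; the full grid runs in the acceptance suite
  for (nm in c("clover", "rounded_square")) {
    for (b in c(0.2, 0.5)) {
      cl <- tk_clean_trial(nm, beta = b, noise = FALSE)
      expect_equal(speed_modulation(differentiate(cl))$beta, b,
                   tolerance = 0.05 * b, label = paste(nm, b))
    }
  }
})
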