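# Pure-frequency target shapes.
#
# A pure-frequency curve is defined by a log-curvature profile that is
# sinusoidal in the tangent (heading) angle theta:
#
#   kappa(theta) = kappa0 * exp(epsilon * sin(nu * theta + phase))
#
# where nu = p/q (in lowest terms) is the angular frequency: the number of
# curvature oscillations per 2*pi of angular displacement. Position follows
# from integrating dx/dtheta = cos(theta)/kappa, dy/dtheta = sin(theta)/kappa
# over theta in [0, 2*pi*q], after which the curve closes.

# canonical task shapes: angular frequency p/q and default log-curvature
# oscillation amplitude (amplitudes are package defaults, configurable)
.shape_catalog <- tibble::tribble(
  ~name,            ~p, ~q, ~epsilon,
  "clover",          4L, 5L, 1.2,
  "petals",          4L, 3L, 1.0,
  "ellipse",         2L, 1L, 0.7,
  "rounded_square",  4L, 1L, 0.8
)

#' Device scale of the reference touchscreen
#'
#' Pixels per millimetre for a 2000 x 1200 px display with a 10.40-inch
#' diagonal, the tablet the task configuration is calibrated for.
#'
#' @return Scale in px/mm (about 8.83).
#' @export
device_scale_px_per_mm <- function() {
  diag_px <- sqrt(2000^2 + 1200^2)
  diag_mm <- 10.40 * 25.4
  diag_px / diag_mm
}

#' Specify a pure-frequency target shape
#'
#' @param name One of `"clover"`, `"petals"`, `"ellipse"`,
#'   `"rounded_square"`, or any label when `nu` is supplied explicitly.
#' @param nu Angular frequency as an integer pair `c(p, q)` in lowest terms
#'   (oscillations per 2*pi of angular displacement is `p/q`). Defaults to
#'   the catalog value for the named shape.
#' @param epsilon Log-curvature oscillation amplitude (> 0, dimensionless).
#' @param max_dim_px Size cap in pixels: the larger bounding-box dimension of
#'   the generated curve. Default is 9 cm at the reference device scale.
#' @param samples_per_cycle Output samples per 2*pi of angular displacement.
#'
#' @return A `shape_spec` list.
#' @export
shape_spec <- function(name,
                       nu = NULL,
                       epsilon = NULL,
                       max_dim_px = round(90 * device_scale_px_per_mm()),
                       samples_per_cycle = 512L) {
  row <- .shape_catalog[.shape_catalog$name == name, ]
  if (is.null(nu)) {
    if (nrow(row) == 0) {
      abort(paste0("unknown shape '", name, "'; supply nu = c(p, q)"))
    }
    nu <- c(row$p, row$q)
  }
  if (length(nu) != 2 || any(nu != round(nu)) || any(nu < 1)) {
    abort("nu must be a pair of positive integers c(p, q): rational angular frequency")
  }
  nu <- as.integer(round(nu))
  g <- .gcd(nu[1], nu[2])
  nu <- nu %/% g
  if (is.null(epsilon)) {
    epsilon <- if (nrow(row)) row$epsilon else 1
  }
  stopifnot(epsilon > 0, max_dim_px > 0, samples_per_cycle >= 16)
  structure(
    list(name = name, p = nu[1], q = nu[2], epsilon = epsilon,
         max_dim_px = max_dim_px,
         samples_per_cycle = as.integer(samples_per_cycle)),
    class = "shape_spec"
  )
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' @export
print.shape_spec <- function(x, ...) {
  cat(sprintf("<shape_spec> %s: AF %d/%d, epsilon %.3g, max dim %d px\n",
              x$name, x$p, x$q, x$epsilon, x$max_dim_px))
  invisible(x)
}

#' Generate a pure-frequency ideal curve
#'
#' Integrates the heading-angle ODE `dx/dtheta = cos(theta)/kappa(theta)`,
#' `dy/dtheta = sin(theta)/kappa(theta)` with
#' `kappa(theta) = kappa0 * exp(epsilon * sin(nu * theta))` over one closed
#' traversal `theta` in `[0, 2*pi*q]`, using a fixed-step fourth-order
#' scheme at no fewer than 2048 steps per 2*pi. Residual numerical drift is
#' removed by a drift correction linear in theta (total magnitude bounded by
#' the endpoint gap), and the curve is uniformly rescaled so its larger
#' bounding-box dimension equals `max_dim_px`.
#'
#' @param spec A [shape_spec()].
#' @param phase Phase offset of the curvature oscillation (radians).
#'
#' @return An `ideal_curve` tibble with columns `theta` (rad, strictly
#'   increasing), `s` (cumulative arc length, px), `x`, `y` (px, bounding box
#'   centred on the origin), and `kappa` (1/px). Attributes carry the spec,
#'   perimeter, centroid and winding number. The final row duplicates the
#'   starting point at `theta = 2*pi*q`.
#' @export
#' @examples
#' sq <- generate_shape(shape_spec("rounded_square"))
#' count_curvature_oscillations(sq)  # 4 per 2*pi
generate_shape <- function(spec, phase = 0) {
  stopifnot(inherits(spec, "shape_spec"))
  p <- spec$p; q <- spec$q; eps <- spec$epsilon
  spc <- spec$samples_per_cycle
  # fine grid: even refinement so composite Simpson lands on output samples
  m <- 2L * ceiling(2048 / (2 * spc))
  n_fine_per_cycle <- spc * m
  n_fine <- n_fine_per_cycle * q
  h <- 2 * pi / n_fine_per_cycle
  th <- seq(0, by = h, length.out = n_fine + 1)
  kap <- exp(eps * sin((p / q) * th + phase))
  fx <- cos(th) / kap
  fy <- sin(th) / kap
  fs <- 1 / kap
  x <- .cumsimpson(fx, h)
  y <- .cumsimpson(fy, h)
  s <- .cumsimpson(fs, h)
  # keep even fine indices (where Simpson partial sums are defined)
  keep <- seq(1, n_fine + 1, by = 2)
  th <- th[keep]; kap <- kap[keep]; x <- x[keep]; y <- y[keep]; s <- s[keep]
  # thin to the requested output resolution
  step <- (m %/% 2)
  out <- seq(1, length(th), by = step)
  th <- th[out]; kap <- kap[out]; x <- x[out]; y <- y[out]; s <- s[out]

  # closure: remove linear-in-theta drift (endpoint gap spread along curve)
  gap <- c(x[length(x)] - x[1], y[length(y)] - y[1])
  frac <- (th - th[1]) / (th[length(th)] - th[1])
  x <- x - gap[1] * frac
  y <- y - gap[2] * frac
  perim <- s[length(s)]
  res_gap <- sqrt(sum((c(x[length(x)], y[length(y)]) - c(x[1], y[1]))^2))
  if (res_gap > 1e-6 * perim) {
    abort(sprintf("curve failed to close: residual gap %.3g px (%.3g of perimeter)",
                  res_gap, res_gap / perim))
  }

  # uniform rescale so the larger bounding-box dimension hits the size cap
  wh <- c(diff(range(x)), diff(range(y)))
  lam <- spec$max_dim_px / max(wh)
  x <- x * lam; y <- y * lam; s <- s * lam; kap <- kap / lam
  # centre the bounding box on the origin
  x <- x - mean(range(x))
  y <- y - mean(range(y))

  # arc-length-weighted centroid and winding number about it
  ds <- diff(s)
  cx <- sum((x[-1] + x[-length(x)]) / 2 * ds) / sum(ds)
  cy <- sum((y[-1] + y[-length(y)]) / 2 * ds) / sum(ds)
  ang <- .unwrap(atan2(y - cy, x - cx))
  winding <- round((ang[length(ang)] - ang[1]) / (2 * pi))

  curve <- tibble::tibble(theta = th, s = s, x = x, y = y, kappa = kap)
  structure(
    curve,
    spec = spec,
    perimeter = s[length(s)] * 1,
    centroid = c(x = cx, y = cy),
    winding = as.integer(winding),
    closed = TRUE,
    class = c("ideal_curve", class(curve))
  )
}

# cumulative Simpson integral from 0; values valid at even indices (1-based
# odd positions); odd fine indices filled by trapezoid (discarded by caller)
.cumsimpson <- function(f, h) {
  n <- length(f)
  inc <- (h / 3) * (f[seq(1, n - 2, by = 2)] +
                    4 * f[seq(2, n - 1, by = 2)] +
                    f[seq(3, n, by = 2)])
  out <- numeric(n)
  out[seq(3, n, by = 2)] <- cumsum(inc)
  # odd interior points (unused downstream): trapezoid fill
  out[seq(2, n - 1, by = 2)] <-
    out[seq(1, n - 2, by = 2)] + (h / 2) * (f[seq(1, n - 2, by = 2)] + f[seq(2, n - 1, by = 2)])
  out
}

.unwrap <- function(a) {
  d <- diff(a)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(a[1], a[1] + cumsum(d))
}

#' Count curvature oscillations per 2*pi of angular displacement
#'
#' Counts strict local maxima of curvature over the curve's theta span and
#' normalizes per 2*pi. For a closed pure-frequency curve with angular
#' frequency p/q traversed over theta in `[0, 2*pi*q]` the result is exactly
#' p/q.
#'
#' @param curve An `ideal_curve`.
#' @return Oscillations per 2*pi of angular displacement (a scalar).
#' @export
count_curvature_oscillations <- function(curve) {
  stopifnot(inherits(curve, "ideal_curve"))
  th <- curve$theta
  kap <- curve$kappa
  span <- th[length(th)] - th[1]
  if (span < 2 * pi - 1e-9) {
    abort("curve must span at least one full 2*pi of angular displacement")
  }
  if (diff(range(kap)) <= 1e-9 * mean(kap)) {
    abort("degenerate curve: curvature is constant, oscillation count undefined")
  }
  closed <- isTRUE(attr(curve, "closed"))
  if (closed) {
    k <- kap[-length(kap)]   # drop duplicated endpoint, compare circularly
    n <- length(k)
    prv <- k[c(n, seq_len(n - 1))]
    nxt <- k[c(seq_len(n - 1) + 1, 1)]
    n_max <- sum(k > prv & k > nxt)
  } else {
    n <- length(kap)
    i <- 2:(n - 1)
    n_max <- sum(kap[i] > kap[i - 1] & kap[i] > kap[i + 1])
  }
  if (n_max == 0) {
    abort("no strict curvature maxima found; oscillation count undefined")
  }
  n_max * 2 * pi / span
}

#' Nearest-point frame on an ideal curve
#'
#' For each query point, finds the arc-length position on the densely sampled
#' curve polyline minimizing Euclidean distance (nearest vertex, refined by
#' exact projection onto the adjacent segments), and returns the tangent
#' direction there and the signed normal distance of the point from the
#' tangent line (positive to the left of the travel direction). Ties are
#' broken toward the smallest arc length.
#'
#' @param curve An `ideal_curve` (dense sampling recommended: at least 256
#'   samples per cycle).
#' @param points A data frame (or tibble) with columns `x` and `y`, in px.
#'
#' @return A tibble with one row per query point: `s` (arc length of the
#'   nearest point), `tangent_x`, `tangent_y` (unit tangent), `distance`
#'   (signed normal distance, px).
#' @export
nearest_point_frame <- function(curve, points) {
  stopifnot(inherits(curve, "ideal_curve"))
  if (nrow(curve) < 2) abort("empty or degenerate curve")
  qx <- points$x; qy <- points$y
  nq <- length(qx)
  cx <- curve$x; cy <- curve$y; cs <- curve$s
  nv <- length(cx)

  # nearest vertex, chunked to bound memory
  best <- integer(nq)
  v2 <- cx^2 + cy^2
  chunk <- max(1L, floor(4e6 / nv))
  for (i0 in seq(1, nq, by = chunk)) {
    ii <- i0:min(nq, i0 + chunk - 1)
    d2 <- outer(qx[ii]^2 + qy[ii]^2, v2, "+") -
      2 * (cbind(qx[ii], qy[ii]) %*% rbind(cx, cy))
    best[ii] <- max.col(-d2, ties.method = "first")
  }

  out_s <- numeric(nq); out_tx <- numeric(nq); out_ty <- numeric(nq)
  out_d <- numeric(nq)
  for (i in seq_len(nq)) {
    segs <- max(1L, best[i] - 2L):min(nv - 1L, best[i] + 1L)
    ax <- cx[segs]; ay <- cy[segs]
    bx <- cx[segs + 1L]; by <- cy[segs + 1L]
    ex <- bx - ax; ey <- by - ay
    len2 <- ex^2 + ey^2
    tt <- pmin(1, pmax(0, ((qx[i] - ax) * ex + (qy[i] - ay) * ey) / len2))
    px <- ax + tt * ex; py <- ay + tt * ey
    d2 <- (qx[i] - px)^2 + (qy[i] - py)^2
    j <- which(d2 <= min(d2) + 1e-12)[1]   # tie -> smallest arc length
    el <- sqrt(len2[j])
    out_tx[i] <- ex[j] / el
    out_ty[i] <- ey[j] / el
    out_s[i] <- cs[segs[j]] + tt[j] * (cs[segs[j] + 1L] - cs[segs[j]])
    # signed perpendicular offset from the tangent line; left of travel > 0
    out_d[i] <- out_tx[i] * (qy[i] - py[j]) - out_ty[i] * (qx[i] - px[j])
  }
  tibble::tibble(s = out_s, tangent_x = out_tx, tangent_y = out_ty,
                 distance = out_d)
}

#' Write / read an ideal curve as tabular text
#'
#' The curve samples are written as a tab-separated table (columns `theta`,
#' `s`, `x`, `y`, `kappa`) preceded by a `#`-commented key-value config block
#' (`name`, `p`, `q`, `epsilon`, `max_dim_px`, `samples_per_cycle`).
#'
#' @param curve An `ideal_curve`.
#' @param path Output file path.
#' @return `write_shape()` returns `path` invisibly; `read_shape()` returns
#'   the reconstructed `ideal_curve`.
#' @export
write_shape <- function(curve, path) {
  spec <- attr(curve, "spec")
  hdr <- c(
    paste0("# name: ", spec$name),
    paste0("# p: ", spec$p),
    paste0("# q: ", spec$q),
    paste0("# epsilon: ", format(spec$epsilon, digits = 17)),
    paste0("# max_dim_px: ", spec$max_dim_px),
    paste0("# samples_per_cycle: ", spec$samples_per_cycle)
  )
  writeLines(hdr, path)
  readr::write_tsv(as.data.frame(curve), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_shape
#' @export
read_shape <- function(path) {
  lines <- readLines(path, n = 20)
  kv <- grep("^# ", lines, value = TRUE)
  keys <- sub("^# ([^:]+): .*$", "\\1", kv)
  vals <- sub("^# [^:]+: ", "", kv)
  cfg <- setNames(as.list(vals), keys)
  spec <- shape_spec(
    name = cfg$name,
    nu = c(as.integer(cfg$p), as.integer(cfg$q)),
    epsilon = as.numeric(cfg$epsilon),
    max_dim_px = as.numeric(cfg$max_dim_px),
    samples_per_cycle = as.integer(cfg$samples_per_cycle)
  )
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  curve <- tibble::as_tibble(tab)
  ds <- diff(curve$s)
  cx <- sum((curve$x[-1] + curve$x[-nrow(curve)]) / 2 * ds) / sum(ds)
  cy <- sum((curve$y[-1] + curve$y[-nrow(curve)]) / 2 * ds) / sum(ds)
  ang <- .unwrap(atan2(curve$y - cy, curve$x - cx))
  structure(
    curve,
    spec = spec,
    perimeter = curve$s[nrow(curve)],
    centroid = c(x = cx, y = cy),
    winding = as.integer(round((ang[length(ang)] - ang[1]) / (2 * pi))),
    closed = TRUE,
    class = c("ideal_curve", class(curve))
  )
}

#' Plot an ideal curve
#'
#' @param object An `ideal_curve`.
#' @param colour_by Column mapped to colour (default curvature).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ideal_curve <- function(object, colour_by = "kappa", ...) {
  spec <- attr(object, "spec")
  ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$y,
                                       colour = .data[[colour_by]])) +
    ggplot2::geom_path(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("%s (AF %d/%d)", spec$name, spec$p, spec$q),
      x = "x (px)", y = "y (px)", colour = colour_by
    ) +
    ggplot2::theme_minimal()
}
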