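#' Pull settings for the constant-velocity steering protocol
#'
#' Parameters of the moving harmonic steering potential
#' `U = 1/2 k [v t - (x - x0)]^2` and of the overdamped Langevin integrator.
#' Units follow molecular-simulation convention: energy in kcal/mol, length
#' in angstroms, time in nanoseconds; the defaults `k = 5 (kcal/mol)/A^2`
#' and `v = 1.5 A/ns` are the standard constant-velocity protocol values.
#'
#' @param k Spring constant, (kcal/mol)/A^2 (default 5).
#' @param v Pulling rate, A/ns (default 1.5).
#' @param x0 Initial pulled-coordinate value (default 0).
#' @param dt Integration step, ns (default 1e-4).
#' @param n_steps Number of steps (default 40000, i.e. 4 ns).
#' @param gamma Friction, kcal/mol * ns / A^2 (default 0.05; the overdamped
#'   relaxation time gamma/k of 10 ps then sits well below the smoothing
#'   scale of the rupture detector, so thermal force noise averages out).
#' @param temperature Thermal energy k_B T in kcal/mol (default 0.5924,
#'   298 K).
#' @param record_every Store every this-many-th integration step (default
#'   25, i.e. one sample per 2.5 ps at the default `dt`); the steering-force
#'   identity holds at every recorded sample.
#' @return A `pull_settings` object.
#' @export
pull_settings <- function(k = 5, v = 1.5, x0 = 0, dt = 1e-4, n_steps = 40000,
                          gamma = 0.05, temperature = 0.5924,
                          record_every = 25) {
  stopifnot(k > 0, v > 0, dt > 0, n_steps >= 1, gamma > 0, temperature >= 0,
            record_every >= 1)
  structure(list(k = k, v = v, x0 = x0, dt = dt, n_steps = as.integer(n_steps),
                 gamma = gamma, temperature = temperature,
                 record_every = as.integer(record_every)),
            class = "pull_settings")
}

#' Energy landscape built from Gaussian wells
#'
#' `U(x) = sum_i -depth_i exp(-(x - position_i)^2 / (2 width_i^2))`:
#' continuously differentiable, finite everywhere, with a bound (closed)
#' well and an unbound flat region beyond the last well. Stands in for the
#' inter-domain interaction that an all-atom system would provide.
#'
#' @param wells Data frame with columns `position` (A), `depth` (kcal/mol,
#'   positive = attractive) and `width` (A).
#' @return A `pull_landscape` with `potential(x)` and `gradient(x)`
#'   functions plus the well table.
#' @export
landscape <- function(wells) {
  wells <- as_tibble(wells)
  stopifnot(all(c("position", "depth", "width") %in% names(wells)),
            all(wells$width > 0))
  U <- function(x) {
    out <- 0
    for (i in seq_len(nrow(wells))) {
      z <- (x - wells$position[i]) / wells$width[i]
      out <- out - wells$depth[i] * exp(-0.5 * z^2)
    }
    out
  }
  dU <- function(x) {
    out <- 0
    for (i in seq_len(nrow(wells))) {
      z <- (x - wells$position[i]) / wells$width[i]
      out <- out + wells$depth[i] * z / wells$width[i] * exp(-0.5 * z^2)
    }
    out
  }
  structure(list(wells = wells, potential = U, gradient = dU),
            class = "pull_landscape")
}

#' @rdname landscape
#' @param depth,width,position Well parameters for the single-well
#'   convenience constructor (defaults 30 kcal/mol, 1.2 A, 0: a bound well
#'   whose maximum restoring force, ~15 kcal/mol/A, stands an order of
#'   magnitude above the thermal force noise sqrt(k*k_B*T) of the default
#'   spring).
#' @export
single_well_landscape <- function(depth = 30, width = 1.2, position = 0) {
  landscape(tibble(position = position, depth = depth, width = width))
}

#' @rdname landscape
#' @param depth2,width2,position2 Second (outer) well (defaults 30 kcal/mol,
#'   1.2 A, 8 A). By default the outer well is the deeper one, so escaping
#'   it is the rate-limiting, dominant rupture and the inner-well escape is
#'   an earlier, smaller force drop — the two-stage opening pattern.
#' @export
two_well_landscape <- function(depth = 12, width = 1.2, position = 0,
                               depth2 = 30, width2 = 1.2, position2 = 8) {
  landscape(tibble(position = c(position, position2),
                   depth = c(depth, depth2), width = c(width, width2)))
}

#' Steering potential energy and force
#'
#' `U = 1/2 k [v t - (x - x0)]^2`; the force on the pulled coordinate is
#' `F = k [v t - (x - x0)]` (signed along the pulling direction). Vectorized
#' over `x` and `t`.
#'
#' @param x Pulled coordinate value(s).
#' @param t Time(s), ns.
#' @param settings A [pull_settings()].
#' @return Tibble with `U` and `F`.
#' @export
steering_energy_force <- function(x, t, settings) {
  stopifnot(inherits(settings, "pull_settings"))
  ext <- settings$v * t - (x - settings$x0)
  tibble(U = 0.5 * settings$k * ext^2, F = settings$k * ext)
}

#' Integrate a constant-velocity pulling trajectory
#'
#' Euler-Maruyama integration of the overdamped Langevin equation
#' `dx = [-U'(x) + F_steer] / gamma dt + sqrt(2 T dt / gamma) dW` with the
#' moving-spring steering force. The recorded force equals
#' `k * (reference - x)` at every step by construction. The step size is
#' validated against the smallest landscape feature (drift per step must be
#' below a tenth of the narrowest well width); a trajectory leaving the
#' simulated range is truncated and flagged.
#'
#' @param land A [landscape()].
#' @param settings A [pull_settings()].
#' @param seed Integer seed.
#' @return A `pull_trajectory` tibble: `time`, `x`, `reference`, `force`;
#'   attributes `settings`, `landscape`, `diverged`.
#' @export
integrate_pull <- function(land, settings, seed = NULL) {
  stopifnot(inherits(land, "pull_landscape"),
            inherits(settings, "pull_settings"))
  # validate dt: bound the deterministic drift per step
  grid <- seq(min(land$wells$position) - 5 * max(land$wells$width),
              max(land$wells$position) + 5 * max(land$wells$width),
              length.out = 400)
  # the spring force cannot exceed the landscape's maximum restoring force
  # plus the steady drag and a thermal allowance before the particle yields
  fmax <- 2 * max(abs(land$gradient(grid))) + settings$gamma * settings$v +
    5 * sqrt(settings$k * settings$temperature)
  if (fmax / settings$gamma * settings$dt > 0.1 * min(land$wells$width)) {
    abort("dt too large: drift per step exceeds a tenth of the smallest landscape feature")
  }
  x_max <- max(abs(grid)) + abs(settings$x0) +
    settings$v * settings$n_steps * settings$dt + 100
  res <- run_seeded(seed,
    langevin_pull(land$wells$position, land$wells$depth, land$wells$width,
                  settings$k, settings$v, settings$x0, settings$dt,
                  settings$n_steps, settings$gamma, settings$temperature,
                  x_max, settings$record_every))
  n <- length(res$x)
  out <- tibble(time = (seq_len(n) - 1) * settings$dt * settings$record_every,
                x = res$x, reference = res$reference, force = res$force)
  attr(out, "settings") <- settings
  attr(out, "landscape") <- land
  attr(out, "diverged") <- res$diverged
  class(out) <- c("pull_trajectory", class(out))
  if (res$diverged) warn("trajectory left the simulated range; truncated")
  out
}

#' Detect the critical turning point (rupture) of a force trace
#'
#' On the moving-average-smoothed force the turning point is the last local
#' maximum after which the force stays below `drop_fraction` of that maximum
#' for at least `sustain_frames` samples — the formalization of the abrupt
#' force drop that marks domain dissociation.
#'
#' @param force Numeric force series (or a `pull_trajectory`).
#' @param smooth_window Moving-average window, samples (default 51).
#' @param drop_fraction Drop threshold relative to the peak (default 0.2).
#' @param sustain_frames Samples the force must remain below the threshold
#'   (default 200 recorded samples, i.e. 0.5 ns at the default recording
#'   cadence).
#' @param min_peak_fraction Candidate maxima must reach this fraction of the
#'   global smoothed maximum (default 0.5) — the rupture peak is by
#'   definition a dominant feature, and this keeps post-rupture noise bumps
#'   from qualifying.
#' @param min_significance Candidate maxima must also stand this many
#'   smoothed-noise standard deviations above zero (default 6; the noise
#'   scale is estimated robustly from first differences), so featureless
#'   noise yields no detection.
#' @param time Optional time axis (taken from a `pull_trajectory` input).
#' @return A `rupture_event` (list with `turning_index`, `turning_time`,
#'   `peak_force`, `post_drop_mean`) or `NULL` when no rupture is found.
#' @export
detect_turning_point <- function(force, smooth_window = 51,
                                 drop_fraction = 0.2, sustain_frames = 200,
                                 min_peak_fraction = 0.5,
                                 min_significance = 6, time = NULL) {
  if (inherits(force, "pull_trajectory")) {
    time <- force$time
    force <- force$force
  }
  n <- length(force)
  if (n <= 2 * smooth_window) abort("series shorter than 2 * smooth_window")
  if (is.null(time)) time <- seq_len(n) - 1
  s <- moving_average(force, smooth_window)
  noise_floor <- min_significance * stats::mad(diff(force)) / sqrt(2) /
    sqrt(max(smooth_window, 1))
  # local maxima of the smoothed series
  up <- c(FALSE, diff(s) > 0)
  dn <- c(diff(s) < 0, FALSE)
  cand <- which(up & dn & s > 0 & s > noise_floor &
                  s >= min_peak_fraction * max(s, na.rm = TRUE))
  if (!length(cand)) return(NULL)
  for (i in rev(cand)) {
    thr <- drop_fraction * s[i]
    below <- s[(i + 1):n] < thr
    if (!any(below)) next
    # first run of sub-threshold samples at least sustain_frames long
    # (transient rebinding right after the drop is allowed to re-spike)
    r <- rle(below)
    ends <- cumsum(r$lengths)
    hit <- which(r$values & r$lengths >= sustain_frames)
    if (!length(hit)) next
    j <- i + ends[hit[1]] - r$lengths[hit[1]] + 1
    post <- force[j:n]
    ev <- list(turning_index = i, turning_time = time[i],
               peak_force = max(force[max(1, i - smooth_window):
                                        min(n, i + smooth_window)]),
               post_drop_mean = mean(post))
    class(ev) <- "rupture_event"
    return(ev)
  }
  NULL
}

#' @export
print.rupture_event <- function(x, ...) {
  cat(sprintf("<rupture_event> turning time %.4g, peak force %.4g, post-drop mean %.4g\n",
              x$turning_time, x$peak_force, x$post_drop_mean))
  invisible(x)
}

moving_average <- function(x, w) {
  if (w <= 1) return(x)
  k <- rep(1 / w, w)
  as.numeric(stats::filter(x, k, sides = 2)) -> s
  # fill the edges with shrinking windows
  half <- floor(w / 2)
  n <- length(x)
  for (i in seq_len(half)) {
    s[i] <- mean(x[1:(i + half)])
    s[n - i + 1] <- mean(x[(n - i + 1 - half):n])
  }
  s
}

#' Mean-shift changepoints by binary segmentation
#'
#' Recursive binary segmentation on the segment means: the best split (the
#' one minimizing the two-segment residual sum of squares) is accepted when
#' its cost reduction exceeds `penalty`, then both sides are searched
#' recursively. With `penalty = NULL` a noise-scaled default
#' `2 * sigma^2 * log(n)` is used, with `sigma` estimated robustly from
#' first differences (MAD / sqrt(2)).
#'
#' @param x Numeric series (finite).
#' @param penalty Minimum SSE reduction to accept a split, or `NULL` for the
#'   default.
#' @param min_seg Minimum segment length (default 5).
#' @return Sorted integer vector of changepoint indices (first index of each
#'   new segment); empty when none.
#' @export
detect_distance_steps <- function(x, penalty = NULL, min_seg = 5) {
  stopifnot(all(is.finite(x)))
  n <- length(x)
  if (n < 2 * min_seg) return(integer(0))
  if (is.null(penalty)) {
    sigma <- stats::mad(diff(x)) / sqrt(2)
    if (sigma == 0) sigma <- 1e-12
    penalty <- 2 * sigma^2 * log(n)
  }
  cps <- integer(0)
  segment <- function(lo, hi) {
    len <- hi - lo + 1
    if (len < 2 * min_seg) return(invisible())
    seg <- x[lo:hi]
    cs <- cumsum(seg); cs2 <- cumsum(seg^2)
    ks <- seq(min_seg, len - min_seg)
    sse1 <- cs2[ks] - cs[ks]^2 / ks
    sse2 <- (cs2[len] - cs2[ks]) - (cs[len] - cs[ks])^2 / (len - ks)
    sse0 <- cs2[len] - cs[len]^2 / len
    gain <- sse0 - (sse1 + sse2)
    b <- which.max(gain)
    if (gain[b] > penalty) {
      cp <- lo + ks[b] # first index of the right segment (absolute)
      cps <<- c(cps, cp)
      segment(lo, cp - 1)
      segment(cp, hi)
    }
    invisible()
  }
  segment(1, n)
  sort(cps)
}

#' Synchrony of distance steps with the force turning point
#'
#' Flags each named distance series as synchronous with the rupture when any
#' of its changepoints lies within `tolerance` samples of the turning point;
#' the signed lag (nearest changepoint minus turning index, in samples) is
#' reported either way, so an early step (e.g. a first-stage dissociation
#' preceding the rupture) shows up as a negative-lag, non-synchronous event.
#'
#' @param rupture A `rupture_event` from [detect_turning_point()].
#' @param steps Named list of changepoint index vectors, one per distance
#'   series (from [detect_distance_steps()]).
#' @param tolerance Matching window in samples.
#' @return Tibble with `distance`, `synchronous`, `lag` (samples; `NA` when
#'   the series has no changepoints), `n_steps`.
#' @export
synchrony_report <- function(rupture, steps, tolerance) {
  stopifnot(inherits(rupture, "rupture_event"), tolerance >= 0)
  purrr::imap_dfr(steps, function(cp, name) {
    if (!length(cp)) {
      return(tibble(distance = name, synchronous = FALSE, lag = NA_real_,
                    n_steps = 0L))
    }
    lags <- cp - rupture$turning_index
    nearest <- lags[which.min(abs(lags))]
    tibble(distance = name, synchronous = abs(nearest) <= tolerance,
           lag = nearest, n_steps = length(cp))
  })
}

#' Write / read force or distance series as TSV
#'
#' Two-column TSV (`time`, `value`); any force/distance series from an
#' external simulation in this layout can be fed to the detectors.
#'
#' @param series Tibble or data frame with `time` and `value` columns (for a
#'   `pull_trajectory`, the force is written).
#' @param path File path.
#' @export
write_series <- function(series, path) {
  if (inherits(series, "pull_trajectory")) {
    series <- tibble(time = series$time, value = series$force)
  }
  stopifnot(all(c("time", "value") %in% names(series)))
  readr::write_tsv(as_tibble(series)[, c("time", "value")], path)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("time", "value") %in% names(out)))
  out
}
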