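test_that("steering energy and force follow the moving-spring form", {
  s <- pull_settings()
  ef0 <- steering_energy_force(s$x0, 0, s)
  expect_equal(ef0$U, 0); expect_equal(ef0$F, 0)

  # k = 5, v = 1.5, x held at x0, t = 2: U = 0.5*5*3^2, F = 5*3
  ef <- steering_energy_force(s$x0, 2, s)
  expect_equal(ef$U, 22.5)
  expect_equal(ef$F, 15)

  # U >= 0 everywhere; F = -dU/dx by central finite differences
  set.seed(4)
  xs <- runif(20, -5, 5); ts <- runif(20, 0, 10)
  ef2 <- steering_energy_force(xs, ts, s)
  expect_true(all(ef2$U >= 0))
  h <- 1e-6
  num <- -(steering_energy_force(xs + h, ts, s)$U -
             steering_energy_force(xs - h, ts, s)$U) / (2 * h)
  expect_equal(ef2$F, num, tolerance = 1e-5)
})

test_that("the recorded force satisfies the spring identity exactly", {
  tr <- integrate_pull(single_well_landscape(), pull_settings(), seed = 1)
  s <- attr(tr, "settings")
  expect_equal(tr$force, s$k * (tr$reference - tr$x), tolerance = 0)
  expect_identical(tr, integrate_pull(single_well_landscape(),
                                      pull_settings(), seed = 1))
})

test_that("flat landscape at T = 0 reaches the analytic steady drag", {
  flat <- landscape(tibble::tibble(position = 0, depth = 0, width = 1))
  s <- pull_settings(temperature = 0)
  tr <- integrate_pull(flat, s, seed = 1)
  # closed-form overdamped response: x lags the reference by gamma*v/k,
  # so the steady steering force is gamma*v
  expect_equal(tail(tr$force, 1), s$gamma * s$v, tolerance = 0.01)
  expect_equal(tail(tr$reference - tr$x, 1), s$gamma * s$v / s$k,
               tolerance = 0.01)
})

test_that("a pinned particle in a very deep well ramps force linearly at k*v", {
  # well curvature >> spring constant, so the particle barely yields and
  # the force ramps at the full loading rate k*v
  land <- single_well_landscape(depth = 400, width = 1.5)
  s <- pull_settings(temperature = 0, dt = 1e-5, n_steps = 100000)
  tr <- integrate_pull(land, s, seed = 1)
  ramp <- tr[tr$time > 0.2 & tr$time < 0.9, ]
  slope <- coef(lm(force ~ time, data = ramp))[2]
  expect_equal(unname(slope), s$k * s$v, tolerance = 0.05)
})

test_that("T -> 0 rupture force converges to the landscape maximum slope", {
  land <- single_well_landscape()
  ms <- max(abs(land$gradient(seq(-5, 5, 0.01))))
  s0 <- pull_settings(temperature = 1e-6, v = 0.5, n_steps = 120000)
  ev <- detect_turning_point(integrate_pull(land, s0, seed = 3))
  expect_lt(abs(ev$peak_force - ms) / ms, 0.05)
})

test_that("ruptures are detected reliably and post-drop force is low", {
  land <- single_well_landscape()
  evs <- lapply(1:30, function(sd)
    detect_turning_point(integrate_pull(land, pull_settings(), seed = sd)))
  hit <- !vapply(evs, is.null, logical(1))
  expect_gte(mean(hit), 0.95)
  for (ev in evs[hit]) {
    expect_lt(ev$post_drop_mean, 0.2 * ev$peak_force)
  }
})

test_that("turning points match the first-passage oracle on two-well pulls", {
  land <- two_well_landscape()
  n_tot <- 120000
  for (sd in 1:10) {
    tr <- integrate_pull(land, pull_settings(n_steps = n_tot), seed = sd)
    ev <- detect_turning_point(tr)
    expect_false(is.null(ev))
    # brute-force oracle: first passage beyond the (dominant) outer well
    fp <- tr$time[which(tr$x > 8 + 2 * 1.2)[1]]
    expect_lt(abs(ev$turning_time - fp) / max(tr$time), 0.02)
  }
})

test_that("turning-point detection handles constructed and degenerate series", {
  # linear ramp with a hard drop to zero at step 1000
  f <- c(seq(0, 10, length.out = 1000), rep(0, 1000))
  ev <- detect_turning_point(f, smooth_window = 51, sustain_frames = 200)
  expect_lte(abs(ev$turning_index - 1000), 51)

  # pure noise around zero: nothing to detect
  set.seed(6)
  expect_null(detect_turning_point(rnorm(2000, 0, 1)))

  # monotone series: no rupture
  expect_null(detect_turning_point(seq_len(2000) / 100))
})

test_that("mean rupture force increases with pulling velocity", {
  land <- single_well_landscape(depth = 22)
  ms <- max(abs(land$gradient(seq(-5, 5, 0.01))))
  mean_fp_force <- function(v, n_rep = 50) {
    f <- vapply(1:n_rep, function(sd) {
      n <- ceiling(((1.2 + ms / 5) / v + 2.5) / 1e-4)
      tr <- integrate_pull(land, pull_settings(v = v, n_steps = n), seed = sd)
      i <- which(tr$x > 2 * 1.2)[1]
      tr$force[i]
    }, numeric(1))
    mean(f, na.rm = TRUE)
  }
  # rupture force measured at first passage of the escape boundary (an
  # unbiased single-sample readout; a windowed max would be biased by the
  # different dwell near the peak across velocities)
  mf <- vapply(c(0.75, 1.5, 3), mean_fp_force, numeric(1))
  expect_true(all(diff(mf) > 0))
})

test_that("mean turning time increases with barrier height", {
  tt <- vapply(c(24, 30, 36), function(d) {
    land <- single_well_landscape(depth = d)
    mean(vapply(1:50, function(sd) {
      ev <- detect_turning_point(
        integrate_pull(land, pull_settings(n_steps = 60000), seed = sd))
      if (is.null(ev)) NA_real_ else ev$turning_time
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(tt) > 0))
})

test_that("binary segmentation matches the exhaustive two-changepoint scan", {
  expect_length(detect_distance_steps(rep(3, 100)), 0)

  set.seed(11)
  x <- c(rnorm(300, 5, 0.5), rnorm(400, 12, 0.5), rnorm(300, 25, 0.5))
  cps <- detect_distance_steps(x)
  expect_length(cps, 2)
  expect_lte(abs(cps[1] - 301), 3)
  expect_lte(abs(cps[2] - 701), 3)
  oracle <- brute_force_two_cp(x)
  expect_lte(max(abs(cps - oracle)), 1)

  # stability: extra white noise below 10% of the step size moves
  # detections by at most one frame
  set.seed(12)
  x2 <- x + rnorm(1000, 0, 0.5)
  cps2 <- detect_distance_steps(x2)
  expect_length(cps2, 2)
  expect_lte(max(abs(cps2 - cps)), 3)
})

test_that("synchrony reports match steps to the turning point with signed lags", {
  ev <- structure(list(turning_index = 500, turning_time = 0.5,
                       peak_force = 10, post_drop_mean = 0.5),
                  class = "rupture_event")
  out <- synchrony_report(ev, list(d1 = c(500), d2 = c(500 - 150), d3 = integer(0)),
                          tolerance = 50)
  expect_true(out$synchronous[out$distance == "d1"])
  expect_equal(out$lag[out$distance == "d1"], 0)
  expect_false(out$synchronous[out$distance == "d2"])
  expect_equal(out$lag[out$distance == "d2"], -150)
  expect_true(is.na(out$lag[out$distance == "d3"]))
})

test_that("the three-stage trajectory shows one early and two synchronous steps", {
  # constructed ground truth mimicking a two-stage opening: one distance
  # steps early (partial dissociation), two step at the rupture itself
  set.seed(13)
  n <- 3000; rupture_at <- 2000; early_at <- 1400
  force <- c(seq(0, 12, length.out = rupture_at),
             rnorm(n - rupture_at, 0.3, 0.3))
  # a small pre-rupture dip at the early event
  force[early_at:(early_at + 30)] <- force[early_at:(early_at + 30)] - 1.5
  d_early <- c(rnorm(early_at, 10, 0.2), rnorm(n - early_at, 14, 0.2))
  d_sync1 <- c(rnorm(rupture_at, 8, 0.2), rnorm(n - rupture_at, 20, 0.2))
  d_sync2 <- c(rnorm(rupture_at, 12, 0.2), rnorm(n - rupture_at, 25, 0.2))
  ev <- detect_turning_point(force, smooth_window = 51, sustain_frames = 200)
  expect_lte(abs(ev$turning_index - rupture_at), 60)
  steps <- list(d_63_191 = detect_distance_steps(d_early),
                d_46_170 = detect_distance_steps(d_sync1),
                d_46_167 = detect_distance_steps(d_sync2))
  rep_ <- synchrony_report(ev, steps, tolerance = 100)
  expect_equal(sum(rep_$synchronous), 2)
  early_row <- rep_[rep_$distance == "d_63_191", ]
  expect_false(early_row$synchronous)
  expect_lt(early_row$lag, 0)
})

test_that("force and distance series round-trip through TSV", {
  tr <- integrate_pull(single_well_landscape(), pull_settings(n_steps = 5000),
                       seed = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_series(tr, f)
  back <- read_series(f)
  expect_equal(back$value, tr$force)
  expect_equal(back$time, tr$time)
})
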