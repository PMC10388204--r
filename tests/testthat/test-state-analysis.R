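ideal_tbl <- function(values, trace_id = "t", frame = seq_along(values)) {
  tibble::tibble(trace_id = trace_id, frame = frame,
                 time_s = (frame - 1) * 0.1, efficiency_ideal = values,
                 efficiency = values)
}

test_that("transition pairs are compiled exactly from change points", {
  # constant trajectory: no pairs
  expect_equal(nrow(build_tdp(ideal_tbl(rep(0.4, 30)))$pairs), 0)
  # explicit construction
  tdp <- build_tdp(ideal_tbl(c(0.2, 0.2, 0.4, 0.4, 0.2)))
  expect_equal(tdp$pairs$e_from, c(0.2, 0.4))
  expect_equal(tdp$pairs$e_to, c(0.4, 0.2))
  # histogram mass equals the number of pairs
  expect_equal(sum(tdp$histogram), nrow(tdp$pairs))
  # a frame gap (bleach cut) breaks the pair chain
  gap <- ideal_tbl(c(0.2, 0.4, 0.6), frame = c(1, 2, 10))
  expect_equal(nrow(build_tdp(gap)$pairs), 1)
})

test_that("the 3-state benchmark reproduces the transition-density structure", {
  # idealized trajectories taken from the generator's true state paths
  m <- yykt6_model()
  tr <- simulate_traces(m, 150, 400, seed = 13)
  tr$efficiency_ideal <- m$efficiency_means[tr$state]
  tdp <- build_tdp(dplyr::filter(tr, pre_bleach))
  lab <- function(e) match(round(e, 2), round(m$efficiency_means, 2))
  from <- lab(tdp$pairs$e_from); to <- lab(tdp$pairs$e_to)
  n12 <- sum((from == 1 & to == 2) | (from == 2 & to == 1))
  n23 <- sum((from == 2 & to == 3) | (from == 3 & to == 2))
  n13 <- sum((from == 1 & to == 3) | (from == 3 & to == 1))
  expect_gt(n12, n23)
  expect_lt(n13 / nrow(tdp$pairs), 0.02)
})

test_that("global centers and thresholds follow the midpoint rule", {
  vals <- rep(c(0.20, 0.42, 0.68), times = c(50, 40, 10))
  gs <- derive_global_states(ideal_tbl(vals), 3)
  expect_equal(gs$centers, c(0.20, 0.42, 0.68))
  expect_equal(gs$thresholds, c(0.31, 0.55))

  # K = 1: single weighted mean, no thresholds
  gs1 <- derive_global_states(ideal_tbl(vals), 1)
  expect_equal(gs1$centers, mean(vals))
  expect_length(gs1$thresholds, 0)

  # permuting trace order changes nothing
  set.seed(1)
  tb <- ideal_tbl(vals)
  gs2 <- derive_global_states(tb[sample(nrow(tb)), ], 3)
  expect_equal(gs2, gs)

  expect_error(derive_global_states(ideal_tbl(rep(0.5, 10)), 3), "reduce K")
})

test_that("threshold assignment yields exact fractions, dwells and counts", {
  vals <- c(rep(0.2, 50), rep(0.7, 50))
  st <- assign_and_count(ideal_tbl(vals), c(0.2, 0.7), 0.45, frame_dt = 0.1)
  expect_equal(st$fractions, c(0.5, 0.5))
  expect_equal(sum(st$fractions), 1)

  # 10 A, 5 B, 10 A at 0.1 s per frame
  v2 <- c(rep(0.2, 10), rep(0.7, 5), rep(0.2, 10))
  st2 <- assign_and_count(ideal_tbl(v2), c(0.2, 0.7), 0.45, frame_dt = 0.1)
  dw <- st2$dwell_summaries
  expect_equal(dw$mean_dwell_s[dw$state_global == 1], 1.0)
  expect_equal(dw$mean_dwell_s[dw$state_global == 2], 0.5)
  expect_equal(st2$transition_counts, matrix(c(0L, 1L, 1L, 0L), 2, 2))
  expect_equal(sum(diag(st2$transition_counts)), 0)
  # conservation
  expect_equal(st2$n_frames, length(v2))
})

test_that("every compiled transition crosses at least one threshold", {
  m <- yykt6_model()
  tr <- quick_traces(m, 30, 600, seed = 21)
  ideal <- idealize_traces(tr, 3, n_restarts = 2, seed = 1)
  gs <- derive_global_states(ideal, 3)
  st <- assign_and_count(ideal, gs$centers, gs$thresholds)
  lab <- st$labeled
  tdp <- build_tdp(lab)
  crossings <- mapply(function(a, b) {
    sum(gs$thresholds > pmin(a, b) & gs$thresholds < pmax(a, b))
  }, tdp$pairs$e_from, tdp$pairs$e_to)
  # pairs between efficiencies in the same threshold bin don't change the
  # global label; every pair of *labeled* states must cross a threshold
  changed <- dplyr::group_by(lab, trace_id)
  changed <- dplyr::mutate(changed, moved = state_global != dplyr::lag(state_global))
  tdp_lab <- build_tdp(dplyr::mutate(lab, efficiency_ideal = gs$centers[state_global]))
  cross2 <- mapply(function(a, b) {
    sum(gs$thresholds > pmin(a, b) & gs$thresholds < pmax(a, b))
  }, tdp_lab$pairs$e_from, tdp_lab$pairs$e_to)
  expect_true(all(cross2 >= 1))
})

test_that("modal efficiencies come from Gaussian fits to per-state histograms", {
  # noiseless single state: the mode is exact
  lab <- tibble::tibble(efficiency = rep(0.42, 200), state_global = 1L)
  mp <- most_probable_efficiencies(lab)
  expect_equal(mp$modal_efficiency, 0.42, tolerance = 0.015)
  expect_false(mp$low_confidence)

  # a state with few frames is flagged low confidence
  lab2 <- tibble::tibble(efficiency = rnorm(30, 0.3, 0.05), state_global = 1L)
  expect_true(most_probable_efficiencies(lab2)$low_confidence)

  # symmetric contamination from neighbors leaves the mode in place
  set.seed(2)
  x <- c(rnorm(4000, 0.42, 0.05), rnorm(400, 0.20, 0.05), rnorm(400, 0.68, 0.05))
  lab3 <- tibble::tibble(efficiency = x, state_global = 1L)
  expect_equal(most_probable_efficiencies(lab3)$modal_efficiency, 0.42,
               tolerance = 0.025)
})

test_that("pooled histograms are density-normalized and orderable by breadth", {
  h <- build_fret_histogram(tibble::tibble(efficiency = rep(0.5, 100)),
                            bins = 50, range = c(0, 1))
  expect_equal(sum(h$count > 0), 1)
  expect_equal(sum(h$density) * diff(h$bin_mid[1:2]), 1)

  tr3 <- compute_efficiency(simulate_traces(yykt6_model(bleach_lifetime_s = Inf),
                                            80, 200, seed = 3))
  tr5 <- compute_efficiency(simulate_traces(rykt6_model(bleach_lifetime_s = Inf),
                                            80, 200, seed = 3))
  e3 <- tr3$efficiency[tr3$eff_valid]; e5 <- tr5$efficiency[tr5$eff_valid]
  expect_gt(var(e5), var(e3))
  expect_gt(mean(e5 > 0.6), mean(e3 > 0.6))
})

test_that("population comparisons implement the Welch two-tailed t test", {
  pm <- function(fr, movies = paste0("m", seq_along(fr))) {
    tibble::tibble(movie = movies, state_global = 1L, fraction = fr)
  }
  # identical groups: p = 1 for the degenerate equal-constant case
  out <- compare_populations(pm(c(0.5, 0.5)), pm(c(0.5, 0.5)))
  expect_equal(out$p, 1)

  # hand-computed 3 vs 3 Welch instance
  a <- c(0.50, 0.55, 0.45); b <- c(0.30, 0.35, 0.40)
  out2 <- compare_populations(pm(a), pm(b))
  sa <- var(a) / 3; sb <- var(b) / 3
  t_manual <- (mean(a) - mean(b)) / sqrt(sa + sb)
  df_manual <- (sa + sb)^2 / (sa^2 / 2 + sb^2 / 2)
  expect_equal(out2$t, t_manual)
  expect_equal(out2$df, df_manual)
  expect_equal(out2$p, 2 * stats::pt(-abs(t_manual), df_manual))

  # swapping groups negates t, keeps p
  out3 <- compare_populations(pm(b), pm(a))
  expect_equal(out3$t, -out2$t)
  expect_equal(out3$p, out2$p)
  expect_match(attr(out2, "note"), "no multiplicity")
})

test_that("a closed-state-stabilized ground truth shifts populations detectably", {
  m <- yykt6_model()
  ms <- shift_model(m, 0.25)
  expect_gt(sum(ms$occupancy * ms$efficiency_means),
            sum(m$occupancy * m$efficiency_means))
  run_one <- function(model, seed) {
    tr <- quick_traces(model, 40, 600, seed = seed, n_movies = 4)
    ideal <- idealize_traces(tr, 3, n_restarts = 2, seed = seed)
    gs <- derive_global_states(ideal, 3)
    assign_and_count(ideal, gs$centers, gs$thresholds)$per_movie_fractions
  }
  cmp <- compare_populations(run_one(m, 31), run_one(ms, 32))
  # the lowest (open) state loses occupancy significantly
  expect_lt(cmp$p[cmp$state_global == 1], 0.05)
  expect_gt(cmp$mean_a[cmp$state_global == 1],
            cmp$mean_b[cmp$state_global == 1])
})
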