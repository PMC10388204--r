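test_that("forward-backward reduces to closed forms and brute force", {
  # K = 1: log-likelihood is the sum of per-frame Normal log densities
  m1 <- fret_hmm(1, matrix(1, 1, 1), 0.4, 0.01)
  x <- c(0.35, 0.42, 0.5, 0.39)
  fb <- forward_backward(m1, x)
  expect_equal(fb$loglik, sum(dnorm(x, 0.4, 0.1, log = TRUE)))
  expect_true(all(fb$posterior == 1))

  # two frames, K = 2: matches enumeration over the 4 paths
  init <- c(0.6, 0.4)
  A <- matrix(c(0.8, 0.2, 0.3, 0.7), 2, 2, byrow = TRUE)
  m2 <- fret_hmm(init, A, c(0.2, 0.7), c(0.01, 0.02))
  x2 <- c(0.25, 0.6)
  bf <- brute_force_loglik(m2$initial, m2$transition, m2$means, m2$variances, x2)
  fb2 <- forward_backward(m2, x2)
  expect_equal(fb2$loglik, bf$loglik)
  expect_lt(max(abs(rowSums(fb2$posterior) - 1)), 1e-9)

  # symmetric two-state model on a symmetric series: swap symmetry
  ms <- fret_hmm(c(0.5, 0.5), matrix(0.5, 2, 2), c(-1, 1), c(1, 1))
  fbs <- forward_backward(ms, c(-0.3, 0.3))
  expect_equal(fbs$posterior[1, 1], fbs$posterior[2, 2])
  expect_equal(fbs$posterior[1, 2], fbs$posterior[2, 1])
})

test_that("forward and Viterbi agree with exhaustive path enumeration", {
  set.seed(31)
  for (K in 2:3) {
    init <- runif(K); init <- init / sum(init)
    A <- matrix(runif(K * K) + 0.1, K, K); A <- A / rowSums(A)
    means <- sort(runif(K)); vars <- runif(K, 0.002, 0.02)
    m <- fret_hmm(init, A, means, vars)
    x <- rnorm(6, sample(means, 6, replace = TRUE), 0.1)
    bf <- brute_force_loglik(m$initial, m$transition, m$means, m$variances, x)
    expect_equal(forward_backward(m, x)$loglik, bf$loglik)
    vt <- viterbi(m, x)
    expect_equal(attr(vt, "logprob"), bf$best_logprob)
    expect_equal(vt$state, unname(bf$best_path))
    expect_equal(vt$efficiency_ideal, m$means[vt$state])
  }
})

test_that("Viterbi breaks ties toward the lower state index", {
  # perfectly symmetric construction: every path probability is tied
  # (0.25/0.75/0.5 are exactly representable, so the log densities are
  # bitwise identical)
  m <- fret_hmm(c(0.5, 0.5), matrix(0.5, 2, 2), c(0.25, 0.75), c(0.01, 0.01))
  x <- rep(0.5, 5) # exactly midway between the state means
  vt <- viterbi(m, x)
  expect_equal(vt$state, rep(1L, 5))
})

test_that("Baum-Welch reaches the single-state fixed point and recovers parameters", {
  set.seed(5)
  x <- rnorm(300, 0.45, 0.07)
  f1 <- baum_welch(x, 1, n_restarts = 1)
  expect_equal(f1$model$means, mean(x), tolerance = 1e-6)
  expect_equal(f1$model$variances, var(x) * (299 / 300), tolerance = 1e-3)

  m <- gt_model(c(0.2, 0.7), matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2,
                                    byrow = TRUE),
                efficiency_sds = 0.05, camera_sd = 0, bleach_lifetime_s = Inf)
  tr <- compute_efficiency(simulate_traces(m, 1, 2000, seed = 6))
  f2 <- baum_welch(tr$efficiency, 2, n_restarts = 3, seed = 2)
  expect_lt(max(abs(f2$model$means - c(0.2, 0.7))), 0.02)
  # EM guarantee asserted on the stored trace
  expect_true(all(diff(f2$objective_trace) > -1e-8))
  expect_error(baum_welch(rnorm(5), 3), "longer than")
})

test_that("VB bound is monotone and agrees with ML in the data-dominated limit", {
  m <- gt_model(c(0.2, 0.7), matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2,
                                    byrow = TRUE),
                efficiency_sds = 0.05, camera_sd = 0, bleach_lifetime_s = Inf)
  tr <- compute_efficiency(simulate_traces(m, 1, 3000, seed = 8))
  x <- tr$efficiency
  fv <- vb_em(x, 2, n_restarts = 3, seed = 3)
  fm <- baum_welch(x, 2, n_restarts = 3, seed = 3)
  expect_true(all(diff(fv$objective_trace) > -1e-6))
  expect_lt(max(abs(fv$model$means - fm$model$means)), 0.01)
  # the bound cannot exceed the maximum log-likelihood
  expect_lt(fv$objective, fm$objective)

  # no-data case returns the prior-predictive model, flagged degenerate
  f0 <- vb_em(numeric(0), 2)
  expect_true(f0$degenerate)
  expect_equal(f0$objective, 0)
})

test_that("canonical ordering makes results invariant to state relabeling", {
  init <- c(0.3, 0.7); A <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  a <- fret_hmm(init, A, c(0.2, 0.6), c(0.01, 0.01))
  b <- fret_hmm(init[2:1], A[2:1, 2:1], c(0.6, 0.2), c(0.01, 0.01))
  expect_equal(a$means, b$means)
  expect_equal(a$transition, b$transition)
  x <- c(0.2, 0.6, 0.2)
  expect_equal(forward_backward(a, x)$loglik, forward_backward(b, x)$loglik)
  expect_equal(viterbi(a, x)$state, viterbi(b, x)$state)
})

test_that("state-count selection is parsimonious and finds the 3-state truth", {
  # 1-state data: parsimony picks K = 1
  m1 <- gt_model(0.5, matrix(1, 1, 1), bleach_lifetime_s = Inf)
  tr1 <- quick_traces(m1, 10, 150, seed = 2)
  sel1 <- select_states(tr1, 1:4, n_restarts = 2, seed = 2)
  expect_equal(sel1$K, 1)

  # scaled-down benchmark selection: 3-state truth recovered
  tr3 <- quick_traces(yykt6_model(), 40, 1000, seed = 3)
  sel3 <- select_states(tr3, 1:5, n_restarts = 2, seed = 3)
  expect_equal(sel3$K, 3)
  expect_equal(nrow(sel3$table), 5)
})

test_that("per-trace fits recover means and occupancies of the 3-state truth", {
  # scaled-down parameter-recovery property: seeded replicates, median errors
  errs_mean <- errs_occ <- numeric(0)
  for (rep_seed in 1:3) {
    tr <- quick_traces(yykt6_model(), 100, 1000, seed = 100 + rep_seed)
    ideal <- idealize_traces(tr, 3, n_restarts = 2, seed = rep_seed)
    gs <- derive_global_states(ideal, 3)
    st <- assign_and_count(ideal, gs$centers, gs$thresholds)
    errs_mean <- c(errs_mean, max(abs(gs$centers - c(0.20, 0.42, 0.68))))
    errs_occ <- c(errs_occ, max(abs(st$fractions - c(0.507, 0.397, 0.102))))
  }
  expect_lt(median(errs_mean), 0.02)
  expect_lt(median(errs_occ), 0.03)
})
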