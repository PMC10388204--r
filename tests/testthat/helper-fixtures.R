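# shared fixtures built in code; everything seeded

quick_traces <- function(model, n_traces, n_frames, seed = 1, ...) {
  tr <- simulate_traces(model, n_traces, n_frames, seed = seed, ...)
  tr <- detect_bleach(tr)
  tr <- compute_efficiency(tr)
  suppressMessages(filter_traces(tr, min_frames = 50))
}

# independent brute-force HMM path sum: log P(x) by enumerating all K^n paths
brute_force_loglik <- function(init, trans, means, vars, x) {
  n <- length(x); K <- length(init)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  lp <- apply(paths, 1, function(s) {
    l <- log(init[s[1]]) + dnorm(x[1], means[s[1]], sqrt(vars[s[1]]), log = TRUE)
    if (n > 1) for (t in 2:n) {
      l <- l + log(trans[s[t - 1], s[t]]) +
        dnorm(x[t], means[s[t]], sqrt(vars[s[t]]), log = TRUE)
    }
    l
  })
  list(loglik = log(sum(exp(lp - max(lp)))) + max(lp),
       best_logprob = max(lp),
       best_path = paths[which.max(lp), ])
}

# exhaustive two-changepoint mean-shift scan (minimum total SSE)
brute_force_two_cp <- function(x, min_seg = 5) {
  n <- length(x)
  best <- c(NA, NA); best_sse <- Inf
  sse <- function(seg) sum((seg - mean(seg))^2)
  for (a in seq(min_seg, n - 2 * min_seg)) {
    for (b in seq(a + min_seg, n - min_seg)) {
      s <- sse(x[1:a]) + sse(x[(a + 1):b]) + sse(x[(b + 1):n])
      if (s < best_sse) { best_sse <- s; best <- c(a + 1, b + 1) }
    }
  }
  best # first indices of segments 2 and 3
}

# exhaustive single-changepoint scan (two-segment SSE), downward only
brute_force_bleach <- function(x, window = 5) {
  n <- length(x)
  ks <- seq(window, n - window)
  sse <- vapply(ks, function(k) {
    sum((x[1:k] - mean(x[1:k]))^2) + sum((x[(k + 1):n] - mean(x[(k + 1):n]))^2)
  }, numeric(1))
  k <- ks[which.min(sse)]
  if (mean(x[(k + 1):n]) >= mean(x[1:k])) return(NA_integer_)
  k + 1L
}
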