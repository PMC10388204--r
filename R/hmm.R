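#' Construct / validate a Gaussian-emission HMM
#'
#' @param initial Initial state probabilities (length `K`).
#' @param transition Row-stochastic `K x K` matrix.
#' @param means Per-state emission means, in FRET-efficiency units.
#' @param variances Per-state emission variances (> 0).
#' @return An object of class `fret_hmm`. States are stored in canonical
#'   order (strictly increasing means).
#' @export
fret_hmm <- function(initial, transition, means, variances) {
  K <- length(means)
  initial <- as.numeric(initial); means <- as.numeric(means)
  variances <- as.numeric(variances); transition <- as.matrix(transition)
  stopifnot(length(initial) == K, length(variances) == K,
            all(dim(transition) == c(K, K)))
  if (any(initial < -1e-12) || abs(sum(initial) - 1) > 1e-10)
    abort("initial must be a probability vector")
  if (any(transition < -1e-12) || any(abs(rowSums(transition) - 1) > 1e-10))
    abort("transition rows must sum to 1")
  if (any(variances <= 0)) abort("variances must be positive")
  o <- order(means)
  structure(list(K = K, initial = pmax(initial[o], 0),
                 transition = pmax(transition[o, o, drop = FALSE], 0),
                 means = means[o], variances = variances[o]),
            class = "fret_hmm")
}

#' @export
print.fret_hmm <- function(x, ...) {
  cat(sprintf("<fret_hmm> K = %d\n", x$K))
  print(tibble(state = seq_len(x$K), mean = x$means,
               sd = sqrt(x$variances), initial = x$initial))
  invisible(x)
}

log_emissions <- function(model, series) {
  vapply(seq_len(model$K),
         function(k) dnorm(series, model$means[k], sqrt(model$variances[k]),
                           log = TRUE),
         numeric(length(series)))
}

#' Forward-backward inference
#'
#' Scaled forward-backward pass; returns the log-likelihood and per-frame
#' posterior state probabilities (rows summing to 1).
#'
#' @param model A [fret_hmm()].
#' @param series Numeric efficiency series (finite).
#' @return List with `loglik`, `posterior` (n x K matrix), `xi_sum`
#'   (expected transition counts, K x K).
#' @export
forward_backward <- function(model, series) {
  stopifnot(inherits(model, "fret_hmm"), all(is.finite(series)))
  logB <- matrix(log_emissions(model, series), ncol = model$K)
  if (any(!is.finite(logB) & !(logB == -Inf))) abort("non-finite emissions")
  if (any(apply(logB, 1, max) == -Inf)) {
    warn("frame(s) with zero probability under all states; floored")
    logB[logB == -Inf] <- -746
  }
  fb <- fb_scaled(logB, log(model$initial), log(model$transition))
  list(loglik = fb$loglik, posterior = fb$gamma, xi_sum = fb$xi_sum)
}

init_means <- function(series, K, jitter_sd = 0) {
  m <- as.numeric(quantile(series, probs = (2 * seq_len(K) - 1) / (2 * K)))
  if (K > 1) {
    km <- tryCatch(kmeans(series, centers = matrix(m, ncol = 1),
                          algorithm = "Lloyd", iter.max = 25),
                   error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(km)) m <- sort(as.numeric(km$centers))
  }
  if (jitter_sd > 0) m <- m + rnorm(K, 0, jitter_sd)
  sort(m)
}

start_model <- function(series, K, jitter_sd) {
  m <- init_means(series, K, jitter_sd)
  v <- rep(max(var(series) / max(K, 1), 1e-4), K)
  A <- matrix(0.1 / max(K - 1, 1), K, K); diag(A) <- if (K > 1) 0.9 else 1
  list(initial = rep(1 / K, K), transition = A, means = m, variances = v)
}

#' Maximum-likelihood HMM fit (Baum-Welch)
#'
#' EM on a single efficiency series with Gaussian emissions. The
#' log-likelihood is non-decreasing across iterations (an EM guarantee that
#' the test-suite asserts on every fit); collapsed variances are floored at
#' `1e-8` with a warning. The best of `n_restarts` jittered initializations
#' is returned, states sorted by mean.
#'
#' @param series Numeric efficiency series, length > `2 * K`.
#' @param K Number of states.
#' @param tol Convergence tolerance on the objective increment (default 1e-6).
#' @param max_iter Maximum EM iterations (default 500).
#' @param n_restarts Random restarts (default 10); restart means are jittered
#'   by Normal(0, 0.05) around the quantile/k-means initialization.
#' @param seed Integer seed for the restart jitter.
#' @return A `fret_fit` object: `model`, `objective` (final log-likelihood),
#'   `objective_trace`, `n_iterations`, `converged`, `restarts_used`,
#'   `method`.
#' @export
baum_welch <- function(series, K, tol = 1e-6, max_iter = 500,
                       n_restarts = 10, seed = NULL) {
  series <- as.numeric(series)
  stopifnot(all(is.finite(series)), K >= 1)
  if (length(series) <= 2 * K) abort("series must be longer than 2 * K")
  run_seeded(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- tryCatch(
        em_once(series, K, start_model(series, K, if (r == 1) 0 else 0.05),
                tol, max_iter),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$objective > best$objective))
        best <- fit
    }
    if (is.null(best)) abort("all Baum-Welch restarts failed")
    best$restarts_used <- n_restarts
    best$method <- "ml"
    class(best) <- "fret_fit"
    best
  })
}

em_once <- function(x, K, par, tol, max_iter) {
  n <- length(x)
  ll_trace <- numeric(0)
  ll_prev <- -Inf
  floored <- FALSE
  for (it in seq_len(max_iter)) {
    logB <- vapply(seq_len(K),
                   function(k) dnorm(x, par$means[k], sqrt(par$variances[k]),
                                     log = TRUE), numeric(n))
    logB <- matrix(logB, ncol = K)
    fb <- fb_scaled(logB, log(par$initial), log(par$transition))
    ll <- fb$loglik
    ll_trace <- c(ll_trace, ll)
    g <- fb$gamma
    Nk <- colSums(g)
    mu <- colSums(g * x) / Nk
    vv <- colSums(g * (x - rep(mu, each = n))^2) / Nk
    if (any(vv < 1e-8)) { vv <- pmax(vv, 1e-8); floored <- TRUE }
    A <- fb$xi_sum
    rs <- rowSums(A)
    A[rs <= 0, ] <- 1 / K
    A[rs > 0, ] <- A[rs > 0, , drop = FALSE] / rs[rs > 0]
    A <- pmax(A, 0); A <- A / rowSums(A)
    par <- list(initial = pmax(fb$gamma1, 1e-12) / sum(pmax(fb$gamma1, 1e-12)),
                transition = A, means = mu, variances = vv)
    if (is.finite(ll_prev) && ll - ll_prev < tol) break
    ll_prev <- ll
  }
  if (floored) warn("variance collapse: floored at 1e-8")
  model <- fret_hmm(par$initial, par$transition, par$means, par$variances)
  list(model = model, objective = ll_trace[length(ll_trace)],
       objective_trace = ll_trace, n_iterations = length(ll_trace),
       converged = length(ll_trace) < max_iter)
}

#' Variational-Bayes prior specification
#'
#' Conjugate hyperparameters: symmetric Dirichlet over the initial vector and
#' each transition row, Normal-Gamma over each state's (mean, precision).
#' Defaults are weak and centered at the series mean so the data dominate.
#'
#' @param series The series the prior will be centered on.
#' @param alpha Dirichlet concentration (default 1).
#' @param m0 Prior emission mean center (default `mean(series)`).
#' @param kappa0 Prior mean strength (default 0.25).
#' @param a0,b0 Gamma shape/rate over the emission precision
#'   (defaults 2.5, 0.01).
#' @return List of hyperparameters.
#' @export
vb_prior <- function(series, alpha = 1, m0 = mean(series), kappa0 = 0.25,
                     a0 = 2.5, b0 = 0.01) {
  list(alpha = alpha, m0 = m0, kappa0 = kappa0, a0 = a0, b0 = b0)
}

#' Variational-Bayes HMM fit with evidence lower bound
#'
#' Conjugate variational EM for the Gaussian-emission HMM. The objective is
#' the evidence lower bound (ELBO), non-decreasing across iterations (the
#' test-suite asserts this on every fit); the reported model is the posterior
#' mean. The mean ELBO across traces is the model-selection criterion of
#' [select_states()].
#'
#' @inheritParams baum_welch
#' @param prior A [vb_prior()]; defaults to weak data-centered hyperparameters.
#' @return A `fret_fit` with `method = "vb"`, `objective` = ELBO, and the
#'   posterior hyperparameters in `$posterior`.
#' @export
vb_em <- function(series, K, prior = NULL, tol = 1e-6, max_iter = 500,
                  n_restarts = 10, seed = NULL) {
  series <- as.numeric(series)
  stopifnot(K >= 1)
  if (length(series) == 0) {
    prior <- prior %||% list(alpha = 1, m0 = 0.5, kappa0 = 0.25, a0 = 2.5, b0 = 0.01)
    model <- fret_hmm(rep(1 / K, K), matrix(1 / K, K, K),
                      seq(0, 1, length.out = K + 2)[2:(K + 1)],
                      rep(prior$b0 / (prior$a0 - 1), K))
    out <- list(model = model, objective = 0, objective_trace = numeric(0),
                n_iterations = 0L, converged = TRUE, restarts_used = 0L,
                method = "vb", degenerate = TRUE)
    class(out) <- "fret_fit"
    return(out)
  }
  stopifnot(all(is.finite(series)))
  if (length(series) <= 2 * K) abort("series must be longer than 2 * K")
  prior <- prior %||% vb_prior(series)
  run_seeded(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- tryCatch(
        vb_once(series, K, prior, start_model(series, K, if (r == 1) 0 else 0.05),
                tol, max_iter),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$objective > best$objective))
        best <- fit
    }
    if (is.null(best)) abort("all VB restarts failed")
    best$restarts_used <- n_restarts
    best$method <- "vb"
    class(best) <- "fret_fit"
    best
  })
}

vb_once <- function(x, K, prior, par, tol, max_iter) {
  n <- length(x)
  # seed the posterior from hard assignments to the initial means
  lab <- max.col(-abs(outer(x, par$means, "-")), ties.method = "first")
  g <- matrix(0, n, K); g[cbind(seq_len(n), lab)] <- 1
  xi <- diag(0.9 * pmax(colSums(g) - 1, 0), K) + 0.1
  post <- vb_mstep(x, g, xi, g[1, ], prior, K)
  elbo_trace <- numeric(0)
  elbo_prev <- -Inf
  for (it in seq_len(max_iter)) {
    tp <- vb_tilted(post, x, K)
    fb <- fb_scaled(tp$logB, tp$log_init, tp$log_trans)
    elbo <- fb$loglik - vb_kl(post, prior, K)
    elbo_trace <- c(elbo_trace, elbo)
    post <- vb_mstep(x, fb$gamma, fb$xi_sum, fb$gamma1, prior, K)
    if (is.finite(elbo_prev) && elbo - elbo_prev < tol) break
    elbo_prev <- elbo
  }
  vmean <- post$b / pmax(post$a - 1, 0.5)
  model <- fret_hmm(post$alpha_init / sum(post$alpha_init),
                    post$alpha_trans / rowSums(post$alpha_trans),
                    post$m, vmean)
  list(model = model, objective = elbo_trace[length(elbo_trace)],
       objective_trace = elbo_trace, n_iterations = length(elbo_trace),
       converged = length(elbo_trace) < max_iter, posterior = post)
}

vb_mstep <- function(x, g, xi_sum, g1, prior, K) {
  n <- length(x)
  Nk <- colSums(g)
  xbar <- ifelse(Nk > 0, colSums(g * x) / pmax(Nk, 1e-12), prior$m0)
  Sk <- colSums(g * (x - rep(xbar, each = n))^2)
  kappa <- prior$kappa0 + Nk
  m <- (prior$kappa0 * prior$m0 + Nk * xbar) / kappa
  a <- prior$a0 + Nk / 2
  b <- prior$b0 + 0.5 * Sk +
    0.5 * prior$kappa0 * Nk * (xbar - prior$m0)^2 / kappa
  list(alpha_init = prior$alpha + g1,
       alpha_trans = prior$alpha + xi_sum,
       kappa = kappa, m = m, a = a, b = b)
}

vb_tilted <- function(post, x, K) {
  log_init <- digamma(post$alpha_init) - digamma(sum(post$alpha_init))
  log_trans <- digamma(post$alpha_trans) -
    digamma(rowSums(post$alpha_trans))
  logB <- vapply(seq_len(K), function(k) {
    0.5 * (digamma(post$a[k]) - log(post$b[k]) - log(2 * pi) -
             1 / post$kappa[k] - (post$a[k] / post$b[k]) * (x - post$m[k])^2)
  }, numeric(length(x)))
  list(logB = matrix(logB, ncol = K), log_init = log_init,
       log_trans = matrix(log_trans, K, K))
}

kl_dirichlet <- function(a, b) {
  if (length(b) == 1) b <- rep(b, length(a))
  lgamma(sum(a)) - lgamma(sum(b)) - sum(lgamma(a) - lgamma(b)) +
    sum((a - b) * (digamma(a) - digamma(sum(a))))
}

kl_normalgamma <- function(m, kappa, a, b, m0, kappa0, a0, b0) {
  kl_gamma <- (a - a0) * digamma(a) - lgamma(a) + lgamma(a0) +
    a0 * (log(b) - log(b0)) + a * (b0 - b) / b
  kl_norm <- 0.5 * (log(kappa / kappa0) + kappa0 / kappa - 1 +
                      kappa0 * (a / b) * (m - m0)^2)
  kl_gamma + kl_norm
}

vb_kl <- function(post, prior, K) {
  kl <- kl_dirichlet(post$alpha_init, prior$alpha)
  for (j in seq_len(K)) kl <- kl + kl_dirichlet(post$alpha_trans[j, ], prior$alpha)
  kl + sum(kl_normalgamma(post$m, post$kappa, post$a, post$b,
                          prior$m0, prior$kappa0, prior$a0, prior$b0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select the number of conformational states
#'
#' Fits every trace independently at each candidate `K` and selects the `K`
#' maximizing the mean per-trace objective: the mean evidence lower bound
#' (criterion `"evidence"`, default, mirroring mean-log-evidence selection)
#' or the mean of `-BIC/2` from maximum-likelihood fits (criterion `"bic"`).
#' Ties go to the smaller `K` (parsimony).
#'
#' @param traces A trace tibble with valid `efficiency` values (see
#'   [compute_efficiency()]), or a list of numeric efficiency series.
#' @param K_range Candidate state counts (default `1:6`).
#' @param criterion `"evidence"` or `"bic"`.
#' @param n_restarts Restarts per fit (default 3).
#' @param seed Integer seed.
#' @param ... Passed to [vb_em()] / [baum_welch()].
#' @return A `state_selection` object: `K` (selected), `table` (per-K mean
#'   objective tibble), `criterion`, `n_traces`.
#' @export
select_states <- function(traces, K_range = 1:6,
                          criterion = c("evidence", "bic"),
                          n_restarts = 3, seed = NULL, ...) {
  criterion <- match.arg(criterion)
  series_list <- as_series_list(traces)
  if (!length(K_range)) abort("K_range must be non-empty")
  scores <- matrix(NA_real_, length(series_list), length(K_range))
  for (ki in seq_along(K_range)) {
    K <- K_range[ki]
    for (si in seq_along(series_list)) {
      x <- series_list[[si]]
      if (length(x) <= 2 * K + 1) next
      s <- if (is.null(seed)) NULL else (seed + si) %% .Machine$integer.max
      scores[si, ki] <- if (criterion == "evidence") {
        vb_em(x, K, n_restarts = n_restarts, seed = s, ...)$objective
      } else {
        fit <- baum_welch(x, K, n_restarts = n_restarts, seed = s, ...)
        p <- (K - 1) + K * (K - 1) + 2 * K
        fit$objective - 0.5 * p * log(length(x))
      }
    }
  }
  keep <- complete.cases(scores)
  if (!any(keep)) abort("no trace long enough for the requested K_range")
  mean_obj <- colMeans(scores[keep, , drop = FALSE])
  best <- which(mean_obj >= max(mean_obj) - 1e-9)
  if (length(best) > 1) inform("tie in mean objective; smaller K selected")
  Ksel <- K_range[min(best)]
  structure(list(K = Ksel,
                 table = tibble(K = K_range, mean_objective = mean_obj,
                                n_traces = sum(keep)),
                 criterion = criterion, n_traces = sum(keep)),
            class = "state_selection")
}

#' @export
print.state_selection <- function(x, ...) {
  cat(sprintf("<state_selection> K* = %d by mean %s over %d traces\n",
              x$K, x$criterion, x$n_traces))
  print(x$table)
  invisible(x)
}

as_series_list <- function(traces) {
  if (is.data.frame(traces)) {
    tr <- prebleach_frames(traces)
    split(tr$efficiency, tr$trace_id)
  } else if (is.list(traces)) {
    traces
  } else {
    list(as.numeric(traces))
  }
}

#' Viterbi idealization of one series
#'
#' Most probable state path under a fitted model; each frame's idealized
#' efficiency is the fitted mean of its assigned state. Ties are broken
#' toward the lower state index. Deterministic.
#'
#' @param model A [fret_hmm()].
#' @param series Numeric efficiency series.
#' @return Tibble with `frame`, `state`, `efficiency_ideal`; the path log
#'   probability is attached as attribute `"logprob"`.
#' @export
viterbi <- function(model, series) {
  stopifnot(inherits(model, "fret_hmm"))
  logB <- matrix(log_emissions(model, series), ncol = model$K)
  vt <- viterbi_path(logB, log(model$initial), log(model$transition))
  out <- tibble(frame = seq_along(series), state = as.integer(vt$path),
                efficiency_ideal = model$means[vt$path])
  attr(out, "logprob") <- vt$logprob
  out
}

#' Fit and idealize every trace at a fixed K
#'
#' Per-trace HMM fit (variational Bayes by default, as the selection stage
#' uses) followed by Viterbi idealization. Operates on valid pre-bleach
#' frames only.
#'
#' @param traces Trace tibble after [compute_efficiency()].
#' @param K Number of states (e.g. from [select_states()]).
#' @param method `"vb"` (default) or `"ml"`.
#' @param n_restarts Restarts per fit (default 3).
#' @param seed Integer seed.
#' @param ... Passed to the fitter.
#' @return The pre-bleach trace tibble with `state_ideal` and
#'   `efficiency_ideal` columns; per-trace fits in attribute `"fits"`.
#' @export
idealize_traces <- function(traces, K, method = c("vb", "ml"),
                            n_restarts = 3, seed = NULL, ...) {
  method <- match.arg(method)
  tr <- prebleach_frames(traces)
  ids <- unique(tr$trace_id)
  fits <- vector("list", length(ids)); names(fits) <- ids
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    sub <- tr[tr$trace_id == ids[i], ]
    x <- sub$efficiency
    if (length(x) <= 2 * K + 1) next
    s <- if (is.null(seed)) NULL else (seed + i) %% .Machine$integer.max
    fit <- if (method == "vb") vb_em(x, K, n_restarts = n_restarts, seed = s, ...)
           else baum_welch(x, K, n_restarts = n_restarts, seed = s, ...)
    vt <- viterbi(fit$model, x)
    sub$state_ideal <- vt$state
    sub$efficiency_ideal <- vt$efficiency_ideal
    fits[[ids[i]]] <- fit
    out[[i]] <- sub
  }
  res <- bind_rows(out)
  if (!nrow(res)) abort("no trace long enough to idealize at this K")
  attr(res, "fits") <- fits[!vapply(fits, is.null, logical(1))]
  res
}
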