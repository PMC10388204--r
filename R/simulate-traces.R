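#' Sample a hidden conformational state path
#'
#' Draws a realization of the per-frame Markov chain of a ground-truth model,
#' starting from its stationary distribution.
#'
#' @param model A [gt_model()].
#' @param n_frames Number of frames (>= 1).
#' @param seed Integer seed; the draw is reproducible under an identical seed.
#' @return Integer vector of state indices (1-based), length `n_frames`.
#' @export
simulate_state_path <- function(model, n_frames, seed = NULL) {
  stopifnot(inherits(model, "gt_model"), n_frames >= 1)
  run_seeded(seed, sample_markov(model$occupancy, model$transition_matrix,
                                 as.integer(n_frames)))
}

#' Simulate one dual-channel intensity trace from a state path
#'
#' For each frame the true efficiency is drawn from the Gaussian emission of
#' the occupied state; the acceptor channel receives `e * T` and the donor
#' `(1 - e) * T` photons (`T` = total intensity), each with additive camera
#' noise. A photobleaching time is drawn from an exponential with the model's
#' mean dye lifetime; from the first bleached frame onward both channels
#' contain camera noise only.
#'
#' @param path Integer state path (from [simulate_state_path()]).
#' @param model The generating [gt_model()].
#' @param seed Integer seed.
#' @param trace_id Identifier stored in the output (default `"trace_1"`).
#' @return A tibble with columns `trace_id`, `frame`, `time_s`, `donor`,
#'   `acceptor` and ground-truth columns `state`, `efficiency_true`,
#'   `pre_bleach`; the per-trace bleach frame (first dark frame, `NA` if the
#'   dye outlives the recording) is repeated in `bleach_frame_true`.
#' @export
simulate_trace <- function(path, model, seed = NULL, trace_id = "trace_1") {
  stopifnot(inherits(model, "gt_model"), all(path >= 1), all(path <= model$K))
  n <- length(path)
  run_seeded(seed, {
    e <- rnorm(n, model$efficiency_means[path], model$efficiency_sds[path])
    bleach_frame <- NA_integer_
    if (is.finite(model$bleach_lifetime_s)) {
      tb <- rexp(1, rate = 1 / model$bleach_lifetime_s)
      bf <- floor(tb / model$frame_dt) + 1L # first frame past the bleach time
      if (bf <= n) bleach_frame <- bf
    }
    lit <- if (is.na(bleach_frame)) rep(TRUE, n) else seq_len(n) < bleach_frame
    T0 <- model$total_intensity
    acceptor <- ifelse(lit, e * T0, 0) + rnorm(n, 0, model$camera_sd)
    donor <- ifelse(lit, (1 - e) * T0, 0) + rnorm(n, 0, model$camera_sd)
    tibble(trace_id = trace_id, frame = seq_len(n),
           time_s = (seq_len(n) - 1) * model$frame_dt,
           donor = donor, acceptor = acceptor,
           state = as.integer(path), efficiency_true = e,
           pre_bleach = lit, bleach_frame_true = bleach_frame)
  })
}

#' Simulate a batch of smFRET traces
#'
#' Convenience wrapper drawing `n_traces` independent state paths and traces
#' under one seed, with movie (acquisition) labels for replicate-level
#' statistics.
#'
#' @inheritParams simulate_trace
#' @param n_traces Number of molecules.
#' @param n_frames Frames recorded per molecule.
#' @param n_movies Number of acquisitions the traces are (evenly) attributed
#'   to; stored in a `movie` column. Default 5.
#' @return Tibble in the [simulate_trace()] layout with an extra `movie`
#'   column.
#' @export
simulate_traces <- function(model, n_traces, n_frames, seed = NULL,
                            n_movies = 5) {
  stopifnot(n_traces >= 1)
  run_seeded(seed, {
    out <- purrr::map(seq_len(n_traces), function(i) {
      p <- sample_markov(model$occupancy, model$transition_matrix,
                         as.integer(n_frames))
      tr <- simulate_trace(p, model, seed = NULL,
                           trace_id = sprintf("trace_%03d", i))
      tr$movie <- sprintf("movie_%02d", ((i - 1) %% n_movies) + 1)
      tr
    })
    bind_rows(out)
  })
}

# Evaluate `expr` under `seed` without clobbering the caller's RNG state;
# a NULL seed uses (and advances) the current stream.
run_seeded <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}
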