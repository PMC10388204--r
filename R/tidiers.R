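#' Tidy / glance methods for fitted objects
#'
#' Broom-style summaries: `tidy()` returns one row per estimated component,
#' `glance()` one row per fit.
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.fret_fit <- function(x, ...) {
  m <- x$model
  tibble(state = seq_len(m$K), mean = m$means, variance = m$variances,
         sd = sqrt(m$variances), initial = m$initial)
}

#' @rdname tidiers
#' @export
glance.fret_fit <- function(x, ...) {
  tibble(K = x$model$K, objective = x$objective, method = x$method,
         n_iterations = x$n_iterations, converged = x$converged,
         restarts_used = x$restarts_used)
}

#' @rdname tidiers
#' @export
tidy.fret_hmm <- function(x, ...) {
  tibble(state = seq_len(x$K), mean = x$means, variance = x$variances,
         initial = x$initial)
}

#' @rdname tidiers
#' @export
tidy.state_selection <- function(x, ...) x$table

#' @rdname tidiers
#' @export
glance.state_selection <- function(x, ...) {
  tibble(K = x$K, criterion = x$criterion, n_traces = x$n_traces)
}

#' @rdname tidiers
#' @export
tidy.fret_states <- function(x, ...) {
  dw <- x$dwell_summaries
  tibble(state = seq_len(x$K), center = x$centers,
         fraction = x$fractions,
         mean_dwell_s = dw$mean_dwell_s[match(seq_len(x$K),
                                              dw$state_global)],
         n_dwells = dw$n_dwells[match(seq_len(x$K), dw$state_global)])
}

#' @rdname tidiers
#' @export
glance.fret_states <- function(x, ...) {
  tibble(K = x$K, n_frames = x$n_frames,
         n_transitions = sum(x$transition_counts))
}

#' @rdname tidiers
#' @export
tidy.itc_fit <- function(x, ...) {
  tibble(term = c("N", "K_D", "dH", "offset"),
         estimate = c(x$N, x$K_D, x$dH, x$offset),
         std_error = c(x$se["N"],
                       x$K_D * log(10) * x$se["log10_K_D"],
                       x$se["dH"], x$se["offset"]))
}

#' @rdname tidiers
#' @export
glance.itc_fit <- function(x, ...) {
  tibble(K_D_uM = x$K_D * 1e6, sse = x$sse, converged = x$converged,
         no_detectable_binding = "no_detectable_binding" %in% x$flags,
         low_confidence = "low_confidence" %in% x$flags)
}

#' @rdname tidiers
#' @export
tidy.fret_tdp <- function(x, ...) x$pairs

#' @rdname tidiers
#' @export
glance.rupture_event <- function(x, ...) {
  tibble(turning_time = x$turning_time, peak_force = x$peak_force,
         post_drop_mean = x$post_drop_mean)
}
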