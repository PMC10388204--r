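#' Compile the transition density of a set of idealized trajectories
#'
#' Collects one (E_initial, E_final) pair per change point of each idealized
#' trajectory — the transition density plot (TDP) — and bins the pairs on a
#' square grid. Only consecutive pre-bleach frames contribute; a change point
#' is any frame where the idealized efficiency differs from the previous
#' frame of the same trace.
#'
#' @param idealized Tibble from [idealize_traces()] (needs `trace_id`,
#'   `frame`, `efficiency_ideal`).
#' @param range Efficiency range of the grid (default `c(0, 1)`).
#' @param bins Bins per axis (default 50).
#' @return A `fret_tdp` object: `pairs` tibble (`trace_id`, `frame`,
#'   `e_from`, `e_to`), `histogram` matrix (from-rows, to-columns),
#'   `bin_edges`.
#' @export
build_tdp <- function(idealized, range = c(0, 1), bins = 50) {
  pairs <- idealized %>% group_by(.data$trace_id) %>%
    arrange(.data$frame, .by_group = TRUE) %>%
    mutate(e_prev = lag(.data$efficiency_ideal),
           contiguous = .data$frame - lag(.data$frame) == 1) %>%
    ungroup() %>%
    filter(!is.na(.data$e_prev), .data$contiguous,
           .data$efficiency_ideal != .data$e_prev) %>%
    select("trace_id", "frame", e_from = "e_prev",
           e_to = "efficiency_ideal")
  edges <- seq(range[1], range[2], length.out = bins + 1)
  h <- matrix(0L, bins, bins)
  if (nrow(pairs)) {
    bi <- pmin(pmax(findInterval(pairs$e_from, edges, all.inside = TRUE), 1), bins)
    bj <- pmin(pmax(findInterval(pairs$e_to, edges, all.inside = TRUE), 1), bins)
    for (t in seq_along(bi)) h[bi[t], bj[t]] <- h[bi[t], bj[t]] + 1L
  } else {
    inform("no transitions found; empty TDP returned")
  }
  structure(list(pairs = pairs, histogram = h, bin_edges = edges),
            class = "fret_tdp")
}

#' @export
print.fret_tdp <- function(x, ...) {
  cat(sprintf("<fret_tdp> %d transition pairs on a %d x %d grid\n",
              nrow(x$pairs), nrow(x$histogram), ncol(x$histogram)))
  invisible(x)
}

#' Derive global state centers and thresholds
#'
#' Pools all idealized efficiencies (frame-weighted) and clusters them with
#' exact one-dimensional k-means: the globally optimal partition is found by
#' dynamic programming over the sorted unique values weighted by their frame
#' counts (in one dimension optimal clusters are contiguous, so the exact
#' solution is cheap and fully deterministic — no initialization, no local
#' minima). Thresholds are the midpoints between adjacent sorted centers —
#' the automated counterpart of reading state boundaries off the transition
#' density plot.
#'
#' @param idealized Tibble from [idealize_traces()].
#' @param K Number of global states.
#' @return List with `centers` (sorted, length `K`) and `thresholds`
#'   (length `K - 1`).
#' @export
derive_global_states <- function(idealized, K) {
  x <- idealized$efficiency_ideal
  x <- x[is.finite(x)]
  stopifnot(K >= 1, length(x) >= 1)
  tab <- table(x)
  v <- as.numeric(names(tab))
  w <- as.numeric(tab)
  if (length(v) < K) {
    abort(sprintf("only %d distinct idealized values; reduce K", length(v)))
  }
  if (K == 1) {
    return(list(centers = sum(w * v) / sum(w), thresholds = numeric(0)))
  }
  centers <- kmeans1d_weighted(v, w, K)
  list(centers = centers,
       thresholds = (centers[-1] + centers[-K]) / 2)
}

# Exact weighted 1-D k-means via dynamic programming on sorted values.
# Optimal clusters in 1-D are intervals; minimize total weighted
# within-cluster sum of squares.
kmeans1d_weighted <- function(v, w, K) {
  o <- order(v); v <- v[o]; w <- w[o]
  B <- length(v)
  cw <- cumsum(w); cwv <- cumsum(w * v); cwv2 <- cumsum(w * v^2)
  seg_sse <- function(i, j) { # vectorized over i (same j)
    W <- cw[j] - ifelse(i > 1, cw[i - 1], 0)
    S <- cwv[j] - ifelse(i > 1, cwv[i - 1], 0)
    S2 <- cwv2[j] - ifelse(i > 1, cwv2[i - 1], 0)
    S2 - S^2 / W
  }
  cost <- matrix(Inf, K, B)
  back <- matrix(0L, K, B)
  cost[1, ] <- vapply(seq_len(B), function(j) seg_sse(1, j), numeric(1))
  for (k in 2:K) {
    for (j in k:B) {
      i <- k:j # first index of cluster k
      cand <- cost[k - 1, i - 1] + seg_sse(i, j)
      b <- which.min(cand)
      cost[k, j] <- cand[b]
      back[k, j] <- i[b]
    }
  }
  # recover interval boundaries and weighted means
  bounds <- integer(K + 1); bounds[K + 1] <- B
  j <- B
  for (k in K:2) { bounds[k] <- back[k, j] - 1L; j <- bounds[k] }
  bounds[1] <- 0L
  centers <- vapply(seq_len(K), function(k) {
    i <- (bounds[k] + 1):bounds[k + 1]
    sum(w[i] * v[i]) / sum(w[i])
  }, numeric(1))
  sort(centers)
}

#' Threshold analysis: assign frames to global states and count
#'
#' Labels every idealized frame by the threshold interval containing its
#' idealized efficiency, then derives the headline statistics: pooled
#' occupancies (time-weighted over frames), per-acquisition occupancies,
#' per-state dwell times (consecutive-run lengths times the frame duration)
#' and the between-state transition count matrix.
#'
#' @param idealized Tibble from [idealize_traces()]; a `movie` column, if
#'   present, defines the per-acquisition grouping.
#' @param centers,thresholds From [derive_global_states()].
#' @param frame_dt Seconds per frame (default taken from a `time_s` column if
#'   available, else 0.1).
#' @return A `fret_states` object: `K`, `centers`, `thresholds`, `fractions`,
#'   `per_movie_fractions` (tibble), `dwell_summaries` (tibble),
#'   `transition_counts` (K x K, zero diagonal), `n_frames`, `labeled`
#'   (the input with a `state_global` column).
#' @export
assign_and_count <- function(idealized, centers, thresholds,
                             frame_dt = NULL) {
  K <- length(centers)
  stopifnot(length(thresholds) == K - 1)
  if (K > 1 && (any(diff(thresholds) <= 0) ||
                any(thresholds <= centers[-K] | thresholds >= centers[-1]))) {
    abort("thresholds must increase and interleave the centers")
  }
  if (is.null(frame_dt)) {
    frame_dt <- if ("time_s" %in% names(idealized) && nrow(idealized) > 1) {
      dtv <- diff(sort(unique(idealized$time_s)))
      if (length(dtv)) min(dtv) else 0.1
    } else 0.1
  }
  lab <- idealized %>%
    mutate(state_global = findInterval(.data$efficiency_ideal, thresholds) + 1L)
  counts <- tabulate(lab$state_global, nbins = K)
  fractions <- counts / sum(counts)
  per_movie <- NULL
  if ("movie" %in% names(lab)) {
    per_movie <- lab %>% count(.data$movie, .data$state_global) %>%
      group_by(.data$movie) %>%
      mutate(fraction = .data$n / sum(.data$n)) %>% ungroup() %>%
      tidyr::complete(movie = unique(lab$movie),
                      state_global = seq_len(K),
                      fill = list(n = 0L, fraction = 0))
  }
  runs <- lab %>% group_by(.data$trace_id) %>%
    arrange(.data$frame, .by_group = TRUE) %>%
    mutate(new_run = .data$frame - lag(.data$frame, default = -10L) != 1L |
             .data$state_global != lag(.data$state_global,
                                       default = -1L)) %>%
    mutate(run_id = cumsum(.data$new_run)) %>% ungroup()
  dwell <- runs %>% group_by(.data$trace_id, .data$run_id) %>%
    summarise(state_global = first(.data$state_global),
              len = n(), .groups = "drop") %>%
    group_by(.data$state_global) %>%
    summarise(mean_dwell_s = mean(.data$len) * frame_dt,
              n_dwells = n(), .groups = "drop") %>%
    tidyr::complete(state_global = seq_len(K),
                    fill = list(mean_dwell_s = NA_real_, n_dwells = 0L))
  trans <- matrix(0L, K, K)
  steps <- runs %>% group_by(.data$trace_id) %>%
    arrange(.data$frame, .by_group = TRUE) %>%
    mutate(prev = lag(.data$state_global),
           contiguous = .data$frame - lag(.data$frame) == 1) %>%
    ungroup() %>%
    filter(!is.na(.data$prev), .data$contiguous,
           .data$prev != .data$state_global)
  if (nrow(steps)) {
    for (r in seq_len(nrow(steps)))
      trans[steps$prev[r], steps$state_global[r]] <-
        trans[steps$prev[r], steps$state_global[r]] + 1L
  }
  structure(list(K = K, centers = centers, thresholds = thresholds,
                 fractions = fractions, per_movie_fractions = per_movie,
                 dwell_summaries = dwell, transition_counts = trans,
                 n_frames = sum(counts), frame_dt = frame_dt,
                 labeled = lab),
            class = "fret_states")
}

#' @export
print.fret_states <- function(x, ...) {
  cat(sprintf("<fret_states> %d states over %d frames\n", x$K, x$n_frames))
  print(tidy(x))
  invisible(x)
}

#' Most probable efficiency of each global state
#'
#' For each state, fits a Gaussian to the histogram of the *raw* efficiencies
#' of its assigned frames; the fitted mean is the state's most probable
#' (modal) efficiency. Falls back to the peak bin center when the fit fails.
#' States with fewer than 50 frames are flagged low-confidence.
#'
#' @param labeled Tibble with raw `efficiency` and `state_global` columns
#'   (the `labeled` element of a [assign_and_count()] result).
#' @param bins Histogram bins (default 50 over `range`).
#' @param range Histogram range (default `c(-0.2, 1.2)` so unclamped values
#'   contribute).
#' @return Tibble with `state_global`, `modal_efficiency`, `n_frames`,
#'   `low_confidence`, `fit_ok`.
#' @export
most_probable_efficiencies <- function(labeled, bins = 50,
                                       range = c(-0.2, 1.2)) {
  stopifnot(all(c("efficiency", "state_global") %in% names(labeled)))
  edges <- seq(range[1], range[2], length.out = bins + 1)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  states <- sort(unique(labeled$state_global))
  purrr::map_dfr(states, function(s) {
    x <- labeled$efficiency[labeled$state_global == s]
    x <- x[is.finite(x)]
    width <- diff(edges)[1]
    if (length(x) > 1 && sd(x) < width / 2) {
      # (near-)degenerate state: the histogram is a single spike and a
      # Gaussian fit is meaningless; the mode is the value itself
      return(tibble(state_global = s, modal_efficiency = median(x),
                    n_frames = length(x), low_confidence = length(x) < 50,
                    fit_ok = FALSE))
    }
    h <- hist_counts(x, edges)
    peak <- mids[which.max(h)]
    fit <- gauss_fit(mids, h, mu0 = peak, s0 = max(sd(x), 0.02))
    tibble(state_global = s,
           modal_efficiency = if (is.null(fit)) peak else unname(fit["mu"]),
           n_frames = length(x),
           low_confidence = length(x) < 50,
           fit_ok = !is.null(fit))
  })
}

hist_counts <- function(x, edges) {
  b <- findInterval(x, edges, all.inside = TRUE)
  tabulate(b, nbins = length(edges) - 1)
}

gauss_fit <- function(mids, counts, mu0, s0) {
  df <- data.frame(x = mids, y = counts)
  fit <- tryCatch(
    nls(y ~ A * exp(-(x - mu)^2 / (2 * s^2)), data = df,
        start = list(A = max(counts), mu = mu0, s = s0),
        control = list(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  co <- coef(fit)
  if (!is.finite(co["mu"])) return(NULL)
  c(mu = unname(co["mu"]), s = abs(unname(co["s"])))
}

#' Density-normalized FRET efficiency histogram
#'
#' Pools all (or per-state) raw-efficiency frames into a density-normalized
#' histogram table, the standard presentation of smFRET population data.
#'
#' @param traces Tibble with an `efficiency` column (raw frames); for
#'   `by_state = TRUE` a `state_global` column is required.
#' @param bins Number of bins (default 50).
#' @param range Display range (default `c(0, 1)`); values outside are
#'   excluded from the histogram only.
#' @param by_state Build one histogram per assigned state.
#' @return Tibble with `bin_mid`, `count`, `density` (and `state_global` when
#'   `by_state`). Densities integrate to 1 over the range.
#' @export
build_fret_histogram <- function(traces, bins = 50, range = c(0, 1),
                                 by_state = FALSE) {
  edges <- seq(range[1], range[2], length.out = bins + 1)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  width <- diff(edges)[1]
  one <- function(x) {
    x <- x[is.finite(x) & x >= range[1] & x <= range[2]]
    if (!length(x)) abort("no frames in histogram range")
    h <- hist_counts(x, edges)
    tibble(bin_mid = mids, count = h, density = h / sum(h) / width)
  }
  if (!by_state) return(one(traces$efficiency))
  stopifnot("state_global" %in% names(traces))
  traces %>% group_by(.data$state_global) %>%
    dplyr::group_modify(~ one(.x$efficiency)) %>% ungroup()
}

#' Compare per-acquisition state populations between two groups
#'
#' Welch two-sample two-tailed t test per state on the per-movie occupancy
#' fractions of two experimental groups. No multiplicity correction is
#' applied (each state is reported marginally); the output carries a note
#' flagging this.
#'
#' @param group_a,group_b Per-movie fraction tibbles (`movie`,
#'   `state_global`, `fraction`), e.g. the `per_movie_fractions` element of
#'   [assign_and_count()] results; at least two movies per group.
#' @return Tibble with `state_global`, `mean_a`, `mean_b`, `t`, `df`, `p`;
#'   attribute `"note"` records the absence of multiplicity correction.
#' @export
compare_populations <- function(group_a, group_b) {
  states <- sort(union(group_a$state_global, group_b$state_global))
  if (length(unique(group_a$movie)) < 2 || length(unique(group_b$movie)) < 2)
    abort("need at least two movies per group")
  out <- purrr::map_dfr(states, function(s) {
    a <- group_a$fraction[group_a$state_global == s]
    b <- group_b$fraction[group_b$state_global == s]
    if (sd(a) == 0 && sd(b) == 0) {
      tibble(state_global = s, mean_a = mean(a), mean_b = mean(b),
             t = if (mean(a) == mean(b)) 0 else Inf * sign(mean(a) - mean(b)),
             df = NA_real_, p = if (mean(a) == mean(b)) 1 else 0)
    } else {
      tt <- t.test(a, b, var.equal = FALSE, alternative = "two.sided")
      tibble(state_global = s, mean_a = mean(a), mean_b = mean(b),
             t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value)
    }
  })
  attr(out, "note") <- "two-tailed Welch t tests; no multiplicity correction"
  out
}
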