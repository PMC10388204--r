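#' Write / read trace tables
#'
#' Traces are stored as plain TSV with at least the columns `trace_id`,
#' `frame`, `time_s`, `donor`, `acceptor`; any extra columns are preserved.
#' The reader tolerates additional columns and never reorders rows.
#'
#' @param traces Trace tibble.
#' @param path File path.
#' @return `write_traces()` returns `path` invisibly; `read_traces()` returns
#'   a tibble.
#' @export
write_traces <- function(traces, path) {
  needed <- c("trace_id", "frame", "time_s", "donor", "acceptor")
  missing <- setdiff(needed, names(traces))
  if (length(missing)) abort(paste("traces missing columns:",
                                   paste(missing, collapse = ", ")))
  readr::write_tsv(traces, path)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("trace_id", "frame", "time_s", "donor", "acceptor")
  missing <- setdiff(needed, names(out))
  if (length(missing)) abort(paste("trace file missing columns:",
                                   paste(missing, collapse = ", ")))
  out
}

#' Compute apparent FRET efficiency per frame
#'
#' `E = (A - bg_A) / [(A - bg_A) + gamma * (D - bg_D)]` with a detection
#' correction factor `gamma`. Frames whose denominator is not positive are
#' flagged invalid (`eff_valid = FALSE`, efficiency `NA`). Values outside
#' \[0, 1\] are retained — clamping before model fitting would bias the
#' emission means; display stages restrict ranges instead. If a
#' `bleach_frame` (or ground-truth `bleach_frame_true`) column is present,
#' post-bleach frames are marked invalid too.
#'
#' @param traces Trace tibble.
#' @param gamma Positive correction factor (default 1: apparent efficiency).
#' @param background_d,background_a Constant channel backgrounds subtracted
#'   before the ratio (default 0).
#' @param valid_range Efficiencies outside this window are flagged invalid
#'   (default `c(-0.5, 1.5)`): values moderately outside \[0, 1\] are noise
#'   around the extremes and are kept unclamped, while far-out values can
#'   only arise from near-zero denominators (dark frames) and would poison
#'   downstream fits. Set to `c(-Inf, Inf)` to keep everything.
#' @return The input tibble with `efficiency` and `eff_valid` columns.
#' @export
compute_efficiency <- function(traces, gamma = 1, background_d = 0,
                               background_a = 0,
                               valid_range = c(-0.5, 1.5)) {
  if (gamma <= 0) abort("gamma must be > 0")
  a <- traces$acceptor - background_a
  d <- traces$donor - background_d
  den <- a + gamma * d
  eff <- ifelse(den > 0, a / den, NA_real_)
  valid <- den > 0 & is.finite(eff) &
    !is.na(eff) & eff >= valid_range[1] & eff <= valid_range[2]
  bf <- bleach_column(traces)
  if (!is.null(bf)) valid <- valid & (is.na(bf) | traces$frame < bf)
  traces$efficiency <- ifelse(valid, eff, NA_real_)
  traces$eff_valid <- valid
  dead <- traces %>% group_by(.data$trace_id) %>%
    summarise(ok = any(.data$eff_valid), .groups = "drop") %>%
    filter(!.data$ok)
  if (nrow(dead)) inform(sprintf(
    "%d trace(s) have no valid efficiency frames and will be dropped by filter_traces()",
    nrow(dead)))
  traces
}

bleach_column <- function(traces) {
  if ("bleach_frame" %in% names(traces)) return(traces$bleach_frame)
  if ("bleach_frame_true" %in% names(traces)) return(traces$bleach_frame_true)
  NULL
}

#' Detect the photobleaching step of each trace
#'
#' Scans the total intensity (donor + acceptor) of each trace for the single
#' downward mean-shift changepoint that maximizes the two-segment likelihood
#' (equivalently, minimizes the two-segment residual sum of squares), and
#' accepts it when the standardized shift `(mean_pre - mean_post) / sd_pooled`
#' exceeds `z_threshold`. Returns the first dark frame; traces without an
#' accepted downward step get `NA`.
#'
#' @param traces Trace tibble.
#' @param window Minimum segment length on either side of the candidate
#'   changepoint (default 5); traces must be at least `2 * window` long.
#' @param z_threshold Minimum standardized downward shift (default 4).
#' @return The input tibble with a per-trace `bleach_frame` column (repeated
#'   within trace).
#' @export
detect_bleach <- function(traces, window = 5, z_threshold = 4) {
  stopifnot(window >= 2, z_threshold > 0)
  bf_tbl <- traces %>% group_by(.data$trace_id) %>%
    summarise(bleach_frame = {
      tot <- .data$donor + .data$acceptor
      frames <- .data$frame
      idx <- bleach_changepoint(tot, window, z_threshold)
      if (is.na(idx)) NA_integer_ else frames[idx]
    }, .groups = "drop")
  traces$bleach_frame <- NULL
  left_join(traces, bf_tbl, by = "trace_id")
}

# Exhaustive single-changepoint scan on a total-intensity series.
# Returns the index of the first post-step sample, or NA.
bleach_changepoint <- function(x, window, z_threshold) {
  n <- length(x)
  if (n < 2 * window) abort("trace shorter than 2 * window")
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  ks <- seq(window, n - window) # last index of the first segment
  m1 <- cs[ks] / ks
  m2 <- (cs[n] - cs[ks]) / (n - ks)
  ss1 <- cs2[ks] - cs[ks]^2 / ks
  ss2 <- (cs2[n] - cs2[ks]) - (cs[n] - cs[ks])^2 / (n - ks)
  sse <- ss1 + ss2
  best <- which.min(sse)
  if (m2[best] >= m1[best]) return(NA_integer_) # only downward shifts count
  sp <- sqrt(sse[best] / (n - 2))
  if (sp <= 0) sp <- .Machine$double.eps
  z <- (m1[best] - m2[best]) / sp
  if (z > z_threshold) ks[best] + 1L else NA_integer_
}

#' Quality-filter traces
#'
#' Keeps traces whose pre-bleach segment is at least `min_frames` long and
#' whose mean pre-bleach total intensity reaches `min_total_intensity`;
#' traces with no valid efficiency frames (if [compute_efficiency()] ran) are
#' always rejected. The rejection tally is attached as the `"rejections"`
#' attribute.
#'
#' @param traces Trace tibble (ideally after [detect_bleach()] and
#'   [compute_efficiency()]).
#' @param min_frames Minimum pre-bleach length (default 50).
#' @param min_total_intensity Minimum mean pre-bleach donor + acceptor
#'   (default 0).
#' @return Filtered tibble; errors if no trace survives.
#' @export
filter_traces <- function(traces, min_frames = 50, min_total_intensity = 0) {
  stopifnot(min_frames >= 0, min_total_intensity >= 0)
  bf <- bleach_column(traces)
  pre <- if (is.null(bf)) rep(TRUE, nrow(traces)) else is.na(bf) | traces$frame < bf
  has_eff <- "eff_valid" %in% names(traces)
  stats <- traces %>% mutate(.pre = pre) %>%
    group_by(.data$trace_id) %>%
    summarise(n_pre = sum(.data$.pre),
              mean_tot = if (any(.data$.pre))
                mean((.data$donor + .data$acceptor)[.data$.pre]) else 0,
              any_valid = if (has_eff) any(.data$eff_valid) else TRUE,
              .groups = "drop")
  stats$reason <- dplyr::case_when(
    stats$n_pre < min_frames ~ "short",
    stats$mean_tot < min_total_intensity ~ "dim",
    !stats$any_valid ~ "invalid_efficiency",
    TRUE ~ "kept")
  report <- stats %>% count(.data$reason, name = "n")
  keep <- stats$trace_id[stats$reason == "kept"]
  if (!length(keep)) abort("no traces survived filtering; relax the thresholds")
  out <- traces %>% filter(.data$trace_id %in% keep)
  attr(out, "rejections") <- report
  out
}

#' Pre-bleach frames with valid efficiencies
#'
#' Helper used by the modeling stages: restricts a trace tibble to frames
#' before the (detected or ground-truth) bleach frame that carry a valid
#' efficiency value.
#' @param traces Trace tibble after [compute_efficiency()].
#' @return Filtered tibble.
#' @export
prebleach_frames <- function(traces) {
  if (!"efficiency" %in% names(traces)) {
    abort("run compute_efficiency() first")
  }
  traces %>% filter(.data$eff_valid)
}
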