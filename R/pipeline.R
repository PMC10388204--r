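#' Default pipeline configuration
#'
#' All tunables of the trace-to-populations pipeline in one nested list:
#' ground truth (a benchmark name or explicit [gt_model()] parameters),
#' simulation size, filtering thresholds, HMM settings and histogram/TDP
#' grids. Values not supplied fall back to the package defaults (100 ms
#' frames, 20 s bleach lifetime, 50 x 50 TDP bins on \[0, 1\], evidence
#' criterion).
#'
#' @param ground_truth `"yykt6"`, `"rykt6"`, or a [gt_model()].
#' @param n_traces,n_frames Simulation size (defaults 200 traces x 400
#'   frames).
#' @param K Fixed state count; `NULL` (default) selects it by
#'   [select_states()] over `K_range`.
#' @param K_range Candidate counts when selecting (default `1:6`).
#' @param criterion Selection criterion (default `"evidence"`).
#' @param min_frames,min_total_intensity Filtering thresholds (defaults 50,
#'   0).
#' @param n_restarts HMM restarts per fit (default 3).
#' @param bins,range TDP/histogram grid (defaults 50 bins on `c(0, 1)`).
#' @param seed Global seed (default 1).
#' @param out_dir Output directory (`NULL`: nothing written).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(ground_truth = "yykt6", n_traces = 200,
                            n_frames = 400, K = NULL, K_range = 1:6,
                            criterion = "evidence", min_frames = 50,
                            min_total_intensity = 0, n_restarts = 3,
                            bins = 50, range = c(0, 1), seed = 1,
                            out_dir = NULL) {
  structure(list(ground_truth = ground_truth, n_traces = n_traces,
                 n_frames = n_frames, K = K, K_range = K_range,
                 criterion = criterion, min_frames = min_frames,
                 min_total_intensity = min_total_intensity,
                 n_restarts = n_restarts, bins = bins, range = range,
                 seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

resolve_model <- function(gt) {
  if (inherits(gt, "gt_model")) return(gt)
  switch(as.character(gt),
         yykt6 = yykt6_model(),
         rykt6 = rykt6_model(),
         abort(sprintf("unknown ground truth '%s'", gt)))
}

#' Run the trace-to-populations pipeline
#'
#' Executes, in order: trace simulation (or TSV input), bleach detection,
#' efficiency computation, quality filtering, state-count selection (unless
#' `K` is fixed), per-trace HMM idealization, transition-density
#' compilation, global state derivation, threshold assignment and modal
#' efficiencies. Identical config + seed gives bit-identical results; when
#' `out_dir` is set, results and a manifest (resolved config, file hashes)
#' are written there as JSON/TSV.
#'
#' @param config A [pipeline_config()].
#' @param traces Optional pre-existing trace tibble (skips simulation).
#' @return A `pipeline_result` list: `config`, `selection` (or `NULL`), `K`,
#'   `states` ([assign_and_count()] result), `modal` (modal-efficiency
#'   tibble), `tdp`, `histogram`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), traces = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  model <- resolve_model(config$ground_truth)
  if (is.null(traces)) {
    traces <- simulate_traces(model, config$n_traces, config$n_frames,
                              seed = config$seed)
  }
  traces <- detect_bleach(traces)
  traces <- compute_efficiency(traces)
  traces <- filter_traces(traces, config$min_frames,
                          config$min_total_intensity)
  selection <- NULL
  K <- config$K
  if (is.null(K)) {
    selection <- select_states(traces, config$K_range,
                               criterion = config$criterion,
                               n_restarts = config$n_restarts,
                               seed = config$seed)
    K <- selection$K
  }
  ideal <- idealize_traces(traces, K, n_restarts = config$n_restarts,
                           seed = config$seed)
  tdp <- build_tdp(ideal, range = config$range, bins = config$bins)
  gs <- derive_global_states(ideal, K)
  states <- assign_and_count(ideal, gs$centers, gs$thresholds,
                             frame_dt = model$frame_dt)
  modal <- most_probable_efficiencies(states$labeled)
  hist <- build_fret_histogram(traces, bins = config$bins,
                               range = config$range)
  res <- list(config = config, selection = selection, K = K, states = states,
              modal = modal, tdp = tdp, histogram = hist)
  if (!is.null(config$out_dir)) res$manifest <- write_results(res, config)
  class(res) <- "pipeline_result"
  res
}

write_results <- function(res, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  jw <- function(x, name) {
    p <- file.path(config$out_dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    p
  }
  paths["results"] <- jw(list(
    K = res$K,
    selection = if (!is.null(res$selection)) res$selection$table,
    centers = res$states$centers, thresholds = res$states$thresholds,
    fractions = res$states$fractions,
    modal_efficiency = res$modal$modal_efficiency,
    dwell = res$states$dwell_summaries,
    transition_counts = res$states$transition_counts), "results.json")
  p <- file.path(config$out_dir, "histogram.tsv")
  readr::write_tsv(res$histogram, p); paths["histogram"] <- p
  p <- file.path(config$out_dir, "tdp.tsv")
  tdp_grid <- as_tibble(as.data.frame(as.table(res$tdp$histogram)))
  names(tdp_grid) <- c("bin_from", "bin_to", "count")
  readr::write_tsv(tdp_grid, p); paths["tdp"] <- p
  manifest <- list(config = unclass(config)[!vapply(unclass(config), is.null,
                                                    logical(1))],
                   files = lapply(paths, function(f)
                     list(path = basename(f), md5 = unname(tools::md5sum(f)))))
  manifest$config$out_dir <- NULL
  mpath <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  manifest
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> K = %d\n", x$K))
  print(tidy(x$states))
  invisible(x)
}
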