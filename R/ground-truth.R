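#' Ground-truth hidden-state model for synthetic smFRET traces
#'
#' Defines the generative model behind a synthetic single-molecule FRET
#' experiment: a per-frame discrete Markov chain over `K` conformational
#' states, Gaussian per-state emission of the true FRET efficiency, a single
#' exponential photobleaching event that truncates the usable trace, and
#' additive camera noise on both detection channels.
#'
#' @param efficiency_means Per-state mean FRET efficiency, strictly increasing.
#' @param transition_matrix `K x K` row-stochastic per-frame transition
#'   probability matrix (rows must sum to 1 within `1e-12`).
#' @param efficiency_sds Per-state emission spread of the true efficiency
#'   (recycled to length `K`). Default 0.035, chosen so that together with the
#'   default camera noise the *apparent* per-state width of the computed
#'   efficiency is about 0.05 — the histogram width at which adjacent states
#'   0.13-0.16 apart are visibly resolved, as in the measured distributions.
#' @param occupancy Optional stationary distribution. If supplied it must match
#'   the stationary distribution of `transition_matrix` within `1e-6`;
#'   otherwise it is computed from the matrix.
#' @param frame_dt Seconds per frame (camera exposure). Default 0.1 s.
#' @param bleach_lifetime_s Mean dye survival time in seconds; `Inf` disables
#'   photobleaching. Default 20 s.
#' @param total_intensity Mean summed photon counts per frame. Default 200.
#' @param camera_sd Additive Gaussian noise per channel, in counts. Default 5%
#'   of `total_intensity`.
#'
#' @return An object of class `gt_model`.
#' @seealso [yykt6_model()], [rykt6_model()], [simulate_traces()]
#' @export
gt_model <- function(efficiency_means, transition_matrix,
                     efficiency_sds = 0.035, occupancy = NULL,
                     frame_dt = 0.1, bleach_lifetime_s = 20,
                     total_intensity = 200,
                     camera_sd = 0.05 * total_intensity) {
  efficiency_means <- as.numeric(efficiency_means)
  K <- length(efficiency_means)
  if (K < 1) abort("need at least one state")
  if (K > 1 && any(diff(efficiency_means) <= 0)) {
    abort("efficiency_means must be strictly increasing")
  }
  transition_matrix <- as.matrix(transition_matrix)
  if (!all(dim(transition_matrix) == c(K, K))) {
    abort("transition_matrix must be K x K")
  }
  if (any(transition_matrix < 0) ||
      any(abs(rowSums(transition_matrix) - 1) > 1e-12)) {
    abort("transition_matrix rows must be non-negative and sum to 1 (within 1e-12)")
  }
  pi_stat <- stationary_distribution(transition_matrix)
  if (!is.null(occupancy)) {
    occupancy <- as.numeric(occupancy)
    if (length(occupancy) != K || any(abs(occupancy - pi_stat) > 1e-6)) {
      abort("occupancy is not the stationary distribution of transition_matrix (tolerance 1e-6)")
    }
  } else {
    occupancy <- pi_stat
  }
  efficiency_sds <- rep_len(as.numeric(efficiency_sds), K)
  stopifnot(frame_dt > 0, bleach_lifetime_s > 0, total_intensity > 0, camera_sd >= 0)
  structure(
    list(K = K, occupancy = occupancy, efficiency_means = efficiency_means,
         efficiency_sds = efficiency_sds, transition_matrix = transition_matrix,
         frame_dt = frame_dt, bleach_lifetime_s = bleach_lifetime_s,
         total_intensity = total_intensity, camera_sd = camera_sd),
    class = "gt_model")
}

#' @export
print.gt_model <- function(x, ...) {
  cat(sprintf("<gt_model> %d states, frame_dt = %g s, bleach lifetime = %g s\n",
              x$K, x$frame_dt, x$bleach_lifetime_s))
  print(tibble(state = seq_len(x$K), mean = x$efficiency_means,
               sd = x$efficiency_sds, occupancy = x$occupancy))
  invisible(x)
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Left Perron eigenvector, normalized to sum to 1.
#' @param P Row-stochastic matrix.
#' @return Numeric vector.
#' @export
stationary_distribution <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

#' Reversible per-frame transition matrix from target occupancies
#'
#' Builds a detailed-balance (reversible) transition matrix whose stationary
#' distribution equals `occupancy`, from symmetric per-frame exchange fluxes
#' `flux[i, j] = occupancy[i] * P[i, j]`. This is the natural way to pin both
#' the equilibrium populations and the relative frequency of each
#' state-to-state transition.
#'
#' @param occupancy Target stationary distribution (sums to 1).
#' @param flux Symmetric matrix of per-frame exchange probabilities
#'   (off-diagonal); diagonal ignored.
#' @return Row-stochastic matrix with the requested stationary distribution.
#' @export
exchange_chain <- function(occupancy, flux) {
  occupancy <- as.numeric(occupancy)
  K <- length(occupancy)
  flux <- as.matrix(flux)
  stopifnot(all(dim(flux) == K), isTRUE(all.equal(flux, t(flux))))
  P <- flux / occupancy # row i: flux[i, j] / pi_i
  diag(P) <- 0
  rs <- rowSums(P)
  if (any(rs >= 1)) abort("exchange fluxes too large for a valid per-frame matrix")
  diag(P) <- 1 - rs
  P
}

#' Three-state benchmark ground truth (yeast Ykt6 lacking its C-terminal motif)
#'
#' State means 0.20/0.42/0.68 with equilibrium occupancies 50.7/39.7/10.2%,
#' the reported conformational landscape of the yeast protein. Exchange fluxes
#' are chosen so that transitions between the two open states dominate and
#' direct lowest-to-highest jumps are rare (under 2% of all transitions),
#' matching the observed transition-density structure.
#'
#' @param ... Passed on to [gt_model()] to override defaults.
#' @return A `gt_model`.
#' @export
yykt6_model <- function(...) {
  occ <- c(0.507, 0.397, 0.102)
  occ <- occ / sum(occ)
  flux <- matrix(0, 3, 3)
  flux[1, 2] <- flux[2, 1] <- 0.020
  flux[2, 3] <- flux[3, 2] <- 0.006
  flux[1, 3] <- flux[3, 1] <- 2e-4
  gt_model(efficiency_means = c(0.20, 0.42, 0.68),
           transition_matrix = exchange_chain(occ, flux),
           occupancy = occ, ...)
}

#' Five-state benchmark ground truth (rat Ykt6 lacking its C-terminal motif)
#'
#' State means 0.20/0.35/0.48/0.64/0.79 with occupancies
#' 31.4/19.8/19.3/16.2/13.3%. Exchange is nearest-neighbor along the
#' efficiency ladder.
#'
#' @inheritParams yykt6_model
#' @return A `gt_model`.
#' @export
rykt6_model <- function(...) {
  occ <- c(0.314, 0.198, 0.193, 0.162, 0.133)
  occ <- occ / sum(occ)
  flux <- matrix(0, 5, 5)
  for (i in 1:4) flux[i, i + 1] <- flux[i + 1, i] <- 0.1 * min(occ[i], occ[i + 1])
  gt_model(efficiency_means = c(0.20, 0.35, 0.48, 0.64, 0.79),
           transition_matrix = exchange_chain(occ, flux),
           occupancy = occ, ...)
}

#' Shifted variant of a ground-truth model (occupancy moved to closed states)
#'
#' Reweights the stationary distribution of an existing model toward the
#' high-efficiency (closed) states, emulating the population shift a
#' closed-state-stabilizing ligand produces, while keeping the same state
#' means. Used for group-comparison tests.
#'
#' @param model A `gt_model`.
#' @param shift Fraction of occupancy moved from the lowest to the highest
#'   state (default 0.25).
#' @return A `gt_model` with the shifted equilibrium.
#' @export
shift_model <- function(model, shift = 0.25) {
  occ <- model$occupancy
  K <- model$K
  moved <- min(shift, occ[1] * 0.9)
  occ[1] <- occ[1] - moved
  occ[K] <- occ[K] + moved
  occ <- occ / sum(occ)
  # keep the same relative flux pattern, rescaled to stay sub-stochastic
  flux <- model$transition_matrix * model$occupancy
  flux <- (flux + t(flux)) / 2
  diag(flux) <- 0
  P <- exchange_chain(occ, flux)
  gt_model(efficiency_means = model$efficiency_means, transition_matrix = P,
           efficiency_sds = model$efficiency_sds, frame_dt = model$frame_dt,
           bleach_lifetime_s = model$bleach_lifetime_s,
           total_intensity = model$total_intensity, camera_sd = model$camera_sd)
}
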