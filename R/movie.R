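#' Specification of a synthetic dual-view movie
#'
#' Geometry and noise of a small image stack emulating a dual-view
#' single-molecule acquisition: one sub-image per channel, related by a fixed
#' translation, diffraction-limited spots rendered as isotropic Gaussians,
#' constant background and Poisson shot noise.
#'
#' @param width,height Frame size in pixels (per channel view).
#' @param n_frames Number of frames.
#' @param psf_sigma Gaussian point-spread sigma, pixels (default 1.5).
#' @param spot_positions Data frame with sub-pixel `x`, `y` donor-view
#'   coordinates, one row per molecule (all inside the frame).
#' @param channel_offset Length-2 translation (dx, dy) from donor to
#'   acceptor view (default `c(0, 0)`).
#' @param background_level Constant background counts per pixel (default 10).
#' @return A `movie_spec` object.
#' @export
movie_spec <- function(width, height, n_frames, spot_positions,
                       psf_sigma = 1.5, channel_offset = c(0, 0),
                       background_level = 10) {
  spot_positions <- as_tibble(spot_positions)
  stopifnot(psf_sigma > 0, width >= 8, height >= 8, n_frames >= 1,
            all(c("x", "y") %in% names(spot_positions)))
  inb <- function(p, off) all(p$x + off[1] >= 1 & p$x + off[1] <= width &
                                p$y + off[2] >= 1 & p$y + off[2] <= height)
  if (!inb(spot_positions, c(0, 0)) || !inb(spot_positions, channel_offset))
    abort("spot positions (donor and offset acceptor view) must lie inside the frame")
  structure(list(width = width, height = height, n_frames = n_frames,
                 psf_sigma = psf_sigma, spot_positions = spot_positions,
                 channel_offset = channel_offset,
                 background_level = background_level),
            class = "movie_spec")
}

# unit-mass isotropic Gaussian PSF sampled at pixel centers
render_spot <- function(img, x, y, sigma, intensity) {
  r <- ceiling(4 * sigma)
  xs <- max(1, floor(x) - r):min(ncol(img), ceiling(x) + r)
  ys <- max(1, floor(y) - r):min(nrow(img), ceiling(y) + r)
  gx <- dnorm(xs, x, sigma)
  gy <- dnorm(ys, y, sigma)
  img[ys, xs] <- img[ys, xs] + intensity * outer(gy, gx)
  img
}

#' Simulate a dual-view image stack from intensity traces
#'
#' Renders each molecule as a Gaussian spot whose integrated intensity per
#' frame equals the corresponding trace value (donor trace in the donor
#' view, acceptor trace in the acceptor view at the channel offset), adds
#' the constant background and applies Poisson shot noise. Spots closer than
#' `4 * psf_sigma` trigger a warning (their apertures overlap downstream).
#'
#' @param spec A [movie_spec()]; one spot per trace.
#' @param traces Trace tibble ([simulate_traces()] layout); trace order maps
#'   to spot order.
#' @param noise Apply Poisson noise (default TRUE).
#' @param seed Integer seed.
#' @return List with `donor` and `acceptor` arrays of dimension
#'   `c(height, width, n_frames)`.
#' @export
simulate_movie <- function(spec, traces, noise = TRUE, seed = NULL) {
  stopifnot(inherits(spec, "movie_spec"))
  ids <- unique(traces$trace_id)
  if (length(ids) != nrow(spec$spot_positions))
    abort("need exactly one trace per spot")
  pos <- spec$spot_positions
  if (nrow(pos) > 1) {
    dmin <- min(stats::dist(as.matrix(pos[, c("x", "y")])))
    if (dmin < 4 * spec$psf_sigma)
      warn(sprintf("spots closer than 4*psf_sigma (min distance %.2f px)", dmin))
  }
  D <- array(spec$background_level,
             dim = c(spec$height, spec$width, spec$n_frames))
  A <- array(spec$background_level,
             dim = c(spec$height, spec$width, spec$n_frames))
  off <- spec$channel_offset
  for (f in seq_len(spec$n_frames)) {
    for (i in seq_along(ids)) {
      tr <- traces[traces$trace_id == ids[i] & traces$frame == f, ]
      if (!nrow(tr)) next
      D[, , f] <- render_spot(D[, , f], pos$x[i], pos$y[i], spec$psf_sigma,
                              max(tr$donor[1], 0))
      A[, , f] <- render_spot(A[, , f], pos$x[i] + off[1], pos$y[i] + off[2],
                              spec$psf_sigma, max(tr$acceptor[1], 0))
    }
  }
  if (noise) {
    run_seeded(seed, {
      D[] <- rpois(length(D), D)
      A[] <- rpois(length(A), A)
    })
  }
  list(donor = D, acceptor = A)
}

#' Write / read an image stack as multi-page TIFF
#'
#' 16-bit unsigned pages; counts are stored as `value / 65535` (the R TIFF
#' writer's normalized convention) and rescaled on read, so integer photon
#' counts below 65535 round-trip exactly.
#'
#' @param stack Array `c(height, width, n_frames)`.
#' @param path File path.
#' @export
write_stack <- function(stack, path) {
  pages <- lapply(seq_len(dim(stack)[3]),
                  function(f) pmin(pmax(stack[, , f], 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (f in seq_along(pages)) arr[, , f] <- pages[[f]] * 65535
  arr
}

gaussian_smooth <- function(img, sigma) {
  r <- max(1, ceiling(3 * sigma))
  k <- dnorm(-r:r, 0, sigma); k <- k / sum(k)
  pad <- function(m, n, side) {
    if (side == "rows") m[c(rep(1, n), seq_len(nrow(m)), rep(nrow(m), n)), ]
    else m[, c(rep(1, n), seq_len(ncol(m)), rep(ncol(m), n))]
  }
  # separable convolution with replicated edges
  m <- pad(img, r, "rows")
  m <- apply(m, 2, function(col) stats::filter(col, k, sides = 2))
  m <- m[(r + 1):(r + nrow(img)), , drop = FALSE]
  m <- pad(m, r, "cols")
  m <- t(apply(m, 1, function(row) stats::filter(row, k, sides = 2)))
  m[, (r + 1):(r + ncol(img)), drop = FALSE]
}

#' Detect diffraction-limited spots in one frame
#'
#' Local maxima of a Gaussian-smoothed frame exceeding
#' `median + z_threshold * MAD` of the smoothed image (robust statistics, so
#' the spots themselves do not inflate the threshold), with non-maximum
#' suppression within `min_separation` pixels and centroid refinement by
#' center of mass in a 5x5 window.
#'
#' @param frame 2-D numeric matrix (rows = y, columns = x).
#' @param z_threshold Detection threshold in smoothed-image SDs (default 5).
#' @param min_separation Suppression radius, pixels (default 5).
#' @param psf_sigma Smoothing sigma (default 1.5).
#' @return Tibble with sub-pixel `x`, `y` and `intensity` (smoothed peak
#'   value); zero rows when nothing is found.
#' @export
detect_spots <- function(frame, z_threshold = 5, min_separation = 5,
                         psf_sigma = 1.5) {
  stopifnot(is.matrix(frame), all(is.finite(frame)))
  s <- gaussian_smooth(frame, psf_sigma)
  thr <- median(s) + z_threshold * stats::mad(s)
  h <- nrow(s); w <- ncol(s)
  if (h < 3 || w < 3) return(tibble(x = numeric(0), y = numeric(0), intensity = numeric(0)))
  core <- s[2:(h - 1), 2:(w - 1)]
  ismax <- core >= s[1:(h - 2), 2:(w - 1)] & core >= s[3:h, 2:(w - 1)] &
    core >= s[2:(h - 1), 1:(w - 2)] & core >= s[2:(h - 1), 3:w] &
    core >= s[1:(h - 2), 1:(w - 2)] & core >= s[3:h, 3:w] &
    core >= s[1:(h - 2), 3:w] & core >= s[3:h, 1:(w - 2)] &
    core > thr
  idx <- which(ismax, arr.ind = TRUE)
  if (!nrow(idx)) return(tibble(x = numeric(0), y = numeric(0), intensity = numeric(0)))
  cand <- tibble(y = idx[, 1] + 1, x = idx[, 2] + 1,
                 intensity = core[idx])
  cand <- cand[order(-cand$intensity), ]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) {
      j <- (i + 1):nrow(cand)
      d2 <- (cand$x[j] - cand$x[i])^2 + (cand$y[j] - cand$y[i])^2
      keep[j[d2 < min_separation^2]] <- FALSE
    }
  }
  cand <- cand[keep, ]
  # center-of-mass refinement on the background-subtracted smoothed image
  base <- median(s)
  refine <- function(cx, cy) {
    xs <- max(1, cx - 2):min(w, cx + 2)
    ys <- max(1, cy - 2):min(h, cy + 2)
    win <- pmax(s[ys, xs, drop = FALSE] - base, 0)
    tot <- sum(win)
    if (tot <= 0) return(c(cx, cy))
    c(sum(rep(xs, each = length(ys)) * win) / tot,
      sum(rep(ys, times = length(xs)) * win) / tot)
  }
  ref <- t(mapply(refine, cand$x, cand$y))
  tibble(x = unname(ref[, 1]), y = unname(ref[, 2]),
         intensity = unname(cand$intensity))
}

#' Pair donor- and acceptor-view detections
#'
#' Greedy nearest-neighbor matching of acceptor positions to
#' `donor + offset` within `tolerance` pixels; unmatched spots are dropped
#' (count reported). An ambiguous match — two acceptor candidates within
#' tolerance of the same donor and within 1 px of each other — drops both.
#'
#' @param donor_spots,acceptor_spots Tibbles from [detect_spots()].
#' @param offset Known donor-to-acceptor translation `c(dx, dy)`.
#' @param tolerance Matching radius, pixels (default 2).
#' @return Tibble with `donor_idx`, `acceptor_idx`, donor `x`, `y`;
#'   attribute `"unmatched"` holds the dropped counts.
#' @export
pair_channels <- function(donor_spots, acceptor_spots, offset = c(0, 0),
                          tolerance = 2) {
  nd <- nrow(donor_spots); na <- nrow(acceptor_spots)
  if (!nd || !na) {
    out <- tibble(donor_idx = integer(0), acceptor_idx = integer(0),
                  x = numeric(0), y = numeric(0))
    attr(out, "unmatched") <- c(donor = nd, acceptor = na, ambiguous = 0)
    return(out)
  }
  taken <- rep(FALSE, na)
  res <- list(); amb <- 0L
  for (i in seq_len(nd)) {
    tx <- donor_spots$x[i] + offset[1]
    ty <- donor_spots$y[i] + offset[2]
    d <- sqrt((acceptor_spots$x - tx)^2 + (acceptor_spots$y - ty)^2)
    d[taken] <- Inf
    ok <- which(d <= tolerance)
    if (length(ok) >= 2) {
      o <- ok[order(d[ok])][1:2]
      dd <- sqrt((acceptor_spots$x[o[1]] - acceptor_spots$x[o[2]])^2 +
                   (acceptor_spots$y[o[1]] - acceptor_spots$y[o[2]])^2)
      if (dd < 1) { taken[o] <- TRUE; amb <- amb + 1L; next }
    }
    if (!length(ok)) next
    j <- ok[which.min(d[ok])]
    taken[j] <- TRUE
    res[[length(res) + 1]] <- tibble(donor_idx = i, acceptor_idx = j,
                                     x = donor_spots$x[i],
                                     y = donor_spots$y[i])
  }
  out <- bind_rows(res)
  if (!nrow(out)) out <- tibble(donor_idx = integer(0),
                                acceptor_idx = integer(0),
                                x = numeric(0), y = numeric(0))
  attr(out, "unmatched") <- c(donor = nd - nrow(out),
                              acceptor = na - nrow(out), ambiguous = amb)
  out
}

#' Extract an aperture-photometry intensity trace
#'
#' Per frame: summed pixel intensity inside a circular aperture centered on
#' the (sub-pixel) coordinate, minus the annulus median times the aperture
#' pixel count (local background). Errors if the aperture is clipped by the
#' frame edge.
#'
#' @param stack Array `c(height, width, n_frames)`.
#' @param x,y Sub-pixel spot coordinate.
#' @param aperture_radius Aperture radius, pixels (default 3).
#' @param annulus Inner/outer background annulus radii (default `c(5, 7)`).
#' @return Numeric intensity series, one value per frame.
#' @export
extract_trace <- function(stack, x, y, aperture_radius = 3,
                          annulus = c(5, 7)) {
  stopifnot(aperture_radius < annulus[1], annulus[1] < annulus[2])
  h <- dim(stack)[1]; w <- dim(stack)[2]; nf <- dim(stack)[3]
  if (x - aperture_radius < 1 || x + aperture_radius > w ||
      y - aperture_radius < 1 || y + aperture_radius > h) {
    abort("aperture clipped by frame edge; trace rejected")
  }
  xs <- max(1, floor(x - annulus[2])):min(w, ceiling(x + annulus[2]))
  ys <- max(1, floor(y - annulus[2])):min(h, ceiling(y + annulus[2]))
  dx <- outer(rep(1, length(ys)), xs) - x
  dy <- outer(ys, rep(1, length(xs))) - y
  r <- sqrt(dx^2 + dy^2)
  ap <- r <= aperture_radius
  an <- r >= annulus[1] & r <= annulus[2]
  n_ap <- sum(ap)
  vapply(seq_len(nf), function(f) {
    win <- stack[ys, xs, f]
    sum(win[ap]) - median(win[an]) * n_ap
  }, numeric(1))
}

#' Full extraction: dual-view stacks to a trace table
#'
#' Detects spots on the average of the first `detect_frames` frames of each
#' view (the brightest, pre-bleach part of the movie), pairs the channels at
#' the given offset, and extracts aperture-photometry traces for every pair.
#'
#' @param donor_stack,acceptor_stack Arrays `c(height, width, n_frames)`.
#' @param offset Donor-to-acceptor translation `c(dx, dy)`.
#' @param frame_dt Seconds per frame (default 0.1).
#' @param detect_frames Frames averaged for detection (default 10).
#' @param z_threshold,min_separation,psf_sigma Passed to [detect_spots()].
#' @param aperture_radius,annulus Passed to [extract_trace()].
#' @param tolerance Pairing radius (default 2).
#' @return Trace tibble (`trace_id`, `frame`, `time_s`, `donor`, `acceptor`)
#'   with the paired coordinates in attribute `"spots"`.
#' @export
extract_movie_traces <- function(donor_stack, acceptor_stack, offset = c(0, 0),
                                 frame_dt = 0.1, detect_frames = 10,
                                 z_threshold = 5, min_separation = 5,
                                 psf_sigma = 1.5, aperture_radius = 3,
                                 annulus = c(5, 7), tolerance = 2) {
  nf <- dim(donor_stack)[3]
  nd <- min(detect_frames, nf)
  davg <- apply(donor_stack[, , seq_len(nd), drop = FALSE], c(1, 2), mean)
  aavg <- apply(acceptor_stack[, , seq_len(nd), drop = FALSE], c(1, 2), mean)
  ds <- detect_spots(davg, z_threshold, min_separation, psf_sigma)
  as_ <- detect_spots(aavg, z_threshold, min_separation, psf_sigma)
  pairs <- pair_channels(ds, as_, offset, tolerance)
  if (!nrow(pairs)) abort("no paired spots found")
  out <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    d <- tryCatch(extract_trace(donor_stack, pairs$x[i], pairs$y[i],
                                aperture_radius, annulus),
                  error = function(e) NULL)
    a <- tryCatch(extract_trace(acceptor_stack,
                                pairs$x[i] + offset[1], pairs$y[i] + offset[2],
                                aperture_radius, annulus),
                  error = function(e) NULL)
    if (is.null(d) || is.null(a)) return(NULL)
    tibble(trace_id = sprintf("spot_%03d", i), frame = seq_len(nf),
           time_s = (seq_len(nf) - 1) * frame_dt, donor = d, acceptor = a)
  })
  attr(out, "spots") <- pairs
  out
}
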