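test_that("state paths honor degenerate chains and stationarity", {
  m1 <- gt_model(0.5, matrix(1, 1, 1))
  expect_equal(unique(simulate_state_path(m1, 50, seed = 1)), 1L)

  # identity transition matrix: the initial state is absorbing
  m_abs <- gt_model(c(0.2, 0.8), diag(2), occupancy = NULL)
  p <- simulate_state_path(m_abs, 200, seed = 3)
  expect_length(unique(p), 1)

  # long-run occupancy matches the stationary distribution (LLN); oracle is
  # the Perron eigenvector, computed independently of the sampler
  m <- yykt6_model()
  p <- simulate_state_path(m, 1e6, seed = 7)
  emp <- tabulate(p, 3) / 1e6
  eig <- stationary_distribution(m$transition_matrix)
  expect_lt(max(abs(emp - eig)), 0.01)
})

test_that("state path sampling is reproducible and validates its inputs", {
  m <- yykt6_model()
  expect_identical(simulate_state_path(m, 500, seed = 11),
                   simulate_state_path(m, 500, seed = 11))
  bad <- m$transition_matrix
  bad[1, ] <- bad[1, ] * 1.5
  expect_error(gt_model(m$efficiency_means, bad), "sum to 1")
})

test_that("trace emission follows the generative model", {
  # noiseless single state: exact channel split
  m0 <- gt_model(0.5, matrix(1, 1, 1), efficiency_sds = 0, camera_sd = 0,
                 total_intensity = 200, bleach_lifetime_s = Inf)
  tr <- simulate_trace(rep(1L, 20), m0, seed = 1)
  expect_equal(tr$donor, rep(100, 20))
  expect_equal(tr$acceptor, rep(100, 20))
  expect_true(all(is.na(tr$bleach_frame_true)))
  expect_true(all(tr$pre_bleach))

  # batch determinism
  m <- yykt6_model()
  expect_identical(simulate_traces(m, 5, 100, seed = 2),
                   simulate_traces(m, 5, 100, seed = 2))
})

test_that("pooled raw-efficiency histogram is tri-modal at the generator means", {
  m <- yykt6_model(bleach_lifetime_s = Inf)
  tr <- compute_efficiency(simulate_traces(m, 500, 200, seed = 5))
  d <- density(tr$efficiency[tr$eff_valid], bw = 0.01, from = -0.1, to = 1)
  # local maxima of the pooled density
  peaks <- d$x[which(diff(sign(diff(d$y))) == -2) + 1]
  modes <- vapply(m$efficiency_means,
                  function(mu) peaks[which.min(abs(peaks - mu))], numeric(1))
  expect_lt(max(abs(modes - m$efficiency_means)), 0.03)
})

test_that("bleaching truncates both channels to camera noise", {
  m <- yykt6_model(bleach_lifetime_s = 2) # short-lived dye
  tr <- simulate_traces(m, 30, 400, seed = 9)
  bf <- dplyr::distinct(tr, trace_id, bleach_frame_true)
  expect_true(any(!is.na(bf$bleach_frame_true)))
  post <- dplyr::filter(tr, !pre_bleach)
  expect_lt(abs(mean(post$donor + post$acceptor)), 3 * m$camera_sd)
})

test_that("simulated titration heats reduce to the analytic limits", {
  p <- itc_protocol()
  # zero noise reproduces model heats exactly
  truth <- list(N = 1, K_D = 38.5e-6, dH = -5, offset = 0.1)
  iso <- simulate_itc(truth, p, noise_sd = 0)
  expect_equal(iso$heat_kcal_per_mol, model_heats(truth, p))
  # dH = 0: all heats equal the offset
  iso0 <- simulate_itc(list(N = 1, K_D = 1e-5, dH = 0, offset = 0.07), p)
  expect_equal(iso0$heat_kcal_per_mol, rep(0.07, 19))
  # K_D -> 1 M: binding vanishes, heats approach the offset, flat and monotone
  iso_w <- simulate_itc(list(N = 1, K_D = 1, dH = -5, offset = 0), p)
  expect_lt(max(abs(iso_w$heat_kcal_per_mol)), 1e-3)
  expect_true(all(diff(abs(iso_w$heat_kcal_per_mol)) < 1e-6))
})

test_that("movie rendering matches its construction", {
  # zero spots: pure background with Poisson statistics
  sp <- movie_spec(width = 24, height = 24, n_frames = 30,
                   spot_positions = tibble::tibble(x = numeric(0), y = numeric(0)),
                   background_level = 20)
  tr_none <- tibble::tibble(trace_id = character(0), frame = integer(0),
                            time_s = numeric(0), donor = numeric(0),
                            acceptor = numeric(0))
  mov <- simulate_movie(sp, tr_none, seed = 1)
  expect_equal(mean(mov$donor), 20, tolerance = 0.02)
  expect_equal(var(as.numeric(mov$donor)), 20, tolerance = 0.1)

  # one static noiseless spot: aperture photometry recovers the trace value
  # within ~1% (PSF truncation; analytic Gaussian mass within the aperture)
  tr1 <- tibble::tibble(trace_id = "t", frame = 1:4, time_s = (0:3) * 0.1,
                        donor = rep(1000, 4), acceptor = rep(640, 4))
  sp1 <- movie_spec(width = 32, height = 32, n_frames = 4, psf_sigma = 1,
                    spot_positions = tibble::tibble(x = 16.5, y = 15.8),
                    background_level = 7)
  mv1 <- simulate_movie(sp1, tr1, noise = FALSE)
  got <- extract_trace(mv1$donor, 16.5, 15.8)
  expect_equal(got[1], 1000 * (1 - exp(-9 / 2)), tolerance = 0.005)
  expect_lt(abs(got[1] - 1000) / 1000, 0.02)

  # channel offset displaces the acceptor-view centroid by construction
  sp2 <- movie_spec(width = 32, height = 32, n_frames = 4, psf_sigma = 1,
                    spot_positions = tibble::tibble(x = 14.2, y = 15.8),
                    channel_offset = c(3.5, 0), background_level = 0)
  mv2 <- simulate_movie(sp2, tr1, noise = FALSE)
  cd <- detect_spots(mv2$donor[, , 1], psf_sigma = 1)
  ca <- detect_spots(mv2$acceptor[, , 1], psf_sigma = 1)
  expect_equal(ca$x - cd$x, 3.5, tolerance = 0.1)

  # overlapping spots are warned about
  spw <- movie_spec(width = 32, height = 32, n_frames = 1, psf_sigma = 1.5,
                    spot_positions = tibble::tibble(x = c(10, 12), y = c(10, 10)))
  tr2 <- tibble::tibble(trace_id = c("a", "b"), frame = c(1L, 1L),
                        time_s = c(0, 0), donor = c(100, 100),
                        acceptor = c(100, 100))
  expect_warning(simulate_movie(spw, tr2, noise = FALSE), "closer than")
})

test_that("TIFF stacks round-trip integer counts", {
  arr <- array(rpois(16 * 16 * 3, 50), dim = c(16, 16, 3))
  f <- withr::local_tempfile(fileext = ".tif")
  write_stack(arr, f)
  back <- read_stack(f)
  expect_equal(round(back), arr, ignore_attr = TRUE)
})
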