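# fretdyn

Conformational-state analysis for single-molecule FRET, with companion
one-site ITC fitting and a steered-pulling toy model.

Immobilized, dye-labeled protein molecules report conformational changes as
jumps in FRET efficiency. Given dual-channel intensity traces (or synthetic
ones generated from explicit ground truth), `fretdyn` answers the standard
questions of such an experiment: how many conformational states are visited,
at which efficiencies, with what populations and dwell times, and whether a
mutation or ligand shifts the balance.

The core of the package is the per-trace Gaussian-emission hidden Markov
model. For a trace of efficiencies `E_1..E_n`,

- `baum_welch()` maximizes the likelihood by EM (monotone by construction);
- `vb_em()` performs conjugate variational Bayes (Dirichlet priors on the
  initial/transition probabilities, Normal–Gamma on emissions) and returns
  the evidence lower bound;
- `select_states()` chooses the number of states K by maximizing the mean
  per-trace evidence over a candidate range (parsimony on ties);
- `viterbi()` idealizes each trace into its most probable state path.

Idealized trajectories feed the population analysis: `build_tdp()` compiles
the transition-density histogram of (E_before, E_after) pairs,
`derive_global_states()` finds global state centers by exact 1-D k-means
and puts thresholds at midpoints, and `assign_and_count()` reports
time-weighted occupancies, dwell summaries, transition counts and per-movie
fractions for Welch t-test group comparisons (`compare_populations()`).

Supporting modules:

- **synthetic data** — `gt_model()` / `simulate_traces()` generate traces
  (Markov state paths, Gaussian emissions, exponential photobleaching,
  camera noise); `simulate_movie()` renders dual-view image stacks;
  `simulate_itc()` produces titration heats. Benchmarks `yykt6_model()`
  (3 states) and `rykt6_model()` (5 states) carry published conformational
  landscapes as ground truth.
- **movie extraction** — `detect_spots()`, `pair_channels()`,
  `extract_movie_traces()`: aperture photometry from TIFF stacks.
- **ITC** — `model_heats()` / `fit_isotherm()`: the standard single-site
  displacement-cell isotherm with multi-start least squares, non-binding
  and low-c flags.
- **pulling toy** — `integrate_pull()` (overdamped Langevin under a
  constant-velocity harmonic spring, `U = ½k[vt − (x − x0)]²`),
  `detect_turning_point()` (rupture), `detect_distance_steps()`
  (changepoints) and `synchrony_report()`.

All user-facing functions take data frames first and return tibbles;
`tidy()`/`glance()` methods summarize fitted objects and `autoplot()`
methods draw the standard figures.

## Worked example

Simulate the three-state benchmark, run the pipeline at K = 3, and read off
the recovered landscape:

```r
library(fretdyn)

res <- run_pipeline(pipeline_config(ground_truth = "yykt6",
                                    n_traces = 200, n_frames = 1000,
                                    K = 3, seed = 1))
round(res$states$fractions * 100, 1)
#> [1] 51.1 38.6 10.3
round(res$states$centers, 3)
#> [1] 0.197 0.423 0.693
round(res$modal$modal_efficiency, 3)
#> [1] 0.200 0.420 0.679
```

The generating truth is occupancies 50.7/39.7/10.2% at efficiencies
0.20/0.42/0.68: the pipeline recovers the populations within about one
percentage point and the modal efficiencies within 0.01–0.02. A fitted ITC
isotherm round-trips its dissociation constant:

```r
iso <- simulate_itc(list(N = 1, K_D = 38.5e-6, dH = -5, offset = 0))
glance(fit_isotherm(iso))
#> # A tibble: 1 × 5
#>   K_D_uM      sse converged no_detectable_binding low_confidence
#>    <dbl>    <dbl> <lgl>     <lgl>                 <lgl>
#> 1   38.5 3.55e-22 TRUE      FALSE                 FALSE
```

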