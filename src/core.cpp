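#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for a (possibly unnormalized) HMM.
// logb: n x K per-frame log emission weights; loginit: K; logtrans: K x K.
// Unnormalized inputs are allowed (variational E-steps pass tilted
// sub-probabilities); loglik is then the log normalizer of the chain.
// [[Rcpp::export]]
List fb_scaled(NumericMatrix logb, NumericVector loginit, NumericMatrix logtrans) {
  const int n = logb.nrow(), K = logb.ncol();
  NumericMatrix alpha(n, K), beta(n, K), gamma(n, K);
  NumericVector logc(n);

  // shift emissions per frame for numerical range, fold shift into logc
  NumericVector bmax(n);
  NumericMatrix B(n, K);
  for (int t = 0; t < n; ++t) {
    double m = logb(t, 0);
    for (int k = 1; k < K; ++k) if (logb(t, k) > m) m = logb(t, k);
    if (!R_finite(m)) m = 0.0; // all -Inf frame: floor below
    bmax[t] = m;
    for (int k = 0; k < K; ++k) {
      double v = logb(t, k) - m;
      B(t, k) = (v < -745.0) ? 0.0 : std::exp(v);
    }
  }

  NumericMatrix A(K, K);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j)
      A(i, j) = std::exp(logtrans(i, j));
  NumericVector pi0(K);
  for (int k = 0; k < K; ++k) pi0[k] = std::exp(loginit[k]);

  // forward
  double c = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = pi0[k] * B(0, k); c += alpha(0, k); }
  if (c <= 0) { c = 1e-300; }
  for (int k = 0; k < K; ++k) alpha(0, k) /= c;
  logc[0] = std::log(c);
  for (int t = 1; t < n; ++t) {
    c = 0.0;
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int i = 0; i < K; ++i) s += alpha(t - 1, i) * A(i, k);
      alpha(t, k) = s * B(t, k);
      c += alpha(t, k);
    }
    if (c <= 0) c = 1e-300;
    for (int k = 0; k < K; ++k) alpha(t, k) /= c;
    logc[t] = std::log(c);
  }

  // backward
  for (int k = 0; k < K; ++k) beta(n - 1, k) = 1.0;
  for (int t = n - 2; t >= 0; --t) {
    double cc = std::exp(logc[t + 1]);
    for (int i = 0; i < K; ++i) {
      double s = 0.0;
      for (int j = 0; j < K; ++j) s += A(i, j) * B(t + 1, j) * beta(t + 1, j);
      beta(t, i) = s / cc;
    }
  }

  // posteriors and pairwise sums
  NumericMatrix xi(K, K);
  for (int t = 0; t < n; ++t) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); s += gamma(t, k); }
    if (s <= 0) s = 1e-300;
    for (int k = 0; k < K; ++k) gamma(t, k) /= s;
  }
  for (int t = 0; t < n - 1; ++t) {
    double cc = std::exp(logc[t + 1]);
    double s = 0.0;
    NumericMatrix tmp(K, K);
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < K; ++j) {
        tmp(i, j) = alpha(t, i) * A(i, j) * B(t + 1, j) * beta(t + 1, j) / cc;
        s += tmp(i, j);
      }
    if (s <= 0) s = 1e-300;
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < K; ++j)
        xi(i, j) += tmp(i, j) / s;
  }

  double loglik = 0.0;
  for (int t = 0; t < n; ++t) loglik += logc[t] + bmax[t];

  return List::create(_["loglik"] = loglik, _["gamma"] = gamma,
                      _["xi_sum"] = xi, _["gamma1"] = gamma(0, _));
}

// Viterbi decoding; ties broken toward the lower state index.
// [[Rcpp::export]]
List viterbi_path(NumericMatrix logb, NumericVector loginit, NumericMatrix logtrans) {
  const int n = logb.nrow(), K = logb.ncol();
  NumericMatrix delta(n, K);
  IntegerMatrix psi(n, K);
  for (int k = 0; k < K; ++k) delta(0, k) = loginit[k] + logb(0, k);
  for (int t = 1; t < n; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = R_NegInf; int arg = 0;
      for (int i = 0; i < K; ++i) {
        double v = delta(t - 1, i) + logtrans(i, k);
        if (v > best) { best = v; arg = i; } // strict: first (lowest) index wins ties
      }
      delta(t, k) = best + logb(t, k);
      psi(t, k) = arg;
    }
  }
  IntegerVector path(n);
  double best = R_NegInf; int arg = 0;
  for (int k = 0; k < K; ++k) if (delta(n - 1, k) > best) { best = delta(n - 1, k); arg = k; }
  path[n - 1] = arg;
  for (int t = n - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  for (int t = 0; t < n; ++t) path[t] += 1; // 1-based for R
  return List::create(_["path"] = path, _["logprob"] = best);
}

// Discrete Markov chain sampler using R's RNG (seed-respecting).
// [[Rcpp::export]]
IntegerVector sample_markov(NumericVector init, NumericMatrix trans, int n) {
  const int K = init.size();
  IntegerVector path(n);
  RNGScope scope;
  auto draw = [&](const double *p) {
    double u = unif_rand(), acc = 0.0;
    for (int k = 0; k < K; ++k) { acc += p[k]; if (u <= acc) return k; }
    return K - 1;
  };
  std::vector<double> row(K);
  for (int k = 0; k < K; ++k) row[k] = init[k];
  path[0] = draw(row.data());
  for (int t = 1; t < n; ++t) {
    int s = path[t - 1];
    for (int k = 0; k < K; ++k) row[k] = trans(s, k);
    path[t] = draw(row.data());
  }
  for (int t = 0; t < n; ++t) path[t] += 1;
  return path;
}

// Overdamped Langevin (Euler-Maruyama) under a moving harmonic steering
// potential on a sum-of-Gaussian-wells landscape. Uses R's RNG.
// Landscape: U(x) = sum_i -depth_i * exp(-(x-pos_i)^2 / (2 w_i^2)).
// [[Rcpp::export]]
List langevin_pull(NumericVector pos, NumericVector depth, NumericVector width,
                   double k, double v, double x0, double dt, int n_steps,
                   double gamma, double temperature, double x_max,
                   int record_every) {
  const int nw = pos.size();
  const int n_rec = n_steps / record_every + 1;
  NumericVector x(n_rec), force(n_rec), reference(n_rec);
  RNGScope scope;
  const double noise = std::sqrt(2.0 * temperature * dt / gamma);
  double xc = x0;
  bool diverged = false;
  int m = 0;
  x[0] = xc; reference[0] = x0; force[0] = 0.0; m = 1;
  for (int s = 1; s <= n_steps; ++s) {
    double t = s * dt;
    double ref = x0 + v * t;
    // landscape gradient
    double dU = 0.0;
    for (int i = 0; i < nw; ++i) {
      double z = (xc - pos[i]) / width[i];
      dU += depth[i] * z / width[i] * std::exp(-0.5 * z * z);
    }
    double fs = k * (ref - xc); // steering force before the step
    xc += (-dU + fs) / gamma * dt + (temperature > 0 ? noise * norm_rand() : 0.0);
    bool bad = !R_finite(xc) || std::fabs(xc) > x_max;
    if (s % record_every == 0 || bad) {
      if (m < n_rec) {
        x[m] = xc; reference[m] = ref; force[m] = k * (ref - xc); ++m;
      }
    }
    if (bad) { diverged = true; break; }
  }
  if (m < n_rec) {
    x = x[Range(0, m - 1)]; force = force[Range(0, m - 1)];
    reference = reference[Range(0, m - 1)];
  }
  return List::create(_["x"] = x, _["reference"] = reference, _["force"] = force,
                      _["diverged"] = diverged, _["record_every"] = record_every);
}
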