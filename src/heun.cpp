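#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Drift of the coupled system. S is n x 4 (A, X, Y, Z); neighbour sums are
// taken over the CSR adjacency (nb_idx 0-based, nb_ptr length n+1) and
// divided by the nominal coordination number.
static void drift(const std::vector<double>& S, int n,
                  const IntegerVector& nb_idx, const IntegerVector& nb_ptr,
                  double coord, const NumericVector& p,
                  std::vector<double>& out) {
  const double a = p[0], b = p[1], c = p[2], q = p[3], r = p[4], s = p[5];
  const double hn = p[6];
  for (int i = 0; i < n; ++i) {
    double xb = 0.0, yb = 0.0;
    for (int k = nb_ptr[i]; k < nb_ptr[i + 1]; ++k) {
      xb += S[nb_idx[k] + n];      // X column
      yb += S[nb_idx[k] + 2 * n];  // Y column
    }
    xb /= coord; yb /= coord;
    const double A = S[i], X = S[i + n], Y = S[i + 2 * n], Z = S[i + 3 * n];
    const double An = std::pow(A, hn), Xn = std::pow(X, hn),
                 Yn = std::pow(Y, hn), Zn = std::pow(Z, hn);
    const double stab = b * std::pow(Y * yb, hn);
    out[i]         = 1.0 / (1.0 + r * Yn + r * Zn) - A;
    out[i + n]     = q * An / (q + a * std::pow(xb, hn)) - X;
    out[i + 2 * n] = (q * An + stab) / (q + stab + c * Xn + c * Zn) - Y;
    out[i + 3 * n] = (Xn + s * Zn) / (1.0 + s * Zn) - Z;
  }
}

// One Heun-Maruyama segment with constant parameters. Noise is additive on
// X and Y only; the same Wiener increment enters predictor and corrector.
// States are clamped at `lower` after each stage. Samples are recorded at
// steps k (1-based within this segment) where (step_offset + k) %
// record_every == 0, matching the global sampling grid across segments.
// [[Rcpp::export(name = ".hm_segment_cpp")]]
List hm_segment_cpp(NumericMatrix S0, IntegerVector nb_idx,
                    IntegerVector nb_ptr, double coord, NumericVector p,
                    double dt, int n_steps, int record_every,
                    int step_offset, bool noise_on, double lower) {
  const int n = S0.nrow();
  std::vector<double> S(S0.begin(), S0.end());
  std::vector<double> f1(4 * n), f2(4 * n), Sp(4 * n);
  const double eta_x = p[7], eta_y = p[8], sq = std::sqrt(dt);

  int n_rec = 0;
  for (int k = 1; k <= n_steps; ++k)
    if ((step_offset + k) % record_every == 0) ++n_rec;
  NumericVector samples(static_cast<R_xlen_t>(n_rec) * n * 4);
  IntegerVector rec_steps(n_rec);

  long long clamped = 0;
  double max_clamp = 0.0;  // largest undershoot below `lower` seen
  int m = 0;
  for (int k = 1; k <= n_steps; ++k) {
    drift(S, n, nb_idx, nb_ptr, coord, p, f1);
    NumericVector dwx, dwy;
    if (noise_on) { dwx = rnorm(n); dwy = rnorm(n); }
    for (int i = 0; i < n; ++i) {
      double gx = noise_on ? eta_x * sq * dwx[i] : 0.0;
      double gy = noise_on ? eta_y * sq * dwy[i] : 0.0;
      Sp[i]         = S[i] + f1[i] * dt;
      Sp[i + n]     = S[i + n] + f1[i + n] * dt + gx;
      Sp[i + 2 * n] = S[i + 2 * n] + f1[i + 2 * n] * dt + gy;
      Sp[i + 3 * n] = S[i + 3 * n] + f1[i + 3 * n] * dt;
    }
    for (int j = 0; j < 4 * n; ++j) if (Sp[j] < lower) Sp[j] = lower;
    drift(Sp, n, nb_idx, nb_ptr, coord, p, f2);
    for (int i = 0; i < n; ++i) {
      double gx = noise_on ? eta_x * sq * dwx[i] : 0.0;
      double gy = noise_on ? eta_y * sq * dwy[i] : 0.0;
      S[i]         += 0.5 * (f1[i] + f2[i]) * dt;
      S[i + n]     += 0.5 * (f1[i + n] + f2[i + n]) * dt + gx;
      S[i + 2 * n] += 0.5 * (f1[i + 2 * n] + f2[i + 2 * n]) * dt + gy;
      S[i + 3 * n] += 0.5 * (f1[i + 3 * n] + f2[i + 3 * n]) * dt;
    }
    for (int j = 0; j < 4 * n; ++j)
      if (S[j] < lower) {
        if (lower - S[j] > max_clamp) max_clamp = lower - S[j];
        S[j] = lower; ++clamped;
      }
    for (int j = 0; j < 4 * n; ++j)
      if (!std::isfinite(S[j]))
        stop("non-finite state in cell %d at segment step %d",
             (j % n) + 1, k);
    if ((step_offset + k) % record_every == 0) {
      std::copy(S.begin(), S.end(),
                samples.begin() + static_cast<R_xlen_t>(m) * 4 * n);
      rec_steps[m++] = step_offset + k;
    }
  }
  NumericMatrix Sf(n, 4);
  std::copy(S.begin(), S.end(), Sf.begin());
  return List::create(_["final"] = Sf, _["samples"] = samples,
                      _["rec_steps"] = rec_steps,
                      _["n_clamped"] = static_cast<double>(clamped),
                      _["max_clamp"] = max_clamp,
                      _["n_updates"] = static_cast<double>(n_steps) * 4 * n);
}
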