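// Entropy estimators for short EEG windows.
//
// Conventions (fixed package-wide, see the methods vignette):
//   sample entropy  - Richman/Moorman, strict d < r, self-matches excluded,
//                     N - m template vectors for both lengths
//   approximate     - Pincus, d <= r, self-matches included
//   fuzzy           - Chen et al., baseline-removed templates, exp(-(d/r)^n),
//                     self-matches excluded, N - m vectors for both lengths
// All distances are Chebyshev (max component difference).
#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

static double samp_en(const double* x, int N, int m, double r) {
  const int nt = N - m; // template count for both m and m+1
  if (nt < 2 || r <= 0.0) return NA_REAL;
  long long A = 0, B = 0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) >= r) { ok = false; break; }
      }
      if (!ok) continue;
      ++B;
      if (std::fabs(x[i + m] - x[j + m]) < r) ++A;
    }
  }
  if (A == 0 || B == 0) return NA_REAL;
  return -std::log((double)A / (double)B);
}

static double approx_en(const double* x, int N, int m, double r) {
  const int nm = N - m + 1;  // m-vector count
  const int nm1 = N - m;     // (m+1)-vector count
  if (nm1 < 1 || r < 0.0) return NA_REAL;
  std::vector<long long> cm(nm, 1), cm1(nm1, 1); // self-matches
  for (int i = 0; i < nm - 1; ++i) {
    for (int j = i + 1; j < nm; ++j) {
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { ok = false; break; }
      }
      if (!ok) continue;
      ++cm[i]; ++cm[j];
      if (j < nm1 && std::fabs(x[i + m] - x[j + m]) <= r) { ++cm1[i]; ++cm1[j]; }
    }
  }
  double phim = 0.0, phim1 = 0.0;
  for (int i = 0; i < nm; ++i) phim += std::log((double)cm[i] / nm);
  for (int i = 0; i < nm1; ++i) phim1 += std::log((double)cm1[i] / nm1);
  return phim / nm - phim1 / nm1;
}

static inline double fuzzy_sim(double d, double r, double n_exp, double dcut) {
  // similarity below exp(-45) ~ 3e-20 is dropped; bias ~1e-18 on the mean
  if (d > dcut) return 0.0;
  const double u = d / r;
  const double p = (n_exp == 2.0) ? u * u
                 : (n_exp == 1.0) ? u : std::pow(u, n_exp);
  return std::exp(-p);
}

static double fuzzy_en(const double* x, int N, int m, double n_exp, double r) {
  const int nt = N - m; // template count for both lengths
  if (nt < 2 || r <= 0.0) return NA_REAL;
  const double dcut = r * std::pow(45.0, 1.0 / n_exp);
  // baseline-removed templates, stored contiguously
  std::vector<double> tm((size_t)nt * m), tm1((size_t)nt * (m + 1));
  for (int i = 0; i < nt; ++i) {
    double mu = 0.0, mu1 = 0.0;
    for (int k = 0; k < m; ++k) mu += x[i + k];
    for (int k = 0; k <= m; ++k) mu1 += x[i + k];
    mu /= m; mu1 /= (m + 1);
    for (int k = 0; k < m; ++k) tm[(size_t)i * m + k] = x[i + k] - mu;
    for (int k = 0; k <= m; ++k) tm1[(size_t)i * (m + 1) + k] = x[i + k] - mu1;
  }
  double sm = 0.0, sm1 = 0.0;
  if (m == 2) {
    // centred length-2 templates are (a, -a), so the Chebyshev distance
    // reduces to |a_i - a_j| with a_i = (x_i - x_{i+1}) / 2
    std::vector<double> a(nt);
    for (int i = 0; i < nt; ++i) a[i] = 0.5 * (x[i] - x[i + 1]);
    for (int i = 0; i < nt - 1; ++i) {
      const double ai = a[i];
      const double c0 = tm1[(size_t)i * 3], c1 = tm1[(size_t)i * 3 + 1],
                   c2 = tm1[(size_t)i * 3 + 2];
      for (int j = i + 1; j < nt; ++j) {
        sm += fuzzy_sim(std::fabs(ai - a[j]), r, n_exp, dcut);
        double d1 = std::fabs(c0 - tm1[(size_t)j * 3]);
        const double e1 = std::fabs(c1 - tm1[(size_t)j * 3 + 1]);
        if (e1 > d1) d1 = e1;
        const double e2 = std::fabs(c2 - tm1[(size_t)j * 3 + 2]);
        if (e2 > d1) d1 = e2;
        sm1 += fuzzy_sim(d1, r, n_exp, dcut);
      }
    }
  } else {
    for (int i = 0; i < nt - 1; ++i) {
      const double* ti = &tm[(size_t)i * m];
      const double* ti1 = &tm1[(size_t)i * (m + 1)];
      for (int j = i + 1; j < nt; ++j) {
        const double* tj = &tm[(size_t)j * m];
        double d = 0.0;
        for (int k = 0; k < m; ++k) {
          const double a = std::fabs(ti[k] - tj[k]);
          if (a > d) d = a;
        }
        sm += fuzzy_sim(d, r, n_exp, dcut);
        const double* tj1 = &tm1[(size_t)j * (m + 1)];
        double d1 = 0.0;
        for (int k = 0; k <= m; ++k) {
          const double a = std::fabs(ti1[k] - tj1[k]);
          if (a > d1) d1 = a;
        }
        sm1 += fuzzy_sim(d1, r, n_exp, dcut);
      }
    }
  }
  const double denom = 0.5 * (double)nt * (nt - 1);
  const double phim = sm / denom, phim1 = sm1 / denom;
  if (phim <= 0.0 || phim1 <= 0.0) return NA_REAL;
  return std::log(phim / phim1);
}

static double renyi_en(const double* x, int N, double q, int bins) {
  double lo = x[0], hi = x[0];
  for (int i = 1; i < N; ++i) {
    if (x[i] < lo) lo = x[i];
    if (x[i] > hi) hi = x[i];
  }
  if (hi <= lo) return 0.0; // all mass in one bin
  const double w = (hi - lo) / bins;
  std::vector<int> cnt(bins, 0);
  for (int i = 0; i < N; ++i) {
    int b = (int)((x[i] - lo) / w);
    if (b >= bins) b = bins - 1;
    if (b < 0) b = 0;
    ++cnt[b];
  }
  double s = 0.0;
  for (int b = 0; b < bins; ++b) {
    if (cnt[b] > 0) s += std::pow((double)cnt[b] / N, q);
  }
  return std::log(s) / (1.0 - q);
}

static void coarse(const double* x, int N, int tau, std::vector<double>& y) {
  const int ny = N / tau;
  y.assign(ny, 0.0);
  for (int j = 0; j < ny; ++j) {
    double s = 0.0;
    for (int k = 0; k < tau; ++k) s += x[j * tau + k];
    y[j] = s / tau;
  }
}

// [[Rcpp::export]]
double cpp_sample_entropy(NumericVector x, int m, double r) {
  return samp_en(x.begin(), x.size(), m, r);
}

// [[Rcpp::export]]
double cpp_approximate_entropy(NumericVector x, int m, double r) {
  return approx_en(x.begin(), x.size(), m, r);
}

// [[Rcpp::export]]
double cpp_fuzzy_entropy(NumericVector x, int m, double n_exp, double r) {
  return fuzzy_en(x.begin(), x.size(), m, n_exp, r);
}

// [[Rcpp::export]]
double cpp_renyi_entropy(NumericVector x, double q, int bins) {
  return renyi_en(x.begin(), x.size(), q, bins);
}

// [[Rcpp::export]]
NumericVector cpp_multiscale_entropy(NumericVector x, int m, double r, int tau_max) {
  NumericVector out(tau_max);
  std::vector<double> y;
  for (int tau = 1; tau <= tau_max; ++tau) {
    coarse(x.begin(), x.size(), tau, y);
    out[tau - 1] = samp_en(y.data(), (int)y.size(), m, r);
  }
  return out;
}

// Batch driver: all requested features for every window of one band signal.
// starts: 0-based window start offsets; w: window length in samples.
// Row order: mse tau=1..tau_max (if requested), then ae, fe, re, de.
// Zero-variance windows yield NaN in every row (flagged upstream).
// [[Rcpp::export]]
NumericMatrix cpp_stream_features(NumericVector sig, IntegerVector starts, int w,
                                  int m, double r_factor, double n_exp, double q,
                                  int bins, int tau_max,
                                  bool do_mse, bool do_ae, bool do_fe,
                                  bool do_re, bool do_de) {
  const int nw = starts.size();
  const int nrow = (do_mse ? tau_max : 0) + do_ae + do_fe + do_re + do_de;
  NumericMatrix out(nrow, nw);
  std::vector<double> y;
  for (int c = 0; c < nw; ++c) {
    const double* x = sig.begin() + starts[c];
    double mu = 0.0;
    for (int i = 0; i < w; ++i) mu += x[i];
    mu /= w;
    double ss = 0.0;
    for (int i = 0; i < w; ++i) { const double d = x[i] - mu; ss += d * d; }
    const double var = ss / (w - 1);
    const double sd = std::sqrt(var);
    int rrow = 0;
    if (sd <= 0.0) {
      for (int i = 0; i < nrow; ++i) out(i, c) = NA_REAL;
      continue;
    }
    const double r = r_factor * sd;
    if (do_mse) {
      for (int tau = 1; tau <= tau_max; ++tau) {
        coarse(x, w, tau, y);
        out(rrow++, c) = samp_en(y.data(), (int)y.size(), m, r);
      }
    }
    if (do_ae) out(rrow++, c) = approx_en(x, w, m, r);
    if (do_fe) out(rrow++, c) = fuzzy_en(x, w, m, n_exp, r);
    if (do_re) out(rrow++, c) = renyi_en(x, w, q, bins);
    if (do_de) out(rrow++, c) = 0.5 * std::log(2.0 * M_PI * M_E * var);
  }
  return out;
}
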