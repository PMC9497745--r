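// db6 discrete wavelet transform with half-sample symmetric extension.
// Analysis keeps floor((n + L - 1)/2) coefficients per level; synthesis
// trims L-2 leading samples and cuts back to the recorded input length,
// which makes the multilevel round trip exact to machine precision.
#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

#define DB6_LEN 12

static const double DB6_DEC_LO[DB6_LEN] = {
  -0.0010773010853084796, 0.004777257510945511, 0.0005538422011614961,
  -0.03158203931748603, 0.027522865530305727, 0.09750160558732304,
  -0.12976686756726194, -0.22626469396543983, 0.31525035170919763,
  0.7511339080210954, 0.49462389039845306, 0.11154074335010947
};
static const double DB6_DEC_HI[DB6_LEN] = {
  -0.11154074335010947, 0.49462389039845306, -0.7511339080210954,
  0.31525035170919763, 0.22626469396543983, -0.12976686756726194,
  -0.09750160558732304, 0.027522865530305727, 0.03158203931748603,
  0.0005538422011614961, -0.004777257510945511, -0.0010773010853084796
};
static const double DB6_REC_LO[DB6_LEN] = {
  0.11154074335010947, 0.49462389039845306, 0.7511339080210954,
  0.31525035170919763, -0.22626469396543983, -0.12976686756726194,
  0.09750160558732304, 0.027522865530305727, -0.03158203931748603,
  0.0005538422011614961, 0.004777257510945511, -0.0010773010853084796
};
static const double DB6_REC_HI[DB6_LEN] = {
  -0.0010773010853084796, -0.004777257510945511, 0.0005538422011614961,
  0.03158203931748603, 0.027522865530305727, -0.09750160558732304,
  -0.12976686756726194, 0.22626469396543983, 0.31525035170919763,
  -0.7511339080210954, 0.49462389039845306, -0.11154074335010947
};

// reflect an out-of-range index into [0, n) with half-sample symmetry
static inline int sym_reflect(int s, int n) {
  if (n == 1) return 0;
  while (s < 0 || s >= n) {
    if (s < 0) s = -s - 1;
    if (s >= n) s = 2 * n - s - 1;
  }
  return s;
}

static void dwt_step(const std::vector<double>& x,
                     std::vector<double>& cA, std::vector<double>& cD) {
  const int n = (int)x.size();
  const int out = (n + DB6_LEN - 1) / 2;
  cA.assign(out, 0.0);
  cD.assign(out, 0.0);
  for (int i = 0; i < out; ++i) {
    double sa = 0.0, sd = 0.0;
    for (int j = 0; j < DB6_LEN; ++j) {
      const double v = x[sym_reflect(2 * i + 1 - j, n)];
      sa += DB6_DEC_LO[j] * v;
      sd += DB6_DEC_HI[j] * v;
    }
    cA[i] = sa;
    cD[i] = sd;
  }
}

static void idwt_step(const std::vector<double>& cA, const std::vector<double>& cD,
                      int out_len, std::vector<double>& out) {
  const int la = (int)cA.size();
  out.assign(out_len, 0.0);
  // full[t] = sum_i cA[i] * rec_lo[t - 2i] + cD[i] * rec_hi[t - 2i], trimmed by L-2
  for (int k = 0; k < out_len; ++k) {
    const int t = k + DB6_LEN - 2;
    double s = 0.0;
    int i0 = (t - DB6_LEN + 1 + 1) / 2; // ceil((t - L + 1)/2)
    if (2 * i0 < t - DB6_LEN + 1) ++i0;
    if (i0 < 0) i0 = 0;
    int i1 = t / 2;
    if (i1 > la - 1) i1 = la - 1;
    for (int i = i0; i <= i1; ++i) {
      const int j = t - 2 * i;
      s += cA[i] * DB6_REC_LO[j] + cD[i] * DB6_REC_HI[j];
    }
    out[k] = s;
  }
}

struct Decomp {
  std::vector< std::vector<double> > details; // details[0] = level 1 (finest)
  std::vector<double> approx;                 // level J approximation
  std::vector<int> lens;                      // input length at each level, lens[0] = n
};

static void wavedec(const std::vector<double>& x, int J, Decomp& d) {
  d.details.assign(J, std::vector<double>());
  d.lens.assign(J, 0);
  std::vector<double> a = x, cA, cD;
  for (int j = 0; j < J; ++j) {
    d.lens[j] = (int)a.size();
    dwt_step(a, cA, cD);
    d.details[j] = cD;
    a = cA;
  }
  d.approx = a;
}

static void waverec(const Decomp& d, std::vector<double>& out) {
  const int J = (int)d.details.size();
  std::vector<double> a = d.approx, tmp;
  for (int j = J - 1; j >= 0; --j) {
    idwt_step(a, d.details[j], d.lens[j], tmp);
    a = tmp;
  }
  out = a;
}

// [[Rcpp::export]]
List cpp_wavedec(NumericVector x, int J) {
  std::vector<double> xs(x.begin(), x.end());
  Decomp d;
  wavedec(xs, J, d);
  List dets(J);
  for (int j = 0; j < J; ++j) dets[j] = wrap(d.details[j]);
  return List::create(_["approx"] = wrap(d.approx),
                      _["details"] = dets,
                      _["lens"] = wrap(d.lens));
}

// [[Rcpp::export]]
NumericVector cpp_waverec(NumericVector approx, List details, IntegerVector lens) {
  Decomp d;
  const int J = details.size();
  d.details.resize(J);
  for (int j = 0; j < J; ++j) {
    NumericVector v = details[j];
    d.details[j].assign(v.begin(), v.end());
  }
  d.approx.assign(approx.begin(), approx.end());
  d.lens.assign(lens.begin(), lens.end());
  std::vector<double> out;
  waverec(d, out);
  return wrap(out);
}

// Reconstruct the signal contribution of each decomposition level separately.
// Returns an n x (J+1) matrix: columns D1..DJ then AJ; columns sum to x.
// [[Rcpp::export]]
NumericMatrix cpp_band_reconstruct(NumericVector x, int J) {
  std::vector<double> xs(x.begin(), x.end());
  Decomp d;
  wavedec(xs, J, d);
  const int n = (int)xs.size();
  NumericMatrix out(n, J + 1);
  std::vector<double> rec;
  for (int keep = 0; keep <= J; ++keep) {
    Decomp z;
    z.lens = d.lens;
    z.approx.assign(d.approx.size(), 0.0);
    z.details.resize(J);
    for (int j = 0; j < J; ++j) z.details[j].assign(d.details[j].size(), 0.0);
    if (keep < J) z.details[keep] = d.details[keep];
    else z.approx = d.approx;
    waverec(z, rec);
    for (int i = 0; i < n; ++i) out(i, keep) = rec[i];
  }
  return out;
}

// Halve coefficients whose magnitude exceeds mean(c) + 2 sd(c) (sample sd).
static void threshold_inplace(std::vector<double>& c) {
  const int n = (int)c.size();
  if (n < 2) return;
  double mu = 0.0;
  for (int i = 0; i < n; ++i) mu += c[i];
  mu /= n;
  double ss = 0.0;
  for (int i = 0; i < n; ++i) { const double d = c[i] - mu; ss += d * d; }
  const double T = mu + 2.0 * std::sqrt(ss / (n - 1));
  for (int i = 0; i < n; ++i)
    if (std::fabs(c[i]) > T) c[i] *= 0.5;
}

// Wavelet-threshold artifact correction of one signal: decompose to J levels,
// apply the mean + 2 sd halving rule at every level, reconstruct.
// [[Rcpp::export]]
NumericVector cpp_artifact_correct(NumericVector x, int J) {
  std::vector<double> xs(x.begin(), x.end());
  Decomp d;
  wavedec(xs, J, d);
  for (int j = 0; j < J; ++j) threshold_inplace(d.details[j]);
  threshold_inplace(d.approx);
  std::vector<double> out;
  waverec(d, out);
  return wrap(out);
}
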