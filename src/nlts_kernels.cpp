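#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Grassberger-Procaccia correlation sums at a set of radii.
// points: N x m embedded trajectory; Chebyshev (max) norm; pairs closer than
// `theiler` samples in time are excluded. Returns C(r) = #{pairs d <= r} /
// #valid pairs for each radius.
// [[Rcpp::export]]
NumericVector gp_corr_sum_cpp(NumericMatrix points, NumericVector radii,
                              int theiler) {
  const int N = points.nrow(), m = points.ncol(), nr = radii.size();
  std::vector<double> lr(nr);
  NumericVector counts(nr);
  double npairs = 0.0;
  for (int i = 0; i < N; ++i) {
    for (int j = i + theiler + 1; j < N; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double a = std::fabs(points(i, k) - points(j, k));
        if (a > d) d = a;
      }
      npairs += 1.0;
      for (int r = nr - 1; r >= 0; --r) {
        if (d <= radii[r]) counts[r] += 1.0; else break;
      }
    }
  }
  if (npairs == 0) stop("no valid pairs after Theiler exclusion");
  for (int r = 0; r < nr; ++r) counts[r] /= npairs;
  return counts;
}

// Rosenstein mean log divergence curve. For each reference point find its
// nearest neighbour at temporal distance > theiler, then track the mean of
// log Euclidean distance over k = 0..k_max steps ahead.
// [[Rcpp::export]]
NumericVector rosenstein_cpp(NumericMatrix points, int theiler, int k_max) {
  const int N = points.nrow(), m = points.ncol();
  std::vector<int> nn(N, -1);
  for (int i = 0; i < N; ++i) {
    double best = std::numeric_limits<double>::infinity();
    for (int j = 0; j < N; ++j) {
      if (std::abs(i - j) <= theiler) continue;
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double a = points(i, k) - points(j, k);
        d += a * a;
      }
      if (d < best && d > 0.0) { best = d; nn[i] = j; }
    }
  }
  NumericVector out(k_max + 1);
  std::vector<double> cnt(k_max + 1, 0.0);
  for (int i = 0; i < N; ++i) {
    int j = nn[i];
    if (j < 0) continue;
    for (int k = 0; k <= k_max; ++k) {
      if (i + k >= N || j + k >= N) break;
      double d = 0.0;
      for (int c = 0; c < m; ++c) {
        double a = points(i + k, c) - points(j + k, c);
        d += a * a;
      }
      if (d > 0.0) {
        out[k] += 0.5 * std::log(d);
        cnt[k] += 1.0;
      }
    }
  }
  for (int k = 0; k <= k_max; ++k)
    out[k] = cnt[k] > 0 ? out[k] / cnt[k] : NA_REAL;
  return out;
}

// Sample entropy: -log(A/B) with template length m, tolerance r (absolute),
// Chebyshev norm, self-matches excluded.
// [[Rcpp::export]]
List sampen_cpp(NumericVector x, int m, double r) {
  const int N = x.size();
  double B = 0.0, A = 0.0;
  const int nm = N - m;
  for (int i = 0; i < nm; ++i) {
    for (int j = i + 1; j < nm; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double a = std::fabs(x[i + k] - x[j + k]);
        if (a > d) d = a;
      }
      if (d <= r) {
        B += 1.0;
        double a = std::fabs(x[i + m] - x[j + m]);
        if (a > d) d = a;
        if (d <= r) A += 1.0;
      }
    }
  }
  return List::create(_["A"] = A, _["B"] = B);
}

// Average mutual information (equal-width histogram, `bins` x `bins`) between
// x(t) and x(t+lag), for lag = 1..max_lag. Returned in nats.
// [[Rcpp::export]]
NumericVector ami_cpp(NumericVector x, int max_lag, int bins) {
  const int N = x.size();
  double lo = min(x), hi = max(x);
  if (hi <= lo) stop("constant signal: mutual information undefined");
  double scale = bins / (hi - lo) * (1.0 - 1e-12);
  std::vector<int> bx(N);
  for (int i = 0; i < N; ++i)
    bx[i] = (int)((x[i] - lo) * scale);
  NumericVector out(max_lag);
  std::vector<double> joint(bins * bins), px(bins), py(bins);
  for (int lag = 1; lag <= max_lag; ++lag) {
    int M = N - lag;
    if (M < 10) { out[lag - 1] = NA_REAL; continue; }
    std::fill(joint.begin(), joint.end(), 0.0);
    std::fill(px.begin(), px.end(), 0.0);
    std::fill(py.begin(), py.end(), 0.0);
    for (int i = 0; i < M; ++i) {
      joint[bx[i] * bins + bx[i + lag]] += 1.0;
      px[bx[i]] += 1.0;
      py[bx[i + lag]] += 1.0;
    }
    double mi = 0.0;
    for (int a = 0; a < bins; ++a) {
      if (px[a] == 0) continue;
      for (int b = 0; b < bins; ++b) {
        double j = joint[a * bins + b];
        if (j == 0 || py[b] == 0) continue;
        mi += (j / M) * std::log(j * M / (px[a] * py[b]));
      }
    }
    out[lag - 1] = mi;
  }
  return out;
}

// False-nearest-neighbour fraction for embedding dimension m (Kennel
// criterion). points_m: N x m embedding; xnext: the (m*lag)-ahead scalar used
// to extend each point to dimension m+1 (length N, NA-free).
// [[Rcpp::export]]
double fnn_fraction_cpp(NumericMatrix points_m, NumericVector xnext,
                        int theiler, double rtol, double atol, double sd_x) {
  const int N = points_m.nrow(), m = points_m.ncol();
  double fnn = 0.0, total = 0.0;
  for (int i = 0; i < N; ++i) {
    double best = std::numeric_limits<double>::infinity();
    int jb = -1;
    for (int j = 0; j < N; ++j) {
      if (std::abs(i - j) <= theiler) continue;
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double a = points_m(i, k) - points_m(j, k);
        d += a * a;
      }
      if (d < best && d > 0.0) { best = d; jb = j; }
    }
    if (jb < 0) continue;
    double rd = std::sqrt(best);
    double extra = std::fabs(xnext[i] - xnext[jb]);
    total += 1.0;
    double rd1 = std::sqrt(best + extra * extra);
    if (extra / rd > rtol || rd1 / sd_x > atol) fnn += 1.0;
  }
  return total > 0 ? fnn / total : NA_REAL;
}
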