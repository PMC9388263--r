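#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Synchronization likelihood between two channels (M = 2).
// Time-delay embedding (dimension m, lag), Theiler/sharpening window
// w1 < |i-j| < w2, per-channel critical distance as the rank statistic at
// reference recurrence probability p_ref. For each reference vector i the
// per-channel likelihood is the fraction of that channel's recurrences at
// which the other channel also recurs; the pair value averages over i and
// both channels. Equals 1 for identical signals, ~p_ref for independent ones.
// [[Rcpp::export]]
double sl_pair_cpp(NumericVector x, NumericVector y, int m, int lag,
                   double p_ref, int w1, int w2, int stride) {
  const int N = x.size();
  const int n_vec = N - (m - 1) * lag;
  if (n_vec <= w1 + 1)
    stop("signal too short for embedding and Theiler window");

  std::vector<double> dx, dy, tmp;
  double acc = 0.0;
  int n_used = 0;

  for (int i = 0; i < n_vec; i += stride) {
    dx.clear(); dy.clear();
    int j_lo1 = std::max(0, i - w2 + 1), j_hi1 = i - w1 - 1;
    int j_lo2 = i + w1 + 1, j_hi2 = std::min(n_vec - 1, i + w2 - 1);
    for (int side = 0; side < 2; ++side) {
      int lo = side == 0 ? j_lo1 : j_lo2;
      int hi = side == 0 ? j_hi1 : j_hi2;
      for (int j = lo; j <= hi; ++j) {
        double sx = 0.0, sy = 0.0;
        for (int k = 0; k < m; ++k) {
          double ex = x[i + k * lag] - x[j + k * lag];
          double ey = y[i + k * lag] - y[j + k * lag];
          sx += ex * ex; sy += ey * ey;
        }
        dx.push_back(std::sqrt(sx));
        dy.push_back(std::sqrt(sy));
      }
    }
    const int W = (int)dx.size();
    if (W < 2) continue;
    int n_ref = (int)std::ceil(p_ref * W);
    if (n_ref < 1) n_ref = 1;

    tmp = dx;
    std::nth_element(tmp.begin(), tmp.begin() + (n_ref - 1), tmp.end());
    double eps_x = tmp[n_ref - 1];
    tmp = dy;
    std::nth_element(tmp.begin(), tmp.begin() + (n_ref - 1), tmp.end());
    double eps_y = tmp[n_ref - 1];

    int nx = 0, ny = 0, both = 0;
    for (int j = 0; j < W; ++j) {
      bool hx = dx[j] <= eps_x, hy = dy[j] <= eps_y;
      if (hx) ++nx;
      if (hy) ++ny;
      if (hx && hy) ++both;
    }
    if (nx > 0 && ny > 0) {
      acc += 0.5 * ((double)both / nx + (double)both / ny);
      ++n_used;
    }
  }
  if (n_used == 0) stop("no reference vectors with a valid window");
  return acc / n_used;
}

// Correlation sums C_m(r) for m = 1..m_max on a common truncated point set
// (all vectors that exist at m_max), Euclidean norm, Theiler exclusion
// |i-j| <= theiler, optional point subsampling for large N.
// Returns an m_max x length(rs) matrix; rs must be sorted ascending.
// [[Rcpp::export]]
NumericMatrix corr_sums_cpp(NumericVector x, int tau, int m_max,
                            NumericVector rs, int theiler, int max_points) {
  const int N = x.size();
  const int n_vec = N - (m_max - 1) * tau;
  if (n_vec < 2) stop("signal too short for the embedding schedule");
  int stride = 1;
  if (max_points > 1 && n_vec > max_points)
    stride = (n_vec + max_points - 1) / max_points;
  std::vector<int> idx;
  for (int i = 0; i < n_vec; i += stride) idx.push_back(i);
  const int np = (int)idx.size();
  const int nr = rs.size();

  // hist[m][k]: pairs whose distance at dimension m+1 first fits under rs[k]
  std::vector< std::vector<long long> > hist(m_max,
      std::vector<long long>(nr + 1, 0));
  std::vector<long long> n_pairs(m_max, 0);

  for (int a = 0; a < np; ++a) {
    for (int b = a + 1; b < np; ++b) {
      if (idx[b] - idx[a] <= theiler) continue;
      double sq = 0.0;
      for (int m = 0; m < m_max; ++m) {
        double e = x[idx[a] + m * tau] - x[idx[b] + m * tau];
        sq += e * e;
        double d = std::sqrt(sq);
        int k = (int)(std::lower_bound(rs.begin(), rs.end(), d) - rs.begin());
        ++hist[m][k];
        ++n_pairs[m];
      }
    }
  }
  NumericMatrix C(m_max, nr);
  for (int m = 0; m < m_max; ++m) {
    long long cum = 0;
    for (int k = 0; k < nr; ++k) {
      cum += hist[m][k];
      C(m, k) = n_pairs[m] > 0 ? (double)cum / (double)n_pairs[m] : NA_REAL;
    }
  }
  return C;
}

// Approximate entropy, standard convention: N-m+1 template vectors,
// Chebyshev distance, self-matches included, Phi^m - Phi^{m+1}.
// [[Rcpp::export]]
double apen_cpp(NumericVector x, int m, double r) {
  const int N = x.size();
  if (N < m + 2) stop("signal too short for approximate entropy");
  const int nm = N - m + 1;       // vectors of length m
  const int nm1 = N - m;          // vectors of length m + 1
  std::vector<long long> cm(nm, 1), cm1(nm1, 1);   // self matches

  for (int i = 0; i < nm; ++i) {
    for (int j = i + 1; j < nm; ++j) {
      double mx = 0.0;
      for (int k = 0; k < m; ++k) {
        double d = std::fabs(x[i + k] - x[j + k]);
        if (d > mx) mx = d;
      }
      if (mx <= r) {
        ++cm[i]; ++cm[j];
        if (i < nm1 && j < nm1) {
          double d = std::fabs(x[i + m] - x[j + m]);
          if (std::max(mx, d) <= r) { ++cm1[i]; ++cm1[j]; }
        }
      }
    }
  }
  double phi_m = 0.0, phi_m1 = 0.0;
  for (int i = 0; i < nm; ++i) phi_m += std::log((double)cm[i] / nm);
  phi_m /= nm;
  for (int i = 0; i < nm1; ++i) phi_m1 += std::log((double)cm1[i] / nm1);
  phi_m1 /= nm1;
  return phi_m - phi_m1;
}

// Rosenstein average log-divergence curve: for each embedded point, the
// nearest neighbor outside the Theiler window is tracked for `horizon`
// steps; returns mean ln d(k) for k = 0..horizon (NA where no pairs).
// [[Rcpp::export]]
NumericVector lyap_divergence_cpp(NumericVector x, int m, int tau,
                                  int theiler, int horizon) {
  const int N = x.size();
  const int n_vec = N - (m - 1) * tau;
  const int n_use = n_vec - horizon;
  if (n_use < 2) stop("signal too short for the divergence horizon");

  NumericVector acc(horizon + 1);
  IntegerVector cnt(horizon + 1);

  for (int i = 0; i < n_use; ++i) {
    int best = -1; double best_d = R_PosInf;
    for (int j = 0; j < n_use; ++j) {
      if (std::abs(i - j) <= theiler) continue;
      double sq = 0.0;
      for (int k = 0; k < m; ++k) {
        double e = x[i + k * tau] - x[j + k * tau];
        sq += e * e;
      }
      if (sq < best_d) { best_d = sq; best = j; }
    }
    if (best < 0 || best_d <= 0.0) continue;
    for (int h = 0; h <= horizon; ++h) {
      double sq = 0.0;
      for (int k = 0; k < m; ++k) {
        double e = x[i + h + k * tau] - x[best + h + k * tau];
        sq += e * e;
      }
      if (sq > 0.0) {
        acc[h] += 0.5 * std::log(sq);
        ++cnt[h];
      }
    }
  }
  for (int h = 0; h <= horizon; ++h)
    acc[h] = cnt[h] > 0 ? acc[h] / cnt[h] : NA_REAL;
  return acc;
}
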