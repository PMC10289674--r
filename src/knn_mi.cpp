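// k-nearest-neighbour machinery for continuous and mixed discrete-continuous
// mutual information estimation (Kraskov algorithm 1, max-norm joint space).
//
// Brute-force O(n^2) searches written as dimension-outer sweeps over the
// column-major data (SIMD-friendly contiguous access) with a small top-k
// insertion buffer: at the sample sizes this package targets (n <= a few
// thousand, d <= ~7) this beats tree structures and keeps one code path.
#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// fill dist[j] = max-norm distance from point i to every j (column-major m)
static inline void cheb_all(const double *__restrict m, int n, int d, int i,
                            double *__restrict dist) {
  if (d == 1) {
    const double xi = m[i];
    for (int j = 0; j < n; ++j) dist[j] = std::fabs(m[j] - xi);
    return;
  }
  if (d == 2) { // fused two-column pass (the motor-score case)
    const double *__restrict c1 = m, *__restrict c2 = m + n;
    const double xi = c1[i], yi = c2[i];
    for (int j = 0; j < n; ++j) {
      double a = std::fabs(c1[j] - xi), b = std::fabs(c2[j] - yi);
      dist[j] = a > b ? a : b;
    }
    return;
  }
  const double *col = m;
  {
    const double xi = col[i];
    for (int j = 0; j < n; ++j) dist[j] = std::fabs(col[j] - xi);
  }
  for (int c = 1; c < d; ++c) {
    col += n;
    const double xi = col[i];
    for (int j = 0; j < n; ++j) {
      double diff = std::fabs(col[j] - xi);
      if (diff > dist[j]) dist[j] = diff;
    }
  }
}

// maintain the k smallest values seen (tiny k: insertion into sorted buffer)
struct TopK {
  double *buf;
  int k, filled;
  explicit TopK(double *b, int kk) : buf(b), k(kk), filled(0) {}
  inline void push(double v) {
    if (filled < k) {
      int p = filled++;
      while (p > 0 && buf[p - 1] > v) { buf[p] = buf[p - 1]; --p; }
      buf[p] = v;
    } else if (v < buf[k - 1]) {
      int p = k - 1;
      while (p > 0 && buf[p - 1] > v) { buf[p] = buf[p - 1]; --p; }
      buf[p] = v;
    }
  }
  inline double kth() const { return buf[k - 1]; }
};

// KSG algorithm 1 estimate of I(X;Y) in nats.
// eps_i is the max-norm distance in the joint space to the k-th nearest
// neighbour; n_x, n_y count marginal points strictly within eps_i.
// I = psi(k) + psi(n) - <psi(nx+1) + psi(ny+1)>.
// [[Rcpp::export]]
double ksg_mi_nats_cpp(NumericMatrix X, NumericMatrix Y, int k) {
  const int n = X.nrow(), dx = X.ncol(), dy = Y.ncol();
  if (Y.nrow() != n) stop("X and Y must have the same number of rows");
  if (k < 1 || n <= k) stop("need n > k");
  const double *px = X.begin(), *py = Y.begin();
  std::vector<double> ddx(n), ddy(n), kbuf(k);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    cheb_all(px, n, dx, i, ddx.data());
    cheb_all(py, n, dy, i, ddy.data());
    ddx[i] = R_PosInf; // exclude self from the joint search
    TopK top(kbuf.data(), k);
    const double *__restrict ax = ddx.data(), *__restrict ay = ddy.data();
    for (int j = 0; j < n; ++j) {
      double v = ax[j] > ay[j] ? ax[j] : ay[j];
      top.push(v);
    }
    const double eps = top.kth();
    ddx[i] = 0.0; // self counts in both marginals (the +1 of the formula)
    int nx = 0, ny = 0;
    for (int j = 0; j < n; ++j) {
      nx += ax[j] < eps;
      ny += ay[j] < eps;
    }
    // the self point satisfies ddx[i] = 0 < eps, so nx = (strict count) + 1,
    // exactly the nx+1 of the digamma formula; same for ny
    acc += R::digamma((double)nx) + R::digamma((double)ny);
  }
  return R::digamma((double)k) + R::digamma((double)n) - acc / n;
}

// Mixed discrete-continuous MI (Ross 2014 construction) in nats.
// For each point, the k-th-neighbour max-norm distance is found among
// same-label points; m_i counts points of any label within that distance.
// I = psi(N) - <psi(N_label)> + psi(k) - <psi(m)>.
// [[Rcpp::export]]
double mixed_mi_nats_cpp(IntegerVector labels, NumericMatrix Y, int k) {
  const int n = Y.nrow(), d = Y.ncol();
  if (labels.size() != n) stop("labels length must match rows of Y");
  const double *py = Y.begin();
  const int *cls = labels.begin();
  std::vector<double> dist(n), kbuf(k);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    cheb_all(py, n, d, i, dist.data());
    TopK top(kbuf.data(), k);
    int nc = 0;
    const int ci = cls[i];
    for (int j = 0; j < n; ++j) {
      if (cls[j] != ci) continue;
      ++nc; // includes self
      if (j != i) top.push(dist[j]);
    }
    if (nc <= k) stop("a label class has fewer than k+1 members");
    const double dk = top.kth();
    int m = 0;
    for (int j = 0; j < n; ++j)
      m += dist[j] <= dk;
    --m; // remove self (dist 0)
    acc += R::digamma((double)nc) + R::digamma((double)m);
  }
  return R::digamma((double)n) + R::digamma((double)k) - acc / n;
}

// k-th-nearest-neighbour max-norm distances in the joint standard-scored
// space; used for the noise-sensitivity diagnostics.
// [[Rcpp::export]]
NumericVector knn_kth_dist_cpp(NumericMatrix Z, int k) {
  const int n = Z.nrow(), d = Z.ncol();
  if (k < 1 || n <= k) stop("need n > k");
  const double *pz = Z.begin();
  std::vector<double> dist(n), kbuf(k);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    cheb_all(pz, n, d, i, dist.data());
    TopK top(kbuf.data(), k);
    for (int j = 0; j < n; ++j)
      if (j != i) top.push(dist[j]);
    out[i] = top.kth();
  }
  return out;
}
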