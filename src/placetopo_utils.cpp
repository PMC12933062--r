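#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Kraskov-Stoegbauer-Grassberger mutual information, algorithm 1.
// Chebyshev metric in the joint space; marginal neighbour counts use the
// strict inequality |u_j - u_i| < eps_i. Returns nats.
// [[Rcpp::export]]
double ksg_mi_cpp(NumericVector x, NumericVector y, int k) {
  const int n = x.size();
  if (y.size() != n) stop("x and y must have equal length");
  if (k < 1 || k >= n) stop("k must be in [1, n-1]");

  std::vector<double> xs(x.begin(), x.end()), ys(y.begin(), y.end());
  std::sort(xs.begin(), xs.end());
  std::sort(ys.begin(), ys.end());

  double acc = 0.0;
  std::vector<double> knn(k);
  for (int i = 0; i < n; ++i) {
    // k smallest joint Chebyshev distances to other points
    int filled = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double d = std::max(std::fabs(x[j] - x[i]), std::fabs(y[j] - y[i]));
      if (filled < k) {
        knn[filled++] = d;
        if (filled == k) std::make_heap(knn.begin(), knn.end());
      } else if (d < knn.front()) {
        std::pop_heap(knn.begin(), knn.end());
        knn.back() = d;
        std::push_heap(knn.begin(), knn.end());
      }
    }
    double eps = knn.front();
    // strict counts within eps in each marginal (excluding self)
    long nx = (std::lower_bound(xs.begin(), xs.end(), x[i] + eps) -
               std::upper_bound(xs.begin(), xs.end(), x[i] - eps)) - 1;
    long ny = (std::lower_bound(ys.begin(), ys.end(), y[i] + eps) -
               std::upper_bound(ys.begin(), ys.end(), y[i] - eps)) - 1;
    if (nx < 0) nx = 0;
    if (ny < 0) ny = 0;
    acc += R::digamma((double)nx + 1.0) + R::digamma((double)ny + 1.0);
  }
  return R::digamma((double)k) + R::digamma((double)n) - acc / n;
}

// small fast PRNG (xorshift128+), seeded from R's RNG so every resampling
// routine stays reproducible under set.seed()
struct FastRng {
  uint64_t s0, s1;
  FastRng() {
    GetRNGstate();
    s0 = (uint64_t)(unif_rand() * 4294967296.0) << 32 |
         (uint64_t)(unif_rand() * 4294967296.0);
    s1 = (uint64_t)(unif_rand() * 4294967296.0) << 32 |
         (uint64_t)(unif_rand() * 4294967296.0);
    if (s0 == 0 && s1 == 0) s1 = 0x9E3779B97F4A7C15ULL;
    PutRNGstate();
  }
  inline uint64_t next() {
    uint64_t x = s0;
    const uint64_t y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  // unbiased-enough integer in [0, n) for resampling purposes
  inline int below(int n) { return (int)(next() % (uint64_t)n); }
};

static double median_inplace(std::vector<double> &v) {
  const size_t n = v.size();
  const size_t h = n / 2;
  std::nth_element(v.begin(), v.begin() + h, v.end());
  double m = v[h];
  if (n % 2 == 0) {
    double lo = *std::max_element(v.begin(), v.begin() + h);
    m = 0.5 * (m + lo);
  }
  return m;
}

// B bootstrap resample medians of x (resampling with replacement), using
// R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericVector boot_medians_cpp(NumericVector x, int B) {
  const int n = x.size();
  if (n < 1) stop("empty sample");
  NumericVector out(B);
  std::vector<double> buf(n);
  FastRng rng;
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < n; ++i) buf[i] = x[rng.below(n)];
    out[b] = median_inplace(buf);
  }
  return out;
}

// iter medians of size-m subsets of y drawn WITHOUT replacement within each
// draw (partial Fisher-Yates), using R's RNG.
// [[Rcpp::export]]
NumericVector subset_medians_cpp(NumericVector y, int m, int iter) {
  const int n = y.size();
  if (m < 1 || m > n) stop("subset size out of range");
  NumericVector out(iter);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::vector<double> buf(m);
  FastRng rng;
  for (int it = 0; it < iter; ++it) {
    for (int i = 0; i < m; ++i) {
      int j = i + rng.below(n - i);
      std::swap(idx[i], idx[j]);
      buf[i] = y[idx[i]];
    }
    out[it] = median_inplace(buf);
  }
  return out;
}
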