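// Regression random forest with histogram-accelerated variance-reduction
// splits. Candidate thresholds are midpoints between consecutive distinct
// feature values (exact CART) unless a feature has more than `max_bins`
// distinct values, in which case quantile thresholds are used. Per-tree
// training rows are drawn without replacement. A dedicated mt19937 makes
// training bit-reproducible for a given seed, independent of R's RNG.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <random>
#include <cstdint>

using namespace Rcpp;

namespace {

struct TreeBuf {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // x <= threshold goes left
  std::vector<int> left, right;
  std::vector<double> value;     // leaf prediction (node mean)
  int add_node() {
    feature.push_back(-1); threshold.push_back(0.0);
    left.push_back(-1); right.push_back(-1); value.push_back(0.0);
    return (int)feature.size() - 1;
  }
};

struct NodeTask { int node, lo, hi; };

} // namespace

// Bin features once: thresholds[j] sorted ascending; binned(i,j) = number
// of thresholds <= x(i,j), so "bin <= c" means "x <= thresholds[c]".
static void bin_features(const NumericMatrix& X, int max_bins,
                         std::vector<std::vector<double>>& thresholds,
                         std::vector<std::vector<uint16_t>>& binned) {
  const int n = X.nrow(), p = X.ncol();
  thresholds.assign(p, {});
  binned.assign(p, std::vector<uint16_t>(n));
  std::vector<double> col(n);
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) col[i] = X(i, j);
    std::vector<double> s(col);
    std::sort(s.begin(), s.end());
    s.erase(std::unique(s.begin(), s.end()), s.end());
    std::vector<double>& t = thresholds[j];
    if ((int)s.size() <= 1) {
      // constant feature: no thresholds
    } else if ((int)s.size() - 1 <= max_bins) {
      t.reserve(s.size() - 1);
      for (size_t k = 0; k + 1 < s.size(); ++k)
        t.push_back(0.5 * (s[k] + s[k + 1]));
    } else {
      t.reserve(max_bins);
      for (int k = 1; k <= max_bins; ++k) {
        size_t idx = (size_t)((double)k * (s.size() - 1) / (max_bins + 1));
        double thr = 0.5 * (s[idx] + s[idx + 1 < s.size() ? idx + 1 : idx]);
        if (t.empty() || thr > t.back()) t.push_back(thr);
      }
    }
    for (int i = 0; i < n; ++i) {
      binned[j][i] = (uint16_t)(std::upper_bound(t.begin(), t.end(), col[i]) -
                                t.begin());
    }
  }
}

static void grow_tree(TreeBuf& tree, std::vector<int>& idx, int n_use,
                      const NumericVector& y,
                      const std::vector<std::vector<double>>& thresholds,
                      const std::vector<std::vector<uint16_t>>& binned,
                      int mtry, int min_node, std::mt19937& rng,
                      std::vector<int>& feat_pool,
                      std::vector<double>& hsum, std::vector<int>& hcnt) {
  const int p = (int)binned.size();
  std::vector<NodeTask> stack;
  int root = tree.add_node();
  stack.push_back({root, 0, n_use});

  while (!stack.empty()) {
    NodeTask task = stack.back(); stack.pop_back();
    const int lo = task.lo, hi = task.hi, nn = hi - lo;
    double sum = 0.0, sumsq = 0.0;
    for (int i = lo; i < hi; ++i) { double v = y[idx[i]]; sum += v; sumsq += v * v; }
    const double mean = sum / nn;
    tree.value[task.node] = mean;
    const double node_var = sumsq / nn - mean * mean;
    if (nn <= min_node || node_var <= 1e-14) continue;

    // sample mtry candidate features without replacement
    int best_f = -1, best_c = -1;
    double best_score = sum * sum / nn; // maximize sumL^2/nL + sumR^2/nR
    for (int k = 0; k < mtry; ++k) {
      int r = k + (int)(rng() % (uint32_t)(p - k));
      std::swap(feat_pool[k], feat_pool[r]);
      const int f = feat_pool[k];
      const int nb = (int)thresholds[f].size();
      if (nb == 0) continue;
      const std::vector<uint16_t>& bf = binned[f];
      // histogram over the touched bin range only (hsum/hcnt enter and
      // leave this loop all-zero; re-zeroing touches node bins only)
      int bmin = nb, bmax = 0;
      for (int i = lo; i < hi; ++i) {
        const int b = bf[idx[i]];
        hsum[b] += y[idx[i]];
        ++hcnt[b];
        if (b < bmin) bmin = b;
        if (b > bmax) bmax = b;
      }
      if (bmin < bmax) {
        double sL = 0.0; int nL = 0;
        const int cmax = bmax - 1 < nb - 1 ? bmax - 1 : nb - 1;
        for (int c = bmin; c <= cmax; ++c) {   // left: bin <= c
          sL += hsum[c]; nL += hcnt[c];
          if (nL == 0) continue;
          const int nR = nn - nL;
          if (nR == 0) break;
          const double sR = sum - sL;
          const double score = sL * sL / nL + sR * sR / nR;
          if (score > best_score + 1e-12) {
            best_score = score; best_f = f; best_c = c;
          }
        }
      }
      for (int i = lo; i < hi; ++i) {
        const int b = bf[idx[i]];
        hsum[b] = 0.0;
        hcnt[b] = 0;
      }
    }
    if (best_f < 0) continue;

    const std::vector<uint16_t>& bf = binned[best_f];
    const int cut = best_c;
    std::vector<int>::iterator mid = std::partition(
      idx.begin() + lo, idx.begin() + hi,
      [&](int i) { return bf[i] <= cut; });
    const int m = (int)(mid - idx.begin());
    if (m == lo || m == hi) continue; // should not happen

    tree.feature[task.node] = best_f;
    tree.threshold[task.node] = thresholds[best_f][best_c];
    const int nl = tree.add_node();
    const int nr = tree.add_node();
    tree.left[task.node] = nl;
    tree.right[task.node] = nr;
    stack.push_back({nl, lo, m});
    stack.push_back({nr, m, hi});
  }
}

// [[Rcpp::export(name = ".rf_train_cpp")]]
List rf_train_cpp(NumericMatrix X, NumericVector y, int n_trees,
                  double sample_frac, int mtry, int min_node,
                  int max_bins, int seed) {
  const int n = X.nrow(), p = X.ncol();
  if (n < 2) stop("need at least 2 training samples");
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;

  std::vector<std::vector<double>> thresholds;
  std::vector<std::vector<uint16_t>> binned;
  bin_features(X, max_bins, thresholds, binned);

  int n_use = (int)std::ceil(sample_frac * n);
  if (n_use < 1) n_use = 1;
  if (n_use > n) n_use = n;

  std::mt19937 rng((uint32_t)seed);
  List trees(n_trees);
  std::vector<int> pool(n), idx, feat_pool(p);
  std::vector<double> hsum(max_bins + 2);
  std::vector<int> hcnt(max_bins + 2);
  for (int i = 0; i < n; ++i) pool[i] = i;

  for (int t = 0; t < n_trees; ++t) {
    // subsample without replacement (partial Fisher-Yates)
    for (int k = 0; k < n_use; ++k) {
      int r = k + (int)(rng() % (uint32_t)(n - k));
      std::swap(pool[k], pool[r]);
    }
    idx.assign(pool.begin(), pool.begin() + n_use);
    for (int j = 0; j < p; ++j) feat_pool[j] = j;

    TreeBuf tree;
    grow_tree(tree, idx, n_use, y, thresholds, binned, mtry, min_node, rng,
              feat_pool, hsum, hcnt);
    trees[t] = List::create(
      _["feature"] = IntegerVector(tree.feature.begin(), tree.feature.end()),
      _["threshold"] = NumericVector(tree.threshold.begin(), tree.threshold.end()),
      _["left"] = IntegerVector(tree.left.begin(), tree.left.end()),
      _["right"] = IntegerVector(tree.right.begin(), tree.right.end()),
      _["value"] = NumericVector(tree.value.begin(), tree.value.end()));
  }
  return List::create(_["trees"] = trees, _["p"] = p);
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(List model, NumericMatrix X) {
  List trees = model["trees"];
  const int n = X.nrow(), nt = trees.size();
  NumericVector out(n);
  for (int t = 0; t < nt; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    IntegerVector left = tr["left"], right = tr["right"];
    NumericVector value = tr["value"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0)
        node = X(i, feature[node]) <= threshold[node] ? left[node] : right[node];
      out[i] += value[node];
    }
  }
  for (int i = 0; i < n; ++i) out[i] /= nt;
  return out;
}
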