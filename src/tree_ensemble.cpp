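#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Randomized regression-tree ensemble for per-target-gene network inference.
// For each target gene j a forest is grown predicting j from all other genes;
// the importance of regulator i is its accumulated variance (SSE) reduction,
// averaged over trees and divided by the sample count, so that with the
// target standardized to unit variance the column sum approximates the
// explained-variance mass. Uses R's RNG: seeded from R via set.seed().

namespace {

struct Node {
  std::vector<int> idx;  // sample indices in this node
};

// best split of `idx` on feature values v (length n over all samples):
// maximises SSE reduction = SL^2/nL + SR^2/nR - S^2/n. Returns reduction
// (<= 0 if none) and fills threshold/left partition.
double best_split_on_feature(const std::vector<int>& idx,
                             const double* v, const double* y,
                             double sum_y, double& thr_out) {
  const int m = (int)idx.size();
  static thread_local std::vector<std::pair<double, double>> vals;
  vals.clear();
  vals.reserve(m);
  for (int k = 0; k < m; ++k) vals.push_back({v[idx[k]], y[idx[k]]});
  std::sort(vals.begin(), vals.end());
  if (vals.front().first == vals.back().first) return -1.0;  // constant
  double base = sum_y * sum_y / m;
  double sL = 0.0, best = -1.0;
  for (int k = 0; k < m - 1; ++k) {
    sL += vals[k].second;
    if (vals[k].first == vals[k + 1].first) continue;  // no split inside ties
    int nL = k + 1, nR = m - nL;
    double sR = sum_y - sL;
    double red = sL * sL / nL + sR * sR / nR - base;
    if (red > best) {
      best = red;
      thr_out = 0.5 * (vals[k].first + vals[k + 1].first);
    }
  }
  return best;
}

}  // namespace

// [[Rcpp::export(name = ".tree_ensemble_importance")]]
NumericMatrix tree_ensemble_importance(NumericMatrix X, int n_trees = 100,
                                       int k_candidates = 0,
                                       int min_node_size = 5,
                                       bool bootstrap = true) {
  const int n = X.nrow();  // samples
  const int p = X.ncol();  // genes
  if (p < 3) stop("need at least 3 genes");
  if (n < 10) stop("need at least 10 samples");

  // standardize each gene to zero mean / unit variance; constant genes -> 0
  NumericMatrix Z(n, p);
  std::vector<bool> constant(p, false);
  for (int j = 0; j < p; ++j) {
    double m = 0.0;
    for (int i = 0; i < n; ++i) m += X(i, j);
    m /= n;
    double ss = 0.0;
    for (int i = 0; i < n; ++i) ss += (X(i, j) - m) * (X(i, j) - m);
    double sd = std::sqrt(ss / (n - 1));
    if (sd <= 0.0) {
      constant[j] = true;
      for (int i = 0; i < n; ++i) Z(i, j) = 0.0;
    } else {
      for (int i = 0; i < n; ++i) Z(i, j) = (X(i, j) - m) / sd;
    }
  }

  NumericMatrix W(p, p);  // W(i, j): importance of regulator i for target j

  std::vector<int> regs(p - 1);
  std::vector<double> yv(n);

  for (int target = 0; target < p; ++target) {
    if (constant[target]) continue;
    int nr = 0;
    for (int j = 0; j < p; ++j)
      if (j != target) regs[nr++] = j;
    int K = k_candidates > 0 ? std::min(k_candidates, nr)
                             : std::max(1, (int)std::floor(std::sqrt((double)nr)));
    for (int i = 0; i < n; ++i) yv[i] = Z(i, target);

    std::vector<double> imp(p, 0.0);

    for (int t = 0; t < n_trees; ++t) {
      // bootstrap sample of the rows
      std::vector<int> root_idx(n);
      if (bootstrap) {
        for (int i = 0; i < n; ++i)
          root_idx[i] = (int)(unif_rand() * n) % n;
      } else {
        for (int i = 0; i < n; ++i) root_idx[i] = i;
      }
      std::vector<Node> stack;
      stack.push_back({std::move(root_idx)});
      while (!stack.empty()) {
        Node node = std::move(stack.back());
        stack.pop_back();
        const int m = (int)node.idx.size();
        if (m < 2 * min_node_size) continue;
        double sum_y = 0.0, sum_y2 = 0.0;
        for (int k = 0; k < m; ++k) {
          sum_y += yv[node.idx[k]];
          sum_y2 += yv[node.idx[k]] * yv[node.idx[k]];
        }
        if (sum_y2 - sum_y * sum_y / m < 1e-12) continue;  // pure node
        // draw K candidate regulators without replacement (partial shuffle)
        for (int k = 0; k < K; ++k) {
          int r = k + (int)(unif_rand() * (nr - k));
          if (r >= nr) r = nr - 1;
          std::swap(regs[k], regs[r]);
        }
        double best_red = 0.0, best_thr = 0.0;
        int best_f = -1;
        for (int k = 0; k < K; ++k) {
          int f = regs[k];
          double thr;
          double red = best_split_on_feature(node.idx, &Z(0, f), yv.data(),
                                             sum_y, thr);
          if (red > best_red) {
            best_red = red;
            best_thr = thr;
            best_f = f;
          }
        }
        if (best_f < 0) continue;
        imp[best_f] += best_red;
        Node left, right;
        for (int k = 0; k < m; ++k) {
          if (Z(node.idx[k], best_f) <= best_thr)
            left.idx.push_back(node.idx[k]);
          else
            right.idx.push_back(node.idx[k]);
        }
        stack.push_back(std::move(left));
        stack.push_back(std::move(right));
      }
    }
    for (int i = 0; i < p; ++i)
      if (i != target) W(i, target) = imp[i] / n_trees / n;
  }
  return W;
}
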