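#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Random forest of CART classification trees: bootstrap per tree, `mtry`
// features tried per split, gini impurity, grown to purity (depth-capped).
// Uses R's RNG so results are reproducible under set.seed().
//
// A tree is a flat table; row k holds: feature (0-based, -1 for leaf),
// threshold, left child, right child, leaf prediction (positive fraction).

namespace {

struct TreeBuilder {
  const NumericMatrix& X;
  const IntegerVector& y;
  int mtry, max_depth;
  std::vector<double> feat, thr, pred;
  std::vector<int> left, right;

  TreeBuilder(const NumericMatrix& X_, const IntegerVector& y_, int mtry_,
              int max_depth_)
      : X(X_), y(y_), mtry(mtry_), max_depth(max_depth_) {}

  int build(std::vector<int>& idx, int depth) {
    int node = (int)feat.size();
    feat.push_back(-1); thr.push_back(0.0);
    left.push_back(-1); right.push_back(-1); pred.push_back(0.0);

    int n = (int)idx.size(), npos = 0;
    for (int i : idx) npos += y[i];
    pred[node] = (double)npos / n;
    if (npos == 0 || npos == n || depth >= max_depth || n < 2) return node;

    // sample mtry candidate features without replacement (R RNG)
    int d = X.ncol();
    int m = std::min(mtry, d);
    std::vector<int> cols(d);
    for (int k = 0; k < d; ++k) cols[k] = k;
    for (int k = 0; k < m; ++k) {
      int j = k + (int)std::floor(unif_rand() * (d - k));
      if (j >= d) j = d - 1;
      std::swap(cols[k], cols[j]);
    }

    double base = (double)npos / n;
    double best_gain = 1e-12;
    int best_f = -1;
    double best_t = 0.0;
    double parent_gini = 2.0 * base * (1.0 - base);

    std::vector<std::pair<double, int>> vals(n);
    for (int c = 0; c < m; ++c) {
      int f = cols[c];
      for (int i = 0; i < n; ++i) vals[i] = {X(idx[i], f), y[idx[i]]};
      std::sort(vals.begin(), vals.end());
      int lpos = 0;
      for (int i = 0; i < n - 1; ++i) {
        lpos += vals[i].second;
        if (vals[i].first == vals[i + 1].first) continue;
        int ln = i + 1, rn = n - ln, rpos = npos - lpos;
        double pl = (double)lpos / ln, pr = (double)rpos / rn;
        double g = parent_gini -
                   ((double)ln / n) * 2.0 * pl * (1.0 - pl) -
                   ((double)rn / n) * 2.0 * pr * (1.0 - pr);
        if (g > best_gain) {
          best_gain = g;
          best_f = f;
          best_t = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (best_f < 0) return node;

    std::vector<int> li, ri;
    for (int i : idx) {
      if (X(i, best_f) <= best_t) li.push_back(i); else ri.push_back(i);
    }
    if (li.empty() || ri.empty()) return node;
    feat[node] = best_f;
    thr[node] = best_t;
    int l = build(li, depth + 1);
    int r = build(ri, depth + 1);
    left[node] = l;
    right[node] = r;
    return node;
  }
};

double predict_tree(const NumericMatrix& tree, const NumericMatrix& X, int row) {
  int node = 0;
  while (tree(node, 0) >= 0) {
    int f = (int)tree(node, 0);
    node = (X(row, f) <= tree(node, 1)) ? (int)tree(node, 2)
                                        : (int)tree(node, 3);
  }
  return tree(node, 4);
}

} // namespace

// [[Rcpp::export]]
List forest_train(const NumericMatrix X, const IntegerVector y, int n_trees,
                  int mtry, int max_depth = 30) {
  RNGScope scope;
  const int n = X.nrow();
  List trees(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      int j = (int)std::floor(unif_rand() * n);
      if (j >= n) j = n - 1;
      idx[i] = j;
    }
    TreeBuilder tb(X, y, mtry, max_depth);
    tb.build(idx, 0);
    int m = (int)tb.feat.size();
    NumericMatrix tab(m, 5);
    for (int k = 0; k < m; ++k) {
      tab(k, 0) = tb.feat[k];
      tab(k, 1) = tb.thr[k];
      tab(k, 2) = tb.left[k];
      tab(k, 3) = tb.right[k];
      tab(k, 4) = tb.pred[k];
    }
    trees[t] = tab;
  }
  return trees;
}

// Positive-vote fraction per row: each tree votes its leaf majority class.
// [[Rcpp::export]]
NumericVector forest_score(const List trees, const NumericMatrix X) {
  const int n = X.nrow(), T = trees.size();
  NumericVector out(n, 0.0);
  for (int t = 0; t < T; ++t) {
    NumericMatrix tree = trees[t];
    for (int i = 0; i < n; ++i) {
      double p = predict_tree(tree, X, i);
      if (p > 0.5) out[i] += 1.0;
    }
  }
  for (int i = 0; i < n; ++i) out[i] /= T;
  return out;
}
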