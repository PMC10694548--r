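// Gradient-boosted decision trees for binary classification.
//
// Second-order boosting with logistic loss: per round, each tree is grown
// level-wise to a depth limit using the exact greedy split search over
// presorted feature columns. Split gain and leaf weights follow the usual
// regularized Newton form
//   gain = GL^2/(HL+lambda) + GR^2/(HR+lambda) - G^2/(H+lambda),
//   w    = -G/(H+lambda),
// with G/H the sums of first/second derivatives of the loss. Training is
// fully deterministic: there is no row or column subsampling.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct TreeNodes {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold;
  std::vector<int> left, right;
  std::vector<double> value;     // leaf weight (already scaled by eta)
  int add_node() {
    feature.push_back(-1);
    threshold.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    value.push_back(0.0);
    return static_cast<int>(feature.size()) - 1;
  }
};

}  // namespace

// [[Rcpp::export]]
List gbm_train_cpp(NumericMatrix X, NumericVector y, int n_trees,
                   double learning_rate, int max_depth, double lambda,
                   double min_child_weight) {
  const int n = X.nrow(), p = X.ncol();
  if (n_trees < 1) stop("n_trees must be >= 1");
  if (max_depth < 1) stop("max_depth must be >= 1");

  // presort column orders once; X is constant across boosting rounds
  std::vector<std::vector<int>> order(p, std::vector<int>(n));
  for (int j = 0; j < p; ++j) {
    std::vector<int>& oj = order[j];
    for (int i = 0; i < n; ++i) oj[i] = i;
    const double* col = &X(0, j);
    std::stable_sort(oj.begin(), oj.end(),
                     [col](int a, int b) { return col[a] < col[b]; });
  }

  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  ybar = std::min(1.0 - 1e-6, std::max(1e-6, ybar));
  const double base = std::log(ybar / (1.0 - ybar));

  std::vector<double> F(n, base), g(n), h(n);
  List trees(n_trees);

  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) {
      const double prob = 1.0 / (1.0 + std::exp(-F[i]));
      g[i] = prob - y[i];
      h[i] = std::max(prob * (1.0 - prob), 1e-16);
    }

    TreeNodes tree;
    const int root = tree.add_node();
    std::vector<double> node_G(1, 0.0), node_H(1, 0.0);
    for (int i = 0; i < n; ++i) {
      node_G[root] += g[i];
      node_H[root] += h[i];
    }
    std::vector<int> node_of(n, root);
    std::vector<int> active(1, root);

    for (int depth = 0; depth < max_depth && !active.empty(); ++depth) {
      const int n_nodes = static_cast<int>(tree.feature.size());
      std::vector<int> slot(n_nodes, -1);
      const int m = static_cast<int>(active.size());
      for (int a = 0; a < m; ++a) slot[active[a]] = a;

      std::vector<double> best_gain(m, 1e-12), best_thr(m, 0.0);
      std::vector<double> best_gl(m, 0.0), best_hl(m, 0.0);
      std::vector<int> best_feat(m, -1);

      std::vector<double> gl(m), hl(m), last(m);
      std::vector<int> cnt(m);
      for (int j = 0; j < p; ++j) {
        std::fill(gl.begin(), gl.end(), 0.0);
        std::fill(hl.begin(), hl.end(), 0.0);
        std::fill(cnt.begin(), cnt.end(), 0);
        const std::vector<int>& oj = order[j];
        const double* col = &X(0, j);
        for (int k = 0; k < n; ++k) {
          const int row = oj[k];
          const int nd = node_of[row];
          const int a = slot[nd];
          if (a < 0) continue;
          const double x = col[row];
          if (cnt[a] > 0 && x > last[a]) {
            const double G = node_G[nd], H = node_H[nd];
            const double gr = G - gl[a], hr = H - hl[a];
            if (hl[a] >= min_child_weight && hr >= min_child_weight) {
              const double gain = gl[a] * gl[a] / (hl[a] + lambda) +
                                  gr * gr / (hr + lambda) -
                                  G * G / (H + lambda);
              if (gain > best_gain[a]) {
                best_gain[a] = gain;
                best_feat[a] = j;
                best_thr[a] = 0.5 * (last[a] + x);
                best_gl[a] = gl[a];
                best_hl[a] = hl[a];
              }
            }
          }
          gl[a] += g[row];
          hl[a] += h[row];
          last[a] = x;
          ++cnt[a];
        }
      }

      std::vector<int> next_active;
      for (int a = 0; a < m; ++a) {
        const int nd = active[a];
        if (best_feat[a] < 0) {
          tree.value[nd] = -learning_rate * node_G[nd] / (node_H[nd] + lambda);
          continue;
        }
        const int lc = tree.add_node();
        const int rc = tree.add_node();
        tree.feature[nd] = best_feat[a];
        tree.threshold[nd] = best_thr[a];
        tree.left[nd] = lc;
        tree.right[nd] = rc;
        node_G.push_back(best_gl[a]);
        node_H.push_back(best_hl[a]);
        node_G.push_back(node_G[nd] - best_gl[a]);
        node_H.push_back(node_H[nd] - best_hl[a]);
        next_active.push_back(lc);
        next_active.push_back(rc);
      }
      // reassign rows of split nodes to their children
      for (int i = 0; i < n; ++i) {
        const int nd = node_of[i];
        if (tree.feature[nd] >= 0) {
          node_of[i] = X(i, tree.feature[nd]) <= tree.threshold[nd]
                           ? tree.left[nd] : tree.right[nd];
        }
      }
      active.swap(next_active);
    }
    // nodes still active at the depth limit become leaves
    for (int nd : active) {
      tree.value[nd] = -learning_rate * node_G[nd] / (node_H[nd] + lambda);
    }

    for (int i = 0; i < n; ++i) F[i] += tree.value[node_of[i]];

    trees[t] = List::create(
        _["feature"] = IntegerVector(tree.feature.begin(), tree.feature.end()),
        _["threshold"] = NumericVector(tree.threshold.begin(), tree.threshold.end()),
        _["left"] = IntegerVector(tree.left.begin(), tree.left.end()),
        _["right"] = IntegerVector(tree.right.begin(), tree.right.end()),
        _["value"] = NumericVector(tree.value.begin(), tree.value.end()));
  }

  return List::create(_["trees"] = trees, _["base_score"] = base,
                      _["n_features"] = p);
}

// [[Rcpp::export]]
NumericVector gbm_predict_cpp(List model, NumericMatrix X) {
  const int n = X.nrow();
  const int p = as<int>(model["n_features"]);
  if (X.ncol() != p) stop("feature count mismatch: model expects %d, got %d",
                          p, X.ncol());
  List trees = model["trees"];
  NumericVector out(n, as<double>(model["base_score"]));
  for (int t = 0; t < trees.size(); ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    IntegerVector left = tr["left"], right = tr["right"];
    NumericVector value = tr["value"];
    for (int i = 0; i < n; ++i) {
      int nd = 0;
      while (feature[nd] >= 0) {
        nd = X(i, feature[nd]) <= threshold[nd] ? left[nd] : right[nd];
      }
      out[i] += value[nd];
    }
  }
  for (int i = 0; i < n; ++i) out[i] = 1.0 / (1.0 + std::exp(-out[i]));
  return out;
}
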