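#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
#include <random>
using namespace Rcpp;

// Minimal CART + bagging ensemble for binary classification (Gini impurity).
// Self-contained so results are reproducible bit-for-bit from the seed:
// only raw mersenne-twister draws are used, never stdlib distributions.

namespace {

struct Node {
  int feature;      // -1 for leaf
  double threshold; // x <= threshold goes left
  int left, right;  // child indices, -1 for leaf
  int pred;         // majority class at node (0/1)
};

struct Rng {
  std::mt19937 gen;
  explicit Rng(uint32_t seed) : gen(seed) {}
  // bounded draw; modulo bias is irrelevant at these n
  int below(int n) { return static_cast<int>(gen() % static_cast<uint32_t>(n)); }
};

struct GrowCtx {
  const NumericMatrix& X;
  const IntegerVector& y;
  int mtry, min_split, max_depth;
  Rng& rng;
  std::vector<Node> nodes;
  GrowCtx(const NumericMatrix& X_, const IntegerVector& y_, int mtry_,
          int min_split_, int max_depth_, Rng& rng_)
      : X(X_), y(y_), mtry(mtry_), min_split(min_split_), max_depth(max_depth_),
        rng(rng_) {}
};

int majority(const GrowCtx& c, const std::vector<int>& idx) {
  int n1 = 0;
  for (int i : idx) n1 += c.y[i];
  int n0 = static_cast<int>(idx.size()) - n1;
  return n1 > n0 ? 1 : 0; // tie -> class 0
}

int grow(GrowCtx& c, std::vector<int>& idx, int depth) {
  const int n = static_cast<int>(idx.size());
  int n1 = 0;
  for (int i : idx) n1 += c.y[i];
  const int n0 = n - n1;

  Node node;
  node.feature = -1; node.threshold = 0.0; node.left = node.right = -1;
  node.pred = n1 > n0 ? 1 : 0;

  const bool stop = (n < c.min_split) || (n0 == 0) || (n1 == 0) ||
                    (c.max_depth >= 0 && depth >= c.max_depth);
  if (!stop) {
    const int p = c.X.ncol();
    // sample mtry distinct features (partial Fisher-Yates)
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    const int m = std::min(c.mtry, p);
    for (int j = 0; j < m; ++j) std::swap(feats[j], feats[j + c.rng.below(p - j)]);

    const double parent = 1.0 - (double(n0) * n0 + double(n1) * n1) / (double(n) * n);
    double best_gain = 1e-12;
    int best_f = -1;
    double best_thr = 0.0;

    std::vector<std::pair<double, int>> vals(n);
    for (int j = 0; j < m; ++j) {
      const int f = feats[j];
      for (int i = 0; i < n; ++i) vals[i] = {c.X(idx[i], f), c.y[idx[i]]};
      std::sort(vals.begin(), vals.end());
      int l1 = 0;
      for (int i = 0; i < n - 1; ++i) {
        l1 += vals[i].second;
        if (vals[i + 1].first <= vals[i].first) continue; // no split between ties
        const int nl = i + 1, nr = n - nl;
        const int l0 = nl - l1, r1 = n1 - l1, r0 = nr - r1;
        const double gl = 1.0 - (double(l0) * l0 + double(l1) * l1) / (double(nl) * nl);
        const double gr = 1.0 - (double(r0) * r0 + double(r1) * r1) / (double(nr) * nr);
        const double gain = parent - (nl * gl + nr * gr) / n;
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }

    if (best_f >= 0) {
      std::vector<int> li, ri;
      li.reserve(n); ri.reserve(n);
      for (int i : idx)
        (c.X(i, best_f) <= best_thr ? li : ri).push_back(i);
      node.feature = best_f;
      node.threshold = best_thr;
      const int self = static_cast<int>(c.nodes.size());
      c.nodes.push_back(node);
      c.nodes[self].left = grow(c, li, depth + 1);
      c.nodes[self].right = grow(c, ri, depth + 1);
      return self;
    }
  }
  c.nodes.push_back(node);
  return static_cast<int>(c.nodes.size()) - 1;
}

} // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int n_trees, int mtry,
                int min_split, int max_depth, int seed) {
  const int n = X.nrow();
  Rng rng(static_cast<uint32_t>(seed));
  List trees(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = rng.below(n); // bootstrap
    GrowCtx ctx(X, y, mtry, min_split, max_depth, rng);
    ctx.nodes.reserve(64);
    grow(ctx, idx, 0);
    const int nn = static_cast<int>(ctx.nodes.size());
    IntegerVector feature(nn), left(nn), right(nn), pred(nn);
    NumericVector threshold(nn);
    for (int k = 0; k < nn; ++k) {
      feature[k] = ctx.nodes[k].feature;
      threshold[k] = ctx.nodes[k].threshold;
      left[k] = ctx.nodes[k].left;
      right[k] = ctx.nodes[k].right;
      pred[k] = ctx.nodes[k].pred;
    }
    trees[t] = List::create(_["feature"] = feature, _["threshold"] = threshold,
                            _["left"] = left, _["right"] = right, _["pred"] = pred);
  }
  return trees;
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), nt = trees.size();
  NumericVector votes(n); // fraction of trees voting class 1
  for (int t = 0; t < nt; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"], left = tr["left"], right = tr["right"],
                  pred = tr["pred"];
    NumericVector threshold = tr["threshold"];
    for (int i = 0; i < n; ++i) {
      int k = 0;
      while (feature[k] >= 0)
        k = (X(i, feature[k]) <= threshold[k]) ? left[k] : right[k];
      votes[i] += pred[k];
    }
  }
  return votes / double(nt);
}
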