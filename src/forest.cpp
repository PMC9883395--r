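// Random forest for two-class score matrices: CART trees grown to purity on
// bootstrap samples, Gini split criterion, `mtry` candidate features per
// split. Uses R's RNG (unif_rand) so `set.seed()` in R makes training
// deterministic.

#include <Rcpp.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // split: x <= thr goes left
  std::vector<int> left, right;
  std::vector<int> pred;         // leaf class (0/1), -1 for internal
};

int new_node(Tree& t) {
  t.feature.push_back(-1);
  t.threshold.push_back(0.0);
  t.left.push_back(-1);
  t.right.push_back(-1);
  t.pred.push_back(-1);
  return (int)t.feature.size() - 1;
}

int rand_int(int n) {  // uniform on 0..n-1 via R RNG
  int v = (int)(unif_rand() * n);
  return v >= n ? n - 1 : v;
}

void grow(Tree& t, int node, std::vector<int>& idx, int lo, int hi,
          const NumericMatrix& X, const IntegerVector& y, int mtry,
          int min_node, std::vector<int>& feat_pool) {
  const int n = hi - lo;
  int n1 = 0;
  for (int i = lo; i < hi; ++i) n1 += y[idx[i]];
  const int n0 = n - n1;

  if (n0 == 0 || n1 == 0 || n < std::max(2, min_node)) {
    t.pred[node] = (n1 > n0) ? 1 : 0;
    return;
  }

  const int p = X.ncol();
  // partial Fisher-Yates for mtry distinct candidate features
  for (int i = 0; i < p; ++i) feat_pool[i] = i;
  int best_f = -1;
  double best_thr = 0.0, best_gain = 0.0;
  const double parent = 2.0 * n0 * n1 / (double)n; // n * gini(parent)

  std::vector<std::pair<double, int> > vals;
  vals.reserve(n);
  for (int m = 0; m < mtry; ++m) {
    const int r = m + rand_int(p - m);
    std::swap(feat_pool[m], feat_pool[r]);
    const int f = feat_pool[m];
    vals.clear();
    for (int i = lo; i < hi; ++i) {
      vals.push_back(std::make_pair(X(idx[i], f), idx[i]));
    }
    std::sort(vals.begin(), vals.end());
    int l1 = 0;
    for (int i = 0; i < n - 1; ++i) {
      l1 += y[vals[i].second];
      if (vals[i + 1].first <= vals[i].first) continue; // not a boundary
      const int nl = i + 1, nr = n - nl;
      const int l0 = nl - l1, r1 = n1 - l1, r0 = nr - r1;
      const double child = 2.0 * l0 * l1 / (double)nl +
                           2.0 * r0 * r1 / (double)nr;
      const double gain = parent - child;
      if (gain > best_gain + 1e-12) {
        best_gain = gain;
        best_f = f;
        best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
      }
    }
  }

  if (best_f < 0) { // no informative split among candidates
    t.pred[node] = (n1 > n0) ? 1 : 0;
    return;
  }

  int mid = lo;
  for (int i = lo; i < hi; ++i) {
    if (X(idx[i], best_f) <= best_thr) std::swap(idx[i], idx[mid++]);
  }
  if (mid == lo || mid == hi) { // numeric ties defeated the partition
    t.pred[node] = (n1 > n0) ? 1 : 0;
    return;
  }

  t.feature[node] = best_f;
  t.threshold[node] = best_thr;
  const int ln = new_node(t), rn = new_node(t);
  t.left[node] = ln;
  t.right[node] = rn;
  grow(t, ln, idx, lo, mid, X, y, mtry, min_node, feat_pool);
  grow(t, rn, idx, mid, hi, X, y, mtry, min_node, feat_pool);
}

} // namespace

// [[Rcpp::export]]
List rf_fit_cpp(const NumericMatrix& X, const IntegerVector& y,
                int n_trees, int mtry, int min_node) {
  const int n = X.nrow();
  List forest(n_trees);
  std::vector<int> idx(n), feat_pool(X.ncol());
  GetRNGstate();
  for (int b = 0; b < n_trees; ++b) {
    for (int i = 0; i < n; ++i) idx[i] = rand_int(n); // bootstrap
    Tree t;
    const int root = new_node(t);
    grow(t, root, idx, 0, n, X, y, mtry, min_node, feat_pool);
    forest[b] = List::create(
      _["feature"] = wrap(t.feature), _["threshold"] = wrap(t.threshold),
      _["left"] = wrap(t.left), _["right"] = wrap(t.right),
      _["pred"] = wrap(t.pred));
  }
  PutRNGstate();
  return forest;
}

// [[Rcpp::export]]
NumericVector rf_vote_cpp(const List& forest, const NumericMatrix& X) {
  const int n = X.nrow(), n_trees = forest.size();
  NumericVector votes(n); // fraction of trees voting class 1
  for (int b = 0; b < n_trees; ++b) {
    List t = forest[b];
    IntegerVector feature = t["feature"];
    NumericVector threshold = t["threshold"];
    IntegerVector left = t["left"], right = t["right"], pred = t["pred"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0) {
        node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                        : right[node];
      }
      votes[i] += pred[node];
    }
  }
  return votes / (double)n_trees;
}
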