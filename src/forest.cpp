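#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Minimal CART random forest for classification (gini impurity, bootstrap
// resampling, mtry features per split, majority vote). Uses R's RNG so
// set.seed() on the R side makes training reproducible.

struct TreeBuf {
  std::vector<int> feature;   // -1 for leaf
  std::vector<double> thr;    // go left if x <= thr
  std::vector<int> left, right, pred;
};

static int majority(const std::vector<int>& idx, const IntegerVector& y, int K) {
  std::vector<int> cnt(K, 0);
  for (size_t i = 0; i < idx.size(); ++i) ++cnt[y[idx[i]]];
  int best = 0;
  for (int k = 1; k < K; ++k) if (cnt[k] > cnt[best]) best = k;
  return best;
}

static bool pure(const std::vector<int>& idx, const IntegerVector& y) {
  for (size_t i = 1; i < idx.size(); ++i)
    if (y[idx[i]] != y[idx[0]]) return false;
  return true;
}

static double gini(const std::vector<int>& cnt, int n) {
  if (n == 0) return 0.0;
  double g = 1.0;
  for (size_t k = 0; k < cnt.size(); ++k) {
    double p = (double)cnt[k] / n;
    g -= p * p;
  }
  return g;
}

static int grow_node(TreeBuf& t, const NumericMatrix& X, const IntegerVector& y,
                     int K, int mtry, int min_node, std::vector<int>& idx) {
  int me = (int)t.feature.size();
  t.feature.push_back(-1);
  t.thr.push_back(0.0);
  t.left.push_back(-1);
  t.right.push_back(-1);
  t.pred.push_back(majority(idx, y, K));
  int n = (int)idx.size();
  if (n < min_node || pure(idx, y)) return me;

  int p = X.ncol();
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  // partial Fisher-Yates for mtry features
  int m = std::min(mtry, p);
  for (int j = 0; j < m; ++j) {
    int pick = j + (int)(unif_rand() * (p - j));
    if (pick >= p) pick = p - 1;
    std::swap(feats[j], feats[pick]);
  }

  double best_score = R_PosInf, best_thr = 0.0;
  int best_f = -1;
  std::vector<std::pair<double,int> > vals(n);
  std::vector<int> cl(K), cr(K);
  for (int j = 0; j < m; ++j) {
    int f = feats[j];
    for (int i = 0; i < n; ++i)
      vals[i] = std::make_pair(X(idx[i], f), y[idx[i]]);
    std::sort(vals.begin(), vals.end());
    if (vals[0].first == vals[n - 1].first) continue;
    std::fill(cl.begin(), cl.end(), 0);
    std::fill(cr.begin(), cr.end(), 0);
    for (int i = 0; i < n; ++i) ++cr[vals[i].second];
    for (int i = 0; i < n - 1; ++i) {
      ++cl[vals[i].second];
      --cr[vals[i].second];
      if (vals[i + 1].first == vals[i].first) continue;
      int nl = i + 1, nrt = n - nl;
      double score = nl * gini(cl, nl) + nrt * gini(cr, nrt);
      if (score < best_score) {
        best_score = score;
        best_f = f;
        best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
      }
    }
  }
  if (best_f < 0) return me;

  std::vector<int> li, ri;
  for (int i = 0; i < n; ++i) {
    if (X(idx[i], best_f) <= best_thr) li.push_back(idx[i]);
    else ri.push_back(idx[i]);
  }
  if (li.empty() || ri.empty()) return me;
  t.feature[me] = best_f;
  t.thr[me] = best_thr;
  int l = grow_node(t, X, y, K, mtry, min_node, li);
  t.left[me] = l;
  int r = grow_node(t, X, y, K, mtry, min_node, ri);
  t.right[me] = r;
  return me;
}

// [[Rcpp::export]]
List cpp_grow_forest(const NumericMatrix& X, const IntegerVector& y, int K,
                     int ntree, int mtry, int min_node = 2) {
  RNGScope scope;
  int n = X.nrow();
  List forest(ntree);
  for (int b = 0; b < ntree; ++b) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      int pick = (int)(unif_rand() * n);
      if (pick >= n) pick = n - 1;
      idx[i] = pick;
    }
    TreeBuf t;
    grow_node(t, X, y, K, mtry, min_node, idx);
    forest[b] = List::create(_["feature"] = wrap(t.feature),
                             _["thr"] = wrap(t.thr),
                             _["left"] = wrap(t.left),
                             _["right"] = wrap(t.right),
                             _["pred"] = wrap(t.pred));
  }
  return forest;
}

static int tree_pred(const List& tree, const NumericMatrix& X, int i) {
  IntegerVector feature = tree["feature"];
  NumericVector thr = tree["thr"];
  IntegerVector left = tree["left"], right = tree["right"], pred = tree["pred"];
  int node = 0;
  while (feature[node] >= 0) {
    node = (X(i, feature[node]) <= thr[node]) ? left[node] : right[node];
  }
  return pred[node];
}

// Vote counts per class using the first ntree_use trees (so one grown forest
// can be evaluated at several sizes during cross-validation).
// [[Rcpp::export]]
IntegerMatrix cpp_forest_votes(const List& forest, const NumericMatrix& X,
                               int K, int ntree_use) {
  int n = X.nrow();
  int nt = std::min((int)forest.size(), ntree_use);
  IntegerMatrix votes(n, K);
  for (int b = 0; b < nt; ++b) {
    List tree = forest[b];
    for (int i = 0; i < n; ++i) ++votes(i, tree_pred(tree, X, i));
  }
  return votes;
}
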