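// Compact random-forest classifier: Gini CART trees on bootstrap samples
// with per-node feature subsampling, out-of-bag error, class-vote
// probabilities and mean-decrease-in-impurity importances. Written for the
// threshold-uncertainty analysis: tens of columns, 1e3-1e5 rows.
#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
using namespace Rcpp;

struct Node {
  int feature = -1;      // -1 marks a leaf
  double threshold = 0;  // goes left if x <= threshold
  int left = -1, right = -1;
  int label = -1;        // leaf majority class
};

struct TreeBuilder {
  const NumericMatrix& X;
  const IntegerVector& y;
  int K, mtry, min_node, max_depth;
  std::mt19937_64& rng;
  std::vector<Node> nodes;
  std::vector<double>& importance;  // accumulated Gini decrease

  TreeBuilder(const NumericMatrix& X_, const IntegerVector& y_, int K_,
              int mtry_, int min_node_, int max_depth_,
              std::mt19937_64& rng_, std::vector<double>& imp_)
      : X(X_), y(y_), K(K_), mtry(mtry_), min_node(min_node_),
        max_depth(max_depth_), rng(rng_), importance(imp_) {}

  static double gini(const std::vector<int>& cnt, int n) {
    if (n == 0) return 0.0;
    double g = 1.0;
    for (int c : cnt) { double p = double(c) / n; g -= p * p; }
    return g;
  }

  int majority(const std::vector<int>& idx) {
    std::vector<int> cnt(K, 0);
    for (int i : idx) cnt[y[i]]++;
    int best = 0;
    for (int c = 1; c < K; ++c) if (cnt[c] > cnt[best]) best = c;
    return best;
  }

  int build(std::vector<int>& idx, int depth) {
    int me = (int)nodes.size();
    nodes.emplace_back();
    int n = (int)idx.size();
    std::vector<int> cnt(K, 0);
    for (int i : idx) cnt[y[i]]++;
    int nonzero = 0;
    for (int c : cnt) if (c > 0) nonzero++;
    double g_parent = gini(cnt, n);
    if (nonzero <= 1 || n < 2 * min_node ||
        (max_depth > 0 && depth >= max_depth)) {
      nodes[me].label = majority(idx);
      return me;
    }
    int p = X.ncol();
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    std::shuffle(feats.begin(), feats.end(), rng);
    int ntry = std::min(mtry, p);

    double best_gain = 1e-12;
    int best_f = -1;
    double best_thr = 0;
    std::vector<int> order(idx);
    for (int t = 0; t < ntry; ++t) {
      int f = feats[t];
      std::sort(order.begin(), order.end(), [&](int a, int b) {
        return X(a, f) < X(b, f);
      });
      std::vector<int> lcnt(K, 0);
      std::vector<int> rcnt(cnt);
      for (int i = 0; i + 1 < n; ++i) {
        int row = order[i];
        lcnt[y[row]]++; rcnt[y[row]]--;
        double xv = X(row, f), xn = X(order[i + 1], f);
        if (xv == xn) continue;
        int nl = i + 1, nr = n - nl;
        if (nl < min_node || nr < min_node) continue;
        double gl = gini(lcnt, nl), gr = gini(rcnt, nr);
        double gain = g_parent - (nl * gl + nr * gr) / n;
        if (gain > best_gain) {
          best_gain = gain; best_f = f;
          best_thr = xv + (xn - xv) / 2.0;
        }
      }
    }
    if (best_f < 0) {
      nodes[me].label = majority(idx);
      return me;
    }
    importance[best_f] += best_gain * n;
    std::vector<int> lidx, ridx;
    lidx.reserve(n); ridx.reserve(n);
    for (int i : idx) {
      if (X(i, best_f) <= best_thr) lidx.push_back(i);
      else ridx.push_back(i);
    }
    nodes[me].feature = best_f;
    nodes[me].threshold = best_thr;
    int l = build(lidx, depth + 1);
    int r = build(ridx, depth + 1);
    nodes[me].left = l; nodes[me].right = r;
    return me;
  }

  int predict_row(const NumericMatrix& M, int row) const {
    int cur = 0;
    while (nodes[cur].feature >= 0)
      cur = (M(row, nodes[cur].feature) <= nodes[cur].threshold)
                ? nodes[cur].left : nodes[cur].right;
    return nodes[cur].label;
  }
};

// [[Rcpp::export(name = ".rf_fit_predict")]]
List rf_fit_predict(NumericMatrix X, IntegerVector y, int n_classes,
                    NumericMatrix Xpred, int n_trees, int mtry,
                    int min_node, int max_depth, double seed) {
  int n = X.nrow(), p = X.ncol(), m = Xpred.nrow();
  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_int_distribution<int> pick(0, n - 1);

  std::vector<double> importance(p, 0.0);
  std::vector<std::vector<int>> oob_votes(n, std::vector<int>(n_classes, 0));
  NumericMatrix votes(m, n_classes);

  for (int t = 0; t < n_trees; ++t) {
    std::vector<char> inbag(n, 0);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) { idx[i] = pick(rng); inbag[idx[i]] = 1; }
    TreeBuilder tb(X, y, n_classes, mtry, min_node, max_depth, rng,
                   importance);
    tb.nodes.reserve(2 * n / std::max(1, min_node));
    tb.build(idx, 0);
    for (int i = 0; i < n; ++i)
      if (!inbag[i]) oob_votes[i][tb.predict_row(X, i)]++;
    for (int i = 0; i < m; ++i) votes(i, tb.predict_row(Xpred, i))++;
  }

  int oob_n = 0, oob_wrong = 0;
  IntegerVector oob_pred(n, NA_INTEGER);
  for (int i = 0; i < n; ++i) {
    int tot = 0, best = 0;
    for (int c = 0; c < n_classes; ++c) {
      tot += oob_votes[i][c];
      if (oob_votes[i][c] > oob_votes[i][best]) best = c;
    }
    if (tot > 0) {
      oob_pred[i] = best;
      oob_n++;
      if (best != y[i]) oob_wrong++;
    }
  }
  NumericMatrix prob(m, n_classes);
  for (int i = 0; i < m; ++i)
    for (int c = 0; c < n_classes; ++c) prob(i, c) = votes(i, c) / n_trees;
  NumericVector imp(p);
  for (int j = 0; j < p; ++j) imp[j] = importance[j] / n_trees;
  double oob_error = oob_n > 0 ? double(oob_wrong) / oob_n : NA_REAL;
  return List::create(_["oob_error"] = oob_error, _["importance"] = imp,
                      _["prob"] = prob, _["oob_pred"] = oob_pred);
}
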