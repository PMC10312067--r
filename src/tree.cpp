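#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Axis-aligned regression tree grown by greedy SSE minimisation.
// Split convention: x <= threshold goes LEFT, x > threshold goes RIGHT,
// with the threshold at the midpoint of adjacent distinct observed values.
// This matches the half-open interval convention (lower, upper] used by the
// rule machinery: the left child is (lower, threshold], the right child is
// (threshold, upper).

struct Node {
  int feature;      // -1 for leaf
  double threshold;
  int left, right;  // child indices, -1 for leaf
  double pred;      // mean response in node
  int n;
  int depth;
};

struct SplitResult {
  bool found;
  int feature;
  double threshold;
  double sse;       // total child SSE
};

static SplitResult best_split(const NumericMatrix& X, const NumericVector& y,
                              const std::vector<int>& idx, int min_leaf) {
  SplitResult best;
  best.found = false;
  best.sse = R_PosInf;
  const int n = (int)idx.size();
  const int p = X.ncol();
  if (n < 2 * min_leaf) return best;

  std::vector<int> ord(n);
  std::vector<double> xs(n), ys(n);

  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) ord[i] = idx[i];
    // stable sort on feature j so ties keep row order => determinism
    std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
      return X(a, j) < X(b, j);
    });
    for (int i = 0; i < n; ++i) {
      xs[i] = X(ord[i], j);
      ys[i] = y[ord[i]];
    }
    double total = 0.0, total2 = 0.0;
    for (int i = 0; i < n; ++i) { total += ys[i]; total2 += ys[i] * ys[i]; }
    double lsum = 0.0, lsum2 = 0.0;
    for (int k = 0; k < n - 1; ++k) {
      lsum += ys[k];
      lsum2 += ys[k] * ys[k];
      if (xs[k + 1] <= xs[k]) continue;          // no boundary between ties
      const int nl = k + 1, nr = n - nl;
      if (nl < min_leaf || nr < min_leaf) continue;
      const double rsum = total - lsum, rsum2 = total2 - lsum2;
      const double sse = (lsum2 - lsum * lsum / nl) + (rsum2 - rsum * rsum / nr);
      // strict < : first feature / lowest threshold wins ties
      if (sse < best.sse - 1e-12) {
        best.found = true;
        best.feature = j;
        best.threshold = 0.5 * (xs[k] + xs[k + 1]);
        best.sse = sse;
      }
    }
  }
  return best;
}

// [[Rcpp::export]]
List cpp_tree_fit(NumericMatrix X, NumericVector y, int max_depth, int min_leaf) {
  const int n = X.nrow();
  if (min_leaf < 1) min_leaf = 1;
  std::vector<Node> nodes;
  std::vector<std::vector<int> > members;

  std::vector<int> root(n);
  for (int i = 0; i < n; ++i) root[i] = i;

  nodes.push_back(Node());
  members.push_back(root);
  nodes[0].depth = 0;

  for (size_t k = 0; k < nodes.size(); ++k) {
    const std::vector<int>& idx = members[k];
    double s = 0.0;
    for (size_t i = 0; i < idx.size(); ++i) s += y[idx[i]];
    nodes[k].n = (int)idx.size();
    nodes[k].pred = idx.empty() ? 0.0 : s / idx.size();
    nodes[k].feature = -1;
    nodes[k].left = nodes[k].right = -1;

    if (nodes[k].depth >= max_depth) continue;
    SplitResult sp = best_split(X, y, idx, min_leaf);
    if (!sp.found) continue;
    // require a real SSE reduction over the parent
    double s2 = 0.0;
    for (size_t i = 0; i < idx.size(); ++i) s2 += y[idx[i]] * y[idx[i]];
    const double parent_sse = s2 - s * s / idx.size();
    if (!(sp.sse < parent_sse - 1e-10)) continue;

    std::vector<int> li, ri;
    li.reserve(idx.size());
    ri.reserve(idx.size());
    for (size_t i = 0; i < idx.size(); ++i) {
      if (X(idx[i], sp.feature) <= sp.threshold) li.push_back(idx[i]);
      else ri.push_back(idx[i]);
    }
    nodes[k].feature = sp.feature;
    nodes[k].threshold = sp.threshold;
    nodes[k].left = (int)nodes.size();
    nodes.push_back(Node());
    nodes.back().depth = nodes[k].depth + 1;
    members.push_back(li);
    nodes[k].right = (int)nodes.size();
    nodes.push_back(Node());
    nodes.back().depth = nodes[k].depth + 1;
    members.push_back(ri);
  }

  const int m = (int)nodes.size();
  IntegerVector feature(m), left(m), right(m), nn(m), depth(m);
  NumericVector threshold(m), pred(m);
  for (int k = 0; k < m; ++k) {
    feature[k] = nodes[k].feature;
    threshold[k] = nodes[k].threshold;
    left[k] = nodes[k].left;
    right[k] = nodes[k].right;
    pred[k] = nodes[k].pred;
    nn[k] = nodes[k].n;
    depth[k] = nodes[k].depth;
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["left"] = left, _["right"] = right, _["pred"] = pred,
                      _["n"] = nn, _["depth"] = depth);
}

static int leaf_of(const IntegerVector& feature, const NumericVector& threshold,
                   const IntegerVector& left, const IntegerVector& right,
                   const NumericMatrix& X, int i) {
  int k = 0;
  while (feature[k] >= 0) {
    k = (X(i, feature[k]) <= threshold[k]) ? left[k] : right[k];
  }
  return k;
}

// [[Rcpp::export]]
NumericVector cpp_tree_predict(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"], right = tree["right"];
  NumericVector threshold = tree["threshold"], pred = tree["pred"];
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = pred[leaf_of(feature, threshold, left, right, X, i)];
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_tree_leaf(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"], right = tree["right"];
  NumericVector threshold = tree["threshold"];
  const int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = leaf_of(feature, threshold, left, right, X, i) + 1;  // 1-based
  return out;
}

// Bagged trees: boot is an n_boot x B matrix of 1-based row indices drawn in R
// (keeps all randomness under R's RNG / the caller's seed).
// [[Rcpp::export]]
List cpp_bag_fit(NumericMatrix X, NumericVector y, IntegerMatrix boot,
                 int max_depth, int min_leaf) {
  const int B = boot.ncol(), nb = boot.nrow(), p = X.ncol();
  List trees(B);
  NumericMatrix Xb(nb, p);
  NumericVector yb(nb);
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < nb; ++i) {
      const int r = boot(i, b) - 1;
      for (int j = 0; j < p; ++j) Xb(i, j) = X(r, j);
      yb[i] = y[r];
    }
    trees[b] = cpp_tree_fit(Xb, yb, max_depth, min_leaf);
  }
  return trees;
}

// [[Rcpp::export]]
NumericVector cpp_bag_predict(List trees, NumericMatrix X) {
  const int B = trees.size(), n = X.nrow();
  NumericVector out(n);
  for (int b = 0; b < B; ++b) {
    NumericVector pb = cpp_tree_predict(trees[b], X);
    for (int i = 0; i < n; ++i) out[i] += pb[i];
  }
  for (int i = 0; i < n; ++i) out[i] /= B;
  return out;
}
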