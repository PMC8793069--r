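#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <limits>

using namespace Rcpp;

// Level-wise CART regression-tree builder.
//
// Splits minimize within-region squared error: for a node with target sum S
// and count C, splitting into (S_L, C_L) / (S_R, C_R) reduces the SSE by
//   S_L^2/C_L + S_R^2/C_R - S^2/C  >= 0.
// Candidate thresholds are midpoints between consecutive distinct sorted
// feature values; samples with x <= s go left. Ties in the loss are broken
// toward the lower feature index, then the lower threshold (features are
// scanned in order and thresholds ascending, so strict improvement keeps
// the first-seen optimum).
//
// `order` holds, per feature, the sample indices sorted by feature value;
// it is computed once per dataset and reused across boosting rounds.

// [[Rcpp::export]]
List fit_tree_impl(NumericMatrix X, IntegerMatrix order, NumericVector y,
                   int max_depth, int min_leaf) {
  const int n = X.nrow(), p = X.ncol();
  if (order.nrow() != n || order.ncol() != p)
    stop("presort order does not match feature matrix");
  if (y.size() != n) stop("targets do not match feature matrix");

  // growable flat tree arrays; node 0 is the root
  std::vector<int> feature(1, -1), left(1, -1), right(1, -1), depth(1, 0),
      nsamp(1, n);
  std::vector<double> threshold(1, NA_REAL), value(1, 0.0);

  std::vector<int> node_of(n, 0);  // current node of every sample

  for (int lvl = 0; lvl < max_depth; ++lvl) {
    // active nodes are the current leaves at this depth
    std::vector<int> active;
    for (size_t m = 0; m < feature.size(); ++m)
      if (feature[m] == -1 && depth[m] == (int)lvl) active.push_back((int)m);
    if (active.empty()) break;

    int n_nodes = (int)feature.size();
    std::vector<int> slot(n_nodes, -1);  // node id -> dense slot
    const int na = (int)active.size();
    for (int a = 0; a < na; ++a) slot[active[a]] = a;

    std::vector<double> sum(na, 0.0), sumsq(na, 0.0);
    std::vector<int> cnt(na, 0);
    for (int i = 0; i < n; ++i) {
      int s = slot[node_of[i]];
      if (s < 0) continue;
      sum[s] += y[i];
      sumsq[s] += y[i] * y[i];
      cnt[s] += 1;
    }

    // best_gain starts below zero: an impure node accepts its best valid
    // split even at zero gain (needed for XOR-like targets where purity is
    // only reachable two levels down)
    std::vector<double> best_gain(na, -1.0), best_thr(na, 0.0);
    std::vector<int> best_feat(na, -1);

    std::vector<double> lsum(na), lval(na);
    std::vector<int> lcnt(na);

    // 1/k lookup avoids two divisions per candidate threshold
    std::vector<double> rec(n + 1, 0.0);
    for (int k = 1; k <= n; ++k) rec[k] = 1.0 / k;
    std::vector<double> parent_score(na);
    for (int a = 0; a < na; ++a)
      parent_score[a] = sum[a] * sum[a] * rec[cnt[a]];
    std::vector<int> sl(n);  // per-sample dense slot, -1 if settled
    for (int i = 0; i < n; ++i) sl[i] = slot[node_of[i]];

    const double* xptr = REAL(X);
    const int* optr = INTEGER(order);
    const double* yptr = REAL(y);
    for (int j = 0; j < p; ++j) {
      std::fill(lsum.begin(), lsum.end(), 0.0);
      std::fill(lcnt.begin(), lcnt.end(), 0);
      // v > NaN is false, so the first sample in a node never splits
      std::fill(lval.begin(), lval.end(),
                std::numeric_limits<double>::quiet_NaN());
      const double* xj = xptr + (size_t)j * n;
      const int* oj = optr + (size_t)j * n;
      for (int k = 0; k < n; ++k) {
        int i = oj[k];
        int s = sl[i];
        if (s < 0) continue;
        double v = xj[i];
        int lc = lcnt[s];
        int rc = cnt[s] - lc;
        if (v > lval[s] && lc >= min_leaf && rc >= min_leaf) {
          double rsum = sum[s] - lsum[s];
          double gain = lsum[s] * lsum[s] * rec[lc] +
                        rsum * rsum * rec[rc] - parent_score[s];
          if (gain > best_gain[s]) {
            best_gain[s] = gain;
            best_feat[s] = j;
            best_thr[s] = 0.5 * (lval[s] + v);
          }
        }
        lsum[s] += yptr[i];
        lcnt[s] = lc + 1;
        lval[s] = v;
      }
    }

    // materialize splits; nodes without a useful split become leaves
    std::vector<int> newleft(na, -1), newright(na, -1);
    bool any_split = false;
    for (int a = 0; a < na; ++a) {
      int m = active[a];
      // pure nodes (SSE ~ 0) and nodes with no valid candidate stay
      // leaves; the epsilon absorbs round-off in the sum-of-squares
      // identity for constant targets
      double sse = sumsq[a] - sum[a] * sum[a] / cnt[a];
      double eps = 1e-12 * std::max(1.0, sumsq[a]);
      if (best_feat[a] < 0 || sse <= eps) {
        value[m] = sum[a] / cnt[a];
        continue;
      }
      any_split = true;
      feature[m] = best_feat[a];
      threshold[m] = best_thr[a];
      newleft[a] = (int)feature.size();
      feature.push_back(-1); left.push_back(-1); right.push_back(-1);
      depth.push_back(lvl + 1); nsamp.push_back(0);
      threshold.push_back(NA_REAL); value.push_back(0.0);
      newright[a] = (int)feature.size();
      feature.push_back(-1); left.push_back(-1); right.push_back(-1);
      depth.push_back(lvl + 1); nsamp.push_back(0);
      threshold.push_back(NA_REAL); value.push_back(0.0);
      left[m] = newleft[a];
      right[m] = newright[a];
    }
    if (!any_split) break;

    for (int i = 0; i < n; ++i) {
      int m = node_of[i];
      int s = (m < n_nodes) ? slot[m] : -1;
      if (s < 0 || feature[m] == -1) continue;
      int child = (X(i, feature[m]) <= threshold[m]) ? left[m] : right[m];
      node_of[i] = child;
      nsamp[child] += 1;
    }
  }

  // leaf values for max-depth leaves created in the final round
  {
    size_t nm = feature.size();
    std::vector<double> s(nm, 0.0);
    std::vector<int> c(nm, 0);
    for (int i = 0; i < n; ++i) {
      s[node_of[i]] += y[i];
      c[node_of[i]] += 1;
    }
    for (size_t m = 0; m < nm; ++m)
      if (feature[m] == -1 && c[m] > 0) value[m] = s[m] / c[m];
  }

  return List::create(
      _["feature"] = wrap(feature), _["threshold"] = wrap(threshold),
      _["left"] = wrap(left), _["right"] = wrap(right),
      _["value"] = wrap(value), _["n"] = wrap(nsamp),
      _["depth"] = wrap(depth), _["leaf_of"] = wrap(node_of));
}

// Route each row of X to its leaf; returns 0-based node indices.
// [[Rcpp::export]]
IntegerVector tree_leaf_impl(IntegerVector feature, NumericVector threshold,
                             IntegerVector left, IntegerVector right,
                             NumericMatrix X) {
  const int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int m = 0;
    while (feature[m] != -1) {
      m = (X(i, feature[m]) <= threshold[m]) ? left[m] : right[m];
    }
    out[i] = m;
  }
  return out;
}
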