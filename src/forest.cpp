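// Bagged CART regression trees with out-of-bag permutation importance.
//
// Used by rank_variable_importance(): the environment-driver analysis needs
// an ensemble-of-regression-trees predictor, and the fitting loops are too
// hot for interpreted R once response-permutation nulls (hundreds of
// ensemble refits) come into play. Uses R's RNG throughout so results are
// reproducible under set.seed().

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Node {
  int feat = -1;          // -1 => leaf
  double thr = 0.0;
  int left = -1, right = -1;
  double value = 0.0;
};

struct Tree {
  std::vector<Node> nodes;

  double predict(const NumericMatrix& X, int row) const {
    int id = 0;
    while (nodes[id].feat >= 0)
      id = (X(row, nodes[id].feat) <= nodes[id].thr) ? nodes[id].left
                                                     : nodes[id].right;
    return nodes[id].value;
  }
  // predict with one feature's value overridden (for permutation importance)
  double predict_swap(const NumericMatrix& X, int row, int feat,
                      double swapped) const {
    int id = 0;
    while (nodes[id].feat >= 0) {
      double v = (nodes[id].feat == feat) ? swapped : X(row, nodes[id].feat);
      id = (v <= nodes[id].thr) ? nodes[id].left : nodes[id].right;
    }
    return nodes[id].value;
  }
};

int rand_below(int n) {  // uniform integer in [0, n)
  int k = static_cast<int>(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

// sample `take` distinct feature indices out of p (partial Fisher-Yates)
void sample_features(std::vector<int>& pool, int take, std::vector<int>& out) {
  int p = static_cast<int>(pool.size());
  for (int i = 0; i < take; ++i) {
    int j = i + rand_below(p - i);
    std::swap(pool[i], pool[j]);
    out[i] = pool[i];
  }
}

void grow(Tree& tree, const NumericMatrix& X, const NumericVector& y,
          std::vector<int>& rows, int lo, int hi, int mtry, int minnode,
          std::vector<int>& pool, int node_id) {
  int n = hi - lo;
  double sum = 0.0, sum2 = 0.0;
  for (int i = lo; i < hi; ++i) {
    sum += y[rows[i]];
    sum2 += y[rows[i]] * y[rows[i]];
  }
  double mean = sum / n;
  double sse = sum2 - sum * sum / n;
  Node& self = tree.nodes[node_id];
  self.value = mean;
  if (n < 2 * minnode || sse <= 1e-12) return;  // leaf

  std::vector<int> feats(mtry);
  sample_features(pool, mtry, feats);
  std::sort(feats.begin(), feats.end());  // order-stable tie breaking

  int best_feat = -1;
  double best_thr = 0.0, best_score = sse - 1e-12;
  std::vector<int> idx(rows.begin() + lo, rows.begin() + hi);
  for (int f : feats) {
    std::sort(idx.begin(), idx.end(), [&](int a, int b) {
      return X(a, f) < X(b, f);
    });
    double lsum = 0.0, lsum2 = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      double yi = y[idx[i]];
      lsum += yi;
      lsum2 += yi * yi;
      int nl = i + 1, nr = n - nl;
      if (nl < minnode || nr < minnode) continue;
      if (X(idx[i], f) == X(idx[i + 1], f)) continue;  // not a valid cut
      double rsum = sum - lsum, rsum2 = sum2 - lsum2;
      double score = (lsum2 - lsum * lsum / nl) + (rsum2 - rsum * rsum / nr);
      if (score < best_score) {
        best_score = score;
        best_feat = f;
        best_thr = 0.5 * (X(idx[i], f) + X(idx[i + 1], f));
      }
    }
  }
  if (best_feat < 0) return;  // no admissible split improves SSE

  // partition rows[lo, hi) in place
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(rows[i], best_feat) <= best_thr) std::swap(rows[mid++], rows[i]);
  if (mid == lo || mid == hi) return;  // numerical guard

  int left_id = static_cast<int>(tree.nodes.size());
  tree.nodes.emplace_back();
  int right_id = static_cast<int>(tree.nodes.size());
  tree.nodes.emplace_back();
  tree.nodes[node_id].feat = best_feat;
  tree.nodes[node_id].thr = best_thr;
  tree.nodes[node_id].left = left_id;
  tree.nodes[node_id].right = right_id;
  grow(tree, X, y, rows, lo, mid, mtry, minnode, pool, left_id);
  grow(tree, X, y, rows, mid, hi, mtry, minnode, pool, right_id);
}

}  // namespace

// Fit a bagged regression-tree ensemble and return out-of-bag permutation
// importance (mean increase in OOB MSE when one feature is shuffled) plus
// the ensemble OOB MSE.
// [[Rcpp::export(rng = true)]]
List rf_importance_cpp(NumericMatrix X, NumericVector y, int ntree,
                       int mtry, int minnode) {
  const int n = X.nrow(), p = X.ncol();
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;

  NumericVector importance(p);
  std::vector<double> oob_pred_sum(n, 0.0);
  std::vector<int> oob_pred_cnt(n, 0);
  std::vector<int> pool(p), rows(n), oob, perm;
  std::vector<char> inbag(n);
  int trees_with_oob = 0;

  for (int t = 0; t < ntree; ++t) {
    std::fill(inbag.begin(), inbag.end(), 0);
    for (int i = 0; i < n; ++i) {
      rows[i] = rand_below(n);
      inbag[rows[i]] = 1;
    }
    for (int j = 0; j < p; ++j) pool[j] = j;
    Tree tree;
    tree.nodes.emplace_back();
    grow(tree, X, y, rows, 0, n, mtry, minnode, pool, 0);

    oob.clear();
    for (int i = 0; i < n; ++i)
      if (!inbag[i]) oob.push_back(i);
    if (oob.empty()) continue;
    ++trees_with_oob;

    double mse0 = 0.0;
    for (int i : oob) {
      double pr = tree.predict(X, i);
      oob_pred_sum[i] += pr;
      oob_pred_cnt[i] += 1;
      mse0 += (y[i] - pr) * (y[i] - pr);
    }
    mse0 /= oob.size();

    perm.assign(oob.begin(), oob.end());
    for (int f = 0; f < p; ++f) {
      // permute feature f's values across the OOB rows
      for (int i = static_cast<int>(perm.size()) - 1; i > 0; --i)
        std::swap(perm[i], perm[rand_below(i + 1)]);
      double msep = 0.0;
      for (size_t k = 0; k < oob.size(); ++k) {
        double pr = tree.predict_swap(X, oob[k], f, X(perm[k], f));
        msep += (y[oob[k]] - pr) * (y[oob[k]] - pr);
      }
      msep /= oob.size();
      importance[f] += msep - mse0;
    }
  }

  if (trees_with_oob > 0)
    for (int f = 0; f < p; ++f) importance[f] /= trees_with_oob;

  double oob_mse = NA_REAL;
  int covered = 0;
  double acc = 0.0;
  for (int i = 0; i < n; ++i)
    if (oob_pred_cnt[i] > 0) {
      double pr = oob_pred_sum[i] / oob_pred_cnt[i];
      acc += (y[i] - pr) * (y[i] - pr);
      ++covered;
    }
  if (covered > 0) oob_mse = acc / covered;

  return List::create(_["importance"] = importance, _["oob_mse"] = oob_mse);
}
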