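// Random forest for binary classification with OOB permutation importance.
// Self-contained (std::mt19937) so results are reproducible from the seed
// across platforms, independent of R's RNG state.
#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Node {
  int feat = -1;        // -1 for leaf
  double thr = 0.0;
  int left = -1, right = -1;
  int pred = 0;         // majority class at node
};

struct Tree {
  std::vector<Node> nodes;
  std::vector<int> used_features;
};

inline double gini(int n0, int n1) {
  double n = n0 + n1;
  if (n <= 0.0) return 0.0;
  double p0 = n0 / n, p1 = n1 / n;
  return 1.0 - p0 * p0 - p1 * p1;
}

class Builder {
public:
  Builder(const NumericMatrix& X, const IntegerVector& y, int mtry,
          int min_node, std::mt19937& rng)
    : X_(X), y_(y), mtry_(mtry), min_node_(min_node), rng_(rng) {}

  Tree build(const std::vector<int>& samples) {
    tree_ = Tree();
    used_.assign(X_.ncol(), false);
    grow(samples);
    for (int j = 0; j < (int)used_.size(); ++j)
      if (used_[j]) tree_.used_features.push_back(j);
    return tree_;
  }

private:
  int grow(const std::vector<int>& s) {
    int n1 = 0;
    for (int i : s) n1 += y_[i];
    int n0 = (int)s.size() - n1;
    Node node;
    node.pred = (n1 > n0) ? 1 : 0;
    int id = (int)tree_.nodes.size();
    tree_.nodes.push_back(node);
    if (n0 == 0 || n1 == 0 || (int)s.size() < 2 * min_node_) return id;

    // sample mtry candidate features without replacement
    int p = X_.ncol();
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    for (int k = 0; k < mtry_ && k < p; ++k) {
      std::uniform_int_distribution<int> d(k, p - 1);
      std::swap(feats[k], feats[d(rng_)]);
    }

    double parent_g = gini(n0, n1);
    double best_gain = 1e-12;
    int best_f = -1;
    double best_thr = 0.0;
    std::vector<std::pair<double, int>> vals(s.size());
    for (int k = 0; k < mtry_ && k < p; ++k) {
      int f = feats[k];
      for (size_t i = 0; i < s.size(); ++i)
        vals[i] = {X_(s[i], f), y_[s[i]]};
      std::sort(vals.begin(), vals.end());
      int l0 = 0, l1 = 0;
      for (size_t i = 0; i + 1 < vals.size(); ++i) {
        if (vals[i].second) ++l1; else ++l0;
        if (vals[i].first == vals[i + 1].first) continue;
        int r0 = n0 - l0, r1 = n1 - l1;
        int nl = l0 + l1, nr = r0 + r1;
        if (nl < min_node_ || nr < min_node_) continue;
        double g = parent_g -
          (nl * gini(l0, l1) + nr * gini(r0, r1)) / (double)s.size();
        if (g > best_gain) {
          best_gain = g;
          best_f = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (best_f < 0) return id;

    std::vector<int> ls, rs;
    for (int i : s)
      (X_(i, best_f) <= best_thr ? ls : rs).push_back(i);
    if (ls.empty() || rs.empty()) return id;
    used_[best_f] = true;
    tree_.nodes[id].feat = best_f;
    tree_.nodes[id].thr = best_thr;
    int li = grow(ls);
    tree_.nodes[id].left = li;
    int ri = grow(rs);
    tree_.nodes[id].right = ri;
    return id;
  }

  const NumericMatrix& X_;
  const IntegerVector& y_;
  int mtry_, min_node_;
  std::mt19937& rng_;
  Tree tree_;
  std::vector<bool> used_;
};

inline int predict_one(const Tree& t, const NumericMatrix& X, int row,
                       int swap_feat = -1, double swap_val = 0.0) {
  int id = 0;
  while (t.nodes[id].feat >= 0) {
    const Node& nd = t.nodes[id];
    double v = (nd.feat == swap_feat) ? swap_val : X(row, nd.feat);
    id = (v <= nd.thr) ? nd.left : nd.right;
  }
  return t.nodes[id].pred;
}

} // namespace

// Fit a forest and return mean-decrease-accuracy permutation importance
// (computed on each tree's out-of-bag samples) plus the OOB error.
// [[Rcpp::export]]
List cpp_rf_importance(NumericMatrix X, IntegerVector y, int ntree = 500,
                       int mtry = 0, int min_node = 1, int seed = 1) {
  int n = X.nrow(), p = X.ncol();
  if (mtry <= 0) mtry = std::max(1, (int)std::floor(std::sqrt((double)p)));
  std::mt19937 rng(seed);
  std::uniform_int_distribution<int> pick(0, n - 1);

  NumericVector importance(p, 0.0);
  std::vector<int> imp_counts(p, 0);
  std::vector<int> oob_votes1(n, 0), oob_total(n, 0);

  for (int t = 0; t < ntree; ++t) {
    std::vector<int> boot(n);
    std::vector<bool> inbag(n, false);
    for (int i = 0; i < n; ++i) {
      boot[i] = pick(rng);
      inbag[boot[i]] = true;
    }
    Builder b(X, y, mtry, min_node, rng);
    Tree tree = b.build(boot);

    std::vector<int> oob;
    for (int i = 0; i < n; ++i)
      if (!inbag[i]) oob.push_back(i);
    if (oob.empty()) continue;

    int base_correct = 0;
    for (int i : oob) {
      int pr = predict_one(tree, X, i);
      if (pr == y[i]) ++base_correct;
      oob_votes1[i] += pr;
      ++oob_total[i];
    }
    // permutation importance, restricted to features the tree uses
    std::vector<int> perm(oob);
    for (int f : tree.used_features) {
      std::shuffle(perm.begin(), perm.end(), rng);
      int correct = 0;
      for (size_t k = 0; k < oob.size(); ++k) {
        int pr = predict_one(tree, X, oob[k], f, X(perm[k], f));
        if (pr == y[oob[k]]) ++correct;
      }
      importance[f] += (base_correct - correct) / (double)oob.size();
      ++imp_counts[f];
    }
  }
  for (int f = 0; f < p; ++f)
    if (imp_counts[f] > 0) importance[f] /= ntree; // unused features keep 0

  int err = 0, cnt = 0;
  for (int i = 0; i < n; ++i) {
    if (oob_total[i] == 0) continue;
    int pr = (2 * oob_votes1[i] > oob_total[i]) ? 1 : 0;
    if (pr != y[i]) ++err;
    ++cnt;
  }
  double oob_err = cnt ? err / (double)cnt : NA_REAL;
  return List::create(_["importance"] = importance, _["oob_error"] = oob_err);
}
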