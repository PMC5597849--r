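// Random forest for binary classification: CART trees with Gini splits,
// bootstrap resampling, out-of-bag probability scores and permutation
// importance (mean decrease in OOB accuracy). Self-contained so the
// pipeline does not depend on an external forest implementation; the
// RNG is std::mt19937 seeded explicitly, independent of R's RNG state.
#include <Rcpp.h>
#include <algorithm>
#include <random>
#include <vector>
using namespace Rcpp;

namespace {

struct Node {
  int feat = -1;  // -1 marks a leaf
  double thr = 0.0;
  int left = -1, right = -1;
  double prob = 0.0;  // leaf: fraction of class 1 in the node
};

struct Tree {
  std::vector<Node> nodes;

  double predict_row(const std::vector<double>& row) const {
    int i = 0;
    while (nodes[i].feat >= 0)
      i = (row[nodes[i].feat] <= nodes[i].thr) ? nodes[i].left : nodes[i].right;
    return nodes[i].prob;
  }
};

class Builder {
public:
  const double* X;  // column-major n x p
  const int* y;
  int n, p, mtry;
  std::mt19937& rng;
  Tree& tree;
  std::vector<int> feat_pool;
  std::vector<std::pair<double, int> > buf;

  Builder(const double* X_, const int* y_, int n_, int p_, int mtry_,
          std::mt19937& rng_, Tree& t)
      : X(X_), y(y_), n(n_), p(p_), mtry(mtry_), rng(rng_), tree(t),
        feat_pool(p_) {
    for (int j = 0; j < p_; ++j) feat_pool[j] = j;
  }

  int build(std::vector<int>& idx, int lo, int hi) {
    int m = hi - lo;
    int pos = 0;
    for (int i = lo; i < hi; ++i) pos += y[idx[i]];
    int id = (int)tree.nodes.size();
    tree.nodes.push_back(Node());
    if (pos == 0 || pos == m || m < 2) {
      tree.nodes[id].prob = (double)pos / m;
      return id;
    }
    int best_f = -1;
    double best_thr = 0.0, best_score = -1.0;
    for (int t = 0; t < mtry; ++t) {
      std::uniform_int_distribution<int> pick(t, p - 1);
      std::swap(feat_pool[t], feat_pool[pick(rng)]);
      int f = feat_pool[t];
      buf.clear();
      for (int i = lo; i < hi; ++i)
        buf.push_back(std::make_pair(X[(size_t)f * n + idx[i]], y[idx[i]]));
      std::sort(buf.begin(), buf.end());
      int pl = 0;
      for (int i = 0; i + 1 < m; ++i) {
        pl += buf[i].second;
        if (buf[i].first == buf[i + 1].first) continue;
        int nl = i + 1, nr = m - nl, pr = pos - pl;
        double score =
            (double)(pl * pl + (nl - pl) * (nl - pl)) / nl +
            (double)(pr * pr + (nr - pr) * (nr - pr)) / nr;
        if (score > best_score) {
          best_score = score;
          best_f = f;
          best_thr = buf[i].first + 0.5 * (buf[i + 1].first - buf[i].first);
        }
      }
    }
    if (best_f < 0) {  // no valid split among tried features
      tree.nodes[id].prob = (double)pos / m;
      return id;
    }
    int mid = lo;
    for (int i = lo; i < hi; ++i)
      if (X[(size_t)best_f * n + idx[i]] <= best_thr) std::swap(idx[mid++], idx[i]);
    if (mid == lo || mid == hi) {  // numeric degeneracy
      tree.nodes[id].prob = (double)pos / m;
      return id;
    }
    tree.nodes[id].feat = best_f;
    tree.nodes[id].thr = best_thr;
    int l = build(idx, lo, mid);
    int r = build(idx, mid, hi);
    tree.nodes[id].left = l;
    tree.nodes[id].right = r;
    return id;
  }
};

}  // namespace

// [[Rcpp::export(name = ".rf_cpp")]]
List rf_cpp(NumericMatrix X, IntegerVector y, int ntree, int mtry, int seed,
            Nullable<NumericMatrix> Xtest_ = R_NilValue,
            bool importance = false) {
  const int n = X.nrow(), p = X.ncol();
  if (mtry < 1) mtry = std::max(1, (int)std::floor(std::sqrt((double)p)));
  if (mtry > p) mtry = p;
  std::mt19937 master((unsigned)seed);

  std::vector<double> oob_sum(n, 0.0);
  std::vector<int> oob_cnt(n, 0);
  std::vector<double> imp(p, 0.0);
  NumericMatrix Xtest;
  int ntest = 0;
  if (Xtest_.isNotNull()) {
    Xtest = Xtest_.get();
    ntest = Xtest.nrow();
  }
  std::vector<double> test_sum(ntest, 0.0);

  std::vector<int> idx(n), inbag(n);
  std::vector<double> row(p);

  for (int t = 0; t < ntree; ++t) {
    std::mt19937 rng(master());
    std::fill(inbag.begin(), inbag.end(), 0);
    std::uniform_int_distribution<int> pick(0, n - 1);
    for (int i = 0; i < n; ++i) {
      int k = pick(rng);
      idx[i] = k;
      inbag[k] = 1;
    }
    Tree tree;
    Builder b(REAL(X), INTEGER(y), n, p, mtry, rng, tree);
    b.build(idx, 0, n);

    std::vector<int> oob;
    for (int i = 0; i < n; ++i)
      if (!inbag[i]) oob.push_back(i);
    for (size_t k = 0; k < oob.size(); ++k) {
      int i = oob[k];
      for (int j = 0; j < p; ++j) row[j] = X(i, j);
      double pr = tree.predict_row(row);
      oob_sum[i] += pr;
      oob_cnt[i] += 1;
    }
    for (int i = 0; i < ntest; ++i) {
      for (int j = 0; j < p; ++j) row[j] = Xtest(i, j);
      test_sum[i] += tree.predict_row(row);
    }

    if (importance && !oob.empty()) {
      int correct = 0;
      for (size_t k = 0; k < oob.size(); ++k) {
        int i = oob[k];
        for (int j = 0; j < p; ++j) row[j] = X(i, j);
        correct += ((tree.predict_row(row) > 0.5) ? 1 : 0) == y[i];
      }
      double acc = (double)correct / oob.size();
      std::vector<int> perm(oob);
      for (int f = 0; f < p; ++f) {
        std::shuffle(perm.begin(), perm.end(), rng);
        int pc = 0;
        for (size_t k = 0; k < oob.size(); ++k) {
          int i = oob[k];
          for (int j = 0; j < p; ++j) row[j] = X(i, j);
          row[f] = X(perm[k], f);
          pc += ((tree.predict_row(row) > 0.5) ? 1 : 0) == y[i];
        }
        imp[f] += acc - (double)pc / oob.size();
      }
    }
  }

  NumericVector oob_prob(n, NA_REAL);
  for (int i = 0; i < n; ++i)
    if (oob_cnt[i] > 0) oob_prob[i] = oob_sum[i] / oob_cnt[i];
  NumericVector test_prob(ntest);
  for (int i = 0; i < ntest; ++i) test_prob[i] = test_sum[i] / ntree;
  NumericVector importance_out(p);
  for (int j = 0; j < p; ++j) importance_out[j] = imp[j] / ntree;

  return List::create(_["oob_prob"] = oob_prob, _["test_prob"] = test_prob,
                      _["importance"] = importance_out);
}

// Exact two-sided permutation p-value for the Spearman correlation of
// two rank vectors (n <= 10), enumerating all n! orderings of ry.
// Valid with average ranks under ties. The statistic sum(rx * ry_perm)
// is monotone in the correlation, so tail counting on |S - mu| matches
// tail counting on |rho|.
// [[Rcpp::export(name = ".spearman_perm_p")]]
double spearman_perm_p(NumericVector rx, NumericVector ry) {
  int n = rx.size();
  if (n != ry.size()) stop("length mismatch");
  if (n > 10) stop("exact enumeration limited to n <= 10");
  double sx = 0.0, sy = 0.0;
  for (int i = 0; i < n; ++i) {
    sx += rx[i];
    sy += ry[i];
  }
  double mu = sx * sy / n;
  double obs = 0.0;
  for (int i = 0; i < n; ++i) obs += rx[i] * ry[i];
  double target = std::fabs(obs - mu) - 1e-9;
  std::vector<double> b(ry.begin(), ry.end());
  std::sort(b.begin(), b.end());
  long long hits = 0, total = 0;
  do {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += rx[i] * b[i];
    if (std::fabs(s - mu) >= target) ++hits;
    ++total;
  } while (std::next_permutation(b.begin(), b.end()));
  // with tied ranks next_permutation enumerates distinct orderings only;
  // each distinct ordering has equal multiplicity, so the ratio is exact
  return (double)hits / total;
}
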