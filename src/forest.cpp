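// Random-forest primitives for binary classification of expression profiles.
//
// Self-contained CART forest: bootstrap resampling, Gini split criterion,
// mtry random feature candidates per node, normalized mean-decrease-in-impurity
// (Gini) importance, leaf class-probability estimates, and per-sample
// decision-path attributions (prediction decomposed along each tree path).
//
// Split search uses per-feature quantile binning (<= 256 bins, cut values kept
// on the original scale) so node evaluation is a single histogram pass instead
// of a sort; expression features with few distinct values are represented
// exactly. A local splitmix64 RNG keeps results bit-reproducible for a given
// seed across platforms, independent of R's RNG state.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
#include <cstring>

using namespace Rcpp;

namespace {

const int MAX_BINS = 256;

struct SplitMix64 {
  uint64_t s;
  explicit SplitMix64(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform integer in [0, n); modulo bias negligible for n << 2^64
  int unif_int(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

inline double gini_impurity(double n_pos, double n_tot) {
  if (n_tot <= 0.0) return 0.0;
  double p = n_pos / n_tot;
  return 2.0 * p * (1.0 - p);
}

// Quantile cut points for one feature; bin(x) = #cuts strictly below x,
// i.e. lower_bound, so "x <= cut[b]" sends bins 0..b left.
void make_cuts(const double* col, int n, std::vector<double>& cuts) {
  std::vector<double> v(col, col + n);
  std::sort(v.begin(), v.end());
  cuts.clear();
  int n_distinct = 1;
  for (int i = 1; i < n; ++i)
    if (v[i] != v[i - 1]) ++n_distinct;
  if (n_distinct <= MAX_BINS) {
    for (int i = 1; i < n; ++i)
      if (v[i] != v[i - 1]) cuts.push_back(0.5 * (v[i] + v[i - 1]));
  } else {
    for (int q = 1; q < MAX_BINS; ++q) {
      int at = static_cast<int>(static_cast<long long>(q) * n / MAX_BINS);
      if (at <= 0 || at >= n) continue;
      if (v[at] != v[at - 1]) {
        double c = 0.5 * (v[at] + v[at - 1]);
        if (cuts.empty() || c > cuts.back()) cuts.push_back(c);
      }
    }
  }
}

struct Tree {
  std::vector<int> feature;
  std::vector<double> threshold;
  std::vector<int> left, right;
  std::vector<double> prob;  // fraction of positive class among node samples

  int new_node() {
    feature.push_back(-1);
    threshold.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    prob.push_back(0.0);
    return static_cast<int>(feature.size()) - 1;
  }
};

struct Builder {
  const uint8_t* B;  // binned matrix, column-major n x p
  const int* y;
  const std::vector<std::vector<double> >* cuts;
  int n, p;
  int mtry, min_leaf, max_depth;
  SplitMix64* rng;
  Tree* tree;
  std::vector<double>* imp;     // per-tree raw impurity decrease
  std::vector<int> feat_order;  // scratch
  // histogram scratch; kept all-zero between features (only touched bins are
  // cleared after use, so small nodes cost O(node size), not O(MAX_BINS))
  int hist_cnt[MAX_BINS];
  int hist_pos[MAX_BINS];

  // idx: bootstrap sample indices (with duplicates) belonging to this node
  int build(std::vector<int>& idx, int depth) {
    int node = tree->new_node();
    int m = static_cast<int>(idx.size());
    int pos = 0;
    for (int i = 0; i < m; ++i) pos += y[idx[i]];
    tree->prob[node] = static_cast<double>(pos) / m;

    bool stop = (pos == 0 || pos == m || m < 2 * min_leaf ||
                 (max_depth > 0 && depth >= max_depth));
    if (stop) return node;

    double g_parent = gini_impurity(pos, m);
    int best_f = -1, best_bin = -1;
    double best_gain = 1e-12;

    for (int i = 0; i < p; ++i) feat_order[i] = i;
    int tried = 0;
    for (int i = 0; i < p && tried < mtry; ++i) {
      int j = i + rng->unif_int(p - i);
      std::swap(feat_order[i], feat_order[j]);
      int f = feat_order[i];
      int nb = static_cast<int>((*cuts)[f].size()) + 1;
      if (nb < 2) continue;  // globally constant feature

      const uint8_t* bf = B + static_cast<size_t>(f) * n;
      int lo = MAX_BINS, hi = -1;
      for (int k = 0; k < m; ++k) {
        int b = bf[idx[k]];
        ++hist_cnt[b];
        hist_pos[b] += y[idx[k]];
        if (b < lo) lo = b;
        if (b > hi) hi = b;
      }
      if (lo == hi) {  // constant within node
        hist_cnt[lo] = hist_pos[lo] = 0;
        continue;
      }
      ++tried;

      int nl = 0, posl = 0;
      for (int b = lo; b < hi; ++b) {
        nl += hist_cnt[b];
        posl += hist_pos[b];
        if (hist_cnt[b] == 0) continue;
        int nr = m - nl;
        if (nl < min_leaf || nr < min_leaf) continue;
        double g = g_parent -
                   (nl * gini_impurity(posl, nl) +
                    nr * gini_impurity(pos - posl, nr)) / m;
        if (g > best_gain) {
          best_gain = g;
          best_f = f;
          best_bin = b;
        }
      }
      for (int b = lo; b <= hi; ++b) hist_cnt[b] = hist_pos[b] = 0;
    }
    if (best_f < 0) return node;

    (*imp)[best_f] += static_cast<double>(m) / n * best_gain;

    // place the threshold mid-way across any empty-bin gap, as a sort-based
    // CART would: otherwise unseen values inside the gap all fall right
    int nb2 = MAX_BINS;
    {
      const uint8_t* bf = B + static_cast<size_t>(best_f) * n;
      for (int k = 0; k < m; ++k) {
        int b = bf[idx[k]];
        if (b > best_bin && b < nb2) nb2 = b;
      }
    }
    double thr_lo = (*cuts)[best_f][best_bin];
    double thr_hi = (nb2 - 1 < static_cast<int>((*cuts)[best_f].size()))
                        ? (*cuts)[best_f][nb2 - 1] : thr_lo;

    std::vector<int> lidx, ridx;
    lidx.reserve(m);
    const uint8_t* bf = B + static_cast<size_t>(best_f) * n;
    for (int k = 0; k < m; ++k) {
      if (bf[idx[k]] <= best_bin) lidx.push_back(idx[k]);
      else ridx.push_back(idx[k]);
    }
    idx.clear();
    idx.shrink_to_fit();

    tree->feature[node] = best_f;
    tree->threshold[node] = 0.5 * (thr_lo + thr_hi);
    tree->left[node] = build(lidx, depth + 1);
    tree->right[node] = build(ridx, depth + 1);
    return node;
  }
};

}  // namespace

// Quantile-bin a feature matrix once; reusable across many fits on row
// subsets (cross-validation folds, label permutations) where re-sorting every
// column would dominate runtime.
// [[Rcpp::export(name = ".rf_bin_cpp")]]
List rf_bin_cpp(NumericMatrix X) {
  int n = X.nrow(), p = X.ncol();
  List cut_list(p);
  RawMatrix B(n, p);
  const double* xp = REAL(X);
  for (int f = 0; f < p; ++f) {
    const double* col = xp + static_cast<size_t>(f) * n;
    std::vector<double> cuts;
    make_cuts(col, n, cuts);
    uint8_t* bf = reinterpret_cast<uint8_t*>(RAW(B)) +
                  static_cast<size_t>(f) * n;
    for (int i = 0; i < n; ++i)
      bf[i] = static_cast<uint8_t>(
          std::lower_bound(cuts.begin(), cuts.end(), col[i]) - cuts.begin());
    cut_list[f] = NumericVector(cuts.begin(), cuts.end());
  }
  return List::create(_["bins"] = B, _["cuts"] = cut_list, _["n"] = n,
                      _["p"] = p);
}

// Train on prebinned data, restricted to `rows` (0-based indices into the
// binned matrix). y is aligned with the full binned matrix.
// [[Rcpp::export(name = ".rf_train_binned_cpp")]]
List rf_train_binned_cpp(List bin, IntegerVector y, IntegerVector rows,
                         int n_trees, int mtry, int min_leaf, int max_depth,
                         int seed) {
  RawMatrix B = bin["bins"];
  List cut_list = bin["cuts"];
  int n_all = bin["n"], p = bin["p"];
  if (y.size() != n_all) stop("length(y) must equal binned matrix rows");
  int n_sub = rows.size();
  if (n_sub < 2) stop("need at least two samples");
  if (mtry < 1 || mtry > p) stop("mtry out of range");
  for (int i = 0; i < n_sub; ++i)
    if (rows[i] < 0 || rows[i] >= n_all) stop("row index out of range");

  std::vector<std::vector<double> > cuts(p);
  for (int f = 0; f < p; ++f) {
    NumericVector c = cut_list[f];
    cuts[f].assign(c.begin(), c.end());
  }

  std::vector<int> feat_all, left_all, right_all, offs(1, 0);
  std::vector<double> thr_all, prob_all;
  NumericVector importance(p);
  std::vector<double> imp_tree(p);

  for (int t = 0; t < n_trees; ++t) {
    SplitMix64 rng(static_cast<uint64_t>(seed) * 0x100000001B3ULL +
                   static_cast<uint64_t>(t) + 1ULL);
    std::vector<int> idx(n_sub);
    for (int i = 0; i < n_sub; ++i) idx[i] = rows[rng.unif_int(n_sub)];

    Tree tree;
    std::fill(imp_tree.begin(), imp_tree.end(), 0.0);
    Builder b;
    b.B = reinterpret_cast<const uint8_t*>(RAW(B));
    b.y = INTEGER(y);
    b.cuts = &cuts;
    b.n = n_all;
    b.p = p;
    b.mtry = mtry;
    b.min_leaf = min_leaf;
    b.max_depth = max_depth;
    b.rng = &rng;
    b.tree = &tree;
    b.imp = &imp_tree;
    b.feat_order.resize(p);
    std::memset(b.hist_cnt, 0, sizeof(b.hist_cnt));
    std::memset(b.hist_pos, 0, sizeof(b.hist_pos));
    b.build(idx, 0);

    double tot = 0.0;
    for (int j = 0; j < p; ++j) tot += imp_tree[j];
    if (tot > 0.0)
      for (int j = 0; j < p; ++j) importance[j] += imp_tree[j] / tot;

    int base = offs.back();
    for (size_t k = 0; k < tree.feature.size(); ++k) {
      feat_all.push_back(tree.feature[k]);
      thr_all.push_back(tree.threshold[k]);
      left_all.push_back(tree.left[k] < 0 ? -1 : tree.left[k] + base);
      right_all.push_back(tree.right[k] < 0 ? -1 : tree.right[k] + base);
      prob_all.push_back(tree.prob[k]);
    }
    offs.push_back(base + static_cast<int>(tree.feature.size()));
  }

  for (int j = 0; j < p; ++j) importance[j] /= n_trees;

  return List::create(
      _["feature"] = IntegerVector(feat_all.begin(), feat_all.end()),
      _["threshold"] = NumericVector(thr_all.begin(), thr_all.end()),
      _["left"] = IntegerVector(left_all.begin(), left_all.end()),
      _["right"] = IntegerVector(right_all.begin(), right_all.end()),
      _["prob"] = NumericVector(prob_all.begin(), prob_all.end()),
      _["offsets"] = IntegerVector(offs.begin(), offs.end()),
      _["importance"] = importance, _["n_trees"] = n_trees, _["p"] = p);
}

// [[Rcpp::export(name = ".rf_train_cpp")]]
List rf_train_cpp(NumericMatrix X, IntegerVector y, int n_trees, int mtry,
                  int min_leaf, int max_depth, int seed) {
  List bin = rf_bin_cpp(X);
  IntegerVector rows(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) rows[i] = i;
  return rf_train_binned_cpp(bin, y, rows, n_trees, mtry, min_leaf, max_depth,
                             seed);
}

// Mean over trees of the leaf positive-class fraction.
// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(List forest, NumericMatrix X) {
  IntegerVector feat = forest["feature"], left = forest["left"],
                right = forest["right"], offs = forest["offsets"];
  NumericVector thr = forest["threshold"], prob = forest["prob"];
  int n_trees = forest["n_trees"], p_model = forest["p"];
  int n = X.nrow();
  if (X.ncol() != p_model) stop("feature count mismatch between model and X");

  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int t = 0; t < n_trees; ++t) {
      int node = offs[t];
      while (feat[node] >= 0)
        node = (X(i, feat[node]) <= thr[node]) ? left[node] : right[node];
      acc += prob[node];
    }
    out[i] = acc / n_trees;
  }
  return out;
}

// Decision-path attribution: for each sample, the change in positive-class
// probability along each split edge is credited to the split feature and
// averaged over trees. Row sums equal prediction minus mean root probability.
// [[Rcpp::export(name = ".rf_contrib_cpp")]]
NumericMatrix rf_contrib_cpp(List forest, NumericMatrix X) {
  IntegerVector feat = forest["feature"], left = forest["left"],
                right = forest["right"], offs = forest["offsets"];
  NumericVector thr = forest["threshold"], prob = forest["prob"];
  int n_trees = forest["n_trees"], p_model = forest["p"];
  int n = X.nrow();
  if (X.ncol() != p_model) stop("feature count mismatch between model and X");

  NumericMatrix out(n, p_model);
  for (int i = 0; i < n; ++i) {
    for (int t = 0; t < n_trees; ++t) {
      int node = offs[t];
      while (feat[node] >= 0) {
        int nxt = (X(i, feat[node]) <= thr[node]) ? left[node] : right[node];
        out(i, feat[node]) += prob[nxt] - prob[node];
        node = nxt;
      }
    }
  }
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < p_model; ++j) out(i, j) /= n_trees;
  return out;
}
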