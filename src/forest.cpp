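#include <Rcpp.h>
#include <random>
#include <vector>
using namespace Rcpp;

// Flat regression-tree representation, one matrix per tree with columns
// 0: left child, 1: right child (0-based node ids, -1 at leaves)
// 2: split variable (0-based, -1 at leaves)
// 3: split value (numeric splits, x <= value goes left)
// 4: node prediction (leaves only)
struct Tree {
  std::vector<int> left, right, var;
  std::vector<double> split, pred;
};

static std::vector<Tree> unpack_forest(const List& forest) {
  std::vector<Tree> trees(forest.size());
  for (R_xlen_t t = 0; t < forest.size(); ++t) {
    NumericMatrix m = forest[t];
    int nn = m.nrow();
    Tree& tr = trees[t];
    tr.left.resize(nn); tr.right.resize(nn); tr.var.resize(nn);
    tr.split.resize(nn); tr.pred.resize(nn);
    for (int i = 0; i < nn; ++i) {
      tr.left[i]  = (int) m(i, 0);
      tr.right[i] = (int) m(i, 1);
      tr.var[i]   = (int) m(i, 2);
      tr.split[i] = m(i, 3);
      tr.pred[i]  = m(i, 4);
    }
  }
  return trees;
}

// predict one row, optionally overriding a single feature's value
static double predict_row(const Tree& tr, const NumericMatrix& X, int row,
                          int override_var, double override_val) {
  int node = 0;
  while (tr.var[node] >= 0) {
    int v = tr.var[node];
    double x = (v == override_var) ? override_val : X(row, v);
    node = (x <= tr.split[node]) ? tr.left[node] : tr.right[node];
  }
  return tr.pred[node];
}

// [[Rcpp::export]]
NumericMatrix cpp_forest_predict(List forest, NumericMatrix X) {
  std::vector<Tree> trees = unpack_forest(forest);
  int n = X.nrow(), T = trees.size();
  NumericMatrix out(n, T);
  for (int t = 0; t < T; ++t)
    for (int i = 0; i < n; ++i)
      out(i, t) = predict_row(trees[t], X, i, -1, 0.0);
  return out;
}

// Per-tree mean-decrease-accuracy: for each tree, squared-error increase on
// its out-of-bag rows after permuting one feature at a time (one fresh
// permutation per feature per tree). Returns trees x features loss matrix.
// [[Rcpp::export]]
NumericMatrix cpp_forest_mda(List forest, NumericMatrix X, NumericVector y,
                             IntegerMatrix inbag, int seed) {
  std::vector<Tree> trees = unpack_forest(forest);
  int n = X.nrow(), p = X.ncol(), T = trees.size();
  NumericMatrix loss(T, p);
  std::mt19937 rng((unsigned) seed);
  std::vector<int> oob; oob.reserve(n);
  std::vector<double> base; base.reserve(n);
  std::vector<double> pool; pool.reserve(n);
  for (int t = 0; t < T; ++t) {
    const Tree& tr = trees[t];
    oob.clear();
    for (int i = 0; i < n; ++i)
      if (inbag(i, t) == 0) oob.push_back(i);
    if (oob.empty()) continue;
    double err0 = 0.0;
    base.clear();
    for (int i : oob) {
      double pr = predict_row(tr, X, i, -1, 0.0);
      base.push_back(pr);
      double d = y[i] - pr;
      err0 += d * d;
    }
    err0 /= oob.size();
    // features never used by this tree keep loss 0; mark used ones
    std::vector<bool> used(p, false);
    for (size_t k = 0; k < tr.var.size(); ++k)
      if (tr.var[k] >= 0) used[tr.var[k]] = true;
    for (int j = 0; j < p; ++j) {
      if (!used[j]) { loss(t, j) = 0.0; continue; }
      pool.clear();
      for (int i : oob) pool.push_back(X(i, j));
      std::shuffle(pool.begin(), pool.end(), rng);
      double err = 0.0;
      for (size_t k = 0; k < oob.size(); ++k) {
        double pr = predict_row(tr, X, oob[k], j, pool[k]);
        double d = y[oob[k]] - pr;
        err += d * d;
      }
      err /= oob.size();
      loss(t, j) = err - err0;
    }
  }
  return loss;
}

// Interventional Shapley values for a tree ensemble. For each explained row
// x and background row z, a single recursive pass per tree assigns each
// leaf's value to the features whose coalition membership decides whether
// the (x, z) hybrid reaches that leaf, with exact Shapley weights
// (a-1)! b! / (a+b)! where a features must be present and b absent.
struct ShapWalker {
  const Tree* tr;
  const NumericMatrix* X; // explained rows
  const NumericMatrix* B; // background rows
  int xi, zi;
  std::vector<signed char> state; // 0 free, 1 needs j in S, 2 needs j out
  std::vector<int> constrained;
  int a, b;
  std::vector<double> fact;
  std::vector<double> phi;

  void init(int p) {
    state.assign(p, 0);
    constrained.clear();
    a = b = 0;
    fact.resize(p + 2);
    fact[0] = 1.0;
    for (int i = 1; i <= p + 1; ++i) fact[i] = fact[i - 1] * i;
    phi.assign(p, 0.0);
  }

  void walk(int node) {
    int v = tr->var[node];
    if (v < 0) {
      double val = tr->pred[node];
      if (a + b == 0) return;
      double w_in  = (a > 0) ? fact[a - 1] * fact[b] / fact[a + b] : 0.0;
      double w_out = (b > 0) ? fact[a] * fact[b - 1] / fact[a + b] : 0.0;
      for (int f : constrained) {
        if (state[f] == 1) phi[f] += val * w_in;
        else               phi[f] -= val * w_out;
      }
      return;
    }
    bool xl = (*X)(xi, v) <= tr->split[node];
    bool zl = (*B)(zi, v) <= tr->split[node];
    int xchild = xl ? tr->left[node] : tr->right[node];
    int zchild = zl ? tr->left[node] : tr->right[node];
    if (state[v] == 1) { walk(xchild); return; }
    if (state[v] == 2) { walk(zchild); return; }
    if (xchild == zchild) { walk(xchild); return; }
    state[v] = 1; ++a; constrained.push_back(v);
    walk(xchild);
    state[v] = 2; --a; ++b;
    walk(zchild);
    state[v] = 0; --b; constrained.pop_back();
  }
};

// [[Rcpp::export]]
NumericMatrix cpp_forest_shap(List forest, NumericMatrix X, NumericMatrix B) {
  std::vector<Tree> trees = unpack_forest(forest);
  int n = X.nrow(), p = X.ncol(), T = trees.size(), nb = B.nrow();
  NumericMatrix out(n, p);
  ShapWalker w;
  w.X = &X; w.B = &B;
  double scale = 1.0 / ((double) T * nb);
  for (int t = 0; t < T; ++t) {
    w.tr = &trees[t];
    for (int i = 0; i < n; ++i) {
      w.xi = i;
      for (int z = 0; z < nb; ++z) {
        w.zi = z;
        w.init(p);
        w.walk(0);
        for (int j = 0; j < p; ++j) out(i, j) += w.phi[j] * scale;
      }
    }
  }
  return out;
}
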