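#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Interventional Shapley values for a forest of regression trees.
//
// The value function for foreground row x and background row b is
// v(S) = f(x_S, b_{S^c}): the tree evaluated on a hybrid point taking
// coordinates in S from x and the rest from b.  For a single tree the
// indicator that a hybrid reaches leaf L factorizes over the distinct
// features on the root-to-leaf path: L is reached iff every feature whose
// path conditions only x satisfies is in S (set A) and every feature only
// b satisfies is outside S (set B); if some feature is satisfied by
// neither, L is unreachable for every S.  The Shapley values of the game
// v_L(S) = value_L * [A subset of S and B disjoint from S] are
//   phi_j =  value_L * (|A|-1)! |B|! / (|A|+|B|)!   for j in A,
//   phi_j = -value_L * |A|! (|B|-1)! / (|A|+|B|)!   for j in B,
// and zero otherwise.  Summing over leaves and averaging over background
// rows and trees gives the forest attribution; by construction
// sum_j phi_j(x) = f(x) - mean_b f(b) exactly.

struct Tree {
  std::vector<int> left, right, var;
  std::vector<double> val, pred;
};

// Precomputed combinatorial weights, indexed [a * stride + d]:
// wpos = (a-1)! d! / (a+d)!,  wneg = a! (d-1)! / (a+d)!  (0 where undefined).
struct WeightTable {
  std::vector<double> wpos, wneg;
  size_t stride;
  void build(int max_ad) {
    stride = (size_t)max_ad + 1;
    wpos.assign(stride * stride, 0.0);
    wneg.assign(stride * stride, 0.0);
    for (int a = 0; a <= max_ad; ++a) {
      for (int d = 0; a + d <= max_ad; ++d) {
        double lg = std::lgamma((double)(a + d) + 1.0);
        if (a > 0)
          wpos[(size_t)a * stride + d] =
            std::exp(std::lgamma((double)a) + std::lgamma((double)d + 1.0) - lg);
        if (d > 0)
          wneg[(size_t)a * stride + d] =
            std::exp(std::lgamma((double)a + 1.0) + std::lgamma((double)d) - lg);
      }
    }
  }
};

struct PairCtx {
  const Tree* t;
  const double* x;   // foreground row, stride sx between features
  const double* b;   // background row, stride sb between features
  size_t sx, sb;
  double* phi;       // output row, stride sp between features
  size_t sp;
  double scale;
  const WeightTable* wt;
  std::vector<int> xs, bs;  // features required from x / from b on the path
};


static bool contains(const std::vector<int>& v, int f) {
  for (size_t i = 0; i < v.size(); ++i) if (v[i] == f) return true;
  return false;
}

static void recurse(PairCtx& c, int node) {
  const Tree& t = *c.t;
  if (t.left[node] < 0) {  // leaf
    int a = (int)c.xs.size(), d = (int)c.bs.size();
    if (a == 0 && d == 0) return;  // reached by both x and b: cancels
    double v = t.pred[node] * c.scale;
    size_t cell = (size_t)a * c.wt->stride + (size_t)d;
    if (a > 0) {
      double w = v * c.wt->wpos[cell];
      for (int i = 0; i < a; ++i) c.phi[c.sp * (size_t)c.xs[i]] += w;
    }
    if (d > 0) {
      double w = v * c.wt->wneg[cell];
      for (int i = 0; i < d; ++i) c.phi[c.sp * (size_t)c.bs[i]] -= w;
    }
    return;
  }
  int f = t.var[node];
  double thr = t.val[node];
  bool xl = c.x[c.sx * (size_t)f] <= thr;
  bool bl = c.b[c.sb * (size_t)f] <= thr;
  if (xl == bl) {  // feature irrelevant at this node
    recurse(c, xl ? t.left[node] : t.right[node]);
    return;
  }
  bool x_has = contains(c.xs, f), b_has = contains(c.bs, f);
  // branch satisfied by x only: f must be taken from x; contradiction if
  // an earlier condition on f was satisfiable only by b.
  if (!b_has) {
    bool added = false;
    if (!x_has) { c.xs.push_back(f); added = true; }
    recurse(c, xl ? t.left[node] : t.right[node]);
    if (added) c.xs.pop_back();
  }
  if (!x_has) {
    bool added = false;
    if (!b_has) { c.bs.push_back(f); added = true; }
    recurse(c, bl ? t.left[node] : t.right[node]);
    if (added) c.bs.pop_back();
  }
}

static double tree_predict(const Tree& t, const double* row, size_t stride) {
  int node = 0;
  while (t.left[node] >= 0) {
    node = (row[stride * (size_t)t.var[node]] <= t.val[node]) ? t.left[node]
                                                              : t.right[node];
  }
  return t.pred[node];
}

// trees: list of lists with integer vectors `left`, `right`, `var`
// (0-based node/feature ids, -1 at leaves) and numeric vectors `val`
// (split threshold; rule is x <= val goes left) and `pred` (leaf value,
// 0 at internal nodes).  X: foreground rows (n x p); B: background rows
// (m x p).  Returns list(phi = n x p, base = mean background forest
// prediction, pred = forest prediction on X).
// [[Rcpp::export]]
List cpp_forest_shap(List trees, NumericMatrix X, NumericMatrix B) {
  int n = X.nrow(), p = X.ncol(), m = B.nrow(), T = trees.size();
  if (B.ncol() != p) stop("foreground and background have different widths");
  if (m < 1 || T < 1) stop("need at least one background row and one tree");

  std::vector<Tree> forest((size_t)T);
  for (int ti = 0; ti < T; ++ti) {
    List tl = trees[ti];
    IntegerVector l = tl["left"], r = tl["right"], v = tl["var"];
    NumericVector val = tl["val"], pred = tl["pred"];
    Tree& t = forest[ti];
    t.left.assign(l.begin(), l.end());
    t.right.assign(r.begin(), r.end());
    t.var.assign(v.begin(), v.end());
    t.val.assign(val.begin(), val.end());
    t.pred.assign(pred.begin(), pred.end());
  }

  NumericMatrix phi(n, p);
  NumericVector pred_out(n);
  double base = 0.0;
  double scale = 1.0 / ((double)m * (double)T);

  const double* xbase = &X[0];
  const double* bbase = &B[0];
  double* pbase = &phi[0];

  // a + d is bounded by the number of distinct features on a path, hence
  // by the forest depth; size the weight table once for the whole call.
  int max_depth = 0;
  for (int ti = 0; ti < T; ++ti) {
    const Tree& t = forest[ti];
    std::vector<int> depth(t.left.size(), 0);
    for (size_t nd = 0; nd < t.left.size(); ++nd) {
      if (t.left[nd] >= 0) {
        depth[(size_t)t.left[nd]] = depth[nd] + 1;
        depth[(size_t)t.right[nd]] = depth[nd] + 1;
        if (depth[nd] + 1 > max_depth) max_depth = depth[nd] + 1;
      }
    }
  }
  WeightTable wt;
  wt.build(max_depth + 1);

  PairCtx c;
  c.sx = (size_t)n; c.sb = (size_t)m; c.sp = (size_t)n;
  c.scale = scale;
  c.wt = &wt;
  c.xs.reserve(64); c.bs.reserve(64);

  for (int ti = 0; ti < T; ++ti) {
    const Tree& t = forest[ti];
    c.t = &t;
    for (int bi = 0; bi < m; ++bi) {
      base += tree_predict(t, bbase + bi, (size_t)m) * scale;
    }
    for (int i = 0; i < n; ++i) {
      pred_out[i] += tree_predict(t, xbase + i, (size_t)n) / (double)T;
      c.x = xbase + i;
      c.phi = pbase + i;
      for (int bi = 0; bi < m; ++bi) {
        c.b = bbase + bi;
        c.xs.clear(); c.bs.clear();
        recurse(c, 0);
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["phi"] = phi, _["base"] = base, _["pred"] = pred_out);
}
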