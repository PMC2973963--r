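// Categorical base classifiers (gain-ratio decision tree, Hamming kNN,
// simplified KStar) and the cross-validated ensemble driver. All functions
// are deterministic; every tie-break is fixed:
//   - tree: attribute ties -> lowest column index; label ties -> control (0)
//   - kNN: distance ties -> training-row order; vote ties -> training-class
//     prior majority (prior tie -> control)
//   - KStar: class-weight ties -> training-class prior majority
// Category codes must lie in [0, MAXCAT); genotypes use only 0..2.
#include <Rcpp.h>
#include <cmath>
#include <array>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const int MAXCAT = 32;

static inline double entropy2(int n0, int n1) {
  int n = n0 + n1;
  if (n == 0) return 0.0;
  double e = 0.0;
  if (n0 > 0) { double p = (double)n0 / n; e -= p * std::log2(p); }
  if (n1 > 0) { double p = (double)n1 / n; e -= p * std::log2(p); }
  return e;
}

static inline int priorMajority(const std::vector<int>& y) {
  int n1 = 0;
  for (size_t i = 0; i < y.size(); ++i) n1 += y[i];
  int n0 = (int)y.size() - n1;
  return n1 > n0 ? 1 : 0;  // tie -> control
}

static void checkCodes(const IntegerMatrix& X) {
  for (int j = 0; j < X.ncol(); ++j)
    for (int i = 0; i < X.nrow(); ++i)
      if (X(i, j) < 0 || X(i, j) >= MAXCAT)
        stop("category codes must lie in [0, %d)", MAXCAT);
}

// ---------------------------------------------------------------------------
// Decision tree (gain-ratio, multiway categorical splits)

struct TreeNode {
  int attr;                      // splitting column, -1 for leaf
  int majority;                  // majority label at this node (tie -> 0)
  std::array<int, MAXCAT> child; // value -> node index, -1 unseen
  TreeNode() : attr(-1), majority(0) { child.fill(-1); }
};

struct Tree {
  std::vector<TreeNode> nodes;
};

// X: column-major training data (cols[j][row])
static int buildNode(Tree& tree,
                     const std::vector< std::vector<int> >& cols,
                     const std::vector<int>& y,
                     std::vector<int>& idx,
                     std::vector<char> used,
                     int depth, int maxDepth) {
  int me = (int)tree.nodes.size();
  tree.nodes.push_back(TreeNode());
  int n1 = 0;
  for (size_t i = 0; i < idx.size(); ++i) n1 += y[idx[i]];
  int n0 = (int)idx.size() - n1;
  tree.nodes[me].majority = n1 > n0 ? 1 : 0;
  if (n0 == 0 || n1 == 0) return me;              // pure
  if (maxDepth > 0 && depth >= maxDepth) return me;

  double nodeH = entropy2(n0, n1);
  double bestRatio = -1.0;
  int bestAttr = -1;
  int nAttr = (int)cols.size();
  int cnt0[MAXCAT], cnt1[MAXCAT];
  for (int a = 0; a < nAttr; ++a) {
    if (used[a]) continue;
    const std::vector<int>& col = cols[a];
    std::fill(cnt0, cnt0 + MAXCAT, 0);
    std::fill(cnt1, cnt1 + MAXCAT, 0);
    for (size_t i = 0; i < idx.size(); ++i) {
      int v = col[idx[i]];
      if (y[idx[i]]) ++cnt1[v]; else ++cnt0[v];
    }
    int nVals = 0;
    double condH = 0.0, splitInfo = 0.0;
    for (int v = 0; v < MAXCAT; ++v) {
      int nv = cnt0[v] + cnt1[v];
      if (nv == 0) continue;
      ++nVals;
      double w = (double)nv / idx.size();
      condH += w * entropy2(cnt0[v], cnt1[v]);
      splitInfo -= w * std::log2(w);
    }
    if (nVals < 2) continue;
    double gain = nodeH - condH;
    if (gain < 0) gain = 0;  // numeric noise
    double ratio = gain / splitInfo;  // splitInfo > 0: >= 2 values present
    if (ratio > bestRatio + 1e-12) { bestRatio = ratio; bestAttr = a; }
  }
  if (bestAttr < 0) return me;  // exhausted attributes

  used[bestAttr] = 1;
  std::vector<int> parts[MAXCAT];
  const std::vector<int>& col = cols[bestAttr];
  for (size_t i = 0; i < idx.size(); ++i)
    parts[col[idx[i]]].push_back(idx[i]);
  tree.nodes[me].attr = bestAttr;
  for (int v = 0; v < MAXCAT; ++v) {
    if (parts[v].empty()) continue;
    int ch = buildNode(tree, cols, y, parts[v], used, depth + 1, maxDepth);
    tree.nodes[me].child[v] = ch;
  }
  return me;
}

static int treeRoute(const Tree& tree, const int* row) {
  int cur = 0;
  for (;;) {
    const TreeNode& nd = tree.nodes[cur];
    if (nd.attr < 0) return nd.majority;
    int nxt = nd.child[row[nd.attr]];
    if (nxt < 0) return nd.majority;  // unseen category
    cur = nxt;
  }
}

// internal core over column-major training data and row-major test rows
static void treePredictCore(const std::vector< std::vector<int> >& cols,
                            const std::vector<int>& y,
                            const std::vector< std::vector<int> >& testRows,
                            int maxDepth, int* out) {
  int ntr = cols.empty() ? 0 : (int)cols[0].size();
  std::vector<int> idx(ntr);
  for (int i = 0; i < ntr; ++i) idx[i] = i;
  Tree tree;
  buildNode(tree, cols, y, idx, std::vector<char>(cols.size(), 0), 0,
            maxDepth);
  for (size_t i = 0; i < testRows.size(); ++i)
    out[i] = treeRoute(tree, testRows[i].data());
}

// ---------------------------------------------------------------------------
// kNN with Hamming (overlap) distance

// neighbour ordering for one test row: indices of the kmax nearest training
// rows by (distance, training-row order); rows are row-major vectors
static void nearestK(const std::vector< std::vector<int> >& trainRows,
                     const int* testRow, int p, int kmax,
                     std::vector<int>& outIdx) {
  int ntr = (int)trainRows.size();
  std::vector< std::pair<int,int> > best;  // (dist, index), sorted
  best.reserve(kmax + 1);
  int worst = p + 1;
  for (int t = 0; t < ntr; ++t) {
    const int* row = trainRows[t].data();
    int d = 0;
    for (int j = 0; j < p; ++j) d += (row[j] != testRow[j]);
    if ((int)best.size() == kmax && d >= worst) continue;
    std::pair<int,int> cand(d, t);
    best.insert(std::lower_bound(best.begin(), best.end(), cand), cand);
    if ((int)best.size() > kmax) best.pop_back();
    if ((int)best.size() == kmax) worst = best.back().first;
  }
  outIdx.clear();
  for (size_t i = 0; i < best.size(); ++i) outIdx.push_back(best[i].second);
}

static int voteK(const std::vector<int>& neigh, const std::vector<int>& y,
                 int k, int prior) {
  int used = std::min<int>(k, (int)neigh.size());
  int n1 = 0;
  for (int i = 0; i < used; ++i) n1 += y[neigh[i]];
  int n0 = used - n1;
  if (n1 > n0) return 1;
  if (n0 > n1) return 0;
  return prior;
}

// ---------------------------------------------------------------------------
// KStar, simplified to the categorical entropic transformation distance: an
// attribute value is transmitted intact with probability (1 - blend) and
// replaced by a uniform draw over the attribute's v training values with
// probability blend, giving per-attribute transformation probabilities
//   P(same) = 1 - blend + blend / v,  P(other) = blend / v.
// A test instance accumulates the product over attributes as the weight of
// each training instance (instance-weighted voting by class).

static void kstarPredictCore(const std::vector< std::vector<int> >& cols,
                             const std::vector<int>& y, int prior,
                             const std::vector< std::vector<int> >& trainRows,
                             const std::vector< std::vector<int> >& testRows,
                             double blend, int* out) {
  int p = (int)cols.size();
  std::vector<double> pSame(p), ratio(p);  // ratio = pDiff / pSame
  double baseW = 1.0;
  for (int j = 0; j < p; ++j) {
    char seen[MAXCAT] = {0};
    int v = 0;
    for (size_t i = 0; i < cols[j].size(); ++i)
      if (!seen[cols[j][i]]) { seen[cols[j][i]] = 1; ++v; }
    pSame[j] = 1.0 - blend + blend / v;
    ratio[j] = (blend / v) / pSame[j];
    baseW *= pSame[j];
  }
  int ntr = (int)trainRows.size();
  std::vector<double> w(ntr);
  for (size_t i = 0; i < testRows.size(); ++i) {
    const int* te = testRows[i].data();
    std::fill(w.begin(), w.end(), baseW);
    for (int j = 0; j < p; ++j) {
      const int* col = cols[j].data();
      const double sel[2] = { 1.0, ratio[j] };
      const int val = te[j];
      for (int t = 0; t < ntr; ++t) w[t] *= sel[col[t] != val];
    }
    double w0 = 0.0, w1 = 0.0;
    for (int t = 0; t < ntr; ++t) {
      if (y[t]) w1 += w[t]; else w0 += w[t];
    }
    out[i] = (w1 > w0) ? 1 : ((w0 > w1) ? 0 : prior);
  }
}

// ---------------------------------------------------------------------------
// conversions

static std::vector< std::vector<int> > matCols(const IntegerMatrix& X) {
  std::vector< std::vector<int> > cols(X.ncol());
  for (int j = 0; j < X.ncol(); ++j) {
    cols[j].resize(X.nrow());
    for (int i = 0; i < X.nrow(); ++i) cols[j][i] = X(i, j);
  }
  return cols;
}

static std::vector< std::vector<int> > matRows(const IntegerMatrix& X) {
  std::vector< std::vector<int> > rows(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) {
    rows[i].resize(X.ncol());
    for (int j = 0; j < X.ncol(); ++j) rows[i][j] = X(i, j);
  }
  return rows;
}

// ---------------------------------------------------------------------------
// exported single-classifier train+predict

// [[Rcpp::export]]
IntegerVector cppTreePredict(IntegerMatrix Xtr, IntegerVector ytr,
                             IntegerMatrix Xte, int maxDepth) {
  checkCodes(Xtr); checkCodes(Xte);
  std::vector<int> y(ytr.begin(), ytr.end());
  IntegerVector out(Xte.nrow());
  if (Xte.nrow() == 0) return out;
  std::vector< std::vector<int> > cols = matCols(Xtr);
  std::vector< std::vector<int> > te = matRows(Xte);
  std::vector<int> buf(te.size());
  treePredictCore(cols, y, te, maxDepth, buf.data());
  std::copy(buf.begin(), buf.end(), out.begin());
  return out;
}

// [[Rcpp::export]]
IntegerVector cppKnnPredict(IntegerMatrix Xtr, IntegerVector ytr,
                            IntegerMatrix Xte, int k) {
  checkCodes(Xtr); checkCodes(Xte);
  std::vector<int> y(ytr.begin(), ytr.end());
  int prior = priorMajority(y);
  IntegerVector out(Xte.nrow());
  std::vector< std::vector<int> > tr = matRows(Xtr);
  std::vector< std::vector<int> > te = matRows(Xte);
  std::vector<int> neigh;
  for (size_t i = 0; i < te.size(); ++i) {
    nearestK(tr, te[i].data(), Xtr.ncol(), k, neigh);
    out[i] = voteK(neigh, y, k, prior);
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cppKstarPredict(IntegerMatrix Xtr, IntegerVector ytr,
                              IntegerMatrix Xte, double blend) {
  checkCodes(Xtr); checkCodes(Xte);
  std::vector<int> y(ytr.begin(), ytr.end());
  int prior = priorMajority(y);
  IntegerVector out(Xte.nrow());
  if (Xte.nrow() == 0) return out;
  std::vector< std::vector<int> > cols = matCols(Xtr);
  std::vector< std::vector<int> > tr = matRows(Xtr);
  std::vector< std::vector<int> > te = matRows(Xte);
  std::vector<int> buf(te.size());
  kstarPredictCore(cols, y, prior, tr, te, blend, buf.data());
  std::copy(buf.begin(), buf.end(), out.begin());
  return out;
}

// ---------------------------------------------------------------------------
// Cross-validated ensemble driver: every classifier is trained on each
// training fold and predicts its held-out fold; predictions are pooled so
// each sample is predicted exactly once per classifier. kNN members share
// the neighbour ordering within a fold.
//
// kinds: 0 = decision_tree, 1 = knn, 2 = kstar
// param: maxDepth (tree, 0 = unlimited), k (knn), blend (kstar)

// [[Rcpp::export]]
IntegerMatrix cppCvEnsemble(IntegerMatrix X, IntegerVector y,
                            IntegerVector fold, IntegerVector kinds,
                            NumericVector param) {
  checkCodes(X);
  int n = X.nrow(), p = X.ncol(), M = kinds.size();
  IntegerMatrix out(n, M);
  int nFold = 0;
  for (int i = 0; i < n; ++i) nFold = std::max(nFold, fold[i]);
  int kmax = 0;
  bool anyTree = false, anyKstar = false;
  for (int s = 0; s < M; ++s) {
    if (kinds[s] == 1) kmax = std::max(kmax, (int)param[s]);
    if (kinds[s] == 0) anyTree = true;
    if (kinds[s] == 2) anyKstar = true;
  }
  std::vector< std::vector<int> > allRows = matRows(X);

  for (int f = 1; f <= nFold; ++f) {
    std::vector<int> trIdx, teIdx;
    for (int i = 0; i < n; ++i)
      (fold[i] == f ? teIdx : trIdx).push_back(i);
    if (teIdx.empty()) continue;
    int ntr = (int)trIdx.size(), nte = (int)teIdx.size();
    std::vector<int> ytr(ntr);
    std::vector< std::vector<int> > trRows(ntr), teRows(nte);
    std::vector< std::vector<int> > trCols(p, std::vector<int>(ntr));
    for (int i = 0; i < ntr; ++i) {
      ytr[i] = y[trIdx[i]];
      trRows[i] = allRows[trIdx[i]];
      for (int j = 0; j < p; ++j) trCols[j][i] = trRows[i][j];
    }
    for (int i = 0; i < nte; ++i) teRows[i] = allRows[teIdx[i]];
    int prior = priorMajority(ytr);

    std::vector<int> treePred(nte), kstarPred(nte);
    if (anyTree)
      treePredictCore(trCols, ytr, teRows, 0, treePred.data());
    if (anyKstar) {
      // all kstar members share one blend in practice; recompute if not
      double blend = -1.0;
      for (int s = 0; s < M; ++s) if (kinds[s] == 2) { blend = param[s]; break; }
      kstarPredictCore(trCols, ytr, prior, trRows, teRows, blend,
                       kstarPred.data());
    }
    std::vector< std::vector<int> > neigh;
    if (kmax > 0) {
      neigh.resize(nte);
      for (int i = 0; i < nte; ++i)
        nearestK(trRows, teRows[i].data(), p, kmax, neigh[i]);
    }
    for (int s = 0; s < M; ++s) {
      if (kinds[s] == 0) {
        std::vector<int> pr(nte);
        if (param[s] > 0)  // depth-limited member: rebuild
          treePredictCore(trCols, ytr, teRows, (int)param[s], pr.data());
        else pr = treePred;
        for (int i = 0; i < nte; ++i) out(teIdx[i], s) = pr[i];
      } else if (kinds[s] == 1) {
        for (int i = 0; i < nte; ++i)
          out(teIdx[i], s) = voteK(neigh[i], ytr, (int)param[s], prior);
      } else {
        std::vector<int> pr(nte);
        bool shared = true;
        double firstBlend = -1.0;
        for (int s2 = 0; s2 < M; ++s2)
          if (kinds[s2] == 2) { firstBlend = param[s2]; break; }
        shared = (param[s] == firstBlend);
        if (shared) pr = kstarPred;
        else kstarPredictCore(trCols, ytr, prior, trRows, teRows, param[s],
                              pr.data());
        for (int i = 0; i < nte; ++i) out(teIdx[i], s) = pr[i];
      }
    }
  }
  return out;
}
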