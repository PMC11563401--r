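// Multivariate random-forest regression trees. The split criterion sums,
// over traits, the reduction in within-node sum of squares normalized by
// the node's sum of squares for that trait, so traits on different scales
// contribute comparably. Tie-breaking is fully deterministic: candidate
// markers are scanned in increasing column order and thresholds in
// increasing value order, and a new best split must strictly improve the
// score. Randomness (bootstrap, mtry draws) uses R's RNG.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

struct TreeNode {
  int splitVar;    // -1 for leaf
  double threshold;
  int left, right; // child indices
  arma::rowvec leafMean;
};

static int sampleInt(int n) { // 0..n-1 via R RNG
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// sample `k` distinct values from 0..n-1 (partial Fisher-Yates), returned sorted
static std::vector<int> sampleWithout(int n, int k) {
  std::vector<int> pool(n);
  for (int i = 0; i < n; ++i) pool[i] = i;
  std::vector<int> out(k);
  for (int i = 0; i < k; ++i) {
    int j = i + sampleInt(n - i);
    std::swap(pool[i], pool[j]);
    out[i] = pool[i];
  }
  std::sort(out.begin(), out.end());
  return out;
}

struct BestSplit {
  int var = -1;
  double threshold = 0.0;
  double score = 0.0;
  bool found = false;
};

static void findSplit(const arma::mat& X, const arma::mat& Y,
                      const std::vector<int>& idx,
                      const std::vector<int>& tryVars,
                      int minNode, BestSplit& best) {
  const int nn = (int)idx.size();
  const int t = Y.n_cols;
  // node totals and sums of squares per trait
  arma::rowvec sumAll(t, arma::fill::zeros);
  arma::rowvec ssAll(t, arma::fill::zeros);
  for (int i = 0; i < nn; ++i) sumAll += Y.row(idx[i]);
  arma::rowvec meanAll = sumAll / nn;
  for (int i = 0; i < nn; ++i) {
    arma::rowvec d = Y.row(idx[i]) - meanAll;
    ssAll += d % d;
  }
  if (arma::accu(ssAll) <= 0) return; // pure node
  std::vector<std::pair<double, int> > ord(nn);
  for (int v : tryVars) {
    for (int i = 0; i < nn; ++i) ord[i] = std::make_pair(X(idx[i], v), idx[i]);
    std::stable_sort(ord.begin(), ord.end(),
                     [](const std::pair<double, int>& a,
                        const std::pair<double, int>& b) {
                       return a.first < b.first;
                     });
    arma::rowvec sumL(t, arma::fill::zeros), sqL(t, arma::fill::zeros);
    arma::rowvec sq2All(t, arma::fill::zeros);
    for (int i = 0; i < nn; ++i) {
      arma::rowvec yr = Y.row(ord[i].second);
      sq2All += yr % yr;
    }
    arma::rowvec sumR, sqR;
    for (int i = 0; i < nn - 1; ++i) {
      arma::rowvec yr = Y.row(ord[i].second);
      sumL += yr;
      sqL += yr % yr;
      if (ord[i + 1].first <= ord[i].first) continue; // not a cut point
      int nL = i + 1, nR = nn - nL;
      if (nL < minNode || nR < minNode) continue;
      sumR = sumAll - sumL;
      sqR = sq2All - sqL;
      double score = 0.0;
      for (int s = 0; s < t; ++s) {
        if (ssAll[s] <= 1e-300) continue;
        double ssl = sqL[s] - sumL[s] * sumL[s] / nL;
        double ssr = sqR[s] - sumR[s] * sumR[s] / nR;
        score += (ssAll[s] - ssl - ssr) / ssAll[s];
      }
      if (!best.found || score > best.score) {
        best.var = v;
        best.threshold = 0.5 * (ord[i].first + ord[i + 1].first);
        best.score = score;
        best.found = true;
      }
    }
  }
}

static int growNode(const arma::mat& X, const arma::mat& Y,
                    std::vector<int>& idx, int mtry, int minNode,
                    int maxDepth, int depth,
                    std::vector<TreeNode>& nodes) {
  const int t = Y.n_cols;
  TreeNode node;
  node.splitVar = -1;
  node.threshold = 0.0;
  node.left = node.right = -1;
  arma::rowvec mean(t, arma::fill::zeros);
  for (size_t i = 0; i < idx.size(); ++i) mean += Y.row(idx[i]);
  node.leafMean = mean / (double)idx.size();
  int self = (int)nodes.size();
  nodes.push_back(node);
  if ((int)idx.size() < 2 * minNode || (maxDepth > 0 && depth >= maxDepth))
    return self;
  std::vector<int> tryVars = sampleWithout(X.n_cols, mtry);
  BestSplit best;
  findSplit(X, Y, idx, tryVars, minNode, best);
  if (!best.found || best.score <= 0) return self;
  std::vector<int> li, ri;
  for (int i : idx) {
    if (X(i, best.var) <= best.threshold) li.push_back(i);
    else ri.push_back(i);
  }
  if (li.empty() || ri.empty()) return self;
  nodes[self].splitVar = best.var;
  nodes[self].threshold = best.threshold;
  int l = growNode(X, Y, li, mtry, minNode, maxDepth, depth + 1, nodes);
  int r = growNode(X, Y, ri, mtry, minNode, maxDepth, depth + 1, nodes);
  nodes[self].left = l;
  nodes[self].right = r;
  return self;
}

// Grow an ensemble. Returns a list of trees; each tree is a list with
// integer matrix `topo` (splitVar, left, right per node), numeric vector
// `threshold` and numeric matrix `leafMean`.
// [[Rcpp::export(name = ".mvrfGrow")]]
List mvrfGrow(const arma::mat& X, const arma::mat& Y, int nTrees, int mtry,
              int minNode, int maxDepth, bool bootstrap) {
  const int n = X.n_rows;
  List trees(nTrees);
  for (int b = 0; b < nTrees; ++b) {
    std::vector<int> idx(n);
    if (bootstrap) {
      for (int i = 0; i < n; ++i) idx[i] = sampleInt(n);
      std::sort(idx.begin(), idx.end()); // canonical order for determinism
    } else {
      for (int i = 0; i < n; ++i) idx[i] = i;
    }
    std::vector<TreeNode> nodes;
    growNode(X, Y, idx, mtry, minNode, maxDepth, 0, nodes);
    int nn = (int)nodes.size();
    IntegerMatrix topo(nn, 3);
    NumericVector thr(nn);
    NumericMatrix lm(nn, Y.n_cols);
    for (int i = 0; i < nn; ++i) {
      topo(i, 0) = nodes[i].splitVar;
      topo(i, 1) = nodes[i].left;
      topo(i, 2) = nodes[i].right;
      thr[i] = nodes[i].threshold;
      for (unsigned s = 0; s < Y.n_cols; ++s) lm(i, s) = nodes[i].leafMean[s];
    }
    trees[b] = List::create(Named("topo") = topo, Named("threshold") = thr,
                            Named("leafMean") = lm);
  }
  return trees;
}

// Average the tree outputs for new rows.
// [[Rcpp::export(name = ".mvrfPredict")]]
NumericMatrix mvrfPredict(List trees, const arma::mat& Xnew, int nTraits) {
  const int n = Xnew.n_rows;
  const int B = trees.size();
  NumericMatrix out(n, nTraits);
  for (int b = 0; b < B; ++b) {
    List tr = trees[b];
    IntegerMatrix topo = tr["topo"];
    NumericVector thr = tr["threshold"];
    NumericMatrix lm = tr["leafMean"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (topo(node, 0) >= 0) {
        node = (Xnew(i, topo(node, 0)) <= thr[node]) ? topo(node, 1)
                                                     : topo(node, 2);
      }
      for (int s = 0; s < nTraits; ++s) out(i, s) += lm(node, s);
    }
  }
  for (int i = 0; i < n; ++i)
    for (int s = 0; s < nTraits; ++s) out(i, s) /= B;
  return out;
}
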