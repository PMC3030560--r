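// Metropolis-Hastings engine for fixed-topology relaxed-clock dating.
//
// State: internal node ages, per-branch rates, clock hyperparameters
// (mu = mean rate, sigma = log-sd) and Yule birth rate lambda. The pruning
// likelihood (GTR+I+Gamma, eigendecomposition supplied by the caller) uses
// double-buffered per-node partials with dirty propagation so that a
// single-branch proposal only recomputes the path to the root. Uses R's
// RNG throughout, so runs are reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Engine {
  int ntip, nint, nn, nE, root, ncat, npat;
  std::vector<int> par, chi;          // per edge, 0-based nodes
  std::vector<int> edgeOfChild;       // node -> incoming edge (-1 for root)
  std::vector<std::vector<int>> childEdges;  // internal node -> 2 edge ids
  std::vector<int> postorder;         // internal nodes, children first
  std::vector<int> postIndex;         // node -> rank in postorder

  // model
  std::vector<double> U, Uinv, eval, pi;      // 4x4 (col-major), 4, 4
  std::vector<double> catRate, catWeight;
  std::vector<double> tipPartial;     // [tip][4*npat]
  std::vector<double> patWeight;

  // buffers
  std::vector<double> P;        // [edge][buf][cat][16]
  std::vector<double> partial;  // [intnode][buf][cat][4*npat]
  std::vector<double> scale;    // [intnode][buf][npat]
  std::vector<int> curP, curPart;
  std::vector<char> edgeDirty, nodeDirty;
  std::vector<int> dirtyEdges, dirtyNodes;

  // state
  std::vector<double> ages, rates;
  double mu, sigma, lambda;

  // calibrations + hyperpriors
  std::vector<int> calNode;
  std::vector<double> calMean, calSd;
  std::vector<int> calTrunc;
  double muMl, muSl, sigRate, lamMl, lamSl;

  bool priorOnly;

  int intIdx(int node) const { return node - ntip; }

  double* Pbuf(int e, int buf, int cat) {
    return &P[((size_t)e * 2 + buf) * ncat * 16 + (size_t)cat * 16];
  }
  double* partBuf(int node, int buf, int cat) {
    return &partial[(((size_t)intIdx(node) * 2 + buf) * ncat + cat) *
                    4 * npat];
  }
  double* scaleBuf(int node, int buf) {
    return &scale[((size_t)intIdx(node) * 2 + buf) * npat];
  }

  void buildTopology() {
    nn = ntip + nint;
    nE = (int)par.size();
    edgeOfChild.assign(nn, -1);
    childEdges.assign(nn, {});
    for (int e = 0; e < nE; ++e) {
      edgeOfChild[chi[e]] = e;
      childEdges[par[e]].push_back(e);
    }
    // postorder by DFS from root
    postorder.clear();
    std::vector<int> stack{root}, out;
    while (!stack.empty()) {
      int nd = stack.back(); stack.pop_back();
      out.push_back(nd);
      for (int e : childEdges[nd])
        if (chi[e] >= ntip) stack.push_back(chi[e]);
    }
    postorder.assign(out.rbegin(), out.rend());
    postIndex.assign(nn, -1);
    for (size_t i = 0; i < postorder.size(); ++i)
      postIndex[postorder[i]] = (int)i;
  }

  void computeP(int e, int buf) {
    double t = rates[e] * (ages[par[e]] - ages[chi[e]]);
    if (t < 0) t = 0;
    for (int c = 0; c < ncat; ++c) {
      double* Pm = Pbuf(e, buf, c);
      double ex[4];
      for (int k = 0; k < 4; ++k) ex[k] = std::exp(eval[k] * t * catRate[c]);
      for (int i = 0; i < 4; ++i)
        for (int j = 0; j < 4; ++j) {
          double v = 0;
          for (int k = 0; k < 4; ++k)
            v += U[i + 4 * k] * ex[k] * Uinv[k + 4 * j];
          Pm[i + 4 * j] = v > 0 ? v : 0;  // col-major? stored [i + 4j]
        }
    }
  }

  // effective buffer of a node/edge given dirty flags
  int effP(int e) const { return edgeDirty[e] ? 1 - curP[e] : curP[e]; }
  int effPart(int nd) const {
    return nodeDirty[nd] ? 1 - curPart[nd] : curPart[nd];
  }

  void computePartial(int node, int buf) {
    for (int c = 0; c < ncat; ++c) {
      double* out = partBuf(node, buf, c);
      bool first = true;
      for (int e : childEdges[node]) {
        int ch = chi[e];
        const double* Pm = Pbuf(e, effP(e), c);
        const double* cp = (ch < ntip)
          ? &tipPartial[(size_t)ch * 4 * npat]
          : partBuf(ch, effPart(ch), c);
        for (int s = 0; s < npat; ++s) {
          for (int i = 0; i < 4; ++i) {
            double v = 0;
            for (int j = 0; j < 4; ++j)
              v += Pm[i + 4 * j] * cp[j + 4 * s];
            if (first) out[i + 4 * s] = v;
            else out[i + 4 * s] *= v;
          }
        }
        first = false;
      }
    }
    // joint scaling across categories per pattern
    double* sc = scaleBuf(node, buf);
    for (int s = 0; s < npat; ++s) {
      double mx = 0;
      for (int c = 0; c < ncat; ++c) {
        const double* out = partBuf(node, buf, c);
        for (int i = 0; i < 4; ++i)
          mx = std::max(mx, out[i + 4 * s]);
      }
      if (mx > 0 && mx != 1.0) {
        for (int c = 0; c < ncat; ++c) {
          double* out = partBuf(node, buf, c);
          for (int i = 0; i < 4; ++i) out[i + 4 * s] /= mx;
        }
      }
      sc[s] = mx > 0 ? std::log(mx) : R_NegInf;
    }
  }

  double logLik() {
    if (priorOnly) return 0.0;
    double ll = 0;
    const int rootBuf = effPart(root);
    for (int s = 0; s < npat; ++s) {
      double site = 0;
      for (int c = 0; c < ncat; ++c) {
        const double* rp = partBuf(root, rootBuf, c);
        double v = 0;
        for (int i = 0; i < 4; ++i) v += pi[i] * rp[i + 4 * s];
        site += catWeight[c] * v;
      }
      double scl = 0;
      for (int nd = ntip; nd < nn; ++nd) scl += scaleBuf(nd, effPart(nd))[s];
      if (site <= 0 || !R_finite(scl)) return R_NegInf;
      ll += patWeight[s] * (std::log(site) + scl);
    }
    return ll;
  }

  double logPrior() {
    double T = ages[root];
    if (T <= 0) return R_NegInf;
    for (int e = 0; e < nE; ++e)
      if (ages[par[e]] < ages[chi[e]]) return R_NegInf;
    double lp = 0;
    double lamNorm = std::log1p(-std::exp(-lambda * T));
    for (int nd = ntip; nd < nn; ++nd) {
      if (nd == root) continue;
      lp += std::log(lambda) - lambda * ages[nd] - lamNorm;
    }
    for (size_t k = 0; k < calNode.size(); ++k) {
      double a = ages[calNode[k]];
      lp += R::dnorm(a, calMean[k], calSd[k], 1);
      if (calTrunc[k]) {
        if (a <= 0) return R_NegInf;
        lp -= R::pnorm(0.0, calMean[k], calSd[k], 0, 1);
      }
    }
    double ml = std::log(mu) - sigma * sigma / 2;
    for (int e = 0; e < nE; ++e)
      lp += R::dlnorm(rates[e], ml, sigma, 1);
    lp += R::dlnorm(mu, muMl, muSl, 1);
    lp += R::dexp(sigma, 1.0 / sigRate, 1);  // R::dexp takes the scale
    lp += R::dlnorm(lambda, lamMl, lamSl, 1);
    return lp;
  }

  void markEdgeDirty(int e) {
    if (!edgeDirty[e]) {
      edgeDirty[e] = 1;
      dirtyEdges.push_back(e);
    }
    // ancestors of the edge's parent node need recomputation, and so does
    // the parent itself
    int nd = par[e];
    while (nd != -1) {
      if (!nodeDirty[nd]) {
        nodeDirty[nd] = 1;
        dirtyNodes.push_back(nd);
      }
      int up = edgeOfChild[nd];
      nd = (up == -1) ? -1 : par[up];
    }
  }

  void recomputeDirty() {
    if (priorOnly) return;
    for (int e : dirtyEdges) computeP(e, 1 - curP[e]);
    std::sort(dirtyNodes.begin(), dirtyNodes.end(),
              [this](int a, int b) { return postIndex[a] < postIndex[b]; });
    for (int nd : dirtyNodes) computePartial(nd, 1 - curPart[nd]);
  }

  void commitDirty() {
    for (int e : dirtyEdges) { curP[e] = 1 - curP[e]; edgeDirty[e] = 0; }
    for (int nd : dirtyNodes) {
      curPart[nd] = 1 - curPart[nd];
      nodeDirty[nd] = 0;
    }
    dirtyEdges.clear();
    dirtyNodes.clear();
  }

  void discardDirty() {
    for (int e : dirtyEdges) edgeDirty[e] = 0;
    for (int nd : dirtyNodes) nodeDirty[nd] = 0;
    dirtyEdges.clear();
    dirtyNodes.clear();
  }
};

}  // namespace

// [[Rcpp::export(name = "run_clock_mcmc", rng = true)]]
List run_clock_mcmc(IntegerVector edgePar, IntegerVector edgeChild, int ntip,
                    List tipPartials, NumericVector patternWeights,
                    NumericMatrix U, NumericMatrix Uinv, NumericVector evals,
                    NumericVector pi,
                    NumericVector catRates, NumericVector catWeights,
                    IntegerVector calNodes, NumericVector calMeans,
                    NumericVector calSds, LogicalVector calTrunc,
                    NumericVector hyper,
                    NumericVector initAges, NumericVector initRates,
                    double initMu, double initSigma, double initLambda,
                    NumericVector moveWeights, NumericVector tuning,
                    double chainLength, double logEvery, bool priorOnly) {
  Engine eg;
  eg.ntip = ntip;
  eg.par.assign(edgePar.begin(), edgePar.end());
  eg.chi.assign(edgeChild.begin(), edgeChild.end());
  eg.nint = (int)initAges.size() - ntip;
  eg.root = ntip;
  eg.buildTopology();
  eg.ncat = (int)catRates.size();
  eg.priorOnly = priorOnly;

  eg.npat = priorOnly ? 1 : (int)patternWeights.size();
  eg.patWeight.assign(patternWeights.begin(), patternWeights.end());
  if (eg.patWeight.empty()) eg.patWeight.assign(1, 0.0);
  eg.tipPartial.assign((size_t)ntip * 4 * eg.npat, 1.0);
  if (!priorOnly) {
    for (int t = 0; t < ntip; ++t) {
      NumericMatrix tp = tipPartials[t];  // 4 x npat
      for (int s = 0; s < eg.npat; ++s)
        for (int i = 0; i < 4; ++i)
          eg.tipPartial[(size_t)t * 4 * eg.npat + 4 * s + i] = tp(i, s);
    }
  }
  eg.U.assign(U.begin(), U.end());        // column-major: U[i + 4k]
  eg.Uinv.assign(Uinv.begin(), Uinv.end());
  eg.eval.assign(evals.begin(), evals.end());
  eg.pi.assign(pi.begin(), pi.end());
  eg.catRate.assign(catRates.begin(), catRates.end());
  eg.catWeight.assign(catWeights.begin(), catWeights.end());

  eg.calNode.assign(calNodes.begin(), calNodes.end());
  eg.calMean.assign(calMeans.begin(), calMeans.end());
  eg.calSd.assign(calSds.begin(), calSds.end());
  eg.calTrunc.assign(calTrunc.begin(), calTrunc.end());
  eg.muMl = hyper[0]; eg.muSl = hyper[1]; eg.sigRate = hyper[2];
  eg.lamMl = hyper[3]; eg.lamSl = hyper[4];

  eg.ages.assign(initAges.begin(), initAges.end());
  eg.rates.assign(initRates.begin(), initRates.end());
  eg.mu = initMu; eg.sigma = initSigma; eg.lambda = initLambda;

  eg.P.assign((size_t)eg.nE * 2 * eg.ncat * 16, 0.0);
  eg.partial.assign((size_t)eg.nint * 2 * eg.ncat * 4 * eg.npat, 0.0);
  eg.scale.assign((size_t)eg.nint * 2 * eg.npat, 0.0);
  eg.curP.assign(eg.nE, 0);
  eg.curPart.assign(eg.nn, 0);
  eg.edgeDirty.assign(eg.nE, 0);
  eg.nodeDirty.assign(eg.nn, 0);

  // full initial evaluation into buffer 0
  if (!priorOnly) {
    for (int e = 0; e < eg.nE; ++e) eg.computeP(e, 0);
    for (int nd : eg.postorder) eg.computePartial(nd, 0);
  }
  double curLik = eg.logLik();
  double curPrior = eg.logPrior();

  const int nMoves = 9;
  std::vector<double> w(moveWeights.begin(), moveWeights.end());
  double wTot = 0;
  for (double v : w) wTot += v;
  std::vector<long> proposed(nMoves, 0), accepted(nMoves, 0);

  long nGen = (long)chainLength;
  long le = (long)logEvery;
  long nRows = nGen / le + 1;
  int nCols = 7 + eg.nint + eg.nE;
  NumericMatrix trace(nRows, nCols);
  long row = 0;
  auto logRow = [&](long gen) {
    trace(row, 0) = (double)gen;
    trace(row, 1) = curLik + curPrior;
    trace(row, 2) = curLik;
    trace(row, 3) = curPrior;
    trace(row, 4) = eg.mu;
    trace(row, 5) = eg.sigma;
    trace(row, 6) = eg.lambda;
    for (int k = 0; k < eg.nint; ++k)
      trace(row, 7 + k) = eg.ages[ntip + k];
    for (int e = 0; e < eg.nE; ++e)
      trace(row, 7 + eg.nint + e) = eg.rates[e];
    ++row;
  };
  logRow(0);

  double tunRoot = tuning[0], tunRate = tuning[1], tunMu = tuning[2],
         tunSigma = tuning[3], tunLambda = tuning[4],
         tunMuRate = tuning[5], tunUpDown = tuning[6], tunSpread = tuning[7];
  std::vector<double> savedAges, savedRates;
  double savedMu = 0, savedSigma = 0;

  for (long gen = 1; gen <= nGen; ++gen) {
    double r = unif_rand() * wTot, acc = 0;
    int move = 0;
    for (int k = 0; k < nMoves; ++k) {
      acc += w[k];
      if (r <= acc) { move = k; break; }
    }
    ++proposed[move];
    double logH = 0;
    bool likMove = false, valid = true;
    double oldVal = 0;
    int target = -1;

    switch (move) {
      case 0: {  // root age scale
        double s = std::exp(tunRoot * (unif_rand() - 0.5));
        oldVal = eg.ages[eg.root];
        double mx = 0;
        for (int e : eg.childEdges[eg.root])
          mx = std::max(mx, eg.ages[eg.chi[e]]);
        double nv = oldVal * s;
        if (nv <= mx) { valid = false; break; }
        eg.ages[eg.root] = nv;
        for (int e : eg.childEdges[eg.root]) eg.markEdgeDirty(e);
        logH = std::log(s);
        likMove = true;
        target = eg.root;
        break;
      }
      case 1: {  // internal node age slide
        if (eg.nint < 2) { valid = false; break; }
        int pick = 1 + (int)(unif_rand() * (eg.nint - 1));
        if (pick > eg.nint - 1) pick = eg.nint - 1;
        int nd = ntip + pick;  // skip root (= ntip)
        double lo = 0;
        for (int e : eg.childEdges[nd])
          lo = std::max(lo, eg.ages[eg.chi[e]]);
        double hi = eg.ages[eg.par[eg.edgeOfChild[nd]]];
        if (hi <= lo) { valid = false; break; }
        oldVal = eg.ages[nd];
        eg.ages[nd] = lo + unif_rand() * (hi - lo);
        for (int e : eg.childEdges[nd]) eg.markEdgeDirty(e);
        eg.markEdgeDirty(eg.edgeOfChild[nd]);
        likMove = true;
        target = nd;
        break;
      }
      case 2: {  // single branch-rate scale
        int e = (int)(unif_rand() * eg.nE);
        if (e >= eg.nE) e = eg.nE - 1;
        double s = std::exp(tunRate * (unif_rand() - 0.5));
        oldVal = eg.rates[e];
        eg.rates[e] = oldVal * s;
        eg.markEdgeDirty(e);
        logH = std::log(s);
        likMove = true;
        target = e;
        break;
      }
      case 3: {  // mu scale
        double s = std::exp(tunMu * (unif_rand() - 0.5));
        oldVal = eg.mu;
        eg.mu = oldVal * s;
        logH = std::log(s);
        break;
      }
      case 4: {  // sigma scale
        double s = std::exp(tunSigma * (unif_rand() - 0.5));
        oldVal = eg.sigma;
        eg.sigma = oldVal * s;
        logH = std::log(s);
        break;
      }
      case 5: {  // lambda scale
        double s = std::exp(tunLambda * (unif_rand() - 0.5));
        oldVal = eg.lambda;
        eg.lambda = oldVal * s;
        logH = std::log(s);
        break;
      }
      case 6: {  // joint mu + all-rates scale (keeps rate/mu ratios)
        double s = std::exp(tunMuRate * (unif_rand() - 0.5));
        savedMu = eg.mu;
        savedRates = eg.rates;
        eg.mu *= s;
        for (int e = 0; e < eg.nE; ++e) {
          eg.rates[e] *= s;
          eg.markEdgeDirty(e);
        }
        logH = (eg.nE + 1) * std::log(s);
        likMove = true;
        break;
      }
      case 7: {  // up-down: ages * s, (rates, mu) / s; likelihood invariant
        bool tipsAtZero = true;
        for (int t = 0; t < ntip; ++t)
          if (eg.ages[t] != 0) { tipsAtZero = false; break; }
        if (!tipsAtZero) { valid = false; break; }
        double s = std::exp(tunUpDown * (unif_rand() - 0.5));
        savedAges = eg.ages;
        savedRates = eg.rates;
        savedMu = eg.mu;
        for (int nd = ntip; nd < eg.nn; ++nd) eg.ages[nd] *= s;
        for (int e = 0; e < eg.nE; ++e) eg.rates[e] /= s;
        eg.mu /= s;
        logH = eg.nint * std::log(s) - (eg.nE + 1) * std::log(s);
        // branch expected substitutions are unchanged: no likelihood update
        break;
      }
      case 8: {  // rate-spread: sigma * s, log-rates spread by s around mean
        double s = std::exp(tunSpread * (unif_rand() - 0.5));
        savedSigma = eg.sigma;
        savedRates = eg.rates;
        double mlog = 0;
        for (int e = 0; e < eg.nE; ++e) mlog += std::log(eg.rates[e]);
        mlog /= eg.nE;
        eg.sigma *= s;
        for (int e = 0; e < eg.nE; ++e) {
          eg.rates[e] = std::exp(mlog + s * (std::log(eg.rates[e]) - mlog));
          eg.markEdgeDirty(e);
        }
        logH = eg.nE * std::log(s);
        likMove = true;
        break;
      }
    }

    bool doAccept = false;
    if (valid) {
      double newPrior = eg.logPrior();
      double newLik = curLik;
      if (likMove && !priorOnly) {
        eg.recomputeDirty();
        newLik = eg.logLik();
      }
      double logAlpha = (newLik - curLik) + (newPrior - curPrior) + logH;
      if (R_finite(newPrior) &&
          (logAlpha >= 0 || std::log(unif_rand()) < logAlpha)) {
        doAccept = true;
        curLik = newLik;
        curPrior = newPrior;
      }
    }
    if (doAccept) {
      eg.commitDirty();
      ++accepted[move];
    } else {
      eg.discardDirty();
      switch (move) {  // restore the touched scalar
        case 0: if (valid) eg.ages[eg.root] = oldVal; break;
        case 1: if (valid) eg.ages[target] = oldVal; break;
        case 2: if (valid) eg.rates[target] = oldVal; break;
        case 3: eg.mu = oldVal; break;
        case 4: eg.sigma = oldVal; break;
        case 5: eg.lambda = oldVal; break;
        case 6: eg.mu = savedMu; eg.rates = savedRates; break;
        case 7:
          if (valid) {
            eg.ages = savedAges;
            eg.rates = savedRates;
            eg.mu = savedMu;
          }
          break;
        case 8: eg.sigma = savedSigma; eg.rates = savedRates; break;
      }
    }
    if (gen % le == 0) logRow(gen);
  }

  return List::create(
      Named("trace") = trace,
      Named("proposed") = NumericVector(proposed.begin(), proposed.end()),
      Named("accepted") = NumericVector(accepted.begin(), accepted.end()));
}
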