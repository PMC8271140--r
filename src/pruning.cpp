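// Core numerics: transition matrices for reversible models, Felsenstein
// pruning (batched over sites), marginal ancestral posteriors, stochastic
// (Gillespie) site simulation along a tree, and the null-site score sampler.
//
// Conventions shared with the R layer:
//  - `edge` is an ape edge matrix reordered "postorder" (children before
//    parents) for pruning, "cladewise" (parents before children) for
//    simulation; node numbers are 1-based as in ape (tips 1..nTip, root
//    nTip+1).
//  - transition-probability cubes are indexed by edge row.
//  - tip states are 0-based alphabet indices; -1 encodes missing data
//    (all-ones partial likelihood).
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// P(t) = D^{-1/2} U exp(L t) U' D^{1/2} from the symmetric eigen system of a
// reversible rate matrix; eigen round-off can give tiny negatives, clamped.
// [[Rcpp::export]]
arma::cube cpp_pmats(const arma::mat& U, const arma::vec& lam,
                     const arma::vec& sqrtpi, const arma::vec& len) {
  const arma::uword s = U.n_rows, ne = len.n_elem;
  arma::cube P(s, s, ne);
  const arma::mat Dl = arma::diagmat(1.0 / sqrtpi);
  const arma::mat Dr = arma::diagmat(sqrtpi);
  for (arma::uword e = 0; e < ne; ++e) {
    arma::mat M = U * arma::diagmat(arma::exp(lam * len(e))) * U.t();
    arma::mat Pe = Dl * M * Dr;
    Pe.transform([](double x) { return x > 0.0 ? x : 0.0; });
    P.slice(e) = Pe;
  }
  return P;
}

// Postorder up-pass with per-site log scaling.  D: s x nSites x nNodes
// conditional (downward) partials; logsc: nSites x nNodes accumulated log
// scale factors.  When `P2`/`useP2` are given, edge e uses P2 if useP2[e].
static void up_pass(const IntegerMatrix& edge, int nNodes,
                    const arma::cube& P1, const arma::cube* P2,
                    const IntegerVector* useP2,
                    const IntegerMatrix& tipStates,
                    arma::cube& D, arma::mat& logsc) {
  const int s = P1.n_rows;
  const int nSites = tipStates.ncol(), nTip = tipStates.nrow();
  D.set_size(s, nSites, nNodes);
  D.ones();
  logsc.zeros(nSites, nNodes);
  for (int t = 0; t < nTip; ++t) {
    for (int j = 0; j < nSites; ++j) {
      int st = tipStates(t, j);
      if (st >= 0) {
        D.slice(t).col(j).zeros();
        D.slice(t)(st, j) = 1.0;
      }
    }
  }
  const int ne = edge.nrow();
  for (int e = 0; e < ne; ++e) {
    int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
    const arma::mat& Pe = (P2 != nullptr && (*useP2)[e]) ? P2->slice(e)
                                                         : P1.slice(e);
    arma::mat msg = Pe * D.slice(c);
    D.slice(p) %= msg;
    logsc.col(p) += logsc.col(c);
    arma::rowvec m = arma::max(D.slice(p), 0);
    for (int j = 0; j < nSites; ++j) {
      double mm = m(j);
      if (mm > 0.0 && mm != 1.0) {
        D.slice(p).col(j) /= mm;
        logsc(j, p) += std::log(mm);
      }
    }
  }
}

static arma::vec root_loglik(const arma::cube& D, const arma::mat& logsc,
                             const arma::vec& rootPrior, int rootIdx) {
  const int nSites = D.n_cols;
  arma::vec ll(nSites);
  for (int j = 0; j < nSites; ++j)
    ll(j) = std::log(arma::dot(rootPrior, D.slice(rootIdx).col(j))) +
            logsc(j, rootIdx);
  return ll;
}

// [[Rcpp::export]]
arma::vec cpp_prune(const IntegerMatrix& edge, int nNodes, const arma::cube& P,
                    const IntegerMatrix& tipStates, const arma::vec& rootPrior) {
  arma::cube D;
  arma::mat sc;
  up_pass(edge, nNodes, P, nullptr, nullptr, tipStates, D, sc);
  int root = edge(edge.nrow() - 1, 0) - 1;
  return root_loglik(D, sc, rootPrior, root);
}

// Pruning where foreground edges (isFg[e] != 0) use Pfg and the rest Pbg;
// used by the branch-class profile models.
// [[Rcpp::export]]
arma::vec cpp_prune_mixed(const IntegerMatrix& edge, int nNodes,
                          const arma::cube& Pbg, const arma::cube& Pfg,
                          const IntegerVector& isFg,
                          const IntegerMatrix& tipStates,
                          const arma::vec& rootPrior) {
  arma::cube D;
  arma::mat sc;
  up_pass(edge, nNodes, Pbg, &Pfg, &isFg, tipStates, D, sc);
  int root = edge(edge.nrow() - 1, 0) - 1;
  return root_loglik(D, sc, rootPrior, root);
}

// Two-pass marginal posteriors.  Returns 0-based MAP states (first argmax =
// lowest alphabet index on ties), the posterior of the MAP state, per-site
// log-likelihoods, and optionally the full posterior cube.
// [[Rcpp::export]]
List cpp_marginal(const IntegerMatrix& edge, int nNodes, const arma::cube& P,
                  const IntegerMatrix& tipStates, const arma::vec& rootPrior,
                  bool full = false) {
  arma::cube D;
  arma::mat sc;
  up_pass(edge, nNodes, P, nullptr, nullptr, tipStates, D, sc);
  const int s = P.n_rows, nSites = tipStates.ncol(), ne = edge.nrow();
  const int root = edge(ne - 1, 0) - 1;
  arma::vec ll = root_loglik(D, sc, rootPrior, root);

  // "above" partials, normalised per node/site (scale cancels in posterior)
  arma::cube A(s, nSites, nNodes, arma::fill::zeros);
  A.slice(root).each_col() = rootPrior;
  for (int e = ne - 1; e >= 0; --e) {
    int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
    arma::mat msg = P.slice(e) * D.slice(c);
    msg.transform([](double x) { return x > 0.0 ? x : 1e-300; });
    arma::mat T = (A.slice(p) % D.slice(p)) / msg;
    arma::mat Ac = P.slice(e).t() * T;
    arma::rowvec m = arma::sum(Ac, 0);
    m.transform([](double x) { return x > 0.0 ? x : 1.0; });
    Ac.each_row() /= m;
    A.slice(c) = Ac;
  }

  IntegerMatrix map(nNodes, nSites);
  NumericMatrix mapp(nNodes, nSites);
  arma::cube post;
  if (full) post.set_size(s, nSites, nNodes);
  for (int v = 0; v < nNodes; ++v) {
    arma::mat Pv = A.slice(v) % D.slice(v);
    arma::rowvec m = arma::sum(Pv, 0);
    m.transform([](double x) { return x > 0.0 ? x : 1.0; });
    Pv.each_row() /= m;
    if (full) post.slice(v) = Pv;
    for (int j = 0; j < nSites; ++j) {
      double best = -1.0;
      int bi = 0;
      for (int i = 0; i < s; ++i)
        if (Pv(i, j) > best) { best = Pv(i, j); bi = i; }
      map(v, j) = bi;
      mapp(v, j) = best;
    }
  }
  List out = List::create(_["map"] = map, _["mapProb"] = mapp,
                          _["logLik"] = ll);
  if (full) out["posterior"] = post;
  return out;
}

// Site log-likelihoods across a grid of rate multipliers (per-site rate ML).
// [[Rcpp::export]]
arma::mat cpp_loglik_grid(const IntegerMatrix& edge, int nNodes,
                          const arma::mat& U, const arma::vec& lam,
                          const arma::vec& sqrtpi, const arma::vec& len,
                          const arma::vec& rates,
                          const IntegerMatrix& tipStates,
                          const arma::vec& rootPrior) {
  const int nSites = tipStates.ncol(), nr = rates.n_elem;
  arma::mat out(nSites, nr);
  for (int r = 0; r < nr; ++r) {
    arma::cube P = cpp_pmats(U, lam, sqrtpi, len * rates(r));
    out.col(r) = cpp_prune(edge, nNodes, P, tipStates, rootPrior);
  }
  return out;
}

// Per-site Gillespie simulation along the tree.  `edge`/`len` must be in
// cladewise (parent-before-child) order.  Uses R's RNG, so results are
// reproducible under set.seed().  Returns node states (0-based) and the full
// jump history (1-based site, child node id of the branch, from, to).
// [[Rcpp::export]]
List cpp_sim_sites(const IntegerMatrix& edge, const arma::vec& len, int nNodes,
                   const arma::mat& Q, const arma::vec& siteRates,
                   const arma::vec& rootProbs) {
  const int s = Q.n_rows, nSites = siteRates.n_elem, ne = edge.nrow();
  IntegerMatrix nodeStates(nNodes, nSites);
  std::vector<int> evSite, evChild, evFrom, evTo;
  const int root = edge(0, 0) - 1;
  for (int j = 0; j < nSites; ++j) {
    double u = unif_rand();
    int st = s - 1;
    double acc = 0.0;
    for (int i = 0; i < s; ++i) {
      acc += rootProbs(i);
      if (u <= acc) { st = i; break; }
    }
    nodeStates(root, j) = st;
    const double r = siteRates(j);
    for (int e = 0; e < ne; ++e) {
      int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
      int cur = nodeStates(p, j);
      double t = 0.0;
      const double L = len(e);
      if (r > 0.0) {
        for (;;) {
          double out = -Q(cur, cur) * r;
          if (out <= 0.0) break;
          t += -std::log(unif_rand()) / out;
          if (t >= L) break;
          double u2 = unif_rand() * (-Q(cur, cur));
          double a = 0.0;
          int nxt = -1;
          for (int kk = 0; kk < s; ++kk) {
            if (kk == cur) continue;
            a += Q(cur, kk);
            if (u2 <= a) { nxt = kk; break; }
          }
          if (nxt < 0) {
            for (int kk = s - 1; kk >= 0; --kk)
              if (kk != cur && Q(cur, kk) > 0) { nxt = kk; break; }
          }
          if (nxt < 0) break;
          evSite.push_back(j + 1);
          evChild.push_back(c + 1);
          evFrom.push_back(cur);
          evTo.push_back(nxt);
          cur = nxt;
        }
      }
      nodeStates(c, j) = cur;
    }
  }
  return List::create(_["nodeStates"] = nodeStates,
                      _["site"] = wrap(evSite), _["child"] = wrap(evChild),
                      _["from"] = wrap(evFrom), _["to"] = wrap(evTo));
}

// Null-site score sampler.  For each site, k[j] substitution events are
// placed on distinct branches with probability proportional to branch
// length; event states follow a random walk over a uniform nAA-symbol
// alphabet.  Scores against the fixed phenotype event set are returned for
// all three approaches (columns: convergence, gwas, all-changes), each
// maximised over candidate foreground amino acids.
// [[Rcpp::export]]
IntegerMatrix cpp_null_scores(const arma::vec& bl, const IntegerVector& gain,
                              const IntegerVector& loss,
                              const IntegerVector& k, int nAA) {
  const int nb = bl.n_elem, nSites = k.size();
  IntegerMatrix out(nSites, 3);
  std::vector<double> w(nb);
  std::vector<int> convCnt(nAA), gwasCnt(nAA);
  for (int j = 0; j < nSites; ++j) {
    double tot = 0.0;
    for (int b = 0; b < nb; ++b) { w[b] = bl(b); tot += w[b]; }
    int kk = std::min<int>(k[j], nb);
    std::fill(convCnt.begin(), convCnt.end(), 0);
    std::fill(gwasCnt.begin(), gwasCnt.end(), 0);
    int allScore = 0;
    int cur = (int)(unif_rand() * nAA);
    if (cur >= nAA) cur = nAA - 1;
    for (int d = 0; d < kk; ++d) {
      double u = unif_rand() * tot, a = 0.0;
      int pick = -1;
      for (int b = 0; b < nb; ++b) {
        if (w[b] <= 0.0) continue;
        a += w[b];
        if (u <= a) { pick = b; break; }
      }
      if (pick < 0) {
        for (int b = nb - 1; b >= 0; --b)
          if (w[b] > 0.0) { pick = b; break; }
      }
      if (pick < 0) break;
      tot -= w[pick];
      w[pick] = 0.0;
      int nxt = (int)(unif_rand() * (nAA - 1));
      if (nxt >= nAA - 1) nxt = nAA - 2;
      if (nxt >= cur) nxt += 1;
      const int from = cur, to = nxt;
      cur = nxt;
      if (gain[pick]) { convCnt[to]++; gwasCnt[to]++; }
      if (loss[pick]) gwasCnt[from]++;
      if (gain[pick] || loss[pick]) allScore++;
    }
    int cb = 0, gb = 0;
    for (int a2 = 0; a2 < nAA; ++a2) {
      if (convCnt[a2] > cb) cb = convCnt[a2];
      if (gwasCnt[a2] > gb) gb = gwasCnt[a2];
    }
    out(j, 0) = cb;
    out(j, 1) = gb;
    out(j, 2) = allScore;
  }
  return out;
}
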