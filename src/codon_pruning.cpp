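// Felsenstein pruning for codon models. The rate matrices are reversible
// with respect to pi, so each Q is symmetrised as
// S = diag(sqrt(pi)) Q diag(1/sqrt(pi)) and decomposed once per call;
// P(t) = diag(1/sqrt(pi)) U exp(L t) U' diag(sqrt(pi)). Per-site partial
// likelihoods are rescaled by their column maxima to avoid underflow.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// edge: nedge x 2 (parent, child), 1-based node ids in postorder (children
//   before parents), root = ntip + 1 (ape convention).
// blen: branch length per edge (expected substitutions per codon).
// tipstates: ntip x nsites, 0-based codon state, -1 = gap/missing.
// Qcube: nstate x nstate x M scaled generator matrices.
// Qidx: nedge x K, 1-based slice of Qcube used by each edge in each
//   mixture class.
// pi: stationary distribution, length nstate.
// Returns K x nsites per-site per-class log-likelihoods.
// [[Rcpp::export]]
arma::mat codon_class_siteloglik(const arma::imat& edge,
                                 const arma::vec& blen,
                                 const arma::imat& tipstates,
                                 const arma::cube& Qcube,
                                 const arma::imat& Qidx,
                                 const arma::vec& pi) {
  const uword nedge = edge.n_rows;
  const uword ntip = tipstates.n_rows;
  const uword nsites = tipstates.n_cols;
  const uword ns = pi.n_elem;
  const uword K = Qidx.n_cols;
  const uword M = Qcube.n_slices;
  uword nnode = ntip;
  for (uword e = 0; e < nedge; ++e) {
    if ((uword)edge(e, 0) > nnode) nnode = edge(e, 0);
    if ((uword)edge(e, 1) > nnode) nnode = edge(e, 1);
  }

  vec d = sqrt(pi);
  vec dinv = 1.0 / d;

  // eigendecompose each slice once
  std::vector<vec> lam(M);
  std::vector<mat> U(M);
  for (uword m = 0; m < M; ++m) {
    mat S = Qcube.slice(m);
    S.each_col() %= d;      // diag(d) * Q
    S.each_row() %= dinv.t();  // ... * diag(1/d)
    S = 0.5 * (S + S.t());  // guard symmetry against rounding
    vec l; mat u;
    eig_sym(l, u, S);
    lam[m] = l; U[m] = u;
  }

  mat out(K, nsites);
  for (uword k = 0; k < K; ++k) {
    std::vector<mat> L(nnode + 1);
    std::vector<bool> has(nnode + 1, false);
    rowvec logscale(nsites, fill::zeros);

    for (uword e = 0; e < nedge; ++e) {
      uword p = edge(e, 0), c = edge(e, 1);
      uword m = Qidx(e, k) - 1;
      // P(t) = diag(1/d) U exp(lam t) U' diag(d)
      mat E = U[m];
      E.each_row() %= exp(lam[m].t() * blen(e));
      mat P = E * U[m].t();
      P.each_col() %= dinv;
      P.each_row() %= d.t();
      P.elem(find(P < 0)).zeros();  // clip rounding negatives

      mat Mc(ns, nsites);
      if (c <= ntip) {
        for (uword s = 0; s < nsites; ++s) {
          int st = tipstates(c - 1, s);
          if (st < 0) Mc.col(s).ones();
          else Mc.col(s) = P.col(st);
        }
      } else {
        Mc = P * L[c];
      }
      rowvec mx = max(Mc, 0);
      mx.elem(find(mx <= 0)).ones();  // dead columns stay zero
      Mc.each_row() /= mx;
      logscale += log(mx);
      if (!has[p]) { L[p] = Mc; has[p] = true; }
      else L[p] %= Mc;
    }

    uword root = ntip + 1;
    rowvec rootlik = pi.t() * L[root];
    for (uword s = 0; s < nsites; ++s)
      out(k, s) = std::log(rootlik(s)) + logscale(s);
  }
  return out;
}
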