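// Felsenstein pruning likelihood for GTR + discrete gamma on a fixed
// rooted binary tree.  Branch lengths arrive already multiplied by the
// per-branch clock rate (expected substitutions/site); gamma category
// multipliers scale them per site class.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Eigen-decomposition of the reversible GTR rate matrix, normalized so the
// stationary mean rate is 1.  Returns U, U^{-1} and eigenvalues such that
// P(t) = U diag(exp(lambda t)) Uinv.
static void gtr_eigen(const vec &exch, const vec &pi,
                      mat &U, mat &Uinv, vec &lambda) {
  mat R(4, 4, fill::zeros);
  R(0,1) = R(1,0) = exch(0); // AC
  R(0,2) = R(2,0) = exch(1); // AG
  R(0,3) = R(3,0) = exch(2); // AT
  R(1,2) = R(2,1) = exch(3); // CG
  R(1,3) = R(3,1) = exch(4); // CT
  R(2,3) = R(3,2) = exch(5); // GT
  mat Q = R * diagmat(pi);
  Q.diag() = -sum(Q, 1);
  double mu = -dot(pi, Q.diag());
  Q /= mu;
  vec sq = sqrt(pi);
  mat B = diagmat(sq) * Q * diagmat(1.0 / sq);
  B = 0.5 * (B + B.t());
  mat V;
  eig_sym(lambda, V, B);
  U = diagmat(1.0 / sq) * V;
  Uinv = V.t() * diagmat(sq);
}

// [[Rcpp::export]]
arma::mat gtr_pmat_cpp(const arma::vec &exch, const arma::vec &pi, double t) {
  mat U, Uinv; vec lam;
  gtr_eigen(exch, pi, U, Uinv, lam);
  return U * diagmat(exp(lam * t)) * Uinv;
}

// masks: ntaxa x npat integer matrix of IUPAC bit masks (A=1,C=2,G=4,T=8).
// edge: nedge x 2 (parent, child), 1-based ape numbering, in postorder
// (every child's subtree complete before its edge is processed).
// blen: expected substitutions/site per edge.
// Returns sum_i w_i * log( (1/K) sum_k P(site i | category k) ).
// [[Rcpp::export]]
double pruning_loglik_cpp(const arma::imat &masks,
                          const arma::vec &weights,
                          const arma::imat &edge,
                          const arma::vec &blen,
                          const arma::vec &exch,
                          const arma::vec &pi,
                          const arma::vec &gamma_rates) {
  const uword ntip = masks.n_rows, npat = masks.n_cols;
  const uword nedge = edge.n_rows, ncat = gamma_rates.n_elem;
  const uword nnode = nedge + 1;          // total nodes in a rooted tree
  const uword root = ntip;                // 0-based index of node ntip+1

  mat U, Uinv; vec lam;
  gtr_eigen(exch, pi, U, Uinv, lam);

  // per-category per-pattern log-likelihoods
  mat catll(ncat, npat, fill::zeros);

  // tip partials are shared across categories
  mat tipPart(4, npat);
  cube tips(4, npat, ntip);
  for (uword s = 0; s < ntip; ++s) {
    for (uword j = 0; j < npat; ++j) {
      int m = masks(s, j);
      for (uword a = 0; a < 4; ++a)
        tips(a, j, s) = (m >> a) & 1 ? 1.0 : 0.0;
    }
  }

  for (uword k = 0; k < ncat; ++k) {
    cube part(4, npat, nnode, fill::ones);
    rowvec logscale(npat, fill::zeros);
    for (uword e = 0; e < nedge; ++e) {
      uword p = edge(e, 0) - 1, c = edge(e, 1) - 1;
      double t = blen(e) * gamma_rates(k);
      mat P = U * diagmat(exp(lam * t)) * Uinv;
      P.clamp(0.0, 1.0);  // roundoff can leave tiny negatives at t ~ 0
      mat contrib = c < ntip ? mat(P * tips.slice(c)) : mat(P * part.slice(c));
      part.slice(p) %= contrib;
      // rescale the parent once its second child arrives (cheap heuristic:
      // rescale every time; max per column)
      rowvec mx = max(part.slice(p), 0);
      for (uword j = 0; j < npat; ++j) {
        if (mx(j) > 0 && mx(j) < 1e-80) {
          part.slice(p).col(j) /= mx(j);
          logscale(j) += std::log(mx(j));
        }
      }
    }
    rowvec sitelik = pi.t() * part.slice(root);
    for (uword j = 0; j < npat; ++j)
      catll(k, j) = sitelik(j) > 0 ?
        std::log(sitelik(j)) + logscale(j) : -datum::inf;
  }

  // log-mean-exp over categories, weighted sum over patterns
  double total = 0.0;
  for (uword j = 0; j < npat; ++j) {
    double m = -datum::inf;
    for (uword k = 0; k < ncat; ++k)
      if (catll(k, j) > m) m = catll(k, j);
    if (!std::isfinite(m)) return -datum::inf;
    double s = 0.0;
    for (uword k = 0; k < ncat; ++k) s += std::exp(catll(k, j) - m);
    total += weights(j) * (m + std::log(s / ncat));
  }
  return total;
}
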