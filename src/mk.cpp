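// Mk (k-state continuous-time Markov) likelihood core.
//
// The pruning (post-order conditional likelihood) pass is the hot loop of the
// whole package: it sits inside every optimizer call of every model x tree
// grid cell, so it lives here rather than in R.  Transition probabilities
// P(t) = exp(Qt) are computed by eigendecomposition when the eigenvector
// matrix is well conditioned and by scaling-and-squaring otherwise (masked
// absorbing-state matrices are often defective); the equal-rates (ER) model
// has a closed form and bypasses both.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

namespace {

class PmatEngine {
public:
  PmatEngine(const mat& Q_, double er_rate_) :
    k(Q_.n_rows), Q(Q_), er_rate(er_rate_), use_eig(false) {
    if (er_rate < 0.0) {
      cx_vec eval;
      cx_mat evec;
      if (eig_gen(eval, evec, Q)) {
        cx_mat Vi;
        if (inv(Vi, evec)) {
          double c = cond(evec);
          if (std::isfinite(c) && c < 1e8) {
            V = evec; Vinv = Vi; ev = eval; use_eig = true;
          }
        }
      }
    }
  }

  mat pmat(double t) const {
    if (t <= 0.0) return eye(k, k);
    mat P;
    if (er_rate >= 0.0) {
      // ER: eigenvalues 0 and -k*q; P_ij = 1/k + (delta_ij - 1/k) exp(-k q t)
      double e = std::exp(-static_cast<double>(k) * er_rate * t);
      P.set_size(k, k);
      P.fill((1.0 - e) / k);
      P.diag() += e;
    } else if (use_eig) {
      P = real(V * diagmat(exp(ev * t)) * Vinv);
    } else {
      P = expmat(Q * t);
    }
    P.clamp(0.0, 1.0);
    return P;
  }

private:
  unsigned int k;
  mat Q;
  double er_rate;
  bool use_eig;
  cx_mat V, Vinv;
  cx_vec ev;
};

} // namespace

// [[Rcpp::export]]
arma::mat mk_pmat_cpp(const arma::mat& Q, const double t, const double er_rate) {
  PmatEngine eng(Q, er_rate);
  return eng.pmat(t);
}

// Felsenstein pruning over a post-order edge list (multifurcations allowed).
// edge: ape-style 2-column matrix (parent, child), 1-based, post-order.
// tipL: ntip x k matrix of tip conditional likelihoods (indicator rows).
// root prior: explicit vector, or FitzJohn data-conditional weights.
// [[Rcpp::export]]
Rcpp::List mk_prune_cpp(const arma::umat& edge, const arma::vec& elen,
                        const int ntip, const int nnode,
                        const arma::mat& tipL, const arma::mat& Q,
                        const arma::vec& prior, const bool fitzjohn,
                        const double er_rate) {
  const unsigned int k = Q.n_rows;
  const unsigned int ntot = ntip + nnode;
  PmatEngine eng(Q, er_rate);

  mat L(ntot, k, fill::ones);
  L.rows(0, ntip - 1) = tipL;
  double logsc = 0.0;
  const unsigned int ne = edge.n_rows;

  for (unsigned int e = 0; e < ne; ++e) {
    const unsigned int p = edge(e, 0) - 1;
    const unsigned int c = edge(e, 1) - 1;
    const mat P = eng.pmat(elen(e));
    vec v = P * L.row(c).t();
    const double m = v.max();
    if (!(m > 0.0) || !std::isfinite(m)) {
      return Rcpp::List::create(Rcpp::Named("loglik") = R_NegInf,
                                Rcpp::Named("root_partial") = Rcpp::NumericVector(k));
    }
    v /= m;
    logsc += std::log(m);
    L.row(p) %= v.t();
  }

  const unsigned int root = edge(ne - 1, 0) - 1;
  const rowvec Lr = L.row(root);
  double lik;
  if (fitzjohn) {
    const double s = accu(Lr);
    lik = (s > 0.0) ? dot(Lr, Lr) / s : 0.0;
  } else {
    lik = dot(prior, Lr.t());
  }
  const double ll = (lik > 0.0) ? std::log(lik) + logsc : R_NegInf;
  return Rcpp::List::create(Rcpp::Named("loglik") = ll,
                            Rcpp::Named("root_partial") = Rcpp::wrap(Lr));
}
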