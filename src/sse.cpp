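// State-dependent speciation-extinction (MuSSE/BiSSE family) likelihood core.
//
// Per-branch coupled ODEs (k extinction probabilities E_i, k data
// probabilities D_i) integrated tip-to-root with an adaptive Cash-Karp
// Runge-Kutta 4(5) scheme; node joins multiply D by the per-state speciation
// rate.  k = 1 reduces to the constant-rate birth-death likelihood, which the
// R layer uses both directly and for factorization checks.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

namespace {

struct SsePars {
  unsigned int k;
  vec la, mu, s; // s_i = la_i + mu_i + sum_j q_ij
  mat Qo;        // off-diagonal transition rates, zero diagonal
};

inline void sse_deriv(const SsePars& P, const vec& y, vec& dy) {
  const unsigned int k = P.k;
  const vec E = y.head(k);
  const vec D = y.tail(k);
  dy.head(k) = P.mu - P.s % E + P.Qo * E + P.la % E % E;
  dy.tail(k) = -(P.s % D) + P.Qo * D + 2.0 * (P.la % E % D);
}

// Cash-Karp RK45 with adaptive step-size control.
vec integrate_branch(const SsePars& P, vec y, const double t,
                     const double rtol, const double atol) {
  if (t <= 0.0) return y;
  const unsigned int n = y.n_elem;
  double x = 0.0;
  // initial step: bounded by branch length and by the fastest rate
  double rmax = std::max(P.s.max(), 1e-8);
  double h = std::min(t, 0.1 / rmax);

  vec k1(n), k2(n), k3(n), k4(n), k5(n), k6(n), ytmp(n), y5(n), yerr(n);

  const int MAXSTEP = 1000000;
  for (int it = 0; it < MAXSTEP; ++it) {
    if (x >= t) break;
    if (x + h > t) h = t - x;

    sse_deriv(P, y, k1);
    ytmp = y + h * (0.2 * k1);
    sse_deriv(P, ytmp, k2);
    ytmp = y + h * ((3.0 / 40.0) * k1 + (9.0 / 40.0) * k2);
    sse_deriv(P, ytmp, k3);
    ytmp = y + h * (0.3 * k1 - 0.9 * k2 + 1.2 * k3);
    sse_deriv(P, ytmp, k4);
    ytmp = y + h * ((-11.0 / 54.0) * k1 + 2.5 * k2 - (70.0 / 27.0) * k3 +
                    (35.0 / 27.0) * k4);
    sse_deriv(P, ytmp, k5);
    ytmp = y + h * ((1631.0 / 55296.0) * k1 + (175.0 / 512.0) * k2 +
                    (575.0 / 13824.0) * k3 + (44275.0 / 110592.0) * k4 +
                    (253.0 / 4096.0) * k5);
    sse_deriv(P, ytmp, k6);

    y5 = y + h * ((37.0 / 378.0) * k1 + (250.0 / 621.0) * k3 +
                  (125.0 / 594.0) * k4 + (512.0 / 1771.0) * k6);
    yerr = h * ((37.0 / 378.0 - 2825.0 / 27648.0) * k1 +
                (250.0 / 621.0 - 18575.0 / 48384.0) * k3 +
                (125.0 / 594.0 - 13525.0 / 55296.0) * k4 +
                (-277.0 / 14336.0) * k5 +
                (512.0 / 1771.0 - 0.25) * k6);

    double err = 0.0;
    for (unsigned int i = 0; i < n; ++i) {
      const double sc = atol + rtol * std::max(std::fabs(y(i)), std::fabs(y5(i)));
      err = std::max(err, std::fabs(yerr(i)) / sc);
    }

    if (err <= 1.0) {
      x += h;
      y = y5;
      // keep the system in its physical region: E in [0,1], D >= 0
      // (overshoot of E above 1 makes the quadratic term explosive)
      for (unsigned int i = 0; i < P.k; ++i) {
        if (y(i) < 0.0) y(i) = 0.0;
        if (y(i) > 1.0) y(i) = 1.0;
        if (y(P.k + i) < 0.0) y(P.k + i) = 0.0;
      }
      const double g = (err > 1e-12) ? 0.9 * std::pow(err, -0.2) : 5.0;
      h *= std::min(5.0, std::max(0.2, g));
    } else {
      h *= std::max(0.1, 0.9 * std::pow(err, -0.25));
    }
    if (h < 1e-14 * std::max(t, 1.0)) {
      // hopeless region of parameter space (stiff blow-up); signal an
      // invalid likelihood rather than aborting the optimizer
      y.fill(datum::nan);
      return y;
    }
  }
  return y;
}

} // namespace

// Integrate (E_1..E_k, D_1..D_k) along one branch of length t.
// [[Rcpp::export]]
arma::vec sse_branch_cpp(const arma::vec& y0, const double t,
                         const arma::vec& la, const arma::vec& mu,
                         const arma::mat& Qo,
                         const double rtol, const double atol) {
  SsePars P{static_cast<unsigned int>(la.n_elem), la, mu,
            la + mu + sum(Qo, 1), Qo};
  return integrate_branch(P, y0, t, rtol, atol);
}

// Full-tree MuSSE likelihood over a post-order edge list (binary trees).
// root_mode: 0 = explicit prior weights, 1 = FitzJohn (D-proportional).
// cond_surv: divide D_i by la_i (1 - E_i)^2 at the root before weighting.
// [[Rcpp::export]]
Rcpp::List musse_prune_cpp(const arma::umat& edge, const arma::vec& elen,
                           const int ntip, const int nnode,
                           const arma::mat& tipD, const arma::mat& tipE,
                           const arma::vec& la, const arma::vec& mu,
                           const arma::mat& Qo,
                           const int root_mode, const arma::vec& prior,
                           const bool cond_surv,
                           const double rtol, const double atol) {
  const unsigned int k = la.n_elem;
  const unsigned int ntot = ntip + nnode;
  SsePars P{k, la, mu, la + mu + sum(Qo, 1), Qo};

  mat D(ntot, k, fill::ones), E(ntot, k, fill::zeros);
  D.rows(0, ntip - 1) = tipD;
  E.rows(0, ntip - 1) = tipE;
  uvec nch(ntot, fill::zeros);

  double logsc = 0.0;
  const unsigned int ne = edge.n_rows;

  for (unsigned int e = 0; e < ne; ++e) {
    const unsigned int p = edge(e, 0) - 1;
    const unsigned int c = edge(e, 1) - 1;
    vec y(2 * k);
    y.head(k) = E.row(c).t();
    y.tail(k) = D.row(c).t();
    y = integrate_branch(P, y, elen(e), rtol, atol);
    vec Ee = clamp(y.head(k), 0.0, 1.0);
    vec De = y.tail(k);
    De.transform([](double v) { return v < 0.0 ? 0.0 : v; });
    const double m = De.max();
    if (!(m > 0.0) || !std::isfinite(m)) {
      return Rcpp::List::create(Rcpp::Named("loglik") = R_NegInf);
    }
    De /= m;
    logsc += std::log(m);
    D.row(p) %= De.t();
    if (nch(p) == 0) {
      E.row(p) = Ee.t();
    } else {
      // join: one speciation-rate factor per merge, applied before the
      // parent's own branch is integrated
      E.row(p) = 0.5 * (E.row(p) + Ee.t());
      D.row(p) %= la.t();
    }
    nch(p) += 1;
  }

  const unsigned int root = edge(ne - 1, 0) - 1;
  rowvec Dr = D.row(root);
  const rowvec Er = E.row(root);

  vec w(k);
  if (root_mode == 1) {
    const double s = accu(Dr);
    if (!(s > 0.0)) {
      return Rcpp::List::create(Rcpp::Named("loglik") = R_NegInf);
    }
    w = Dr.t() / s;
  } else {
    w = prior;
  }

  vec Dri = Dr.t();
  if (cond_surv) {
    const vec denom = la % square(1.0 - Er.t());
    Dri /= denom;
  }
  const double lik = dot(w, Dri);
  const double ll = (lik > 0.0 && std::isfinite(lik)) ? std::log(lik) + logsc
                                                      : R_NegInf;
  return Rcpp::List::create(Rcpp::Named("loglik") = ll,
                            Rcpp::Named("root_D") = Rcpp::wrap(Dr),
                            Rcpp::Named("root_E") = Rcpp::wrap(Er));
}
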