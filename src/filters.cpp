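// Exact-inference primitives for linear-Gaussian state-space models and
// discrete Markov chains. These are the inner loops of the variational
// fixed-point iterations, so they are written in Armadillo.
//
// Time convention throughout: the state x_t is indexed t = 0..T with
// x_0 ~ N(mu, Q0) carrying no observation; y_t runs t = 1..T.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;

static arma::mat symm(const arma::mat& A) { return 0.5 * (A + A.t()); }

static double logdet_sym(const arma::mat& A) {
  double val, sign;
  bool ok = arma::log_det(val, sign, symm(A));
  if (!ok || sign <= 0.0) stop("non positive-definite matrix in log-determinant");
  return val;
}

// Kalman filter with per-time responsibility weights h_t scaling the
// observation noise as R / h_t. Implemented in a form that never divides by
// h_t: the innovation covariance is computed as S~ = h * G P G' + R, so the
// h -> 0 limit (skip the measurement update) is handled exactly once h drops
// below eps. Log-likelihood increments are for the effective noise R / h_t.
// [[Rcpp::export]]
List kf_cpp(const arma::vec& mu, const arma::mat& Q0, const arma::mat& F,
            const arma::mat& Q, const arma::mat& G, const arma::mat& R,
            const arma::mat& y, const arma::vec& h, double eps) {
  const arma::uword T = y.n_rows, p = y.n_cols, d = mu.n_elem;

  arma::mat x_filt(d, T + 1), x_pred(d, T);
  arma::cube P_filt(d, d, T + 1), P_pred(d, d, T);
  arma::vec ll(T, arma::fill::zeros);
  arma::uvec skipped(T, arma::fill::zeros);

  arma::vec xf = mu;
  arma::mat Pf = symm(Q0);
  x_filt.col(0) = xf;
  P_filt.slice(0) = Pf;
  const arma::mat Id = arma::eye(d, d);

  for (arma::uword t = 0; t < T; ++t) {
    arma::vec xp = F * xf;
    arma::mat Pp = symm(F * Pf * F.t() + Q);
    x_pred.col(t) = xp;
    P_pred.slice(t) = Pp;

    double ht = h(t);
    if (ht < eps) {
      xf = xp;
      Pf = Pp;
      skipped(t) = 1;
    } else {
      arma::mat GP = G * Pp;                       // p x d
      arma::mat St = symm(ht * GP * G.t() + R);    // h * G P G' + R
      arma::mat Sti;
      if (!arma::inv_sympd(Sti, St)) stop("singular innovation covariance");
      arma::vec innov = y.row(t).t() - G * xp;
      arma::mat Kt = GP.t() * Sti;                 // K = h * Kt
      xf = xp + ht * (Kt * innov);
      arma::mat ImKG = Id - ht * (Kt * G);
      Pf = symm(ImKG * Pp * ImKG.t() + ht * (Kt * R * Kt.t()));
      ll(t) = -0.5 * (p * LOG2PI + logdet_sym(St) - p * std::log(ht) +
                      ht * arma::as_scalar(innov.t() * Sti * innov));
    }
    x_filt.col(t + 1) = xf;
    P_filt.slice(t + 1) = Pf;
  }

  return List::create(
      _["x_filt"] = x_filt, _["P_filt"] = P_filt, _["x_pred"] = x_pred,
      _["P_pred"] = P_pred, _["ll"] = ll, _["loglik"] = arma::accu(ll),
      _["skipped"] = skipped);
}

// RTS smoother with lag-one cross covariances
// Cov(x_t, x_{t-1} | y_{1:T}) = Sigma_{t|T} J_{t-1}'.
// [[Rcpp::export]]
List rts_cpp(const arma::mat& F, const arma::mat& x_filt,
             const arma::cube& P_filt, const arma::mat& x_pred,
             const arma::cube& P_pred) {
  const arma::uword T = x_pred.n_cols, d = x_filt.n_rows;
  arma::mat x_sm(d, T + 1);
  arma::cube P_sm(d, d, T + 1), P_lag(d, d, T);

  x_sm.col(T) = x_filt.col(T);
  P_sm.slice(T) = P_filt.slice(T);

  for (arma::uword t = T; t >= 1; --t) {
    arma::mat Ppi;
    if (!arma::inv_sympd(Ppi, symm(P_pred.slice(t - 1))))
      stop("singular predicted covariance in smoother");
    arma::mat J = P_filt.slice(t - 1) * F.t() * Ppi;  // J_{t-1}
    x_sm.col(t - 1) =
        x_filt.col(t - 1) + J * (x_sm.col(t) - x_pred.col(t - 1));
    P_sm.slice(t - 1) = symm(
        P_filt.slice(t - 1) +
        J * (P_sm.slice(t) - P_pred.slice(t - 1)) * J.t());
    P_lag.slice(t - 1) = P_sm.slice(t) * J.t();
  }

  return List::create(_["x_sm"] = x_sm, _["P_sm"] = P_sm, _["P_lag"] = P_lag);
}

// Leave-one-out (interpolated) predictive log-densities by a two-filter
// construction: the forward predictive N(x_t | y_{1:t-1}) is fused with a
// backward information-form likelihood message from y_{t+1:T}, and the result
// pushed through the observation equation. Requires Q, R positive definite.
// [[Rcpp::export]]
arma::vec interp_cpp(const arma::vec& mu, const arma::mat& Q0,
                     const arma::mat& F, const arma::mat& Q,
                     const arma::mat& G, const arma::mat& R,
                     const arma::mat& y) {
  const arma::uword T = y.n_rows, p = y.n_cols, d = mu.n_elem;

  // forward pass: predicted moments given y_{1:t-1}
  arma::mat xp_all(d, T);
  arma::cube Pp_all(d, d, T);
  {
    arma::vec xf = mu;
    arma::mat Pf = symm(Q0);
    for (arma::uword t = 0; t < T; ++t) {
      arma::vec xp = F * xf;
      arma::mat Pp = symm(F * Pf * F.t() + Q);
      xp_all.col(t) = xp;
      Pp_all.slice(t) = Pp;
      arma::mat St = symm(G * Pp * G.t() + R);
      arma::mat Sti;
      if (!arma::inv_sympd(Sti, St)) stop("singular innovation covariance");
      arma::mat K = Pp * G.t() * Sti;
      xf = xp + K * (y.row(t).t() - G * xp);
      arma::mat ImKG = arma::eye(d, d) - K * G;
      Pf = symm(ImKG * Pp * ImKG.t() + K * R * K.t());
    }
  }

  // backward information-form messages: p(y_{t+1:T} | x_t) up to a constant,
  // parameterized as exp(-x' Lam x / 2 + eta' x)
  arma::mat Qi, Ri;
  if (!arma::inv_sympd(Qi, symm(Q))) stop("state noise covariance must be positive definite");
  if (!arma::inv_sympd(Ri, symm(R))) stop("observation noise covariance must be positive definite");
  const arma::mat GtRiG = G.t() * Ri * G;
  const arma::mat FtQi = F.t() * Qi;

  arma::cube Lam_all(d, d, T);
  arma::mat eta_all(d, T);
  arma::mat Lam(d, d, arma::fill::zeros);
  arma::vec eta(d, arma::fill::zeros);
  for (arma::uword t = T; t >= 1; --t) {
    Lam_all.slice(t - 1) = Lam;  // message excludes y_t
    eta_all.col(t - 1) = eta;
    // absorb y_t, then propagate backward through the dynamics
    arma::mat Lams = Lam + GtRiG;
    arma::vec etas = eta + G.t() * (Ri * y.row(t - 1).t());
    arma::mat Pinv = symm(Qi + Lams);
    arma::mat Pc;
    if (!arma::inv_sympd(Pc, Pinv)) stop("singular matrix in backward message");
    Lam = symm(FtQi * F - FtQi * Pc * Qi * F);
    eta = FtQi * (Pc * etas);
  }

  arma::vec out(T);
  for (arma::uword t = 0; t < T; ++t) {
    arma::mat Ppi;
    if (!arma::inv_sympd(Ppi, symm(Pp_all.slice(t))))
      stop("singular predicted covariance");
    arma::mat Pc;
    if (!arma::inv_sympd(Pc, symm(Ppi + Lam_all.slice(t))))
      stop("singular fused precision");
    arma::vec mc = Pc * (Ppi * xp_all.col(t) + eta_all.col(t));
    arma::mat S = symm(G * Pc * G.t() + R);
    arma::mat Si;
    if (!arma::inv_sympd(Si, S)) stop("singular predictive covariance");
    arma::vec r = y.row(t).t() - G * mc;
    out(t) = -0.5 * (p * LOG2PI + logdet_sym(S) +
                     arma::as_scalar(r.t() * Si * r));
  }
  return out;
}

static double lse(const arma::vec& v) {
  double m = v.max();
  if (!std::isfinite(m)) return m;  // all -inf
  return m + std::log(arma::accu(arma::exp(v - m)));
}

// Log-domain forward-backward for a chain s_0..s_T where s_0 carries no
// emission; logg holds emission log-weights for t = 1..T. logphi(m, n) is the
// log-probability of moving from state n (column) to state m (row).
// [[Rcpp::export]]
List fb_cpp(const arma::mat& logg, const arma::vec& logrho,
            const arma::mat& logphi) {
  const arma::uword T = logg.n_rows, M = logg.n_cols;
  arma::mat la(T + 1, M), lb(T + 1, M, arma::fill::zeros);
  la.row(0) = logrho.t();

  for (arma::uword t = 1; t <= T; ++t) {
    for (arma::uword m = 0; m < M; ++m) {
      arma::vec v = logphi.row(m).t() + la.row(t - 1).t();
      la(t, m) = logg(t - 1, m) + lse(v);
    }
  }
  for (arma::uword t = T; t >= 1; --t) {
    for (arma::uword n = 0; n < M; ++n) {
      arma::vec v = logphi.col(n) + logg.row(t - 1).t() + lb.row(t).t();
      lb(t - 1, n) = lse(v);
    }
  }

  double logZ = lse(la.row(T).t());
  double logZ0 = lse((la.row(0) + lb.row(0)).t());
  if (!std::isfinite(logZ)) stop("all states vetoed: degenerate evidence");

  arma::mat post = arma::exp(la + lb - logZ);  // rows t = 0..T
  // renormalize rows against accumulated rounding
  post.each_col() /= arma::sum(post, 1);

  arma::cube pair(M, M, T);
  for (arma::uword t = 1; t <= T; ++t) {
    for (arma::uword m = 0; m < M; ++m)
      for (arma::uword n = 0; n < M; ++n)
        pair(m, n, t - 1) = std::exp(la(t - 1, n) + logphi(m, n) +
                                     logg(t - 1, m) + lb(t, m) - logZ);
    pair.slice(t - 1) /= arma::accu(pair.slice(t - 1));
  }

  return List::create(_["h"] = post.rows(1, T), _["p0"] = post.row(0).t(),
                      _["pairwise"] = pair, _["log_alpha"] = la,
                      _["log_beta"] = lb, _["logZ"] = logZ,
                      _["logZ_backward"] = logZ0);
}

// Viterbi decoding under the same conventions; returns the MAP path for
// t = 1..T (1-based states).
// [[Rcpp::export]]
arma::uvec viterbi_cpp(const arma::mat& logg, const arma::vec& logrho,
                       const arma::mat& logphi) {
  const arma::uword T = logg.n_rows, M = logg.n_cols;
  arma::mat delta(T + 1, M);
  arma::umat back(T + 1, M, arma::fill::zeros);
  delta.row(0) = logrho.t();

  for (arma::uword t = 1; t <= T; ++t) {
    for (arma::uword m = 0; m < M; ++m) {
      arma::vec v = logphi.row(m).t() + delta.row(t - 1).t();
      arma::uword amax = v.index_max();
      delta(t, m) = logg(t - 1, m) + v(amax);
      back(t, m) = amax;
    }
  }
  arma::uvec path(T);
  arma::uword cur = delta.row(T).index_max();
  for (arma::uword t = T; t >= 1; --t) {
    path(t - 1) = cur + 1;
    cur = back(t, cur);
  }
  return path;
}
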