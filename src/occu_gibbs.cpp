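// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

double rpg1(double zin);  // pg.cpp

// Gibbs sampler for the multi-season single-species occupancy model
//
//   z_it ~ Bernoulli(psi_it),            logit(psi) = X beta
//   y_ijt | z_it ~ Bernoulli(z_it p_ijt), logit(p)  = W alpha + eta_obs
//   eta_o ~ Normal(0, sigma2),           sigma2 ~ InvGamma(shape, scale)
//
// Units ("site-years") are the rows of X; visits are the rows of W and are
// grouped contiguously by site-year. Both logistic submodels are updated by
// Polya-Gamma augmentation with conjugate Gaussian draws; the latent z at
// undetected site-years by its conditional Bernoulli; sigma2 by its
// conjugate inverse-gamma. Linear predictors are clipped at +/- `clip`
// before exponentiation.

static inline double clipv(double x, double c) {
  return x > c ? c : (x < -c ? -c : x);
}

// draw from N(Prec^{-1} rhs, Prec^{-1})
static arma::vec mvn_draw(const arma::mat& prec, const arma::vec& rhs) {
  arma::mat U = arma::chol(prec);  // U'U = prec
  arma::vec m = arma::solve(arma::trimatu(U),
                            arma::solve(arma::trimatl(U.t()), rhs));
  arma::vec zr(rhs.n_elem);
  for (arma::uword i = 0; i < zr.n_elem; ++i) zr(i) = R::norm_rand();
  return m + arma::solve(arma::trimatu(U), zr);
}

// marginal (over z) log-likelihood of one site-year given its visit
// detection linear predictors
static double unit_loglik(double occ_lp, const arma::vec& det_lp,
                          const arma::ivec& yv, bool detected) {
  double lpsi = -std::log1p(std::exp(-occ_lp));      // log psi
  double l1mpsi = -std::log1p(std::exp(occ_lp));     // log(1 - psi)
  if (det_lp.n_elem == 0) return 0.0;                // no data, no contribution
  double s = 0.0, logq = 0.0;
  for (arma::uword j = 0; j < det_lp.n_elem; ++j) {
    double lp = det_lp(j);
    double lgp = -std::log1p(std::exp(-lp));         // log p
    double lg1mp = -std::log1p(std::exp(lp));        // log(1 - p)
    s += yv(j) ? lgp : lg1mp;
    logq += lg1mp;
  }
  if (detected) return lpsi + s;
  // all-zero history: psi * prod(1-p) + (1 - psi)
  double a = lpsi + logq;
  double m = std::max(a, l1mpsi);
  return m + std::log(std::exp(a - m) + std::exp(l1mpsi - m));
}

//' @noRd
// [[Rcpp::export(name = ".occu_gibbs_cpp")]]
List occu_gibbs_cpp(const arma::mat& X, const arma::mat& W,
                    const arma::ivec& vis_start, const arma::ivec& vis_count,
                    const arma::ivec& y, const arma::ivec& obs_idx,
                    int n_observer,
                    int n_iter, int n_burn, int n_thin,
                    double beta_var, double alpha_var,
                    double ig_shape, double ig_scale,
                    double clip) {
  const int U = X.n_rows, P = X.n_cols, V = W.n_rows, Q = W.n_cols;
  const bool has_obs = n_observer > 0;

  arma::ivec detected(U, arma::fill::zeros);
  for (int u = 0; u < U; ++u)
    for (int j = 0; j < vis_count(u); ++j)
      if (y(vis_start(u) + j)) { detected(u) = 1; break; }

  // state, mildly dispersed initial values drawn from R's RNG so that
  // chains started sequentially differ
  arma::vec beta(P), alpha(Q);
  for (int k = 0; k < P; ++k) beta(k) = 0.5 * R::norm_rand();
  for (int k = 0; k < Q; ++k) alpha(k) = 0.5 * R::norm_rand();
  arma::vec eta(std::max(n_observer, 1), arma::fill::zeros);
  double sig2 = 1.0;
  arma::ivec z(U);
  for (int u = 0; u < U; ++u)
    z(u) = detected(u) ? 1 : (R::unif_rand() < 0.5 ? 1 : 0);

  const int n_keep = (n_iter - n_burn) / n_thin;
  arma::mat beta_out(n_keep, P), alpha_out(n_keep, Q);
  arma::mat eta_out(n_keep, has_obs ? n_observer : 0);
  arma::vec sig2_out(n_keep, arma::fill::zeros);
  arma::imat z_out(n_keep, U);
  arma::mat ll_out(n_keep, U);

  const arma::mat B0 = arma::eye(P, P) / beta_var;
  const arma::mat A0 = arma::eye(Q, Q) / alpha_var;

  arma::vec occ_lp(U), det_lp(V), walpha(V);
  int keep = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // linear predictors under current state
    occ_lp = X * beta;
    walpha = W * alpha;
    for (int v = 0; v < V; ++v) {
      double lp = walpha(v) + (has_obs ? eta(obs_idx(v)) : 0.0);
      det_lp(v) = clipv(lp, clip);
    }
    for (int u = 0; u < U; ++u) occ_lp(u) = clipv(occ_lp(u), clip);

    // -- latent occupancy state at undetected site-years
    for (int u = 0; u < U; ++u) {
      if (detected(u)) { z(u) = 1; continue; }
      double logq = 0.0;
      for (int j = 0; j < vis_count(u); ++j)
        logq += -std::log1p(std::exp(det_lp(vis_start(u) + j)));
      double psi = 1.0 / (1.0 + std::exp(-occ_lp(u)));
      double num = psi * std::exp(logq);
      double pr = num / (num + 1.0 - psi);
      z(u) = (R::unif_rand() < pr) ? 1 : 0;
    }

    // -- occupancy coefficients (PG augmentation over all site-years)
    {
      arma::vec om(U);
      for (int u = 0; u < U; ++u) om(u) = rpg1(occ_lp(u));
      arma::mat prec = X.t() * (X.each_col() % om) + B0;
      arma::vec kap(U);
      for (int u = 0; u < U; ++u) kap(u) = z(u) - 0.5;
      beta = mvn_draw(prec, X.t() * kap);
    }

    // -- detection coefficients (visits at currently occupied site-years)
    {
      arma::vec om(V, arma::fill::zeros);
      arma::uvec active(V, arma::fill::zeros);
      for (int u = 0; u < U; ++u) {
        if (!z(u)) continue;
        for (int j = 0; j < vis_count(u); ++j) {
          int v = vis_start(u) + j;
          active(v) = 1;
          om(v) = rpg1(det_lp(v));
        }
      }
      // inactive visits have om = 0 and are zeroed in kappa, so the
      // whole-matrix products only accumulate active visits
      arma::vec kap(V, arma::fill::zeros);
      for (int v = 0; v < V; ++v) {
        if (!active(v)) continue;
        double e = has_obs ? eta(obs_idx(v)) : 0.0;
        kap(v) = y(v) - 0.5 - om(v) * e;
      }
      arma::mat prec = W.t() * (W.each_col() % om) + A0;
      alpha = mvn_draw(prec, W.t() * kap);

      if (has_obs) {
        walpha = W * alpha;
        arma::vec oprec(n_observer), orhs(n_observer, arma::fill::zeros);
        oprec.fill(1.0 / sig2);
        for (int v = 0; v < V; ++v) {
          if (!active(v)) continue;
          int o = obs_idx(v);
          oprec(o) += om(v);
          orhs(o) += y(v) - 0.5 - om(v) * walpha(v);
        }
        for (int o = 0; o < n_observer; ++o)
          eta(o) = orhs(o) / oprec(o) + R::norm_rand() / std::sqrt(oprec(o));
        // observer-effect variance, conjugate inverse-gamma
        double ss = arma::dot(eta, eta);
        double sh = ig_shape + 0.5 * n_observer;
        double rate = ig_scale + 0.5 * ss;
        sig2 = 1.0 / R::rgamma(sh, 1.0 / rate);
      }
    }

    // -- retention
    if (it > n_burn && (it - n_burn) % n_thin == 0) {
      occ_lp = X * beta;
      walpha = W * alpha;
      for (int u = 0; u < U; ++u) occ_lp(u) = clipv(occ_lp(u), clip);
      for (int v = 0; v < V; ++v) {
        double lp = walpha(v) + (has_obs ? eta(obs_idx(v)) : 0.0);
        det_lp(v) = clipv(lp, clip);
      }
      for (int k = 0; k < P; ++k) beta_out(keep, k) = beta(k);
      for (int k = 0; k < Q; ++k) alpha_out(keep, k) = alpha(k);
      if (has_obs) {
        for (int o = 0; o < n_observer; ++o) eta_out(keep, o) = eta(o);
        sig2_out(keep) = sig2;
      }
      for (int u = 0; u < U; ++u) {
        z_out(keep, u) = z(u);
        arma::vec dl(vis_count(u));
        arma::ivec yv(vis_count(u));
        for (int j = 0; j < vis_count(u); ++j) {
          dl(j) = det_lp(vis_start(u) + j);
          yv(j) = y(vis_start(u) + j);
        }
        ll_out(keep, u) = unit_loglik(occ_lp(u), dl, yv, detected(u) == 1);
      }
      ++keep;
    }
    if (it % 512 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["beta"] = beta_out, _["alpha"] = alpha_out,
                      _["eta"] = eta_out, _["sigma_sq_obs"] = sig2_out,
                      _["z"] = z_out, _["loglik"] = ll_out);
}
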