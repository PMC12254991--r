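// Gibbs sampler for uni/bivariate BayesB multiple-marker regression with
// fixed, common-litter and pedigree polygenic terms.
//
// Model (per trait t): y_t = X b_t + W c_t + Z u_t + sum_j z_j d_jt a_jt + e_t
//   e rows ~ N(0, R), c_l ~ N(0, C), u ~ N(0, A (x) U),
//   a_j | included ~ N(0, G_j), inclusion indicator with 2 (univariate) or 4
//   (bivariate) configurations; all covariance matrices inverse-Wishart.
// The marker update marginalizes a_j analytically to score the inclusion
// configurations, then draws a_j from its Gaussian full conditional.
// All randomness comes from R's RNG stream (deterministic under set.seed).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat rwishart_bartlett(double df, const arma::mat& S) {
  const int p = S.n_rows;
  arma::mat L = arma::chol(S, "lower");
  arma::mat A(p, p, arma::fill::zeros);
  for (int i = 0; i < p; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  arma::mat LA = L * A;
  return LA * LA.t();
}

// Inverse-Wishart(nu, Psi) with mean Psi / (nu - p - 1)
static arma::mat riwishart(double nu, const arma::mat& Psi) {
  arma::mat W = rwishart_bartlett(nu, arma::inv_sympd(Psi));
  return arma::inv_sympd(W);
}

// draw N(mu, Sigma) for tiny dimension
static arma::vec rmvnorm_small(const arma::vec& mu, const arma::mat& Sigma) {
  arma::mat L = arma::chol(Sigma, "lower");
  arma::vec z(mu.n_elem);
  for (arma::uword i = 0; i < z.n_elem; ++i) z(i) = R::norm_rand();
  return mu + L * z;
}

// [[Rcpp::export(name = ".bayesb_mcmc_cpp")]]
List bayesb_mcmc_cpp(const arma::mat& Y,           // n x t, NaN = missing
                     const arma::mat& X,           // n x p fixed design
                     const arma::ivec& litter,     // n, 1..q or 0 = none
                     int n_litter,
                     const arma::ivec& ped_id,     // n, 1..m or empty
                     int n_ped,
                     const arma::ivec& ainv_i,     // triplets of A-inverse
                     const arma::ivec& ainv_j,
                     const arma::vec& ainv_x,
                     const arma::mat& M,           // n x k centered dosages
                     const arma::mat& R0, double nuR,
                     const arma::mat& C0, double nuC,
                     const arma::mat& U0, double nuU,
                     const arma::mat& G0, double nuG,
                     const arma::vec& pi_cfg,      // len 2 (t=1) or 4 (t=2)
                     bool shared_G,
                     int n_iter, int burn_in, int thin,
                     bool store_u, bool store_resid) {
  const int n = Y.n_rows, t = Y.n_cols, p = X.n_cols, k = M.n_cols;
  const bool use_lit = n_litter > 0, use_ped = n_ped > 0;
  const int n_save = (n_iter - burn_in) / thin;
  if (n_save < 1) stop("MCMC schedule saves no draws");

  // state
  arma::mat R = R0, C = C0, U = U0;
  arma::mat Rinv = arma::inv_sympd(R);
  arma::mat Cinv = use_lit ? arma::inv_sympd(C) : arma::mat();
  arma::mat Uinv = use_ped ? arma::inv_sympd(U) : arma::mat();
  arma::mat beta(p, t, arma::fill::zeros);
  arma::mat clit(n_litter > 0 ? n_litter : 0, t, arma::fill::zeros);
  arma::mat u(n_ped > 0 ? n_ped : 0, t, arma::fill::zeros);
  arma::mat alpha(k, t, arma::fill::zeros);
  arma::ivec dcfg(k, arma::fill::zeros);           // 0..3 config codes
  arma::cube Gj(t, t, shared_G ? 1 : std::max(k, 1));
  for (arma::uword s = 0; s < Gj.n_slices; ++s) Gj.slice(s) = G0;

  arma::mat E = Y;                                  // residuals
  E.replace(arma::datum::nan, 0.0);                 // start at 0 for missing
  arma::umat miss(n, t, arma::fill::zeros);
  for (int i = 0; i < n; ++i)
    for (int s = 0; s < t; ++s)
      if (!std::isfinite(Y(i, s))) miss(i, s) = 1;
  const bool any_miss = arma::accu(miss) > 0;

  // precomputations
  arma::vec xx(p);
  for (int c = 0; c < p; ++c) xx(c) = arma::dot(X.col(c), X.col(c));
  arma::vec zz(k);
  for (int j = 0; j < k; ++j) zz(j) = arma::dot(M.col(j), M.col(j));
  std::vector<std::vector<int>> lit_members(n_litter);
  if (use_lit)
    for (int i = 0; i < n; ++i)
      if (litter(i) > 0) lit_members[litter(i) - 1].push_back(i);
  std::vector<std::vector<int>> rec_of(n_ped);
  if (use_ped)
    for (int i = 0; i < n; ++i)
      if (ped_id(i) > 0) rec_of[ped_id(i) - 1].push_back(i);
  // sparse A-inverse: diagonal and off-diagonal adjacency per animal
  arma::vec ainv_diag(std::max(n_ped, 1), arma::fill::zeros);
  std::vector<std::vector<std::pair<int, double>>> ainv_off(n_ped);
  for (arma::uword e = 0; e < ainv_x.n_elem; ++e) {
    int a = ainv_i(e) - 1, b = ainv_j(e) - 1;
    if (a == b) ainv_diag(a) += ainv_x(e);
    else ainv_off[a].push_back(std::make_pair(b, ainv_x(e)));
  }

  // storage
  arma::cube alpha_s(n_save, k, t);
  arma::imat dcfg_s(n_save, k);
  arma::cube beta_s(n_save, std::max(p, 1), t, arma::fill::zeros);
  arma::mat R_s(n_save, t * t), C_s(n_save, t * t), U_s(n_save, t * t);
  arma::mat Gmean_s(n_save, t * t);
  arma::cube u_s(store_u && use_ped ? n_save : 0,
                 store_u && use_ped ? n_ped : 0, store_u && use_ped ? t : 0);
  arma::cube clit_s(use_lit ? n_save : 0, use_lit ? n_litter : 0,
                    use_lit ? t : 0);
  arma::cube E_s(store_resid ? n_save : 0, store_resid ? std::max(n, 1) : 0,
                 store_resid ? t : 0);

  const int n_cfg = (t == 2) ? 4 : 2;
  arma::vec logpi = arma::log(pi_cfg);
  int isave = 0;

  for (int iter = 1; iter <= n_iter; ++iter) {
    // ---- missing-residual augmentation ------------------------------------
    if (any_miss) {
      for (int i = 0; i < n; ++i) {
        if (t == 2) {
          if (miss(i, 0) && miss(i, 1)) {
            arma::vec e2 = rmvnorm_small(arma::zeros(2), R);
            E(i, 0) = e2(0); E(i, 1) = e2(1);
          } else if (miss(i, 0)) {
            double mu = R(0, 1) / R(1, 1) * E(i, 1);
            double v = R(0, 0) - R(0, 1) * R(0, 1) / R(1, 1);
            E(i, 0) = mu + std::sqrt(v) * R::norm_rand();
          } else if (miss(i, 1)) {
            double mu = R(0, 1) / R(0, 0) * E(i, 0);
            double v = R(1, 1) - R(0, 1) * R(0, 1) / R(0, 0);
            E(i, 1) = mu + std::sqrt(v) * R::norm_rand();
          }
        } else if (miss(i, 0)) {
          E(i, 0) = std::sqrt(R(0, 0)) * R::norm_rand();
        }
      }
    }

    // ---- fixed effects (flat prior) ---------------------------------------
    for (int c = 0; c < p; ++c) {
      if (xx(c) <= 0 || n == 0) continue;
      arma::vec bold = beta.row(c).t();
      arma::vec rhs(t);
      for (int s = 0; s < t; ++s)
        rhs(s) = arma::dot(E.col(s), X.col(c)) + xx(c) * bold(s);
      arma::vec mu = rhs / xx(c);
      arma::vec bnew = rmvnorm_small(mu, R / xx(c));
      arma::vec dlt = bnew - bold;
      for (int s = 0; s < t; ++s) E.col(s) -= X.col(c) * dlt(s);
      beta.row(c) = bnew.t();
    }

    // ---- common-litter effects --------------------------------------------
    if (use_lit) {
      for (int l = 0; l < n_litter; ++l) {
        const std::vector<int>& mem = lit_members[l];
        arma::vec cold = clit.row(l).t();
        arma::vec S(t, arma::fill::zeros);
        for (size_t ii = 0; ii < mem.size(); ++ii)
          for (int s = 0; s < t; ++s) S(s) += E(mem[ii], s);
        S += double(mem.size()) * cold;
        arma::mat P = double(mem.size()) * Rinv + Cinv;
        arma::mat Pinv = arma::inv_sympd(P);
        arma::vec cnew = rmvnorm_small(Pinv * (Rinv * S), Pinv);
        arma::vec dlt = cnew - cold;
        for (size_t ii = 0; ii < mem.size(); ++ii)
          for (int s = 0; s < t; ++s) E(mem[ii], s) -= dlt(s);
        clit.row(l) = cnew.t();
      }
    }

    // ---- polygenic effects (single-site, sparse A-inverse) ----------------
    if (use_ped) {
      for (int a = 0; a < n_ped; ++a) {
        const std::vector<int>& rec = rec_of[a];
        arma::vec uold = u.row(a).t();
        arma::vec S(t, arma::fill::zeros);
        for (size_t ii = 0; ii < rec.size(); ++ii)
          for (int s = 0; s < t; ++s) S(s) += E(rec[ii], s);
        S += double(rec.size()) * uold;
        arma::vec nb(t, arma::fill::zeros);
        const std::vector<std::pair<int, double>>& off = ainv_off[a];
        for (size_t e = 0; e < off.size(); ++e)
          nb += off[e].second * u.row(off[e].first).t();
        arma::mat P = double(rec.size()) * Rinv + ainv_diag(a) * Uinv;
        arma::mat Pinv = arma::inv_sympd(P);
        arma::vec mu = Pinv * (Rinv * S - Uinv * nb);
        arma::vec unew = rmvnorm_small(mu, Pinv);
        arma::vec dlt = unew - uold;
        for (size_t ii = 0; ii < rec.size(); ++ii)
          for (int s = 0; s < t; ++s) E(rec[ii], s) -= dlt(s);
        u.row(a) = unew.t();
      }
    }

    // ---- marker effects with inclusion indicators -------------------------
    arma::mat SSg(t, t, arma::fill::zeros); // for shared-G update
    for (int j = 0; j < k; ++j) {
      const arma::mat& G = shared_G ? Gj.slice(0) : Gj.slice(j);
      // add current contribution back
      if (dcfg(j) != 0)
        for (int s = 0; s < t; ++s)
          if (alpha(j, s) != 0.0) E.col(s) += M.col(j) * alpha(j, s);
      arma::vec r(t);
      for (int s = 0; s < t; ++s) r(s) = arma::dot(E.col(s), M.col(j));
      arma::vec m = Rinv * r;
      // score configurations by analytic marginalization of alpha
      arma::vec logw(n_cfg);
      double P1 = 0, P2v = 0, mu1 = 0, mu2 = 0;
      arma::mat P22, P22inv;
      arma::vec mu22;
      if (t == 1) {
        logw(0) = logpi(0);
        P1 = zz(j) * Rinv(0, 0) + 1.0 / G(0, 0);
        logw(1) = logpi(1) +
          0.5 * (-std::log(G(0, 0)) - std::log(P1) + m(0) * m(0) / P1);
      } else {
        logw(0) = logpi(0);
        P1 = zz(j) * Rinv(0, 0) + 1.0 / G(0, 0);
        logw(1) = logpi(1) +
          0.5 * (-std::log(G(0, 0)) - std::log(P1) + m(0) * m(0) / P1);
        P2v = zz(j) * Rinv(1, 1) + 1.0 / G(1, 1);
        logw(2) = logpi(2) +
          0.5 * (-std::log(G(1, 1)) - std::log(P2v) + m(1) * m(1) / P2v);
        P22 = zz(j) * Rinv + arma::inv_sympd(G);
        P22inv = arma::inv_sympd(P22);
        mu22 = P22inv * m;
        double ldG, sgn, ldP;
        arma::log_det(ldG, sgn, G);
        arma::log_det(ldP, sgn, P22);
        logw(3) = logpi(3) + 0.5 * (-ldG - ldP + arma::dot(m, mu22));
      }
      double wmax = logw.max();
      arma::vec w = arma::exp(logw - wmax);
      double uw = R::unif_rand() * arma::accu(w), acc = 0;
      int cfg = 0;
      for (int c = 0; c < n_cfg; ++c) {
        acc += w(c);
        if (uw <= acc) { cfg = c; break; }
      }
      dcfg(j) = cfg;
      alpha.row(j).zeros();
      if (t == 1) {
        if (cfg == 1)
          alpha(j, 0) = m(0) / P1 + R::norm_rand() / std::sqrt(P1);
      } else {
        if (cfg == 1) {
          mu1 = m(0) / P1;
          alpha(j, 0) = mu1 + R::norm_rand() / std::sqrt(P1);
        } else if (cfg == 2) {
          mu2 = m(1) / P2v;
          alpha(j, 1) = mu2 + R::norm_rand() / std::sqrt(P2v);
        } else if (cfg == 3) {
          arma::vec a2 = rmvnorm_small(mu22, P22inv);
          alpha(j, 0) = a2(0); alpha(j, 1) = a2(1);
        }
      }
      if (cfg != 0)
        for (int s = 0; s < t; ++s)
          if (alpha(j, s) != 0.0) E.col(s) -= M.col(j) * alpha(j, s);
      // latent full effect vector for the (co)variance update: inactive
      // components drawn from their conditional prior given the active ones
      arma::vec atil(t);
      if (t == 1) {
        atil(0) = (cfg == 1) ? alpha(j, 0)
                             : std::sqrt(G(0, 0)) * R::norm_rand();
      } else {
        if (cfg == 3) {
          atil(0) = alpha(j, 0); atil(1) = alpha(j, 1);
        } else if (cfg == 1) {
          atil(0) = alpha(j, 0);
          double muc = G(0, 1) / G(0, 0) * atil(0);
          double vc = G(1, 1) - G(0, 1) * G(0, 1) / G(0, 0);
          atil(1) = muc + std::sqrt(std::max(vc, 0.0)) * R::norm_rand();
        } else if (cfg == 2) {
          atil(1) = alpha(j, 1);
          double muc = G(0, 1) / G(1, 1) * atil(1);
          double vc = G(0, 0) - G(0, 1) * G(0, 1) / G(1, 1);
          atil(0) = muc + std::sqrt(std::max(vc, 0.0)) * R::norm_rand();
        } else {
          atil = rmvnorm_small(arma::zeros(2), G);
        }
      }
      if (shared_G) {
        SSg += atil * atil.t();
      } else {
        Gj.slice(j) = riwishart(nuG + 1.0, G0 + atil * atil.t());
      }
    }
    if (shared_G && k > 0)
      Gj.slice(0) = riwishart(nuG + double(k), G0 + SSg);

    // ---- covariance matrices ---------------------------------------------
    if (use_lit) {
      arma::mat SS = clit.t() * clit;
      C = riwishart(nuC + double(n_litter), C0 + SS);
      Cinv = arma::inv_sympd(C);
    }
    if (use_ped) {
      arma::mat SS(t, t, arma::fill::zeros);
      for (arma::uword e = 0; e < ainv_x.n_elem; ++e) {
        int a = ainv_i(e) - 1, b = ainv_j(e) - 1;
        SS += ainv_x(e) * (u.row(a).t() * u.row(b));
      }
      SS = 0.5 * (SS + SS.t());
      U = riwishart(nuU + double(n_ped), U0 + SS);
      Uinv = arma::inv_sympd(U);
    }
    {
      arma::mat SS = (n > 0) ? arma::mat(E.t() * E)
                             : arma::mat(t, t, arma::fill::zeros);
      R = riwishart(nuR + double(n), R0 + SS);
      if (!R.is_finite()) stop("residual covariance diverged at iteration %d",
                               iter);
      Rinv = arma::inv_sympd(R);
    }

    // ---- save -------------------------------------------------------------
    if (iter > burn_in && (iter - burn_in) % thin == 0 && isave < n_save) {
      for (int s = 0; s < t; ++s) {
        for (int j = 0; j < k; ++j) alpha_s(isave, j, s) = alpha(j, s);
        for (int c = 0; c < p; ++c) beta_s(isave, c, s) = beta(c, s);
      }
      for (int j = 0; j < k; ++j) dcfg_s(isave, j) = dcfg(j);
      R_s.row(isave) = arma::vectorise(R).t();
      C_s.row(isave) = use_lit ? arma::vectorise(C).t()
                               : arma::rowvec(t * t, arma::fill::zeros);
      U_s.row(isave) = use_ped ? arma::vectorise(U).t()
                               : arma::rowvec(t * t, arma::fill::zeros);
      arma::mat Gm(t, t, arma::fill::zeros);
      for (arma::uword s2 = 0; s2 < Gj.n_slices; ++s2) Gm += Gj.slice(s2);
      Gmean_s.row(isave) = arma::vectorise(Gm / double(Gj.n_slices)).t();
      if (store_u && use_ped)
        for (int s = 0; s < t; ++s)
          for (int a = 0; a < n_ped; ++a) u_s(isave, a, s) = u(a, s);
      if (use_lit)
        for (int s = 0; s < t; ++s)
          for (int l = 0; l < n_litter; ++l) clit_s(isave, l, s) = clit(l, s);
      if (store_resid)
        for (int s = 0; s < t; ++s)
          for (int i = 0; i < n; ++i) E_s(isave, i, s) = E(i, s);
      ++isave;
    }
    if (iter % 5000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["alpha"] = alpha_s, _["delta_cfg"] = dcfg_s, _["beta"] = beta_s,
    _["R"] = R_s, _["C"] = C_s, _["U"] = U_s, _["G_mean"] = Gmean_s,
    _["u"] = u_s, _["litter"] = clit_s, _["resid"] = E_s,
    _["n_saved"] = isave);
}
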