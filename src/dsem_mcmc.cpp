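// Metropolis-within-Gibbs sampler for the bivariate multilevel VAR(1) DSEM.
//
// Person-level model (deviations w from latent means mu):
//   w_sb[t] = phi_sb*w_sb[t-1] + beta_sb*w_pa[t-1] + N(0, exp(lam_sb))
//   w_pa[t] = phi_pa*w_pa[t-1] + beta_pa*w_sb[t-1] + N(0, exp(lam_pa))
// Day-1 deviations follow the person's stationary distribution (diffuse
// fallback when non-stationary). Between level: each of the 8 effects is
// regressed on the centered predictor with independent residuals, except the
// (mu_sb, mu_pa) pair which has a full 2x2 covariance.
//
// All randomness goes through R's RNG so set.seed() gives exact determinism.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double DIFFUSE_INIT_VAR = 1e6;

// Effect column order, mirrored in R: mu_sb, mu_pa, phi_sb, phi_pa,
// beta_sb, beta_pa, lam_sb, lam_pa.
enum Eff { MU_SB, MU_PA, PHI_SB, PHI_PA, BETA_SB, BETA_PA, LAM_SB, LAM_PA };

// Spectral radius of [[a,b],[c,d]]
static double spec_rad(double a, double b, double c, double d) {
  double tr = a + d, det = a * d - b * c;
  double disc = tr * tr - 4.0 * det;
  if (disc >= 0.0) {
    double s = std::sqrt(disc);
    return std::max(std::fabs((tr + s) / 2.0), std::fabs((tr - s) / 2.0));
  }
  return std::sqrt(det); // complex pair, modulus sqrt(det)
}

// Stationary covariance V solving V = A V A' + diag(psi). Returns false when
// the dynamics are non-stationary or V is not positive definite.
static bool stat_cov(double phi_sb, double beta_sb, double beta_pa,
                     double phi_pa, double psi_sb, double psi_pa,
                     arma::mat22 &V) {
  if (spec_rad(phi_sb, beta_sb, beta_pa, phi_pa) >= 1.0 - 1e-12) return false;
  arma::mat A = {{phi_sb, beta_sb}, {beta_pa, phi_pa}};
  arma::mat K = arma::eye(4, 4) - arma::kron(A, A);
  arma::vec p = {psi_sb, 0.0, 0.0, psi_pa};
  arma::vec v;
  if (!arma::solve(v, K, p)) return false;
  V(0, 0) = v(0);
  V(0, 1) = V(1, 0) = 0.5 * (v(1) + v(2));
  V(1, 1) = v(3);
  double det = V(0, 0) * V(1, 1) - V(0, 1) * V(1, 0);
  return V(0, 0) > 0.0 && det > 0.0;
}

// log N2(x; 0, V) for the day-1 state, with diffuse fallback flag
static double log_init_dens(const arma::vec2 &w1, bool stable,
                            const arma::mat22 &V) {
  if (!stable) {
    return -std::log(2.0 * M_PI) - std::log(DIFFUSE_INIT_VAR) -
           0.5 * (w1(0) * w1(0) + w1(1) * w1(1)) / DIFFUSE_INIT_VAR;
  }
  double det = V(0, 0) * V(1, 1) - V(0, 1) * V(1, 0);
  double q = (w1(0) * w1(0) * V(1, 1) - 2.0 * w1(0) * w1(1) * V(0, 1) +
              w1(1) * w1(1) * V(0, 0)) / det;
  return -std::log(2.0 * M_PI) - 0.5 * std::log(det) - 0.5 * q;
}

// draw N(m, Prec^{-1})
static arma::vec2 draw_mvn2(const arma::vec2 &m, const arma::mat22 &Prec) {
  arma::mat22 U = arma::chol(Prec); // upper
  arma::vec2 z = {norm_rand(), norm_rand()};
  arma::vec2 x = arma::solve(arma::trimatu(U), z);
  return m + x;
}

// draw N(0, V) (covariance parameterisation)
static arma::vec2 draw_mvn2_cov(const arma::mat22 &V) {
  arma::mat22 L = arma::chol(V, "lower");
  arma::vec2 z = {norm_rand(), norm_rand()};
  return L * z;
}

// Wishart(df, inv(S)) via Bartlett, then invert: a draw from IW(S, df)
static arma::mat22 draw_invwishart(const arma::mat22 &S, double df) {
  arma::mat22 Sinv = arma::inv_sympd(S);
  arma::mat22 L = arma::chol(Sinv, "lower");
  arma::mat22 A(arma::fill::zeros);
  A(0, 0) = std::sqrt(R::rchisq(df));
  A(1, 1) = std::sqrt(R::rchisq(df - 1.0));
  A(1, 0) = norm_rand();
  arma::mat22 LA = L * A;
  arma::mat22 W = LA * LA.t();
  return arma::inv_sympd(W);
}

struct Priors {
  double gamma_var, mu_int_var, tau_a, tau_b, wish_df, wish_scale;
  double nh_mu_var, nh_dyn_var;
};

struct State {
  arma::mat u;          // N x 8 person effects
  arma::cube W;         // 2 x T x N deviations
  arma::vec gamma0, gamma1, tau; // length 8
  arma::mat22 Sigma_mu;
  arma::mat lam_step;   // N x 2 RW steps
  arma::mat lam_acc, lam_try;          // adaptation batch counters
  arma::mat lam_acc_tot, lam_try_tot;  // post burn-in acceptance
  double dyn_acc = 0.0, dyn_try = 0.0;
};

struct Data {
  arma::mat y_sb, y_pa; // N x T (NaN on missing)
  arma::umat obs;
  arma::vec pc;
  int N, T;
};

// One full Gibbs sweep over persons and (if hierarchical) the between level.
static void do_sweep(const Data &d, State &s, const Priors &pr,
                     bool hierarchical, bool adapting, int adapt_interval,
                     double gm_sb, double gm_pa, bool stat_init) {
  const int N = d.N, T = d.T;
  for (int i = 0; i < N; ++i) {
    arma::mat Wi = s.W.slice(i); // 2 x T working copy
    double psi_sb = std::exp(s.u(i, LAM_SB)), psi_pa = std::exp(s.u(i, LAM_PA));

    // prior (between-level) moments for this person
    arma::vec pm(8);
    for (int k = 0; k < 8; ++k) pm(k) = s.gamma0(k) + s.gamma1(k) * d.pc(i);
    arma::vec pv = s.tau;
    if (!hierarchical) {
      pm.zeros();
      pm(MU_SB) = gm_sb; pm(MU_PA) = gm_pa;
      pv.fill(pr.nh_dyn_var);
      pv(MU_SB) = pv(MU_PA) = pr.nh_mu_var;
    }

    // --- (1) dynamics rows: conjugate proposal + initial-state MH ---
    for (int row = 0; row < 2; ++row) {
      int phi_k = (row == 0) ? PHI_SB : PHI_PA;
      int beta_k = (row == 0) ? BETA_SB : BETA_PA;
      double psi = (row == 0) ? psi_sb : psi_pa;
      int own = row, other = 1 - row;
      arma::mat22 XtX(arma::fill::zeros);
      arma::vec2 Xty(arma::fill::zeros);
      for (int t = 1; t < T; ++t) {
        arma::vec2 x = {Wi(own, t - 1), Wi(other, t - 1)};
        XtX += x * x.t();
        Xty += x * Wi(own, t);
      }
      arma::mat22 P0(arma::fill::zeros);
      P0(0, 0) = 1.0 / pv(phi_k);
      P0(1, 1) = 1.0 / pv(beta_k);
      arma::vec2 m0 = {pm(phi_k), pm(beta_k)};
      arma::mat22 Pn = P0 + XtX / psi;
      arma::vec2 bn = P0 * m0 + Xty / psi;
      arma::vec2 mn = arma::solve(Pn, bn);
      arma::vec2 prop = draw_mvn2(mn, Pn);
      // MH correction: the day-1 stationary density depends on the lag
      // matrix; the conjugate draw is an independence proposal for it.
      double cphi = s.u(i, phi_k), cbeta = s.u(i, beta_k);
      arma::mat22 Vc, Vp;
      bool sc, sp;
      if (row == 0) {
        sc = stat_cov(cphi, cbeta, s.u(i, BETA_PA), s.u(i, PHI_PA), psi_sb, psi_pa, Vc);
        sp = stat_cov(prop(0), prop(1), s.u(i, BETA_PA), s.u(i, PHI_PA), psi_sb, psi_pa, Vp);
      } else {
        sc = stat_cov(s.u(i, PHI_SB), s.u(i, BETA_SB), cbeta, cphi, psi_sb, psi_pa, Vc);
        sp = stat_cov(s.u(i, PHI_SB), s.u(i, BETA_SB), prop(1), prop(0), psi_sb, psi_pa, Vp);
      }
      arma::vec2 w1 = {Wi(0, 0), Wi(1, 0)};
      double la = stat_init
        ? log_init_dens(w1, sp, Vp) - log_init_dens(w1, sc, Vc)
        : 0.0;
      s.dyn_try += 1.0;
      if (std::log(unif_rand()) < la) {
        s.u(i, phi_k) = prop(0);
        s.u(i, beta_k) = prop(1);
        s.dyn_acc += 1.0;
      }
    }

    arma::mat22 A = {{s.u(i, PHI_SB), s.u(i, BETA_SB)},
                     {s.u(i, BETA_PA), s.u(i, PHI_PA)}};

    // --- (2) latent means, joint bivariate conjugate draw ---
    {
      arma::mat22 V1;
      bool st = stat_cov(A(0, 0), A(0, 1), A(1, 0), A(1, 1), psi_sb, psi_pa, V1);
      arma::mat22 Prec(arma::fill::zeros);
      arma::vec2 lin(arma::fill::zeros);
      arma::mat22 Psi_inv(arma::fill::zeros);
      Psi_inv(0, 0) = 1.0 / psi_sb;
      Psi_inv(1, 1) = 1.0 / psi_pa;
      // a_t = o_t y_t + (1-o_t) w_t : value of w_t(mu) at mu = 0
      auto a_at = [&](int t) {
        arma::vec2 a;
        if (d.obs(i, t)) { a = {d.y_sb(i, t), d.y_pa(i, t)}; }
        else { a = {Wi(0, t), Wi(1, t)}; }
        return a;
      };
      for (int t = 1; t < T; ++t) {
        double ot = d.obs(i, t) ? 1.0 : 0.0;
        double otm = d.obs(i, t - 1) ? 1.0 : 0.0;
        if (ot == 0.0 && otm == 0.0) continue;
        arma::mat22 M = ot * arma::eye(2, 2) - otm * A;
        arma::vec2 c = a_at(t) - A * a_at(t - 1);
        Prec += M.t() * Psi_inv * M;
        lin += M.t() * Psi_inv * c;
      }
      if (d.obs(i, 0)) {
        arma::mat22 V1inv = (stat_init && st)
          ? arma::mat22(arma::inv_sympd(V1))
          : arma::mat22(arma::eye(2, 2) / DIFFUSE_INIT_VAR);
        Prec += V1inv;
        lin += V1inv * arma::vec2({d.y_sb(i, 0), d.y_pa(i, 0)});
      }
      arma::mat22 Pmu;
      arma::vec2 m0 = {pm(MU_SB), pm(MU_PA)};
      if (hierarchical) Pmu = arma::inv_sympd(s.Sigma_mu);
      else Pmu = arma::eye(2, 2) / pr.nh_mu_var;
      Prec += Pmu;
      lin += Pmu * m0;
      arma::vec2 mn = arma::solve(Prec, lin);
      arma::vec2 mu_new = draw_mvn2(mn, Prec);
      s.u(i, MU_SB) = mu_new(0);
      s.u(i, MU_PA) = mu_new(1);
      for (int t = 0; t < T; ++t) {
        if (d.obs(i, t)) {
          Wi(0, t) = d.y_sb(i, t) - mu_new(0);
          Wi(1, t) = d.y_pa(i, t) - mu_new(1);
        }
      }
    }

    // --- (3) log innovation variances, adaptive random-walk Metropolis ---
    for (int sv = 0; sv < 2; ++sv) {
      int lam_k = (sv == 0) ? LAM_SB : LAM_PA;
      double lam_cur = s.u(i, lam_k);
      double sse = 0.0;
      for (int t = 1; t < T; ++t) {
        double pred = (sv == 0)
          ? A(0, 0) * Wi(0, t - 1) + A(0, 1) * Wi(1, t - 1)
          : A(1, 0) * Wi(0, t - 1) + A(1, 1) * Wi(1, t - 1);
        double r = Wi(sv, t) - pred;
        sse += r * r;
      }
      auto target = [&](double lam) {
        double p_sb = (sv == 0) ? std::exp(lam) : psi_sb;
        double p_pa = (sv == 1) ? std::exp(lam) : psi_pa;
        double lp = -0.5 * (T - 1) * lam - 0.5 * sse * std::exp(-lam);
        if (stat_init) {
          arma::mat22 V1;
          bool st = stat_cov(A(0, 0), A(0, 1), A(1, 0), A(1, 1), p_sb, p_pa, V1);
          arma::vec2 w1 = {Wi(0, 0), Wi(1, 0)};
          lp += log_init_dens(w1, st, V1);
        }
        lp += -0.5 * (lam - pm(lam_k)) * (lam - pm(lam_k)) / pv(lam_k);
        return lp;
      };
      double prop = lam_cur + s.lam_step(i, sv) * norm_rand();
      s.lam_try(i, sv) += 1.0;
      if (!adapting) s.lam_try_tot(i, sv) += 1.0;
      if (prop > -40.0 && prop < 40.0 &&
          std::log(unif_rand()) < target(prop) - target(lam_cur)) {
        s.u(i, lam_k) = prop;
        s.lam_acc(i, sv) += 1.0;
        if (!adapting) s.lam_acc_tot(i, sv) += 1.0;
        if (sv == 0) psi_sb = std::exp(prop); else psi_pa = std::exp(prop);
      }
      if (adapting && ((int)s.lam_try(i, sv)) >= adapt_interval) {
        double rate = s.lam_acc(i, sv) / s.lam_try(i, sv);
        if (rate < 0.3) s.lam_step(i, sv) *= 0.8;
        else if (rate > 0.5) s.lam_step(i, sv) *= 1.25;
        s.lam_acc(i, sv) = s.lam_try(i, sv) = 0.0;
      }
    }

    // --- (4) latent states on missing days (and latent day 1) ---
    {
      arma::mat22 V1;
      bool st = stat_cov(A(0, 0), A(0, 1), A(1, 0), A(1, 1), psi_sb, psi_pa, V1);
      arma::mat22 Psi_inv(arma::fill::zeros);
      Psi_inv(0, 0) = 1.0 / psi_sb;
      Psi_inv(1, 1) = 1.0 / psi_pa;
      for (int t = 0; t < T; ++t) {
        if (d.obs(i, t)) continue;
        arma::mat22 Prec(arma::fill::zeros);
        arma::vec2 lin(arma::fill::zeros);
        if (t == 0) {
          arma::mat22 V1inv = (stat_init && st)
            ? arma::mat22(arma::inv_sympd(V1))
            : arma::mat22(arma::eye(2, 2) / DIFFUSE_INIT_VAR);
          Prec += V1inv; // mean zero
        } else {
          arma::vec2 wm = {Wi(0, t - 1), Wi(1, t - 1)};
          arma::vec2 m = A * wm;
          Prec += Psi_inv;
          lin += Psi_inv * m;
        }
        if (t < T - 1) {
          arma::vec2 wp = {Wi(0, t + 1), Wi(1, t + 1)};
          Prec += A.t() * Psi_inv * A;
          lin += A.t() * Psi_inv * wp;
        }
        arma::vec2 mn = arma::solve(Prec, lin);
        arma::vec2 wnew = draw_mvn2(mn, Prec);
        Wi(0, t) = wnew(0);
        Wi(1, t) = wnew(1);
      }
    }

    if (!Wi.is_finite() || !s.u.row(i).is_finite()) {
      stop("Non-finite value in sweep at person %d.", i + 1);
    }
    s.W.slice(i) = Wi;
  }

  // --- (5) between level ---
  if (hierarchical) {
    arma::mat X(N, 2);
    X.col(0).ones();
    X.col(1) = d.pc;
    arma::mat22 XtX = {{(double)N, arma::accu(d.pc)},
                       {arma::accu(d.pc), arma::dot(d.pc, d.pc)}};
    // independent effects
    int singles[6] = {PHI_SB, PHI_PA, BETA_SB, BETA_PA, LAM_SB, LAM_PA};
    for (int j = 0; j < 6; ++j) {
      int k = singles[j];
      arma::vec uk = s.u.col(k);
      arma::mat22 P0(arma::fill::zeros);
      P0(0, 0) = P0(1, 1) = 1.0 / pr.gamma_var;
      arma::mat22 Pn = P0 + XtX / s.tau(k);
      arma::vec2 bn = {arma::accu(uk) / s.tau(k), arma::dot(d.pc, uk) / s.tau(k)};
      arma::vec2 mn = arma::solve(Pn, bn);
      arma::vec2 g = draw_mvn2(mn, Pn);
      s.gamma0(k) = g(0);
      s.gamma1(k) = g(1);
      arma::vec resid = uk - g(0) - g(1) * d.pc;
      double a_n = pr.tau_a + 0.5 * N;
      double b_n = pr.tau_b + 0.5 * arma::dot(resid, resid);
      s.tau(k) = b_n / R::rgamma(a_n, 1.0);
    }
    // latent-mean block: bivariate regression with full covariance
    {
      arma::mat U2 = s.u.cols(MU_SB, MU_PA); // N x 2
      arma::mat22 Sinv = arma::inv_sympd(s.Sigma_mu);
      arma::mat P0(4, 4, arma::fill::zeros);
      P0(0, 0) = 1.0 / pr.mu_int_var;
      P0(1, 1) = 1.0 / pr.gamma_var;
      P0(2, 2) = 1.0 / pr.mu_int_var;
      P0(3, 3) = 1.0 / pr.gamma_var;
      arma::mat Pn = arma::kron(Sinv, arma::mat(XtX)) + P0;
      arma::vec bn = arma::vectorise(X.t() * U2 * Sinv);
      arma::vec mn = arma::solve(Pn, bn);
      arma::mat Uc = arma::chol(Pn);
      arma::vec z(4);
      for (int q = 0; q < 4; ++q) z(q) = norm_rand();
      arma::vec b = mn + arma::solve(arma::trimatu(Uc), z);
      arma::mat B(2, 2);
      B(0, 0) = b(0); B(1, 0) = b(1); // sb: intercept, slope
      B(0, 1) = b(2); B(1, 1) = b(3); // pa
      s.gamma0(MU_SB) = B(0, 0); s.gamma1(MU_SB) = B(1, 0);
      s.gamma0(MU_PA) = B(0, 1); s.gamma1(MU_PA) = B(1, 1);
      arma::mat E = U2 - X * B;
      arma::mat22 Sn = pr.wish_scale * arma::eye(2, 2) + E.t() * E;
      s.Sigma_mu = draw_invwishart(Sn, pr.wish_df + N);
      s.tau(MU_SB) = s.Sigma_mu(0, 0);
      s.tau(MU_PA) = s.Sigma_mu(1, 1);
    }
  }
}

static Priors read_priors(List prior) {
  Priors pr;
  pr.gamma_var = as<double>(prior["gamma_var"]);
  pr.mu_int_var = as<double>(prior["mu_intercept_var"]);
  pr.tau_a = as<double>(prior["tau_shape"]);
  pr.tau_b = as<double>(prior["tau_rate"]);
  pr.wish_df = as<double>(prior["wishart_df"]);
  pr.wish_scale = as<double>(prior["wishart_scale"]);
  pr.nh_mu_var = as<double>(prior["nonhier_mu_var"]);
  pr.nh_dyn_var = as<double>(prior["nonhier_dyn_var"]);
  return pr;
}

// [[Rcpp::export]]
List dsem_mcmc_cpp(const arma::mat &y_sb, const arma::mat &y_pa,
                   const arma::umat &obs, const arma::vec &pc,
                   int n_iter, int burn, int thin, bool hierarchical,
                   List prior, double step_init, int adapt_interval,
                   bool stat_init) {
  const int N = y_sb.n_rows, T = y_sb.n_cols;
  if (N < 1 || T < 2) stop("Need at least 1 person and 2 days.");
  Priors pr = read_priors(prior);
  Data d{y_sb, y_pa, obs, pc, N, T};

  State s;
  s.u = arma::mat(N, 8, arma::fill::zeros);
  s.W = arma::cube(2, T, N, arma::fill::zeros);
  s.gamma0 = s.gamma1 = arma::vec(8, arma::fill::zeros);
  s.tau = arma::vec(8, arma::fill::ones);
  s.Sigma_mu = arma::eye(2, 2);
  s.lam_step = arma::mat(N, 2);
  s.lam_step.fill(step_init);
  s.lam_acc = s.lam_try = arma::mat(N, 2, arma::fill::zeros);
  s.lam_acc_tot = s.lam_try_tot = arma::mat(N, 2, arma::fill::zeros);

  // initialisation from observed moments
  double gm_sb = 0, gm_pa = 0;
  {
    arma::uvec all_obs = arma::find(obs == 1);
    gm_sb = all_obs.n_elem ? arma::mean(y_sb.elem(all_obs)) : 0.0;
    gm_pa = all_obs.n_elem ? arma::mean(y_pa.elem(all_obs)) : 0.0;
  }
  for (int i = 0; i < N; ++i) {
    arma::uvec oi = arma::find(obs.row(i).t() == 1);
    double m_sb = oi.n_elem ? arma::mean(arma::vec(y_sb.row(i).t()).elem(oi)) : gm_sb;
    double m_pa = oi.n_elem ? arma::mean(arma::vec(y_pa.row(i).t()).elem(oi)) : gm_pa;
    s.u(i, MU_SB) = m_sb;
    s.u(i, MU_PA) = m_pa;
    double v_sb = 1.0, v_pa = 1.0;
    if (oi.n_elem >= 2) {
      v_sb = std::max(1e-2, arma::var(arma::vec(y_sb.row(i).t()).elem(oi)));
      v_pa = std::max(1e-2, arma::var(arma::vec(y_pa.row(i).t()).elem(oi)));
    }
    s.u(i, LAM_SB) = std::log(v_sb);
    s.u(i, LAM_PA) = std::log(v_pa);
    for (int t = 0; t < T; ++t) {
      if (obs(i, t)) {
        s.W(0, t, i) = y_sb(i, t) - m_sb;
        s.W(1, t, i) = y_pa(i, t) - m_pa;
      }
    }
  }
  if (hierarchical) {
    for (int k = 0; k < 8; ++k) s.gamma0(k) = arma::mean(s.u.col(k));
    s.tau(MU_SB) = std::max(1.0, arma::var(s.u.col(MU_SB)));
    s.tau(MU_PA) = std::max(1.0, arma::var(s.u.col(MU_PA)));
    s.tau(PHI_SB) = s.tau(PHI_PA) = 0.05;
    s.tau(BETA_SB) = s.tau(BETA_PA) = 0.05;
    s.tau(LAM_SB) = s.tau(LAM_PA) = 0.5;
    s.Sigma_mu(0, 0) = s.tau(MU_SB);
    s.Sigma_mu(1, 1) = s.tau(MU_PA);
    s.Sigma_mu(0, 1) = s.Sigma_mu(1, 0) = 0.0;
  }

  const int n_keep = (n_iter - burn) / thin;
  arma::mat fixed_draws(std::max(n_keep, 1), 25, arma::fill::zeros);
  arma::cube eff_draws(n_keep, N, 8);
  arma::cube state_draws(n_keep, N, 2 * T);
  arma::vec dev_draws(std::max(n_keep, 1), arma::fill::zeros);
  int keep = 0;

  for (int iter = 1; iter <= n_iter; ++iter) {
    do_sweep(d, s, pr, hierarchical, iter <= burn, adapt_interval, gm_sb,
             gm_pa, stat_init);

    if (iter > burn && (iter - burn) % thin == 0 && keep < n_keep) {
      for (int k = 0; k < 8; ++k) {
        fixed_draws(keep, k) = s.gamma0(k);
        fixed_draws(keep, 8 + k) = s.gamma1(k);
        fixed_draws(keep, 16 + k) = s.tau(k);
      }
      fixed_draws(keep, 24) = s.Sigma_mu(0, 1);
      double dev = 0.0;
      for (int i = 0; i < N; ++i) {
        double psi_sb = std::exp(s.u(i, LAM_SB)), psi_pa = std::exp(s.u(i, LAM_PA));
        arma::mat22 A = {{s.u(i, PHI_SB), s.u(i, BETA_SB)},
                         {s.u(i, BETA_PA), s.u(i, PHI_PA)}};
        for (int k = 0; k < 8; ++k) eff_draws(keep, i, k) = s.u(i, k);
        for (int t = 0; t < T; ++t) {
          state_draws(keep, i, t) = s.W(0, t, i);
          state_draws(keep, i, T + t) = s.W(1, t, i);
        }
        for (int t = 1; t < T; ++t) {
          if (!obs(i, t)) continue;
          double m_sb = A(0, 0) * s.W(0, t - 1, i) + A(0, 1) * s.W(1, t - 1, i);
          double m_pa = A(1, 0) * s.W(0, t - 1, i) + A(1, 1) * s.W(1, t - 1, i);
          dev += R::dnorm(s.W(0, t, i), m_sb, std::sqrt(psi_sb), 1);
          dev += R::dnorm(s.W(1, t, i), m_pa, std::sqrt(psi_pa), 1);
        }
        if (obs(i, 0)) {
          arma::mat22 V1;
          bool st = stat_init &&
            stat_cov(A(0, 0), A(0, 1), A(1, 0), A(1, 1), psi_sb, psi_pa, V1);
          arma::vec2 w1 = {s.W(0, 0, i), s.W(1, 0, i)};
          dev += log_init_dens(w1, st, V1);
        }
      }
      dev_draws(keep) = -2.0 * dev;
      ++keep;
    }
  }

  arma::mat lam_rate = s.lam_acc_tot / arma::clamp(s.lam_try_tot, 1.0, arma::datum::inf);
  return List::create(
    _["fixed"] = fixed_draws, _["effects"] = eff_draws,
    _["states"] = state_draws, _["deviance"] = dev_draws,
    _["n_keep"] = keep,
    _["lambda_accept"] = lam_rate, _["lambda_step"] = s.lam_step,
    _["dynamics_accept"] = s.dyn_try > 0 ? s.dyn_acc / s.dyn_try : NA_REAL);
}

// Successive-conditional (Geweke-style) self test of the Gibbs sweep: with
// proper priors, alternately resimulating data given parameters and running
// one sweep given data must leave the prior distribution invariant. Returns
// draws of the between-level parameters and person-effect means.
// [[Rcpp::export]]
arma::mat dsem_geweke_cpp(int N, int T, const arma::vec &pc,
                          const arma::umat &obs, List prior,
                          int n_sweeps, double step, bool stat_init) {
  Priors pr = read_priors(prior);
  Data d;
  d.N = N; d.T = T; d.pc = pc; d.obs = obs;
  d.y_sb = arma::mat(N, T, arma::fill::zeros);
  d.y_pa = arma::mat(N, T, arma::fill::zeros);

  State s;
  s.u = arma::mat(N, 8, arma::fill::zeros);
  s.W = arma::cube(2, T, N, arma::fill::zeros);
  s.gamma0 = arma::vec(8, arma::fill::zeros);
  s.gamma1 = arma::vec(8, arma::fill::zeros);
  s.tau = arma::vec(8, arma::fill::ones);
  s.Sigma_mu = arma::eye(2, 2);
  s.lam_step = arma::mat(N, 2);
  s.lam_step.fill(step);
  s.lam_acc = s.lam_try = arma::mat(N, 2, arma::fill::zeros);
  s.lam_acc_tot = s.lam_try_tot = arma::mat(N, 2, arma::fill::zeros);

  // draw between-level parameters from the prior
  auto draw_prior_params = [&]() {
    for (int k = 0; k < 8; ++k) {
      double v0 = (k == MU_SB || k == MU_PA) ? pr.mu_int_var : pr.gamma_var;
      s.gamma0(k) = std::sqrt(v0) * norm_rand();
      s.gamma1(k) = std::sqrt(pr.gamma_var) * norm_rand();
      if (k != MU_SB && k != MU_PA) {
        s.tau(k) = pr.tau_b / R::rgamma(pr.tau_a, 1.0);
      }
    }
    arma::mat22 S0 = pr.wish_scale * arma::eye(2, 2);
    s.Sigma_mu = draw_invwishart(S0, pr.wish_df);
    s.tau(MU_SB) = s.Sigma_mu(0, 0);
    s.tau(MU_PA) = s.Sigma_mu(1, 1);
  };
  // draw person effects given between-level parameters
  auto draw_effects = [&]() {
    for (int i = 0; i < N; ++i) {
      arma::vec2 mu_mean = {s.gamma0(MU_SB) + s.gamma1(MU_SB) * pc(i),
                            s.gamma0(MU_PA) + s.gamma1(MU_PA) * pc(i)};
      arma::vec2 mu_draw = mu_mean + draw_mvn2_cov(s.Sigma_mu);
      s.u(i, MU_SB) = mu_draw(0);
      s.u(i, MU_PA) = mu_draw(1);
      int singles[6] = {PHI_SB, PHI_PA, BETA_SB, BETA_PA, LAM_SB, LAM_PA};
      for (int j = 0; j < 6; ++j) {
        int k = singles[j];
        s.u(i, k) = s.gamma0(k) + s.gamma1(k) * pc(i) +
                    std::sqrt(s.tau(k)) * norm_rand();
      }
    }
  };
  // resimulate data (and latent states) given current parameters
  auto draw_data = [&]() {
    for (int i = 0; i < N; ++i) {
      double psi_sb = std::exp(s.u(i, LAM_SB)), psi_pa = std::exp(s.u(i, LAM_PA));
      arma::mat22 A = {{s.u(i, PHI_SB), s.u(i, BETA_SB)},
                       {s.u(i, BETA_PA), s.u(i, PHI_PA)}};
      arma::mat22 V1;
      bool st = stat_init &&
        stat_cov(A(0, 0), A(0, 1), A(1, 0), A(1, 1), psi_sb, psi_pa, V1);
      arma::vec2 w;
      if (st) w = draw_mvn2_cov(V1);
      else w = {std::sqrt(DIFFUSE_INIT_VAR) * norm_rand(),
                std::sqrt(DIFFUSE_INIT_VAR) * norm_rand()};
      for (int t = 0; t < T; ++t) {
        if (t > 0) {
          arma::vec2 m = A * w;
          w(0) = m(0) + std::sqrt(psi_sb) * norm_rand();
          w(1) = m(1) + std::sqrt(psi_pa) * norm_rand();
        }
        s.W(0, t, i) = w(0);
        s.W(1, t, i) = w(1);
        d.y_sb(i, t) = s.u(i, MU_SB) + w(0);
        d.y_pa(i, t) = s.u(i, MU_PA) + w(1);
      }
    }
  };

  draw_prior_params();
  draw_effects();
  draw_data();

  arma::mat out(n_sweeps, 27);
  for (int m = 0; m < n_sweeps; ++m) {
    do_sweep(d, s, pr, true, false, 50, 0.0, 0.0, stat_init);
    draw_data();
    for (int k = 0; k < 8; ++k) {
      out(m, k) = s.gamma0(k);
      out(m, 8 + k) = s.gamma1(k);
      out(m, 16 + k) = s.tau(k);
    }
    out(m, 24) = s.Sigma_mu(0, 1);
    out(m, 25) = arma::mean(s.u.col(PHI_SB));
    out(m, 26) = arma::mean(s.u.col(LAM_SB));
  }
  return out;
}

// Batch stationary covariances for standardization: one row per
// (draw, person) combination. Returns stable flag and V entries.
// [[Rcpp::export]]
arma::mat stat_cov_batch_cpp(const arma::vec &phi_sb, const arma::vec &beta_sb,
                             const arma::vec &beta_pa, const arma::vec &phi_pa,
                             const arma::vec &psi_sb, const arma::vec &psi_pa) {
  const int n = phi_sb.n_elem;
  arma::mat out(n, 4);
  arma::mat22 V;
  for (int i = 0; i < n; ++i) {
    bool ok = stat_cov(phi_sb(i), beta_sb(i), beta_pa(i), phi_pa(i),
                       psi_sb(i), psi_pa(i), V);
    out(i, 0) = ok ? 1.0 : 0.0;
    out(i, 1) = ok ? V(0, 0) : NA_REAL;
    out(i, 2) = ok ? V(1, 1) : NA_REAL;
    out(i, 3) = ok ? V(0, 1) : NA_REAL;
  }
  return out;
}
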