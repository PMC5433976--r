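// Gibbs/Metropolis sampler for the joint capture model:
//  (weight, primary) | class g  ~  MVN(class mean + day/year slopes, Sigma_g)
//  sex ~ Bern(invlogit(s0 + s1 day + s2 year))
//  age ~ Bern(invlogit(a0 + a1 day + a2 year))
// Missing sex/age labels are imputed from their full conditional at every
// sweep.  All randomness goes through R's RNG so set.seed() in R gives
// fully deterministic chains.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double softplus(double x) {
  return x > 30.0 ? x : std::log1p(std::exp(x));
}

// Sigma ~ InvWishart(scale V, df) via Bartlett decomposition of the
// Wishart(V^{-1}, df) precision draw; also returns the precision.
static void rinvwish2(const arma::mat& V, double df,
                      arma::mat& Sigma, arma::mat& Prec) {
  arma::mat Vinv = arma::inv_sympd(arma::symmatu(V));
  arma::mat L = arma::chol(Vinv, "lower");
  arma::mat A(2, 2, arma::fill::zeros);
  A(0, 0) = std::sqrt(R::rchisq(df));
  A(1, 1) = std::sqrt(R::rchisq(df - 1.0));
  A(1, 0) = norm_rand();
  arma::mat LA = L * A;
  Prec = arma::symmatu(LA * LA.t());
  Sigma = arma::inv_sympd(Prec);
}

// sum of Bernoulli log-likelihood terms for a logit-linear block
static double bern_loglik(const arma::vec& d, const arma::vec& yr,
                          const arma::ivec& y, const arma::vec& c) {
  double ll = 0.0;
  for (arma::uword i = 0; i < d.n_elem; ++i) {
    double eta = c[0] + c[1] * d[i] + c[2] * yr[i];
    ll += y[i] * eta - softplus(eta);
  }
  return ll;
}

static double normal_lprior(const arma::vec& x, const arma::vec& sd) {
  double lp = 0.0;
  for (arma::uword i = 0; i < x.n_elem; ++i)
    lp += -0.5 * (x[i] / sd[i]) * (x[i] / sd[i]);
  return lp;
}

// class log-likelihood of the morphometric residual sufficient statistics
// under (sigma_w, sigma_p, rho) -- used by the shared-rho variant
static double class_ll(double n, double Sww, double Swp, double Spp,
                       double sw, double sp, double r) {
  double om = 1.0 - r * r;
  return -n * (std::log(sw) + std::log(sp) + 0.5 * std::log(om))
    - 0.5 / om * (Sww / (sw * sw) - 2.0 * r * Swp / (sw * sp)
                  + Spp / (sp * sp));
}

// [[Rcpp::export]]
List mcmc_chain_cpp(const arma::vec& day_c, const arma::vec& year_c,
                    const arma::vec& w, const arma::vec& p,
                    const arma::ivec& sex_obs, const arma::ivec& age_obs,
                    const arma::ivec& paradoxus,
                    List init, List prior,
                    int n_iter, int n_burn, int thin,
                    double target_accept, bool adapt,
                    int cov_model) {       // 0 = per-class IW, 1 = shared rho
  const arma::uword n = day_c.n_elem;

  // ---- state ----
  arma::vec beta = as<arma::vec>(init["beta"]);            // 12
  arma::vec s = as<arma::vec>(init["s"]);                  // 3
  arma::vec a = as<arma::vec>(init["a"]);                  // 3
  arma::ivec sex = as<arma::ivec>(init["sex"]);            // full labels
  arma::ivec age = as<arma::ivec>(init["age"]);
  std::vector<arma::mat> Sigma(4), Prec(4);
  List Sigma0 = init["Sigma"];
  arma::vec logdet(4);
  for (int g = 0; g < 4; ++g) {
    Sigma[g] = as<arma::mat>(Sigma0[g]);
    Prec[g] = arma::inv_sympd(arma::symmatu(Sigma[g]));
    logdet[g] = std::log(arma::det(Sigma[g]));
  }
  double lam_s = as<double>(init["lam_s"]);
  double lam_a = as<double>(init["lam_a"]);
  arma::vec lam_cov = as<arma::vec>(init["lam_cov"]);      // 9 scalars
  double shared_rho = 0.0;
  if (cov_model == 1) {
    shared_rho = 0.5 * std::log((1.0 + Sigma[0](0, 1) /
      std::sqrt(Sigma[0](0, 0) * Sigma[0](1, 1))) /
      (1.0 - Sigma[0](0, 1) /
      std::sqrt(Sigma[0](0, 0) * Sigma[0](1, 1))));        // atanh(rho)
  }

  // ---- priors ----
  arma::vec beta_mean = as<arma::vec>(prior["beta_mean"]);
  arma::vec beta_sd = as<arma::vec>(prior["beta_sd"]);
  arma::vec s_sd = as<arma::vec>(prior["s_sd"]);
  arma::vec a_sd = as<arma::vec>(prior["a_sd"]);
  arma::mat iw_scale = as<arma::mat>(prior["iw_scale"]);
  double iw_df = as<double>(prior["iw_df"]);
  double sigma_hn_sd = as<double>(prior["sigma_hn_sd"]);   // shared-rho only

  // records needing label updates
  std::vector<arma::uword> miss;
  for (arma::uword i = 0; i < n; ++i)
    if (sex_obs[i] < 0 || age_obs[i] < 0) miss.push_back(i);
  const arma::uword n_miss = miss.size();

  // proposal base scales from covariate spread
  double sd_d = arma::stddev(day_c), sd_y = arma::stddev(year_c);
  if (sd_d <= 0) sd_d = 1.0;
  if (sd_y <= 0) sd_y = 1.0;
  arma::vec base(3);
  base[0] = 1.0; base[1] = 1.0 / sd_d; base[2] = 1.0 / sd_y;

  const int n_save = (n_iter - n_burn) / thin;
  arma::mat draws(n_save, 30);
  IntegerMatrix lab_draws(n_save, n_miss);
  int saved = 0;
  long acc_s = 0, acc_a = 0, n_mh = 0;

  double ll_s = bern_loglik(day_c, year_c, sex, s) + normal_lprior(s, s_sd);
  double ll_a = bern_loglik(day_c, year_c, age, a) + normal_lprior(a, a_sd);

  for (int iter = 1; iter <= n_iter; ++iter) {
    // ---- 1. impute missing labels from the full conditional ----
    for (arma::uword k = 0; k < n_miss; ++k) {
      arma::uword i = miss[k];
      double d = day_c[i], yr = year_c[i];
      double eta_s = s[0] + s[1] * d + s[2] * yr;
      double eta_a = a[0] + a[1] * d + a[2] * yr;
      double sp_s = softplus(eta_s), sp_a = softplus(eta_a);
      int ages[2], sexes[2]; int n_ag, n_sx;
      if (paradoxus[i]) {
        n_ag = 1; ages[0] = 0; n_sx = 1; sexes[0] = 1;
      } else {
        if (age_obs[i] < 0) { n_ag = 2; ages[0] = 0; ages[1] = 1; }
        else { n_ag = 1; ages[0] = age_obs[i]; }
        if (sex_obs[i] < 0) { n_sx = 2; sexes[0] = 0; sexes[1] = 1; }
        else { n_sx = 1; sexes[0] = sex_obs[i]; }
      }
      double lp[4]; int cand_a[4], cand_s[4]; int nc = 0;
      double m = -1e300;
      for (int ia = 0; ia < n_ag; ++ia) for (int is = 0; is < n_sx; ++is) {
        int A = ages[ia], S = sexes[is];
        int g = S + 2 * A;
        double ew = w[i] - (beta[g] + beta[4] * d + beta[5] * yr);
        double ep = p[i] - (beta[6 + g] + beta[10] * d + beta[11] * yr);
        const arma::mat& P = Prec[g];
        double q = P(0,0)*ew*ew + 2.0*P(0,1)*ew*ep + P(1,1)*ep*ep;
        double l = -0.5 * logdet[g] - 0.5 * q
          + S * eta_s - sp_s + A * eta_a - sp_a;
        lp[nc] = l; cand_a[nc] = A; cand_s[nc] = S;
        if (l > m) m = l;
        ++nc;
      }
      if (nc == 1) { age[i] = cand_a[0]; sex[i] = cand_s[0]; continue; }
      double tot = 0.0, cw[4];
      for (int c = 0; c < nc; ++c) { cw[c] = std::exp(lp[c] - m); tot += cw[c]; }
      double u = unif_rand() * tot, cum = 0.0;
      int pick = nc - 1;
      for (int c = 0; c < nc; ++c) { cum += cw[c]; if (u <= cum) { pick = c; break; } }
      if (age[i] != cand_a[pick] || sex[i] != cand_s[pick]) {
        // labels feed the Bernoulli likelihoods; update cached values lazily
        age[i] = cand_a[pick]; sex[i] = cand_s[pick];
      }
    }
    if (n_miss > 0) {   // refresh cached logistic likelihoods
      ll_s = bern_loglik(day_c, year_c, sex, s) + normal_lprior(s, s_sd);
      ll_a = bern_loglik(day_c, year_c, age, a) + normal_lprior(a, a_sd);
    }

    // ---- sufficient statistics by class ----
    arma::mat UU[4]; arma::vec Uw[4], Up[4]; arma::vec ncl(4, arma::fill::zeros);
    for (int g = 0; g < 4; ++g) {
      UU[g] = arma::mat(3, 3, arma::fill::zeros);
      Uw[g] = arma::vec(3, arma::fill::zeros);
      Up[g] = arma::vec(3, arma::fill::zeros);
    }
    for (arma::uword i = 0; i < n; ++i) {
      int g = sex[i] + 2 * age[i];
      double d = day_c[i], yr = year_c[i];
      arma::mat& M = UU[g];
      M(0,0) += 1.0;  M(0,1) += d;    M(0,2) += yr;
      M(1,1) += d*d;  M(1,2) += d*yr; M(2,2) += yr*yr;
      Uw[g][0] += w[i]; Uw[g][1] += d * w[i]; Uw[g][2] += yr * w[i];
      Up[g][0] += p[i]; Up[g][1] += d * p[i]; Up[g][2] += yr * p[i];
      ncl[g] += 1.0;
    }
    for (int g = 0; g < 4; ++g) {
      UU[g](1,0) = UU[g](0,1); UU[g](2,0) = UU[g](0,2); UU[g](2,1) = UU[g](1,2);
    }

    // ---- 2. conjugate draw of the 12 mean-structure coefficients ----
    {
      arma::mat P(12, 12, arma::fill::zeros);
      arma::vec b(12, arma::fill::zeros);
      for (int g = 0; g < 4; ++g) {
        double ia = Prec[g](0,0), ib = Prec[g](0,1), ic = Prec[g](1,1);
        int iw[3] = {g, 4, 5}, ip[3] = {6 + g, 10, 11};
        for (int j = 0; j < 3; ++j) {
          for (int k = 0; k < 3; ++k) {
            P(iw[j], iw[k]) += ia * UU[g](j,k);
            P(iw[j], ip[k]) += ib * UU[g](j,k);
            P(ip[j], iw[k]) += ib * UU[g](j,k);
            P(ip[j], ip[k]) += ic * UU[g](j,k);
          }
          b[iw[j]] += ia * Uw[g][j] + ib * Up[g][j];
          b[ip[j]] += ib * Uw[g][j] + ic * Up[g][j];
        }
      }
      for (int j = 0; j < 12; ++j) {
        double prec0 = 1.0 / (beta_sd[j] * beta_sd[j]);
        P(j, j) += prec0;
        b[j] += beta_mean[j] * prec0;
      }
      arma::mat R = arma::chol(arma::symmatu(P));       // upper
      arma::vec m = arma::solve(arma::trimatu(R),
                    arma::solve(arma::trimatl(R.t()), b));
      arma::vec z(12);
      for (int j = 0; j < 12; ++j) z[j] = norm_rand();
      beta = m + arma::solve(arma::trimatu(R), z);
    }

    // residual crossproducts under the new coefficients
    double Sww[4] = {0,0,0,0}, Swp[4] = {0,0,0,0}, Spp[4] = {0,0,0,0};
    for (arma::uword i = 0; i < n; ++i) {
      int g = sex[i] + 2 * age[i];
      double d = day_c[i], yr = year_c[i];
      double ew = w[i] - (beta[g] + beta[4] * d + beta[5] * yr);
      double ep = p[i] - (beta[6 + g] + beta[10] * d + beta[11] * yr);
      Sww[g] += ew * ew; Swp[g] += ew * ep; Spp[g] += ep * ep;
    }

    // ---- 3. covariance update ----
    if (cov_model == 0) {
      for (int g = 0; g < 4; ++g) {
        arma::mat V = iw_scale;
        V(0,0) += Sww[g]; V(0,1) += Swp[g]; V(1,0) += Swp[g]; V(1,1) += Spp[g];
        rinvwish2(V, iw_df + ncl[g], Sigma[g], Prec[g]);
        logdet[g] = std::log(arma::det(Sigma[g]));
      }
    } else {
      // shared-rho variant: componentwise adaptive RW Metropolis on
      // log sigma_w[g], log sigma_p[g] (half-normal priors) and atanh(rho)
      double gamma = adapt && iter <= n_burn ?
        std::pow((double)iter, -0.6) : 0.0;
      double r = std::tanh(shared_rho);
      for (int g = 0; g < 4; ++g) {
        double sw = std::sqrt(Sigma[g](0,0)), sp = std::sqrt(Sigma[g](1,1));
        // sigma_w[g]
        {
          double cur = std::log(sw);
          double prop = cur + lam_cov[g] * norm_rand();
          double swp = std::exp(prop);
          double dl = class_ll(ncl[g], Sww[g], Swp[g], Spp[g], swp, sp, r)
            - class_ll(ncl[g], Sww[g], Swp[g], Spp[g], sw, sp, r)
            - 0.5 * (swp*swp - sw*sw) / (sigma_hn_sd*sigma_hn_sd)
            + (prop - cur);                               // log-scale Jacobian
          if (std::log(unif_rand()) < dl) sw = swp;
          if (gamma > 0)
            lam_cov[g] *= std::exp(gamma * (std::min(1.0, std::exp(dl))
                                            - target_accept));
        }
        // sigma_p[g]
        {
          double cur = std::log(sp);
          double prop = cur + lam_cov[4 + g] * norm_rand();
          double spp2 = std::exp(prop);
          double dl = class_ll(ncl[g], Sww[g], Swp[g], Spp[g], sw, spp2, r)
            - class_ll(ncl[g], Sww[g], Swp[g], Spp[g], sw, sp, r)
            - 0.5 * (spp2*spp2 - sp*sp) / (sigma_hn_sd*sigma_hn_sd)
            + (prop - cur);
          if (std::log(unif_rand()) < dl) sp = spp2;
          if (gamma > 0)
            lam_cov[4 + g] *= std::exp(gamma * (std::min(1.0, std::exp(dl))
                                                - target_accept));
        }
        Sigma[g](0,0) = sw * sw; Sigma[g](1,1) = sp * sp;
        Sigma[g](0,1) = Sigma[g](1,0) = r * sw * sp;
      }
      // rho (uniform prior on (-1,1); atanh transform, Jacobian log(1-r^2))
      {
        double prop = shared_rho + lam_cov[8] * norm_rand();
        double rp = std::tanh(prop);
        double dl = 0.0;
        for (int g = 0; g < 4; ++g) {
          double sw = std::sqrt(Sigma[g](0,0)), sp = std::sqrt(Sigma[g](1,1));
          dl += class_ll(ncl[g], Sww[g], Swp[g], Spp[g], sw, sp, rp)
            - class_ll(ncl[g], Sww[g], Swp[g], Spp[g], sw, sp, r);
        }
        dl += std::log(1.0 - rp*rp) - std::log(1.0 - r*r);
        if (std::log(unif_rand()) < dl) { shared_rho = prop; r = rp; }
        double gam2 = gamma;
        if (gam2 > 0)
          lam_cov[8] *= std::exp(gam2 * (std::min(1.0, std::exp(dl))
                                         - target_accept));
        for (int g = 0; g < 4; ++g) {
          double sw = std::sqrt(Sigma[g](0,0)), sp = std::sqrt(Sigma[g](1,1));
          Sigma[g](0,1) = Sigma[g](1,0) = r * sw * sp;
          Prec[g] = arma::inv_sympd(arma::symmatu(Sigma[g]));
          logdet[g] = std::log(arma::det(Sigma[g]));
        }
      }
    }

    // ---- 4. adaptive RW Metropolis for the logistic blocks ----
    ll_s = bern_loglik(day_c, year_c, sex, s) + normal_lprior(s, s_sd);
    ll_a = bern_loglik(day_c, year_c, age, a) + normal_lprior(a, a_sd);
    {
      arma::vec z(3); for (int j = 0; j < 3; ++j) z[j] = norm_rand();
      arma::vec sp_ = s + lam_s * (base % z);
      double llp = bern_loglik(day_c, year_c, sex, sp_)
        + normal_lprior(sp_, s_sd);
      double dl = llp - ll_s;
      bool ok = std::log(unif_rand()) < dl;
      if (ok) { s = sp_; ll_s = llp; }
      if (adapt && iter <= n_burn)
        lam_s *= std::exp(std::pow((double)iter, -0.6) *
                          (std::min(1.0, std::exp(dl)) - target_accept));
      else { if (ok) ++acc_s; }
    }
    {
      arma::vec z(3); for (int j = 0; j < 3; ++j) z[j] = norm_rand();
      arma::vec ap_ = a + lam_a * (base % z);
      double llp = bern_loglik(day_c, year_c, age, ap_)
        + normal_lprior(ap_, a_sd);
      double dl = llp - ll_a;
      bool ok = std::log(unif_rand()) < dl;
      if (ok) { a = ap_; ll_a = llp; }
      if (adapt && iter <= n_burn)
        lam_a *= std::exp(std::pow((double)iter, -0.6) *
                          (std::min(1.0, std::exp(dl)) - target_accept));
      else { if (ok) ++acc_a; ++n_mh; }
    }

    // ---- 5. save ----
    if (iter > n_burn && (iter - n_burn) % thin == 0 && saved < n_save) {
      for (int g = 0; g < 4; ++g) {
        draws(saved, g) = beta[g];                 // w0[g]
        draws(saved, 6 + g) = beta[6 + g];         // p0[g]
        draws(saved, 12 + g) = std::sqrt(Sigma[g](0,0));
        draws(saved, 16 + g) = std::sqrt(Sigma[g](1,1));
        draws(saved, 20 + g) = Sigma[g](0,1) /
          std::sqrt(Sigma[g](0,0) * Sigma[g](1,1));
      }
      draws(saved, 4) = beta[4];  draws(saved, 5) = beta[5];
      draws(saved, 10) = beta[10]; draws(saved, 11) = beta[11];
      for (int j = 0; j < 3; ++j) {
        draws(saved, 24 + j) = s[j];
        draws(saved, 27 + j) = a[j];
      }
      for (arma::uword k = 0; k < n_miss; ++k) {
        arma::uword i = miss[k];
        lab_draws(saved, k) = 1 + sex[i] + 2 * age[i];
      }
      ++saved;
    }
  }

  return List::create(
    _["draws"] = draws,
    _["labels"] = lab_draws,
    _["miss_idx"] = IntegerVector(miss.begin(), miss.end()),
    _["accept_s"] = n_mh > 0 ? (double)acc_s / n_mh : NA_REAL,
    _["accept_a"] = n_mh > 0 ? (double)acc_a / n_mh : NA_REAL,
    _["lam_s"] = lam_s, _["lam_a"] = lam_a, _["lam_cov"] = lam_cov);
}
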