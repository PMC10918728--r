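// Metropolis-within-Gibbs samplers for the joint relative-abundance +
// classification model. Scenario codes:
//   1 variable, 2 fixed_covariate, 3 fixed_intercov, 4 intercept,
//   5 constant (Dirichlet), 6 main (Dirichlet + z1 in the ecology).
// Conventions: states are 1-based in the interface; v == 0 marks an
// unverified record; the last reported state K is the softmax reference.
// Scalar random-walk proposals adapt toward 0.44 acceptance during
// burn-in (Robbins-Monro on the log proposal scale). Spike-and-slab
// slopes are refreshed from the slab prior whenever their indicator is
// off (Kuo-Mallick), which keeps the indicator flip an exact Gibbs step.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double lse(const double* a, int m) {
  double mx = a[0];
  for (int i = 1; i < m; ++i) if (a[i] > mx) mx = a[i];
  double s = 0.0;
  for (int i = 0; i < m; ++i) s += std::exp(a[i] - mx);
  return mx + std::log(s);
}

struct AdaptScale {
  std::vector<double> log_scale;
  double target;
  AdaptScale(int n, double init, double target_) : log_scale(n, std::log(init)), target(target_) {}
  double scale(int i) const { return std::exp(log_scale[i]); }
  void update(int i, double acc_prob, int iter) {
    double step = std::pow((double)iter, -0.55);
    log_scale[i] += step * (acc_prob - target);
    if (log_scale[i] < -10.0) log_scale[i] = -10.0;
    if (log_scale[i] > 5.0) log_scale[i] = 5.0;
  }
};

// [[Rcpp::export]]
List mcmc_msdm_cpp(IntegerVector y, IntegerVector v,
                   NumericMatrix X, NumericMatrix Z,
                   int J, int K, IntegerVector diag_map, int scenario,
                   double eco_sd, double cls_sd,
                   int n_iter, int n_burnin, int thin,
                   bool adapt, double init_scale, double alpha_fixed) {
  const int S = y.size();
  const int n_e = X.ncol();
  const int n = Z.ncol();
  const bool dirichlet = (scenario == 5 || scenario == 6);
  const bool mmglm = !dirichlet;
  const bool spike_cls = (scenario >= 1 && scenario <= 3);
  const double eco_var = eco_sd * eco_sd, cls_var = cls_sd * cls_sd;

  if (scenario == 6 && n < 1) stop("scenario 'main' needs a classification covariate z1");

  // ---- state ----
  std::vector<double> beta0(J, 0.0);
  std::vector<double> beta(n_e * (size_t)J, 0.0);            // (q, j) -> q + n_e*j
  std::vector<double> beta3(J, 0.0);
  int psi_eco = 1; double nu_eco = 0.5;
  std::vector<double> omega0(J * (size_t)K, 0.0);            // (j, k) -> j + J*k
  std::vector<double> omega(std::max(1, n) * (size_t)J * K, 0.0); // (p,j,k) -> p + n*(j + J*k)
  std::vector<int> psi(std::max(1, n), 1);
  std::vector<double> nu(std::max(1, n), 0.5);
  std::vector<double> OmD(J * (size_t)K, 1.0 / K);           // Dirichlet-form confusion matrix
  double alpha = (alpha_fixed > 0.0) ? alpha_fixed : 1.0;

  // latent true states: verified copied, unverified initialised through the
  // inverse correct-classification map when the reported state has one
  std::vector<int> inv_dm(K, 0);
  for (int j = 0; j < J; ++j) inv_dm[diag_map[j] - 1] = j + 1;
  std::vector<int> V(S);
  std::vector<int> unver;
  for (int s = 0; s < S; ++s) {
    if (v[s] > 0) V[s] = v[s];
    else {
      V[s] = inv_dm[y[s] - 1] > 0 ? inv_dm[y[s] - 1] : 1;
      unver.push_back(s);
    }
  }
  const int n_unver = (int)unver.size();

  // ---- free-parameter bookkeeping for the MMGLM ----
  // omega0 free cells (k < K-1 means non-reference; scenario 3 ties diagonal)
  std::vector<std::pair<int,int> > free_o0;   // (j, k)
  std::vector<std::pair<int,int> > tied_diag; // scenario 3 shared cells
  std::vector<int> free_om;                   // flat (p,j,k) indices
  if (mmglm) {
    for (int k = 0; k < K - 1; ++k)
      for (int j = 0; j < J; ++j) {
        if (scenario == 3 && diag_map[j] - 1 == k) { tied_diag.push_back(std::make_pair(j, k)); continue; }
        free_o0.push_back(std::make_pair(j, k));
      }
    if (scenario == 3 && tied_diag.empty())
      stop("fixed_intercov: no free correct-classification intercept to tie");
    if (scenario != 4) {
      for (int p = 0; p < n; ++p)
        for (int j = 0; j < J; ++j)
          for (int k = 0; k < K - 1; ++k) {
            if ((scenario == 2 || scenario == 3) && diag_map[j] - 1 != k) continue;
            free_om.push_back(p + n * (j + (size_t)J * k));
          }
    }
  }

  // ---- caches ----
  std::vector<double> eta(std::max(1, S) * (size_t)J, 0.0); // (s, j) -> s*J + j
  std::vector<double> z1(S, 0.0);
  if (n >= 1) for (int s = 0; s < S; ++s) z1[s] = Z(s, 0);

  // rebuild the ecological linear predictor cache
  #define RECOMPUTE_ETA() do {                                        \
    for (int s = 0; s < S; ++s)                                       \
      for (int j = 0; j < J; ++j) {                                   \
        double e = beta0[j];                                          \
        for (int q = 0; q < n_e; ++q) e += X(s, q) * beta[q + n_e * (size_t)j]; \
        if (scenario == 6 && psi_eco) e += z1[s] * beta3[j];          \
        eta[s * (size_t)J + j] = e;                                   \
      }                                                               \
  } while (0)
  RECOMPUTE_ETA();

  // classification linear predictor row for true state j of record s
  std::vector<double> rowbuf(K), rowbuf2(K), pbuf(J);
  #define ZETA_ROW(s, j, out) do {                                    \
    for (int k = 0; k < K; ++k) {                                     \
      double zz = omega0[(j) + J * (size_t)k];                        \
      for (int p = 0; p < n; ++p)                                     \
        if (psi[p]) zz += Z((s), p) * omega[p + n * ((j) + (size_t)J * k)]; \
      out[k] = zz;                                                    \
    }                                                                 \
  } while (0)

  // ---- proposal scales ----
  // blocks: eco scalars | shared-diag | free omega0 | free omega | alpha
  const int n_eco_sc = J + n_e * J + (scenario == 6 ? J : 0);
  const int idx_diag = n_eco_sc;
  const int idx_o0 = idx_diag + (scenario == 3 ? 1 : 0);
  const int idx_om = idx_o0 + (int)free_o0.size();
  const int idx_alpha = idx_om + (int)free_om.size();
  AdaptScale scales(idx_alpha + 1, init_scale, 0.44);
  std::vector<double> acc_count(idx_alpha + 1, 0.0), prop_count(idx_alpha + 1, 0.0);

  // ---- storage ----
  const int n_keep = (n_iter - n_burnin) / thin;
  NumericMatrix keep_beta0(n_keep, J), keep_beta(n_keep, n_e * J);
  NumericMatrix keep_beta3(n_keep, scenario == 6 ? J : 0);
  NumericMatrix keep_psi_eco(n_keep, scenario == 6 ? 2 : 0); // psi_eco, nu_eco
  NumericMatrix keep_o0(n_keep, mmglm ? J * K : 0);
  NumericMatrix keep_om(n_keep, (mmglm && scenario != 4) ? n * J * K : 0);
  NumericMatrix keep_psi(n_keep, spike_cls ? n : 0), keep_nu(n_keep, spike_cls ? n : 0);
  NumericMatrix keep_OmD(n_keep, dirichlet ? J * K : 0);
  NumericMatrix keep_alpha(n_keep, dirichlet ? 1 : 0);
  IntegerMatrix keep_V(n_keep, n_unver);
  int keep_row = 0;

  RNGScope rng;

  // ecological log-likelihood with a scalar shift d on column j,
  // multiplier mult[s] (nullptr => 1): returns prop - cur
  // (also used with d = 0 to get plain log-likelihoods)
  std::vector<double> erow(J);

  for (int iter = 1; iter <= n_iter; ++iter) {
    const bool adapting = adapt && iter <= n_burnin;

    // ---------- (i) latent true states ----------
    for (int ii = 0; ii < n_unver; ++ii) {
      int s = unver[ii];
      double emax = eta[s * (size_t)J];
      for (int j = 1; j < J; ++j) if (eta[s * (size_t)J + j] > emax) emax = eta[s * (size_t)J + j];
      double tot = 0.0;
      for (int j = 0; j < J; ++j) {
        double pj = std::exp(eta[s * (size_t)J + j] - emax);
        double om;
        if (mmglm) {
          ZETA_ROW(s, j, rowbuf);
          om = std::exp(rowbuf[y[s] - 1] - lse(&rowbuf[0], K));
        } else {
          om = OmD[j + J * (size_t)(y[s] - 1)];
        }
        pbuf[j] = pj * om;
        tot += pbuf[j];
      }
      if (!(tot > 0.0)) stop("reported state impossible under the current model state");
      double u = R::runif(0.0, tot), c = 0.0;
      int draw = J;
      for (int j = 0; j < J; ++j) { c += pbuf[j]; if (u <= c) { draw = j + 1; break; } }
      V[s] = draw;
    }

    // ---------- (ii) ecological parameters ----------
    int sc_idx = 0;
    for (int j = 0; j < J; ++j) {  // intercepts, then slopes, then beta3
      for (int which = 0; which < 1 + n_e + (scenario == 6 ? 1 : 0); ++which) {
        double* par;
        bool is_b3 = false;
        int q = which - 1;
        if (which == 0) par = &beta0[j];
        else if (q < n_e) par = &beta[q + n_e * (size_t)j];
        else { par = &beta3[j]; is_b3 = true; }

        if (is_b3 && !psi_eco) { // indicator off: slope refreshed from its slab prior
          *par = R::rnorm(0.0, eco_sd);
          ++sc_idx;
          continue;
        }
        double sc = scales.scale(sc_idx);
        double d = R::rnorm(0.0, sc);
        double dll = 0.0;
        for (int s = 0; s < S; ++s) {
          double mult = (which == 0) ? 1.0 : (is_b3 ? z1[s] : X(s, q));
          const double* er = &eta[s * (size_t)J];
          double cur = er[V[s] - 1] - lse(er, J);
          for (int jj = 0; jj < J; ++jj) erow[jj] = er[jj];
          erow[j] += d * mult;
          double prop = erow[V[s] - 1] - lse(&erow[0], J);
          dll += prop - cur;
        }
        double pnew = *par + d;
        double logr = dll + 0.5 * ((*par) * (*par) - pnew * pnew) / eco_var;
        double ap = std::min(1.0, std::exp(logr));
        prop_count[sc_idx] += 1.0;
        if (R::runif(0.0, 1.0) < ap) {
          *par = pnew;
          for (int s = 0; s < S; ++s) {
            double mult = (which == 0) ? 1.0 : (is_b3 ? z1[s] : X(s, q));
            eta[s * (size_t)J + j] += d * mult;
          }
          acc_count[sc_idx] += 1.0;
        }
        if (adapting) scales.update(sc_idx, ap, iter);
        ++sc_idx;
      }
    }

    // spike-and-slab flip for the z1 term in the ecology (scenario 'main')
    if (scenario == 6) {
      double l1 = 0.0, l0 = 0.0;
      for (int s = 0; s < S; ++s) {
        for (int jj = 0; jj < J; ++jj) {
          double base = beta0[jj];
          for (int q = 0; q < n_e; ++q) base += X(s, q) * beta[q + n_e * (size_t)jj];
          erow[jj] = base;
        }
        l0 += erow[V[s] - 1] - lse(&erow[0], J);
        for (int jj = 0; jj < J; ++jj) erow[jj] += z1[s] * beta3[jj];
        l1 += erow[V[s] - 1] - lse(&erow[0], J);
      }
      double m = std::max(l1 + std::log(nu_eco), l0 + std::log(1.0 - nu_eco));
      double w1 = std::exp(l1 + std::log(nu_eco) - m);
      double w0 = std::exp(l0 + std::log(1.0 - nu_eco) - m);
      psi_eco = (R::runif(0.0, 1.0) < w1 / (w1 + w0)) ? 1 : 0;
      nu_eco = R::rbeta(1.0 + psi_eco, 2.0 - psi_eco);
      RECOMPUTE_ETA();
    }

    if (mmglm) {
      // ---------- (iii) MMGLM classification parameters ----------
      // shared correct-classification intercept (scenario 3)
      if (scenario == 3) {
        double sc = scales.scale(idx_diag);
        double d = R::rnorm(0.0, sc);
        double dll = 0.0;
        for (int s = 0; s < S; ++s) {
          int j = V[s] - 1;
          int kd = diag_map[j] - 1;
          ZETA_ROW(s, j, rowbuf);
          double cur = rowbuf[y[s] - 1] - lse(&rowbuf[0], K);
          if (kd < K - 1) rowbuf[kd] += d;
          double prop = rowbuf[y[s] - 1] - lse(&rowbuf[0], K);
          dll += prop - cur;
        }
        double cur_val = omega0[tied_diag[0].first + J * (size_t)tied_diag[0].second];
        double pnew = cur_val + d;
        double logr = dll + 0.5 * (cur_val * cur_val - pnew * pnew) / cls_var;
        double ap = std::min(1.0, std::exp(logr));
        prop_count[idx_diag] += 1.0;
        if (R::runif(0.0, 1.0) < ap) {
          for (size_t t = 0; t < tied_diag.size(); ++t)
            omega0[tied_diag[t].first + J * (size_t)tied_diag[t].second] = pnew;
          acc_count[idx_diag] += 1.0;
        }
        if (adapting) scales.update(idx_diag, ap, iter);
      }

      // free intercepts
      for (size_t f = 0; f < free_o0.size(); ++f) {
        int j = free_o0[f].first, k = free_o0[f].second;
        int si = idx_o0 + (int)f;
        double d = R::rnorm(0.0, scales.scale(si));
        double dll = 0.0;
        for (int s = 0; s < S; ++s) {
          if (V[s] - 1 != j) continue;
          ZETA_ROW(s, j, rowbuf);
          double cur = rowbuf[y[s] - 1] - lse(&rowbuf[0], K);
          rowbuf[k] += d;
          double prop = rowbuf[y[s] - 1] - lse(&rowbuf[0], K);
          dll += prop - cur;
        }
        double cur_val = omega0[j + J * (size_t)k], pnew = cur_val + d;
        double logr = dll + 0.5 * (cur_val * cur_val - pnew * pnew) / cls_var;
        double ap = std::min(1.0, std::exp(logr));
        prop_count[si] += 1.0;
        if (R::runif(0.0, 1.0) < ap) { omega0[j + J * (size_t)k] = pnew; acc_count[si] += 1.0; }
        if (adapting) scales.update(si, ap, iter);
      }

      // free covariate effects (random walk when selected, prior refresh when not)
      for (size_t f = 0; f < free_om.size(); ++f) {
        int flat = free_om[f];
        int p = flat % n;
        int rest = flat / n;
        int j = rest % J, k = rest / J;
        int si = idx_om + (int)f;
        if (spike_cls && !psi[p]) {
          omega[flat] = R::rnorm(0.0, cls_sd);
          continue;
        }
        double d = R::rnorm(0.0, scales.scale(si));
        double dll = 0.0;
        for (int s = 0; s < S; ++s) {
          if (V[s] - 1 != j) continue;
          ZETA_ROW(s, j, rowbuf);
          double cur = rowbuf[y[s] - 1] - lse(&rowbuf[0], K);
          rowbuf[k] += d * Z(s, p);
          double prop = rowbuf[y[s] - 1] - lse(&rowbuf[0], K);
          dll += prop - cur;
        }
        double cur_val = omega[flat], pnew = cur_val + d;
        double logr = dll + 0.5 * (cur_val * cur_val - pnew * pnew) / cls_var;
        double ap = std::min(1.0, std::exp(logr));
        prop_count[si] += 1.0;
        if (R::runif(0.0, 1.0) < ap) { omega[flat] = pnew; acc_count[si] += 1.0; }
        if (adapting) scales.update(si, ap, iter);
      }

      // ---------- (iv) spike-and-slab indicator + inclusion probability ----------
      if (spike_cls) {
        for (int p = 0; p < n; ++p) {
          int saved = psi[p];
          double l1 = 0.0, l0 = 0.0;
          for (int s = 0; s < S; ++s) {
            int j = V[s] - 1;
            psi[p] = 1; ZETA_ROW(s, j, rowbuf);
            psi[p] = 0; ZETA_ROW(s, j, rowbuf2);
            l1 += rowbuf[y[s] - 1] - lse(&rowbuf[0], K);
            l0 += rowbuf2[y[s] - 1] - lse(&rowbuf2[0], K);
          }
          psi[p] = saved;
          double m = std::max(l1 + std::log(nu[p]), l0 + std::log(1.0 - nu[p]));
          double w1 = std::exp(l1 + std::log(nu[p]) - m);
          double w0 = std::exp(l0 + std::log(1.0 - nu[p]) - m);
          psi[p] = (R::runif(0.0, 1.0) < w1 / (w1 + w0)) ? 1 : 0;
          nu[p] = R::rbeta(1.0 + psi[p], 2.0 - psi[p]);
        }
      }
    } else {
      // ---------- (v) Dirichlet classification ----------
      std::vector<double> cnt(J * (size_t)K, 0.0);
      for (int s = 0; s < S; ++s) cnt[(V[s] - 1) + J * (size_t)(y[s] - 1)] += 1.0;
      for (int j = 0; j < J; ++j) {
        double tot = 0.0;
        for (int k = 0; k < K; ++k) {
          double g = R::rgamma(alpha + cnt[j + J * (size_t)k], 1.0);
          OmD[j + J * (size_t)k] = g;
          tot += g;
        }
        for (int k = 0; k < K; ++k) OmD[j + J * (size_t)k] /= tot;
      }
      if (alpha_fixed <= 0.0) {
        // log-scale random walk on the Dirichlet concentration, Exp(1) prior
        double d = R::rnorm(0.0, scales.scale(idx_alpha));
        double anew = alpha * std::exp(d);
        double slog = 0.0;
        for (int j = 0; j < J; ++j)
          for (int k = 0; k < K; ++k) slog += std::log(std::max(OmD[j + J * (size_t)k], 1e-300));
        double ll_cur = J * (R::lgammafn(K * alpha) - K * R::lgammafn(alpha)) + (alpha - 1.0) * slog - alpha;
        double ll_new = J * (R::lgammafn(K * anew) - K * R::lgammafn(anew)) + (anew - 1.0) * slog - anew;
        double logr = ll_new - ll_cur + std::log(anew) - std::log(alpha); // Jacobian
        double ap = std::min(1.0, std::exp(logr));
        prop_count[idx_alpha] += 1.0;
        if (R::runif(0.0, 1.0) < ap) { alpha = anew; acc_count[idx_alpha] += 1.0; }
        if (adapting) scales.update(idx_alpha, ap, iter);
      }
    }

    // ---------- bookkeeping ----------
    if (iter > n_burnin && (iter - n_burnin) % thin == 0 && keep_row < n_keep) {
      for (int j = 0; j < J; ++j) keep_beta0(keep_row, j) = beta0[j];
      for (int i = 0; i < n_e * J; ++i) keep_beta(keep_row, i) = beta[i];
      if (scenario == 6) {
        for (int j = 0; j < J; ++j) keep_beta3(keep_row, j) = beta3[j];
        keep_psi_eco(keep_row, 0) = psi_eco;
        keep_psi_eco(keep_row, 1) = nu_eco;
      }
      if (mmglm) {
        for (int i = 0; i < J * K; ++i) keep_o0(keep_row, i) = omega0[i];
        if (scenario != 4)
          for (int i = 0; i < n * J * K; ++i) keep_om(keep_row, i) = omega[i];
        if (spike_cls)
          for (int p = 0; p < n; ++p) { keep_psi(keep_row, p) = psi[p]; keep_nu(keep_row, p) = nu[p]; }
      } else {
        for (int i = 0; i < J * K; ++i) keep_OmD(keep_row, i) = OmD[i];
        keep_alpha(keep_row, 0) = alpha;
      }
      for (int ii = 0; ii < n_unver; ++ii) keep_V(keep_row, ii) = V[unver[ii]];
      ++keep_row;
    }
  }

  NumericVector acc_rate(idx_alpha + 1), out_scales(idx_alpha + 1);
  for (int i = 0; i <= idx_alpha; ++i) {
    acc_rate[i] = prop_count[i] > 0 ? acc_count[i] / prop_count[i] : NA_REAL;
    out_scales[i] = scales.scale(i);
  }

  return List::create(
    _["beta0"] = keep_beta0, _["beta"] = keep_beta, _["beta3"] = keep_beta3,
    _["psi_eco"] = keep_psi_eco, _["omega0"] = keep_o0, _["omega"] = keep_om,
    _["psi"] = keep_psi, _["nu"] = keep_nu, _["Omega"] = keep_OmD,
    _["alpha"] = keep_alpha, _["V"] = keep_V,
    _["unverified_index"] = IntegerVector(unver.begin(), unver.end()),
    _["acc_rate"] = acc_rate, _["proposal_scales"] = out_scales);
}

// Multinomial-logit sampler for reported-state intensities (the score-
// weighting alternative): Y_s ~ Categorical(softmax(gamma0_k + x' gamma_k))
// with reported state K as the reference.
// [[Rcpp::export]]
List mcmc_multinom_cpp(IntegerVector y, NumericMatrix X, int K,
                       double prior_sd, int n_iter, int n_burnin, int thin,
                       bool adapt, double init_scale) {
  const int S = y.size();
  const int n_e = X.ncol();
  const double pvar = prior_sd * prior_sd;
  std::vector<double> gamma0(K, 0.0);                 // [K-1] pinned at 0
  std::vector<double> gamma(n_e * (size_t)K, 0.0);    // (q, k) -> q + n_e*k
  std::vector<double> eta(std::max(1, S) * (size_t)K, 0.0);
  const int n_par = (K - 1) * (1 + n_e);
  AdaptScale scales(n_par, init_scale, 0.44);
  std::vector<double> acc_count(n_par, 0.0), prop_count(n_par, 0.0);
  const int n_keep = (n_iter - n_burnin) / thin;
  NumericMatrix keep_g0(n_keep, K), keep_g(n_keep, n_e * K);
  int keep_row = 0;
  std::vector<double> erow(K);
  RNGScope rng;

  for (int iter = 1; iter <= n_iter; ++iter) {
    const bool adapting = adapt && iter <= n_burnin;
    int si = 0;
    for (int k = 0; k < K - 1; ++k) {
      for (int which = 0; which <= n_e; ++which) {
        double* par = (which == 0) ? &gamma0[k] : &gamma[(which - 1) + n_e * (size_t)k];
        double d = R::rnorm(0.0, scales.scale(si));
        double dll = 0.0;
        for (int s = 0; s < S; ++s) {
          double mult = (which == 0) ? 1.0 : X(s, which - 1);
          const double* er = &eta[s * (size_t)K];
          double cur = er[y[s] - 1] - lse(er, K);
          for (int kk = 0; kk < K; ++kk) erow[kk] = er[kk];
          erow[k] += d * mult;
          double prop = erow[y[s] - 1] - lse(&erow[0], K);
          dll += prop - cur;
        }
        double pnew = *par + d;
        double logr = dll + 0.5 * ((*par) * (*par) - pnew * pnew) / pvar;
        double ap = std::min(1.0, std::exp(logr));
        prop_count[si] += 1.0;
        if (R::runif(0.0, 1.0) < ap) {
          *par = pnew;
          for (int s = 0; s < S; ++s) {
            double mult = (which == 0) ? 1.0 : X(s, which - 1);
            eta[s * (size_t)K + k] += d * mult;
          }
          acc_count[si] += 1.0;
        }
        if (adapting) scales.update(si, ap, iter);
        ++si;
      }
    }
    if (iter > n_burnin && (iter - n_burnin) % thin == 0 && keep_row < n_keep) {
      for (int k = 0; k < K; ++k) keep_g0(keep_row, k) = gamma0[k];
      for (int i = 0; i < n_e * K; ++i) keep_g(keep_row, i) = gamma[i];
      ++keep_row;
    }
  }
  NumericVector acc_rate(n_par);
  for (int i = 0; i < n_par; ++i)
    acc_rate[i] = prop_count[i] > 0 ? acc_count[i] / prop_count[i] : NA_REAL;
  return List::create(_["gamma0"] = keep_g0, _["gamma"] = keep_g,
                      _["acc_rate"] = acc_rate);
}
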