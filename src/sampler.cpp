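// Update sweep of the adaptive Metropolis-within-Gibbs sampler.
//
// The R side builds the chain state (design caches, initial values,
// proposal scales); each call advances the chain n_iter iterations and
// returns the updated state plus the recorded draws.  All randomness
// comes from R's RNG, so reproducibility is governed by .Random.seed.

#include <Rcpp.h>
using namespace Rcpp;

static inline double log1pexp_d(double x) {
  if (x > 0) return x + log1p(exp(-x));
  return log1p(exp(x));
}

// slice sampler for a random-effect SD: target
// -m*log(s) - ssq/(2 s^2) + log N(s; 0, prior_sd), s > 0
static double slice_sigma_c(double s0, int m, double ssq, double prior_sd) {
  const double w = 0.5;
  const int max_step = 50;
  auto logf = [&](double s) -> double {
    if (s <= 0) return R_NegInf;
    return -m * std::log(s) - ssq / (2 * s * s) +
      R::dnorm(s, 0.0, prior_sd, 1);
  };
  double y = logf(s0) - R::exp_rand();
  double lo = s0 - w * R::unif_rand();
  double hi = lo + w;
  int k = max_step;
  while (k-- > 0 && lo > 0 && logf(lo) > y) lo -= w;
  if (lo < 0) lo = 0;
  k = max_step;
  while (k-- > 0 && logf(hi) > y) hi += w;
  for (;;) {
    double s1 = lo + R::unif_rand() * (hi - lo);
    if (logf(s1) > y) return s1;
    if (s1 < s0) lo = s1; else hi = s1;
  }
}

// sig indices: 0 = year_success, 1 = year_count, 2 = territory, 3 = population

// [[Rcpp::export]]
List zipfec_sweep(List st, int n_iter, bool adapt, bool record,
                  double w, NumericVector b_prior_sd_,
                  double sigma_prior_sd) {
  const double b_sd = b_prior_sd_[0];

  // data (read-only)
  const IntegerVector S = st["S"];
  const NumericMatrix XS_in = st["XS"];
  NumericMatrix XS = clone(XS_in);        // experience columns mutate
  const NumericMatrix XC1 = st["XC1"];
  const IntegerVector C1 = st["C1"];
  const IntegerVector yi = st["yi0"];     // 0-based row -> group maps
  const IntegerVector yi1 = st["yi10"];
  const IntegerVector pi1 = st["pi10"];
  const IntegerVector ti1 = st["ti10"];
  const IntegerVector mi_m = st["mi_m0"]; // 0-based missing-cell rows
  const IntegerVector mi_f = st["mi_f0"];
  const double lgamma_const = st["lgamma_const"];
  const NumericVector rainS_y = st["rainS_y"];
  const NumericVector rainC_y = st["rainC_y"];
  const NumericVector food_p = st["food_p"]; // per-population food flag
  const bool food_exchange_ok = st["food_exchange_ok"];
  const int n = S.size(), n1 = C1.size();
  const int Y = rainS_y.size();

  // parameters (mutable copies)
  NumericVector bs = clone(as<NumericVector>(st["bs"]));
  NumericVector bc = clone(as<NumericVector>(st["bc"]));
  NumericVector sig = clone(as<NumericVector>(st["sig"]));
  NumericVector uS = clone(as<NumericVector>(st["uS"]));
  NumericVector uC = clone(as<NumericVector>(st["uC"]));
  NumericVector vP = clone(as<NumericVector>(st["vP"]));
  NumericVector wT = clone(as<NumericVector>(st["wT"]));
  double piM = st["piM"], piF = st["piF"];
  const int P = vP.size(), T = wT.size();

  // caches
  NumericVector etaS = clone(as<NumericVector>(st["etaS"]));
  NumericVector l1pS = clone(as<NumericVector>(st["l1pS"]));
  NumericVector etaC1 = clone(as<NumericVector>(st["etaC1"]));
  NumericVector expC1 = clone(as<NumericVector>(st["expC1"]));

  // adaptation state
  NumericVector ls_bs = clone(as<NumericVector>(st["ls_bs"]));
  NumericVector ls_bc = clone(as<NumericVector>(st["ls_bc"]));
  NumericVector ls_re = clone(as<NumericVector>(st["ls_re"]));
  NumericVector ls_aux = clone(as<NumericVector>(st["ls_aux"]));
  NumericVector ls_sig = clone(as<NumericVector>(st["ls_sig"]));
  NumericVector acc_sig = clone(as<NumericVector>(st["acc_sig"]));
  NumericVector acc_bs = clone(as<NumericVector>(st["acc_bs"]));
  NumericVector acc_bc = clone(as<NumericVector>(st["acc_bc"]));
  NumericVector acc_re = clone(as<NumericVector>(st["acc_re"]));
  NumericVector acc_aux = clone(as<NumericVector>(st["acc_aux"]));
  int batch = st["batch"];

  const int exp_m_col = 5, exp_f_col = 6;   // XS columns (0-based)
  const int rain_s_col = 8, rain_c_col = 5, food_col = 7; // 0-based
  const int n_par = 22 + 2 * Y + P + T + 3;
  NumericMatrix out(record ? n_iter : 0, record ? n_par : 0);

  std::vector<double> scr1(n), scr2(n), scrC1(n1), scrC2(n1);
  std::vector<double> dele(std::max(std::max(Y, P), T));
  std::vector<double> eps(std::max(std::max(Y, P), T));

  for (int it = 0; it < n_iter; ++it) {
    // ---- success coefficients
    for (int j = 0; j < 9; ++j) {
      double step = R::norm_rand() * std::exp(ls_bs[j]);
      double dll = 0.0;
      for (int i = 0; i < n; ++i) {
        double en = etaS[i] + XS(i, j) * step;
        double l1 = log1pexp_d(en);
        dll += S[i] * (en - etaS[i]) - (l1 - l1pS[i]);
        scr1[i] = en; scr2[i] = l1;
      }
      dll *= w;
      double b_old = bs[j], b_new = b_old + step;
      double dlp = (b_old * b_old - b_new * b_new) / (2 * b_sd * b_sd);
      if (R_FINITE(dll) && std::log(R::unif_rand()) < dll + dlp) {
        bs[j] = b_new;
        for (int i = 0; i < n; ++i) { etaS[i] = scr1[i]; l1pS[i] = scr2[i]; }
        acc_bs[j] += 1;
      }
    }

    // ---- count coefficients
    for (int j = 0; j < 9; ++j) {
      double step = R::norm_rand() * std::exp(ls_bc[j]);
      double dll = 0.0;
      for (int i = 0; i < n1; ++i) {
        double en = etaC1[i] + XC1(i, j) * step;
        double ex = std::exp(en);
        dll += C1[i] * (en - etaC1[i]) - (ex - expC1[i]);
        scrC1[i] = en; scrC2[i] = ex;
      }
      dll *= w;
      double b_old = bc[j], b_new = b_old + step;
      double dlp = (b_old * b_old - b_new * b_new) / (2 * b_sd * b_sd);
      if (R_FINITE(dll) && std::log(R::unif_rand()) < dll + dlp) {
        bc[j] = b_new;
        for (int i = 0; i < n1; ++i) { etaC1[i] = scrC1[i]; expC1[i] = scrC2[i]; }
        acc_bc[j] += 1;
      }
    }

    if (w == 0.0) {
      // prior-only mode: random effects have exact Normal(0, sigma)
      // conditionals -- draw them directly
      for (int g = 0; g < Y; ++g) uS[g] = R::norm_rand() * sig[0];
      for (int g = 0; g < Y; ++g) uC[g] = R::norm_rand() * sig[1];
      for (int g = 0; g < P; ++g) vP[g] = R::norm_rand() * sig[3];
      for (int g = 0; g < T; ++g) wT[g] = R::norm_rand() * sig[2];
      for (int i = 0; i < n; ++i) {
        double e = uS[yi[i]];
        for (int j = 0; j < 9; ++j) e += XS(i, j) * bs[j];
        etaS[i] = e; l1pS[i] = log1pexp_d(e);
      }
      for (int i = 0; i < n1; ++i) {
        double e = uC[yi1[i]] + vP[pi1[i]] + wT[ti1[i]];
        for (int j = 0; j < 9; ++j) e += XC1(i, j) * bc[j];
        etaC1[i] = e; expC1[i] = std::exp(e);
      }
    } else {
      // ---- random-effect blocks: joint proposal, per-group acceptance
      // (groups touch disjoint rows, so the decisions are independent)
      // year effect, success submodel
      {
        double sc = std::exp(ls_re[0]);
        double s2 = sig[0] * sig[0];
        for (int g = 0; g < Y; ++g) { eps[g] = R::norm_rand() * sc; dele[g] = 0.0; }
        for (int i = 0; i < n; ++i) {
          int g = yi[i];
          double en = etaS[i] + eps[g];
          dele[g] += S[i] * eps[g] - (log1pexp_d(en) - l1pS[i]);
        }
        double nacc = 0.0;
        for (int g = 0; g < Y; ++g) {
          double u0 = uS[g], u1 = u0 + eps[g];
          double dlp = (u0 * u0 - u1 * u1) / (2 * s2);
          double d = dele[g] + dlp;
          if (R_FINITE(d) && std::log(R::unif_rand()) < d) { uS[g] = u1; nacc += 1; }
          else eps[g] = 0.0;
        }
        for (int i = 0; i < n; ++i)
          if (eps[yi[i]] != 0.0) { etaS[i] += eps[yi[i]]; l1pS[i] = log1pexp_d(etaS[i]); }
        acc_re[0] += nacc / Y;
      }
      // count-submodel blocks: year (uC), population (vP), territory (wT)
      for (int blk = 1; blk < 4; ++blk) {
        NumericVector& u = (blk == 1) ? uC : (blk == 2 ? vP : wT);
        const IntegerVector& gi = (blk == 1) ? yi1 : (blk == 2 ? pi1 : ti1);
        double s2 = (blk == 1) ? sig[1] * sig[1]
                  : (blk == 2) ? sig[3] * sig[3] : sig[2] * sig[2];
        int G = u.size();
        double sc = std::exp(ls_re[blk]);
        for (int g = 0; g < G; ++g) { eps[g] = R::norm_rand() * sc; dele[g] = 0.0; }
        for (int i = 0; i < n1; ++i) {
          int g = gi[i];
          double en = etaC1[i] + eps[g];
          dele[g] += C1[i] * eps[g] - (std::exp(en) - expC1[i]);
        }
        double nacc = 0.0;
        for (int g = 0; g < G; ++g) {
          double u0 = u[g], u1 = u0 + eps[g];
          double dlp = (u0 * u0 - u1 * u1) / (2 * s2);
          double d = dele[g] + dlp;
          if (R_FINITE(d) && std::log(R::unif_rand()) < d) { u[g] = u1; nacc += 1; }
          else eps[g] = 0.0;
        }
        for (int i = 0; i < n1; ++i)
          if (eps[gi[i]] != 0.0) { etaC1[i] += eps[gi[i]]; expC1[i] = std::exp(etaC1[i]); }
        acc_re[blk] += nacc / G;
      }
    }

    // ---- random-effect SDs (slice, exact conditionals)
    {
      double ssq = 0.0; for (int g = 0; g < Y; ++g) ssq += uS[g] * uS[g];
      sig[0] = slice_sigma_c(sig[0], Y, ssq, sigma_prior_sd);
      ssq = 0.0; for (int g = 0; g < Y; ++g) ssq += uC[g] * uC[g];
      sig[1] = slice_sigma_c(sig[1], Y, ssq, sigma_prior_sd);
      ssq = 0.0; for (int g = 0; g < T; ++g) ssq += wT[g] * wT[g];
      sig[2] = slice_sigma_c(sig[2], T, ssq, sigma_prior_sd);
      ssq = 0.0; for (int g = 0; g < P; ++g) ssq += vP[g] * vP[g];
      sig[3] = slice_sigma_c(sig[3], P, ssq, sigma_prior_sd);
    }

    if (w != 0.0) {
      // ---- ancillary likelihood-invariant moves: move mass between a
      // coefficient and a random-effect vector without touching eta
      auto shift_move = [&](int k, NumericVector& beta, int b_idx,
                            NumericVector& u, double s2,
                            const NumericVector* mult) {
        double d = R::norm_rand() * std::exp(ls_aux[k]);
        double b_old = beta[b_idx], b_new = b_old + d;
        double dlp = (b_old * b_old - b_new * b_new) / (2 * b_sd * b_sd);
        int G = u.size();
        for (int g = 0; g < G; ++g) {
          double du = mult ? d * (*mult)[g] : d;
          double u0 = u[g], u1 = u0 - du;
          dlp += (u0 * u0 - u1 * u1) / (2 * s2);
        }
        if (R_FINITE(dlp) && std::log(R::unif_rand()) < dlp) {
          beta[b_idx] = b_new;
          for (int g = 0; g < G; ++g)
            u[g] -= mult ? d * (*mult)[g] : d;
          acc_aux[k] += 1;
        }
      };
      shift_move(0, bs, 0, uS, sig[0] * sig[0], nullptr);
      shift_move(1, bc, 0, uC, sig[1] * sig[1], nullptr);
      shift_move(2, bc, 0, vP, sig[3] * sig[3], nullptr);
      shift_move(3, bc, 0, wT, sig[2] * sig[2], nullptr);
      shift_move(4, bs, rain_s_col, uS, sig[0] * sig[0], &rainS_y);
      shift_move(5, bc, rain_c_col, uC, sig[1] * sig[1], &rainC_y);
      if (food_exchange_ok)
        shift_move(6, bc, food_col, vP, sig[3] * sig[3], &food_p);
    }

    if (w != 0.0) {
      // ---- non-centered SD rescaling: with u-tilde = u/sigma held fixed,
      // propose sigma on the log scale and rescale u accordingly; this
      // traverses the funnel that centered updates cannot (the likelihood
      // changes, the N(0,1) prior of u-tilde does not; log-scale proposal
      // contributes a log(sigma'/sigma) Jacobian)
      auto rescale_success = [&](int k, int sidx, NumericVector& u) {
        double f = std::exp(R::norm_rand() * std::exp(ls_sig[k]));
        double s0 = sig[sidx], s1 = s0 * f;
        double dll = 0.0;
        for (int i = 0; i < n; ++i) {
          double en = etaS[i] + (f - 1.0) * u[yi[i]];
          double l1 = log1pexp_d(en);
          dll += S[i] * (en - etaS[i]) - (l1 - l1pS[i]);
          scr1[i] = en; scr2[i] = l1;
        }
        double dlp = R::dnorm(s1, 0.0, sigma_prior_sd, 1) -
          R::dnorm(s0, 0.0, sigma_prior_sd, 1) + std::log(f);
        if (R_FINITE(dll) && std::log(R::unif_rand()) < dll + dlp) {
          sig[sidx] = s1;
          for (int g = 0; g < u.size(); ++g) u[g] *= f;
          for (int i = 0; i < n; ++i) { etaS[i] = scr1[i]; l1pS[i] = scr2[i]; }
          acc_sig[k] += 1;
        }
      };
      auto rescale_count = [&](int k, int sidx, NumericVector& u,
                               const IntegerVector& gi) {
        double f = std::exp(R::norm_rand() * std::exp(ls_sig[k]));
        double s0 = sig[sidx], s1 = s0 * f;
        double dll = 0.0;
        for (int i = 0; i < n1; ++i) {
          double en = etaC1[i] + (f - 1.0) * u[gi[i]];
          double ex = std::exp(en);
          dll += C1[i] * (en - etaC1[i]) - (ex - expC1[i]);
          scrC1[i] = en; scrC2[i] = ex;
        }
        double dlp = R::dnorm(s1, 0.0, sigma_prior_sd, 1) -
          R::dnorm(s0, 0.0, sigma_prior_sd, 1) + std::log(f);
        if (R_FINITE(dll) && std::log(R::unif_rand()) < dll + dlp) {
          sig[sidx] = s1;
          for (int g = 0; g < u.size(); ++g) u[g] *= f;
          for (int i = 0; i < n1; ++i) { etaC1[i] = scrC1[i]; expC1[i] = scrC2[i]; }
          acc_sig[k] += 1;
        }
      };
      rescale_success(0, 0, uS);
      rescale_count(1, 1, uC, yi1);
      rescale_count(2, 2, wT, ti1);
      rescale_count(3, 3, vP, pi1);
    }

    // ---- latent missing experience (exact Gibbs) + prevalence updates
    for (int side = 0; side < 2; ++side) {
      const IntegerVector& mi = (side == 0) ? mi_m : mi_f;
      int col = (side == 0) ? exp_m_col : exp_f_col;
      double pi_cur = (side == 0) ? piM : piF;
      if (mi.size() > 0) {
        double b = bs[col];
        double lo = std::log(pi_cur) - std::log(1 - pi_cur);
        for (int k = 0; k < mi.size(); ++k) {
          int i = mi[k];
          double eta0 = etaS[i] - b * XS(i, col);
          double dll = w * (S[i] * b - (log1pexp_d(eta0 + b) - log1pexp_d(eta0)));
          double p1 = 1.0 / (1.0 + std::exp(-(lo + dll)));
          double x = (R::unif_rand() < p1) ? 1.0 : 0.0;
          XS(i, col) = x;
          etaS[i] = eta0 + b * x;
          l1pS[i] = log1pexp_d(etaS[i]);
        }
      }
      double sx = 0.0;
      for (int i = 0; i < n; ++i) sx += XS(i, col);
      double pi_new = R::rbeta(1 + sx, 1 + n - sx);
      if (side == 0) piM = pi_new; else piF = pi_new;
    }

    // ---- adaptation (burn-in only), batches of 50 iterations
    if (adapt && (it + 1) % 50 == 0) {
      batch += 1;
      double delta = std::min(0.1, 1.0 / std::sqrt((double)batch));
      auto tune = [&](NumericVector& ls, NumericVector& acc) {
        for (int j = 0; j < ls.size(); ++j) {
          ls[j] += (acc[j] / 50.0 > 0.44) ? delta : -delta;
          acc[j] = 0;
        }
      };
      tune(ls_bs, acc_bs); tune(ls_bc, acc_bc);
      tune(ls_re, acc_re); tune(ls_aux, acc_aux);
      tune(ls_sig, acc_sig);
    }

    if (record) {
      double ll_s = 0.0, ll_c = 0.0;
      for (int i = 0; i < n; ++i) ll_s += S[i] * etaS[i] - l1pS[i];
      for (int i = 0; i < n1; ++i) ll_c += C1[i] * etaC1[i] - expC1[i];
      ll_c -= lgamma_const;
      int c = 0;
      for (int j = 0; j < 9; ++j) out(it, c++) = bs[j];
      for (int j = 0; j < 9; ++j) out(it, c++) = bc[j];
      for (int j = 0; j < 4; ++j) out(it, c++) = sig[j];
      for (int g = 0; g < Y; ++g) out(it, c++) = uS[g];
      for (int g = 0; g < Y; ++g) out(it, c++) = uC[g];
      for (int g = 0; g < P; ++g) out(it, c++) = vP[g];
      for (int g = 0; g < T; ++g) out(it, c++) = wT[g];
      out(it, c++) = piM;
      out(it, c++) = piF;
      out(it, c++) = -2 * (ll_s + ll_c);
    }
  }

  return List::create(
    _["bs"] = bs, _["bc"] = bc, _["sig"] = sig,
    _["uS"] = uS, _["uC"] = uC, _["vP"] = vP, _["wT"] = wT,
    _["piM"] = piM, _["piF"] = piF,
    _["XS"] = XS, _["etaS"] = etaS, _["l1pS"] = l1pS,
    _["etaC1"] = etaC1, _["expC1"] = expC1,
    _["ls_bs"] = ls_bs, _["ls_bc"] = ls_bc, _["ls_re"] = ls_re,
    _["ls_aux"] = ls_aux, _["ls_sig"] = ls_sig,
    _["acc_bs"] = acc_bs, _["acc_bc"] = acc_bc,
    _["acc_re"] = acc_re, _["acc_aux"] = acc_aux, _["acc_sig"] = acc_sig,
    _["batch"] = batch, _["records"] = out);
}
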