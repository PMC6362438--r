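// Metropolis-within-Gibbs sampler for the habitat- and age-structured
// integrated population model.
//
// Blocks per iteration:
//   1. hidden breeder states of the adult multi-event histories by
//      forward-filtering backward-sampling (FFBS), giving per-year
//      transition counts and aggregate emission counts;
//   2. year-specific vital rates on the link scale (random-walk MH with
//      local likelihood terms only);
//   3. hyper-means (conjugate Gibbs) and hyper-SDs (log-scale MH,
//      Uniform(0, 10) prior);
//   4. constant parameters: habitat-transition logits, detection p,
//      state certainty c (conjugate Beta given the augmented states);
//   5. year-specific immigration means (Uniform(-5, 20) prior, Poisson
//      rate clamped at zero) and initial-size means;
//   6. integer latent states of the count process (successful breeders,
//      survivors, movers, recruits, immigrants, initial sizes) by
//      symmetric integer random walks with local acceptance ratios.
//
// Class order everywhere: Y_S, Y_T, O_S, O_T (0-based k = a*2 + h).
// CMR hidden states 0..8: (a,h,s) -> a*4 + h*2 + s, 8 = dead.

#include <Rcpp.h>
#include <cmath>
#include <cstring>
using namespace Rcpp;

static inline double invlogit(double x) { return 1.0 / (1.0 + std::exp(-x)); }
static inline int k_age(int k) { return k / 2; } // 0 = Y, 1 = O
static inline int k_hab(int k) { return k % 2; } // 0 = S, 1 = T

struct Sampler {
  // dimensions
  int TT, n_ind;
  // data
  IntegerMatrix Rbr, Bbr, Sfl, Ffl, y;     // 4 x TT
  IntegerVector Jc;                         // 2 x 3 x (TT-1): natal, outcome, cohort
  IntegerVector fc, st0;                    // adults (0-based years, 0-based states)
  IntegerVector wgt;                        // multiplicity of each unique history
  IntegerMatrix ev;                         // n_ind x TT, codes 0..6, -1 unused
  bool inc_br, inc_fl, inc_ad, inc_jv, inc_ct;

  // parameters (link scale)
  NumericMatrix xb, xf;                     // 4 x TT
  NumericMatrix xps, xpf;                   // 4 x (TT-1)
  NumericMatrix xpfl;                       // 2 x (TT-1)
  NumericVector mu, sdv;                    // 18 families: b4 f4 pfl2 ps4 pf4
  NumericVector lpsi_s, lpsi_f, lpsi_fl;    // logit P(switch habitat) from S, from T
  double lp, lc;
  NumericMatrix M;                          // 4 x TT (col 0 unused)
  NumericVector lam1;                       // 4

  // latent integers
  IntegerMatrix NB, Im;                     // 4 x TT
  IntegerMatrix succ, svS, svF, mvS, mvF;   // 4 x (TT-1)
  IntegerMatrix recY;                       // 2 x (TT-1)

  // natural-scale caches
  NumericMatrix b, fl;                      // 4 x TT
  NumericMatrix ps, pf;                     // 4 x (TT-1)
  NumericMatrix pfl;                        // 2 x (TT-1)
  double psw_s[2], psw_f[2], psw_fl[2], p, cc;

  // CMR structures
  std::vector<double> TR;                   // (TT-1) x 9 x 9
  std::vector<int> ntr;                     // (TT-1) x 9 x 9
  std::vector<double> cmr_cur;              // cached per-year CMR loglik
  double n_known, n_unk, n_unseen;          // aggregate emissions among live states

  // priors
  double prior_var, sd_hi, M_lo, M_hi, lam1_sd;
  NumericVector lam1_mean;

  // adaptation
  NumericMatrix st_xb, st_xf, st_xps, st_xpf, st_xpfl;
  NumericVector st_psi, st_M, st_lam1, st_sd;
  double st_p;
  IntegerMatrix ac_xb, ac_xf, ac_xps, ac_xpf, ac_xpfl;
  IntegerVector ac_psi, ac_M, ac_lam1, ac_sd;
  int ac_p;

  double &tr(int t, int s, int s2) { return TR[(t * 9 + s) * 9 + s2]; }
  int &nt(int t, int s, int s2) { return ntr[(t * 9 + s) * 9 + s2]; }
  int jcount(int h, int out, int t) const { return Jc[h + 2 * out + 6 * t]; }

  void refresh_caches() {
    for (int k = 0; k < 4; ++k)
      for (int t = 0; t < TT; ++t) {
        b(k, t) = invlogit(xb(k, t));
        fl(k, t) = std::exp(xf(k, t));
        if (t < TT - 1) { ps(k, t) = invlogit(xps(k, t)); pf(k, t) = invlogit(xpf(k, t)); }
      }
    for (int h = 0; h < 2; ++h)
      for (int t = 0; t < TT - 1; ++t) pfl(h, t) = invlogit(xpfl(h, t));
    for (int h = 0; h < 2; ++h) {
      psw_s[h] = invlogit(lpsi_s[h]);
      psw_f[h] = invlogit(lpsi_f[h]);
      psw_fl[h] = invlogit(lpsi_fl[h]);
    }
    p = invlogit(lp); cc = invlogit(lc);
  }

  // transition matrix of year t -> t+1 (t in 0..TT-2)
  void build_TR(int t) {
    for (int s = 0; s < 9; ++s)
      for (int s2 = 0; s2 < 9; ++s2) tr(t, s, s2) = 0.0;
    for (int a = 0; a < 2; ++a)
      for (int h = 0; h < 2; ++h)
        for (int s = 0; s < 2; ++s) {
          int from = a * 4 + h * 2 + s;
          int k = a * 2 + h;
          double phi = (s == 0) ? ps(k, t) : pf(k, t);
          double sw = (s == 0) ? psw_s[h] : psw_f[h];
          for (int h2 = 0; h2 < 2; ++h2) {
            double move = (h2 == h) ? (1.0 - sw) : sw;
            double b2 = b(2 + h2, t + 1);
            tr(t, from, 4 + h2 * 2 + 0) += phi * move * b2;
            tr(t, from, 4 + h2 * 2 + 1) += phi * move * (1.0 - b2);
          }
          tr(t, from, 8) = 1.0 - phi;
        }
    tr(t, 8, 8) = 1.0;
  }
  void build_all_TR() { for (int t = 0; t < TT - 1; ++t) build_TR(t); }

  // emission probability of event e (0..6) in state s under (p, c)
  double emis(int s, int e, double pv, double cv) const {
    if (s == 8) return e == 0 ? 1.0 : 0.0;
    int h = (s / 2) % 2, su = s % 2;
    if (e == 0) return 1.0 - pv;
    int base = h * 3;
    if (e == base + 1 + su) return pv * cv;      // correct known-status code
    if (e == base + 3) return pv * (1.0 - cv);   // unknown-status code
    if (e == base + 2 - su) return 0.0;          // wrong status never recorded
    return 0.0;                                   // wrong habitat
  }

  // ---- FFBS over the unique adult histories ------------------------------
  // Identical histories share the same smoothing distribution, so their
  // hidden paths are drawn jointly: the backward pass propagates state
  // *counts* with multinomial draws instead of one path per bird.
  void ffbs() {
    std::fill(ntr.begin(), ntr.end(), 0);
    n_known = n_unk = n_unseen = 0;
    if (!inc_ad) return;
    std::vector<double> alpha(9 * TT);
    std::vector<int> cnt(9 * TT);
    for (int i = 0; i < n_ind; ++i) {
      int f = fc[i], w = wgt[i];
      if (f >= TT - 1) continue;
      for (int s = 0; s < 9; ++s) alpha[f * 9 + s] = (s == st0[i]) ? 1.0 : 0.0;
      for (int t = f + 1; t < TT; ++t) {
        int e = ev(i, t);
        double tot = 0.0;
        for (int s2 = 0; s2 < 9; ++s2) {
          double acc = 0.0;
          for (int s = 0; s < 9; ++s) acc += alpha[(t - 1) * 9 + s] * tr(t - 1, s, s2);
          acc *= emis(s2, e, p, cc);
          alpha[t * 9 + s2] = acc; tot += acc;
        }
        if (tot <= 0.0) stop("zero-probability adult history at bird %d year %d", i + 1, t + 1);
        for (int s2 = 0; s2 < 9; ++s2) alpha[t * 9 + s2] /= tot;
      }
      // backward count sampling
      for (int t = f; t < TT; ++t)
        for (int s = 0; s < 9; ++s) cnt[t * 9 + s] = 0;
      { // final year: multinomial over the filtered distribution
        double rem_p = 1.0; int rem_n = w;
        for (int s = 0; s < 9 && rem_n > 0; ++s) {
          double pr = alpha[(TT - 1) * 9 + s];
          int d = (s == 8) ? rem_n : (int)R::rbinom(rem_n, std::min(1.0, pr / rem_p));
          cnt[(TT - 1) * 9 + s] = d; rem_n -= d; rem_p -= pr;
          if (rem_p <= 0) { cnt[(TT - 1) * 9 + 8] += rem_n; rem_n = 0; }
        }
      }
      for (int t = TT - 2; t >= f; --t) {
        for (int s2 = 0; s2 < 9; ++s2) {
          int n2 = cnt[(t + 1) * 9 + s2];
          if (n2 == 0) continue;
          double wts[9], tot = 0.0;
          for (int s = 0; s < 9; ++s) { wts[s] = alpha[t * 9 + s] * tr(t, s, s2); tot += wts[s]; }
          if (n2 == 1) { // single categorical draw
            double u = R::runif(0, 1) * tot, acc = 0.0; int pick = 8;
            for (int s = 0; s < 9; ++s) { acc += wts[s]; if (u <= acc) { pick = s; break; } }
            ++cnt[t * 9 + pick]; ++nt(t, pick, s2);
          } else {       // sequential-binomial multinomial
            double rem_p = tot; int rem_n = n2;
            for (int s = 0; s < 9 && rem_n > 0; ++s) {
              int d = (s == 8) ? rem_n : (int)R::rbinom(rem_n, std::min(1.0, wts[s] / rem_p));
              if (d > 0) { cnt[t * 9 + s] += d; nt(t, s, s2) += d; rem_n -= d; }
              rem_p -= wts[s];
              if (rem_p <= 0 && rem_n > 0) { cnt[t * 9 + 8] += rem_n; nt(t, 8, s2) += rem_n; rem_n = 0; }
            }
          }
        }
      }
      for (int t = f + 1; t < TT; ++t) {
        int alive = w - cnt[t * 9 + 8];
        if (alive <= 0) continue;
        int e = ev(i, t);
        if (e == 0) n_unseen += alive;
        else if (e % 3 == 0) n_unk += alive;  // codes 3 and 6
        else n_known += alive;
      }
    }
    for (int t = 0; t < TT - 1; ++t) cmr_cur[t] = year_cmr_ll(t, &TR[t * 81]);
  }

  // CMR log-likelihood of year t under the current count matrix and a
  // candidate transition matrix held in tmp (9x9)
  double year_cmr_ll(int t, const double *Tm) const {
    double ll = 0.0;
    for (int s = 0; s < 8; ++s)
      for (int s2 = 0; s2 < 9; ++s2) {
        int n = ntr[(t * 9 + s) * 9 + s2];
        if (n == 0) continue;
        double v = Tm[s * 9 + s2];
        if (v <= 0.0) return R_NegInf;
        ll += n * std::log(v);
      }
    return ll;
  }
  double year_cmr_ll_cur(int t) const { return year_cmr_ll(t, &TR[t * 81]); }

  void build_TR_tmp(int t, double *Tm,
                    const NumericMatrix &bv, const NumericMatrix &psv,
                    const NumericMatrix &pfv,
                    const double *sws, const double *swf) const {
    for (int i = 0; i < 81; ++i) Tm[i] = 0.0;
    for (int a = 0; a < 2; ++a)
      for (int h = 0; h < 2; ++h)
        for (int s = 0; s < 2; ++s) {
          int from = a * 4 + h * 2 + s;
          int k = a * 2 + h;
          double phi = (s == 0) ? psv(k, t) : pfv(k, t);
          double sw = (s == 0) ? sws[h] : swf[h];
          for (int h2 = 0; h2 < 2; ++h2) {
            double move = (h2 == h) ? (1.0 - sw) : sw;
            double b2 = bv(2 + h2, t + 1);
            Tm[from * 9 + 4 + h2 * 2 + 0] += phi * move * b2;
            Tm[from * 9 + 4 + h2 * 2 + 1] += phi * move * (1.0 - b2);
          }
          Tm[from * 9 + 8] = 1.0 - phi;
        }
    Tm[8 * 9 + 8] = 1.0;
  }

  // recruit Poisson rate into Young habitat h2 at transition t
  double rec_rate(int h2, int t) const {
    double r = 0.0;
    for (int k = 0; k < 4; ++k) {
      int h = k_hab(k);
      double move = (h2 == h) ? (1.0 - psw_fl[h]) : psw_fl[h];
      r += NB(k, t) * b(k, t) * fl(k, t) * pfl(h, t) * move;
    }
    return r;
  }

  // class-specific log-probability terms attached to NB(j, t),
  // excluding the recruitment-rate Poisson terms (those depend on the
  // whole class vector and are added once per proposal via rec_terms)
  double nb_terms(int j, int t) const {
    if (NB(j, t) < 0) return R_NegInf;
    double ll = R::dpois(y(j, t), std::max((double)NB(j, t), 1e-300), true);
    if (t < TT - 1) {
      if (NB(j, t) < succ(j, t)) return R_NegInf;
      ll += R::dbinom(succ(j, t), NB(j, t), b(j, t), true);
      ll += R::dbinom(svF(j, t), NB(j, t) - succ(j, t), pf(j, t), true);
    }
    return ll;
  }

  // recruitment Poisson terms of transition t (rates depend on NB[, t])
  double rec_terms(int t) const {
    if (t >= TT - 1) return 0.0;
    double ll = 0.0;
    for (int h2 = 0; h2 < 2; ++h2)
      ll += R::dpois(recY(h2, t), rec_rate(h2, t), true);
    return ll;
  }

  // juvenile multinomial log-likelihood of cohort t (uses pfl, psw_fl, p)
  double juv_ll(int t, double pfl_S, double pfl_T, const double *swfl, double pv) const {
    double ll = 0.0;
    double ph[2] = { pfl_S, pfl_T };
    for (int h = 0; h < 2; ++h) {
      int nS = jcount(h, 0, t), nT = jcount(h, 1, t), n0 = jcount(h, 2, t);
      if (nS + nT + n0 == 0) continue;
      double move = swfl[h];
      double prS = ph[h] * ((h == 0) ? (1 - move) : move) * pv;
      double prT = ph[h] * ((h == 0) ? move : (1 - move)) * pv;
      double pr0 = 1.0 - ph[h] * pv;
      if ((nS && prS <= 0) || (nT && prT <= 0) || (n0 && pr0 <= 0)) return R_NegInf;
      if (nS) ll += nS * std::log(prS);
      if (nT) ll += nT * std::log(prT);
      if (n0) ll += n0 * std::log(pr0);
    }
    return ll;
  }
  double juv_ll_all(double pv) const {
    if (!inc_jv) return 0.0;
    double ll = 0.0;
    for (int t = 0; t < TT - 1; ++t)
      ll += juv_ll(t, pfl(0, t), pfl(1, t), psw_fl, pv);
    return ll;
  }

  // ---- adaptation helper -------------------------------------------------
  void adapt(double &step, int &acc, int batch) {
    double rate = (double)acc / batch;
    if (rate > 0.5) step *= 1.25; else if (rate < 0.3) step *= 0.8;
    if (step < 1e-4) step = 1e-4;
    if (step > 10) step = 10;
    acc = 0;
  }

  // ---- update blocks -----------------------------------------------------
  int fam_of(const char *what, int k) const {
    if (!std::strcmp(what, "b")) return k;
    if (!std::strcmp(what, "f")) return 4 + k;
    if (!std::strcmp(what, "pfl")) return 8 + k;
    if (!std::strcmp(what, "ps")) return 10 + k;
    return 14 + k; // pf
  }

  void update_xb() {
    double Tm[81];
    for (int k = 0; k < 4; ++k)
      for (int t = 0; t < TT; ++t) {
        int fam = fam_of("b", k);
        double x0 = xb(k, t), x1 = x0 + R::rnorm(0, st_xb(k, t));
        double b0 = b(k, t), b1 = invlogit(x1);
        double ll0 = R::dnorm(x0, mu[fam], sdv[fam], true);
        double ll1 = R::dnorm(x1, mu[fam], sdv[fam], true);
        if (inc_br && Rbr(k, t) > 0) {
          ll0 += R::dbinom(Bbr(k, t), Rbr(k, t), b0, true);
          ll1 += R::dbinom(Bbr(k, t), Rbr(k, t), b1, true);
        }
        bool old_cls = k >= 2;
        double cmr1 = 0.0;
        if (inc_ad && old_cls && t >= 1) {
          ll0 += cmr_cur[t - 1];
          b(k, t) = b1; build_TR_tmp(t - 1, Tm, b, ps, pf, psw_s, psw_f); b(k, t) = b0;
          cmr1 = year_cmr_ll(t - 1, Tm);
          ll1 += cmr1;
        }
        if (inc_ct && t < TT - 1) {
          ll0 += R::dbinom(succ(k, t), NB(k, t), b0, true);
          ll1 += R::dbinom(succ(k, t), NB(k, t), b1, true);
          for (int h2 = 0; h2 < 2; ++h2)
            ll0 += R::dpois(recY(h2, t), rec_rate(h2, t), true);
          b(k, t) = b1;
          for (int h2 = 0; h2 < 2; ++h2)
            ll1 += R::dpois(recY(h2, t), rec_rate(h2, t), true);
          b(k, t) = b0;
        }
        if (std::log(R::runif(0, 1)) < ll1 - ll0) {
          xb(k, t) = x1; b(k, t) = b1;
          if (inc_ad && old_cls && t >= 1) { build_TR(t - 1); cmr_cur[t - 1] = cmr1; }
          ++ac_xb(k, t);
        }
      }
  }

  void update_xf() {
    for (int k = 0; k < 4; ++k)
      for (int t = 0; t < TT; ++t) {
        int fam = fam_of("f", k);
        double x0 = xf(k, t), x1 = x0 + R::rnorm(0, st_xf(k, t));
        double f0 = fl(k, t), f1 = std::exp(x1);
        double ll0 = R::dnorm(x0, mu[fam], sdv[fam], true);
        double ll1 = R::dnorm(x1, mu[fam], sdv[fam], true);
        if (f1 < 0.5) continue; // brood minimum: shifted Poisson needs rate >= 0
        if (inc_fl && Sfl(k, t) > 0) {
          ll0 += R::dpois(Ffl(k, t) - Sfl(k, t), Sfl(k, t) * (2 * f0 - 1), true);
          ll1 += R::dpois(Ffl(k, t) - Sfl(k, t), Sfl(k, t) * (2 * f1 - 1), true);
        }
        if (inc_ct && t < TT - 1) {
          for (int h2 = 0; h2 < 2; ++h2)
            ll0 += R::dpois(recY(h2, t), rec_rate(h2, t), true);
          fl(k, t) = f1;
          for (int h2 = 0; h2 < 2; ++h2)
            ll1 += R::dpois(recY(h2, t), rec_rate(h2, t), true);
          fl(k, t) = f0;
        }
        if (std::log(R::runif(0, 1)) < ll1 - ll0) {
          xf(k, t) = x1; fl(k, t) = f1; ++ac_xf(k, t);
        }
      }
  }

  void update_xpfl() {
    for (int h = 0; h < 2; ++h)
      for (int t = 0; t < TT - 1; ++t) {
        int fam = fam_of("pfl", h);
        double x0 = xpfl(h, t), x1 = x0 + R::rnorm(0, st_xpfl(h, t));
        double v0 = pfl(h, t), v1 = invlogit(x1);
        double ll0 = R::dnorm(x0, mu[fam], sdv[fam], true);
        double ll1 = R::dnorm(x1, mu[fam], sdv[fam], true);
        if (inc_jv) {
          ll0 += juv_ll(t, pfl(0, t), pfl(1, t), psw_fl, p);
          double a = (h == 0) ? v1 : pfl(0, t), bb = (h == 1) ? v1 : pfl(1, t);
          ll1 += juv_ll(t, a, bb, psw_fl, p);
        }
        if (inc_ct) {
          for (int h2 = 0; h2 < 2; ++h2)
            ll0 += R::dpois(recY(h2, t), rec_rate(h2, t), true);
          pfl(h, t) = v1;
          for (int h2 = 0; h2 < 2; ++h2)
            ll1 += R::dpois(recY(h2, t), rec_rate(h2, t), true);
          pfl(h, t) = v0;
        }
        if (std::log(R::runif(0, 1)) < ll1 - ll0) {
          xpfl(h, t) = x1; pfl(h, t) = v1; ++ac_xpfl(h, t);
        }
      }
  }

  void update_xphi(bool succ_phi) {
    double Tm[81];
    NumericMatrix &x = succ_phi ? xps : xpf;
    NumericMatrix &v = succ_phi ? ps : pf;
    NumericMatrix &stp = succ_phi ? st_xps : st_xpf;
    IntegerMatrix &acm = succ_phi ? ac_xps : ac_xpf;
    for (int k = 0; k < 4; ++k)
      for (int t = 0; t < TT - 1; ++t) {
        int fam = fam_of(succ_phi ? "ps" : "pf", k);
        double x0 = x(k, t), x1 = x0 + R::rnorm(0, stp(k, t));
        double v0 = v(k, t), v1 = invlogit(x1);
        double ll0 = R::dnorm(x0, mu[fam], sdv[fam], true);
        double ll1 = R::dnorm(x1, mu[fam], sdv[fam], true);
        double cmr1 = 0.0;
        if (inc_ad) {
          ll0 += cmr_cur[t];
          v(k, t) = v1; build_TR_tmp(t, Tm, b, ps, pf, psw_s, psw_f); v(k, t) = v0;
          cmr1 = year_cmr_ll(t, Tm);
          ll1 += cmr1;
        }
        if (inc_ct) {
          if (succ_phi) {
            ll0 += R::dbinom(svS(k, t), succ(k, t), v0, true);
            ll1 += R::dbinom(svS(k, t), succ(k, t), v1, true);
          } else {
            ll0 += R::dbinom(svF(k, t), NB(k, t) - succ(k, t), v0, true);
            ll1 += R::dbinom(svF(k, t), NB(k, t) - succ(k, t), v1, true);
          }
        }
        if (std::log(R::runif(0, 1)) < ll1 - ll0) {
          x(k, t) = x1; v(k, t) = v1;
          if (inc_ad) { build_TR(t); cmr_cur[t] = cmr1; }
          ++acm(k, t);
        }
      }
  }

  void update_hypers() {
    for (int fam = 0; fam < 18; ++fam) {
      // gather the family's year values
      std::vector<double> xs;
      if (fam < 4) for (int t = 0; t < TT; ++t) xs.push_back(xb(fam, t));
      else if (fam < 8) for (int t = 0; t < TT; ++t) xs.push_back(xf(fam - 4, t));
      else if (fam < 10) for (int t = 0; t < TT - 1; ++t) xs.push_back(xpfl(fam - 8, t));
      else if (fam < 14) for (int t = 0; t < TT - 1; ++t) xs.push_back(xps(fam - 10, t));
      else for (int t = 0; t < TT - 1; ++t) xs.push_back(xpf(fam - 14, t));
      int n = xs.size();
      double sum = 0.0; for (double v : xs) sum += v;
      double s2 = sdv[fam] * sdv[fam];
      double prec = n / s2 + 1.0 / prior_var;
      double mean = (sum / s2) / prec;
      mu[fam] = R::rnorm(mean, std::sqrt(1.0 / prec));
      // sd: log-scale random walk, Uniform(0, sd_hi) prior
      double l0 = std::log(sdv[fam]), l1 = l0 + R::rnorm(0, st_sd[fam]);
      double sd1 = std::exp(l1);
      if (sd1 < sd_hi) {
        double ll0 = 0.0, ll1 = 0.0;
        for (double v : xs) {
          ll0 += R::dnorm(v, mu[fam], sdv[fam], true);
          ll1 += R::dnorm(v, mu[fam], sd1, true);
        }
        // Jacobian of the log transform
        ll0 += l0; ll1 += l1;
        if (std::log(R::runif(0, 1)) < ll1 - ll0) { sdv[fam] = sd1; ++ac_sd[fam]; }
      }
    }
  }

  void update_psi() {
    double Tm[81];
    // adult transition logits: 0,1 -> psi_succ S/T; 2,3 -> psi_fail S/T
    for (int j = 0; j < 4; ++j) {
      bool succ_psi = j < 2; int h = j % 2;
      NumericVector &lv = succ_psi ? lpsi_s : lpsi_f;
      double *sw = succ_psi ? psw_s : psw_f;
      double x0 = lv[h], x1 = x0 + R::rnorm(0, st_psi[j]);
      double v0 = sw[h], v1 = invlogit(x1);
      double ll0 = R::dnorm(x0, 0.0, std::sqrt(prior_var), true);
      double ll1 = R::dnorm(x1, 0.0, std::sqrt(prior_var), true);
      std::vector<double> cmr1;
      if (inc_ad) {
        cmr1.resize(TT - 1);
        for (int t = 0; t < TT - 1; ++t) ll0 += cmr_cur[t];
        sw[h] = v1;
        for (int t = 0; t < TT - 1; ++t) {
          build_TR_tmp(t, Tm, b, ps, pf, psw_s, psw_f);
          cmr1[t] = year_cmr_ll(t, Tm);
          ll1 += cmr1[t];
        }
        sw[h] = v0;
      }
      if (inc_ct) {
        IntegerMatrix &mv = succ_psi ? mvS : mvF;
        IntegerMatrix &svv = succ_psi ? svS : svF;
        for (int t = 0; t < TT - 1; ++t)
          for (int a = 0; a < 2; ++a) {
            int k = a * 2 + h;
            ll0 += R::dbinom(mv(k, t), svv(k, t), v0, true);
            ll1 += R::dbinom(mv(k, t), svv(k, t), v1, true);
          }
      }
      if (std::log(R::runif(0, 1)) < ll1 - ll0) {
        lv[h] = x1; sw[h] = v1;
        if (inc_ad) {
          build_all_TR();
          for (int t = 0; t < TT - 1; ++t) cmr_cur[t] = cmr1[t];
        }
        ++ac_psi[j];
      }
    }
    // natal transition logits
    for (int h = 0; h < 2; ++h) {
      double x0 = lpsi_fl[h], x1 = x0 + R::rnorm(0, st_psi[4 + h]);
      double v0 = psw_fl[h], v1 = invlogit(x1);
      double ll0 = R::dnorm(x0, 0.0, std::sqrt(prior_var), true);
      double ll1 = R::dnorm(x1, 0.0, std::sqrt(prior_var), true);
      ll0 += juv_ll_all(p);
      if (inc_ct)
        for (int t = 0; t < TT - 1; ++t)
          for (int h2 = 0; h2 < 2; ++h2)
            ll0 += R::dpois(recY(h2, t), rec_rate(h2, t), true);
      psw_fl[h] = v1;
      ll1 += juv_ll_all(p);
      if (inc_ct)
        for (int t = 0; t < TT - 1; ++t)
          for (int h2 = 0; h2 < 2; ++h2)
            ll1 += R::dpois(recY(h2, t), rec_rate(h2, t), true);
      psw_fl[h] = v0;
      if (std::log(R::runif(0, 1)) < ll1 - ll0) {
        lpsi_fl[h] = x1; psw_fl[h] = v1; ++ac_psi[4 + h];
      }
    }
  }

  void update_p_c() {
    // c | z is conjugate Beta (uniform prior), c appears only in emissions
    if (inc_ad) {
      cc = R::rbeta(1.0 + n_known, 1.0 + n_unk);
      lc = std::log(cc / (1.0 - cc));
    }
    // p: emissions + juvenile resighting
    double x0 = lp, x1 = x0 + R::rnorm(0, st_p);
    double p0 = p, p1 = invlogit(x1);
    // Uniform(0,1) prior on p expressed on the logit scale
    double ll0 = std::log(p0) + std::log(1.0 - p0);
    double ll1 = std::log(p1) + std::log(1.0 - p1);
    if (inc_ad) {
      ll0 += (n_known + n_unk) * std::log(p0) + n_unseen * std::log(1.0 - p0);
      ll1 += (n_known + n_unk) * std::log(p1) + n_unseen * std::log(1.0 - p1);
    }
    ll0 += juv_ll_all(p0);
    ll1 += juv_ll_all(p1);
    if (std::log(R::runif(0, 1)) < ll1 - ll0) { lp = x1; p = p1; ++ac_p; }
  }

  void update_M_lam1() {
    if (!inc_ct) {
      // without the count stream these parameters have no likelihood:
      // sample them from their priors so ablation reports honest
      // (prior-width) uncertainty
      for (int k = 0; k < 4; ++k) {
        for (int t = 1; t < TT; ++t) M(k, t) = R::runif(M_lo, M_hi);
        double draw;
        do { draw = R::rnorm(lam1_mean[k], lam1_sd); } while (draw <= 0);
        lam1[k] = draw;
      }
      return;
    }
    for (int k = 0; k < 4; ++k) {
      for (int t = 1; t < TT; ++t) {
        double x0 = M(k, t), x1 = x0 + R::rnorm(0, st_M[k]);
        if (x1 < M_lo || x1 > M_hi) continue;
        double ll0 = R::dpois(Im(k, t), std::max(x0, 1e-300), true);
        double ll1 = R::dpois(Im(k, t), std::max(x1, 1e-300), true);
        if (std::log(R::runif(0, 1)) < ll1 - ll0) { M(k, t) = x1; ++ac_M[k]; }
      }
      double x0 = lam1[k], x1 = x0 + R::rnorm(0, st_lam1[k]);
      if (x1 > 0) {
        double ll0 = R::dnorm(x0, lam1_mean[k], lam1_sd, true) +
          R::dpois(NB(k, 0), x0, true);
        double ll1 = R::dnorm(x1, lam1_mean[k], lam1_sd, true) +
          R::dpois(NB(k, 0), x1, true);
        if (std::log(R::runif(0, 1)) < ll1 - ll0) { lam1[k] = x1; ++ac_lam1[k]; }
      }
    }
  }

  static int draw_step() {
    int d = (R::runif(0, 1) < 0.5) ? 1 : -1;
    if (R::runif(0, 1) < 0.3) d *= 2;
    return d;
  }

  // class arriving survivors stay in: Old class of habitat h = 2 + h
  void update_latents() {
    if (!inc_ct) return;
    for (int t = 0; t < TT - 1; ++t) {
      for (int k = 0; k < 4; ++k) {
        // each update draws its own fresh symmetric increment: reusing
        // one increment across coupled updates correlates the proposal
        // with the state and breaks detailed balance
        // succ
        {
          int d = draw_step();
          int s0 = succ(k, t), s1 = s0 + d;
          if (s1 >= 0 && s1 <= NB(k, t)) {
            double ll0 = R::dbinom(s0, NB(k, t), b(k, t), true) +
              R::dbinom(svS(k, t), s0, ps(k, t), true) +
              R::dbinom(svF(k, t), NB(k, t) - s0, pf(k, t), true);
            double ll1 = R::dbinom(s1, NB(k, t), b(k, t), true) +
              R::dbinom(svS(k, t), s1, ps(k, t), true) +
              R::dbinom(svF(k, t), NB(k, t) - s1, pf(k, t), true);
            if (std::log(R::runif(0, 1)) < ll1 - ll0) succ(k, t) = s1;
          }
        }
        int h = k_hab(k);
        int kstay = 2 + h, kmove = 2 + (1 - h);
        // svS: changes the stay-class arrivals at t+1
        {
          int d = draw_step();
          int s0 = svS(k, t), s1 = s0 + d;
          if (s1 >= 0) {
            double ll0 = R::dbinom(s0, succ(k, t), ps(k, t), true) +
              R::dbinom(mvS(k, t), s0, psw_s[h], true) +
              nb_terms(kstay, t + 1) + rec_terms(t + 1);
            NB(kstay, t + 1) += d; svS(k, t) = s1;
            double ll1 = R::dbinom(s1, succ(k, t), ps(k, t), true) +
              R::dbinom(mvS(k, t), s1, psw_s[h], true) +
              nb_terms(kstay, t + 1) + rec_terms(t + 1);
            if (NB(kstay, t + 1) < 0) ll1 = R_NegInf;
            if (std::log(R::runif(0, 1)) >= ll1 - ll0) {
              NB(kstay, t + 1) -= d; svS(k, t) = s0;
            }
          }
        }
        // svF
        {
          int d = draw_step();
          int s0 = svF(k, t), s1 = s0 + d;
          if (s1 >= 0) {
            double ll0 = R::dbinom(s0, NB(k, t) - succ(k, t), pf(k, t), true) +
              R::dbinom(mvF(k, t), s0, psw_f[h], true) +
              nb_terms(kstay, t + 1) + rec_terms(t + 1);
            NB(kstay, t + 1) += d; svF(k, t) = s1;
            double ll1 = R::dbinom(s1, NB(k, t) - succ(k, t), pf(k, t), true) +
              R::dbinom(mvF(k, t), s1, psw_f[h], true) +
              nb_terms(kstay, t + 1) + rec_terms(t + 1);
            if (NB(kstay, t + 1) < 0) ll1 = R_NegInf;
            if (std::log(R::runif(0, 1)) >= ll1 - ll0) {
              NB(kstay, t + 1) -= d; svF(k, t) = s0;
            }
          }
        }
        // mvS: moves birds between the two Old destination classes
        {
          int d = draw_step();
          int s0 = mvS(k, t), s1 = s0 + d;
          if (s1 >= 0) {
            double ll0 = R::dbinom(s0, svS(k, t), psw_s[h], true) +
              nb_terms(kstay, t + 1) + nb_terms(kmove, t + 1) + rec_terms(t + 1);
            NB(kstay, t + 1) -= d; NB(kmove, t + 1) += d; mvS(k, t) = s1;
            double ll1;
            if (NB(kstay, t + 1) < 0 || NB(kmove, t + 1) < 0) ll1 = R_NegInf;
            else ll1 = R::dbinom(s1, svS(k, t), psw_s[h], true) +
              nb_terms(kstay, t + 1) + nb_terms(kmove, t + 1) + rec_terms(t + 1);
            if (std::log(R::runif(0, 1)) >= ll1 - ll0) {
              NB(kstay, t + 1) += d; NB(kmove, t + 1) -= d; mvS(k, t) = s0;
            }
          }
        }
        // mvF
        {
          int d = draw_step();
          int s0 = mvF(k, t), s1 = s0 + d;
          if (s1 >= 0) {
            double ll0 = R::dbinom(s0, svF(k, t), psw_f[h], true) +
              nb_terms(kstay, t + 1) + nb_terms(kmove, t + 1) + rec_terms(t + 1);
            NB(kstay, t + 1) -= d; NB(kmove, t + 1) += d; mvF(k, t) = s1;
            double ll1;
            if (NB(kstay, t + 1) < 0 || NB(kmove, t + 1) < 0) ll1 = R_NegInf;
            else ll1 = R::dbinom(s1, svF(k, t), psw_f[h], true) +
              nb_terms(kstay, t + 1) + nb_terms(kmove, t + 1) + rec_terms(t + 1);
            if (std::log(R::runif(0, 1)) >= ll1 - ll0) {
              NB(kstay, t + 1) += d; NB(kmove, t + 1) -= d; mvF(k, t) = s0;
            }
          }
        }
        // Im at t+1
        {
          int d = draw_step();
          int s0 = Im(k, t + 1), s1 = s0 + d;
          if (s1 >= 0) {
            double rate = std::max(M(k, t + 1), 1e-300);
            double ll0 = R::dpois(s0, rate, true) + nb_terms(k, t + 1) +
              rec_terms(t + 1);
            NB(k, t + 1) += d; Im(k, t + 1) = s1;
            double ll1;
            if (NB(k, t + 1) < 0) ll1 = R_NegInf;
            else ll1 = R::dpois(s1, rate, true) + nb_terms(k, t + 1) +
              rec_terms(t + 1);
            if (std::log(R::runif(0, 1)) >= ll1 - ll0) {
              NB(k, t + 1) -= d; Im(k, t + 1) = s0;
            }
          }
        }
      }
      // recruits
      for (int h2 = 0; h2 < 2; ++h2) {
        int d = draw_step();
        int s0 = recY(h2, t), s1 = s0 + d;
        if (s1 < 0) continue;
        double ll0 = R::dpois(s0, rec_rate(h2, t), true) +
          nb_terms(h2, t + 1) + rec_terms(t + 1);
        NB(h2, t + 1) += d; recY(h2, t) = s1;
        double ll1;
        if (NB(h2, t + 1) < 0) ll1 = R_NegInf;
        else ll1 = R::dpois(s1, rec_rate(h2, t), true) +
          nb_terms(h2, t + 1) + rec_terms(t + 1);
        if (std::log(R::runif(0, 1)) >= ll1 - ll0) {
          NB(h2, t + 1) -= d; recY(h2, t) = s0;
        }
      }
    }
    // initial sizes
    for (int k = 0; k < 4; ++k) {
      int d = draw_step();
      int s0 = NB(k, 0), s1 = s0 + d;
      if (s1 < 0 || s1 < succ(k, 0)) continue;
      double ll0 = R::dpois(s0, lam1[k], true) + nb_terms(k, 0) + rec_terms(0);
      NB(k, 0) = s1;
      double ll1 = R::dpois(s1, lam1[k], true) + nb_terms(k, 0) + rec_terms(0);
      if (std::log(R::runif(0, 1)) >= ll1 - ll0) NB(k, 0) = s0;
    }
  }
};

// [[Rcpp::export]]
List cpp_ipm_mcmc(List data, List init, List prior, List ctrl) {
  Sampler S;
  S.TT = as<int>(data["TT"]);
  S.Rbr = as<IntegerMatrix>(data["Rbr"]); S.Bbr = as<IntegerMatrix>(data["Bbr"]);
  S.Sfl = as<IntegerMatrix>(data["Sfl"]); S.Ffl = as<IntegerMatrix>(data["Ffl"]);
  S.y = as<IntegerMatrix>(data["y"]);
  S.Jc = as<IntegerVector>(data["J"]);
  S.fc = as<IntegerVector>(data["fc"]); S.st0 = as<IntegerVector>(data["st0"]);
  S.wgt = as<IntegerVector>(data["w"]);
  S.ev = as<IntegerMatrix>(data["ev"]);
  S.n_ind = S.fc.size();
  S.inc_br = as<bool>(data["inc_br"]); S.inc_fl = as<bool>(data["inc_fl"]);
  S.inc_ad = as<bool>(data["inc_ad"]); S.inc_jv = as<bool>(data["inc_jv"]);
  S.inc_ct = as<bool>(data["inc_ct"]);

  S.xb = clone(as<NumericMatrix>(init["xb"])); S.xf = clone(as<NumericMatrix>(init["xf"]));
  S.xps = clone(as<NumericMatrix>(init["xps"])); S.xpf = clone(as<NumericMatrix>(init["xpf"]));
  S.xpfl = clone(as<NumericMatrix>(init["xpfl"]));
  S.mu = clone(as<NumericVector>(init["mu"])); S.sdv = clone(as<NumericVector>(init["sd"]));
  S.lpsi_s = clone(as<NumericVector>(init["lpsi_s"]));
  S.lpsi_f = clone(as<NumericVector>(init["lpsi_f"]));
  S.lpsi_fl = clone(as<NumericVector>(init["lpsi_fl"]));
  S.lp = as<double>(init["lp"]); S.lc = as<double>(init["lc"]);
  S.M = clone(as<NumericMatrix>(init["M"])); S.lam1 = clone(as<NumericVector>(init["lam1"]));
  S.NB = clone(as<IntegerMatrix>(init["NB"])); S.Im = clone(as<IntegerMatrix>(init["Im"]));
  S.succ = clone(as<IntegerMatrix>(init["succ"]));
  S.svS = clone(as<IntegerMatrix>(init["svS"])); S.svF = clone(as<IntegerMatrix>(init["svF"]));
  S.mvS = clone(as<IntegerMatrix>(init["mvS"])); S.mvF = clone(as<IntegerMatrix>(init["mvF"]));
  S.recY = clone(as<IntegerMatrix>(init["recY"]));

  S.prior_var = as<double>(prior["prior_var"]);
  S.sd_hi = as<double>(prior["sd_hi"]);
  S.M_lo = as<double>(prior["M_lo"]); S.M_hi = as<double>(prior["M_hi"]);
  S.lam1_sd = as<double>(prior["lam1_sd"]);
  S.lam1_mean = as<NumericVector>(prior["lam1_mean"]);

  int n_iter = as<int>(ctrl["n_iter"]), n_burn = as<int>(ctrl["n_burn"]);
  int thin = as<int>(ctrl["thin"]);
  int n_lat_sweeps = ctrl.containsElementNamed("lat_sweeps") ? as<int>(ctrl["lat_sweeps"]) : 2;
  int TT = S.TT;

  S.b = NumericMatrix(4, TT); S.fl = NumericMatrix(4, TT);
  S.ps = NumericMatrix(4, TT - 1); S.pf = NumericMatrix(4, TT - 1);
  S.pfl = NumericMatrix(2, TT - 1);
  S.TR.assign((TT - 1) * 81, 0.0); S.ntr.assign((TT - 1) * 81, 0);
  S.cmr_cur.assign(TT - 1, 0.0);

  S.st_xb = NumericMatrix(4, TT); std::fill(S.st_xb.begin(), S.st_xb.end(), 0.3);
  S.st_xf = NumericMatrix(4, TT); std::fill(S.st_xf.begin(), S.st_xf.end(), 0.1);
  S.st_xps = NumericMatrix(4, TT - 1); std::fill(S.st_xps.begin(), S.st_xps.end(), 0.3);
  S.st_xpf = NumericMatrix(4, TT - 1); std::fill(S.st_xpf.begin(), S.st_xpf.end(), 0.3);
  S.st_xpfl = NumericMatrix(2, TT - 1); std::fill(S.st_xpfl.begin(), S.st_xpfl.end(), 0.3);
  S.st_psi = NumericVector(6, 0.2); S.st_M = NumericVector(4, 2.0);
  S.st_lam1 = NumericVector(4, 3.0); S.st_sd = NumericVector(18, 0.3);
  S.st_p = 0.2;
  S.ac_xb = IntegerMatrix(4, TT); S.ac_xf = IntegerMatrix(4, TT);
  S.ac_xps = IntegerMatrix(4, TT - 1); S.ac_xpf = IntegerMatrix(4, TT - 1);
  S.ac_xpfl = IntegerMatrix(2, TT - 1);
  S.ac_psi = IntegerVector(6); S.ac_M = IntegerVector(4);
  S.ac_lam1 = IntegerVector(4); S.ac_sd = IntegerVector(18);
  S.ac_p = 0;

  S.refresh_caches();
  S.build_all_TR();

  int n_save = (n_iter - n_burn) / thin;
  int npar = 32 * TT + 36;
  NumericMatrix draws(n_save, npar);
  int isave = 0;
  const int batch = 50;

  for (int it = 0; it < n_iter; ++it) {
    S.ffbs();
    S.update_p_c();
    S.update_xb();
    S.update_xf();
    S.update_xpfl();
    S.update_xphi(true);
    S.update_xphi(false);
    S.update_hypers();
    S.update_psi();
    S.update_M_lam1();
    for (int r = 0; r < n_lat_sweeps; ++r) S.update_latents();

    if (it < n_burn && (it + 1) % batch == 0) {
      for (int k = 0; k < 4; ++k) for (int t = 0; t < TT; ++t) {
        S.adapt(S.st_xb(k, t), S.ac_xb(k, t), batch);
        S.adapt(S.st_xf(k, t), S.ac_xf(k, t), batch);
      }
      for (int k = 0; k < 4; ++k) for (int t = 0; t < TT - 1; ++t) {
        S.adapt(S.st_xps(k, t), S.ac_xps(k, t), batch);
        S.adapt(S.st_xpf(k, t), S.ac_xpf(k, t), batch);
      }
      for (int h = 0; h < 2; ++h) for (int t = 0; t < TT - 1; ++t)
        S.adapt(S.st_xpfl(h, t), S.ac_xpfl(h, t), batch);
      for (int j = 0; j < 6; ++j) S.adapt(S.st_psi[j], S.ac_psi[j], batch);
      for (int k = 0; k < 4; ++k) {
        int a = S.ac_M[k]; a /= (TT - 1); S.adapt(S.st_M[k], a, batch); S.ac_M[k] = 0;
        S.adapt(S.st_lam1[k], S.ac_lam1[k], batch);
      }
      for (int f = 0; f < 18; ++f) S.adapt(S.st_sd[f], S.ac_sd[f], batch);
      S.adapt(S.st_p, S.ac_p, batch);
    }

    if (it >= n_burn && (it - n_burn) % thin == 0 && isave < n_save) {
      int o = 0;
      #define PUT(v) { draws(isave, o) = (v); ++o; }
      for (int t = 0; t < TT; ++t) for (int k = 0; k < 4; ++k) PUT(S.b(k, t));
      for (int t = 0; t < TT; ++t) for (int k = 0; k < 4; ++k) PUT(S.fl(k, t));
      for (int t = 0; t < TT - 1; ++t) for (int h = 0; h < 2; ++h) PUT(S.pfl(h, t));
      for (int t = 0; t < TT - 1; ++t) for (int k = 0; k < 4; ++k) PUT(S.ps(k, t));
      for (int t = 0; t < TT - 1; ++t) for (int k = 0; k < 4; ++k) PUT(S.pf(k, t));
      for (int h = 0; h < 2; ++h) PUT(S.psw_s[h]);
      for (int h = 0; h < 2; ++h) PUT(S.psw_f[h]);
      for (int h = 0; h < 2; ++h) PUT(S.psw_fl[h]);
      PUT(S.p); PUT(S.cc);
      for (int t = 0; t < TT; ++t) for (int k = 0; k < 4; ++k) PUT(S.M(k, t));
      for (int t = 0; t < TT; ++t) for (int k = 0; k < 4; ++k) PUT((double)S.Im(k, t));
      for (int t = 0; t < TT; ++t) for (int k = 0; k < 4; ++k) PUT((double)S.NB(k, t));
      for (int t = 0; t < TT - 1; ++t) for (int h = 0; h < 2; ++h) PUT((double)S.recY(h, t));
      for (int k = 0; k < 4; ++k) PUT(S.lam1[k]);
      for (int f = 0; f < 18; ++f) PUT(S.mu[f]);
      for (int f = 0; f < 18; ++f) PUT(S.sdv[f]);
      #undef PUT
      ++isave;
    }
    if ((it + 1) % 1000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["draws"] = draws, _["n_save"] = isave);
}

// Forward-algorithm log-likelihood for adult multi-event histories,
// given per-year transition matrices and the observation matrix.
// trs: (TT-1) x 9 x 9 (flattened, year-major, row-major), obs: 9 x 7.
// [[Rcpp::export]]
NumericVector cpp_adult_forward(IntegerVector fc, IntegerVector st0,
                                IntegerMatrix ev, NumericVector trs,
                                NumericMatrix obs, int TT) {
  int n = fc.size();
  NumericVector out(n);
  std::vector<double> a0(9), a1(9);
  for (int i = 0; i < n; ++i) {
    int f = fc[i];
    if (f >= TT - 1) { out[i] = 0.0; continue; }
    std::fill(a0.begin(), a0.end(), 0.0);
    a0[st0[i]] = 1.0;
    double ll = 0.0;
    for (int t = f + 1; t < TT; ++t) {
      int e = ev(i, t);
      double tot = 0.0;
      for (int s2 = 0; s2 < 9; ++s2) {
        double acc = 0.0;
        for (int s = 0; s < 9; ++s)
          acc += a0[s] * trs[((t - 1) * 9 + s) * 9 + s2];
        acc *= obs(s2, e);
        a1[s2] = acc; tot += acc;
      }
      if (tot <= 0.0) { ll = R_NegInf; break; }
      ll += std::log(tot);
      for (int s2 = 0; s2 < 9; ++s2) a0[s2] = a1[s2] / tot;
    }
    out[i] = ll;
  }
  return out;
}
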