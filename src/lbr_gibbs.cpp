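#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Spike-slab Gibbs sampler for the SNP-by-sex interaction model
//   y = mu_sex + X b0 + X_m b_m + X_f b_f + e,   e ~ N(0, sigma2_e(sex))
// with Pr(b_kj) = pi_k N(0, sigma2_bk) + (1 - pi_k) delta_0 for
// k in {0 (shared), m, f}, Beta priors on pi_k, scaled-inv-chi2 priors on
// sigma2_bk and the sex-specific residual variances, flat priors on the
// intercepts. Columns of Xm/Xf must arrive centered on the pooled mean.
//
// Update sweep per iteration: intercepts; then for each SNP in order the
// classes 0, m, f (indicator from the effect-integrated Bernoulli
// conditional, then the Gaussian draw if included, exact zero otherwise;
// the shared class uses heteroskedastic error-variance weights over all
// individuals); then slab variances, inclusion proportions and residual
// variances. Residuals are updated incrementally after every change.

static inline double dotcol(const double *x, const double *e, int n) {
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += x[i] * e[i];
  return s;
}

static inline void axpycol(const double *x, double a, double *e, int n) {
  for (int i = 0; i < n; ++i) e[i] += a * x[i];
}

// [[Rcpp::export]]
List lbr_gibbs_cpp(NumericMatrix Xm, NumericMatrix Xf,
                   NumericVector ym, NumericVector yf,
                   NumericVector slabDf, NumericVector slabScale,
                   NumericVector piA, NumericVector piB,
                   NumericVector residDf, NumericVector residScale,
                   int nIter, int burnIn, int thin,
                   NumericVector fixPi, NumericVector fixSigma2b,
                   NumericVector fixSigma2e, NumericVector fixMu) {
  const int nm = Xm.nrow(), nf = Xf.nrow(), p = Xm.ncol();
  if (p < 1) stop("segment has no SNPs");
  if (Xf.ncol() != p) stop("male/female genotype column mismatch");

  const bool pinPi = fixPi.size() == 3;
  const bool pinS2b = fixSigma2b.size() == 3;
  const bool pinS2e = fixSigma2e.size() == 2;
  const bool pinMu = fixMu.size() == 2;

  std::vector<double> b0(p, 0.0), bm(p, 0.0), bf(p, 0.0);
  std::vector<double> em(nm), ef(nf), xxm(p), xxf(p);

  double muM, muF;
  if (pinMu) { muM = fixMu[0]; muF = fixMu[1]; }
  else {
    muM = 0.0; for (int i = 0; i < nm; ++i) muM += ym[i]; muM /= std::max(nm, 1);
    muF = 0.0; for (int i = 0; i < nf; ++i) muF += yf[i]; muF /= std::max(nf, 1);
  }
  for (int i = 0; i < nm; ++i) em[i] = ym[i] - muM;
  for (int i = 0; i < nf; ++i) ef[i] = yf[i] - muF;

  for (int j = 0; j < p; ++j) {
    xxm[j] = dotcol(&Xm(0, j), &Xm(0, j), nm);
    xxf[j] = dotcol(&Xf(0, j), &Xf(0, j), nf);
  }

  double s2em = pinS2e ? fixSigma2e[0]
                       : residScale[0] * residDf[0] / std::max(residDf[0] - 2.0, 0.5);
  double s2ef = pinS2e ? fixSigma2e[1]
                       : residScale[1] * residDf[1] / std::max(residDf[1] - 2.0, 0.5);
  double pi[3], s2b[3];
  for (int k = 0; k < 3; ++k) {
    pi[k] = pinPi ? fixPi[k] : piA[k] / (piA[k] + piB[k]);
    s2b[k] = pinS2b ? fixSigma2b[k]
                    : slabScale[k] * slabDf[k] / std::max(slabDf[k] - 2.0, 0.5);
  }

  const int nStore = (nIter - burnIn) / thin;
  NumericMatrix sb0(p, nStore), sbm(p, nStore), sbf(p, nStore);
  NumericVector smuM(nStore), smuF(nStore), ss2em(nStore), ss2ef(nStore);
  NumericMatrix spi(3, nStore), ss2b(3, nStore);
  int stored = 0;

  RNGScope scope;

  for (int it = 0; it < nIter; ++it) {
    // (a) intercepts, flat prior
    if (!pinMu) {
      double rbar = 0.0;
      for (int i = 0; i < nm; ++i) rbar += em[i];
      rbar = muM + rbar / nm;
      double muNew = rbar + norm_rand() * std::sqrt(s2em / nm);
      double shift = muM - muNew;
      for (int i = 0; i < nm; ++i) em[i] += shift;
      muM = muNew;
      rbar = 0.0;
      for (int i = 0; i < nf; ++i) rbar += ef[i];
      rbar = muF + rbar / nf;
      muNew = rbar + norm_rand() * std::sqrt(s2ef / nf);
      shift = muF - muNew;
      for (int i = 0; i < nf; ++i) ef[i] += shift;
      muF = muNew;
    }

    // (b) effects: SNPs in genomic order, classes 0, m, f at each SNP
    for (int j = 0; j < p; ++j) {
      const double *xm = &Xm(0, j);
      const double *xf = &Xf(0, j);
      // residual cross-products, computed once per SNP and kept in sync
      // with incremental residual updates (x'e shifts by -delta * x'x)
      double dm = dotcol(xm, em.data(), nm);
      double df = dotcol(xf, ef.data(), nf);
      for (int k = 0; k < 3; ++k) {
        double bOld, c, rhs;
        if (k == 0) {
          bOld = b0[j];
          c = xxm[j] / s2em + xxf[j] / s2ef;
          rhs = dm / s2em + df / s2ef + bOld * c;
        } else if (k == 1) {
          bOld = bm[j];
          c = xxm[j] / s2em;
          rhs = dm / s2em + bOld * c;
        } else {
          bOld = bf[j];
          c = xxf[j] / s2ef;
          rhs = df / s2ef + bOld * c;
        }
        if (c <= 0.0) continue;  // monomorphic column: leave effect at 0
        const double C = c + 1.0 / s2b[k];
        bool include;
        if (pi[k] >= 1.0) include = true;
        else if (pi[k] <= 0.0) include = false;
        else {
          double logodds = std::log(pi[k]) - std::log1p(-pi[k]) +
            0.5 * rhs * rhs / C - 0.5 * std::log(s2b[k] * C);
          double u = unif_rand();
          // u < plogis(logodds), computed stably
          include = std::log(u) - std::log1p(-u) < logodds;
        }
        double bNew = 0.0;
        if (include)
          bNew = rhs / C + norm_rand() / std::sqrt(C);
        if (bNew != bOld) {
          double d = bOld - bNew;
          if (k == 0) {
            axpycol(xm, d, em.data(), nm);
            axpycol(xf, d, ef.data(), nf);
            dm += d * xxm[j];
            df += d * xxf[j];
          } else if (k == 1) {
            axpycol(xm, d, em.data(), nm);
            dm += d * xxm[j];
          } else {
            axpycol(xf, d, ef.data(), nf);
            df += d * xxf[j];
          }
        }
        if (k == 0) b0[j] = bNew; else if (k == 1) bm[j] = bNew; else bf[j] = bNew;
      }
    }

    // (c, d) slab variances and inclusion proportions
    for (int k = 0; k < 3; ++k) {
      const std::vector<double> &b = (k == 0) ? b0 : (k == 1) ? bm : bf;
      int m = 0; double ss = 0.0;
      for (int j = 0; j < p; ++j)
        if (b[j] != 0.0) { ++m; ss += b[j] * b[j]; }
      if (!pinS2b)
        s2b[k] = (slabScale[k] * slabDf[k] + ss) / R::rchisq(slabDf[k] + m);
      if (!pinPi)
        pi[k] = R::rbeta(piA[k] + m, piB[k] + p - m);
    }

    // (e) residual variances
    double sseM = dotcol(em.data(), em.data(), nm);
    double sseF = dotcol(ef.data(), ef.data(), nf);
    if (!pinS2e) {
      s2em = (residDf[0] * residScale[0] + sseM) / R::rchisq(residDf[0] + nm);
      s2ef = (residDf[1] * residScale[1] + sseF) / R::rchisq(residDf[1] + nf);
    }
    if (!std::isfinite(sseM) || !std::isfinite(sseF))
      stop("non-finite residuals at iteration %d", it + 1);

    if (it >= burnIn && (it - burnIn) % thin == 0 && stored < nStore) {
      for (int j = 0; j < p; ++j) {
        sb0(j, stored) = b0[j];
        sbm(j, stored) = bm[j];
        sbf(j, stored) = bf[j];
      }
      smuM[stored] = muM; smuF[stored] = muF;
      ss2em[stored] = s2em; ss2ef[stored] = s2ef;
      for (int k = 0; k < 3; ++k) {
        spi(k, stored) = pi[k];
        ss2b(k, stored) = s2b[k];
      }
      ++stored;
    }
  }

  return List::create(
    Named("b0") = sb0, Named("bm") = sbm, Named("bf") = sbf,
    Named("muM") = smuM, Named("muF") = smuF,
    Named("sigma2eM") = ss2em, Named("sigma2eF") = ss2ef,
    Named("pi") = spi, Named("sigma2b") = ss2b);
}

// Per-draw window variances var(X_w beta_w) = beta_w' S_w beta_w, where S
// is the sample covariance matrix of (centered) dosages for one
// chromosome and windows are contiguous index ranges. Exploits the exact
// zeros of spike-slab draws: only nonzero effects enter the double sum,
// so a draw with no included SNP in a window yields exactly 0, and two
// effect vectors identical within a window yield bitwise-equal results.
//
// beta: p x D effect draws; wstart/wend: 1-based inclusive window bounds
// per focal SNP. Returns p x D matrix of window variances.
// [[Rcpp::export]]
NumericMatrix window_qform_cpp(NumericMatrix S, NumericMatrix beta,
                               IntegerVector wstart, IntegerVector wend) {
  const int p = beta.nrow(), D = beta.ncol();
  if (S.nrow() != p || S.ncol() != p) stop("covariance dimension mismatch");
  if (wstart.size() != p || wend.size() != p) stop("window bounds mismatch");
  NumericMatrix out(p, D);
  std::vector<int> nz;
  nz.reserve(p);
  for (int d = 0; d < D; ++d) {
    nz.clear();
    const double *b = &beta(0, d);
    for (int j = 0; j < p; ++j)
      if (b[j] != 0.0) nz.push_back(j);
    for (int j = 0; j < p; ++j) {
      const int a = wstart[j] - 1, e = wend[j] - 1;
      std::vector<int>::const_iterator lo =
        std::lower_bound(nz.begin(), nz.end(), a);
      std::vector<int>::const_iterator hi =
        std::upper_bound(nz.begin(), nz.end(), e);
      double s = 0.0;
      for (std::vector<int>::const_iterator u = lo; u != hi; ++u)
        for (std::vector<int>::const_iterator v = lo; v != hi; ++v)
          s += b[*u] * b[*v] * S(*u, *v);
      out(j, d) = s;
    }
  }
  return out;
}
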