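#' Single-marker regression scan with sex-difference test
#'
#' The classical GWAS baseline: within each sex separately, the (scaled)
#' phenotype is regressed on each SNP's dosage one SNP at a time (simple
#' linear regression with intercept). Sex heterogeneity is tested with
#' the normal-theory difference statistic
#' \deqn{z = (\hat\beta_f - \hat\beta_m) / \sqrt{se_f^2 + se_m^2},}
#' two-sided against the standard normal, and an any-sex-effect test
#' combines the two independent per-sex z statistics,
#' \eqn{z_m^2 + z_f^2 \sim \chi^2_2} (valid because the sexes are
#' disjoint samples).
#'
#' SNPs that are monomorphic within a sex cannot be tested; their
#' p-values are set to 1 and flagged.
#'
#' @param panel imputed [GenotypePanel-class].
#' @param y a [ScaledPhenotype-class] (or numeric, scaled upstream).
#' @return data.frame per SNP: \code{snp_id}, \code{chrom}, \code{bp},
#'   \code{beta_hat_m}, \code{se_m}, \code{beta_hat_f}, \code{se_f},
#'   \code{p_diff}, \code{p_any}, \code{monomorphic}.
#' @export
smrScan <- function(panel, y) {
  d <- dosages(panel)
  if (anyNA(d)) stop("impute missing dosages before the single-marker scan")
  yv <- phenotypeValues(y)
  stopifnot(length(yv) == nrow(d))
  male <- sexOf(panel) == "male"

  perSex <- function(X, yy) {
    n <- nrow(X)
    xbar <- colMeans(X)
    Xc <- sweep(X, 2, xbar)
    yc <- yy - mean(yy)
    sxx <- colSums(Xc^2)
    sxy <- colSums(Xc * yc)
    syy <- sum(yc^2)
    mono <- sxx == 0
    bhat <- ifelse(mono, NA_real_, sxy / sxx)
    rss <- syy - ifelse(mono, 0, bhat^2 * sxx)
    rss <- pmax(rss, 0)
    se <- ifelse(mono, NA_real_, sqrt(rss / ((n - 2) * sxx)))
    list(bhat = bhat, se = se, mono = mono)
  }
  m <- perSex(d[male, , drop = FALSE], yv[male])
  f <- perSex(d[!male, , drop = FALSE], yv[!male])

  mono <- m$mono | f$mono
  zDiff <- (f$bhat - m$bhat) / sqrt(f$se^2 + m$se^2)
  pDiff <- 2 * pnorm(-abs(zDiff))
  zm <- m$bhat / m$se
  zf <- f$bhat / f$se
  pAny <- pchisq(zm^2 + zf^2, df = 2, lower.tail = FALSE)
  pDiff[mono] <- 1
  pAny[mono] <- 1

  mp <- snpMap(panel)
  data.frame(snp_id = mp$snp_id, chrom = mp$chrom, bp = mp$bp,
    beta_hat_m = m$bhat, se_m = m$se,
    beta_hat_f = f$bhat, se_f = f$se,
    p_diff = pDiff, p_any = pAny, monomorphic = mono,
    stringsAsFactors = FALSE)
}
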