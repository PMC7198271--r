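#' Fit the spike-slab sex-interaction model on a SNP segment
#'
#' Runs the Gibbs sampler for the model
#' \deqn{y = \mu_{sex} + X b_0 + X_m b_m + X_f b_f + \varepsilon,}
#' where \eqn{b_0} are effects shared across sexes and \eqn{b_m},
#' \eqn{b_f} are male/female deviations, each with a spike-slab prior
#' (point mass at zero + Gaussian slab), and the residual variance is
#' sex-specific. Sex-specific SNP effects are recovered downstream as
#' \eqn{\beta_m = b_0 + b_m}, \eqn{\beta_f = b_0 + b_f}.
#'
#' SNP columns are centered internally on the pooled (both-sex) mean
#' before sampling. The phenotype must already be scaled to unit pooled
#' variance ([scalePhenotype()]) and the panel free of missing dosages
#' ([imputeMissing()]).
#'
#' @param panel a [GenotypePanel-class] segment (core + buffers;
#'   typically at most ~2000 SNPs).
#' @param y a [ScaledPhenotype-class] aligned with the panel's individuals.
#' @param prior an [LbrPrior-class]; default calibrated from the segment.
#' @param cfg an [McmcConfig-class]; chain settings and optional pinned
#'   parameters for validation runs.
#' @return A [PosteriorSamples-class] with
#'   \code{(nIter - burnIn) / thin} stored draws. Effects that were
#'   spiked out in a draw are stored as exact zeros.
#' @examples
#' set.seed(1)
#' gp <- genotypePanel(matrix(rbinom(200 * 10, 2, 0.3), 200, 10),
#'   sex = rep(c("male", "female"), each = 100))
#' y <- scalePhenotype(rnorm(200))
#' fit <- gibbsFit(gp, y, cfg = mcmcConfig(nIter = 300, burnIn = 100,
#'   thin = 1, seed = 7))
#' nDraws(fit)
#' @export
gibbsFit <- function(panel, y, prior = NULL, cfg = mcmcConfig()) {
  stopifnot(is(panel, "GenotypePanel"), is(cfg, "McmcConfig"))
  if (!is(y, "ScaledPhenotype") || !y@scaled)
    stop("y must be a scaled phenotype (see scalePhenotype)")
  d <- dosages(panel)
  if (anyNA(d)) stop("panel contains missing dosages; run imputeMissing first")
  p <- ncol(d)
  if (p == 0) stop("segment has no SNPs")
  yv <- y@values
  if (length(yv) != nrow(d)) stop("phenotype length does not match panel")

  Xc <- sweep(d, 2, colMeans(d))
  male <- sexOf(panel) == "male"
  if (!any(male) || all(male)) stop("both sexes must be present in the panel")
  if (is.null(prior))
    prior <- lbrPrior(p, sumVarX = sum(apply(Xc, 2, var)), varY = var(yv))
  stopifnot(is(prior, "LbrPrior"))

  Xm <- Xc[male, , drop = FALSE]
  Xf <- Xc[!male, , drop = FALSE]
  set.seed(cfg@seed)
  res <- lbr_gibbs_cpp(Xm, Xf, yv[male], yv[!male],
    prior@slabDf, prior@slabScale, prior@piA, prior@piB,
    prior@residualDf, prior@residualScale,
    cfg@nIter, cfg@burnIn, cfg@thin,
    cfg@fixPi, cfg@fixSigma2b, cfg@fixSigma2e, cfg@fixMu)

  new("PosteriorSamples",
    b0 = res$b0, bm = res$bm, bf = res$bf,
    muM = res$muM, muF = res$muF,
    sigma2eM = res$sigma2eM, sigma2eF = res$sigma2eF,
    pi = res$pi, sigma2b = res$sigma2b,
    snpId = panel@snpId, chrom = panel@chrom, bp = panel@bp,
    seed = cfg@seed)
}

#' Monte Carlo standard error by batch means
#'
#' @param x numeric vector of correlated MCMC draws.
#' @return estimated standard error of \code{mean(x)}.
#' @export
mcStandardError <- function(x) {
  D <- length(x)
  if (D < 2) stop("need at least 2 draws")
  nb <- max(2L, floor(sqrt(D)))
  bs <- D %/% nb
  bm <- colMeans(matrix(x[seq_len(nb * bs)], nrow = bs))
  sd(bm) / sqrt(nb)
}

#' Split-chain potential scale reduction
#'
#' Splits one chain into halves and computes the usual
#' between/within-variance shrink factor; values near 1 indicate the
#' halves agree.
#'
#' @param x numeric vector of draws (or a matrix whose columns are
#'   chains, each of which is split).
#' @return the potential scale reduction factor (scalar).
#' @export
splitRhat <- function(x) {
  x <- as.matrix(x)
  half <- floor(nrow(x) / 2)
  chains <- cbind(x[seq_len(half), , drop = FALSE],
                  x[seq(nrow(x) - half + 1, nrow(x)), , drop = FALSE])
  m <- ncol(chains); nn <- nrow(chains)
  mu <- colMeans(chains)
  W <- mean(apply(chains, 2, var))
  B <- nn * var(mu)
  if (W <= 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Chain diagnostics for a fitted segment
#'
#' Posterior means, Monte Carlo standard errors (batch means) and
#' split-chain potential scale reduction for the residual variances and
#' the three inclusion proportions.
#'
#' @param samples a [PosteriorSamples-class] with at least 2 stored draws.
#' @return data.frame with columns \code{parameter}, \code{mean},
#'   \code{mcse}, \code{rhat}.
#' @export
logDiagnostics <- function(samples) {
  stopifnot(is(samples, "PosteriorSamples"))
  if (nDraws(samples) < 2)
    stop("diagnostics require at least 2 stored draws")
  draws <- list(
    sigma2e_m = samples@sigma2eM,
    sigma2e_f = samples@sigma2eF,
    pi_0 = samples@pi[1, ],
    pi_m = samples@pi[2, ],
    pi_f = samples@pi[3, ])
  data.frame(
    parameter = names(draws),
    mean = vapply(draws, mean, 0),
    mcse = vapply(draws, mcStandardError, 0),
    rhat = vapply(draws, splitRhat, 0),
    row.names = NULL)
}
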