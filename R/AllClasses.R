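#' @useDynLib lbrmap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats var cor sd rnorm rexp runif rchisq qnorm pnorm pchisq
#'   phyper quantile ks.test lm coef acf
#' @importFrom utils read.table write.table head tail
NULL

#' Genotype panel with SNP map and sex labels
#'
#' Container for an n x p biallelic dosage matrix (allele counts in
#' \{0, 1, 2\}, \code{NA} for missing) together with the SNP map
#' (chromosome, base-pair position, identifier) and per-individual sex
#' labels. This is the genotype object consumed by the segment-wise
#' Bayesian fits, the single-marker scan and the window machinery;
#' male and female rows are the two design blocks of the
#' SNP-by-sex interaction model.
#'
#' @slot dosages numeric matrix, individuals x SNPs.
#' @slot snpId character vector of SNP identifiers (length p).
#' @slot chrom character vector of chromosome labels (length p).
#' @slot bp numeric vector of 1-based base-pair positions, strictly
#'   increasing within each chromosome.
#' @slot individualId character vector of individual identifiers (length n).
#' @slot sex factor with levels \code{male}, \code{female} (length n).
#'
#' @seealso [genotypePanel()], [readPlink()], [imputeMissing()]
#' @export
setClass("GenotypePanel",
  representation(
    dosages = "matrix",
    snpId = "character",
    chrom = "character",
    bp = "numeric",
    individualId = "character",
    sex = "factor"
  )
)

setValidity("GenotypePanel", function(object) {
  msg <- character()
  n <- nrow(object@dosages)
  p <- ncol(object@dosages)
  if (length(object@snpId) != p) msg <- c(msg, "snpId length != ncol(dosages)")
  if (length(object@chrom) != p) msg <- c(msg, "chrom length != ncol(dosages)")
  if (length(object@bp) != p) msg <- c(msg, "bp length != ncol(dosages)")
  if (length(object@individualId) != n)
    msg <- c(msg, "individualId length != nrow(dosages)")
  if (length(object@sex) != n) msg <- c(msg, "sex length != nrow(dosages)")
  if (!identical(levels(object@sex), c("male", "female")))
    msg <- c(msg, "sex must be a factor with levels male, female")
  if (anyNA(object@sex)) msg <- c(msg, "every individual must have a sex label")
  d <- object@dosages
  # imputed panels carry fractional dosages in [0, 2]; raw panels are {0,1,2,NA}
  if (any(!is.na(d) & (d < 0 | d > 2)))
    msg <- c(msg, "dosages must lie in [0, 2] or be NA")
  for (ch in unique(object@chrom)) {
    b <- object@bp[object@chrom == ch]
    if (length(b) > 1 && any(diff(b) <= 0)) {
      msg <- c(msg, sprintf("bp not strictly increasing within chromosome %s", ch))
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypePanel
#'
#' @param dosages numeric matrix of allele counts (individuals x SNPs),
#'   entries in \[0, 2\] or \code{NA}.
#' @param snpId,chrom,bp SNP map vectors (length \code{ncol(dosages)}).
#' @param individualId individual identifiers (length \code{nrow(dosages)}).
#' @param sex character or factor of \code{"male"}/\code{"female"}.
#' @return A [GenotypePanel-class] object.
#' @examples
#' gp <- genotypePanel(matrix(c(0, 1, 2, 2, 1, 0), 3, 2),
#'   snpId = c("rs1", "rs2"), chrom = c("1", "1"), bp = c(100, 200),
#'   individualId = c("i1", "i2", "i3"), sex = c("male", "female", "female"))
#' nSnps(gp)
#' @export
genotypePanel <- function(dosages, snpId = NULL, chrom = NULL, bp = NULL,
                          individualId = NULL, sex) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  p <- ncol(dosages)
  n <- nrow(dosages)
  if (is.null(snpId)) snpId <- paste0("snp", seq_len(p))
  if (is.null(chrom)) chrom <- rep("1", p)
  if (is.null(bp)) bp <- as.numeric(seq_len(p))
  if (is.null(individualId)) individualId <- paste0("ind", seq_len(n))
  sex <- factor(as.character(sex), levels = c("male", "female"))
  new("GenotypePanel",
    dosages = dosages, snpId = as.character(snpId),
    chrom = as.character(chrom), bp = as.numeric(bp),
    individualId = as.character(individualId), sex = sex)
}

#' @describeIn genotypePanel Number of SNPs in a panel.
#' @param x a \code{GenotypePanel}.
#' @export
nSnps <- function(x) ncol(x@dosages)

#' @describeIn genotypePanel Number of individuals in a panel.
#' @export
nIndividuals <- function(x) nrow(x@dosages)

#' @describeIn genotypePanel Dosage matrix accessor.
#' @export
dosages <- function(x) x@dosages

#' @describeIn genotypePanel SNP map as a data.frame
#'   (columns \code{snp_id}, \code{chrom}, \code{bp}).
#' @export
snpMap <- function(x) {
  data.frame(snp_id = x@snpId, chrom = x@chrom, bp = x@bp,
             stringsAsFactors = FALSE)
}

#' @describeIn genotypePanel Sex factor accessor.
#' @export
sexOf <- function(x) x@sex

#' @describeIn genotypePanel Individual identifier accessor.
#' @export
individualIds <- function(x) x@individualId

setMethod("show", "GenotypePanel", function(object) {
  cat("GenotypePanel:", nIndividuals(object), "individuals x",
      nSnps(object), "SNPs\n")
  cat("  chromosomes:", paste(unique(object@chrom), collapse = ", "), "\n")
  tab <- table(object@sex)
  cat("  sex: ", tab[["male"]], " male / ", tab[["female"]], " female\n", sep = "")
  nmiss <- sum(is.na(object@dosages))
  if (nmiss > 0) cat("  missing dosages:", nmiss, "\n")
})

#' Subset a genotype panel
#'
#' @param x a \code{GenotypePanel}.
#' @param i individual index (rows).
#' @param j SNP index (columns).
#' @param ... ignored.
#' @param drop ignored; the result is always a \code{GenotypePanel}.
#' @export
setMethod("[", "GenotypePanel", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nIndividuals(x))
  if (missing(j)) j <- seq_len(nSnps(x))
  new("GenotypePanel",
    dosages = x@dosages[i, j, drop = FALSE],
    snpId = x@snpId[j], chrom = x@chrom[j], bp = x@bp[j],
    individualId = x@individualId[i], sex = x@sex[i])
})

#' Scaled phenotype vector
#'
#' A phenotype vector with a flag recording whether it has been scaled
#' to unit pooled variance across the two sexes. The model is always fit
#' on scaled phenotypes so that window variances read as proportions of
#' total phenotypic variance.
#'
#' @slot values numeric phenotype values (one per individual).
#' @slot scaled logical; \code{TRUE} once pooled sample variance is 1.
#' @seealso [scalePhenotype()]
#' @export
setClass("ScaledPhenotype",
  representation(values = "numeric", scaled = "logical"))

setValidity("ScaledPhenotype", function(object) {
  if (length(object@scaled) != 1) return("scaled must be a single logical")
  if (anyNA(object@values)) return("phenotype values must be non-missing")
  if (isTRUE(object@scaled)) {
    v <- var(object@values)
    if (abs(v - 1) > 1e-8)
      return(sprintf("scaled phenotype must have pooled variance 1 (got %g)", v))
  }
  TRUE
})

#' @describeIn scalePhenotype Extract the numeric values of a phenotype.
#' @export
phenotypeValues <- function(y) {
  if (is(y, "ScaledPhenotype")) y@values else as.numeric(y)
}

setMethod("show", "ScaledPhenotype", function(object) {
  cat("ScaledPhenotype: n =", length(object@values),
      if (object@scaled) "(scaled, pooled variance 1)" else "(unscaled)", "\n")
})

#' Spike-slab prior settings for the sex-interaction model
#'
#' Hyper-parameters for the three effect classes of the model: shared
#' (\code{0}), male deviation (\code{m}) and female deviation (\code{f}).
#' Each class k has a spike-slab prior on its SNP effects,
#' \eqn{b_{kj} \sim \pi_k N(0, \sigma^2_{bk}) + (1-\pi_k)\,\delta_0}, with a
#' scaled-inverse-chi-square hyper-prior on the slab variance and a Beta
#' hyper-prior on the inclusion proportion. Residual variances are
#' sex-specific with their own scaled-inverse-chi-square priors.
#'
#' @slot slabDf,slabScale length-3 numeric (classes 0, m, f): df and scale
#'   of the slab-variance hyper-prior.
#' @slot piA,piB length-3 numeric: Beta counts of the inclusion-proportion
#'   hyper-prior.
#' @slot residualDf,residualScale length-2 numeric (male, female): df and
#'   scale of the residual-variance prior.
#' @seealso [lbrPrior()]
#' @export
setClass("LbrPrior",
  representation(slabDf = "numeric", slabScale = "numeric",
                 piA = "numeric", piB = "numeric",
                 residualDf = "numeric", residualScale = "numeric"))

setValidity("LbrPrior", function(object) {
  msg <- character()
  for (s in c("slabDf", "slabScale", "piA", "piB"))
    if (length(slot(object, s)) != 3 || any(slot(object, s) <= 0))
      msg <- c(msg, sprintf("%s must be length 3 and positive", s))
  for (s in c("residualDf", "residualScale"))
    if (length(slot(object, s)) != 2 || any(slot(object, s) <= 0))
      msg <- c(msg, sprintf("%s must be length 2 and positive", s))
  if (length(msg)) msg else TRUE
})

#' Construct prior settings for a segment fit
#'
#' Default hyper-parameters follow the conventions of Bayesian
#' whole-genome regression software: slab scales are chosen so that the
#' prior-expected genetic variance of each effect class equals one third
#' of an overall R-squared guess (apportioned to the segment by its share
#' of genome SNPs), and the sparsity prior puts mean inclusion around
#' 50/p per class.
#'
#' @param p number of SNPs in the segment to be fit.
#' @param sumVarX sum of per-SNP dosage variances over the segment
#'   (pooled individuals). Used to calibrate the slab scale.
#' @param r2 prior guess of total trait R-squared attributable to the
#'   segment's SNPs (default 0.5 scaled by \code{genomeFraction}).
#' @param genomeFraction fraction of genome SNPs in this segment (1 when
#'   fitting a whole panel at once).
#' @param varY phenotype variance (1 after scaling); calibrates the
#'   residual-variance prior scale.
#' @param slabDf,residualDf degrees of freedom (defaults 5).
#' @param piA,piB Beta counts; default \code{piA = 1}, \code{piB = p/50}.
#' @return An [LbrPrior-class] object.
#' @export
lbrPrior <- function(p, sumVarX = p * 0.5, r2 = 0.5, genomeFraction = 1,
                     varY = 1, slabDf = 5, residualDf = 5,
                     piA = 1, piB = max(p / 50, 1)) {
  targetVar <- r2 * genomeFraction / 3     # per effect class
  piMean <- piA / (piA + piB)
  # E[sigma2_bk] = slabScale*slabDf/(slabDf-2); prior genetic var of class k
  # is approx piMean * E[sigma2_bk] * sumVarX
  slabScale <- targetVar * (slabDf - 2) / (slabDf * piMean * max(sumVarX, 1e-12))
  residScale <- varY * (1 - r2 * genomeFraction / 2) * (residualDf - 2) / residualDf
  new("LbrPrior",
    slabDf = rep(slabDf, 3), slabScale = rep(slabScale, 3),
    piA = rep(piA, 3), piB = rep(piB, 3),
    residualDf = rep(residualDf, 2), residualScale = rep(residScale, 2))
}

setMethod("show", "LbrPrior", function(object) {
  cat("LbrPrior (classes 0/m/f):\n")
  cat("  slab df:", object@slabDf[1], " slab scale:",
      signif(object@slabScale, 4), "\n")
  cat("  pi ~ Beta(", object@piA[1], ",", signif(object@piB[1], 4), ")\n")
  cat("  residual df:", object@residualDf[1], " scale:",
      signif(object@residualScale, 4), "\n")
})

#' MCMC run configuration
#'
#' Chain settings for the Gibbs sampler, plus optional fixed values used
#' by validation runs (conjugate-limit and enumeration checks): any of
#' the inclusion proportions, slab variances, residual variances or
#' intercepts may be pinned at known values instead of being sampled.
#'
#' @slot nIter,burnIn,thin integers; stored draws number
#'   \code{(nIter - burnIn) / thin}.
#' @slot seed integer RNG seed.
#' @slot fixPi length-0 (free) or length-3 numeric in \[0, 1\].
#' @slot fixSigma2b length-0 or length-3 positive numeric.
#' @slot fixSigma2e length-0 or length-2 positive numeric.
#' @slot fixMu length-0 or length-2 numeric.
#' @seealso [mcmcConfig()], [gibbsFit()]
#' @export
setClass("McmcConfig",
  representation(nIter = "integer", burnIn = "integer", thin = "integer",
                 seed = "integer", fixPi = "numeric", fixSigma2b = "numeric",
                 fixSigma2e = "numeric", fixMu = "numeric"))

setValidity("McmcConfig", function(object) {
  msg <- character()
  if (object@burnIn >= object@nIter) msg <- c(msg, "burnIn must be < nIter")
  if (object@thin < 1) msg <- c(msg, "thin must be >= 1")
  if (!length(object@fixPi) %in% c(0, 3) ||
      (length(object@fixPi) && any(object@fixPi < 0 | object@fixPi > 1)))
    msg <- c(msg, "fixPi must be empty or 3 probabilities")
  if (!length(object@fixSigma2b) %in% c(0, 3) ||
      (length(object@fixSigma2b) && any(object@fixSigma2b <= 0)))
    msg <- c(msg, "fixSigma2b must be empty or 3 positive values")
  if (!length(object@fixSigma2e) %in% c(0, 2) ||
      (length(object@fixSigma2e) && any(object@fixSigma2e <= 0)))
    msg <- c(msg, "fixSigma2e must be empty or 2 positive values")
  if (!length(object@fixMu) %in% c(0, 2))
    msg <- c(msg, "fixMu must be empty or 2 values")
  if (length(msg)) msg else TRUE
})

#' @rdname McmcConfig-class
#' @param nIter,burnIn,thin chain length, burn-in, keep-every stride.
#'   Defaults give 2000 stored draws, enough for posterior probabilities
#'   with MC standard error around 0.011.
#' @param seed integer RNG seed.
#' @param fixPi,fixSigma2b,fixSigma2e,fixMu optional fixed parameter
#'   values (see slots); leave empty to sample them.
#' @return An [McmcConfig-class] object.
#' @export
mcmcConfig <- function(nIter = 12000L, burnIn = 2000L, thin = 5L, seed = 1L,
                       fixPi = numeric(0), fixSigma2b = numeric(0),
                       fixSigma2e = numeric(0), fixMu = numeric(0)) {
  new("McmcConfig", nIter = as.integer(nIter), burnIn = as.integer(burnIn),
      thin = as.integer(thin), seed = as.integer(seed),
      fixPi = as.numeric(fixPi), fixSigma2b = as.numeric(fixSigma2b),
      fixSigma2e = as.numeric(fixSigma2e), fixMu = as.numeric(fixMu))
}

setMethod("show", "McmcConfig", function(object) {
  cat("McmcConfig: nIter =", object@nIter, "burnIn =", object@burnIn,
      "thin =", object@thin, "seed =", object@seed, "\n")
  cat("  stored draws:", (object@nIter - object@burnIn) %/% object@thin, "\n")
})

#' Posterior samples from the sex-interaction model
#'
#' Stored Gibbs draws for a SNP segment (or, after stitching, a whole
#' panel). Effect draws keep exact zeros whenever the corresponding
#' inclusion indicator was off, which downstream sex-difference
#' probabilities rely on.
#'
#' @slot b0,bm,bf p x D matrices of effect draws (shared, male deviation,
#'   female deviation); exact zeros when spiked out.
#' @slot muM,muF length-D intercept draws.
#' @slot sigma2eM,sigma2eF length-D residual-variance draws.
#' @slot pi 3 x D inclusion-proportion draws (rows: classes 0, m, f).
#' @slot sigma2b 3 x D slab-variance draws.
#' @slot snpId,chrom,bp SNP map for the p SNPs.
#' @slot seed integer seed used for the fit (metadata).
#' @seealso [gibbsFit()], [stitchSamples()], [snpProbabilities()]
#' @export
setClass("PosteriorSamples",
  representation(b0 = "matrix", bm = "matrix", bf = "matrix",
                 muM = "numeric", muF = "numeric",
                 sigma2eM = "numeric", sigma2eF = "numeric",
                 pi = "matrix", sigma2b = "matrix",
                 snpId = "character", chrom = "character", bp = "numeric",
                 seed = "integer"))

setValidity("PosteriorSamples", function(object) {
  msg <- character()
  D <- ncol(object@b0)
  p <- nrow(object@b0)
  if (!all(dim(object@bm) == c(p, D)) || !all(dim(object@bf) == c(p, D)))
    msg <- c(msg, "b0, bm, bf must share dimensions")
  if (length(object@muM) != D || length(object@muF) != D ||
      length(object@sigma2eM) != D || length(object@sigma2eF) != D)
    msg <- c(msg, "scalar-parameter draws must have one entry per stored draw")
  if (any(object@sigma2eM <= 0) || any(object@sigma2eF <= 0))
    msg <- c(msg, "residual variance draws must be positive")
  if (nrow(object@pi) != 3 || nrow(object@sigma2b) != 3)
    msg <- c(msg, "pi and sigma2b must have 3 rows (classes 0, m, f)")
  if (any(object@pi < 0 | object@pi > 1)) msg <- c(msg, "pi draws outside [0,1]")
  if (any(object@sigma2b <= 0)) msg <- c(msg, "slab variance draws must be positive")
  if (length(object@snpId) != p || length(object@chrom) != p ||
      length(object@bp) != p)
    msg <- c(msg, "SNP map length must equal number of SNP rows")
  if (length(msg)) msg else TRUE
})

#' @describeIn PosteriorSamples-class Number of stored draws.
#' @param x a \code{PosteriorSamples}.
#' @export
nDraws <- function(x) ncol(x@b0)

#' @describeIn PosteriorSamples-class Effect draw matrices as a list
#'   with elements \code{b0}, \code{bm}, \code{bf} (p x D each).
#' @export
effectDraws <- function(x) list(b0 = x@b0, bm = x@bm, bf = x@bf)

#' @describeIn PosteriorSamples-class SNP map of the sampled SNPs.
#' @export
sampleSnpMap <- function(x) {
  data.frame(snp_id = x@snpId, chrom = x@chrom, bp = x@bp,
             stringsAsFactors = FALSE)
}

setMethod("show", "PosteriorSamples", function(object) {
  cat("PosteriorSamples:", nrow(object@b0), "SNPs x", ncol(object@b0),
      "stored draws\n")
  cat("  mean residual variances (m, f):",
      signif(mean(object@sigma2eM), 4), signif(mean(object@sigma2eF), 4), "\n")
  cat("  mean inclusion proportions (0, m, f):",
      signif(rowMeans(object@pi), 3), "\n")
})

#' Genome segmentation plan
#'
#' Core/buffer tiling of a SNP panel: disjoint core blocks that jointly
#' cover every SNP exactly once, each extended by flanking buffer SNPs
#' (clipped at chromosome ends) for fitting. Indices are 1-based with
#' inclusive starts and exclusive ends.
#'
#' @slot table data.frame with columns \code{segment_id}, \code{chrom},
#'   \code{core_start}, \code{core_end}, \code{fit_start}, \code{fit_end}
#'   (SNP indices into the planned panel).
#' @seealso [planSegments()]
#' @export
setClass("SegmentPlan", representation(table = "data.frame"))

setValidity("SegmentPlan", function(object) {
  tab <- object@table
  need <- c("segment_id", "chrom", "core_start", "core_end",
            "fit_start", "fit_end")
  if (!all(need %in% names(tab))) return("missing plan columns")
  if (any(tab$fit_start > tab$core_start) || any(tab$fit_end < tab$core_end))
    return("fit interval must contain core interval")
  TRUE
})

#' @describeIn SegmentPlan-class Plan table accessor.
#' @param x a \code{SegmentPlan}.
#' @export
segmentTable <- function(x) x@table

#' @describeIn SegmentPlan-class Number of segments.
#' @export
nSegments <- function(x) nrow(x@table)

setMethod("show", "SegmentPlan", function(object) {
  cat("SegmentPlan:", nrow(object@table), "segments over",
      length(unique(object@table$chrom)), "chromosome(s)\n")
  print(head(object@table, 5))
  if (nrow(object@table) > 5) cat("  ...\n")
})
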