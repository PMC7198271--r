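#' Genotype simulator configuration
#'
#' Settings for the latent-Gaussian haplotype genotype generator. The
#' generator is calibrated to one property real panels exhibit and the
#' local-regression method exploits: squared dosage correlation that
#' decays to (below 0.01) within \code{ldDecayBp} of distance.
#'
#' @param nMale,nFemale sample sizes per sex.
#' @param nChrom number of chromosomes.
#' @param snpsPerChrom SNPs per chromosome.
#' @param meanSpacingBp mean inter-SNP spacing (exponential; default 5 kb).
#' @param ldDecayBp distance at which dosage R-squared has decayed to
#'   ~0 (default 1.5 Mb, within the 1-2 Mb range typical of unstructured
#'   human populations).
#' @param mafRange allele-frequency range, uniform per SNP.
#' @param seed integer RNG seed.
#' @return list of class \code{GenoSimConfig}.
#' @export
genoSimConfig <- function(nMale = 3000L, nFemale = 3000L, nChrom = 2L,
                          snpsPerChrom = 1000L, meanSpacingBp = 5000,
                          ldDecayBp = 1.5e6, mafRange = c(0.05, 0.5),
                          seed = 1L) {
  stopifnot(snpsPerChrom >= 1, nChrom >= 1, nMale >= 1, nFemale >= 1,
            length(mafRange) == 2, mafRange[1] > 0,
            mafRange[1] <= mafRange[2], mafRange[2] <= 0.5)
  structure(list(nMale = as.integer(nMale), nFemale = as.integer(nFemale),
    nChrom = as.integer(nChrom), snpsPerChrom = as.integer(snpsPerChrom),
    meanSpacingBp = meanSpacingBp, ldDecayBp = ldDecayBp,
    mafRange = mafRange, seed = as.integer(seed)),
    class = "GenoSimConfig")
}

#' Trait simulator configuration
#'
#' Settings for the sex-specific trait architecture: causal variants are
#' placed one per \code{causalSpacingBp} stratum, each contributing an
#' expected \code{perVariantR2} of phenotypic variance, with a fraction
#' \code{propGxs} of them having sex-differing effects.
#'
#' @param nCausal number of causal variants (default 150).
#' @param causalSpacingBp stratum width for causal placement (default 2 Mb).
#' @param perVariantR2 expected proportion of phenotypic variance per
#'   causal variant (default 3.3e-4).
#' @param propGxs fraction of causal variants with sex-differing effects
#'   (default 0.4).
#' @param gxsScheme how sex-differing effects are drawn:
#'   \code{"one_sex_only"} (effect in one sex, alternating, zero in the
#'   other), \code{"independent_draw"} (independent per-sex magnitudes
#'   with equal expected per-sex variance), or \code{"mixed"} (half
#'   each; default).
#' @param seed integer RNG seed.
#' @return list of class \code{TraitSimConfig}.
#' @export
traitSimConfig <- function(nCausal = 150L, causalSpacingBp = 2e6,
                           perVariantR2 = 3.3e-4, propGxs = 0.4,
                           gxsScheme = c("mixed", "one_sex_only",
                                         "independent_draw"),
                           seed = 1L) {
  gxsScheme <- match.arg(gxsScheme)
  stopifnot(propGxs >= 0, propGxs <= 1, perVariantR2 * nCausal < 1)
  structure(list(nCausal = as.integer(nCausal),
    causalSpacingBp = causalSpacingBp, perVariantR2 = perVariantR2,
    propGxs = propGxs, gxsScheme = gxsScheme, seed = as.integer(seed)),
    class = "TraitSimConfig")
}

#' Simulate an LD-bearing genotype panel
#'
#' Latent-Gaussian haplotype model: per chromosome, SNP positions are
#' cumulative exponential spacings; each haplotype carries a stationary
#' first-order latent Gaussian process with inter-SNP correlation
#' \eqn{\exp(-d/\phi)}, \eqn{\phi} calibrated so squared dosage
#' correlation falls below 0.01 beyond \code{ldDecayBp}; the allele is
#' the indicator that the latent value exceeds the \eqn{1 - maf_j}
#' quantile, and the dosage is the sum of two independent haplotypes.
#' Sexes are assigned to the first \code{nMale} / last \code{nFemale}
#' rows; the genotype distribution is identical across sexes, so there
#' is no genotype-sex confounding by construction.
#'
#' @param cfg a [genoSimConfig()] list.
#' @return A [GenotypePanel-class] with integer dosages and no missing
#'   values.
#' @export
simulateGenotypes <- function(cfg) {
  stopifnot(inherits(cfg, "GenoSimConfig"))
  set.seed(cfg$seed)
  n <- cfg$nMale + cfg$nFemale
  p <- cfg$snpsPerChrom
  # exp(-2 d / phi) = 0.01 at d = ldDecayBp (binarisation only attenuates)
  phi <- 2 * cfg$ldDecayBp / log(100)
  dosage <- matrix(0L, n, cfg$nChrom * p)
  bp <- numeric(cfg$nChrom * p)
  chrom <- character(cfg$nChrom * p)
  for (ch in seq_len(cfg$nChrom)) {
    pos <- cumsum(pmax(1, round(rexp(p, rate = 1 / cfg$meanSpacingBp))))
    maf <- runif(p, cfg$mafRange[1], cfg$mafRange[2])
    thr <- qnorm(1 - maf)
    rho <- c(0, exp(-diff(pos) / phi))
    Z <- matrix(0, 2L * n, p)
    Z[, 1] <- rnorm(2L * n)
    for (j in 2:p)
      Z[, j] <- rho[j] * Z[, j - 1] + sqrt(1 - rho[j]^2) * rnorm(2L * n)
    A <- Z > matrix(thr, 2L * n, p, byrow = TRUE)
    cols <- (ch - 1L) * p + seq_len(p)
    dosage[, cols] <- A[seq_len(n), ] + A[n + seq_len(n), ]
    bp[cols] <- pos
    chrom[cols] <- as.character(ch)
  }
  genotypePanel(dosage, snpId = paste0("sim", seq_len(cfg$nChrom * p)),
    chrom = chrom, bp = bp,
    individualId = paste0("ind", seq_len(n)),
    sex = rep(c("male", "female"), c(cfg$nMale, cfg$nFemale)))
}

#' Simulate a trait with sex-specific architecture
#'
#' Causal SNPs are drawn one per \code{causalSpacingBp} stratum
#' (uniformly within each stratum). A shared causal variant gets equal
#' per-sex effects with magnitude set so its expected variance
#' contribution is \code{perVariantR2} of the (unit) phenotypic
#' variance; sex-differing variants follow \code{gxsScheme}. The
#' phenotype is the genetic value plus Gaussian noise whose variance
#' tops total pooled variance up to 1; the noise vector is drawn
#' orthogonal to the genetic values so the variance ledger
#' (genetic + residual = total) is exact. The returned phenotype is
#' passed through [scalePhenotype()].
#'
#' @param panel a [GenotypePanel-class] (typically from
#'   [simulateGenotypes()]).
#' @param cfg a [traitSimConfig()] list.
#' @return list with elements \code{y} (a [ScaledPhenotype-class]) and
#'   \code{truth}, a list of class \code{SimulationTruth} holding
#'   \code{table} (per causal SNP: index, id, chrom, bp, true per-sex
#'   effects, GxS flag, realized variance fraction) and the realized
#'   variance components \code{varG}, \code{varE}, \code{varY}.
#' @export
simulateTrait <- function(panel, cfg) {
  stopifnot(is(panel, "GenotypePanel"), inherits(cfg, "TraitSimConfig"))
  set.seed(cfg$seed)
  d <- dosages(panel)
  n <- nrow(d)
  # strata: per chromosome, consecutive causalSpacingBp bins holding >=1 SNP
  strat <- paste(panel@chrom,
                 floor((panel@bp - 1) / cfg$causalSpacingBp), sep = ":")
  stratIds <- unique(strat)
  if (length(stratIds) < cfg$nCausal)
    stop(sprintf("panel spans only %d strata of %g bp; cannot place %d causal variants",
                 length(stratIds), cfg$causalSpacingBp, cfg$nCausal))
  chosen <- sort(sample(length(stratIds), cfg$nCausal))
  causal <- vapply(stratIds[chosen], function(s) {
    cand <- which(strat == s)
    if (length(cand) == 1) cand else cand[sample.int(length(cand), 1)]
  }, 0L)
  causal <- sort(unname(causal))

  nGxs <- round(cfg$propGxs * cfg$nCausal)
  gxsIdx <- if (nGxs > 0) sort(sample(cfg$nCausal, nGxs)) else integer(0)

  freq <- colMeans(d[, causal, drop = FALSE]) / 2
  varExp <- 2 * freq * (1 - freq)            # expected dosage variance (HWE)
  r2 <- cfg$perVariantR2
  betaM <- betaF <- numeric(cfg$nCausal)
  shared <- setdiff(seq_len(cfg$nCausal), gxsIdx)
  sgn <- sample(c(-1, 1), cfg$nCausal, replace = TRUE)
  betaM[shared] <- betaF[shared] <- sgn[shared] * sqrt(r2 / varExp[shared])

  if (nGxs > 0) {
    scheme <- rep(cfg$gxsScheme, nGxs)
    if (cfg$gxsScheme == "mixed")
      scheme <- rep(c("one_sex_only", "independent_draw"), length.out = nGxs)
    maleTurn <- TRUE
    for (i in seq_len(nGxs)) {
      k <- gxsIdx[i]
      if (scheme[i] == "one_sex_only") {
        # doubled variance in the active sex keeps the pooled contribution at r2
        b <- sgn[k] * sqrt(2 * r2 / varExp[k])
        if (maleTurn) { betaM[k] <- b; betaF[k] <- 0 }
        else { betaM[k] <- 0; betaF[k] <- b }
        maleTurn <- !maleTurn
      } else {
        repeat {
          bm <- rnorm(1, 0, sqrt(r2 / varExp[k]))
          bf <- rnorm(1, 0, sqrt(r2 / varExp[k]))
          if (bm != bf) break
        }
        betaM[k] <- bm; betaF[k] <- bf
      }
    }
  }

  male <- sexOf(panel) == "male"
  Xcaus <- d[, causal, drop = FALSE]
  B <- matrix(0, cfg$nCausal, n)
  B[, male] <- betaM
  B[, !male] <- betaF
  contrib <- Xcaus * t(B)
  # center contributions within sex: phenotypes are sex-precorrected
  # upstream, so between-sex genetic mean shifts are not trait variance
  contrib[male, ] <- sweep(contrib[male, , drop = FALSE], 2,
                           colMeans(contrib[male, , drop = FALSE]))
  contrib[!male, ] <- sweep(contrib[!male, , drop = FALSE], 2,
                            colMeans(contrib[!male, , drop = FALSE]))
  g <- rowSums(contrib)
  realizedR2 <- apply(contrib, 2, var)

  varG <- var(g)
  if (varG >= 1)
    stop("realized genetic variance >= 1; lower perVariantR2 or nCausal")
  eps <- rnorm(n)
  gc <- g - mean(g)
  if (sum(gc^2) > 0)
    eps <- eps - gc * sum(eps * gc) / sum(gc^2)   # exact variance ledger
  eps <- eps - mean(eps)
  eps <- eps * sqrt((1 - varG) * (n - 1) / sum(eps^2))
  yRaw <- g + eps

  truth <- structure(list(
    table = data.frame(
      index = causal, snp_id = panel@snpId[causal],
      chrom = panel@chrom[causal], bp = panel@bp[causal],
      beta_m_true = betaM, beta_f_true = betaF,
      gxs = betaM != betaF, realized_r2 = realizedR2,
      stringsAsFactors = FALSE),
    varG = varG, varE = var(eps), varY = var(yRaw)),
    class = "SimulationTruth")
  list(y = scalePhenotype(yRaw), truth = truth)
}

#' @export
print.SimulationTruth <- function(x, ...) {
  cat("SimulationTruth:", nrow(x$table), "causal variants,",
      sum(x$table$gxs), "with sex-differing effects\n")
  cat("  realized variance: genetic", signif(x$varG, 4),
      "residual", signif(x$varE, 4), "total", signif(x$varY, 4), "\n")
  invisible(x)
}

#' Remove causal variants from a panel
#'
#' Masked-causal mode: drops all causal columns so that discovery must
#' rely on LD tagging. The truth table keeps the original base-pair
#' positions for target-area evaluation. Masking is idempotent.
#'
#' @param panel a [GenotypePanel-class].
#' @param truth a \code{SimulationTruth} from [simulateTrait()].
#' @return the panel minus causal columns.
#' @export
maskCausal <- function(panel, truth) {
  drop <- which(panel@snpId %in% truth$table$snp_id)
  if (!length(drop)) return(panel)
  panel[, -drop]
}

#' Desk-scale simulation preset
#'
#' A small two-chromosome design sized for workstation runs: 3000
#' individuals per sex, 2 x 1000 SNPs at 5 kb mean spacing (10 Mb of
#' genome), 10 causal variants (one per Mb stratum) of which 4 have
#' sex-differing effects, with per-variant variance inflated to 2e-3 so
#' power is estimable at this sample size.
#'
#' @param seed integer seed (genotype seed; the trait seed is derived).
#' @return list with \code{geno} and \code{trait} config lists.
#' @export
deskPreset <- function(seed = 1L) {
  list(
    geno = genoSimConfig(nMale = 3000L, nFemale = 3000L, nChrom = 2L,
      snpsPerChrom = 1000L, meanSpacingBp = 5000, seed = seed),
    trait = traitSimConfig(nCausal = 10L, causalSpacingBp = 1e6,
      perVariantR2 = 2e-3, propGxs = 0.4, seed = seed + 1L))
}

#' Full-scale simulation preset
#'
#' The biobank-scale design: 119,190 males and 139,738 females, 10
#' chromosomes x 6000 SNPs, 150 causal variants (one per ~2 Mb), each
#' explaining 3.3e-4 of phenotypic variance on average, 40% with
#' sex-differing effects. This is a cluster-scale configuration; it is
#' not intended to run on a workstation.
#'
#' @param seed integer seed.
#' @return list with \code{geno} and \code{trait} config lists.
#' @export
paperScalePreset <- function(seed = 1L) {
  list(
    geno = genoSimConfig(nMale = 119190L, nFemale = 139738L, nChrom = 10L,
      snpsPerChrom = 6000L, meanSpacingBp = 5000, seed = seed),
    trait = traitSimConfig(nCausal = 150L, causalSpacingBp = 2e6,
      perVariantR2 = 3.3e-4, propGxs = 0.4, seed = seed + 1L))
}

#' Write a simulated dataset to disk
#'
#' Emits the PLINK triplet, a phenotype TSV (\code{individual_id},
#' \code{phenotype}) and a truth TSV, so the full pipeline can run from
#' files exactly as on real data.
#'
#' @param panel a [GenotypePanel-class].
#' @param y a [ScaledPhenotype-class] (or numeric).
#' @param truth a \code{SimulationTruth} (optional).
#' @param dir output directory (created if needed).
#' @param prefix file name prefix (default \code{"sim"}).
#' @return \code{dir}, invisibly.
#' @export
writeSimulation <- function(panel, y, truth = NULL, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writePlink(panel, file.path(dir, prefix))
  write.table(
    data.frame(individual_id = individualIds(panel),
               phenotype = phenotypeValues(y)),
    file.path(dir, paste0(prefix, "_pheno.tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(truth))
    write.table(truth$table, file.path(dir, paste0(prefix, "_truth.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
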