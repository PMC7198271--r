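#' Compose sex-specific effects from posterior draws
#'
#' Per draw, the male- and female-specific effects of SNP j are
#' \eqn{\beta_{mj} = b_{0j} + b_{mj}} and \eqn{\beta_{fj} = b_{0j} + b_{fj}}.
#' Exact zeros are preserved: a SNP excluded from both the shared and the
#' sex class in a draw has an exactly-zero sex-specific effect.
#'
#' @param samples a [PosteriorSamples-class] (stitched or single segment).
#' @return list with p x D matrices \code{beta_m} and \code{beta_f}.
#' @export
sexSpecificEffects <- function(samples) {
  stopifnot(is(samples, "PosteriorSamples"))
  list(beta_m = samples@b0 + samples@bm, beta_f = samples@b0 + samples@bf)
}

#' SNP-level posterior probabilities
#'
#' Computes, per SNP: the posterior means of the sex-specific effects,
#' the posterior probabilities of a nonzero male effect (PPM) and female
#' effect (PPF), the probability that the two differ (PPDiff, the
#' fraction of draws in which the male and female interaction deviations
#' are not both zero), and PP_any = max(PPM, PPF). All zero/equality
#' tests are exact, relying on the point mass of the spike.
#'
#' @param samples a [PosteriorSamples-class].
#' @return data.frame (one row per SNP): \code{snp_id}, \code{chrom},
#'   \code{bp}, \code{mean_beta_m}, \code{mean_beta_f}, \code{PPM},
#'   \code{PPF}, \code{PPDiff}, \code{PP_any}.
#' @export
snpProbabilities <- function(samples) {
  eff <- sexSpecificEffects(samples)
  data.frame(
    snp_id = samples@snpId, chrom = samples@chrom, bp = samples@bp,
    mean_beta_m = rowMeans(eff$beta_m),
    mean_beta_f = rowMeans(eff$beta_f),
    PPM = rowMeans(eff$beta_m != 0),
    PPF = rowMeans(eff$beta_f != 0),
    PPDiff = rowMeans(samples@bm != samples@bf),
    PP_any = pmax(rowMeans(eff$beta_m != 0), rowMeans(eff$beta_f != 0)),
    stringsAsFactors = FALSE)
}

#' Dosage covariance of one chromosome
#'
#' Sample covariance matrix (denominator n - 1) of pooled-centered
#' dosages for the SNPs of one chromosome. Shared by the LD-window rule
#' and the window-variance quadratic forms.
#' @noRd
chromCovariance <- function(Xc, n) crossprod(Xc) / (n - 1)

#' Define an LD-based window around a focal SNP
#'
#' Extends left and right from the focal SNP, adding contiguous SNPs
#' while their squared Pearson correlation with the focal dosage stays
#' at or above \code{r2Threshold}. Extension stops at the first SNP
#' below threshold (after \code{gapTolerance} consecutive failures), at
#' \code{maxBp} distance from the focal SNP, or at the chromosome end.
#' The window always includes the focal SNP.
#'
#' @param panel imputed [GenotypePanel-class].
#' @param focalJ focal SNP index (1-based, panel-wide).
#' @param r2Threshold squared-correlation threshold (default 0.05).
#' @param maxBp maximum distance from the focal SNP (default 1 Mb).
#' @param gapTolerance consecutive below-threshold SNPs tolerated before
#'   stopping (default 0).
#' @return integer vector \code{c(start, end)} of panel-wide SNP indices
#'   (inclusive).
#' @export
defineWindow <- function(panel, focalJ, r2Threshold = 0.05, maxBp = 1e6,
                         gapTolerance = 0L) {
  d <- dosages(panel)
  if (anyNA(d)) stop("impute missing dosages before defining windows")
  ch <- panel@chrom[focalJ]
  onChrom <- which(panel@chrom == ch)
  x0 <- d[, focalJ]
  v0 <- var(x0)
  if (v0 == 0) {
    warning("focal SNP ", panel@snpId[focalJ], " is monomorphic; window = focal SNP")
    return(c(focalJ, focalJ))
  }
  extend <- function(dirIdx) {
    last <- focalJ
    fails <- 0L
    for (k in dirIdx) {
      if (abs(panel@bp[k] - panel@bp[focalJ]) > maxBp) break
      r2 <- suppressWarnings(cor(x0, d[, k]))^2
      if (is.na(r2)) r2 <- 0
      if (r2 >= r2Threshold) {
        last <- k
        fails <- 0L
      } else {
        fails <- fails + 1L
        if (fails > gapTolerance) break
      }
    }
    last
  }
  left <- extend(rev(onChrom[onChrom < focalJ]))
  right <- extend(onChrom[onChrom > focalJ])
  c(left, right)
}

#' Define LD-based windows for every SNP
#'
#' Vectorised equivalent of [defineWindow()] applied to each focal SNP,
#' using per-chromosome dosage covariance matrices. Windows are
#' heavily overlapping and dynamically sized; they never cross
#' chromosome boundaries.
#'
#' @inheritParams defineWindow
#' @return data.frame with columns \code{focal} (SNP index),
#'   \code{start}, \code{end} (inclusive panel-wide indices).
#' @export
defineWindows <- function(panel, r2Threshold = 0.05, maxBp = 1e6,
                          gapTolerance = 0L) {
  d <- dosages(panel)
  if (anyNA(d)) stop("impute missing dosages before defining windows")
  p <- nSnps(panel)
  n <- nIndividuals(panel)
  start <- integer(p); end <- integer(p)
  for (ch in unique(panel@chrom)) {
    idx <- which(panel@chrom == ch)
    Xc <- sweep(d[, idx, drop = FALSE], 2, colMeans(d[, idx, drop = FALSE]))
    S <- chromCovariance(Xc, n)
    v <- diag(S)
    bp <- panel@bp[idx]
    nCh <- length(idx)
    for (jj in seq_len(nCh)) {
      if (v[jj] == 0) { start[idx[jj]] <- end[idx[jj]] <- idx[jj]; next }
      lo <- jj; fails <- 0L
      for (k in rev(seq_len(jj - 1))) {
        if (bp[jj] - bp[k] > maxBp) break
        r2 <- if (v[k] > 0) S[jj, k]^2 / (v[jj] * v[k]) else 0
        if (r2 >= r2Threshold) { lo <- k; fails <- 0L }
        else { fails <- fails + 1L; if (fails > gapTolerance) break }
      }
      hi <- jj; fails <- 0L
      for (k in seq(jj + 1, length.out = nCh - jj)) {
        if (bp[k] - bp[jj] > maxBp) break
        r2 <- if (v[k] > 0) S[jj, k]^2 / (v[jj] * v[k]) else 0
        if (r2 >= r2Threshold) { hi <- k; fails <- 0L }
        else { fails <- fails + 1L; if (fails > gapTolerance) break }
      }
      start[idx[jj]] <- idx[lo]
      end[idx[jj]] <- idx[hi]
    }
  }
  data.frame(focal = seq_len(p), start = start, end = end)
}

#' Per-draw sex-specific window variances
#'
#' For each stored draw and each window j*, computes
#' \eqn{\sigma^2_{g,j^*} = \mathrm{var}(X_{j^*} \beta_{j^*})}: the sample
#' variance (denominator n - 1) over all individuals of the genetic
#' values formed from pooled-centered dosages restricted to the window.
#' Because the phenotype is unit-scaled, these are proportions of total
#' phenotypic variance. Draws whose window effects are all exactly zero
#' yield exactly zero variance.
#'
#' @param panel imputed [GenotypePanel-class] matching the samples.
#' @param windows data.frame from [defineWindows()].
#' @param samples a [PosteriorSamples-class] aligned with the panel.
#' @return list with p x D matrices \code{var_m} and \code{var_f}.
#' @export
windowVariances <- function(panel, windows, samples) {
  stopifnot(nSnps(panel) == nrow(samples@b0),
            nrow(windows) == nSnps(panel))
  d <- dosages(panel)
  if (anyNA(d)) stop("impute missing dosages first")
  eff <- sexSpecificEffects(samples)
  n <- nIndividuals(panel)
  D <- nDraws(samples)
  p <- nSnps(panel)
  varM <- matrix(0, p, D); varF <- matrix(0, p, D)
  for (ch in unique(panel@chrom)) {
    idx <- which(panel@chrom == ch)
    Xc <- sweep(d[, idx, drop = FALSE], 2, colMeans(d[, idx, drop = FALSE]))
    S <- chromCovariance(Xc, n)
    ws <- windows$start[idx] - idx[1] + 1L
    we <- windows$end[idx] - idx[1] + 1L
    varM[idx, ] <- window_qform_cpp(S, eff$beta_m[idx, , drop = FALSE], ws, we)
    varF[idx, ] <- window_qform_cpp(S, eff$beta_f[idx, , drop = FALSE], ws, we)
  }
  list(var_m = varM, var_f = varF)
}

#' Window-level posterior probabilities
#'
#' Per focal SNP: posterior means of the male and female window
#' variances, the probabilities of a nonzero male (PPMvar) and female
#' (PPFvar) window variance, and PPDiffVar, the probability the two
#' variances differ. The events use the point-mass bookkeeping exactly:
#' a window variance is nonzero in a draw iff some sex-specific effect
#' in the window is nonzero, and the male/female variances differ iff
#' some interaction deviation in the window is nonzero (otherwise
#' \eqn{\beta_m = \beta_f} identically within the window).
#'
#' @inheritParams windowVariances
#' @param variances optional precomputed result of [windowVariances()].
#' @return data.frame per focal SNP: \code{snp_id}, \code{chrom},
#'   \code{bp}, \code{window_start_bp}, \code{window_end_bp},
#'   \code{window_start}, \code{window_end}, \code{mean_var_m},
#'   \code{mean_var_f}, \code{PPMvar}, \code{PPFvar}, \code{PPDiffVar}.
#' @export
windowProbabilities <- function(panel, windows, samples, variances = NULL) {
  if (is.null(variances)) variances <- windowVariances(panel, windows, samples)
  eff <- sexSpecificEffects(samples)
  countIn <- function(M) {
    cs <- apply(M != 0, 2, cumsum)        # p x D cumulative nonzero counts
    cs <- rbind(0, cs)
    cs[windows$end + 1L, , drop = FALSE] - cs[windows$start, , drop = FALSE]
  }
  anyM <- countIn(eff$beta_m) > 0
  anyF <- countIn(eff$beta_f) > 0
  anyInter <- (countIn(samples@bm) + countIn(samples@bf)) > 0
  data.frame(
    snp_id = samples@snpId, chrom = samples@chrom, bp = samples@bp,
    window_start = windows$start, window_end = windows$end,
    window_start_bp = samples@bp[windows$start],
    window_end_bp = samples@bp[windows$end],
    mean_var_m = rowMeans(variances$var_m),
    mean_var_f = rowMeans(variances$var_f),
    PPMvar = rowMeans(anyM),
    PPFvar = rowMeans(anyF),
    PPDiffVar = rowMeans(anyInter),
    stringsAsFactors = FALSE)
}

#' Combined SNP- and window-level summary table
#'
#' Runs [snpProbabilities()], [defineWindows()] and
#' [windowProbabilities()] on a stitched fit and merges them into the
#' standard per-SNP output table.
#'
#' @inheritParams windowVariances
#' @param r2Threshold,maxBp,gapTolerance window rule settings
#'   (see [defineWindow()]).
#' @return data.frame with one row per SNP: SNP map, effect means and
#'   probabilities, window extent and window-variance summaries.
#' @export
lbrSummary <- function(panel, samples, r2Threshold = 0.05, maxBp = 1e6,
                       gapTolerance = 0L) {
  snp <- snpProbabilities(samples)
  win <- defineWindows(panel, r2Threshold, maxBp, gapTolerance)
  wp <- windowProbabilities(panel, win, samples)
  cbind(snp,
        wp[, c("window_start", "window_end", "window_start_bp",
               "window_end_bp", "mean_var_m", "mean_var_f",
               "PPMvar", "PPFvar", "PPDiffVar")])
}

#' Write a summary table as TSV
#'
#' @param summary data.frame from [lbrSummary()] (or any per-SNP table).
#' @param path output path.
#' @export
writeSummaryTsv <- function(summary, path) {
  write.table(summary, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
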