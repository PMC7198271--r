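#' Power and FDR for observed-causal selections
#'
#' A selection is true iff the selected SNP itself belongs to the truth
#' set of the relevant class (GxS variants for sex-difference metrics,
#' any-effect variants for any-effect metrics). Power is the fraction
#' of truth-set members selected; FDR is the fraction of selections not
#' in the truth set (0 when nothing is selected).
#'
#' @param selected character (or integer) ids of selected SNPs.
#' @param truthIds ids of the true class members.
#' @return list with \code{power}, \code{fdr}, \code{nSelected}.
#' @export
powerFdrObserved <- function(selected, truthIds) {
  nSel <- length(selected)
  hits <- sum(selected %in% truthIds)
  list(power = if (length(truthIds)) hits / length(truthIds) else 0,
       fdr = if (nSel) (nSel - hits) / nSel else 0,
       nSelected = nSel)
}

#' Power and FDR at a target-area resolution (masked causal)
#'
#' For masked-causal evaluation a causal variant is "tagged" when at
#' least one selected SNP (or any SNP of a selected window) lies within
#' \code{halfWidthBp} of it. Power is the fraction of truth variants
#' tagged; FDR the fraction of selections tagging none. Two selections
#' tagging the same variant count it once for power, and both count as
#' true selections.
#'
#' @param selStartBp,selEndBp numeric vectors: the bp extent of each
#'   selection (equal for single-SNP selections; window bounds for
#'   window selections). Must come from one chromosome per call or be
#'   paired with \code{selChrom}/\code{truthChrom}.
#' @param selChrom chromosome label per selection.
#' @param truthBp,truthChrom positions of the truth (GxS) variants.
#' @param halfWidthBp half-width of the target area (full areas 1 Mb,
#'   500 kb, 250 kb correspond to 5e5, 2.5e5, 1.25e5).
#' @return list with \code{power}, \code{fdr}, \code{nSelected},
#'   \code{tagged} (logical per truth variant).
#' @export
powerFdrTargetArea <- function(selStartBp, selEndBp, selChrom,
                               truthBp, truthChrom, halfWidthBp) {
  stopifnot(halfWidthBp > 0, length(selStartBp) == length(selEndBp),
            length(selStartBp) == length(selChrom),
            length(truthBp) == length(truthChrom))
  nSel <- length(selStartBp)
  nTruth <- length(truthBp)
  tagged <- logical(nTruth)
  selTrue <- logical(nSel)
  if (nSel && nTruth) {
    for (s in seq_len(nSel)) {
      near <- truthChrom == selChrom[s] &
        truthBp >= selStartBp[s] - halfWidthBp &
        truthBp <= selEndBp[s] + halfWidthBp
      selTrue[s] <- any(near)
      tagged <- tagged | near
    }
  }
  list(power = if (nTruth) sum(tagged) / nTruth else 0,
       fdr = if (nSel) sum(!selTrue) / nSel else 0,
       nSelected = nSel, tagged = tagged)
}

#' Power/FDR curve over selection sizes
#'
#' Ranks items by a metric and evaluates observed-causal power and FDR
#' at each selection size.
#'
#' @param ids item identifiers.
#' @param metric numeric ranking metric.
#' @param truthIds ids of true class members.
#' @param sizes selection sizes to evaluate (default 1..length(ids)).
#' @param decreasing rank direction; \code{TRUE} for posterior
#'   probabilities, \code{FALSE} for p-values.
#' @return data.frame with \code{n_selected}, \code{power}, \code{fdr}.
#' @export
powerFdrCurve <- function(ids, metric, truthIds, sizes = NULL,
                          decreasing = TRUE) {
  ord <- order(metric, decreasing = decreasing)
  ranked <- ids[ord]
  if (is.null(sizes)) sizes <- seq_along(ids)
  hits <- cumsum(ranked %in% truthIds)
  data.frame(
    n_selected = sizes,
    power = hits[sizes] / max(length(truthIds), 1),
    fdr = (sizes - hits[sizes]) / sizes)
}

#' Aggregate per-replicate curves into means and 95% CIs
#'
#' Normal-approximation confidence intervals,
#' \eqn{\bar x \pm 1.96\, s/\sqrt{R}}, across Monte Carlo replicates.
#' With a single replicate the CI columns are \code{NA} and flagged.
#'
#' @param values numeric matrix, replicates x points (or a list of
#'   equal-length numeric vectors, one per replicate).
#' @return data.frame with \code{mean}, \code{lower}, \code{upper},
#'   \code{ciDefined}.
#' @export
mcAggregate <- function(values) {
  if (is.list(values)) values <- do.call(rbind, values)
  values <- as.matrix(values)
  R <- nrow(values)
  m <- colMeans(values)
  if (R < 2)
    return(data.frame(mean = m, lower = NA_real_, upper = NA_real_,
                      ciDefined = FALSE))
  se <- apply(values, 2, sd) / sqrt(R)
  data.frame(mean = m, lower = m - 1.96 * se, upper = m + 1.96 * se,
             ciDefined = TRUE)
}

#' Merge window selections into distinct regions
#'
#' Window selections are deduplicated by merging windows that share any
#' SNP index, yielding a list of distinct, non-overlapping regions.
#'
#' @param start,end integer window bounds (inclusive SNP indices), with
#'   chromosome handled by the caller (indices never cross chromosomes).
#' @return data.frame of merged \code{start}, \code{end} and
#'   \code{n_members}.
#' @export
mergeWindows <- function(start, end) {
  if (!length(start)) return(data.frame(start = integer(0), end = integer(0),
                                        n_members = integer(0)))
  ord <- order(start, end)
  start <- start[ord]; end <- end[ord]
  ms <- start[1]; me <- end[1]; cnt <- 1L
  out <- list()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {         # shares an index with the open region
      me <- max(me, end[i]); cnt <- cnt + 1L
    } else {
      out[[length(out) + 1L]] <- c(ms, me, cnt)
      ms <- start[i]; me <- end[i]; cnt <- 1L
    }
  }
  out[[length(out) + 1L]] <- c(ms, me, cnt)
  out <- do.call(rbind, out)
  data.frame(start = out[, 1], end = out[, 2], n_members = out[, 3])
}

#' Hypergeometric enrichment test
#'
#' Upper-tail hypergeometric probability that the overlap between a
#' selected SNP set and an annotated SNP set is at least as large as
#' observed, given the universe: P(X >= overlap) with population
#' |universe|, successes |annotated|, draws |selected|.
#'
#' @param selected,annotated,universe id vectors;
#'   \code{selected} and \code{annotated} must be subsets of
#'   \code{universe}.
#' @return list with \code{p}, \code{overlap}, \code{nSelected},
#'   \code{nAnnotated}, \code{nUniverse}.
#' @export
hypergeomEnrichment <- function(selected, annotated, universe) {
  selected <- unique(selected); annotated <- unique(annotated)
  universe <- unique(universe)
  if (!all(selected %in% universe))
    stop("selected ids must be a subset of the universe")
  if (!all(annotated %in% universe))
    stop("annotated ids must be a subset of the universe")
  ov <- sum(selected %in% annotated)
  p <- phyper(ov - 1, length(annotated),
              length(universe) - length(annotated),
              length(selected), lower.tail = FALSE)
  list(p = p, overlap = ov, nSelected = length(selected),
       nAnnotated = length(annotated), nUniverse = length(universe))
}

#' Plot power and FDR against the number of selections
#'
#' Base-graphics panel in the style of simulation-benchmark figures:
#' one line per method for power (solid) and FDR (dashed) as a function
#' of selection size.
#'
#' @param curves named list of data.frames from [powerFdrCurve()].
#' @param main plot title.
#' @return invisibly, the input list.
#' @export
plotPowerFdr <- function(curves, main = "Power / FDR vs selections") {
  stopifnot(length(curves) >= 1)
  cols <- seq_along(curves)
  xmax <- max(vapply(curves, function(cv) max(cv$n_selected), 0))
  graphics::plot(NULL, xlim = c(1, xmax), ylim = c(0, 1),
                 xlab = "number selected", ylab = "power (solid) / FDR (dashed)",
                 main = main)
  for (i in cols) {
    graphics::lines(curves[[i]]$n_selected, curves[[i]]$power,
                    col = i, lwd = 2)
    graphics::lines(curves[[i]]$n_selected, curves[[i]]$fdr,
                    col = i, lwd = 2, lty = 2)
  }
  graphics::legend("topright", legend = names(curves), col = cols,
                   lwd = 2, bty = "n")
  invisible(curves)
}

#' Standard thresholded operating points
#'
#' Evaluates the conventional mapping thresholds on an observed-causal
#' simulation: posterior-probability cutoffs for the Bayesian metrics
#' and the genome-wide 5e-8 cutoff for single-marker p-values.
#'
#' @param snpSummary data.frame from [snpProbabilities()].
#' @param smr data.frame from [smrScan()].
#' @param truth a \code{SimulationTruth}.
#' @return data.frame with one row per (metric, threshold) pair:
#'   \code{metric}, \code{threshold}, \code{n_selected}, \code{power},
#'   \code{fdr}.
#' @export
operatingPoints <- function(snpSummary, smr, truth) {
  gxsIds <- truth$table$snp_id[truth$table$gxs]
  anyIds <- truth$table$snp_id[truth$table$beta_m_true != 0 |
                               truth$table$beta_f_true != 0]
  rows <- list(
    c(metric = "PPDiff", thr = 0.95),
    c(metric = "PPDiff", thr = 0.90),
    c(metric = "PP_any", thr = 0.95),
    c(metric = "p_diff", thr = 5e-8),
    c(metric = "p_any", thr = 5e-8))
  out <- lapply(rows, function(r) {
    m <- r[["metric"]]; thr <- as.numeric(r[["thr"]])
    if (m %in% c("PPDiff", "PP_any")) {
      sel <- snpSummary$snp_id[snpSummary[[m]] >= thr]
      ids <- if (m == "PPDiff") gxsIds else anyIds
    } else {
      sel <- smr$snp_id[smr[[m]] <= thr]
      ids <- if (m == "p_diff") gxsIds else anyIds
    }
    pf <- powerFdrObserved(sel, ids)
    data.frame(metric = m, threshold = thr, n_selected = pf$nSelected,
               power = pf$power, fdr = pf$fdr)
  })
  do.call(rbind, out)
}
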