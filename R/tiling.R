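#' Plan core/buffer segments over a panel
#'
#' Divides each chromosome into consecutive core blocks of
#' \code{coreSize} SNPs (the final core takes the remainder) and extends
#' each by \code{bufferSize} SNPs per side, clipped at chromosome ends,
#' to form the fit windows. Cores are disjoint and jointly cover every
#' SNP exactly once; buffers never cross chromosome boundaries. The
#' defaults mirror whole-genome practice where 1500-SNP cores span
#' roughly 8 Mb and 250-SNP buffers roughly 1 Mb, enough to absorb local
#' LD at segment edges.
#'
#' @param panel a [GenotypePanel-class] sorted by (chromosome, bp).
#' @param coreSize,bufferSize segment sizes in SNPs.
#' @return A [SegmentPlan-class].
#' @export
planSegments <- function(panel, coreSize = 1500L, bufferSize = 250L) {
  stopifnot(is(panel, "GenotypePanel"), coreSize >= 1, bufferSize >= 0)
  chrom <- panel@chrom
  if (is.unsorted(match(chrom, unique(chrom))))
    stop("panel chromosomes are not contiguous; sort by (chrom, bp) first")
  for (ch in unique(chrom)) {
    b <- panel@bp[chrom == ch]
    if (length(b) > 1 && any(diff(b) <= 0))
      stop("panel not sorted by bp within chromosome ", ch)
  }
  rows <- list()
  sid <- 0L
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    off <- idx[1] - 1L
    nCh <- length(idx)
    nSeg <- max(1L, ceiling(nCh / coreSize))
    for (s in seq_len(nSeg)) {
      cs <- (s - 1L) * coreSize + 1L
      ce <- min(s * coreSize, nCh)
      fs <- max(1L, cs - bufferSize)
      fe <- min(nCh, ce + bufferSize)
      sid <- sid + 1L
      rows[[sid]] <- data.frame(segment_id = sid, chrom = ch,
        core_start = off + cs, core_end = off + ce + 1L,
        fit_start = off + fs, fit_end = off + fe + 1L,
        stringsAsFactors = FALSE)
    }
  }
  plan <- new("SegmentPlan", table = do.call(rbind, rows))
  stopifnot(sum(plan@table$core_end - plan@table$core_start) == nSnps(panel))
  plan
}

#' Write a segment plan as TSV (bp coordinates)
#'
#' @param plan a [SegmentPlan-class].
#' @param panel the planned [GenotypePanel-class] (for bp lookup).
#' @param path output TSV path.
#' @export
writeSegmentPlan <- function(plan, panel, path) {
  tab <- plan@table
  bp <- panel@bp
  out <- data.frame(segment_id = tab$segment_id, chrom = tab$chrom,
    core_start_bp = bp[tab$core_start], core_end_bp = bp[tab$core_end - 1L],
    fit_start_bp = bp[tab$fit_start], fit_end_bp = bp[tab$fit_end - 1L])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Stitch per-segment posterior samples into a genome-wide set
#'
#' For every SNP the effect samples are taken from the unique segment
#' whose core contains it; buffer copies are discarded. Draw t of every
#' segment is aligned positionally as draw t of the stitched set (the
#' segments are fit independently, so cross-segment dependence beyond
#' the buffer span is negligible). Scalar parameters (intercepts,
#' variances, inclusion proportions) are carried from the first segment
#' as representative chain summaries.
#'
#' @param segmentSamples list of [PosteriorSamples-class], one per plan
#'   row, each fit on the corresponding fit window.
#' @param plan the [SegmentPlan-class] used for fitting.
#' @param panel the planned [GenotypePanel-class].
#' @return A genome-wide [PosteriorSamples-class] with one row per
#'   panel SNP, in panel order.
#' @export
stitchSamples <- function(segmentSamples, plan, panel) {
  tab <- plan@table
  stopifnot(length(segmentSamples) == nrow(tab))
  Ds <- vapply(segmentSamples, nDraws, 0L)
  if (length(unique(Ds)) != 1)
    stop("stored draw counts differ between segments: ",
         paste(unique(Ds), collapse = ", "))
  D <- Ds[1]
  p <- nSnps(panel)
  b0 <- matrix(0, p, D); bm <- matrix(0, p, D); bf <- matrix(0, p, D)
  for (s in seq_len(nrow(tab))) {
    smp <- segmentSamples[[s]]
    core <- seq(tab$core_start[s], tab$core_end[s] - 1L)
    local <- core - tab$fit_start[s] + 1L
    if (nrow(smp@b0) != tab$fit_end[s] - tab$fit_start[s])
      stop("segment ", s, " sample size does not match its fit window")
    b0[core, ] <- smp@b0[local, , drop = FALSE]
    bm[core, ] <- smp@bm[local, , drop = FALSE]
    bf[core, ] <- smp@bf[local, , drop = FALSE]
  }
  first <- segmentSamples[[1]]
  new("PosteriorSamples", b0 = b0, bm = bm, bf = bf,
    muM = first@muM, muF = first@muF,
    sigma2eM = first@sigma2eM, sigma2eF = first@sigma2eF,
    pi = first@pi, sigma2b = first@sigma2b,
    snpId = panel@snpId, chrom = panel@chrom, bp = panel@bp,
    seed = first@seed)
}

#' Derive a deterministic per-segment seed
#'
#' @param seed global integer seed.
#' @param segmentIndex 1-based segment index.
#' @return an integer seed below 2^31.
#' @export
segmentSeed <- function(seed, segmentIndex) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(segmentIndex)) %%
               2147483647)
}

#' Tiled genome-wide fit
#'
#' Plans segments, fits each fit window independently with a
#' deterministically derived per-segment seed, and stitches the core
#' samples into a genome-wide [PosteriorSamples-class]. Results do not
#' depend on the order in which segments are fit.
#'
#' @param panel imputed [GenotypePanel-class] (whole panel).
#' @param y a [ScaledPhenotype-class].
#' @param coreSize,bufferSize tiling sizes in SNPs (see [planSegments()]).
#' @param cfg an [McmcConfig-class]; its seed is the global seed.
#' @param prior optional [LbrPrior-class] shared by all segments; by
#'   default each segment calibrates its own from its SNP content.
#' @param segments optional integer subset of segment ids to fit (for
#'   parallel dispatch); default all.
#' @param verbose print per-segment progress.
#' @return list with elements \code{samples} (stitched
#'   [PosteriorSamples-class]), \code{plan}, and \code{segmentSamples}.
#' @export
fitTiled <- function(panel, y, coreSize = 1500L, bufferSize = 250L,
                     cfg = mcmcConfig(), prior = NULL, segments = NULL,
                     verbose = FALSE) {
  plan <- planSegments(panel, coreSize, bufferSize)
  tab <- plan@table
  ids <- if (is.null(segments)) seq_len(nrow(tab)) else as.integer(segments)
  fits <- vector("list", nrow(tab))
  for (s in ids) {
    idx <- seq(tab$fit_start[s], tab$fit_end[s] - 1L)
    segCfg <- cfg
    segCfg@seed <- segmentSeed(cfg@seed, s)
    if (verbose)
      message(sprintf("segment %d/%d: %d SNPs", s, nrow(tab), length(idx)))
    fits[[s]] <- gibbsFit(panel[, idx], y, prior = prior, cfg = segCfg)
  }
  if (!is.null(segments))
    return(list(samples = NULL, plan = plan, segmentSamples = fits))
  list(samples = stitchSamples(fits, plan, panel), plan = plan,
       segmentSamples = fits)
}
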