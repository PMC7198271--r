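#' Read a PLINK 1 binary genotype triplet
#'
#' Decodes a variant-major PLINK 1 \code{.bed} file together with its
#' \code{.bim} SNP map and \code{.fam} individual table into a
#' [GenotypePanel-class]. Dosages count copies of the BIM A1 allele
#' (PLINK 1 convention): byte codes 00 -> 2, 10 -> 1, 11 -> 0, 01 -> NA.
#' Sex is decoded from FAM column 5 (1 = male, 2 = female).
#'
#' @param bedPath,bimPath,famPath file paths; \code{bimPath}/\code{famPath}
#'   default to \code{bedPath} with the extension swapped.
#' @param dropUnknownSex if \code{TRUE}, individuals whose FAM sex code is
#'   not 1 or 2 are dropped; otherwise such codes are an error.
#' @return A [GenotypePanel-class].
#' @seealso [writePlink()]
#' @export
readPlink <- function(bedPath,
                      bimPath = sub("\\.bed$", ".bim", bedPath),
                      famPath = sub("\\.bed$", ".fam", bedPath),
                      dropUnknownSex = FALSE) {
  for (f in c(bedPath, bimPath, famPath))
    if (!file.exists(f)) stop("file not found: ", f)
  bim <- read.table(bimPath, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chrom", "snp_id", "cm", "bp", "a1", "a2"))
  fam <- read.table(famPath, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("fid", "iid", "pat", "mat", "sex", "pheno"))
  n <- nrow(fam); p <- nrow(bim)
  raw <- readBin(bedPath, what = "raw", n = file.size(bedPath))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK 1 bed file (magic bytes mismatch): ", bedPath)
  if (raw[3] != as.raw(0x01))
    stop("only variant-major (SNP-major) bed files are supported")
  bytesPerSnp <- ceiling(n / 4)
  if (length(raw) - 3L != bytesPerSnp * p)
    stop(sprintf("bed payload size %d does not match n=%d, p=%d",
                 length(raw) - 3L, n, p))
  payload <- raw[-(1:3)]
  # 2-bit fields, first individual in the low bits of each byte
  codeMap <- c(`0` = 2, `1` = NA_real_, `2` = 1, `3` = 0)
  ints <- as.integer(payload)
  twoBit <- rbind(ints %% 4L, (ints %/% 4L) %% 4L,
                  (ints %/% 16L) %% 4L, (ints %/% 64L) %% 4L)
  dim(twoBit) <- c(4L * bytesPerSnp, p)
  dosage <- matrix(codeMap[as.character(twoBit[seq_len(n), , drop = FALSE])],
                   nrow = n, ncol = p)
  sexCode <- fam$sex
  keep <- sexCode %in% c(1L, 2L)
  if (!all(keep)) {
    if (!dropUnknownSex)
      stop(sum(!keep), " individual(s) have unknown sex codes in ", famPath,
           "; use dropUnknownSex = TRUE to drop them")
    dosage <- dosage[keep, , drop = FALSE]
    fam <- fam[keep, , drop = FALSE]
    sexCode <- sexCode[keep]
  }
  genotypePanel(dosage,
    snpId = bim$snp_id, chrom = as.character(bim$chrom), bp = bim$bp,
    individualId = fam$iid,
    sex = ifelse(sexCode == 1L, "male", "female"))
}

#' Write a genotype panel as a PLINK 1 binary triplet
#'
#' Inverse of [readPlink()] for integer dosages: writes variant-major
#' \code{.bed}, \code{.bim} (A1 = "A", A2 = "B" placeholders) and
#' \code{.fam}. Fractional (imputed) dosages cannot be represented and
#' are an error.
#'
#' @param panel a [GenotypePanel-class] with dosages in \{0, 1, 2, NA\}.
#' @param prefix output path prefix; files \code{prefix.bed/.bim/.fam}.
#' @return \code{prefix}, invisibly.
#' @export
writePlink <- function(panel, prefix) {
  d <- dosages(panel)
  if (any(!is.na(d) & !(d %in% c(0, 1, 2))))
    stop("writePlink requires integer dosages in {0, 1, 2, NA}")
  n <- nrow(d); p <- ncol(d)
  # dosage -> 2-bit code: 2 -> 00, NA -> 01, 1 -> 10, 0 -> 11
  code <- matrix(3L, n, p)
  code[d == 2] <- 0L
  code[d == 1] <- 2L
  code[is.na(d)] <- 1L
  bytesPerSnp <- ceiling(n / 4)
  padded <- matrix(0L, 4L * bytesPerSnp, p)
  padded[seq_len(n), ] <- code
  idx <- seq(1L, 4L * bytesPerSnp, by = 4L)
  bytes <- padded[idx, , drop = FALSE] +
    4L * padded[idx + 1L, , drop = FALSE] +
    16L * padded[idx + 2L, , drop = FALSE] +
    64L * padded[idx + 3L, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  close(con)
  m <- snpMap(panel)
  write.table(
    data.frame(m$chrom, m$snp_id, 0, m$bp, "A", "B"),
    paste0(prefix, ".bim"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(
    data.frame(individualIds(panel), individualIds(panel), 0, 0,
               ifelse(sexOf(panel) == "male", 1L, 2L), -9),
    paste0(prefix, ".fam"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a phenotype table and align it to a panel
#'
#' Reads a headered TSV with columns \code{individual_id} and
#' \code{phenotype} and returns the phenotype values in the panel's
#' individual order.
#'
#' @param path TSV path.
#' @param panel a [GenotypePanel-class] providing the individual order.
#' @return numeric vector, one value per panel individual.
#' @export
readPhenotypeTsv <- function(path, panel) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("individual_id", "phenotype") %in% names(tab)))
    stop("phenotype TSV must have columns individual_id, phenotype")
  idx <- match(individualIds(panel), tab$individual_id)
  if (anyNA(idx))
    stop("phenotype TSV is missing ", sum(is.na(idx)), " panel individual(s)")
  as.numeric(tab$phenotype[idx])
}

#' Impute missing dosages by the per-SNP mean
#'
#' Missing entries are replaced by the mean dosage of the SNP computed
#' over non-missing individuals, pooled across sexes; non-missing entries
#' are untouched. Mean imputation preserves each SNP's allele frequency,
#' the usual default in whole-genome regression.
#'
#' @param panel a [GenotypePanel-class].
#' @return A panel with no missing dosages.
#' @export
imputeMissing <- function(panel) {
  d <- dosages(panel)
  miss <- is.na(d)
  if (!any(miss)) return(panel)
  allMiss <- colSums(!miss) == 0
  if (any(allMiss))
    stop("SNP(s) with all dosages missing: ",
         paste(panel@snpId[allMiss], collapse = ", "))
  mu <- colMeans(d, na.rm = TRUE)
  idx <- which(miss, arr.ind = TRUE)
  d[idx] <- mu[idx[, 2]]
  out <- panel
  out@dosages <- d
  out
}

#' Scale a phenotype to unit pooled variance
#'
#' Divides by the pooled (both sexes) sample standard deviation without
#' centering; the model's sex-specific intercepts absorb the means. On
#' the unit scale, window variances read directly as proportions of
#' total phenotypic variance.
#'
#' @param y numeric phenotype vector, or a [ScaledPhenotype-class]
#'   (returned unchanged if already scaled).
#' @return A [ScaledPhenotype-class] with pooled variance 1.
#' @export
scalePhenotype <- function(y) {
  if (is(y, "ScaledPhenotype")) {
    if (y@scaled) return(y)
    y <- y@values
  }
  y <- as.numeric(y)
  if (anyNA(y)) stop("phenotype contains missing values")
  v <- var(y)
  if (!is.finite(v) || v <= 0)
    stop("phenotype is constant; cannot scale to unit variance")
  new("ScaledPhenotype", values = y / sqrt(v), scaled = TRUE)
}
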