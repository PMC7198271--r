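# Sex-specific effects, SNP probabilities, LD windows and window
# variances.

# Hand-built PosteriorSamples with known draws.
makeSamples <- function(b0, bm, bf, bp = NULL, chrom = NULL) {
  p <- nrow(b0); D <- ncol(b0)
  if (is.null(bp)) bp <- as.numeric(seq_len(p)) * 1000
  if (is.null(chrom)) chrom <- rep("1", p)
  new("PosteriorSamples", b0 = b0, bm = bm, bf = bf,
      muM = rep(0, D), muF = rep(0, D),
      sigma2eM = rep(1, D), sigma2eF = rep(1, D),
      pi = matrix(0.5, 3, D), sigma2b = matrix(0.1, 3, D),
      snpId = paste0("s", seq_len(p)), chrom = chrom, bp = bp,
      seed = 1L)
}

test_that("sex-specific effects compose elementwise with exact zeros", {
  s <- makeSamples(b0 = matrix(c(0.2, 0, 0), 3, 1),
                   bm = matrix(c(0, 0.1, 0), 3, 1),
                   bf = matrix(c(-0.05, 0, 0), 3, 1))
  eff <- sexSpecificEffects(s)
  expect_equal(eff$beta_m[, 1], c(0.2, 0.1, 0))
  expect_equal(eff$beta_f[, 1], c(0.15, 0, 0))
  expect_identical(eff$beta_m[3, 1], 0)   # all-zero draw stays exactly zero
})

test_that("SNP probabilities count point-mass events exactly", {
  D <- 10
  b0 <- matrix(0, 2, D); bm <- matrix(0, 2, D); bf <- matrix(0, 2, D)
  b0[1, 1:7] <- 0.3                      # shared effect in 7 of 10 draws
  bm[2, 1:4] <- 0.2                      # male deviation in 4 draws
  s <- makeSamples(b0, bm, bf)
  probs <- snpProbabilities(s)
  # SNP 1: no interactions -> PPDiff 0, PPM = PPF = P(b0 != 0)
  expect_equal(probs$PPDiff[1], 0)
  expect_equal(probs$PPM[1], 0.7)
  expect_equal(probs$PPF[1], 0.7)
  # SNP 2: bm != bf in 4 of 10 draws
  expect_equal(probs$PPDiff[2], 0.4)
  expect_equal(probs$PP_any[2], 0.4)
  # invariant: PPDiff bounded by 1 - P(both interaction classes spiked)
  bothZero <- rowMeans(s@bm == 0 & s@bf == 0)
  expect_true(all(probs$PPDiff <= 1 - bothZero + 1e-12))
})

test_that("LD windows follow the r2-threshold extension rule", {
  set.seed(61)
  n <- 500
  # 5 SNPs in perfect LD, then 3 independent SNPs
  x <- rbinom(n, 2, 0.4)
  d <- cbind(x, x, x, x, x,
             rbinom(n, 2, 0.4), rbinom(n, 2, 0.4), rbinom(n, 2, 0.4))
  panel <- genotypePanel(d, bp = (1:8) * 1e4, chrom = rep("1", 8),
                         sex = rep(c("male", "female"), n / 2))
  # interior focal SNP in the perfect-LD block spans all 5
  expect_equal(defineWindow(panel, 3L), c(1, 5))
  # independent focal SNP keeps only itself
  w7 <- defineWindow(panel, 7L)
  expect_equal(w7, c(7, 7))
  # monomorphic focal SNP: window collapses with a warning
  d2 <- d; d2[, 2] <- 1
  panel2 <- genotypePanel(d2, bp = (1:8) * 1e4, chrom = rep("1", 8),
                          sex = rep(c("male", "female"), n / 2))
  expect_warning(w2 <- defineWindow(panel2, 2L), "monomorphic")
  expect_equal(w2, c(2, 2))
  # defineWindows agrees with the per-SNP routine
  all <- defineWindows(panel)
  expect_equal(unname(unlist(all[3, c("start", "end")])), c(1, 5))
  expect_equal(unname(unlist(all[7, c("start", "end")])), c(7, 7))
})

test_that("window width shrinks as the r2 threshold rises (AR-LD panel)", {
  cfg <- genoSimConfig(nMale = 400, nFemale = 400, nChrom = 1,
                       snpsPerChrom = 120, meanSpacingBp = 2e4, seed = 62)
  panel <- simulateGenotypes(cfg)
  widths <- vapply(c(0.02, 0.1, 0.3, 0.7), function(thr) {
    w <- defineWindows(panel, r2Threshold = thr)
    mean(w$end - w$start + 1)
  }, 0)
  expect_true(all(diff(widths) <= 0))
  expect_gt(widths[1], widths[4])
  # windows never cross the chromosome and always hold their focal SNP
  w <- defineWindows(panel, r2Threshold = 0.05)
  expect_true(all(w$start <= w$focal & w$focal <= w$end))
})

test_that("window variances match the brute-force var(X beta) oracle", {
  set.seed(63)
  n <- 300
  cfg <- genoSimConfig(nMale = 150, nFemale = 150, nChrom = 1,
                       snpsPerChrom = 6, meanSpacingBp = 5e3, seed = 63)
  panel <- simulateGenotypes(cfg)
  d <- dosages(panel)
  D <- 4
  b0 <- matrix(rnorm(6 * D, 0, 0.1), 6, D)
  b0[, 2] <- 0                            # an all-zero draw
  bm <- matrix(0, 6, D); bf <- matrix(0, 6, D)
  bm[2, 3] <- 0.25
  s <- makeSamples(b0, bm, bf, bp = panel@bp)
  win <- data.frame(focal = 1:6, start = c(1, 1, 1, 2, 4, 6),
                    end = c(3, 4, 5, 6, 6, 6))
  v <- windowVariances(panel, win, s)
  eff <- sexSpecificEffects(s)
  Xc <- sweep(d, 2, colMeans(d))
  for (j in 1:6) for (dr in 1:D) {
    idx <- seq(win$start[j], win$end[j])
    expect_equal(v$var_m[j, dr],
                 var(Xc[, idx, drop = FALSE] %*% eff$beta_m[idx, dr])[1],
                 tolerance = 1e-10)
    expect_equal(v$var_f[j, dr],
                 var(Xc[, idx, drop = FALSE] %*% eff$beta_f[idx, dr])[1],
                 tolerance = 1e-10)
  }
  # all-zero draw gives exactly zero variance
  expect_identical(v$var_m[1, 2], 0)
  # single-SNP window closed form: beta^2 * var(dosage)
  expect_equal(v$var_m[6, 1], b0[6, 1]^2 * var(d[, 6]),
               tolerance = 1e-12)
  # draws with no interaction effects give equal variances exactly
  expect_identical(v$var_m[, c(1, 2, 4)], v$var_f[, c(1, 2, 4)])
})

test_that("zero-LD subwindow variances add within numerical tolerance", {
  set.seed(64)
  n <- 400
  # two blocks built from a balanced factorial, so their sample
  # covariance is exactly zero (not just zero in expectation)
  a <- rep(c(0, 1), n / 2)
  b <- rep(c(0, 0, 1, 1), n / 4)
  d <- cbind(a, 2 * a, a, b, 2 * b, b)
  panel <- genotypePanel(d, bp = c(1:3 * 1e3, 1:3 * 1e3 + 5e7),
                         chrom = rep("1", 6),
                         sex = rep(c("male", "female"), n / 2))
  beta <- matrix(rnorm(6, 0, 0.2), 6, 1)
  s <- makeSamples(beta, matrix(0, 6, 1), matrix(0, 6, 1), bp = panel@bp)
  winFull <- data.frame(focal = 1:6, start = rep(1, 6), end = rep(6, 6))
  winA <- data.frame(focal = 1:6, start = rep(1, 6), end = rep(3, 6))
  winB <- data.frame(focal = 1:6, start = rep(4, 6), end = rep(6, 6))
  vF <- windowVariances(panel, winFull, s)$var_m[1, 1]
  vA <- windowVariances(panel, winA, s)$var_m[1, 1]
  vB <- windowVariances(panel, winB, s)$var_m[1, 1]
  expect_lt(abs(vF - (vA + vB)), 1e-10)
})

test_that("window probabilities use point-mass logic", {
  D <- 6
  b0 <- matrix(0.2, 3, D)               # shared effects always in
  bm <- matrix(0, 3, D); bf <- matrix(0, 3, D)
  panel <- makeTinyPanel(n = 200, p = 3, seed = 65)
  s <- makeSamples(b0, bm, bf, bp = panel@bp)
  win <- data.frame(focal = 1:3, start = rep(1, 3), end = rep(3, 3))
  wp <- windowProbabilities(panel, win, s)
  # shared-only: both sexes explain variance, no sex difference
  expect_equal(wp$PPMvar, rep(1, 3))
  expect_equal(wp$PPFvar, rep(1, 3))
  expect_equal(wp$PPDiffVar, rep(0, 3))
  # all-zero draws everywhere -> all probabilities zero
  z <- makeSamples(matrix(0, 3, D), bm, bf, bp = panel@bp)
  wpz <- windowProbabilities(panel, win, z)
  expect_equal(wpz$PPMvar + wpz$PPFvar + wpz$PPDiffVar, rep(0, 3))
  # female-only interaction in one draw
  bf2 <- bf; bf2[2, 1:3] <- 0.4
  s2 <- makeSamples(matrix(0, 3, D), bm, bf2, bp = panel@bp)
  wp2 <- windowProbabilities(panel, win, s2)
  expect_equal(wp2$PPFvar, rep(0.5, 3))
  expect_equal(wp2$PPMvar, rep(0, 3))
  expect_equal(wp2$PPDiffVar, rep(0.5, 3))
  # PPDiffVar bounded by fraction of draws with any interaction in window
  anyInter <- mean(colSums(s2@bm != 0 | s2@bf != 0) > 0)
  expect_true(all(wp2$PPDiffVar <= anyInter + 1e-12))
})

test_that("probabilities from disjoint chain halves agree", {
  sf <- makeSignalFit(seed = 66, n = 900, p = 25, nIter = 1600,
                      burnIn = 400, thin = 2)
  probs <- snpProbabilities(sf$fit)
  D <- nDraws(sf$fit)
  h1 <- seq_len(D / 2); h2 <- seq(D / 2 + 1, D)
  eff <- sexSpecificEffects(sf$fit)
  p1 <- rowMeans(eff$beta_m[, h1] != 0)
  p2 <- rowMeans(eff$beta_m[, h2] != 0)
  se <- sqrt(pmax(probs$PPM * (1 - probs$PPM), 0.25 / D) * 2 / D)
  # allow autocorrelation inflation on top of the binomial SE
  expect_true(all(abs(p1 - p2) <= 3 * pmax(4 * se, 0.08)))
})
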