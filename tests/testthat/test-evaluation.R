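# Power/FDR machinery, target areas, aggregation, enrichment.

test_that("observed-causal power and FDR count correctly", {
  pf <- powerFdrObserved(c("A", "B"), c("A", "C"))
  expect_equal(pf$power, 0.5)
  expect_equal(pf$fdr, 0.5)
  # nothing selected: both zero by convention
  pf0 <- powerFdrObserved(character(0), c("A", "C"))
  expect_equal(pf0$power, 0)
  expect_equal(pf0$fdr, 0)
  # select everything: power 1, FDR = 1 - prevalence
  univ <- paste0("s", 1:20)
  pfAll <- powerFdrObserved(univ, univ[1:4])
  expect_equal(pfAll$power, 1)
  expect_equal(pfAll$fdr, 1 - 4 / 20)
})

test_that("power curves are monotone with FDR in [0, 1]", {
  set.seed(101)
  ids <- paste0("s", 1:200)
  metric <- runif(200)
  truth <- sample(ids, 20)
  curve <- powerFdrCurve(ids, metric, truth)
  expect_true(all(diff(curve$power) >= 0))
  expect_true(all(curve$fdr >= 0 & curve$fdr <= 1))
  expect_true(all(curve$power >= 0 & curve$power <= 1))
  expect_equal(curve$power[200], 1)
})

test_that("target-area tagging follows the distance rule", {
  # selection 300 kb from a GxS variant: tagged at 1 Mb, not at 250 kb
  sel <- list(bp = 1.3e6, chrom = "1")
  truthBp <- 1e6; truthChrom <- "1"
  pf1 <- powerFdrTargetArea(sel$bp, sel$bp, sel$chrom, truthBp, truthChrom,
                            halfWidthBp = 5e5)
  expect_equal(pf1$power, 1)
  expect_equal(pf1$fdr, 0)
  pf2 <- powerFdrTargetArea(sel$bp, sel$bp, sel$chrom, truthBp, truthChrom,
                            halfWidthBp = 1.25e5)
  expect_equal(pf2$power, 0)
  expect_equal(pf2$fdr, 1)
  # two selections tagging the same variant: variant counted once,
  # both selections true
  pf3 <- powerFdrTargetArea(c(0.9e6, 1.1e6), c(0.9e6, 1.1e6), c("1", "1"),
                            truthBp, truthChrom, halfWidthBp = 5e5)
  expect_equal(pf3$power, 1)
  expect_equal(pf3$fdr, 0)
  expect_equal(pf3$nSelected, 2)
})

test_that("interval tagging equals the brute-force all-pairs oracle", {
  set.seed(102)
  for (rep in 1:100) {
    nSel <- sample(0:8, 1)
    nTruth <- sample(1:5, 1)
    selBp <- sort(runif(nSel, 0, 1e7))
    selChrom <- sample(c("1", "2"), nSel, replace = TRUE)
    truthBp <- runif(nTruth, 0, 1e7)
    truthChrom <- sample(c("1", "2"), nTruth, replace = TRUE)
    half <- sample(c(1.25e5, 2.5e5, 5e5), 1)
    got <- powerFdrTargetArea(selBp, selBp, selChrom, truthBp, truthChrom,
                              half)
    # O(n^2) oracle
    tag <- rep(FALSE, nTruth); selT <- rep(FALSE, max(nSel, 0))
    if (nSel > 0) for (s in 1:nSel) for (t in 1:nTruth) {
      if (selChrom[s] == truthChrom[t] &&
          abs(selBp[s] - truthBp[t]) <= half) {
        tag[t] <- TRUE; selT[s] <- TRUE
      }
    }
    expect_equal(got$power, sum(tag) / nTruth)
    expect_equal(got$fdr, if (nSel) sum(!selT) / nSel else 0)
  }
})

test_that("target-area power is monotone in the half-width", {
  set.seed(103)
  selBp <- runif(10, 0, 5e6); selChrom <- rep("1", 10)
  truthBp <- runif(6, 0, 5e6); truthChrom <- rep("1", 6)
  pows <- vapply(c(1.25e5, 2.5e5, 5e5), function(h)
    powerFdrTargetArea(selBp, selBp, selChrom, truthBp, truthChrom,
                       h)$power, 0)
  expect_true(all(diff(pows) >= 0))
})

test_that("MC aggregation matches the hand CI formula", {
  set.seed(104)
  x <- matrix(rnorm(30 * 3, mean = 0.5, sd = 0.1), 30, 3)
  agg <- mcAggregate(x)
  for (k in 1:3) {
    m <- mean(x[, k]); se <- sd(x[, k]) / sqrt(30)
    expect_equal(agg$mean[k], m)
    expect_equal(agg$lower[k], m - 1.96 * se)
    expect_equal(agg$upper[k], m + 1.96 * se)
  }
  # identical replicates: zero-width CI
  same <- matrix(0.4, 5, 2)
  aggS <- mcAggregate(same)
  expect_equal(aggS$lower, aggS$upper)
  # one replicate: mean only, CI flagged undefined
  one <- mcAggregate(matrix(c(0.1, 0.2), 1, 2))
  expect_false(any(one$ciDefined))
  expect_true(all(is.na(one$lower)))
})

test_that("hypergeometric enrichment matches combinatorial enumeration", {
  # worked case: universe 10, annotated 4, selected 3, overlap 2
  univ <- paste0("u", 1:10)
  got <- hypergeomEnrichment(c("u1", "u2", "u5"), paste0("u", 1:4), univ)
  expect_equal(got$p, 40 / 120, tolerance = 1e-12)
  expect_equal(got$overlap, 2)
  # exhaustive check over all small instances: enumeration of C(N, n)
  enumP <- function(N, K, n, k) {
    # P(X >= k) by summing the hypergeometric pmf written with choose()
    s <- 0
    for (x in max(k, 0):min(K, n))
      s <- s + choose(K, x) * choose(N - K, n - x)
    s / choose(N, n)
  }
  set.seed(105)
  for (N in c(5, 8, 12)) {
    u <- paste0("x", seq_len(N))
    for (K in c(0, 2, N %/% 2, N)) for (n in c(0, 1, N %/% 3, N)) {
      ann <- if (K) u[seq_len(K)] else character(0)
      sel <- if (n) sample(u, n) else character(0)
      k <- sum(sel %in% ann)
      got <- hypergeomEnrichment(sel, ann, u)
      expect_equal(got$p, enumP(N, K, n, k), tolerance = 1e-12)
    }
  }
  # degenerate conventions
  expect_equal(hypergeomEnrichment(character(0), character(0), univ)$p, 1)
  expect_equal(hypergeomEnrichment(univ, paste0("u", 1:4), univ)$p, 1)
  expect_error(hypergeomEnrichment("zz", "u1", univ), "subset")
})

test_that("overlapping window selections merge into distinct regions", {
  m <- mergeWindows(c(1, 5, 20, 22), c(6, 10, 25, 30))
  expect_equal(m$start, c(1, 20))
  expect_equal(m$end, c(10, 30))
  expect_equal(m$n_members, c(2, 2))
  # disjoint windows stay separate
  m2 <- mergeWindows(c(1, 10), c(5, 12))
  expect_equal(nrow(m2), 2)
  expect_equal(nrow(mergeWindows(integer(0), integer(0))), 0)
})
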