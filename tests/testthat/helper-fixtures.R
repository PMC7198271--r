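# Shared fixture builders and independent oracles.

# Independent-SNP panel with binomial dosages (no LD).
makeTinyPanel <- function(n = 200, p = 10, maf = 0.3, seed = 1,
                          nChrom = 1) {
  set.seed(seed)
  d <- matrix(rbinom(n * p, 2, maf), n, p)
  perChrom <- ceiling(p / nChrom)
  chrom <- as.character(rep(seq_len(nChrom), each = perChrom)[seq_len(p)])
  bp <- unlist(lapply(split(seq_len(p), chrom), seq_along))[order(order(chrom))]
  bp <- as.numeric(ave(seq_len(p), chrom, FUN = seq_along)) * 1000
  genotypePanel(d, chrom = chrom, bp = bp,
                sex = rep(c("male", "female"), length.out = n))
}

# Closed-form posterior mean of the stacked effect vector (b0, bm, bf)
# under the conjugate limit: all effects included (pi = 1), slab and
# residual variances fixed, intercepts fixed at 0. Solves
# (Z' W Z + D)^{-1} Z' W y by direct linear algebra.
ridgeOracle <- function(panel, y, s2b, s2e) {
  d <- dosages(panel)
  Xc <- sweep(d, 2, colMeans(d))
  male <- sexOf(panel) == "male"
  n <- nrow(Xc); p <- ncol(Xc)
  Zm <- Xc; Zm[!male, ] <- 0
  Zf <- Xc; Zf[male, ] <- 0
  Z <- cbind(Xc, Zm, Zf)
  w <- ifelse(male, 1 / s2e[1], 1 / s2e[2])
  Dmat <- diag(rep(1 / s2b, each = p))
  A <- crossprod(Z * w, Z) + Dmat
  rhs <- crossprod(Z * w, y)
  drop(solve(A, rhs))
}

# Brute-force posterior inclusion probabilities for a p-SNP panel by
# enumerating all 2^(3p) indicator configurations; effects integrated
# out in closed form (Gaussian marginal likelihood), pi / slab /
# residual variances / intercepts fixed. Returns a 3 x p matrix of
# P(include) for classes 0, m, f.
enumOracle <- function(panel, y, piK, s2b, s2e) {
  d <- dosages(panel)
  Xc <- sweep(d, 2, colMeans(d))
  male <- sexOf(panel) == "male"
  n <- nrow(Xc); p <- ncol(Xc)
  stopifnot(p <= 3)
  Rdiag <- ifelse(male, s2e[1], s2e[2])
  cols <- list()
  meta <- list()
  for (k in 1:3) for (j in 1:p) {
    z <- Xc[, j]
    if (k == 2) z[!male] <- 0
    if (k == 3) z[male] <- 0
    cols[[length(cols) + 1L]] <- z
    meta[[length(meta) + 1L]] <- c(k, j)
  }
  q <- length(cols)
  configs <- as.matrix(expand.grid(rep(list(0:1), q)))
  logw <- numeric(nrow(configs))
  for (i in seq_len(nrow(configs))) {
    g <- configs[i, ]
    Sigma <- diag(Rdiag)
    for (u in which(g == 1)) {
      k <- meta[[u]][1]
      Sigma <- Sigma + s2b[k] * tcrossprod(cols[[u]])
    }
    ch <- chol(Sigma)
    quad <- sum(backsolve(ch, y, transpose = TRUE)^2)
    loglik <- -sum(log(diag(ch))) - 0.5 * quad - 0.5 * n * log(2 * pi)
    pk <- vapply(meta, function(m) piK[m[1]], 0)
    logprior <- sum(ifelse(g == 1, log(pk), log1p(-pk)))
    logw[i] <- loglik + logprior
  }
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  probs <- matrix(0, 3, p)
  for (u in seq_len(q)) {
    k <- meta[[u]][1]; j <- meta[[u]][2]
    probs[k, j] <- sum(w[configs[, u] == 1])
  }
  probs
}

# Small simulated dataset with one strong male-only and one strong
# shared causal SNP, used across posterior-inference tests.
makeSignalFit <- function(seed = 11, n = 1200, p = 40, nIter = 900,
                          burnIn = 300, thin = 2) {
  panel <- makeTinyPanel(n = n, p = p, seed = seed)
  male <- sexOf(panel) == "male"
  d <- dosages(panel)
  set.seed(seed + 1)
  maleSnp <- min(20L, p)
  y <- 0.3 * d[, 5] + ifelse(male, 0.4 * d[, maleSnp], 0) + rnorm(n)
  yS <- scalePhenotype(y)
  fit <- gibbsFit(panel, yS, cfg = mcmcConfig(nIter = nIter, burnIn = burnIn,
                                              thin = thin, seed = seed))
  list(panel = panel, y = yS, fit = fit, male = male,
       sharedSnp = 5L, maleSnp = maleSnp)
}
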