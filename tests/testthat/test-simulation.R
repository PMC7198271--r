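# Genotype and trait simulators.

test_that("genotype generator is deterministic and respects its config", {
  cfg <- genoSimConfig(nMale = 150, nFemale = 100, nChrom = 2,
                       snpsPerChrom = 50, seed = 81)
  p1 <- simulateGenotypes(cfg)
  p2 <- simulateGenotypes(cfg)
  expect_identical(dosages(p1), dosages(p2))
  expect_equal(nIndividuals(p1), 250)
  expect_equal(nSnps(p1), 100)
  expect_equal(sum(sexOf(p1) == "male"), 150)
  expect_true(all(dosages(p1) %in% 0:2))
  m <- snpMap(p1)
  for (ch in unique(m$chrom))
    expect_true(all(diff(m$bp[m$chrom == ch]) > 0))
})

test_that("LD decays with distance and vanishes by ldDecayBp", {
  cfg <- genoSimConfig(nMale = 1000, nFemale = 1000, nChrom = 1,
                       snpsPerChrom = 400, meanSpacingBp = 2e4,
                       ldDecayBp = 1.5e6, seed = 82)
  panel <- simulateGenotypes(cfg)
  d <- dosages(panel)
  bp <- snpMap(panel)$bp
  # R^2 against SNP 200 at increasing distances
  focal <- 200
  r2 <- cor(d[, focal], d)^2
  dist <- abs(bp - bp[focal])
  near <- dist > 0 & dist < 1e5
  far <- dist > 1.5e6
  expect_gt(mean(r2[near]), 0.2)
  expect_lt(mean(r2[far]), 0.01)
  # binned decay is monotone from near to far
  bins <- cut(dist[dist > 0], c(0, 2e5, 6e5, 1.2e6, Inf))
  bmeans <- tapply(r2[dist > 0], bins, mean)
  expect_true(all(diff(bmeans) < 0))
})

test_that("allele frequencies hit their targets and sexes are exchangeable", {
  cfg <- genoSimConfig(nMale = 1000, nFemale = 1000, nChrom = 1,
                       snpsPerChrom = 150, seed = 83)
  panel <- simulateGenotypes(cfg)
  d <- dosages(panel)
  n <- nrow(d)
  freq <- colMeans(d) / 2
  expect_true(all(freq > 0.01 & freq < 0.6))
  # per-SNP male-female frequency differences within sampling error
  male <- sexOf(panel) == "male"
  fm <- colMeans(d[male, ]) / 2
  ff <- colMeans(d[!male, ]) / 2
  se <- sqrt(freq * (1 - freq) * (1 / sum(male) + 1 / sum(!male)) / 2)
  expect_lt(mean(abs(fm - ff) > 4 * se), 0.02)
  # SNPs on different chromosomes are uncorrelated at the 1/n level
  cfg2 <- genoSimConfig(nMale = 1000, nFemale = 1000, nChrom = 2,
                        snpsPerChrom = 40, seed = 84)
  p2 <- simulateGenotypes(cfg2)
  d2 <- dosages(p2)
  r2cross <- cor(d2[, 1:40], d2[, 41:80])^2
  expect_lt(mean(r2cross), 3 / n)
})

test_that("trait realizes the target per-variant variance fractions", {
  cfg <- genoSimConfig(nMale = 800, nFemale = 800, nChrom = 2,
                       snpsPerChrom = 300, meanSpacingBp = 2e4, seed = 85)
  panel <- simulateGenotypes(cfg)
  tcfg <- traitSimConfig(nCausal = 5, causalSpacingBp = 1e6,
                         perVariantR2 = 2e-3, propGxs = 0.4, seed = 86)
  sim <- simulateTrait(panel, tcfg)
  tt <- sim$truth$table
  expect_equal(nrow(tt), 5)
  expect_equal(sum(tt$gxs), 2)           # round(0.4 * 5)
  expect_true(all(tt$gxs == (tt$beta_m_true != tt$beta_f_true)))
  # mean realized fraction near target (20% relative MC tolerance)
  expect_lt(abs(mean(tt$realized_r2) - 2e-3) / 2e-3, 0.2)
  # total genetic variance fraction approx nCausal * perVariantR2
  expect_lt(abs(sim$truth$varG - 5 * 2e-3) / (5 * 2e-3), 0.35)
  # variance ledger: genetic + residual = total, exactly
  expect_lt(abs(sim$truth$varG + sim$truth$varE - sim$truth$varY), 1e-6)
  # phenotype comes back scaled
  expect_true(sim$y@scaled)
  # determinism
  sim2 <- simulateTrait(panel, tcfg)
  expect_identical(phenotypeValues(sim$y), phenotypeValues(sim2$y))
})

test_that("propGxs = 0 gives identical per-sex effects", {
  cfg <- genoSimConfig(nMale = 300, nFemale = 300, nChrom = 1,
                       snpsPerChrom = 200, meanSpacingBp = 2e4, seed = 87)
  panel <- simulateGenotypes(cfg)
  sim <- simulateTrait(panel, traitSimConfig(nCausal = 4,
    causalSpacingBp = 1e6, perVariantR2 = 1e-3, propGxs = 0, seed = 88))
  tt <- sim$truth$table
  expect_identical(tt$beta_m_true, tt$beta_f_true)
  expect_false(any(tt$gxs))
})

test_that("masking removes causal columns and is idempotent", {
  cfg <- genoSimConfig(nMale = 200, nFemale = 200, nChrom = 1,
                       snpsPerChrom = 100, meanSpacingBp = 5e4, seed = 89)
  panel <- simulateGenotypes(cfg)
  sim <- simulateTrait(panel, traitSimConfig(nCausal = 5,
    causalSpacingBp = 1e6, perVariantR2 = 1e-3, seed = 90))
  masked <- maskCausal(panel, sim$truth)
  expect_equal(nSnps(masked), 95)
  expect_false(any(sim$truth$table$snp_id %in% masked@snpId))
  # truth keeps original positions
  expect_true(all(sim$truth$table$bp %in% panel@bp))
  # idempotent and non-causal dosages untouched
  masked2 <- maskCausal(masked, sim$truth)
  expect_identical(dosages(masked2), dosages(masked))
  keep <- !(panel@snpId %in% sim$truth$table$snp_id)
  expect_identical(dosages(masked), dosages(panel)[, keep])
})

test_that("a panel with too few strata refuses the causal count", {
  cfg <- genoSimConfig(nMale = 100, nFemale = 100, nChrom = 1,
                       snpsPerChrom = 20, meanSpacingBp = 1e3, seed = 91)
  panel <- simulateGenotypes(cfg)
  expect_error(simulateTrait(panel, traitSimConfig(nCausal = 10,
    causalSpacingBp = 2e6, perVariantR2 = 1e-4, seed = 92)), "strata")
})

test_that("simulation round-trips through PLINK and TSV files", {
  dir <- withr::local_tempdir()
  cfg <- genoSimConfig(nMale = 60, nFemale = 60, nChrom = 1,
                       snpsPerChrom = 40, meanSpacingBp = 5e4, seed = 93)
  panel <- simulateGenotypes(cfg)
  sim <- simulateTrait(panel, traitSimConfig(nCausal = 2,
    causalSpacingBp = 1e6, perVariantR2 = 1e-3, seed = 94))
  writeSimulation(panel, sim$y, sim$truth, dir)
  back <- readPlink(file.path(dir, "sim.bed"))
  expect_identical(dosages(back), dosages(panel), ignore_attr = TRUE)
  y <- readPhenotypeTsv(file.path(dir, "sim_pheno.tsv"), back)
  expect_equal(y, phenotypeValues(sim$y), tolerance = 1e-6)
})
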