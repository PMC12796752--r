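test_that("simulated genotypes match their allele-frequency and HWE regime", {
  cfg <- SimulationConfig(nCases = 50L, nControls = 2000L, nSnps = 10L,
                          nBlocks = 10L, mafRange = c(0.5, 0.5),
                          blockLdRho = 0, nBiomarkers = 2L, nFactors = 1L,
                          factorLoadings = matrix(0, 2, 1),
                          missingRate = 0, seed = 1L)
  g <- simulateGenotypes(cfg, "control")
  d <- dosages(g)
  expect_true(all(d %in% c(0, 1, 2)))
  # central 99% binomial interval for p = 0.5, 4000 alleles
  counts <- colSums(d)
  bounds <- qbinom(c(0.005, 0.995), size = 4000, prob = 0.5)
  inside <- counts >= bounds[1] & counts <= bounds[2]
  expect_gte(sum(inside), 9L)
  # HWE consistency under rho = 0, no missingness
  pvals <- hweTest(colSums(d == 0), colSums(d == 1), colSums(d == 2))
  expect_true(all(pvals > 1e-9))
})

test_that("HWE holds across many null SNPs at the QC alpha", {
  cfg <- nullConfig(seed = 3L, n = 400L, nSnps = 1000L, nBlocks = 1000L)
  d <- dosages(simulateGenotypes(cfg, "control"))
  p <- hweTest(colSums(d == 0), colSums(d == 1), colSums(d == 2))
  expect_lte(sum(p < 1e-9), 1L)
})

test_that("degenerate missingness and determinism behave as configured", {
  cfg <- nullConfig(seed = 2L, n = 100L, nSnps = 5L, nBlocks = 5L,
                    missingRate = 1)
  expect_true(all(is.na(dosages(simulateGenotypes(cfg, "control")))))
  cfg2 <- nullConfig(seed = 5L, n = 200L, nSnps = 8L, nBlocks = 2L,
                     missingRate = 0.1)
  expect_identical(simulateGenotypes(cfg2, "control"),
                   simulateGenotypes(cfg2, "control"))
  expect_identical(simulateConfounders(cfg2, "case"),
                   simulateConfounders(cfg2, "case"))
  expect_false(identical(dosages(simulateGenotypes(cfg2, "case")),
                         dosages(simulateGenotypes(cfg2, "control"))[1:50, ]))
})

test_that("within-block LD follows the copula construction", {
  cfg <- SimulationConfig(nCases = 50L, nControls = 5000L, nSnps = 4L,
                          nBlocks = 2L, mafRange = c(0.3, 0.3),
                          blockLdRho = 0.9, nBiomarkers = 2L, nFactors = 1L,
                          factorLoadings = matrix(0, 2, 1),
                          missingRate = 0, seed = 4L)
  d <- dosages(simulateGenotypes(cfg, "control"))
  blocks <- snpInfo(simulateGenotypes(cfg, "control"))$block
  sameBlock <- cor(d[, 1], d[, 2])
  crossBlock <- cor(d[, 2], d[, 3])
  expect_gt(sameBlock, 0.5)
  expect_lt(abs(crossBlock), 0.1)
  # direct bivariate-normal threshold oracle for the allele-indicator
  # correlation implied by latent rho = 0.9 at maf = 0.3
  set.seed(99)
  z1 <- rnorm(2e5)
  z2 <- sqrt(0.9) * z1 + sqrt(0.1) * rnorm(2e5)
  oracle <- cor(z1 < qnorm(0.3), z2 < qnorm(0.3))
  expect_lt(abs(sameBlock - oracle), 0.1)
})

test_that("confounders have the documented shape and coding", {
  cfg <- nullConfig(seed = 1L)
  cf <- simulateConfounders(cfg, "case")
  expect_equal(nrow(cf), 50L)
  expect_gte(ncol(cf), 2L)
  expect_true(all(cf$sex %in% c(0, 1)))
  for (fl in grep("^flag", names(cf), value = TRUE))
    expect_true(all(cf[[fl]] %in% c(0, 1)))
})

test_that("structureless panels are uncorrelated and planted effects recover", {
  cfg <- SimulationConfig(nCases = 50L, nControls = 5000L, nSnps = 3L,
                          nBlocks = 3L, nBiomarkers = 4L, nFactors = 1L,
                          factorLoadings = matrix(0, 4, 1),
                          confounderEffects = matrix(0, 4, 4),
                          missingRate = 0, seed = 6L)
  co <- simulateCohort(cfg, "control")
  r <- cor(biomarkerValues(co@biomarkers))
  expect_lt(max(abs(r[upper.tri(r)])), 0.1)

  # OLS recovers a planted beta inside its 95% CI at nominal coverage
  hits <- 0L
  for (s in 1:100) {
    cfgS <- SimulationConfig(nCases = 50L, nControls = 1000L, nSnps = 3L,
                             nBlocks = 3L, nBiomarkers = 2L, nFactors = 1L,
                             factorLoadings = matrix(0, 2, 1),
                             confounderEffects = matrix(0, 2, 4),
                             plantedEffects = plantedEffect(2L, 1L, 0.5),
                             missingRate = 0, seed = 1000L + s)
    coS <- simulateCohort(cfgS, "control")
    fit <- summary(lm(biomarkerValues(coS@biomarkers)[, 1] ~
                        dosages(coS@genotypes)[, 2]))$coefficients
    ci <- fit[2, 1] + c(-1, 1) * qt(0.975, 998) * fit[2, 2]
    if (ci[1] <= 0.5 && 0.5 <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})

test_that("duplicate biomarker pairs exceed the correlation exclusion bound", {
  cfg <- demoConfig(seed = 2L)
  co <- simulateCohort(cfg, "control")
  v <- biomarkerValues(co@biomarkers)
  expect_gt(cor(v[, 11], v[, 12]), 0.9)
})

test_that("cohort files round-trip and the truth file is complete", {
  cfg <- demoConfig(seed = 3L, nCases = 60L, nControls = 120L)
  co <- simulateCohort(cfg, "case")
  dir <- withr::local_tempdir()
  writeCohort(co, dir)
  rt <- readCohort(dir)
  expect_identical(unname(dosages(rt$genotypes)),
                   unname(dosages(co@genotypes)))
  expect_lt(max(abs(biomarkerValues(rt$biomarkers) -
                    biomarkerValues(co@biomarkers))), 1e-12)
  expect_identical(snpInfo(rt$genotypes)$block, snpInfo(co@genotypes)$block)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(nrow(truth$plantedEffects), 10L)
  expect_setequal(names(truth$plantedEffects),
                  c("snp", "biomarker", "betaCases", "betaControls"))
  # blocks.bed: 0-based half-open, non-overlapping, covers every SNP
  bed <- read.table(file.path(dir, "blocks.bed"), sep = "\t")
  bed <- bed[order(bed[[2]]), ]
  expect_true(all(bed[[3]] > bed[[2]]))
  expect_true(all(bed[[2]][-1] >= head(bed[[3]], -1)))
  assigned <- assignBlocks(snpInfo(co@genotypes)$chrom,
                           snpInfo(co@genotypes)$pos, rt$blocks)
  expect_identical(assigned, snpInfo(co@genotypes)$block)
})

test_that("invalid configurations are rejected", {
  expect_error(SimulationConfig(mafRange = c(0, 0.5)), "mafRange")
  expect_error(SimulationConfig(mafRange = c(0.1, 0.6)), "mafRange")
  expect_error(SimulationConfig(nSnps = 5L, nBlocks = 6L), "nBlocks")
  expect_error(SimulationConfig(missingRate = 1.2), "missingRate")
  expect_error(SimulationConfig(nSnps = 10L, nBlocks = 2L,
                                plantedEffects = plantedEffect(11L, 1L, 0.3)),
               "out of range")
})
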