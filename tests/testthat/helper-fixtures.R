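# Small fixtures built in code, shared across test files.

# A tiny null simulation config (no planted effects, no factor structure).
nullConfig <- function(seed = 1L, n = 500L, nSnps = 20L, nBiomarkers = 3L,
                       nBlocks = 4L, missingRate = 0, rho = 0) {
  SimulationConfig(nCases = 50L, nControls = n, nSnps = nSnps,
                   nBlocks = nBlocks, nBiomarkers = nBiomarkers,
                   nFactors = 1L,
                   factorLoadings = matrix(0, nBiomarkers, 1L),
                   confounderEffects = matrix(0, nBiomarkers, 4L),
                   blockLdRho = rho, missingRate = missingRate, seed = seed)
}

# Two columns with an exact sample correlation r, built by orthogonalizing
# noise against x and rescaling.
exactCorPair <- function(n, r, seed = 1L) {
  set.seed(seed)
  x <- scale(rnorm(n))[, 1L]
  z <- rnorm(n)
  z <- scale(residuals(lm(z ~ x)))[, 1L]
  y <- r * x + sqrt(1 - r^2) * z
  cbind(x = x, y = y)
}

# Association table with given z-scores for one biomarker (se constant).
zRecords <- function(z, se = 0.05, biomarker = "bm1",
                     ids = sprintf("snp%03d", seq_along(z))) {
  beta <- z * se
  data.frame(snp_id = ids, chrom = "chr1",
             pos = 100 * seq_along(z), biomarker = biomarker,
             method = "CMS", beta = beta, se = se,
             p = 2 * pnorm(-abs(z)), n = 1000L, covariates = "",
             stringsAsFactors = FALSE)
}

# Summary statistics with two disjoint biomarker clusters driven by two
# disjoint variant sets (plus weak noise elsewhere): the planted structure
# a 2-component decomposition must recover. The clusters hold different
# numbers of biomarkers so the two singular values are well separated
# (row standardization equalizes per-row strength, and equal cluster sizes
# would make the leading pair degenerate up to rotation).
twoClusterRecords <- function(nVarPerCluster = 15L, nBmPerCluster = c(8L, 4L),
                              zSignal = 8, seed = 1L) {
  set.seed(seed)
  bms <- sprintf("bm%02d", seq_len(sum(nBmPerCluster)))
  snps <- sprintf("snp%03d", seq_len(2L * nVarPerCluster))
  bmCluster <- rep(1:2, nBmPerCluster)
  varCluster <- rep(1:2, each = nVarPerCluster)
  varSign <- sample(c(-1, 1), length(snps), replace = TRUE)
  rows <- list()
  for (i in seq_along(bms)) {
    for (j in seq_along(snps)) {
      z <- if (bmCluster[i] == varCluster[j])
        zSignal * runif(1, 0.7, 1.3) * varSign[j] else
        rnorm(1, 0, 0.2)
      se <- 0.04
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = snps[j], chrom = "chr1", pos = 50 * j, biomarker = bms[i],
        method = "CMS", beta = z * se, se = se, p = 2 * pnorm(-abs(z)),
        n = 2000L, covariates = "", stringsAsFactors = FALSE)
    }
  }
  list(records = do.call(rbind, rows), bmCluster = bmCluster,
       varCluster = varCluster, bms = bms, snps = snps)
}

# Exact mid-p multinomial HWE oracle: enumerate all genotype tables of
# total n under multinomial sampling at the observed allele frequency;
# each table is scored with its own re-estimated frequency (the same
# statistic hweTest uses); p = P(chi2 > obs) + 0.5 P(chi2 = obs).
hweChiStat <- function(a, b, c) {
  n <- a + b + c
  q <- (2 * c + b) / (2 * n)
  p <- 1 - q
  if (q == 0 || q == 1) return(0)
  e <- c(n * p^2, 2 * n * p * q, n * q^2)
  sum((c(a, b, c) - e)^2 / e)
}

hweExactOracle <- function(a, b, c) {
  n <- a + b + c
  q <- (2 * c + b) / (2 * n)
  p <- 1 - q
  probs <- c(p^2, 2 * p * q, q^2)
  s0 <- hweChiStat(a, b, c)
  above <- 0
  equal <- 0
  for (x in 0:n) for (y in 0:(n - x)) {
    z <- n - x - y
    s <- hweChiStat(x, y, z)
    pr <- dmultinom(c(x, y, z), prob = probs)
    if (s > s0 + 1e-9) above <- above + pr
    else if (s > s0 - 1e-9) equal <- equal + pr
  }
  above + 0.5 * equal
}
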