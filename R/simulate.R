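#' Construct a simulation configuration
#'
#' Defaults describe the study design emulated throughout the package: a
#' small case cohort against a very large control cohort (875 vs 36,033
#' individuals), biallelic SNPs in Hardy-Weinberg proportions with
#' block-structured LD, and a correlated biomarker panel driven by shared
#' latent factors (lipoprotein-subclass style redundancy). Tests and the
#' worked examples use \code{demoConfig()}, a scaled-down preset.
#'
#' @param nCases,nControls cohort sizes.
#' @param nSnps,nBlocks SNP and LD-block counts; blocks are contiguous runs.
#' @param mafRange minor-allele-frequency bounds in (0, 0.5].
#' @param blockLdRho within-block latent (copula) correlation in [0, 1).
#' @param nBiomarkers,nFactors panel size and latent factor count.
#' @param factorLoadings nBiomarkers x nFactors matrix; \code{NULL} builds a
#'   block-diagonal default with loading 0.7, grouping biomarkers into
#'   contiguous factor groups.
#' @param noiseSd residual biomarker noise SD.
#' @param duplicatePairs list of length-2 index vectors forced to r > 0.9.
#' @param plantedEffects data.frame from \code{plantedEffect()} rows.
#' @param confounderEffects nBiomarkers x nConfounders matrix; \code{NULL}
#'   gives modest default effects (0.1 age-like, 0.2 sex-like, 0.1 flags).
#' @param nExtraFlags extra binary comorbidity-like confounders.
#' @param missingRate genotype missingness probability.
#' @param caseMaf optional per-SNP MAF override for the case cohort.
#' @param seed root seed for every stream of the generator.
#' @return A \linkS4class{SimulationConfig}.
#' @export
SimulationConfig <- function(nCases = 875L, nControls = 36033L,
                             nSnps = 300L, nBlocks = 30L,
                             mafRange = c(0.05, 0.45), blockLdRho = 0.5,
                             nBiomarkers = 12L, nFactors = 2L,
                             factorLoadings = NULL, noiseSd = 1,
                             duplicatePairs = list(),
                             plantedEffects = NULL,
                             confounderEffects = NULL, nExtraFlags = 2L,
                             missingRate = 0.02, caseMaf = numeric(0),
                             seed = 1L) {
  nBiomarkers <- .assertCount(nBiomarkers, "nBiomarkers")
  nFactors <- .assertCount(nFactors, "nFactors")
  nExtraFlags <- .assertCount(nExtraFlags, "nExtraFlags", min = 0L)
  if (is.null(factorLoadings)) {
    factorLoadings <- matrix(0, nBiomarkers, nFactors)
    grp <- ceiling(seq_len(nBiomarkers) / ceiling(nBiomarkers / nFactors))
    factorLoadings[cbind(seq_len(nBiomarkers), grp)] <- 0.7
  }
  nConf <- 2L + nExtraFlags
  if (is.null(confounderEffects))
    confounderEffects <- matrix(rep(c(0.1, 0.2, rep(0.1, nExtraFlags)),
                                    each = nBiomarkers),
                                nBiomarkers, nConf)
  if (is.null(plantedEffects))
    plantedEffects <- data.frame(snp = integer(0), biomarker = integer(0),
                                 betaCases = numeric(0),
                                 betaControls = numeric(0))
  new("SimulationConfig",
      nCases = .assertCount(nCases, "nCases"),
      nControls = .assertCount(nControls, "nControls"),
      nSnps = .assertCount(nSnps, "nSnps"),
      nBlocks = .assertCount(nBlocks, "nBlocks"),
      mafRange = as.numeric(mafRange), blockLdRho = as.numeric(blockLdRho),
      nBiomarkers = nBiomarkers, nFactors = nFactors,
      factorLoadings = factorLoadings, noiseSd = as.numeric(noiseSd),
      duplicatePairs = duplicatePairs, plantedEffects = plantedEffects,
      confounderEffects = confounderEffects, nExtraFlags = nExtraFlags,
      missingRate = as.numeric(missingRate), caseMaf = as.numeric(caseMaf),
      seed = as.integer(seed))
}

#' One planted SNP-to-biomarker effect
#'
#' @param snp,biomarker 1-based indices into the simulated SNPs/biomarkers.
#' @param betaCases,betaControls per-cohort true effects (standardized-trait
#'   units per minor-allele dosage unit); unequal values create true
#'   cross-cohort heterogeneity.
#' @return One-row data.frame suitable for rbind-ing into
#'   \code{plantedEffects}.
#' @export
plantedEffect <- function(snp, biomarker, betaCases, betaControls = betaCases) {
  data.frame(snp = as.integer(snp), biomarker = as.integer(biomarker),
             betaCases = as.numeric(betaCases),
             betaControls = as.numeric(betaControls))
}

#' Demo-scale simulation preset
#'
#' A scaled-down two-cohort design (200 cases / 2000 controls, 300 SNPs in
#' 30 blocks, 12 biomarkers on 2 shared factors, one near-duplicate pair,
#' 10 planted effects) that exercises every pipeline stage in seconds.
#'
#' @param seed root seed.
#' @param nCases,nControls cohort sizes of the preset.
#' @return A \linkS4class{SimulationConfig}.
#' @export
demoConfig <- function(seed = 1L, nCases = 200L, nControls = 2000L) {
  betas <- seq(0.2, 0.5, length.out = 10) * rep(c(1, -1), 5)
  pe <- do.call(rbind, lapply(1:10, function(i)
    plantedEffect(snp = i * 25L, biomarker = ((i - 1L) %% 10L) + 1L,
                  betaCases = betas[i], betaControls = betas[i])))
  SimulationConfig(nCases = nCases, nControls = nControls,
                   nSnps = 300L, nBlocks = 30L,
                   nBiomarkers = 12L, nFactors = 2L,
                   duplicatePairs = list(c(11L, 12L)),
                   plantedEffects = pe, missingRate = 0.02, seed = seed)
}

# Shared SNP metadata: ids, positions (0-based, chr1, 1 kb spacing),
# block assignment (contiguous, near-equal sizes), and MAFs drawn once
# from the config seed so both cohorts agree.
.snpMeta <- function(config) {
  n <- config@nSnps
  blockSizes <- diff(floor(seq(0, n, length.out = config@nBlocks + 1L)))
  block <- rep(sprintf("block%04d", seq_len(config@nBlocks)), blockSizes)
  maf <- withSeed(deriveSeed(config@seed, "snp-maf"),
                  stats::runif(n, config@mafRange[1], config@mafRange[2]))
  data.frame(snp_id = sprintf("snp%05d", seq_len(n)),
             chrom = "chr1", pos = 1000 * seq_len(n),
             a1 = "A", a2 = "G", block = block, maf = maf,
             stringsAsFactors = FALSE)
}

.cohortN <- function(config, cohort) {
  switch(cohort, case = config@nCases, control = config@nControls,
         stop("cohort must be 'case' or 'control'"))
}

#' Simulate genotypes for one cohort
#'
#' Each allele copy is drawn through a latent Gaussian copula: latent
#' variables share correlation \code{blockLdRho} within an LD block and are
#' independent across blocks; an allele is minor when its latent value falls
#' below the MAF quantile. Dosage counts minor alleles, so marginally each
#' SNP is binomial(2, maf) - i.e. in Hardy-Weinberg proportions - while SNPs
#' within a block are in LD. Missingness is applied i.i.d.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param cohort \code{"case"} or \code{"control"}; selects cohort size, the
#'   optional case MAF override, and an independent random stream.
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
simulateGenotypes <- function(config, cohort = c("case", "control")) {
  cohort <- match.arg(cohort)
  validObject(config)
  meta <- .snpMeta(config)
  maf <- meta$maf
  if (cohort == "case" && length(config@caseMaf)) maf <- config@caseMaf
  n <- .cohortN(config, cohort)
  rho <- config@blockLdRho
  thr <- stats::qnorm(maf)
  blocks <- meta$block
  dos <- withSeed(deriveSeed(config@seed, paste0("geno-", cohort)), {
    d <- matrix(0, n, config@nSnps)
    for (copy in 1:2) {
      z <- matrix(stats::rnorm(n * config@nSnps), n, config@nSnps)
      if (rho > 0) {
        for (b in unique(blocks)) {
          cols <- which(blocks == b)
          u <- stats::rnorm(n)
          z[, cols] <- sqrt(rho) * u + sqrt(1 - rho) * z[, cols]
        }
      }
      d <- d + (z < rep(thr, each = n))
    }
    if (config@missingRate > 0)
      d[stats::runif(length(d)) < config@missingRate] <- NA_real_
    d
  })
  rownames(dos) <- sprintf("%s%05d", substr(cohort, 1, 2), seq_len(n))
  GenotypeMatrix(dos, meta[, c("snp_id", "chrom", "pos", "a1", "a2", "block")])
}

#' Simulate confounders for one cohort
#'
#' One continuous age-like column, one binary sex-like column, and
#' \code{nExtraFlags} binary comorbidity-like flags; deterministic given the
#' config seed and cohort tag.
#'
#' @inheritParams simulateGenotypes
#' @return data.frame with \code{age}, \code{sex}, \code{flag1}, ...
#' @export
simulateConfounders <- function(config, cohort = c("case", "control")) {
  cohort <- match.arg(cohort)
  n <- .cohortN(config, cohort)
  withSeed(deriveSeed(config@seed, paste0("conf-", cohort)), {
    out <- data.frame(age = round(stats::rnorm(n, 55, 8), 1),
                      sex = stats::rbinom(n, 1L, 0.5))
    for (j in seq_len(config@nExtraFlags))
      out[[paste0("flag", j)]] <- stats::rbinom(n, 1L, 0.2)
    rownames(out) <- NULL
    out
  })
}

#' Simulate the biomarker panel for one cohort
#'
#' Realizes Y = G B + C Gamma + F Lambda' + E: planted genetic effects
#' (per-cohort betas), confounder effects on standardized confounders,
#' i.i.d. standard-normal latent factors with loading matrix Lambda, and
#' i.i.d. Gaussian noise. Missing genotypes are mean-imputed for generation
#' only. Duplicate pairs are then realized by overwriting the second member
#' with the first plus small independent noise, forcing r > 0.9.
#'
#' @param genotypes \linkS4class{GenotypeMatrix} for the cohort.
#' @param confounders data.frame from \code{simulateConfounders}.
#' @inheritParams simulateGenotypes
#' @return A \linkS4class{BiomarkerPanel}.
#' @export
simulateBiomarkers <- function(genotypes, confounders, config,
                               cohort = c("case", "control")) {
  cohort <- match.arg(cohort)
  n <- nrow(genotypes@dosage)
  stopifnot(nrow(confounders) == n)
  G <- genotypes@dosage
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2L]]
  }
  B <- matrix(0, ncol(G), config@nBiomarkers)
  pe <- config@plantedEffects
  if (nrow(pe)) {
    beta <- if (cohort == "case") pe$betaCases else pe$betaControls
    B[cbind(pe$snp, pe$biomarker)] <- beta
  }
  Cs <- scale(data.matrix(confounders))
  Cs[, apply(data.matrix(confounders), 2L, stats::sd) == 0] <- 0
  withSeed(deriveSeed(config@seed, paste0("bio-", cohort)), {
    FF <- matrix(stats::rnorm(n * config@nFactors), n, config@nFactors)
    E <- matrix(stats::rnorm(n * config@nBiomarkers, sd = config@noiseSd),
                n, config@nBiomarkers)
    Y <- G %*% B + Cs %*% t(config@confounderEffects) +
      FF %*% t(config@factorLoadings) + E
    for (pair in config@duplicatePairs) {
      s <- stats::sd(Y[, pair[1L]])
      Y[, pair[2L]] <- Y[, pair[1L]] + stats::rnorm(n, sd = 0.1 * s)
    }
    colnames(Y) <- sprintf("bm%03d", seq_len(config@nBiomarkers))
    groupNames <- c("HDL", "LDL", "VLDL", "IDL", "FattyAcids", "AminoAcids",
                    "ApoLipoproteins", "OtherLipids")
    grp <- ceiling(seq_len(config@nBiomarkers) /
                     ceiling(config@nBiomarkers / config@nFactors))
    groups <- groupNames[(grp - 1L) %% length(groupNames) + 1L]
    BiomarkerPanel(Y, groups)
  })
}

#' Simulate one full cohort (genotypes, confounders, biomarkers, truth)
#'
#' @inheritParams simulateGenotypes
#' @return A \linkS4class{CohortData}.
#' @export
simulateCohort <- function(config, cohort = c("case", "control")) {
  cohort <- match.arg(cohort)
  g <- simulateGenotypes(config, cohort)
  cf <- simulateConfounders(config, cohort)
  bm <- simulateBiomarkers(g, cf, config, cohort)
  meta <- .snpMeta(config)
  maf <- meta$maf
  if (cohort == "case" && length(config@caseMaf)) maf <- config@caseMaf
  truth <- list(config = config, maf = stats::setNames(maf, meta$snp_id),
                blocks = blockMapFromSnpInfo(g@snpInfo), cohort = cohort)
  new("CohortData", genotypes = g, biomarkers = bm, confounders = cf,
      truth = truth)
}

#' Simulate both cohorts of a two-cohort study
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return Named list with elements \code{case} and \code{control}.
#' @export
simulateStudy <- function(config) {
  list(case = simulateCohort(config, "case"),
       control = simulateCohort(config, "control"))
}
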