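#' @import methods
NULL

#' GenotypeMatrix: individuals x SNPs minor-allele dosage matrix
#'
#' Dosages count copies of the minor allele (0 = homozygous major,
#' 1 = heterozygote, 2 = homozygous minor, \code{NA} = missing). Per-SNP
#' metadata travels alongside: identifier, chromosome, 0-based position,
#' minor (a1) and major (a2) allele, and an LD-block id (may be \code{NA}
#' before block assignment).
#'
#' @slot dosage numeric matrix, individuals in rows, SNPs in columns.
#' @slot snpInfo data.frame with columns \code{snp_id}, \code{chrom},
#'   \code{pos}, \code{a1}, \code{a2}, \code{block}; one row per SNP.
#' @export
setClass("GenotypeMatrix",
  representation(dosage = "matrix", snpInfo = "data.frame"))

setValidity("GenotypeMatrix", function(object) {
  d <- object@dosage
  info <- object@snpInfo
  msgs <- character()
  if (ncol(d) != nrow(info))
    msgs <- c(msgs, "ncol(dosage) must equal nrow(snpInfo)")
  need <- c("snp_id", "chrom", "pos", "a1", "a2", "block")
  if (!all(need %in% names(info)))
    msgs <- c(msgs, paste("snpInfo must have columns:", paste(need, collapse = ", ")))
  v <- d[!is.na(d)]
  if (length(v) && !all(v %in% c(0, 1, 2)))
    msgs <- c(msgs, "dosage entries must be in {0, 1, 2, NA}")
  if ("snp_id" %in% names(info) && anyDuplicated(info$snp_id))
    msgs <- c(msgs, "snp_id values must be unique")
  if (length(msgs)) msgs else TRUE
})

#' BiomarkerPanel: individuals x biomarkers continuous trait matrix
#'
#' Continuous biomarker measurements (e.g. NMR lipoprotein-subclass lipids)
#' with a group label per biomarker (HDL, VLDL, fatty acids, ...).
#'
#' @slot values numeric matrix, individuals in rows, biomarkers in columns
#'   (column names are biomarker ids).
#' @slot groups named character vector mapping biomarker id to group label.
#' @export
setClass("BiomarkerPanel",
  representation(values = "matrix", groups = "character"))

setValidity("BiomarkerPanel", function(object) {
  msgs <- character()
  if (is.null(colnames(object@values)))
    msgs <- c(msgs, "values must have biomarker column names")
  if (length(object@groups) != ncol(object@values))
    msgs <- c(msgs, "one group label per biomarker required")
  else if (!identical(names(object@groups), colnames(object@values)))
    msgs <- c(msgs, "names(groups) must equal colnames(values)")
  if (length(msgs)) msgs else TRUE
})

#' SimulationConfig: parameters of the synthetic two-cohort generator
#'
#' Defines the study conditions: two cohorts of (typically very) unequal
#' size sharing SNP metadata and allele frequencies, block-structured LD via
#' a Gaussian copula, a latent-factor biomarker panel with forced
#' near-duplicate pairs, confounders with effects on biomarkers, and planted
#' SNP-to-biomarker effects that may differ between cohorts.
#'
#' @slot nCases,nControls cohort sizes (small and large cohort).
#' @slot nSnps,nBlocks SNP count and LD-block count (blocks are contiguous).
#' @slot mafRange length-2 minor-allele-frequency bounds in (0, 0.5].
#' @slot blockLdRho within-block latent correlation in [0, 1).
#' @slot nBiomarkers,nFactors biomarker count and latent factor count.
#' @slot factorLoadings nBiomarkers x nFactors loading matrix.
#' @slot noiseSd residual biomarker noise standard deviation.
#' @slot duplicatePairs list of length-2 integer vectors; each second member
#'   is rebuilt as a near copy (r > 0.9) of the first.
#' @slot plantedEffects data.frame with columns \code{snp}, \code{biomarker},
#'   \code{betaCases}, \code{betaControls} (standardized-trait units per
#'   minor-allele dosage unit).
#' @slot confounderEffects nBiomarkers x nConfounders effect matrix.
#' @slot nExtraFlags number of binary comorbidity-like confounder flags
#'   beyond the age-like and sex-like columns.
#' @slot missingRate genotype missingness probability in [0, 1].
#' @slot caseMaf optional per-SNP MAF override for the case cohort
#'   (length 0 = shared MAFs).
#' @slot seed root seed; all stage streams derive from it.
#' @export
setClass("SimulationConfig",
  representation(
    nCases = "integer", nControls = "integer",
    nSnps = "integer", nBlocks = "integer",
    mafRange = "numeric", blockLdRho = "numeric",
    nBiomarkers = "integer", nFactors = "integer",
    factorLoadings = "matrix", noiseSd = "numeric",
    duplicatePairs = "list", plantedEffects = "data.frame",
    confounderEffects = "matrix", nExtraFlags = "integer",
    missingRate = "numeric", caseMaf = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  if (object@nCases < 1L || object@nControls < 1L || object@nSnps < 1L ||
      object@nBiomarkers < 1L)
    msgs <- c(msgs, "nCases, nControls, nSnps, nBiomarkers must all be >= 1")
  if (length(object@mafRange) != 2L || any(object@mafRange <= 0) ||
      any(object@mafRange > 0.5) || object@mafRange[1] > object@mafRange[2])
    msgs <- c(msgs, "mafRange must be an ordered pair within (0, 0.5]")
  if (object@blockLdRho < 0 || object@blockLdRho >= 1)
    msgs <- c(msgs, "blockLdRho must be in [0, 1)")
  if (object@missingRate < 0 || object@missingRate > 1)
    msgs <- c(msgs, "missingRate must be in [0, 1]")
  if (object@nBlocks < 1L || object@nBlocks > object@nSnps)
    msgs <- c(msgs, "nBlocks must be in [1, nSnps]")
  if (!all(dim(object@factorLoadings) == c(object@nBiomarkers, object@nFactors)))
    msgs <- c(msgs, "factorLoadings must be nBiomarkers x nFactors")
  pe <- object@plantedEffects
  if (nrow(pe)) {
    if (!all(c("snp", "biomarker", "betaCases", "betaControls") %in% names(pe)))
      msgs <- c(msgs, "plantedEffects needs snp, biomarker, betaCases, betaControls")
    else {
      if (any(pe$snp < 1 | pe$snp > object@nSnps) ||
          any(pe$biomarker < 1 | pe$biomarker > object@nBiomarkers))
        msgs <- c(msgs, "plantedEffects reference SNP/biomarker indices out of range")
      if (!all(is.finite(pe$betaCases)) || !all(is.finite(pe$betaControls)))
        msgs <- c(msgs, "planted betas must be finite")
    }
  }
  if (nrow(object@confounderEffects) != object@nBiomarkers)
    msgs <- c(msgs, "confounderEffects must have nBiomarkers rows")
  if (length(object@caseMaf) &&
      length(object@caseMaf) != object@nSnps)
    msgs <- c(msgs, "caseMaf override must have one entry per SNP")
  if (length(msgs)) msgs else TRUE
})

#' CohortData: genotypes + biomarkers + confounders for one cohort
#'
#' The three tables share individual ordering; \code{truth} carries the
#' generating configuration, realized allele frequencies and block
#' assignments so downstream stages can be checked against ground truth.
#'
#' @slot genotypes a \linkS4class{GenotypeMatrix}.
#' @slot biomarkers a \linkS4class{BiomarkerPanel}.
#' @slot confounders data.frame of per-individual covariates.
#' @slot truth list with elements \code{config}, \code{maf}, \code{blocks},
#'   \code{cohort}.
#' @export
setClass("CohortData",
  representation(genotypes = "GenotypeMatrix", biomarkers = "BiomarkerPanel",
                 confounders = "data.frame", truth = "list"))

setValidity("CohortData", function(object) {
  n <- nrow(object@genotypes@dosage)
  msgs <- character()
  if (nrow(object@biomarkers@values) != n || nrow(object@confounders) != n)
    msgs <- c(msgs, "genotypes, biomarkers and confounders must share individuals")
  blocks <- object@genotypes@snpInfo$block
  if (anyNA(blocks)) {
    msgs <- c(msgs, "every SNP must carry a block id")
  } else {
    r <- rle(as.character(blocks))
    if (anyDuplicated(r$values))
      msgs <- c(msgs, "block ids must partition SNPs into contiguous runs")
  }
  if (length(msgs)) msgs else TRUE
})

#' DegasMatrix: filtered, Z-scored biomarker x variant summary matrix
#'
#' The matrix W that is factorized: Z-scores beta/se, censored by p and
#' standard-error filters, collapsed to one lead variant per LD block,
#' zero-filled and row-standardized so each biomarker row has mean 0 and
#' unit variance.
#'
#' @slot W numeric matrix (biomarkers x variants).
#' @slot variantInfo data.frame with \code{snp_id}, \code{chrom}, \code{pos}.
#' @slot filters list recording the censoring/collapse settings applied.
#' @export
setClass("DegasMatrix",
  representation(W = "matrix", variantInfo = "data.frame", filters = "list"))

setValidity("DegasMatrix", function(object) {
  msgs <- character()
  if (nrow(object@variantInfo) != ncol(object@W))
    msgs <- c(msgs, "variantInfo must describe the columns of W")
  if (ncol(object@W) > 0 && any(colSums(abs(object@W)) == 0))
    msgs <- c(msgs, "W must contain no all-zero variant columns")
  if (nrow(object@W) > 0) {
    mu <- rowMeans(object@W)
    v <- apply(object@W, 1L, stats::var)
    if (any(abs(mu) > 1e-8) || any(abs(v - 1) > 1e-6))
      msgs <- c(msgs, "biomarker rows must be centered and unit-variance")
  }
  if (length(msgs)) msgs else TRUE
})

#' DegasDecomposition: truncated SVD factors of a DegasMatrix
#'
#' W ~ U diag(S) V' with orthonormal U (biomarker singular vectors) and V
#' (variant singular vectors), singular values S sorted non-increasing, and
#' a deterministic sign convention (largest-magnitude entry of each U column
#' is positive).
#'
#' @slot U biomarkers x k orthonormal matrix.
#' @slot S length-k non-increasing, non-negative singular values.
#' @slot V variants x k orthonormal matrix.
#' @slot k retained component count.
#' @slot variantInfo data.frame describing rows of V.
#' @export
setClass("DegasDecomposition",
  representation(U = "matrix", S = "numeric", V = "matrix", k = "integer",
                 variantInfo = "data.frame"))

setValidity("DegasDecomposition", function(object) {
  k <- object@k
  msgs <- character()
  if (ncol(object@U) != k || ncol(object@V) != k || length(object@S) != k)
    msgs <- c(msgs, "U, V, S dimensions must agree with k")
  if (any(diff(object@S) > 1e-12) || any(object@S < 0))
    msgs <- c(msgs, "singular values must be non-negative and non-increasing")
  if (max(abs(crossprod(object@U) - diag(k))) > 1e-8)
    msgs <- c(msgs, "U columns must be orthonormal")
  if (max(abs(crossprod(object@V) - diag(k))) > 1e-8)
    msgs <- c(msgs, "V columns must be orthonormal")
  if (length(msgs)) msgs else TRUE
})
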