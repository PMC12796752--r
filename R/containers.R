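#' Construct a GenotypeMatrix
#'
#' @param dosage individuals x SNPs matrix of minor-allele dosages
#'   (0/1/2/NA).
#' @param snpInfo per-SNP metadata data.frame (\code{snp_id}, \code{chrom},
#'   \code{pos} 0-based, \code{a1} minor allele, \code{a2} major allele,
#'   \code{block}); \code{block} may be omitted and defaults to \code{NA}.
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
GenotypeMatrix <- function(dosage, snpInfo) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (!"block" %in% names(snpInfo))
    snpInfo[["block"]] <- rep(NA_character_, nrow(snpInfo))
  snpInfo$snp_id <- as.character(snpInfo$snp_id)
  snpInfo$chrom <- as.character(snpInfo$chrom)
  snpInfo$pos <- as.integer(snpInfo$pos)
  snpInfo$a1 <- as.character(snpInfo$a1)
  snpInfo$a2 <- as.character(snpInfo$a2)
  snpInfo$block <- as.character(snpInfo$block)
  rownames(snpInfo) <- NULL
  if (is.null(colnames(dosage))) colnames(dosage) <- snpInfo$snp_id
  new("GenotypeMatrix", dosage = dosage, snpInfo = snpInfo)
}

#' Construct a BiomarkerPanel
#'
#' @param values individuals x biomarkers numeric matrix with biomarker ids
#'   as column names.
#' @param groups character vector of group labels (recycled if length 1);
#'   defaults to \code{"unassigned"}.
#' @return A \linkS4class{BiomarkerPanel}.
#' @export
BiomarkerPanel <- function(values, groups = "unassigned") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("bm%03d", seq_len(ncol(values)))
  if (length(groups) == 1L) groups <- rep(groups, ncol(values))
  names(groups) <- colnames(values)
  new("BiomarkerPanel", values = values, groups = groups)
}

# Accessors --------------------------------------------------------------

#' @describeIn GenotypeMatrix-accessors dosage matrix (individuals x SNPs)
#' @export
dosages <- function(x) x@dosage

#' Accessors for GenotypeMatrix and BiomarkerPanel
#'
#' @param x a \linkS4class{GenotypeMatrix} or \linkS4class{BiomarkerPanel}.
#' @name GenotypeMatrix-accessors
#' @return The requested component.
NULL

#' @describeIn GenotypeMatrix-accessors per-SNP metadata data.frame
#' @export
snpInfo <- function(x) x@snpInfo

#' @describeIn GenotypeMatrix-accessors SNP count
#' @export
nSnps <- function(x) ncol(x@dosage)

#' @describeIn GenotypeMatrix-accessors individual count
#' @export
nIndividuals <- function(x) {
  if (is(x, "GenotypeMatrix")) nrow(x@dosage) else nrow(x@values)
}

#' @describeIn GenotypeMatrix-accessors biomarker value matrix
#' @export
biomarkerValues <- function(x) x@values

#' @describeIn GenotypeMatrix-accessors named biomarker group labels
#' @export
biomarkerGroups <- function(x) x@groups

#' @describeIn GenotypeMatrix-accessors biomarker ids
#' @export
biomarkerIds <- function(x) colnames(x@values)

#' Minor allele frequency per SNP
#'
#' Computed on non-missing dosages as mean(dosage) / 2 and folded to the
#' minor side (values > 0.5 are reported as 1 - f).
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @param fold fold frequencies above 0.5 to the minor side (default TRUE).
#' @return Named numeric vector of allele frequencies.
#' @export
alleleFrequency <- function(x, fold = TRUE) {
  f <- colMeans(x@dosage, na.rm = TRUE) / 2
  if (fold) f <- pmin(f, 1 - f)
  names(f) <- x@snpInfo$snp_id
  f
}

#' Subset a GenotypeMatrix by SNP
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @param keep logical or integer index over SNPs.
#' @return A \linkS4class{GenotypeMatrix} with the selected SNPs.
#' @export
subsetSnps <- function(x, keep) {
  GenotypeMatrix(x@dosage[, keep, drop = FALSE],
                 x@snpInfo[keep, , drop = FALSE])
}

# show methods -----------------------------------------------------------

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@dosage), "individuals x",
      ncol(object@dosage), "SNPs\n")
  miss <- mean(is.na(object@dosage))
  cat(sprintf("  missingness: %.2f%%; chroms: %s\n", 100 * miss,
              paste(unique(object@snpInfo$chrom), collapse = ", ")))
})

setMethod("show", "BiomarkerPanel", function(object) {
  cat("BiomarkerPanel:", nrow(object@values), "individuals x",
      ncol(object@values), "biomarkers\n")
  tab <- table(object@groups)
  cat("  groups:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nCases, "cases /", object@nControls,
      "controls;", object@nSnps, "SNPs in", object@nBlocks, "blocks;",
      object@nBiomarkers, "biomarkers,", object@nFactors, "factors\n")
  cat(sprintf("  MAF in [%.3g, %.3g], LD rho = %.2f, missing = %.3g, seed = %d\n",
              object@mafRange[1], object@mafRange[2], object@blockLdRho,
              object@missingRate, object@seed))
  cat("  planted effects:", nrow(object@plantedEffects),
      "| duplicate pairs:", length(object@duplicatePairs), "\n")
})

setMethod("show", "CohortData", function(object) {
  cat("CohortData (", object@truth$cohort, " cohort)\n", sep = "")
  show(object@genotypes)
  show(object@biomarkers)
  cat("  confounders:", paste(names(object@confounders), collapse = ", "), "\n")
})

setMethod("show", "DegasMatrix", function(object) {
  cat("DegasMatrix:", nrow(object@W), "biomarkers x", ncol(object@W),
      "variants (Z-scored, row-standardized)\n")
  f <- object@filters
  if (length(f))
    cat(sprintf("  filters: p <= %g, se <= %g; censored cells zero-filled\n",
                f$pMax, f$seMax))
})

setMethod("show", "DegasDecomposition", function(object) {
  cat("DegasDecomposition: k =", object@k, "components;",
      nrow(object@U), "biomarkers x", nrow(object@V), "variants\n")
  cat("  singular values:", paste(signif(utils::head(object@S, 5), 4),
                                  collapse = ", "),
      if (object@k > 5) "...\n" else "\n")
})
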