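#' Inverse normal rank transformation
#'
#' Maps values to standard-normal quantiles of their (Blom-offset) ranks:
#' Phi^-1((rank - 3/8) / (n + 1/4)) over non-missing entries, with average
#' ranks for ties. Used to tame outliers and skew in biomarker
#' distributions before association testing.
#'
#' @param values numeric vector; \code{NA}s stay \code{NA}.
#' @return Transformed vector of the same length and order.
#' @export
inverseNormalTransform <- function(values) {
  ok <- !is.na(values)
  x <- values[ok]
  if (length(unique(x)) < 2L) stop("degenerate biomarker", call. = FALSE)
  n <- length(x)
  r <- rank(x, ties.method = "average")
  out <- values
  out[ok] <- stats::qnorm((r - 3 / 8) / (n + 1 / 4))
  out
}

#' Apply the inverse normal transform to every biomarker of a panel
#'
#' @param panel a \linkS4class{BiomarkerPanel}.
#' @return A transformed \linkS4class{BiomarkerPanel}.
#' @export
transformPanel <- function(panel) {
  v <- apply(panel@values, 2L, inverseNormalTransform)
  dimnames(v) <- dimnames(panel@values)
  BiomarkerPanel(v, panel@groups)
}

#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' 1-df chi-square test of observed genotype counts against the p^2, 2pq,
#' q^2 proportions expected at the sample allele frequency. Monomorphic
#' SNPs return p = 1 by convention.
#'
#' @param nHomMajor,nHet,nHomMinor genotype counts.
#' @return p-value (scalar; inputs are recycled if vectors).
#' @export
hweTest <- function(nHomMajor, nHet, nHomMinor) {
  counts <- cbind(nHomMajor, nHet, nHomMinor)
  if (any(counts < 0, na.rm = TRUE)) stop("negative genotype counts")
  n <- rowSums(counts)
  if (any(n <= 0)) stop("total genotype count must be positive")
  q <- (2 * counts[, 3L] + counts[, 2L]) / (2 * n)   # minor allele freq
  p <- 1 - q
  mono <- q == 0 | q == 1
  expd <- cbind(n * p^2, 2 * n * p * q, n * q^2)
  chi2 <- rowSums((counts - expd)^2 / expd)
  out <- stats::pchisq(chi2, df = 1L, lower.tail = FALSE)
  out[mono] <- 1
  unname(out)
}

#' QC thresholds for variant filtering
#'
#' @param mafMin minimum minor allele frequency (variants below are
#'   removed; default 0.05).
#' @param missingMax maximum per-SNP missing rate (default 0.10).
#' @param hwePMin minimum Hardy-Weinberg p-value (default 1e-9).
#' @return A validated list of class \code{QCThresholds}.
#' @export
qcThresholds <- function(mafMin = 0.05, missingMax = 0.10, hwePMin = 1e-9) {
  .assertProb(mafMin, "mafMin")
  .assertProb(missingMax, "missingMax")
  .assertProb(hwePMin, "hwePMin")
  structure(list(mafMin = mafMin, missingMax = missingMax,
                 hwePMin = hwePMin), class = "QCThresholds")
}

#' Variant quality control
#'
#' Removes SNPs with minor allele frequency below \code{mafMin}, missing
#' rate above \code{missingMax}, or Hardy-Weinberg p below \code{hwePMin}.
#' MAF is computed on non-missing dosages of the cohort at hand (per-cohort
#' QC), and a SNP may fail several criteria; all reasons are recorded.
#'
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param thresholds a \code{\link{qcThresholds}} object.
#' @return List with \code{genotypes} (filtered) and \code{report}, a
#'   data.frame (snp_id, maf, missing, hweP, pass, reasons) carrying
#'   attribute \code{counts}: retained/removed totals and removals per
#'   criterion.
#' @export
variantQC <- function(genotypes, thresholds = qcThresholds()) {
  d <- genotypes@dosage
  if (ncol(d) == 0L || nrow(d) == 0L) stop("empty genotype matrix")
  maf <- alleleFrequency(genotypes)
  miss <- colMeans(is.na(d))
  nAA <- colSums(d == 0, na.rm = TRUE)
  nAa <- colSums(d == 1, na.rm = TRUE)
  naa <- colSums(d == 2, na.rm = TRUE)
  hweP <- hweTest(nAA, nAa, naa)
  failMaf <- maf < thresholds$mafMin
  failMiss <- miss >= thresholds$missingMax
  failHwe <- hweP < thresholds$hwePMin
  pass <- !(failMaf | failMiss | failHwe)
  reasons <- mapply(function(a, b, c)
    paste(c("maf", "missing", "hwe")[c(a, b, c)], collapse = ","),
    failMaf, failMiss, failHwe)
  report <- data.frame(snp_id = genotypes@snpInfo$snp_id,
                       maf = unname(maf), missing = unname(miss),
                       hweP = hweP, pass = pass, reasons = reasons,
                       stringsAsFactors = FALSE)
  attr(report, "counts") <- list(
    input = ncol(d), retained = sum(pass), removed = sum(!pass),
    removed_maf = sum(failMaf), removed_missing = sum(failMiss),
    removed_hwe = sum(failHwe))
  list(genotypes = subsetSnps(genotypes, pass), report = report)
}

#' Allowed-covariate mask from biomarker correlations
#'
#' Entry (m, l) is TRUE iff biomarker l is an admissible covariate
#' candidate for outcome m: the pairwise-complete Pearson correlation
#' satisfies |r| <= rMax and l != m. Highly correlated biomarkers (|r| >
#' rMax, e.g. near-duplicate lipoprotein measures) are mutually excluded to
#' limit false positives from proxy covariates.
#'
#' @param panel a \linkS4class{BiomarkerPanel}.
#' @param rMax exclusion threshold (strict >; default 0.9).
#' @return Symmetric logical matrix with FALSE diagonal.
#' @export
biomarkerCorrelationMask <- function(panel, rMax = 0.9) {
  v <- panel@values
  sds <- apply(v, 2L, stats::sd, na.rm = TRUE)
  if (any(sds == 0, na.rm = TRUE)) {
    warning("constant biomarker(s): ",
            paste(colnames(v)[which(sds == 0)], collapse = ", "),
            "; correlation treated as 0")
  }
  r <- suppressWarnings(stats::cor(v, use = "pairwise.complete.obs"))
  r[!is.finite(r)] <- 0
  # strict-> exclusion: |r| equal to rMax stays admissible; 1e-9 guard
  # keeps the boundary stable under floating-point rounding
  mask <- abs(r) <= rMax + 1e-9
  diag(mask) <- FALSE
  mask
}

#' Case-control biomarker difference tests
#'
#' Two-sided Mann-Whitney U test per biomarker between the two cohorts,
#' with Benjamini-Hochberg adjustment across biomarkers.
#'
#' @param panelCases,panelControls \linkS4class{BiomarkerPanel}s sharing
#'   biomarker ids.
#' @return data.frame with columns biomarker, U, p, pAdj.
#' @export
biomarkerDifferenceTests <- function(panelCases, panelControls) {
  a <- panelCases@values
  b <- panelControls@values
  if (nrow(a) == 0L || nrow(b) == 0L) stop("empty cohort")
  stopifnot(identical(colnames(a), colnames(b)))
  res <- lapply(colnames(a), function(id) {
    w <- suppressWarnings(stats::wilcox.test(a[, id], b[, id],
                                             exact = FALSE))
    data.frame(biomarker = id, U = unname(w$statistic), p = w$p.value)
  })
  out <- do.call(rbind, res)
  out$pAdj <- stats::p.adjust(out$p, method = "BH")
  out
}
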