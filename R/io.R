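# Canonical interchange: TSV with header, UTF-8, '.' decimal, 'NA' missing.
.writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

.readTsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    na.strings = "NA", check.names = FALSE)
}

#' Read / write association tables
#'
#' The TSV dialect shared by the GWAS, region-summary, cohort-comparison
#' and decomposition stages: columns snp_id, chrom, pos, biomarker,
#' method, beta, se, p, n, covariates (comma-joined ids, empty when none).
#'
#' @param records association table.
#' @param path file path.
#' @return \code{readAssociations}: the table as a data.frame.
#' @export
writeAssociations <- function(records, path) .writeTsv(records, path)

#' @rdname writeAssociations
#' @export
readAssociations <- function(path) {
  out <- .readTsv(path)
  need <- c("snp_id", "biomarker", "method", "beta", "se", "p", "n")
  if (!all(need %in% names(out)))
    stop("association table at ", path, " lacks columns: ",
         paste(setdiff(need, names(out)), collapse = ", "))
  if (!"covariates" %in% names(out)) out$covariates <- ""
  out$covariates[is.na(out$covariates)] <- ""
  out
}

#' Read / write a biomarker panel as TSV
#'
#' Wide layout: one row per individual, one column per biomarker; group
#' labels in a companion two-column TSV (biomarker, group).
#'
#' @param panel a \linkS4class{BiomarkerPanel}.
#' @param path biomarker TSV path; the group file is
#'   \code{<path>.groups.tsv}.
#' @return \code{readBiomarkerPanel}: a \linkS4class{BiomarkerPanel}.
#' @export
writeBiomarkerPanel <- function(panel, path) {
  .writeTsv(as.data.frame(panel@values), path)
  .writeTsv(data.frame(biomarker = names(panel@groups),
                       group = unname(panel@groups)),
            paste0(path, ".groups.tsv"))
  invisible(path)
}

#' @rdname writeBiomarkerPanel
#' @export
readBiomarkerPanel <- function(path) {
  v <- as.matrix(.readTsv(path))
  gpath <- paste0(path, ".groups.tsv")
  groups <- "unassigned"
  if (file.exists(gpath)) {
    g <- .readTsv(gpath)
    groups <- stats::setNames(g$group, g$biomarker)[colnames(v)]
  }
  BiomarkerPanel(v, unname(groups))
}

#' Read / write genotype dosages as plain TSV
#'
#' The package's text dialect for genotype matrices: columns snp_id,
#' chrom, pos (0-based), a1, a2, block, then one column per individual
#' holding 0/1/2/NA minor-allele dosages.
#'
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param path file path.
#' @return \code{readDosageTsv}: a \linkS4class{GenotypeMatrix}.
#' @export
writeDosageTsv <- function(genotypes, path) {
  d <- t(genotypes@dosage)
  out <- cbind(genotypes@snpInfo, as.data.frame(d))
  .writeTsv(out, path)
}

#' @rdname writeDosageTsv
#' @export
readDosageTsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, na.strings = "NA",
                         check.names = FALSE,
                         colClasses = c(snp_id = "character",
                                        chrom = "character",
                                        a1 = "character", a2 = "character",
                                        block = "character"))
  meta <- c("snp_id", "chrom", "pos", "a1", "a2", "block")
  if (!all(meta %in% names(x)))
    stop("dosage TSV at ", path, " lacks metadata columns")
  d <- t(as.matrix(x[, setdiff(names(x), meta), drop = FALSE]))
  colnames(d) <- x$snp_id
  GenotypeMatrix(d, x[, meta])
}

#' Write a full simulated cohort to a directory
#'
#' Emits PLINK bed/bim/fam, biomarkers.tsv (+ group companion),
#' confounders.tsv, blocks.bed and truth.json (planted effects, realized
#' MAFs, block assignment, generator settings). Round-trips through
#' \code{\link{readCohort}}.
#'
#' @param cohortData a \linkS4class{CohortData}.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeCohort <- function(cohortData, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create cohort directory: ", dir)
  writePlink(cohortData@genotypes, file.path(dir, "genotypes"))
  writeBiomarkerPanel(cohortData@biomarkers, file.path(dir, "biomarkers.tsv"))
  .writeTsv(cohortData@confounders, file.path(dir, "confounders.tsv"))
  writeBlockMap(cohortData@truth$blocks, file.path(dir, "blocks.bed"))
  cfg <- cohortData@truth$config
  truth <- list(
    cohort = cohortData@truth$cohort,
    maf = as.list(cohortData@truth$maf),
    plantedEffects = cfg@plantedEffects,
    config = list(nCases = cfg@nCases, nControls = cfg@nControls,
                  nSnps = cfg@nSnps, nBlocks = cfg@nBlocks,
                  mafRange = cfg@mafRange, blockLdRho = cfg@blockLdRho,
                  nBiomarkers = cfg@nBiomarkers, nFactors = cfg@nFactors,
                  noiseSd = cfg@noiseSd, missingRate = cfg@missingRate,
                  seed = cfg@seed),
    blockOfSnp = as.list(stats::setNames(cohortData@genotypes@snpInfo$block,
                                         cohortData@genotypes@snpInfo$snp_id)))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort directory written by \code{\link{writeCohort}}
#'
#' @param dir cohort directory.
#' @return List with genotypes (block ids restored from truth.json),
#'   biomarkers, confounders, blocks (\code{GRanges}), truth (parsed
#'   truth.json).
#' @export
readCohort <- function(dir) {
  gm <- readPlink(file.path(dir, "genotypes"))
  truthPath <- file.path(dir, "truth.json")
  truth <- if (file.exists(truthPath))
    jsonlite::read_json(truthPath, simplifyVector = TRUE) else NULL
  if (!is.null(truth$blockOfSnp))
    gm@snpInfo$block <- unlist(truth$blockOfSnp)[gm@snpInfo$snp_id]
  blocksPath <- file.path(dir, "blocks.bed")
  list(genotypes = gm,
       biomarkers = readBiomarkerPanel(file.path(dir, "biomarkers.tsv")),
       confounders = .readTsv(file.path(dir, "confounders.tsv")),
       blocks = if (file.exists(blocksPath)) readBlockMap(blocksPath) else NULL,
       truth = truth)
}

#' Serialize a variant QC report
#'
#' Per-SNP table as TSV plus summary counts as JSON.
#'
#' @param report QC report data.frame from \code{\link{variantQC}}.
#' @param prefix output path prefix (writes \code{<prefix>.tsv} and
#'   \code{<prefix>.json}).
#' @return The prefix, invisibly.
#' @export
writeQCReport <- function(report, prefix) {
  .writeTsv(report, paste0(prefix, ".tsv"))
  jsonlite::write_json(attr(report, "counts"), paste0(prefix, ".json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(prefix)
}
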