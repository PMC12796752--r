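#' Pipeline configuration
#'
#' Collects every stage setting: cohort input directories (layout of
#' \code{\link{writeCohort}}), QC thresholds, CMS settings, the base
#' genome-wide alpha and the effective-test variance target, winner's
#' curse and decomposition settings, the output directory and the root
#' seed.
#'
#' @param caseDir,controlDir cohort directories.
#' @param outDir output directory.
#' @param qc a \code{\link{qcThresholds}} object.
#' @param cms a \code{\link{cmsSettings}} object.
#' @param alpha base genome-wide significance level (default 5e-8).
#' @param varianceThreshold effective-test cumulative variance target
#'   (default 0.99).
#' @param wcThreshold,wcBoot winner's-curse selection threshold and
#'   bootstrap count.
#' @param degasPMax,degasSeMax,degasK,degasTopN decomposition settings;
#'   \code{degasSeMax = 0.08} presumes biobank-scale standard errors and
#'   should be relaxed for small cohorts.
#' @param degasCohort which cohort's CMS summary statistics to decompose
#'   (default \code{"case"}; small cohorts may not support the censoring
#'   filters, in which case choose \code{"control"}).
#' @param seed root seed.
#' @return A validated list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(caseDir, controlDir, outDir,
                           qc = qcThresholds(), cms = cmsSettings(),
                           alpha = 5e-8, varianceThreshold = 0.99,
                           wcThreshold = 1e-4, wcBoot = 100L,
                           degasPMax = 0.001, degasSeMax = 0.08,
                           degasK = 24L, degasTopN = 5000L,
                           degasCohort = c("case", "control"), seed = 1L) {
  degasCohort <- match.arg(degasCohort)
  for (d in c(caseDir, controlDir))
    if (!dir.exists(d)) stop("cohort directory not found: ", d)
  .assertProb(alpha, "alpha", openLeft = TRUE)
  .assertProb(varianceThreshold, "varianceThreshold", openLeft = TRUE)
  structure(list(caseDir = caseDir, controlDir = controlDir,
                 outDir = outDir, qc = qc, cms = cms, alpha = alpha,
                 varianceThreshold = varianceThreshold,
                 wcThreshold = wcThreshold, wcBoot = as.integer(wcBoot),
                 degasPMax = degasPMax, degasSeMax = degasSeMax,
                 degasK = as.integer(degasK),
                 degasTopN = as.integer(degasTopN),
                 degasCohort = degasCohort,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Run the full two-cohort pipeline
#'
#' Stage order: preprocess (transform + QC) -> association scan (both
#' cohorts, both methods) -> region summary (lead SNPs, effective tests,
#' adjusted threshold, significance calls) -> cohort comparison (winner's
#' curse, heterogeneity, effect correlation) -> decomposition. Each
#' stage's outputs are written before the next starts, so a later failure
#' preserves earlier outputs; the manifest records config, input
#' checksums, stage timings and (on failure) the failed stage.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return The run manifest (list), invisibly; all outputs under
#'   \code{config$outDir}.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  out <- config$outDir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  inputs <- c(list.files(config$caseDir, full.names = TRUE),
              list.files(config$controlDir, full.names = TRUE))
  manifest <- list(
    package = "MetaboGWAS",
    version = as.character(utils::packageVersion("MetaboGWAS")),
    rversion = R.version.string,
    seed = config$seed,
    config = config[setdiff(names(config), c("qc", "cms"))],
    qc = unclass(config$qc), cms = unclass(config$cms),
    inputChecksums = as.list(tools::md5sum(inputs)),
    stages = list())
  stage <- "preprocess"
  env <- new.env()
  finishStage <- function(name, t0) {
    manifest$stages[[name]] <<- list(seconds = round(as.numeric(
      difftime(Sys.time(), t0, units = "secs")), 3))
  }
  writeManifest <- function() {
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result <- tryCatch({
    ## preprocess -------------------------------------------------------
    t0 <- Sys.time()
    cohorts <- list(case = readCohort(config$caseDir),
                    control = readCohort(config$controlDir))
    for (nm in names(cohorts)) {
      qc <- variantQC(cohorts[[nm]]$genotypes, config$qc)
      cohorts[[nm]]$genotypes <- qc$genotypes
      writeQCReport(qc$report, file.path(out, paste0("qc_", nm)))
      cohorts[[nm]]$biomarkers <- transformPanel(cohorts[[nm]]$biomarkers)
    }
    diffs <- biomarkerDifferenceTests(cohorts$case$biomarkers,
                                      cohorts$control$biomarkers)
    .writeTsv(diffs, file.path(out, "biomarker_difference_tests.tsv"))
    finishStage("preprocess", t0)
    writeManifest()

    ## association scan -------------------------------------------------
    stage <- "mgwas"
    t0 <- Sys.time()
    assoc <- list()
    for (nm in names(cohorts)) {
      for (method in c("STD", "CMS")) {
        tab <- runMGWAS(cohorts[[nm]]$genotypes, cohorts[[nm]]$biomarkers,
                        cohorts[[nm]]$confounders, config$cms, method)
        key <- paste0(nm, "_", tolower(method))
        assoc[[key]] <- tab
        writeAssociations(tab, file.path(out, paste0("assoc_", key, ".tsv")))
      }
    }
    finishStage("mgwas", t0)
    writeManifest()

    ## region summary ---------------------------------------------------
    stage <- "region_summary"
    t0 <- Sys.time()
    leads <- list()
    thresholds <- list()
    for (nm in names(cohorts)) {
      blocks <- cohorts[[nm]]$blocks
      if (is.null(blocks))
        stop("blocks.bed missing for cohort '", nm, "'")
      nEff <- effectiveTests(cohorts[[nm]]$biomarkers,
                             config$varianceThreshold)
      thr <- adjustedThreshold(config$alpha, nEff)
      thresholds[[nm]] <- list(nEff = nEff, threshold = thr)
      for (method in c("std", "cms")) {
        key <- paste0(nm, "_", method)
        tab <- assoc[[key]]
        ids <- assignBlocks(tab$chrom, tab$pos, blocks)
        lead <- leadSnpPerBlock(tab, ids)
        called <- callSignificant(lead, thr,
                                  biomarkerGroups(cohorts[[nm]]$biomarkers))
        leads[[key]] <- called$table
        .writeTsv(called$table, file.path(out, paste0("leads_", key, ".tsv")))
      }
    }
    jsonlite::write_json(thresholds, file.path(out, "thresholds.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    finishStage("region_summary", t0)
    writeManifest()

    ## cohort comparison ------------------------------------------------
    stage <- "cohort_compare"
    t0 <- Sys.time()
    adj <- winnersCurseAdjust(assoc$case_cms, config$wcThreshold,
                              config$wcBoot, deriveSeed(config$seed, "wc"))
    writeAssociations(adj, file.path(out, "assoc_case_cms_adjusted.tsv"))
    het <- heterogeneityTest(adj, assoc$control_cms)
    .writeTsv(het, file.path(out, "heterogeneity.tsv"))
    corr <- effectCorrelation(adj, assoc$control_cms,
                              biomarkerGroups(cohorts$case$biomarkers))
    jsonlite::write_json(corr, file.path(out, "correlation_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    finishStage("cohort_compare", t0)
    writeManifest()

    ## decomposition ----------------------------------------------------
    stage <- "degas"
    t0 <- Sys.time()
    dc <- config$degasCohort
    zm <- buildZMatrix(assoc[[paste0(dc, "_cms")]], config$degasPMax,
                       config$degasSeMax, cohorts[[dc]]$blocks)
    k <- min(config$degasK, dim(zm@W))
    dec <- tsvd(zm, k)
    ve <- varianceExplained(dec, zm)
    .writeTsv(ve, file.path(out, "degas_variance_explained.tsv"))
    .writeTsv(as.data.frame(factorScores(dec)),
              file.path(out, "degas_factor_scores.tsv"))
    .writeTsv(as.data.frame(contributionScores(dec, "biomarker")),
              file.path(out, "degas_contribution_biomarker.tsv"))
    .writeTsv(as.data.frame(squaredCosines(dec)),
              file.path(out, "degas_squared_cosines.tsv"))
    for (comp in seq_len(k)) {
      top <- topContributors(dec, comp, min(config$degasTopN, nrow(dec@V)))
      writeTopContributorsBed(top, file.path(
        out, sprintf("degas_top_contributors_c%02d.bed", comp)))
    }
    finishStage("degas", t0)
    manifest$status <- "ok"
    writeManifest()
    list(assoc = assoc, leads = leads, thresholds = thresholds,
         heterogeneity = het, correlation = corr, decomposition = dec,
         zMatrix = zm, varianceExplained = ve, manifest = manifest)
  }, error = function(e) {
    manifest$status <<- "failed"
    manifest$failedStage <<- stage
    manifest$error <<- conditionMessage(e)
    writeManifest()
    stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
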