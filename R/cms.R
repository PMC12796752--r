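#' CMS settings
#'
#' Tunables of the covariate-selection regression: the correlation
#' exclusion bound, the number of AIC-ranked candidate covariates retained,
#' the variance-explained exclusion rule, and the alpha of the
#' genotype-association (MANOVA + conditional) screen.
#'
#' @param rMax correlation exclusion bound (default 0.9, strict >).
#' @param topK number of candidates kept after AIC ranking (default 30).
#' @param maxVarExplained drop candidates whose univariate R-squared against
#'   the outcome exceeds this (default 0.70).
#' @param genotypeAssocAlpha alpha of the genotype-association screen
#'   (default 0.05).
#' @return A validated list of class \code{CMSSettings}.
#' @export
cmsSettings <- function(rMax = 0.9, topK = 30L, maxVarExplained = 0.70,
                        genotypeAssocAlpha = 0.05) {
  .assertProb(rMax, "rMax")
  .assertCount(topK, "topK")
  .assertProb(maxVarExplained, "maxVarExplained")
  .assertProb(genotypeAssocAlpha, "genotypeAssocAlpha", openLeft = TRUE)
  structure(list(rMax = rMax, topK = as.integer(topK),
                 maxVarExplained = maxVarExplained,
                 genotypeAssocAlpha = genotypeAssocAlpha),
            class = "CMSSettings")
}

# OLS of y on [1, g, X2]; returns the g coefficient with t-based inference.
# X2 may be NULL. Rows must already be complete.
.olsGenotypeEffect <- function(y, g, X2 = NULL) {
  X <- cbind(`(Intercept)` = 1, g = g, X2)
  n <- nrow(X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(drop, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  df <- n - ncol(X)
  if (df <= 0) stop("not enough complete observations", call. = FALSE)
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))[order(qrX$pivot), order(qrX$pivot), drop = FALSE]
  se <- sqrt(sigma2 * diag(XtXinv))
  tstat <- beta[2L] / se[2L]
  list(beta = unname(beta[2L]), se = unname(se[2L]),
       p = 2 * stats::pt(-abs(tstat), df), n = n, df = df)
}

.completeRows <- function(y, g, C = NULL, Yl = NULL) {
  ok <- !is.na(y) & !is.na(g)
  if (!is.null(C) && ncol(C)) ok <- ok & stats::complete.cases(C)
  if (!is.null(Yl) && ncol(Yl)) ok <- ok & stats::complete.cases(Yl)
  ok
}

.assocRecord <- function(snpId = NA_character_, chrom = NA_character_,
                         pos = NA_real_, biomarker, method, fit, covNames) {
  data.frame(snp_id = snpId, chrom = chrom, pos = pos, biomarker = biomarker,
             method = method, beta = fit$beta, se = fit$se, p = fit$p,
             n = fit$n, covariates = .covString(covNames),
             stringsAsFactors = FALSE)
}

#' Standard (STD) linear regression of one biomarker on one SNP
#'
#' Ordinary least squares of y on [1, g, C] over complete cases, reporting
#' the dosage coefficient with two-sided t inference (residual df).
#'
#' @param y transformed biomarker vector.
#' @param g minor-allele dosage vector.
#' @param C optional data.frame/matrix of confounders (always included,
#'   never screened).
#' @param snpId,biomarker identifiers stored in the record.
#' @return One-row association record data.frame (snp_id, chrom, pos,
#'   biomarker, method, beta, se, p, n, covariates).
#' @export
stdRegression <- function(y, g, C = NULL, snpId = NA_character_,
                          biomarker = NA_character_) {
  Cm <- if (is.null(C)) NULL else data.matrix(C)
  ok <- .completeRows(y, g, Cm)
  y <- y[ok]; g <- g[ok]
  if (!is.null(Cm)) Cm <- Cm[ok, , drop = FALSE]
  nC <- if (is.null(Cm)) 0L else ncol(Cm)
  if (length(y) < 2L + nC + 1L) stop("not enough complete observations")
  if (stats::var(g) == 0) stop("monomorphic in analysis set", call. = FALSE)
  fit <- .olsGenotypeEffect(y, g, Cm)
  .assocRecord(snpId = snpId, biomarker = biomarker, method = "STD",
               fit = fit, covNames = colnames(Cm))
}

#' AIC-ranked candidate covariates for one outcome biomarker
#'
#' From the biomarkers the correlation mask allows for outcome m, drops any
#' whose univariate R-squared against the outcome exceeds
#' \code{maxVarExplained}, ranks the rest by ascending AIC of the
#' univariate model outcome ~ candidate, and returns at most \code{topK}.
#'
#' @param m outcome biomarker id.
#' @param panel a (transformed) \linkS4class{BiomarkerPanel}.
#' @param mask logical matrix from \code{\link{biomarkerCorrelationMask}}.
#' @param settings a \code{\link{cmsSettings}} object.
#' @return Character vector of candidate biomarker ids, best first (may be
#'   empty).
#' @export
selectCandidateCovariates <- function(m, panel, mask,
                                      settings = cmsSettings()) {
  v <- panel@values
  stopifnot(m %in% colnames(v))
  cand <- colnames(v)[mask[m, ]]
  cand <- setdiff(cand, m)
  if (!length(cand)) return(character(0))
  y <- v[, m]
  stats <- vapply(cand, function(l) {
    x <- v[, l]
    ok <- !is.na(y) & !is.na(x)
    n <- sum(ok)
    if (n < 3L) return(c(r2 = NA_real_, aic = NA_real_))
    fit <- stats::lm(y[ok] ~ x[ok])
    c(r2 = summary(fit)$r.squared, aic = stats::AIC(fit))
  }, numeric(2))
  keep <- !is.na(stats["r2", ]) & stats["r2", ] <= settings$maxVarExplained
  cand <- cand[keep]
  if (!length(cand)) return(character(0))
  cand <- cand[order(stats["aic", keep])]
  utils::head(cand, settings$topK)
}

#' Screen out candidate covariates associated with the tested variant
#'
#' Stage 1: one-way MANOVA (Pillai) of the candidate set across genotype
#' classes; if non-significant at \code{genotypeAssocAlpha} all candidates
#' are kept. Otherwise candidates are dropped one at a time - each round
#' removing the candidate with the smallest univariate p against dosage -
#' and the joint test repeated until non-significant or the set is empty.
#' Covariates correlated with the variant would absorb genuine genetic
#' signal; this screen is what keeps the CMS estimate unbiased.
#'
#' @param candidates candidate biomarker ids (from
#'   \code{\link{selectCandidateCovariates}}).
#' @param g dosage vector.
#' @param panel the biomarker panel.
#' @param settings a \code{\link{cmsSettings}} object.
#' @return Retained candidate ids, in the original order.
#' @export
filterGenotypeAssociatedCovariates <- function(candidates, g, panel,
                                               settings = cmsSettings()) {
  if (!length(candidates)) return(character(0))
  v <- panel@values
  alpha <- settings$genotypeAssocAlpha
  pUni <- vapply(candidates, function(l) {
    x <- v[, l]
    ok2 <- !is.na(g) & !is.na(x)
    if (sum(ok2) < 4L || stats::var(g[ok2]) == 0) return(1)
    .olsGenotypeEffect(x[ok2], g[ok2])$p
  }, numeric(1))
  current <- candidates
  repeat {
    if (!length(current)) return(character(0))
    Ym <- v[, current, drop = FALSE]
    ok <- !is.na(g) & stats::complete.cases(Ym)
    gg <- g[ok]
    if (length(unique(gg)) < 2L) {
      warning("fewer than 2 genotype classes; genotype screen skipped")
      return(current)
    }
    pJoint <- .jointGenotypeP(Ym[ok, , drop = FALSE], gg)
    if (is.na(pJoint) || pJoint >= alpha) return(current)
    current <- current[-which.min(pUni[current])]
  }
}

# Joint test of candidate matrix across genotype classes: MANOVA (Pillai)
# for >= 2 responses, one-way ANOVA F for a single response. Returns NA
# (treated as non-significant, with a warning) when the fit is degenerate.
.jointGenotypeP <- function(Ym, g) {
  gf <- factor(g)
  out <- tryCatch({
    if (ncol(Ym) == 1L) {
      a <- stats::anova(stats::lm(Ym[, 1L] ~ gf))
      a[["Pr(>F)"]][1L]
    } else {
      fit <- stats::manova(Ym ~ gf)
      s <- summary(fit, test = "Pillai")$stats
      s[1L, "Pr(>F)"]
    }
  }, error = function(e) {
    warning("genotype screen joint test failed (", conditionMessage(e),
            "); candidates kept")
    NA_real_
  })
  out
}

#' CMS regression: OLS with selected proxy covariates
#'
#' Fits y ~ [1, g, C, Y_l] where Y_l are the screened covariate biomarkers.
#' With an empty covariate set this reduces exactly to
#' \code{\link{stdRegression}}.
#'
#' @inheritParams stdRegression
#' @param selectedCovariates biomarker ids that passed
#'   \code{\link{filterGenotypeAssociatedCovariates}}.
#' @param panel the biomarker panel supplying covariate columns.
#' @return One-row association record with method \code{"CMS"}.
#' @export
cmsRegression <- function(y, g, C = NULL, selectedCovariates = character(0),
                          panel = NULL, snpId = NA_character_,
                          biomarker = NA_character_) {
  Yl <- NULL
  if (length(selectedCovariates)) {
    stopifnot(!is.null(panel))
    Yl <- panel@values[, selectedCovariates, drop = FALSE]
  }
  Cm <- if (is.null(C)) NULL else data.matrix(C)
  ok <- .completeRows(y, g, Cm, Yl)
  y <- y[ok]; g <- g[ok]
  if (!is.null(Cm)) Cm <- Cm[ok, , drop = FALSE]
  if (!is.null(Yl)) Yl <- Yl[ok, , drop = FALSE]
  X2 <- cbind(Cm, Yl)
  nX <- if (is.null(X2)) 0L else ncol(X2)
  if (length(y) < 2L + nX + 1L) stop("not enough complete observations")
  if (stats::var(g) == 0) stop("monomorphic in analysis set", call. = FALSE)
  fit <- .olsGenotypeEffect(y, g, X2)
  .assocRecord(snpId = snpId, biomarker = biomarker, method = "CMS",
               fit = fit,
               covNames = c(colnames(Cm), selectedCovariates))
}

#' Run the metabolite GWAS over all SNP x biomarker pairs
#'
#' One association record per (SNP, biomarker) pair, complete-case per
#' pair. For CMS, candidate covariates are pre-selected once per outcome
#' biomarker (mask + variance rule + AIC ranking) and the
#' genotype-association screen is re-run for every pair. Per-pair failures
#' (e.g. monomorphic in the analysis set) are returned as flagged rows with
#' NA estimates rather than aborting the scan.
#'
#' @param genotypes QC'd \linkS4class{GenotypeMatrix}.
#' @param panel transformed \linkS4class{BiomarkerPanel}.
#' @param confounders data.frame of confounders (always included).
#' @param settings a \code{\link{cmsSettings}} object.
#' @param method \code{"STD"} or \code{"CMS"}.
#' @return Association table: one data.frame row per pair with columns
#'   snp_id, chrom, pos, biomarker, method, beta, se, p, n, covariates,
#'   note.
#' @export
runMGWAS <- function(genotypes, panel, confounders = NULL,
                     settings = cmsSettings(), method = c("STD", "CMS")) {
  method <- match.arg(method)
  d <- genotypes@dosage
  info <- genotypes@snpInfo
  v <- panel@values
  Cm <- if (is.null(confounders)) NULL else data.matrix(confounders)
  candidates <- NULL
  if (method == "CMS") {
    mask <- biomarkerCorrelationMask(panel, settings$rMax)
    candidates <- lapply(stats::setNames(nm = colnames(v)), function(m)
      selectCandidateCovariates(m, panel, mask, settings))
  }
  rows <- vector("list", ncol(d) * ncol(v))
  idx <- 0L
  for (j in seq_len(ncol(d))) {
    g <- d[, j]
    for (m in colnames(v)) {
      idx <- idx + 1L
      rec <- tryCatch({
        if (method == "STD") {
          r <- stdRegression(v[, m], g, Cm, snpId = info$snp_id[j],
                             biomarker = m)
        } else {
          sel <- filterGenotypeAssociatedCovariates(candidates[[m]], g,
                                                    panel, settings)
          r <- cmsRegression(v[, m], g, Cm, sel, panel,
                             snpId = info$snp_id[j], biomarker = m)
        }
        r$note <- ""
        r
      }, error = function(e) {
        data.frame(snp_id = info$snp_id[j], chrom = NA_character_,
                   pos = NA_real_, biomarker = m, method = method,
                   beta = NA_real_, se = NA_real_, p = NA_real_,
                   n = NA_integer_, covariates = "",
                   note = conditionMessage(e), stringsAsFactors = FALSE)
      })
      rec$chrom <- info$chrom[j]
      rec$pos <- info$pos[j]
      rows[[idx]] <- rec
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genomic inflation factor
#'
#' lambda = median of the 1-df chi-square quantiles of the p-values divided
#' by the null median 0.45494; lambda near 1 indicates a calibrated test.
#'
#' @param pValues numeric vector of p-values in (0, 1].
#' @return Positive scalar lambda.
#' @export
genomicInflation <- function(pValues) {
  pValues <- pValues[!is.na(pValues)]
  if (!length(pValues)) stop("no p-values")
  if (any(pValues <= 0 | pValues > 1)) stop("p-values must be in (0, 1]")
  chi <- stats::qchisq(pValues, df = 1L, lower.tail = FALSE)
  stats::median(chi) / stats::qchisq(0.5, df = 1L)
}
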