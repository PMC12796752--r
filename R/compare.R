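#' Winner's-curse adjustment by summary-statistic parametric bootstrap
#'
#' Effect sizes of variants selected for significance are biased away from
#' zero, worst in small cohorts. For each biomarker independently, the
#' bootstrap draws beta* ~ Normal(beta_hat, se^2) per record; for every
#' originally selected record the selection-conditional bias is estimated
#' as the mean of (beta* - beta_hat) over replicates in which the record is
#' again selected in the same direction (|beta*|/se beyond the z threshold
#' of \code{selectionThreshold}); that bias is subtracted from the
#' record's beta. Unselected records pass through unchanged, and se and p
#' are never altered.
#'
#' @param records association table carrying beta, se, p, biomarker.
#' @param selectionThreshold p-value threshold defining selection.
#' @param nBoot bootstrap replicates (>= 10; default 100).
#' @param seed RNG seed (deterministic output).
#' @return The input table plus a \code{beta_adjusted} column.
#' @export
winnersCurseAdjust <- function(records, selectionThreshold, nBoot = 100L,
                               seed = 1L) {
  if (nBoot < 10L) stop("nBoot must be >= 10")
  if (any(records$se <= 0, na.rm = TRUE)) stop("se must be positive")
  .assertProb(selectionThreshold, "selectionThreshold", openLeft = TRUE)
  zThr <- stats::qnorm(selectionThreshold / 2, lower.tail = FALSE)
  records$beta_adjusted <- records$beta
  withSeed(deriveSeed(seed, "winners-curse"), {
    for (bm in unique(records$biomarker)) {
      rows <- which(records$biomarker == bm & !is.na(records$p))
      if (!length(rows)) next
      beta <- records$beta[rows]
      se <- records$se[rows]
      selected <- records$p[rows] < selectionThreshold
      if (!any(selected)) next
      draws <- matrix(stats::rnorm(length(rows) * nBoot, mean = beta,
                                   sd = se),
                      nrow = length(rows), ncol = nBoot)
      for (i in which(selected)) {
        b <- draws[i, ]
        sel <- abs(b) / se[i] > zThr & sign(b) == sign(beta[i])
        if (any(sel))
          records$beta_adjusted[rows[i]] <- beta[i] - mean(b[sel] - beta[i])
      }
    }
  })
  records
}

#' Cochran's Q heterogeneity test for two cohorts
#'
#' Fixed-effect inverse-variance scheme: weights 1/se^2, pooled effect
#' sum(w b)/sum(w), Q = sum(w (b - pooled)^2), df = 1, p from the
#' chi-square survival function. For two studies Q reduces to
#' (b1 - b2)^2 / (se1^2 + se2^2).
#'
#' @param beta1,se1,beta2,se2 per-cohort effects and standard errors
#'   (vectorized).
#' @return data.frame with Q, df, p.
#' @export
cochranQ <- function(beta1, se1, beta2, se2) {
  if (any(c(se1, se2) <= 0, na.rm = TRUE)) stop("se must be positive")
  w1 <- 1 / se1^2
  w2 <- 1 / se2^2
  pooled <- (w1 * beta1 + w2 * beta2) / (w1 + w2)
  Q <- w1 * (beta1 - pooled)^2 + w2 * (beta2 - pooled)^2
  data.frame(Q = Q, df = 1L,
             p = stats::pchisq(Q, df = 1L, lower.tail = FALSE))
}

#' I-squared heterogeneity percentage
#'
#' Proportion of total variation attributable to between-group
#' heterogeneity: max(0, (Q - df) / Q) x 100; defined as 0 at Q = 0.
#'
#' @param Q Cochran's Q (>= 0).
#' @param df degrees of freedom (>= 1).
#' @return Percentage in [0, 100].
#' @export
iSquared <- function(Q, df = 1L) {
  stopifnot(all(Q >= 0, na.rm = TRUE), all(df >= 1))
  out <- ifelse(Q > 0, pmax(0, (Q - df) / Q) * 100, 0)
  unname(out)
}

#' Heterogeneity table across two cohorts
#'
#' Matches records on (snp_id, biomarker) and computes Q, df, p and
#' I-squared per pair. By default the first table's adjusted betas
#' (\code{beta_adjusted}, if present) are used for cohort 1 - matching the
#' convention of adjusting the small cohort before comparison - and raw
#' betas otherwise.
#'
#' @param records1,records2 association tables (cohort 1 is typically the
#'   small, winner's-curse-adjusted cohort).
#' @param useAdjusted use \code{beta_adjusted} of cohort 1 when available.
#' @return data.frame: snp_id, biomarker, beta1, se1, beta2, se2, Q, df,
#'   p_het, I2.
#' @export
heterogeneityTest <- function(records1, records2, useAdjusted = TRUE) {
  b1col <- if (useAdjusted && "beta_adjusted" %in% names(records1))
    "beta_adjusted" else "beta"
  m <- merge(records1[, c("snp_id", "biomarker", b1col, "se")],
             records2[, c("snp_id", "biomarker", "beta", "se")],
             by = c("snp_id", "biomarker"), suffixes = c("1", "2"))
  names(m)[names(m) == b1col] <- "beta1"
  names(m)[names(m) == "beta"] <- "beta2"
  q <- cochranQ(m$beta1, m$se1, m$beta2, m$se2)
  m$Q <- q$Q
  m$df <- q$df
  m$p_het <- q$p
  m$I2 <- iSquared(q$Q, q$df)
  m
}

#' Two-proportion z-test for minor allele frequency difference
#'
#' Pooled two-proportion z-test using cohort sizes (individual counts) as
#' denominators; two-sided p.
#'
#' @param maf1,n1 MAF and size of cohort 1.
#' @param maf2,n2 MAF and size of cohort 2.
#' @return data.frame with z and p.
#' @export
mafZTest <- function(maf1, n1, maf2, n2) {
  stopifnot(all(maf1 > 0 & maf1 < 1), all(maf2 > 0 & maf2 < 1),
            all(n1 >= 1), all(n2 >= 1))
  pooled <- (n1 * maf1 + n2 * maf2) / (n1 + n2)
  degenerate <- pooled <= 0 | pooled >= 1
  if (any(degenerate)) warning("degenerate pooled frequency; p set to 1")
  se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  z <- ifelse(degenerate, 0, (maf1 - maf2) / se)
  data.frame(z = z, p = ifelse(degenerate, 1, 2 * stats::pnorm(-abs(z))))
}

#' Chi-square test of genotype distribution between cohorts
#'
#' Pearson test of independence on the 2 x 3 table of genotype-class
#' counts (hom major / het / hom minor), dropping genotype classes absent
#' in both cohorts; no continuity correction. Expected cells below 1 set a
#' warning flag rather than aborting.
#'
#' @param counts 2 x 3 matrix (cohorts x genotype classes).
#' @return List with chi2, df, p, expectedBelow1 flag.
#' @export
genotypeChisq <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 2L, all(counts >= 0), all(rowSums(counts) > 0))
  keep <- colSums(counts) > 0
  counts <- counts[, keep, drop = FALSE]
  expd <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  chi2 <- sum((counts - expd)^2 / expd)
  df <- (nrow(counts) - 1L) * (ncol(counts) - 1L)
  list(chi2 = chi2, df = df,
       p = if (df >= 1L) stats::pchisq(chi2, df, lower.tail = FALSE) else 1,
       expectedBelow1 = any(expd < 1))
}

#' Cross-cohort effect-size correlation, overall and per biomarker group
#'
#' Pairs are matched on (snp_id, biomarker); Pearson correlation with
#' two-sided p is reported overall and per group. Groups with fewer than 3
#' shared pairs are skipped with a notice.
#'
#' @param records1,records2 association tables.
#' @param grouping optional named map biomarker id -> group label.
#' @param useAdjusted use \code{beta_adjusted} of cohort 1 when available.
#' @return List with \code{overall} (r, p, nPairs) and \code{byGroup}
#'   data.frame.
#' @export
effectCorrelation <- function(records1, records2, grouping = NULL,
                              useAdjusted = TRUE) {
  b1col <- if (useAdjusted && "beta_adjusted" %in% names(records1))
    "beta_adjusted" else "beta"
  m <- merge(records1[, c("snp_id", "biomarker", b1col)],
             records2[, c("snp_id", "biomarker", "beta")],
             by = c("snp_id", "biomarker"))
  names(m)[3:4] <- c("beta1", "beta2")
  m <- m[stats::complete.cases(m[, c("beta1", "beta2")]), , drop = FALSE]
  if (nrow(m) < 3L) stop("fewer than 3 shared (snp, biomarker) pairs")
  ct <- stats::cor.test(m$beta1, m$beta2)
  overall <- list(r = unname(ct$estimate), p = ct$p.value, nPairs = nrow(m))
  byGroup <- NULL
  if (!is.null(grouping)) {
    m$group <- grouping[m$biomarker]
    rows <- lapply(split(m, m$group), function(d) {
      if (nrow(d) < 3L) {
        message("group '", d$group[1L], "' skipped: fewer than 3 pairs")
        return(NULL)
      }
      ctg <- stats::cor.test(d$beta1, d$beta2)
      data.frame(group = d$group[1L], r = unname(ctg$estimate),
                 p = ctg$p.value, nPairs = nrow(d))
    })
    byGroup <- do.call(rbind, rows)
    rownames(byGroup) <- NULL
  }
  list(overall = overall, byGroup = byGroup)
}

#' Bonferroni-adjusted threshold
#'
#' @param alpha family-wise alpha.
#' @param nTests number of tests (>= 1).
#' @return alpha / nTests.
#' @export
bonferroniThreshold <- function(alpha, nTests) {
  .assertProb(alpha, "alpha", openLeft = TRUE)
  if (!is.numeric(nTests) || nTests < 1) stop("nTests must be >= 1")
  alpha / nTests
}
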