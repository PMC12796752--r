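#' Build the Z-scored summary matrix for decomposition
#'
#' Cells are z = beta/se per (biomarker, variant). Marginal effects with
#' p > \code{pMax} or se > \code{seMax} are censored (unreliable
#' estimates); variants censored across every biomarker are dropped; one
#' lead variant is retained per LD block (smallest p over all biomarkers,
#' ties by position then id); remaining missing cells are zero-filled and
#' each biomarker row is centered and scaled to unit variance. The
#' fill-then-standardize order follows the decomposition framework's
#' convention (censoring shrinks a biomarker's dense signal rather than
#' deleting rows); \code{standardizeBeforeFill} switches to the
#' alternative order.
#'
#' @param records association table with snp_id, chrom, pos, biomarker,
#'   beta, se, p.
#' @param pMax,seMax censoring thresholds (defaults 0.001 and 0.08).
#' @param blockMap optional \code{GRanges} block map for the lead-variant
#'   collapse; \code{NULL} keeps all variants.
#' @param standardizeBeforeFill standardize rows on the censored (NA)
#'   matrix before zero-filling instead of after (default FALSE).
#' @return A \linkS4class{DegasMatrix}.
#' @export
buildZMatrix <- function(records, pMax = 0.001, seMax = 0.08,
                         blockMap = NULL, standardizeBeforeFill = FALSE) {
  r <- records[!is.na(records$p) & !is.na(records$se), , drop = FALSE]
  r$z <- r$beta / r$se
  r$z[r$p > pMax | r$se > seMax] <- NA_real_
  if (!is.null(blockMap)) {
    vinfo <- unique(r[, c("snp_id", "chrom", "pos")])
    vinfo$block <- assignBlocks(vinfo$chrom, vinfo$pos, blockMap)
    vinfo$block <- ifelse(is.na(vinfo$block),
                          paste0("unassigned:", vinfo$snp_id), vinfo$block)
    best <- r[!is.na(r$z), c("snp_id", "p")]
    best <- merge(best, vinfo, by = "snp_id")
    best <- best[order(best$block, best$p, best$pos, best$snp_id), ]
    leadIds <- best$snp_id[!duplicated(best$block)]
    r <- r[r$snp_id %in% leadIds, , drop = FALSE]
  }
  bms <- unique(r$biomarker)
  snps <- unique(r[, c("snp_id", "chrom", "pos")])
  snps <- snps[order(snps$chrom, snps$pos, snps$snp_id), , drop = FALSE]
  W <- matrix(NA_real_, length(bms), nrow(snps),
              dimnames = list(bms, snps$snp_id))
  W[cbind(match(r$biomarker, bms), match(r$snp_id, snps$snp_id))] <- r$z
  keepVar <- colSums(!is.na(W)) > 0
  W <- W[, keepVar, drop = FALSE]
  snps <- snps[keepVar, , drop = FALSE]
  nOk <- rowSums(!is.na(W))
  if (any(nOk < 2L)) {
    warning("dropping biomarker row(s) with < 2 informative cells: ",
            paste(rownames(W)[nOk < 2L], collapse = ", "))
    W <- W[nOk >= 2L, , drop = FALSE]
  }
  stdRows <- function(M) {
    mu <- rowMeans(M, na.rm = TRUE)
    sd <- apply(M, 1L, stats::sd, na.rm = TRUE)
    if (any(sd == 0, na.rm = TRUE))
      stop("constant biomarker row(s) cannot be standardized: ",
           paste(rownames(M)[which(sd == 0)], collapse = ", "))
    (M - mu) / sd
  }
  if (standardizeBeforeFill) {
    W <- stdRows(W)
    W[is.na(W)] <- 0
  } else {
    W[is.na(W)] <- 0
    W <- stdRows(W)
  }
  keepVar2 <- colSums(abs(W)) > 0
  W <- W[, keepVar2, drop = FALSE]
  snps <- snps[keepVar2, , drop = FALSE]
  rownames(snps) <- NULL
  new("DegasMatrix", W = W, variantInfo = snps,
      filters = list(pMax = pMax, seMax = seMax,
                     collapsed = !is.null(blockMap),
                     standardizeBeforeFill = standardizeBeforeFill))
}

#' Truncated singular value decomposition of the summary matrix
#'
#' Rank-k SVD W ~ U diag(S) V' by dense LAPACK, truncated to the leading k
#' components; singular values sorted non-increasing. Deterministic sign
#' convention: the largest-magnitude entry of each U column is positive
#' (V flipped in step).
#'
#' @param W a \linkS4class{DegasMatrix} or plain numeric matrix.
#' @param k number of retained components (default 24).
#' @return A \linkS4class{DegasDecomposition}.
#' @export
tsvd <- function(W, k = 24L) {
  vinfo <- data.frame(snp_id = character(0), chrom = character(0),
                      pos = numeric(0))
  M <- W
  if (is(W, "DegasMatrix")) {
    M <- W@W
    vinfo <- W@variantInfo
  } else {
    vinfo <- data.frame(snp_id = colnames(M) %||% as.character(seq_len(ncol(M))),
                        chrom = NA_character_, pos = NA_real_)
  }
  k <- .assertCount(k, "k")
  if (k > min(dim(M)))
    stop("k = ", k, " exceeds min(dim(W)) = ", min(dim(M)))
  sv <- svd(M, nu = k, nv = k)
  U <- sv$u
  V <- sv$v
  S <- sv$d[seq_len(k)]
  for (j in seq_len(k)) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) {
      U[, j] <- -U[, j]
      V[, j] <- -V[, j]
    }
  }
  rownames(U) <- rownames(M)
  rownames(V) <- colnames(M) %||% vinfo$snp_id
  new("DegasDecomposition", U = U, S = S, V = V, k = k, variantInfo = vinfo)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Factor scores F = U diag(S)
#'
#' @param decomp a \linkS4class{DegasDecomposition}.
#' @param axis \code{"biomarker"} (U-side, default) or \code{"variant"}
#'   (V-side).
#' @return Entities x k matrix of factor scores.
#' @export
factorScores <- function(decomp, axis = c("biomarker", "variant")) {
  axis <- match.arg(axis)
  M <- if (axis == "biomarker") decomp@U else decomp@V
  sweep(M, 2L, decomp@S, `*`)
}

#' Contribution scores: squared singular-vector entries
#'
#' Each entity's share of one component; per component, contributions sum
#' to 1 by column orthonormality.
#'
#' @inheritParams factorScores
#' @return Entities x k matrix of contribution scores.
#' @export
contributionScores <- function(decomp, axis = c("biomarker", "variant")) {
  axis <- match.arg(axis)
  M <- if (axis == "biomarker") decomp@U else decomp@V
  M^2
}

#' Squared cosine scores: a component's share of one entity's signal
#'
#' Squared factor scores normalized across the k retained components; rows
#' sum to 1. All-zero factor-score rows are undefined and reported as NA.
#'
#' @inheritParams factorScores
#' @return Entities x k matrix; rows sum to 1 (or are all NA).
#' @export
squaredCosines <- function(decomp, axis = c("biomarker", "variant")) {
  f2 <- factorScores(decomp, axis)^2
  tot <- rowSums(f2)
  out <- f2 / tot
  out[tot == 0, ] <- NA_real_
  out
}

#' Variance explained per component
#'
#' s_k^2 / ||W||_F^2 per component plus the cumulative sum.
#'
#' @param decomp a \linkS4class{DegasDecomposition}.
#' @param W the decomposed \linkS4class{DegasMatrix} (or matrix).
#' @return data.frame with component, proportion, cumulative.
#' @export
varianceExplained <- function(decomp, W) {
  M <- if (is(W, "DegasMatrix")) W@W else W
  tot <- sum(M^2)
  if (tot == 0) stop("zero matrix has no variance to explain")
  prop <- decomp@S^2 / tot
  data.frame(component = seq_along(prop), proportion = prop,
             cumulative = cumsum(prop))
}

#' Top contributing variants of one component
#'
#' Variants ranked by descending contribution score (squared V entry) for
#' the chosen component, ties broken by variant id.
#'
#' @param decomp a \linkS4class{DegasDecomposition}.
#' @param component component index in 1..k.
#' @param n number of variants to return (default 5000); if larger than
#'   the variant count, all are returned with a notice.
#' @return data.frame: rank, snp_id, chrom, pos, score.
#' @export
topContributors <- function(decomp, component, n = 5000L) {
  stopifnot(component >= 1L, component <= decomp@k)
  score <- decomp@V[, component]^2
  info <- decomp@variantInfo
  o <- order(-score, info$snp_id)
  if (n > length(score)) {
    message("n exceeds variant count; returning all ", length(score),
            " variants")
    n <- length(score)
  }
  o <- o[seq_len(n)]
  data.frame(rank = seq_len(n), snp_id = info$snp_id[o],
             chrom = info$chrom[o], pos = info$pos[o],
             score = unname(score[o]), stringsAsFactors = FALSE)
}

#' Export top contributors as BED
#'
#' 0-based half-open single-base intervals with the contribution score in
#' column 5 (full precision; downstream enrichment tools consume the
#' regions).
#'
#' @param top data.frame from \code{\link{topContributors}}.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeTopContributorsBed <- function(top, path) {
  bed <- data.frame(chrom = top$chrom, start = top$pos,
                    end = top$pos + 1, name = top$snp_id,
                    score = top$score)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
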