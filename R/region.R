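#' @importFrom GenomicRanges GRanges findOverlaps seqnames start end
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols queryHits subjectHits
NULL

#' Build an LD-block map
#'
#' Blocks are half-open 0-based intervals [start, end) per chromosome,
#' non-overlapping and sorted, each with a unique id. Internally stored as
#' a \code{GRanges} (1-based closed, converted at the boundary) with a
#' \code{blockId} metadata column.
#'
#' @param chrom,start,end,blockId parallel vectors (start/end 0-based
#'   half-open).
#' @return A \code{GRanges} block map.
#' @export
ldBlockMap <- function(chrom, start, end, blockId) {
  if (any(end <= start)) stop("malformed block map: end must exceed start")
  if (anyDuplicated(blockId)) stop("malformed block map: duplicate block ids")
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  S4Vectors::mcols(gr)$blockId <- as.character(blockId)
  gr <- gr[order(as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr))]
  self <- GenomicRanges::findOverlaps(gr, drop.self = TRUE)
  if (length(self) > 0L)
    stop("malformed block map: overlapping intervals")
  gr
}

#' Derive the block map from simulated SNP metadata
#'
#' Each block's interval spans its SNP positions, [min pos, max pos + 1).
#'
#' @param snpInfo per-SNP metadata with \code{chrom}, \code{pos} (0-based)
#'   and \code{block}.
#' @return A \code{GRanges} block map.
#' @export
blockMapFromSnpInfo <- function(snpInfo) {
  sp <- split(snpInfo, snpInfo$block)
  sp <- sp[unique(snpInfo$block)]
  ldBlockMap(chrom = vapply(sp, function(x) x$chrom[1L], character(1)),
             start = vapply(sp, function(x) min(x$pos), numeric(1)),
             end = vapply(sp, function(x) max(x$pos) + 1, numeric(1)),
             blockId = names(sp))
}

#' Read / write a block map as BED
#'
#' Plain 4-column BED: chrom, 0-based start, half-open end, block id.
#'
#' @param path file path.
#' @return \code{readBlockMap}: a \code{GRanges} block map.
#' @export
readBlockMap <- function(path) {
  if (!file.exists(path)) stop("block BED not found: ", path)
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 4L) stop("block BED needs 4 columns: ", path)
  ldBlockMap(bed[[1L]], bed[[2L]], bed[[3L]], bed[[4L]])
}

#' @rdname readBlockMap
#' @param blockMap a \code{GRanges} block map.
#' @export
writeBlockMap <- function(blockMap, path) {
  bed <- data.frame(chrom = as.character(GenomicRanges::seqnames(blockMap)),
                    start = GenomicRanges::start(blockMap) - 1L,
                    end = GenomicRanges::end(blockMap),
                    name = S4Vectors::mcols(blockMap)$blockId)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Assign SNPs to LD blocks
#'
#' Half-open convention: a 0-based position p belongs to block [start, end)
#' iff start <= p < end. Positions outside every block get the sentinel
#' \code{NA}.
#'
#' @param chrom,pos parallel vectors of SNP chromosome and 0-based position.
#' @param blockMap a \code{GRanges} block map.
#' @return Character vector of block ids (\code{NA} = unassigned).
#' @export
assignBlocks <- function(chrom, pos, blockMap) {
  snps <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, width = 1L))
  hit <- GenomicRanges::findOverlaps(snps, blockMap, select = "first")
  S4Vectors::mcols(blockMap)$blockId[hit]
}

#' Lead SNP per (block, biomarker)
#'
#' The most significant SNP within each region represents that block for
#' each biomarker. Ties are broken by smaller position, then lexicographic
#' snp_id. SNPs outside every block each form their own singleton block
#' (\code{unassigned:<snp_id>}). Flagged rows (NA p) are ignored.
#'
#' @param records association table (dialect of \code{\link{runMGWAS}}).
#' @param blockIds block id per record row (e.g. from
#'   \code{\link{assignBlocks}} matched on snp_id).
#' @return Lead table: the winning record per (block_id, biomarker) plus
#'   \code{block_id} and \code{n_snps_in_block}.
#' @export
leadSnpPerBlock <- function(records, blockIds) {
  stopifnot(length(blockIds) == nrow(records))
  records$block_id <- ifelse(is.na(blockIds),
                             paste0("unassigned:", records$snp_id), blockIds)
  ok <- !is.na(records$p)
  r <- records[ok, , drop = FALSE]
  o <- order(r$block_id, r$biomarker, r$p, r$pos, r$snp_id)
  r <- r[o, , drop = FALSE]
  lead <- r[!duplicated(r[, c("block_id", "biomarker")]), , drop = FALSE]
  cnt <- stats::aggregate(snp_id ~ block_id + biomarker, data = r,
                          FUN = function(x) length(unique(x)))
  names(cnt)[3L] <- "n_snps_in_block"
  out <- merge(lead, cnt, by = c("block_id", "biomarker"), sort = FALSE)
  rownames(out) <- NULL
  out[order(out$block_id, out$biomarker), , drop = FALSE]
}

#' Effective number of independent biomarker tests
#'
#' Smallest number of principal components of the biomarker correlation
#' matrix whose eigenvalues account for at least \code{varianceThreshold}
#' of total variance. Correlated traits share components, so this count
#' relaxes the Bonferroni burden relative to the raw trait count.
#'
#' @param panel a \linkS4class{BiomarkerPanel}.
#' @param varianceThreshold cumulative variance target (default 0.99).
#' @return Integer count of effective tests.
#' @export
effectiveTests <- function(panel, varianceThreshold = 0.99) {
  v <- panel@values
  if (ncol(v) < 2L) return(ncol(v))
  cc <- stats::complete.cases(v)
  R <- if (sum(cc) >= ncol(v)) stats::cor(v[cc, , drop = FALSE])
       else suppressWarnings(stats::cor(v, use = "pairwise.complete.obs"))
  R[!is.finite(R)] <- 0
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  cum <- cumsum(ev) / sum(ev)
  as.integer(which(cum >= varianceThreshold)[1L])
}

#' Effective-test-adjusted significance threshold
#'
#' @param alpha base genome-wide threshold (default 5e-8).
#' @param nEff effective number of tests (>= 1).
#' @return alpha / nEff.
#' @export
adjustedThreshold <- function(alpha = 5e-8, nEff) {
  .assertProb(alpha, "alpha", openLeft = TRUE)
  if (!is.numeric(nEff) || nEff < 1) stop("nEff must be >= 1")
  alpha / nEff
}

#' Flag significant lead associations
#'
#' Strict comparison p < threshold; summary counts per biomarker group when
#' a grouping is supplied.
#'
#' @param leads lead table from \code{\link{leadSnpPerBlock}}.
#' @param threshold significance threshold.
#' @param groups optional named map biomarker id -> group label.
#' @return List with \code{table} (leads + \code{significant} flag) and
#'   \code{counts} (total and, if grouped, per-group significant counts).
#' @export
callSignificant <- function(leads, threshold, groups = NULL) {
  leads$significant <- !is.na(leads$p) & leads$p < threshold
  counts <- list(total = sum(leads$significant))
  if (!is.null(groups)) {
    g <- groups[leads$biomarker]
    tab <- table(g[leads$significant])
    counts$byGroup <- as.list(tab)
  }
  list(table = leads, counts = counts)
}
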