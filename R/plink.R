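#' Write a GenotypeMatrix as a PLINK 1 bed/bim/fam triple
#'
#' Variant-major .bed (magic 0x6c 0x1b 0x01, 2 bits per genotype, 4
#' individuals per byte). A1 in the .bim is the minor allele; dosage d
#' (minor-allele count) maps to the codes hom-A1 (d = 2), het (d = 1),
#' hom-A2 (d = 0), missing (NA). Positions are written 1-based in the
#' .bim (the only 1-based boundary of the package).
#'
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param prefix path prefix; .bed/.bim/.fam are appended.
#' @return The prefix, invisibly.
#' @export
writePlink <- function(genotypes, prefix) {
  d <- genotypes@dosage
  info <- genotypes@snpInfo
  n <- nrow(d)
  ids <- rownames(d) %||% sprintf("ind%05d", seq_len(n))
  fam <- data.frame(fid = ids, iid = ids, pat = 0L, mat = 0L,
                    sex = 0L, pheno = -9L)
  tryCatch({
    utils::write.table(fam, paste0(prefix, ".fam"), sep = " ",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    bim <- data.frame(chrom = sub("^chr", "", info$chrom), snp = info$snp_id,
                      cm = 0, pos = info$pos + 1L, a1 = info$a1, a2 = info$a2)
    utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    # codes per individual: 0 -> 3 (hom A2), 1 -> 2 (het), 2 -> 0 (hom A1),
    # NA -> 1 (missing); packed little-endian 4 per byte, variant-major
    codes <- matrix(3L, n, ncol(d))
    codes[!is.na(d) & d == 1] <- 2L
    codes[!is.na(d) & d == 2] <- 0L
    codes[is.na(d)] <- 1L
    nBytes <- ceiling(n / 4)
    pad <- nBytes * 4L - n
    if (pad > 0) codes <- rbind(codes, matrix(0L, pad, ncol(d)))
    shift <- rep(c(1L, 4L, 16L, 64L), nBytes)
    grp <- rep(seq_len(nBytes), each = 4L)
    bytes <- vapply(seq_len(ncol(d)), function(j)
      as.raw(rowsum(codes[, j] * shift, grp)[, 1L]),
      raw(nBytes))
    con <- file(paste0(prefix, ".bed"), "wb")
    on.exit(close(con))
    writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
    writeBin(as.vector(bytes), con)
  }, error = function(e)
    stop("failed writing PLINK files at '", prefix, "': ",
         conditionMessage(e), call. = FALSE))
  invisible(prefix)
}

# 256 x 4 lookup: byte value -> four 2-bit plink codes -> dosages
.plinkByteLookup <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      m <- matrix(NA_real_, 256L, 4L)
      map <- c(`0` = 2, `1` = NA, `2` = 1, `3` = 0)  # code -> minor dosage
      for (b in 0:255) {
        codes <- bitwAnd(bitwShiftR(b, c(0L, 2L, 4L, 6L)), 3L)
        m[b + 1L, ] <- map[as.character(codes)]
      }
      tab <<- m
    }
    tab
  }
})

#' Read a PLINK 1 bed/bim/fam triple
#'
#' Minor-allele dosage orientation is enforced: when the stated A1 has
#' sample frequency above 0.5 the SNP's dosages are flipped (d -> 2 - d),
#' alleles swapped, and the flip recorded in the returned object's
#' \code{flipped} attribute on \code{snpInfo}.
#'
#' @param prefix path prefix of the triple.
#' @param flipToMinor enforce minor-allele orientation (default TRUE).
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
readPlink <- function(prefix, flipToMinor = TRUE) {
  for (ext in c(".bed", ".bim", ".fam"))
    if (!file.exists(paste0(prefix, ext)))
      stop("missing PLINK file: ", prefix, ext)
  fam <- utils::read.table(paste0(prefix, ".fam"), stringsAsFactors = FALSE,
                           colClasses = "character")
  bim <- utils::read.table(paste0(prefix, ".bim"), stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  n <- nrow(fam)
  p <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), what = "raw",
                 n = file.info(paste0(prefix, ".bed"))$size)
  if (length(raw) < 3L || raw[1L] != 0x6c || raw[2L] != 0x1b)
    stop("not a PLINK bed file: ", prefix, ".bed")
  if (raw[3L] != 0x01) stop("only variant-major bed supported")
  body <- raw[-(1:3)]
  nBytes <- ceiling(n / 4)
  if (length(body) != nBytes * p)
    stop(sprintf("bed size mismatch at '%s': %d bytes for %d individuals x %d variants (expected %d)",
                 prefix, length(body), n, p, nBytes * p))
  lookup <- .plinkByteLookup()
  vals <- lookup[as.integer(body) + 1L, , drop = FALSE]
  d <- matrix(t(vals), nrow = nBytes * 4L, ncol = p)[seq_len(n), , drop = FALSE]
  rownames(d) <- fam[[2L]]
  info <- data.frame(snp_id = as.character(bim[[2L]]),
                     chrom = paste0("chr", bim[[1L]]),
                     pos = bim[[4L]] - 1L,
                     a1 = as.character(bim[[5L]]),
                     a2 = as.character(bim[[6L]]),
                     block = NA_character_, stringsAsFactors = FALSE)
  flipped <- rep(FALSE, p)
  if (flipToMinor) {
    f <- colMeans(d, na.rm = TRUE) / 2
    flip <- !is.na(f) & f > 0.5
    if (any(flip)) {
      d[, flip] <- 2 - d[, flip]
      tmp <- info$a1[flip]
      info$a1[flip] <- info$a2[flip]
      info$a2[flip] <- tmp
      flipped <- flip
      message(sum(flip), " SNP(s) flipped to minor-allele orientation")
    }
  }
  gm <- GenotypeMatrix(d, info)
  attr(gm@snpInfo, "flipped") <- flipped
  gm
}
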