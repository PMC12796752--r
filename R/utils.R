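#' Derive a stage-specific seed from a root seed
#'
#' One root seed governs a whole run; per-stage streams are derived by stable
#' hashing of a stage tag so that stages are reproducible independently of
#' each other and of evaluation order.
#'
#' @param seed integer root seed.
#' @param tag character stage tag, e.g. \code{"geno-case"}.
#' @return An integer seed in \code{[0, 2^31 - 2]}.
#' @export
deriveSeed <- function(seed, tag) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(tag), length(tag) == 1L)
  codes <- utf8ToInt(tag)
  h <- 0
  for (k in seq_along(codes)) h <- (h * 131 + codes[k]) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483647)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Small argument checkers -----------------------------------------------------

.assertProb <- function(x, name, openLeft = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (openLeft && x <= 0) || (!openLeft && x < 0) || x > 1)
    stop(sprintf("'%s' must be a probability in %s", name,
                 if (openLeft) "(0, 1]" else "[0, 1]"), call. = FALSE)
  invisible(x)
}

.assertCount <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}

# Comma-joined covariate label used in the association TSV dialect
.covString <- function(ids) if (length(ids) == 0L) "" else paste(ids, collapse = ",")

.covCount <- function(s) {
  if (is.na(s) || !nzchar(s)) 0L else length(strsplit(s, ",", fixed = TRUE)[[1L]])
}
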