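## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive an independent sub-seed from a master seed.
#'
#' Each generator draws from its own stream so that adding a generator
#' does not perturb the draws of the others. Kept below 2^31 - 1.
#' @noRd
derive_seed <- function(seed, stream) {
  s <- (as.numeric(seed) %% 2147483647) * 7919 + 104729 * as.numeric(stream)
  as.integer(s %% 2147483646) + 1L
}

#' log2 ratio of two non-negative signals with zero-protection.
#'
#' The pseudocount is added to numerator and denominator only where either
#' is zero, so exact ratios are preserved wherever both values are positive
#' and 0/0 maps to log2(1) = 0.
#' @noRd
log2_ratio_values <- function(num, den, pseudocount = 1) {
  zero <- num <= 0 | den <= 0
  num[zero] <- num[zero] + pseudocount
  den[zero] <- den[zero] + pseudocount
  log2(num / den)
}

#' Write a data frame as TSV with provenance header comments.
#' @noRd
write_tsv_header <- function(df, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by write_tsv_header (comment lines skipped).
#' @noRd
read_tsv_header <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Stable md5 of an R object (used for config hashes in output headers).
#' @noRd
object_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  ## dput gives a text serialization independent of R version internals
  dput(x, file = f)
  unname(tools::md5sum(f))
}

opposite_strand <- function(strand) {
  out <- ifelse(strand == "+", "-", "+")
  out[!strand %in% c("+", "-")] <- NA_character_
  out
}

check_strand <- function(strand) {
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'", call. = FALSE)
  strand
}
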