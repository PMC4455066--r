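#' Strand-specific signal container
#'
#' Dense per-base values on the forward and reverse strand of each
#' chromosome. Two modes are supported: `"coverage"` (non-negative read
#' coverage or abundance) and `"log2_ratio"` (signed log2 mutant/WT or
#' IP/input ratios).
#'
#' @param chromosomes named numeric vector of chromosome lengths.
#' @param mode `"coverage"` or `"log2_ratio"`.
#' @return A `StrandedSignal`: list with `values[[chrom]][[strand]]`
#'   numeric vectors (length = chromosome length, initialized to 0) and a
#'   `mode` flag.
#' @export
stranded_signal <- function(chromosomes, mode = c("coverage", "log2_ratio")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(chromosomes), !is.null(names(chromosomes)))
  values <- lapply(chromosomes, function(len) {
    list("+" = numeric(len), "-" = numeric(len))
  })
  structure(list(values = values, mode = mode,
                 chromosomes = chromosomes),
            class = "StrandedSignal")
}

#' @export
print.StrandedSignal <- function(x, ...) {
  cat("StrandedSignal (", x$mode, "): ",
      length(x$chromosomes), " chromosome(s), ",
      format(sum(x$chromosomes), big.mark = ","), " bp/strand\n", sep = "")
  invisible(x)
}

signal_values <- function(signal, chrom, strand) {
  check_strand(strand)
  v <- signal$values[[chrom]]
  if (is.null(v)) stop("unknown chromosome: ", chrom)
  v[[strand]]
}

`signal_values<-` <- function(signal, chrom, strand, value) {
  signal$values[[chrom]][[strand]] <- value
  signal
}

#' Add a constant over an interval of a stranded signal
#' @noRd
signal_add <- function(signal, chrom, strand, start, end, value) {
  if (end <= start) return(signal)
  len <- signal$chromosomes[[chrom]]
  start <- max(start, 0); end <- min(end, len)
  if (end <= start) return(signal)
  idx <- (start + 1):end
  signal$values[[chrom]][[strand]][idx] <-
    signal$values[[chrom]][[strand]][idx] + value
  signal
}

#' Mean signal over a genomic interval
#'
#' Arithmetic mean of the per-base values over the 0-based half-open
#' interval `[start, end)` on one strand.
#'
#' @param signal a `StrandedSignal` (per-base).
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param start,end interval bounds, 0-based half-open.
#' @return mean value (numeric scalar).
#' @export
mean_signal <- function(signal, chrom, strand, start, end) {
  len <- signal$chromosomes[[chrom]]
  if (is.null(len)) stop("unknown chromosome: ", chrom)
  if (end <= start) stop("empty interval [", start, ", ", end, ")")
  if (start < 0 || end > len) stop("interval outside chromosome bounds")
  mean(signal$values[[chrom]][[strand]][(start + 1):end])
}

#' Read a pair of bedGraph files into a stranded signal
#'
#' One bedGraph per strand. Positions not covered by any interval are 0.
#' Overlapping intervals within one file are rejected as ambiguous: input
#' tracks are expected to partition the covered positions.
#'
#' @param path_fwd,path_rev bedGraph files for the forward and reverse
#'   strand.
#' @param annotation a `GenomeAnnotation` supplying chromosome lengths.
#' @param mode signal mode of the resulting object.
#' @return a `StrandedSignal`.
#' @export
read_stranded_signal <- function(path_fwd, path_rev, annotation,
                                 mode = c("coverage", "log2_ratio")) {
  mode <- match.arg(mode)
  sig <- stranded_signal(annotation$chromosomes, mode)
  for (side in list(list(path = path_fwd, strand = "+"),
                    list(path = path_rev, strand = "-"))) {
    gr <- rtracklayer::import(side$path, format = "bedGraph")
    if (!length(gr)) next
    chroms <- as.character(GenomicRanges::seqnames(gr))
    bad <- !chroms %in% names(annotation$chromosomes)
    if (any(bad)) stop("bedGraph interval on unknown chromosome: ",
                       paste(unique(chroms[bad]), collapse = ", "))
    if (any(GenomicRanges::end(gr) > annotation$chromosomes[chroms]) ||
        any(GenomicRanges::start(gr) < 1))
      stop("bedGraph interval beyond chromosome length")
    red <- GenomicRanges::reduce(gr)
    if (sum(GenomicRanges::width(red)) < sum(GenomicRanges::width(gr)))
      stop("overlapping bedGraph intervals in ", side$path,
           " (ambiguous value)")
    for (k in seq_along(gr)) {
      ch <- chroms[k]
      idx <- GenomicRanges::start(gr)[k]:GenomicRanges::end(gr)[k]
      sig$values[[ch]][[side$strand]][idx] <- gr$score[k]
    }
  }
  if (mode == "coverage") {
    neg <- any(vapply(sig$values, function(v)
      any(v[["+"]] < 0) || any(v[["-"]] < 0), logical(1)))
    if (neg) stop("negative values in coverage-mode signal")
  }
  sig
}

#' Write a stranded signal as a pair of bedGraph files
#'
#' Zero runs are omitted, so `read_stranded_signal()` on the output
#' reconstructs the signal exactly.
#'
#' @param signal a `StrandedSignal`.
#' @param path_fwd,path_rev output files (forward / reverse strand).
#' @return invisibly, `c(path_fwd, path_rev)`.
#' @export
write_stranded_signal <- function(signal, path_fwd, path_rev) {
  write_one <- function(strand, path) {
    rows <- list()
    for (ch in names(signal$values)) {
      v <- signal$values[[ch]][[strand]]
      r <- rle(v)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths       # 0-based
      keep <- r$values != 0
      if (any(keep)) {
        rows[[ch]] <- data.frame(chrom = ch, start = starts[keep],
                                 end = ends[keep], value = r$values[keep])
      }
    }
    df <- if (length(rows)) do.call(rbind, rows)
          else data.frame(chrom = character(), start = numeric(),
                          end = numeric(), value = numeric())
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    path
  }
  write_one("+", path_fwd)
  write_one("-", path_rev)
  invisible(c(path_fwd, path_rev))
}

#' Per-base log2 ratio of two coverage signals
#'
#' Builds a `log2_ratio`-mode signal `log2(num/den)` position by position.
#' Where either signal is zero a pseudocount is added to both channels, so
#' exact ratios are preserved wherever both are positive and positions
#' covered in neither channel map to 0.
#'
#' @param num,den coverage-mode `StrandedSignal`s on the same chromosomes
#'   (e.g. mutant and WT, or IP and input).
#' @param pseudocount value added to both channels at zero positions.
#' @return a `StrandedSignal` in `log2_ratio` mode.
#' @export
log2_ratio_signal <- function(num, den, pseudocount = 1) {
  stopifnot(identical(num$chromosomes, den$chromosomes),
            num$mode == "coverage", den$mode == "coverage")
  out <- stranded_signal(num$chromosomes, "log2_ratio")
  for (ch in names(out$values)) {
    for (st in c("+", "-")) {
      out$values[[ch]][[st]] <- log2_ratio_values(
        num$values[[ch]][[st]], den$values[[ch]][[st]], pseudocount)
    }
  }
  out
}

#' Scale every value of a signal by a constant
#' @noRd
signal_scale <- function(signal, factor) {
  for (ch in names(signal$values)) {
    signal$values[[ch]][["+"]] <- signal$values[[ch]][["+"]] * factor
    signal$values[[ch]][["-"]] <- signal$values[[ch]][["-"]] * factor
  }
  signal
}
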