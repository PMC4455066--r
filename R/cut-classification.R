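#' CUT class intervals for every gene
#'
#' Cryptic unstable transcripts (CUTs) fall into three positional classes
#' relative to an annotated gene: PROMPTs (promoter upstream transcripts,
#' antisense, initiating near the TSS), antisense (AS) transcripts over
#' the gene body, and short 3' intergenic transcripts (3'IGTs) on the
#' sense strand downstream of the TTS. This derives the three intervals
#' for each gene purely from annotation-relative position.
#'
#' For a forward-strand gene `[s, e)`: PROMPT = reverse strand
#' `[s - w, s)`, AS = reverse strand `[s, e)`, IGT3 = forward strand
#' `[e, e + w)`; mirrored for reverse-strand genes. Intervals are clipped
#' at chromosome bounds.
#'
#' @param ann a `GenomeAnnotation`.
#' @param w_bp window length for the PROMPT and 3'IGT intervals (default
#'   500 bp; see the methods vignette for the rationale).
#' @return A `TranscriptClassMap`: data frame with columns `gene`,
#'   `class` (`"PROMPT"`, `"AS"`, `"IGT3"`), `chrom`, `strand`, `start`,
#'   `end`; rows with empty clipped intervals are dropped. The window is
#'   recorded in `attr(, "w_bp")`.
#' @export
classify_cut_intervals <- function(ann, w_bp = 500) {
  stopifnot(w_bp >= 0)
  g <- ann$genes
  len <- ann$chromosomes[g$chrom]
  fwd <- g$strand == "+"
  prompt <- data.frame(
    gene = g$id, class = "PROMPT", chrom = g$chrom,
    strand = opposite_strand(g$strand),
    start = ifelse(fwd, g$start - w_bp, g$end),
    end = ifelse(fwd, g$start, g$end + w_bp))
  as_int <- data.frame(
    gene = g$id, class = "AS", chrom = g$chrom,
    strand = opposite_strand(g$strand),
    start = g$start, end = g$end)
  igt3 <- data.frame(
    gene = g$id, class = "IGT3", chrom = g$chrom, strand = g$strand,
    start = ifelse(fwd, g$end, g$start - w_bp),
    end = ifelse(fwd, g$end + w_bp, g$start))
  out <- rbind(prompt, as_int, igt3)
  lens <- ann$chromosomes[out$chrom]
  out$start <- pmax(out$start, 0)
  out$end <- pmin(out$end, lens)
  out <- out[out$end > out$start, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, w_bp = w_bp, class = c("TranscriptClassMap", "data.frame"))
}

#' Gene-selection criteria for composite profiling
#'
#' Composite profiles only use genes whose flanks are uncontaminated by
#' neighbouring transcription: a minimum strand-relative intergenic gap is
#' required on each side. The sense analysis requires a wide 3' gap (the
#' 3' flank is profiled), the antisense analysis a wide 5' gap.
#'
#' @param min_gap_3prime_bp,min_gap_5prime_bp minimum intergenic distance
#'   (bp) to the nearest neighbouring gene in the 3' / 5' direction.
#' @return a `SelectionCriteria` list.
#' @export
selection_criteria <- function(min_gap_3prime_bp = 600,
                               min_gap_5prime_bp = 100) {
  stopifnot(min_gap_3prime_bp >= 0, min_gap_5prime_bp >= 0)
  structure(list(min_gap_3prime_bp = min_gap_3prime_bp,
                 min_gap_5prime_bp = min_gap_5prime_bp),
            class = "SelectionCriteria")
}

#' Intergenic gaps of every gene, strand-relative
#'
#' Distance from each gene boundary to the nearest neighbouring gene
#' boundary (by default on either strand; the filter's purpose is an
#' uncontaminated flank signal, which any overlapping neighbour would
#' spoil). A neighbour overlapping the boundary gives gap 0; no neighbour
#' on a side gives `Inf`.
#'
#' @param ann a `GenomeAnnotation`.
#' @param neighbours `"both"` (default) or `"same"`: which strands count
#'   as neighbours.
#' @return data frame with columns `id`, `gap5`, `gap3` (bp).
#' @export
intergenic_gaps <- function(ann, neighbours = c("both", "same")) {
  neighbours <- match.arg(neighbours)
  g <- ann$genes
  n <- nrow(g)
  gap_left <- gap_right <- rep(Inf, n)
  for (i in seq_len(n)) {
    same_chrom <- g$chrom == g$chrom[i]
    other <- same_chrom & seq_len(n) != i
    if (neighbours == "same") other <- other & g$strand == g$strand[i]
    if (!any(other)) next
    s <- g$start[i]; e <- g$end[i]
    lf <- other & g$start < s
    if (any(lf)) gap_left[i] <- max(0, s - max(g$end[lf]))
    rt <- other & g$end > e
    if (any(rt)) gap_right[i] <- max(0, min(g$start[rt]) - e)
  }
  fwd <- g$strand == "+"
  data.frame(id = g$id,
             gap5 = ifelse(fwd, gap_left, gap_right),
             gap3 = ifelse(fwd, gap_right, gap_left),
             stringsAsFactors = FALSE)
}

#' Select genes with sufficiently isolated flanks
#'
#' Applies [selection_criteria()] to the strand-relative intergenic gaps:
#' a gene passes when its 5' gap is at least `min_gap_5prime_bp` and its
#' 3' gap at least `min_gap_3prime_bp` (comparisons inclusive).
#'
#' @param ann a `GenomeAnnotation`.
#' @param criteria a `SelectionCriteria`.
#' @param neighbours passed to [intergenic_gaps()].
#' @return character vector of selected gene ids.
#' @export
select_genes <- function(ann, criteria = selection_criteria(),
                         neighbours = c("both", "same")) {
  gaps <- intergenic_gaps(ann, neighbours = match.arg(neighbours))
  keep <- gaps$gap5 >= criteria$min_gap_5prime_bp &
          gaps$gap3 >= criteria$min_gap_3prime_bp
  gaps$id[keep]
}

#' Write CUT class intervals as BED6
#'
#' One BED record per non-empty class interval, named `geneid:class`.
#'
#' @param class_map a `TranscriptClassMap` from
#'   [classify_cut_intervals()].
#' @param path output BED file.
#' @return `path`, invisibly.
#' @export
write_class_bed <- function(class_map, path) {
  df <- data.frame(chrom = class_map$chrom,
                   start = class_map$start, end = class_map$end,
                   name = paste0(class_map$gene, ":", class_map$class),
                   score = 0, strand = class_map$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
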