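#' Genome annotation container
#'
#' Holds the coordinate backbone used by every analysis: chromosome
#' lengths, gene spans and intron spans. All coordinates are stored
#' 0-based half-open (`[start, end)`); GFF3 input (1-based closed) is
#' converted at the boundary. The transcription start site (TSS) of a
#' forward-strand gene is `start`; for a reverse-strand gene it is
#' `end - 1`. "Upstream" and "downstream" are always strand-relative.
#'
#' @param chromosomes named numeric vector of chromosome lengths (bp).
#' @param genes data frame with columns `id`, `chrom`, `strand` (`"+"` or
#'   `"-"`), `start`, `end` (0-based half-open), and optionally `is_orf`
#'   (logical, default `TRUE`) and `in_mmi1_regulon` (logical, default
#'   `FALSE`, marks meiotic mRNAs of the Mmi1 regulon).
#' @param introns data frame with columns `id`, `gene` (parent gene id),
#'   `start`, `end`, or `NULL` for an intronless annotation. Chromosome
#'   and strand are inherited from the parent gene.
#' @return An object of class `GenomeAnnotation`: a list with elements
#'   `chromosomes`, `genes` and `introns`.
#' @examples
#' ann <- genome_annotation(
#'   chromosomes = c(chrS = 10000),
#'   genes = data.frame(id = "g1", chrom = "chrS", strand = "+",
#'                      start = 1000, end = 3000),
#'   introns = data.frame(id = "g1.i1", gene = "g1",
#'                        start = 1500, end = 1600))
#' @export
genome_annotation <- function(chromosomes, genes, introns = NULL) {
  stopifnot(is.numeric(chromosomes), length(chromosomes) >= 1,
            !is.null(names(chromosomes)))
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  required <- c("id", "chrom", "strand", "start", "end")
  if (!all(required %in% names(genes)))
    stop("genes must have columns: ", paste(required, collapse = ", "))
  if (is.null(genes$is_orf)) genes$is_orf <- TRUE
  if (is.null(genes$in_mmi1_regulon)) genes$in_mmi1_regulon <- FALSE
  genes <- genes[, c(required, "is_orf", "in_mmi1_regulon")]
  if (is.null(introns)) {
    introns <- data.frame(id = character(), gene = character(),
                          chrom = character(), strand = character(),
                          start = numeric(), end = numeric(),
                          stringsAsFactors = FALSE)
  } else {
    introns <- as.data.frame(introns, stringsAsFactors = FALSE)
    if (!all(c("id", "gene", "start", "end") %in% names(introns)))
      stop("introns must have columns: id, gene, start, end")
    idx <- match(introns$gene, genes$id)
    if (anyNA(idx))
      stop("intron parent gene not found: ",
           paste(unique(introns$gene[is.na(idx)]), collapse = ", "))
    introns$chrom <- genes$chrom[idx]
    introns$strand <- genes$strand[idx]
    introns <- introns[, c("id", "gene", "chrom", "strand", "start", "end")]
  }
  ann <- structure(list(chromosomes = chromosomes, genes = genes,
                        introns = introns),
                   class = "GenomeAnnotation")
  validate_annotation(ann)
}

#' Validate a GenomeAnnotation against its structural invariants
#'
#' Checks that gene spans are non-empty, lie within their chromosome,
#' gene ids are unique, and introns lie strictly inside their parent gene.
#'
#' @param ann a `GenomeAnnotation`.
#' @return `ann`, invisibly usable, after passing all checks.
#' @export
validate_annotation <- function(ann) {
  g <- ann$genes
  check_strand(g$strand)
  if (anyDuplicated(g$id))
    stop("duplicated gene ids: ",
         paste(unique(g$id[duplicated(g$id)]), collapse = ", "))
  if (any(g$end <= g$start)) stop("gene with empty or negative span")
  bad_chrom <- !g$chrom %in% names(ann$chromosomes)
  if (any(bad_chrom))
    stop("gene on unknown chromosome: ",
         paste(unique(g$chrom[bad_chrom]), collapse = ", "))
  len <- ann$chromosomes[g$chrom]
  if (any(g$start < 0 | g$end > len))
    stop("gene span outside chromosome bounds: ",
         paste(g$id[g$start < 0 | g$end > len], collapse = ", "))
  i <- ann$introns
  if (nrow(i)) {
    if (anyDuplicated(i$id)) stop("duplicated intron ids")
    idx <- match(i$gene, g$id)
    if (anyNA(idx)) stop("intron with unknown parent gene")
    inside <- i$start > g$start[idx] & i$end < g$end[idx] & i$end > i$start
    if (!all(inside))
      stop("intron not strictly inside its parent gene: ",
           paste(i$id[!inside], collapse = ", "))
  }
  ann
}

#' @export
print.GenomeAnnotation <- function(x, ...) {
  cat("GenomeAnnotation:", length(x$chromosomes), "chromosome(s),",
      nrow(x$genes), "genes,", nrow(x$introns), "introns\n")
  invisible(x)
}

gene_lookup <- function(ann, id) {
  idx <- match(id, ann$genes$id)
  if (anyNA(idx)) stop("unknown gene id: ",
                       paste(id[is.na(idx)], collapse = ", "))
  ann$genes[idx, , drop = FALSE]
}

#' Genes without any annotated intron
#' @param ann a `GenomeAnnotation`.
#' @param orf_only keep only open reading frames (default `TRUE`).
#' @return character vector of gene ids.
#' @export
intronless_genes <- function(ann, orf_only = TRUE) {
  g <- ann$genes
  keep <- !(g$id %in% ann$introns$gene)
  if (orf_only) keep <- keep & g$is_orf
  g$id[keep]
}

#' Exonic flank windows of introns
#'
#' For each intron returns the two fixed-width exonic windows that abut it:
#' the window of `flank_bp` base pairs immediately 5' and immediately 3'
#' of the intron (strand-relative labels; coordinates genomic).
#'
#' @param ann a `GenomeAnnotation`.
#' @param intron_ids intron ids (default: all introns).
#' @param flank_bp window width in bp (default 20).
#' @return data frame with one row per intron: id, chrom, strand, intron
#'   span, and `left`/`right` genomic windows plus strand-relative
#'   `up`/`down` window coordinates.
#' @export
intron_flanks <- function(ann, intron_ids = NULL, flank_bp = 20) {
  i <- ann$introns
  if (!is.null(intron_ids)) {
    idx <- match(intron_ids, i$id)
    if (anyNA(idx)) stop("unknown intron id: ",
                         paste(intron_ids[is.na(idx)], collapse = ", "))
    i <- i[idx, , drop = FALSE]
  }
  g <- gene_lookup(ann, i$gene)
  left_start <- pmax(i$start - flank_bp, g$start)
  right_end <- pmin(i$end + flank_bp, g$end)
  data.frame(id = i$id, gene = i$gene, chrom = i$chrom, strand = i$strand,
             start = i$start, end = i$end,
             left_start = left_start, left_end = i$start,
             right_start = i$end, right_end = right_end,
             stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------
## Readers / writers
## ---------------------------------------------------------------------

parse_sequence_regions <- function(path) {
  head_lines <- readLines(path, n = 200)
  dirs <- grep("^##sequence-region", head_lines, value = TRUE)
  if (!length(dirs)) return(NULL)
  parts <- strsplit(trimws(sub("^##sequence-region\\s+", "", dirs)), "\\s+")
  lens <- vapply(parts, function(p) as.numeric(p[3]), numeric(1))
  names(lens) <- vapply(parts, `[`, character(1), 1)
  lens
}

#' Read a genome annotation from GFF3 or BED
#'
#' GFF3 coordinates (1-based closed) are converted to the internal 0-based
#' half-open convention. Introns are taken from explicit `intron` features
#' when present, otherwise derived as the gaps between `exon` features of
#' the same parent. Chromosome lengths come from `##sequence-region`
#' directives, the `chrom_lengths` argument, or (as a fallback) the
#' maximum annotated end per chromosome.
#'
#' @param path GFF3 (`.gff`, `.gff3`) or BED (`.bed`) file.
#' @param chrom_lengths optional named vector of chromosome lengths.
#' @return a `GenomeAnnotation`.
#' @export
read_annotation <- function(path, chrom_lengths = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  is_bed <- grepl("\\.bed$", path, ignore.case = TRUE)
  gr <- tryCatch(
    rtracklayer::import(path,
                        format = if (is_bed) "bed" else "gff3"),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (is_bed) {
    genes <- data.frame(
      id = if (!is.null(gr$name)) as.character(gr$name)
           else paste0("gene", seq_along(gr)),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      start = GenomicRanges::start(gr) - 1,    # import.bed returns 1-based
      end = GenomicRanges::end(gr),
      stringsAsFactors = FALSE)
    introns <- NULL
  } else {
    type <- as.character(gr$type)
    gg <- gr[type == "gene"]
    if (!length(gg)) stop("no gene features in ", path)
    gid <- as.character(gg$ID %||% gg$Name)
    genes <- data.frame(
      id = gid,
      chrom = as.character(GenomicRanges::seqnames(gg)),
      strand = as.character(GenomicRanges::strand(gg)),
      start = GenomicRanges::start(gg) - 1,
      end = GenomicRanges::end(gg),
      stringsAsFactors = FALSE)
    if (!is.null(gg$is_orf)) genes$is_orf <- gg$is_orf %in% c("true", "TRUE", "1")
    if (!is.null(gg$mmi1_regulon))
      genes$in_mmi1_regulon <- gg$mmi1_regulon %in% c("true", "TRUE", "1")
    introns <- gff_introns(gr, genes)
  }
  lens <- chrom_lengths %||% parse_sequence_regions(path)
  if (is.null(lens)) {
    ends <- tapply(genes$end, genes$chrom, max)
    lens <- as.numeric(ends)
    names(lens) <- names(ends)
  }
  genome_annotation(lens, genes, introns)
}

## Extract introns from a GFF3 GRanges: explicit intron features, else
## gaps between exons sharing a Parent (the parent may be the gene itself
## or an mRNA whose Parent is the gene).
gff_introns <- function(gr, genes) {
  type <- as.character(gr$type)
  parent_of <- function(feat) {
    p <- feat$Parent
    vapply(seq_along(p), function(k) {
      pk <- unlist(p[k])
      if (!length(pk)) NA_character_ else as.character(pk[1])
    }, character(1))
  }
  ## map a feature parent id to a gene id (directly or via an mRNA record)
  tx <- gr[type %in% c("mRNA", "transcript")]
  tx_parent <- if (length(tx)) stats::setNames(parent_of(tx),
                                               as.character(tx$ID)) else c()
  to_gene <- function(pid) {
    out <- ifelse(pid %in% genes$id, pid, unname(tx_parent[pid]))
    if (anyNA(out)) stop("feature parent not resolvable to a gene")
    out
  }
  ii <- gr[type == "intron"]
  if (length(ii)) {
    gene <- to_gene(parent_of(ii))
    ids <- as.character(ii$ID %||% paste0(gene, ".i", seq_along(ii)))
    return(data.frame(id = ids, gene = gene,
                      start = GenomicRanges::start(ii) - 1,
                      end = GenomicRanges::end(ii),
                      stringsAsFactors = FALSE))
  }
  ex <- gr[type == "exon"]
  if (!length(ex)) return(NULL)
  gene <- to_gene(parent_of(ex))
  ex_df <- data.frame(gene = gene,
                      start = GenomicRanges::start(ex) - 1,
                      end = GenomicRanges::end(ex))
  ## exons must lie inside the parent gene span
  gidx <- match(ex_df$gene, genes$id)
  if (any(ex_df$start < genes$start[gidx] | ex_df$end > genes$end[gidx]))
    stop("exon outside its parent gene span")
  out <- do.call(rbind, lapply(split(ex_df, ex_df$gene), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) < 2) return(NULL)
    data.frame(gene = d$gene[1],
               start = d$end[-nrow(d)], end = d$start[-1])
  }))
  if (is.null(out) || !nrow(out)) return(NULL)
  out <- out[out$end > out$start, , drop = FALSE]
  rownames(out) <- NULL
  out$id <- paste0(out$gene, ".i", stats::ave(out$start, out$gene,
                                              FUN = seq_along))
  out[, c("id", "gene", "start", "end")]
}

#' Write a genome annotation as GFF3
#'
#' Inverse of [read_annotation()]: genes and introns are written as GFF3
#' features (1-based closed coordinates) with `##sequence-region`
#' directives carrying the chromosome lengths, so a round trip reproduces
#' spans exactly.
#'
#' @param ann a `GenomeAnnotation`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  g <- ann$genes
  i <- ann$introns
  attr_col <- paste0("ID=", g$id, ";is_orf=", tolower(g$is_orf),
                     ";mmi1_regulon=", tolower(g$in_mmi1_regulon))
  lines <- c("##gff-version 3",
             paste("##sequence-region", names(ann$chromosomes), 1,
                   format(ann$chromosomes, scientific = FALSE,
                          trim = TRUE)),
             paste(g$chrom, "exosurv", "gene", g$start + 1, g$end, ".",
                   g$strand, ".", attr_col, sep = "\t"))
  if (nrow(i)) {
    lines <- c(lines,
               paste(i$chrom, "exosurv", "intron", i$start + 1, i$end, ".",
                     i$strand, ".",
                     paste0("ID=", i$id, ";Parent=", i$gene), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
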