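#' Composite-profile configuration
#'
#' Geometry of the composite (metagene) matrices: number of gene-body
#' bins, number of flank columns per side, and the spacing of same-strand
#' probes (2 x the 40-bp alternating design resolution, so 10 flank
#' probes cover 800 bp).
#'
#' @param n_bins gene-body bins (default 15).
#' @param flank_probes flank columns per side (default 10).
#' @param probe_pitch_bp same-strand probe spacing in bp (default 80);
#'   also the flank window width when profiling per-base signals.
#' @param exon_flank_bp exonic flank width for meta-intron profiles
#'   (default 20).
#' @param pseudocount zero-protection used when logging coverage.
#' @return a `ProfileConfig` list.
#' @export
profile_config <- function(n_bins = 15, flank_probes = 10,
                           probe_pitch_bp = 80, exon_flank_bp = 20,
                           pseudocount = 1) {
  stopifnot(n_bins >= 1, flank_probes >= 0, probe_pitch_bp > 0,
            exon_flank_bp >= 0, pseudocount > 0)
  structure(list(n_bins = n_bins, flank_probes = flank_probes,
                 probe_pitch_bp = probe_pitch_bp,
                 exon_flank_bp = exon_flank_bp,
                 pseudocount = pseudocount),
            class = "ProfileConfig")
}

profile_column_labels <- function(config) {
  c(if (config$flank_probes > 0)
      sprintf("u%02d", config$flank_probes:1),
    sprintf("b%02d", seq_len(config$n_bins)),
    if (config$flank_probes > 0)
      sprintf("d%02d", seq_len(config$flank_probes)))
}

body_columns <- function(config) {
  sprintf("b%02d", seq_len(config$n_bins))
}

## Mean of per-base values over [start, end) clipped to the chromosome;
## NA when the clipped window is empty.
window_mean <- function(values, start, end, chrom_len) {
  start <- max(start, 0); end <- min(end, chrom_len)
  if (end <= start) return(NA_real_)
  mean(values[(start + 1):end])
}

#' Bin one gene into a composite-profile row
#'
#' The gene body is split into `n_bins` equal real-valued intervals in
#' strand-relative 5' to 3' order. For probe signals each bin averages
#' the log2 ratios of the probes whose centers fall in the bin on the
#' profiled strand (the gene's own strand for `orientation = "sense"`,
#' the opposite strand for `"antisense"`); bins without a probe are NA.
#' Flank columns take the `flank_probes` nearest probes on the profiled
#' strand beyond the TSS (5' side) and TTS (3' side), outermost first.
#' For per-base log2-ratio signals, bins and flank windows of
#' `probe_pitch_bp` are averaged directly.
#'
#' @param gene one-row gene data frame (as in `ann$genes`).
#' @param signal a `ProbeSignal` or a `StrandedSignal` in `log2_ratio`
#'   mode.
#' @param config a [profile_config()].
#' @param orientation `"sense"` or `"antisense"`.
#' @return named numeric row: `u10..u01` (5' flank), `b01..bN` (body),
#'   `d01..d10` (3' flank).
#' @export
bin_gene_row <- function(gene, signal, config = profile_config(),
                         orientation = c("sense", "antisense")) {
  orientation <- match.arg(orientation)
  strand_used <- if (orientation == "sense") gene$strand
                 else opposite_strand(gene$strand)
  fwd <- gene$strand == "+"
  s <- gene$start; e <- gene$end
  nb <- config$n_bins; fp <- config$flank_probes
  bounds <- seq(s, e, length.out = nb + 1)

  if (inherits(signal, "ProbeSignal")) {
    pr <- signal$probes
    pr <- pr[pr$chrom == gene$chrom & pr$strand == strand_used, ,
             drop = FALSE]
    pr <- pr[order(pr$center), , drop = FALSE]
    in_body <- pr$center >= s & pr$center < e
    body_pr <- pr[in_body, , drop = FALSE]
    ## ties at a bin boundary go to the downstream (genomic-right) bin
    bin_idx <- findInterval(body_pr$center, bounds,
                            rightmost.closed = TRUE)
    bin_idx[bin_idx > nb] <- nb
    bins <- vapply(seq_len(nb), function(b) {
      v <- body_pr$value[bin_idx == b]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
    take_flank <- function(side) {
      ## side "left" = genomic coordinates below the gene start
      if (side == "left") {
        v <- pr$value[pr$center < s]
        v <- utils::tail(v, fp)             # nearest last
        v <- c(rep(NA_real_, fp - length(v)), v)   # outermost first
      } else {
        v <- pr$value[pr$center >= e]
        v <- utils::head(v, fp)
        v <- c(v, rep(NA_real_, fp - length(v)))   # nearest first
      }
      v
    }
    left <- take_flank("left"); right <- take_flank("right")
    if (fwd) {
      up <- left                      # outermost .. nearest TSS
      down <- right                   # nearest TTS .. outermost
    } else {
      up <- rev(right)                # outermost .. nearest (high coords)
      down <- rev(left)
      bins <- rev(bins)
    }
  } else {
    stopifnot(inherits(signal, "StrandedSignal"),
              signal$mode == "log2_ratio")
    v <- signal_values(signal, gene$chrom, strand_used)
    chrom_len <- signal$chromosomes[[gene$chrom]]
    bins <- vapply(seq_len(nb), function(b) {
      lo <- ceiling(bounds[b]); hi <- ceiling(bounds[b + 1])
      window_mean(v, lo, hi, chrom_len)
    }, numeric(1))
    pitch <- config$probe_pitch_bp
    left <- vapply(seq_len(fp), function(k)
      window_mean(v, s - k * pitch, s - (k - 1) * pitch, chrom_len),
      numeric(1))                    # nearest first
    right <- vapply(seq_len(fp), function(k)
      window_mean(v, e + (k - 1) * pitch, e + k * pitch, chrom_len),
      numeric(1))                    # nearest first
    if (fwd) {
      up <- rev(left); down <- right
    } else {
      up <- rev(right); down <- left
      bins <- rev(bins)
    }
  }
  stats::setNames(c(up, bins, down), profile_column_labels(config))
}

#' Build a composite matrix over a set of genes
#'
#' One [bin_gene_row()] per gene; all rows share the column layout
#' (5' flank, body bins, 3' flank).
#'
#' @param ann a `GenomeAnnotation`.
#' @param gene_ids genes to profile.
#' @param signal probe or per-base log2-ratio signal.
#' @param config a [profile_config()].
#' @param orientation `"sense"` or `"antisense"`.
#' @return a `CompositeMatrix`: numeric matrix, rownames = gene ids, with
#'   `orientation` and `config` attributes.
#' @export
composite_matrix <- function(ann, gene_ids, signal,
                             config = profile_config(),
                             orientation = c("sense", "antisense")) {
  orientation <- match.arg(orientation)
  if (!length(gene_ids)) stop("no genes to profile")
  genes <- gene_lookup(ann, gene_ids)
  rows <- lapply(seq_len(nrow(genes)), function(i)
    bin_gene_row(genes[i, , drop = FALSE], signal, config, orientation))
  m <- do.call(rbind, rows)
  rownames(m) <- gene_ids
  structure(m, orientation = orientation, config = config,
            class = c("CompositeMatrix", class(m)))
}

#' Column-wise geometric average of a composite matrix
#'
#' Entries are log2 ratios, so the arithmetic mean of each column equals
#' the log2 of the geometric mean of the underlying ratios. Missing
#' entries are ignored; a column missing in every row yields NA.
#'
#' @param matrix a `CompositeMatrix` (or any numeric matrix of log2
#'   values).
#' @return named numeric vector of per-column log2 values.
#' @export
composite_average <- function(matrix) {
  if (!nrow(matrix)) stop("empty composite matrix")
  out <- colMeans(matrix, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}

#' Normalize composite profiles to WT
#'
#' Anchors the mean sense gene-body expression at 0 on the log2 scale to
#' compensate the artificial global shift that strong AS/intergenic
#' accumulation causes in ratio channels. The offset is the grand mean of
#' the sense profile's body-bin columns (flanks excluded) and is
#' subtracted from every column of both profiles, so sense/AS differences
#' are untouched.
#'
#' @param sense_profile,as_profile per-column log2 profiles from
#'   [composite_average()].
#' @param config the [profile_config()] used to build them.
#' @return list with `sense`, `antisense` (shifted profiles) and
#'   `offset`.
#' @export
normalize_to_wt <- function(sense_profile, as_profile,
                            config = profile_config()) {
  body <- sense_profile[body_columns(config)]
  if (all(is.na(body))) stop("all sense gene-body columns are missing")
  offset <- mean(body, na.rm = TRUE)
  list(sense = sense_profile - offset,
       antisense = as_profile - offset,
       offset = offset)
}

#' Composite expression profiles (mutant vs WT)
#'
#' The full expression-profiling pipeline: select genes per orientation
#' (sense analysis needs an empty 3' flank, AS analysis an empty 5'
#' flank), build both composite matrices, take per-column geometric
#' averages, and normalize the mean sense gene-body expression to WT
#' (0 on the log2 scale).
#'
#' @param ann a `GenomeAnnotation`.
#' @param ratio_signal log2(mutant/WT) signal (probe or per-base).
#' @param config a [profile_config()].
#' @param criteria_sense selection for the sense analysis (default: at
#'   least 600 bp intergenic in 3', 100 bp in 5').
#' @param criteria_as selection for the AS analysis (default mirrored:
#'   600 bp in 5', 100 bp in 3').
#' @param neighbours passed to [select_genes()].
#' @return an `exosurv_composite` list: `sense`, `antisense` (normalized
#'   profiles), `offset`, `matrices`, and `n_genes` per orientation.
#' @export
expression_composite <- function(ann, ratio_signal,
                                 config = profile_config(),
                                 criteria_sense = selection_criteria(600, 100),
                                 criteria_as = selection_criteria(100, 600),
                                 neighbours = "both") {
  sense_ids <- select_genes(ann, criteria_sense, neighbours)
  as_ids <- select_genes(ann, criteria_as, neighbours)
  if (!length(sense_ids) || !length(as_ids))
    stop("no genes pass the selection criteria")
  m_sense <- composite_matrix(ann, sense_ids, ratio_signal, config, "sense")
  m_as <- composite_matrix(ann, as_ids, ratio_signal, config, "antisense")
  norm <- normalize_to_wt(composite_average(m_sense),
                          composite_average(m_as), config)
  structure(list(sense = norm$sense, antisense = norm$antisense,
                 offset = norm$offset,
                 matrices = list(sense = m_sense, antisense = m_as),
                 n_genes = c(sense = length(sense_ids),
                             antisense = length(as_ids)),
                 config = config),
            class = "exosurv_composite")
}

#' Composite RIP-enrichment profiles (IP vs input)
#'
#' Identical machinery to [expression_composite()] applied to a
#' log2(IP/input) signal, but without the WT normalization and keeping
#' negative (under-enriched) values: RIP profiles report enrichment
#' relative to input directly.
#'
#' @inheritParams expression_composite
#' @param ip_over_input_signal log2(IP/input) signal.
#' @return an `exosurv_composite` list (offset 0).
#' @export
rip_composite <- function(ann, ip_over_input_signal,
                          config = profile_config(),
                          criteria_sense = selection_criteria(600, 100),
                          criteria_as = selection_criteria(100, 600),
                          neighbours = "both") {
  sense_ids <- select_genes(ann, criteria_sense, neighbours)
  as_ids <- select_genes(ann, criteria_as, neighbours)
  if (!length(sense_ids) || !length(as_ids))
    stop("no genes pass the selection criteria")
  m_sense <- composite_matrix(ann, sense_ids, ip_over_input_signal,
                              config, "sense")
  m_as <- composite_matrix(ann, as_ids, ip_over_input_signal,
                           config, "antisense")
  structure(list(sense = composite_average(m_sense),
                 antisense = composite_average(m_as),
                 offset = 0,
                 matrices = list(sense = m_sense, antisense = m_as),
                 n_genes = c(sense = length(sense_ids),
                             antisense = length(as_ids)),
                 config = config),
            class = "exosurv_composite")
}

#' @export
print.exosurv_composite <- function(x, ...) {
  cat("Composite profiles:", x$n_genes["sense"], "sense /",
      x$n_genes["antisense"], "antisense genes,",
      length(x$sense), "columns; WT offset",
      format(x$offset, digits = 3), "\n")
  invisible(x)
}

#' Plot-ready copy of a profile with negatives dropped
#'
#' Expression composite plots conventionally show only positive values
#' (accumulation); this replaces negative entries with NA.
#'
#' @param profile named numeric profile.
#' @return profile with negative values set to NA.
#' @export
positive_only <- function(profile) {
  profile[!is.na(profile) & profile < 0] <- NA_real_
  profile
}

#' Per-gene mean log2 values for a reporting gene set
#'
#' Mean sense-strand log2 value over each gene body: the per-gene view
#' used to report expression changes or RIP enrichment of a regulon
#' (e.g. Mmi1-regulon meiotic mRNAs).
#'
#' @param ann a `GenomeAnnotation`.
#' @param gene_ids genes to report (non-empty; unknown ids are an error).
#' @param signal probe or per-base log2-ratio signal.
#' @return data frame with columns `gene`, `mean_log2` (NA when no
#'   signal overlaps the gene body).
#' @export
regulon_report <- function(ann, gene_ids, signal) {
  if (!length(gene_ids)) stop("gene list is empty")
  genes <- gene_lookup(ann, gene_ids)
  vals <- vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    if (inherits(signal, "ProbeSignal")) {
      pr <- signal$probes
      v <- pr$value[pr$chrom == g$chrom & pr$strand == g$strand &
                    pr$center >= g$start & pr$center < g$end]
      if (length(v)) mean(v) else NA_real_
    } else {
      v <- signal_values(signal, g$chrom, g$strand)
      window_mean(v, g$start, g$end, signal$chromosomes[[g$chrom]])
    }
  }, numeric(1))
  data.frame(gene = gene_ids, mean_log2 = vals, stringsAsFactors = FALSE)
}

#' Write composite profiles as a tab-delimited table
#'
#' One row per column position: label, sense value, AS value, and the
#' number of contributing genes per orientation.
#'
#' @param composite an `exosurv_composite`.
#' @param path output file.
#' @param header provenance comment lines.
#' @return `path`, invisibly.
#' @export
write_composite_table <- function(composite, path, header = character()) {
  df <- data.frame(position = names(composite$sense),
                   sense = unname(composite$sense),
                   antisense = unname(composite$antisense),
                   n_sense = colSums(!is.na(composite$matrices$sense)),
                   n_antisense = colSums(!is.na(composite$matrices$antisense)))
  write_tsv_header(df, path, header)
}

#' Plot composite profiles in the mirrored-axis layout
#'
#' Sense profile on top, antisense below with a mirrored axis; solid
#' where positive (over-enrichment), dotted where negative.
#'
#' @param composite an `exosurv_composite`.
#' @param main plot title.
#' @param drop_negative drop negative values (expression convention)
#'   instead of plotting them dotted (RIP convention).
#' @return invisibly, `composite`.
#' @export
plot_composite <- function(composite, main = "Composite profile",
                           drop_negative = FALSE) {
  s <- composite$sense; a <- composite$antisense
  if (drop_negative) { s <- positive_only(s); a <- positive_only(a) }
  ylim <- range(c(s, -a), na.rm = TRUE, finite = TRUE)
  x <- seq_along(s)
  graphics::plot(x, s, type = "l", col = "firebrick", ylim = ylim,
                 xlab = "position (5' flank | bins | 3' flank)",
                 ylab = "log2 ratio (AS mirrored)", main = main,
                 xaxt = "n")
  graphics::axis(1, at = x, labels = names(s), las = 2, cex.axis = 0.6)
  graphics::lines(x, -a, col = "steelblue")
  graphics::abline(h = 0, lty = 3)
  invisible(composite)
}
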