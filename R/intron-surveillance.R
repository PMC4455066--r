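#' Intron filter settings
#'
#' Introns entering the meta-intron analysis must sit in open reading
#' frames, be 20-400 bp long (inclusive), and avoid expression extremes:
#' the lowest `low_pct` percent and highest `high_pct` percent of introns
#' by their expression proxy (median WT coverage of the two flanking
#' exonic windows) are excluded.
#'
#' @param min_len_bp,max_len_bp intron length bounds (default 20, 400).
#' @param orf_only keep only introns of ORFs (default `TRUE`).
#' @param low_pct,high_pct percent of introns excluded at each expression
#'   extreme (default 10 and 10).
#' @param exon_flank_bp width of the flanking exonic windows used as the
#'   expression proxy (default 20).
#' @return an `IntronFilter` list.
#' @export
intron_filter <- function(min_len_bp = 20, max_len_bp = 400,
                          orf_only = TRUE, low_pct = 10, high_pct = 10,
                          exon_flank_bp = 20) {
  stopifnot(min_len_bp <= max_len_bp, low_pct >= 0, high_pct >= 0,
            low_pct + high_pct < 100)
  structure(list(min_len_bp = min_len_bp, max_len_bp = max_len_bp,
                 orf_only = orf_only, low_pct = low_pct,
                 high_pct = high_pct, exon_flank_bp = exon_flank_bp),
            class = "IntronFilter")
}

#' Normalize coverage so intronless-gene medians center on 100
#'
#' Computes the median per-base sense coverage of every intronless ORF,
#' then rescales the whole signal so that the median of these per-gene
#' medians equals 100 exactly. Scaling commutes with the median, so the
#' operation is idempotent.
#'
#' @param signal coverage-mode `StrandedSignal`.
#' @param ann a `GenomeAnnotation` with at least one intronless ORF.
#' @return the rescaled signal, with the factor in
#'   `attr(, "norm_factor")`.
#' @export
normalize_coverage <- function(signal, ann) {
  stopifnot(signal$mode == "coverage")
  ids <- intronless_genes(ann)
  if (!length(ids)) stop("no intronless ORFs in the annotation")
  meds <- intronless_gene_medians(signal, ann, ids)
  m <- stats::median(meds)
  if (m <= 0) stop("median intronless-gene coverage is zero")
  factor <- 100 / m
  out <- signal_scale(signal, factor)
  attr(out, "norm_factor") <- factor
  out
}

#' Per-gene median sense coverage of intronless ORFs
#'
#' @param signal coverage-mode `StrandedSignal`.
#' @param ann a `GenomeAnnotation`.
#' @param ids gene ids (default: all intronless ORFs).
#' @return named numeric vector of per-gene medians.
#' @export
intronless_gene_medians <- function(signal, ann,
                                    ids = intronless_genes(ann)) {
  genes <- gene_lookup(ann, ids)
  vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    stats::median(signal_values(signal, g$chrom, g$strand)[
      (g$start + 1):g$end])
  }, numeric(1)) |> stats::setNames(ids)
}

#' Filter introns by length, ORF membership and expression percentile
#'
#' The expression proxy of an intron is the median WT sense coverage over
#' its two flanking exonic windows (concatenated). After the length and
#' ORF filters, the `floor(low_pct/100 * N)` lowest-proxy and
#' `floor(high_pct/100 * N)` highest-proxy introns are dropped (ties
#' broken by intron id for determinism).
#'
#' @param ann a `GenomeAnnotation`.
#' @param wt_coverage normalized WT coverage signal.
#' @param filter an [intron_filter()].
#' @param details return the full per-intron table instead of ids.
#' @return character vector of surviving intron ids, or (with
#'   `details = TRUE`) a data frame with id, length, proxy and `kept`.
#' @export
filter_introns <- function(ann, wt_coverage, filter = intron_filter(),
                           details = FALSE) {
  i <- ann$introns
  if (!nrow(i)) stop("annotation has no introns")
  g <- gene_lookup(ann, i$gene)
  len <- i$end - i$start
  pass <- len >= filter$min_len_bp & len <= filter$max_len_bp
  if (filter$orf_only) pass <- pass & g$is_orf
  fl <- intron_flanks(ann, i$id, filter$exon_flank_bp)
  proxy <- vapply(seq_len(nrow(i)), function(k) {
    v <- signal_values(wt_coverage, i$chrom[k], i$strand[k])
    vals <- c(if (fl$left_end[k] > fl$left_start[k])
                v[(fl$left_start[k] + 1):fl$left_end[k]],
              if (fl$right_end[k] > fl$right_start[k])
                v[(fl$right_start[k] + 1):fl$right_end[k]])
    stats::median(vals)
  }, numeric(1))
  kept <- rep(FALSE, nrow(i))
  idx <- which(pass)
  n <- length(idx)
  if (n) {
    ord <- idx[order(proxy[idx], i$id[idx])]
    drop_low <- floor(filter$low_pct / 100 * n)
    drop_high <- floor(filter$high_pct / 100 * n)
    keep_idx <- ord[seq_len(n) > drop_low & seq_len(n) <= n - drop_high]
    kept[keep_idx] <- TRUE
  }
  if (details)
    return(data.frame(id = i$id, gene = i$gene, length = len,
                      proxy = proxy, pass_structure = pass, kept = kept,
                      stringsAsFactors = FALSE))
  i$id[kept]
}

#' Mean coverage of intron bodies and their exon flanks
#' @noRd
intron_region_means <- function(ann, intron_ids, signal, exon_flank_bp) {
  fl <- intron_flanks(ann, intron_ids, exon_flank_bp)
  t(vapply(seq_len(nrow(fl)), function(k) {
    v <- signal_values(signal, fl$chrom[k], fl$strand[k])
    body <- mean(v[(fl$start[k] + 1):fl$end[k]])
    flank_vals <- c(if (fl$left_end[k] > fl$left_start[k])
                      v[(fl$left_start[k] + 1):fl$left_end[k]],
                    if (fl$right_end[k] > fl$right_start[k])
                      v[(fl$right_start[k] + 1):fl$right_end[k]])
    c(body = body, flank = mean(flank_vals))
  }, c(body = 0, flank = 0)))
}

#' Rank introns by retention increase and select the upper quartile
#'
#' Score = (mean mutant intronic coverage - mean WT intronic coverage) /
#' (mean mutant flank-exon coverage): the increase in intronic signal
#' normalized to the gene's expression level in the mutant. Introns are
#' sorted by descending score (ties broken by id) and the top
#' `ceil(N/4)` flagged as selected. Introns with zero mutant flank
#' coverage are dropped from the ranking with a warning.
#'
#' @param ann a `GenomeAnnotation`.
#' @param intron_ids introns to rank (e.g. from [filter_introns()]).
#' @param wt,mut normalized coverage signals.
#' @param exon_flank_bp flank width (default 20).
#' @return an `IntronRanking` data frame: id, score, selected, ordered by
#'   rank.
#' @export
rank_and_select_introns <- function(ann, intron_ids, wt, mut,
                                    exon_flank_bp = 20) {
  if (!length(intron_ids)) stop("no introns to rank")
  m_wt <- intron_region_means(ann, intron_ids, wt, exon_flank_bp)
  m_mut <- intron_region_means(ann, intron_ids, mut, exon_flank_bp)
  ok <- m_mut[, "flank"] > 0
  if (!all(ok)) {
    warning(sum(!ok), " intron(s) dropped: zero mutant flank coverage")
    intron_ids <- intron_ids[ok]
    m_wt <- m_wt[ok, , drop = FALSE]
    m_mut <- m_mut[ok, , drop = FALSE]
  }
  if (!length(intron_ids)) stop("no rankable introns")
  score <- (m_mut[, "body"] - m_wt[, "body"]) / m_mut[, "flank"]
  ranking <- data.frame(id = intron_ids, score = unname(score),
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$score, ranking$id), , drop = FALSE]
  rownames(ranking) <- NULL
  ranking$selected <- select_upper_quartile(nrow(ranking))
  structure(ranking, class = c("IntronRanking", "data.frame"))
}

#' Upper-quartile selection mask
#'
#' The top `ceil(N/4)` of N ranked items are selected; this rounding is
#' the convention under which ranking 3,935 introns selects exactly 984.
#'
#' @param n number of ranked items (>= 1).
#' @return logical vector: `TRUE` for the first `ceil(n/4)` positions.
#' @export
select_upper_quartile <- function(n) {
  stopifnot(n >= 1)
  seq_len(n) <= ceiling(n / 4)
}

#' Meta-intron composite profile
#'
#' Each intron is divided into 40 equal bins (fractional widths are fine
#' for short introns) flanked by one column per exonic base pair over
#' `exon_flank_bp` on either side, in strand-relative 5' to 3' order,
#' sense strand only. Entries are log2 of the mean coverage per column
#' (zero coverage replaced by the pseudocount before the log), and the
#' profile is the per-column arithmetic mean of the log2 values -- the
#' log2 of the geometric mean coverage.
#'
#' @param ann a `GenomeAnnotation`.
#' @param intron_ids introns to profile.
#' @param signal normalized coverage-mode `StrandedSignal`.
#' @param n_bins intron body bins (default 40).
#' @param exon_flank_bp exonic flank width (default 20): one column per
#'   base pair.
#' @param pseudocount replacement for zero coverage before the log.
#' @return list with `profile` (named per-column log2 means), `matrix`
#'   (introns x columns log2 values) and the column `labels`.
#' @export
intron_composite <- function(ann, intron_ids, signal, n_bins = 40,
                             exon_flank_bp = 20, pseudocount = 1) {
  stopifnot(signal$mode == "coverage")
  if (!length(intron_ids)) stop("no introns to profile")
  fl <- intron_flanks(ann, intron_ids, exon_flank_bp)
  labels <- c(if (exon_flank_bp > 0) sprintf("e5_%02d", exon_flank_bp:1),
              sprintf("i%02d", seq_len(n_bins)),
              if (exon_flank_bp > 0) sprintf("e3_%02d", seq_len(exon_flank_bp)))
  log2p <- function(x) log2(ifelse(x <= 0, pseudocount, x))
  rows <- lapply(seq_len(nrow(fl)), function(k) {
    v <- signal_values(signal, fl$chrom[k], fl$strand[k])
    bounds <- seq(fl$start[k], fl$end[k], length.out = n_bins + 1)
    cum <- c(0, cumsum(v))
    bins <- vapply(seq_len(n_bins), function(b) {
      ## fractional-width bins: length-weighted mean over the real interval
      lo <- bounds[b]; hi <- bounds[b + 1]
      lo_i <- floor(lo); hi_i <- ceiling(hi)
      w <- pmin(hi, (lo_i:(hi_i - 1)) + 1) - pmax(lo, lo_i:(hi_i - 1))
      sum(v[(lo_i + 1):hi_i] * w) / (hi - lo)
    }, numeric(1))
    left <- if (fl$left_end[k] > fl$left_start[k])
      v[(fl$left_start[k] + 1):fl$left_end[k]] else numeric(0)
    left <- c(rep(NA_real_, exon_flank_bp - length(left)), left)
    right <- if (fl$right_end[k] > fl$right_start[k])
      v[(fl$right_start[k] + 1):fl$right_end[k]] else numeric(0)
    right <- c(right, rep(NA_real_, exon_flank_bp - length(right)))
    row <- if (fl$strand[k] == "+") c(left, bins, right)
           else c(rev(right), rev(bins), rev(left))
    log2p(row)
  })
  m <- do.call(rbind, rows)
  colnames(m) <- labels
  rownames(m) <- intron_ids
  prof <- colMeans(m, na.rm = TRUE)
  prof[is.nan(prof)] <- NA_real_
  list(profile = prof, matrix = m, labels = labels)
}

## Contiguous reads only, as a data frame; gapped reads excluded.
contiguous_reads <- function(reads) {
  df <- as.data.frame(reads)
  df[is.na(df$start2), , drop = FALSE]
}

overlaps <- function(a_start, a_end, b_start, b_end) {
  a_start < b_end & a_end > b_start
}

#' Fraction of intron-overlapping reads that span an exon boundary
#'
#' Among contiguous (ungapped) reads overlapping at least 1 bp of an
#' intron on the matching strand, the fraction that also overlap at least
#' 1 bp of an adjacent exonic flank. Spliced (gapped) reads are excluded
#' entirely. High values indicate that intronic signal comes from
#' unspliced pre-mRNA rather than excised intron lariats.
#'
#' @param reads a `ReadSet`.
#' @param ann a `GenomeAnnotation`.
#' @param intron_ids introns to consider (default all).
#' @param exon_flank_bp adjacent exonic window width (default 20).
#' @return fraction in \[0, 1\], or NA when no read overlaps an intron.
#' @export
boundary_span_fraction <- function(reads, ann, intron_ids = NULL,
                                   exon_flank_bp = 20) {
  ids <- intron_ids %||% ann$introns$id
  fl <- intron_flanks(ann, ids, exon_flank_bp)
  cr <- contiguous_reads(reads)
  if (!nrow(cr) || !nrow(fl)) return(NA_real_)
  in_intron <- span_boundary <- rep(FALSE, nrow(cr))
  for (k in seq_len(nrow(fl))) {
    same <- cr$chrom == fl$chrom[k] & cr$strand == fl$strand[k]
    hit <- same & overlaps(cr$start1, cr$end1, fl$start[k], fl$end[k])
    in_intron <- in_intron | hit
    cross <- hit & (overlaps(cr$start1, cr$end1,
                             fl$left_start[k], fl$left_end[k]) |
                    overlaps(cr$start1, cr$end1,
                             fl$right_start[k], fl$right_end[k]))
    span_boundary <- span_boundary | cross
  }
  if (!any(in_intron)) return(NA_real_)
  sum(span_boundary) / sum(in_intron)
}

#' Junction-level spliced / unspliced quantification
#'
#' For one intron: spliced support S = gapped reads whose gap matches the
#' intron span exactly; unspliced support US = contiguous reads
#' overlapping both the intron and an adjacent exonic flank. Gapped reads
#' whose gap overlaps the intron without matching it exactly are
#' mis-spliced and counted separately. When a WT read set is supplied the
#' US/S ratio is also reported normalized to the WT ratio.
#'
#' @param reads mutant (or sample) `ReadSet`.
#' @param ann a `GenomeAnnotation`.
#' @param intron_id one intron id.
#' @param wt_reads optional WT `ReadSet` for normalization.
#' @param exon_flank_bp adjacent exonic window width (default 20).
#' @return list: `spliced`, `unspliced`, `misspliced`, `us_ratio`
#'   (NA when S = 0) and, when `wt_reads` is given, `wt_us_ratio` and
#'   `normalized_ratio` = (US/S) / (US/S)_WT.
#' @export
quantify_splicing <- function(reads, ann, intron_id, wt_reads = NULL,
                              exon_flank_bp = 20) {
  fl <- intron_flanks(ann, intron_id, exon_flank_bp)
  count_one <- function(rs) {
    df <- as.data.frame(rs)
    same <- df$chrom == fl$chrom & df$strand == fl$strand
    gapped <- same & !is.na(df$start2)
    exact <- gapped & df$end1 == fl$start & df$start2 == fl$end
    mis <- gapped & !exact &
      overlaps(df$end1, df$start2, fl$start, fl$end)
    contig <- same & is.na(df$start2)
    us <- contig & overlaps(df$start1, df$end1, fl$start, fl$end) &
      (overlaps(df$start1, df$end1, fl$left_start, fl$left_end) |
       overlaps(df$start1, df$end1, fl$right_start, fl$right_end))
    c(S = sum(exact), US = sum(us), mis = sum(mis))
  }
  n <- count_one(reads)
  out <- list(spliced = unname(n["S"]), unspliced = unname(n["US"]),
              misspliced = unname(n["mis"]),
              us_ratio = if (n["S"] > 0) unname(n["US"] / n["S"])
                         else NA_real_)
  if (!is.null(wt_reads)) {
    nw <- count_one(wt_reads)
    out$wt_spliced <- unname(nw["S"])
    out$wt_unspliced <- unname(nw["US"])
    out$wt_us_ratio <- if (nw["S"] > 0) unname(nw["US"] / nw["S"])
                       else NA_real_
    out$normalized_ratio <-
      if (!is.na(out$us_ratio) && !is.na(out$wt_us_ratio) &&
          out$wt_us_ratio > 0) out$us_ratio / out$wt_us_ratio
      else NA_real_
  }
  out
}

#' Stabilization-versus-splicing diagnostic
#'
#' Distinguishes stabilization of unspliced pre-mRNAs from a splicing
#' defect (and from no effect) by comparing three geometric-mean
#' mutant/WT fold-changes: over selected intron bodies, over their
#' flanking exonic windows, and over intronless gene bodies. If a
#' mutation stabilizes unspliced pre-mRNA, intronic and exonic coverage
#' rise together while intronless genes are unaffected; a splicing defect
#' raises intronic coverage above the exonic increase.
#'
#' @param wt,mut normalized coverage signals.
#' @param ann a `GenomeAnnotation`.
#' @param intron_ids introns entering the intron/exon fold-changes.
#' @param tau agreement tolerance in log2 units (default 0.5).
#' @param pseudocount zero-protection for the log ratios.
#' @return a `stabilization_report` list: per-category log2 fold-changes
#'   and a `verdict` among `"stabilization"`, `"splicing defect"`,
#'   `"no change"`, `"ambiguous"`.
#' @export
stabilization_diagnostic <- function(wt, mut, ann, intron_ids,
                                     tau = 0.5, pseudocount = 1) {
  if (!length(intron_ids)) stop("no introns supplied")
  il <- intronless_genes(ann)
  if (!length(il)) stop("annotation has no intronless ORFs")
  m_wt <- intron_region_means(ann, intron_ids, wt, 20)
  m_mut <- intron_region_means(ann, intron_ids, mut, 20)
  lfc <- function(num, den)
    mean(log2_ratio_values(num, den, pseudocount))
  intron_fc <- lfc(m_mut[, "body"], m_wt[, "body"])
  exon_fc <- lfc(m_mut[, "flank"], m_wt[, "flank"])
  genes <- gene_lookup(ann, il)
  gb <- function(sig) vapply(seq_len(nrow(genes)), function(i)
    mean(signal_values(sig, genes$chrom[i], genes$strand[i])[
      (genes$start[i] + 1):genes$end[i]]), numeric(1))
  intronless_fc <- lfc(gb(mut), gb(wt))
  verdict <-
    if (abs(intron_fc) <= tau && abs(exon_fc) <= tau &&
        abs(intronless_fc) <= tau) "no change"
    else if (intron_fc - exon_fc > tau) "splicing defect"
    else if (intron_fc > tau && abs(intron_fc - exon_fc) <= tau &&
             abs(intronless_fc) <= tau) "stabilization"
    else "ambiguous"
  structure(list(intron_log2fc = intron_fc, exon_log2fc = exon_fc,
                 intronless_log2fc = intronless_fc, tau = tau,
                 verdict = verdict),
            class = "stabilization_report")
}

#' @export
print.stabilization_report <- function(x, ...) {
  cat("Stabilization diagnostic (tau =", x$tau, "log2):\n",
      sprintf("  intron log2FC      %6.3f\n", x$intron_log2fc),
      sprintf("  exon-flank log2FC  %6.3f\n", x$exon_log2fc),
      sprintf("  intronless log2FC  %6.3f\n", x$intronless_log2fc),
      "  verdict:", x$verdict, "\n")
  invisible(x)
}
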