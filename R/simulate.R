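#' Effect profile for signal and read simulation
#'
#' Bundles the genotype-specific effects the generators emulate: per
#' transcript-class fold-changes (mutant relative to WT), intron-retention
#' fractions for both genotypes, and the spread of multiplicative noise.
#'
#' Two canonical scenarios are provided by the defaults plus two presets:
#' a CUT-degradation mutant accumulates PROMPT/AS/3'IGT transcripts
#' (fold-changes > 1 on the CUT classes, retention unchanged), while a
#' splicing-surveillance mutant stabilizes unspliced pre-mRNAs (retention
#' raised in the mutant, CUT classes unchanged).
#'
#' @param fold_changes named numeric vector of mutant/WT fold-changes,
#'   names among `mRNA`, `meiotic_mRNA`, `PROMPT`, `AS`, `IGT3`; missing
#'   classes default to 1. All values must be >= 0.
#' @param retention_wt,retention_mut probability that a transcript copy
#'   retains a given intron in the WT / mutant background (defaults 0.05
#'   and 0.15: a three-fold retention increase).
#' @param noise_sd standard deviation of the log2 multiplicative noise
#'   applied per gene feature in the mutant channel (default 0).
#' @param cut_baseline_frac WT abundance of CUT regions as a fraction of
#'   the mean mRNA baseline (default 0.05: detectable but low in WT).
#' @param w_bp PROMPT/3'IGT window length passed to
#'   [classify_cut_intervals()].
#' @param seed master seed; generators derive independent sub-streams.
#' @return an `EffectProfile` list.
#' @export
effect_profile <- function(fold_changes = c(mRNA = 1),
                           retention_wt = 0.05, retention_mut = 0.15,
                           noise_sd = 0, cut_baseline_frac = 0.05,
                           w_bp = 500, seed = 1) {
  classes <- c("mRNA", "meiotic_mRNA", "PROMPT", "AS", "IGT3")
  fc <- stats::setNames(rep(1, length(classes)), classes)
  if (length(fold_changes)) {
    if (is.null(names(fold_changes)) ||
        !all(names(fold_changes) %in% classes))
      stop("fold_changes must be named with classes among: ",
           paste(classes, collapse = ", "))
    fc[names(fold_changes)] <- fold_changes
  }
  if (any(fc < 0)) stop("fold-changes must be >= 0")
  if (retention_wt < 0 || retention_wt > 1 ||
      retention_mut < 0 || retention_mut > 1)
    stop("retention fractions must lie in [0, 1]")
  stopifnot(noise_sd >= 0, cut_baseline_frac >= 0)
  structure(list(fold_changes = fc, retention_wt = retention_wt,
                 retention_mut = retention_mut, noise_sd = noise_sd,
                 cut_baseline_frac = cut_baseline_frac,
                 w_bp = w_bp, seed = as.integer(seed)),
            class = "EffectProfile")
}

#' Generate a toy genome annotation
#'
#' One chromosome of genes with random strands, lengths and intergenic
#' gaps. A configurable fraction of genes carries 1-3 introns. The
#' default geometry keeps gaps wider than the composite-profile selection
#' thresholds and keeps intron spacing wider than typical short-read
#' lengths, so every downstream stage is exercised on realistic input.
#'
#' @param n_genes number of genes (>= 1).
#' @param seed RNG seed; the generator is a pure function of its
#'   arguments and the seed.
#' @param intron_rate fraction of genes carrying introns (default 0.5).
#' @param gene_length_range,gap_range uniform sampling ranges (bp) for
#'   gene lengths and intergenic gaps.
#' @param intron_length_range intron length bounds (default 20-400 bp,
#'   the span accepted by the intron filter). Lengths are drawn
#'   log-normally with median `intron_length_median` and clipped to this
#'   range, emulating the short-intron statistics of fission yeast.
#' @param intron_length_median median intron length in bp (default 60).
#' @param intron_margin minimum exonic distance (bp) between introns and
#'   from introns to the gene ends (default 60, above the default
#'   simulated read length so no read spans two junctions).
#' @param regulon_frac fraction of genes flagged as Mmi1-regulon meiotic
#'   mRNAs (default 0.05).
#' @param chrom_name chromosome name.
#' @param edge_pad bp of gene-free sequence at both chromosome ends.
#' @return a `GenomeAnnotation`.
#' @export
make_toy_genome <- function(n_genes, seed = 1, intron_rate = 0.5,
                            gene_length_range = c(1200, 3000),
                            gap_range = c(600, 1600),
                            intron_length_range = c(20, 400),
                            intron_length_median = 60,
                            intron_margin = 60,
                            regulon_frac = 0.05,
                            chrom_name = "chrS", edge_pad = 1000) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  stopifnot(gene_length_range[1] <= gene_length_range[2],
            intron_length_range[1] <= intron_length_range[2])
  min_body <- 2 * intron_margin + intron_length_range[1]
  if (intron_rate > 0 && gene_length_range[1] < min_body)
    stop("gene_length_range too small to fit introns with the given margin")
  with_seed(derive_seed(seed, 1), {
    lens <- round(stats::runif(n_genes, gene_length_range[1],
                               gene_length_range[2]))
    gaps <- round(stats::runif(n_genes, gap_range[1], gap_range[2]))
    strands <- sample(c("+", "-"), n_genes, replace = TRUE)
    starts <- edge_pad + cumsum(c(0, (lens + gaps)[-n_genes]))
    ends <- starts + lens
    chrom_len <- ends[n_genes] + edge_pad
    genes <- data.frame(
      id = sprintf("g%04d", seq_len(n_genes)), chrom = chrom_name,
      strand = strands, start = starts, end = ends,
      is_orf = TRUE,
      in_mmi1_regulon = stats::runif(n_genes) < regulon_frac,
      stringsAsFactors = FALSE)
    has_intron <- stats::runif(n_genes) < intron_rate
    introns <- NULL
    if (any(has_intron)) {
      rows <- lapply(which(has_intron), function(i) {
        k <- sample(1:3, 1)
        placed <- list()
        cursor <- genes$start[i] + intron_margin
        limit <- genes$end[i] - intron_margin
        for (j in seq_len(k)) {
          ilen <- round(stats::rlnorm(1, log(intron_length_median), 0.45))
          ilen <- min(max(ilen, intron_length_range[1]),
                      intron_length_range[2])
          ## leave room for this intron and the trailing margin
          if (cursor + ilen > limit) break
          lo <- cursor
          hi <- limit - ilen
          ## spread remaining introns across the remaining body
          pos <- round(stats::runif(1, lo, lo + (hi - lo) / (k - j + 1)))
          placed[[j]] <- c(pos, pos + ilen)
          cursor <- pos + ilen + intron_margin
        }
        if (!length(placed)) return(NULL)
        m <- do.call(rbind, placed)
        data.frame(gene = genes$id[i], start = m[, 1], end = m[, 2])
      })
      rows <- rows[!vapply(rows, is.null, logical(1))]
      if (length(rows)) {
        introns <- do.call(rbind, rows)
        introns$id <- paste0(introns$gene, ".i",
                             stats::ave(introns$start, introns$gene,
                                        FUN = seq_along))
        introns <- introns[, c("id", "gene", "start", "end")]
      }
    }
    genome_annotation(stats::setNames(chrom_len, chrom_name),
                      genes, introns)
  })
}

## Per-gene feature noise factors for the mutant channel: one log-normal
## draw per (gene, feature) so binning does not average the noise away.
feature_noise <- function(n, noise_sd) {
  if (noise_sd == 0) rep(1, n) else 2^stats::rnorm(n, 0, noise_sd)
}

#' Simulate WT and mutant strand-specific coverage
#'
#' Each gene receives a log-normal baseline abundance painted as sense
#' coverage over its exons; intronic positions receive the baseline times
#' the genotype's intron-retention fraction. Each CUT region (PROMPT, AS,
#' 3'IGT geometry from [classify_cut_intervals()]) receives a low WT
#' baseline. The mutant channel multiplies each feature by its class
#' fold-change and by per-feature multiplicative log-normal noise.
#'
#' With `noise_sd = 0` the realized fold-change of every class interval
#' equals the configured fold-change exactly.
#'
#' @param ann a `GenomeAnnotation`.
#' @param effect an [effect_profile()].
#' @return list with coverage-mode `StrandedSignal`s `wt` and `mut`, and
#'   the per-gene `baselines` used.
#' @export
simulate_signals <- function(ann, effect = effect_profile()) {
  g <- ann$genes
  n <- nrow(g)
  fc <- effect$fold_changes
  with_seed(derive_seed(effect$seed, 2), {
    baselines <- stats::rlnorm(n, meanlog = log(100), sdlog = 1)
    cut_base <- effect$cut_baseline_frac * mean(baselines)
    gene_class <- ifelse(g$in_mmi1_regulon, "meiotic_mRNA", "mRNA")
    noise_sense <- feature_noise(n, effect$noise_sd)
    noise_prompt <- feature_noise(n, effect$noise_sd)
    noise_as <- feature_noise(n, effect$noise_sd)
    noise_igt3 <- feature_noise(n, effect$noise_sd)
    noise_intron <- feature_noise(nrow(ann$introns), effect$noise_sd)

    wt <- stranded_signal(ann$chromosomes, "coverage")
    mut <- stranded_signal(ann$chromosomes, "coverage")
    ## sense gene bodies (exonic level; introns corrected below)
    for (i in seq_len(n)) {
      wt <- signal_add(wt, g$chrom[i], g$strand[i], g$start[i], g$end[i],
                       baselines[i])
      mut <- signal_add(mut, g$chrom[i], g$strand[i], g$start[i], g$end[i],
                        baselines[i] * fc[[gene_class[i]]] * noise_sense[i])
    }
    ## intronic positions: replace the exonic level with baseline x retention
    ii <- ann$introns
    for (k in seq_len(nrow(ii))) {
      i <- match(ii$gene[k], g$id)
      wt <- signal_add(wt, ii$chrom[k], ii$strand[k], ii$start[k], ii$end[k],
                       baselines[i] * (effect$retention_wt - 1))
      mut_exonic <- baselines[i] * fc[[gene_class[i]]] * noise_sense[i]
      mut_intron <- baselines[i] * fc[[gene_class[i]]] *
        effect$retention_mut * noise_intron[k]
      mut <- signal_add(mut, ii$chrom[k], ii$strand[k], ii$start[k], ii$end[k],
                        mut_intron - mut_exonic)
    }
    ## CUT regions
    cuts <- classify_cut_intervals(ann, effect$w_bp)
    noise_by_class <- list(PROMPT = noise_prompt, AS = noise_as,
                           IGT3 = noise_igt3)
    for (k in seq_len(nrow(cuts))) {
      i <- match(cuts$gene[k], g$id)
      cl <- cuts$class[k]
      wt <- signal_add(wt, cuts$chrom[k], cuts$strand[k],
                       cuts$start[k], cuts$end[k], cut_base)
      mut <- signal_add(mut, cuts$chrom[k], cuts$strand[k],
                        cuts$start[k], cuts$end[k],
                        cut_base * fc[[cl]] * noise_by_class[[cl]][i])
    }
    list(wt = wt, mut = mut,
         baselines = stats::setNames(baselines, g$id))
  })
}

#' Simulate tiling-probe log2 ratios from a pair of coverage signals
#'
#' Probes are placed every `probe_resolution` bp along each chromosome,
#' alternating between the forward and reverse strand (so same-strand
#' probes sit 2 x resolution apart). Each probe reports the log2 ratio of
#' the mean per-base mutant vs WT signal over its window on its strand;
#' windows where either channel is zero receive a pseudocount in both.
#'
#' @param ann a `GenomeAnnotation`.
#' @param wt,mut coverage-mode `StrandedSignal`s.
#' @param probe_resolution bp between consecutive probes (default 40).
#' @param pseudocount zero-protection added to both channels.
#' @return a `ProbeSignal`: list with `probes` (data frame: chrom,
#'   center, strand, value), `resolution`, and `mode = "log2_ratio"`.
#' @export
simulate_probe_ratios <- function(ann, wt, mut, probe_resolution = 40,
                                  pseudocount = 1) {
  stopifnot(wt$mode == "coverage", mut$mode == "coverage")
  rows <- lapply(names(ann$chromosomes), function(ch) {
    len <- ann$chromosomes[[ch]]
    n_probes <- floor(len / probe_resolution)
    if (n_probes < 1) return(NULL)
    k <- seq_len(n_probes) - 1
    start <- k * probe_resolution
    end <- start + probe_resolution
    center <- start + probe_resolution / 2
    strand <- ifelse(k %% 2 == 0, "+", "-")
    wt_mean <- mut_mean <- numeric(n_probes)
    for (st in c("+", "-")) {
      sel <- strand == st
      cw <- c(0, cumsum(wt$values[[ch]][[st]]))
      cm <- c(0, cumsum(mut$values[[ch]][[st]]))
      wt_mean[sel] <- (cw[end[sel] + 1] - cw[start[sel] + 1]) /
        probe_resolution
      mut_mean[sel] <- (cm[end[sel] + 1] - cm[start[sel] + 1]) /
        probe_resolution
    }
    data.frame(chrom = ch, center = center, strand = strand,
               value = log2_ratio_values(mut_mean, wt_mean, pseudocount),
               stringsAsFactors = FALSE)
  })
  probes <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(probes) <- NULL
  structure(list(probes = probes, resolution = probe_resolution,
                 mode = "log2_ratio"),
            class = "ProbeSignal")
}

#' @export
print.ProbeSignal <- function(x, ...) {
  cat("ProbeSignal:", nrow(x$probes), "probes at", x$resolution,
      "bp resolution (alternating strands)\n")
  invisible(x)
}

#' Simulate stranded reads with spliced gaps
#'
#' Reads are sampled from transcript copies: a copy retains each intron
#' independently with the genotype's retention probability. Spliced-out
#' introns shorten the transcript; a read crossing the junction of a
#' spliced intron is emitted as a gapped read whose gap equals the intron
#' span exactly, while retained introns yield contiguous reads.
#'
#' @param ann a `GenomeAnnotation`.
#' @param effect an [effect_profile()]; genes are weighted by fresh
#'   log-normal baselines from the effect's read stream.
#' @param n_reads number of reads.
#' @param read_length read length in bp (default 50).
#' @param genotype `"mut"` or `"wt"`: which retention fraction applies.
#' @param seed optional override of the effect's seed.
#' @return a `ReadSet`: data frame with columns chrom, strand, start1,
#'   end1, start2, end2 (NA segment 2 for contiguous reads).
#' @export
simulate_reads <- function(ann, effect = effect_profile(), n_reads,
                           read_length = 50,
                           genotype = c("mut", "wt"), seed = NULL) {
  genotype <- match.arg(genotype)
  if (n_reads < 0) stop("n_reads must be >= 0")
  g <- ann$genes
  if (read_length > max(g$end - g$start))
    stop("read_length larger than every transcript")
  retention <- if (genotype == "mut") effect$retention_mut
               else effect$retention_wt
  ## guard: a read must never span two junctions (ReadSet allows one gap)
  ii <- ann$introns
  if (nrow(ii)) {
    for (gid in unique(ii$gene)) {
      d <- ii[ii$gene == gid, , drop = FALSE]
      d <- d[order(d$start), , drop = FALSE]
      gr <- g[match(gid, g$id), ]
      chunks <- diff(c(gr$start, t(cbind(d$start, d$end)), gr$end))
      exon_chunks <- chunks[seq(1, length(chunks), by = 2)]
      if (any(exon_chunks < read_length))
        stop("read_length ", read_length, " exceeds an exonic chunk of ",
             "gene ", gid, "; reads would span two junctions")
    }
  }
  base_seed <- if (is.null(seed)) effect$seed else seed
  stream <- if (genotype == "mut") 3 else 4
  with_seed(derive_seed(base_seed, stream), {
    weights <- stats::rlnorm(nrow(g), log(100), 1) * (g$end - g$start)
    gene_idx <- sample.int(nrow(g), n_reads, replace = TRUE,
                           prob = weights)
    out <- vector("list", n_reads)
    for (r in seq_len(n_reads)) {
      i <- gene_idx[r]
      gid <- g$id[i]
      ints <- ii[ii$gene == gid, , drop = FALSE]
      ints <- ints[order(ints$start), , drop = FALSE]
      retained <- if (nrow(ints))
        stats::runif(nrow(ints)) < retention else logical(0)
      ## genomic segments of this transcript copy
      seg_start <- g$start[i]; segs <- list()
      if (nrow(ints)) {
        for (k in seq_len(nrow(ints))) {
          if (!retained[k]) {
            segs[[length(segs) + 1]] <- c(seg_start, ints$start[k])
            seg_start <- ints$end[k]
          }
        }
      }
      segs[[length(segs) + 1]] <- c(seg_start, g$end[i])
      segs <- do.call(rbind, segs)
      seg_len <- segs[, 2] - segs[, 1]
      tx_len <- sum(seg_len)
      if (read_length > tx_len) { out[[r]] <- NULL; next }
      pos <- floor(stats::runif(1, 0, tx_len - read_length + 1))
      ## map [pos, pos + read_length) from transcript to genome
      offs <- cumsum(c(0, seg_len))
      s1 <- findInterval(pos, offs, rightmost.closed = FALSE)
      s2 <- findInterval(pos + read_length - 1, offs)
      a_start <- segs[s1, 1] + (pos - offs[s1])
      if (s1 == s2) {
        out[[r]] <- data.frame(chrom = g$chrom[i], strand = g$strand[i],
                               start1 = a_start,
                               end1 = a_start + read_length,
                               start2 = NA_real_, end2 = NA_real_)
      } else {
        len1 <- segs[s1, 2] - a_start
        out[[r]] <- data.frame(chrom = g$chrom[i], strand = g$strand[i],
                               start1 = a_start, end1 = segs[s1, 2],
                               start2 = segs[s2, 1],
                               end2 = segs[s2, 1] + read_length - len1)
      }
    }
    reads <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    rownames(reads) <- NULL
    structure(reads, class = c("ReadSet", "data.frame"))
  })
}

#' Protein-complex specification for purification simulation
#'
#' Describes a multi-subunit complex as disjoint named submodules with
#' per-protein expected abundances (fraction of the bait), plus named
#' deletion backgrounds that each remove a set of submodules.
#'
#' @param submodules named list of character vectors of protein ids;
#'   submodules must be disjoint.
#' @param bait bait protein id; must belong to exactly one submodule.
#' @param baseline_abundance named numeric vector: expected fraction of
#'   bait per protein (bait itself 1).
#' @param backgrounds named list: each element the submodule names
#'   removed by that deletion background.
#' @param contaminant_count number of sub-threshold contaminant proteins.
#' @param contaminant_ibaq_range iBAQ range of contaminants (kept below
#'   the significance floor).
#' @return a `ComplexSpec` list.
#' @export
complex_spec <- function(submodules, bait, baseline_abundance,
                         backgrounds = list(),
                         contaminant_count = 15,
                         contaminant_ibaq_range = c(1000, 49000)) {
  all_ids <- unlist(submodules, use.names = FALSE)
  if (anyDuplicated(all_ids)) stop("submodules must be disjoint")
  if (sum(vapply(submodules, function(s) bait %in% s, logical(1))) != 1)
    stop("bait must belong to exactly one submodule")
  if (!all(all_ids %in% names(baseline_abundance)))
    stop("baseline_abundance must cover every submodule member")
  for (b in backgrounds)
    if (!all(b %in% names(submodules)))
      stop("background removes unknown submodule: ",
           paste(setdiff(b, names(submodules)), collapse = ", "))
  structure(list(submodules = submodules, bait = bait,
                 baseline_abundance = baseline_abundance,
                 backgrounds = backgrounds,
                 contaminant_count = contaminant_count,
                 contaminant_ibaq_range = contaminant_ibaq_range),
            class = "ComplexSpec")
}

#' Default synthetic four-submodule complex
#'
#' A bait-centred complex with four disjoint submodules and four deletion
#' backgrounds chosen so that every submodule has a distinct presence
#' pattern across the wild-type plus deletion purifications.
#'
#' @return a `ComplexSpec`.
#' @export
default_complex_spec <- function() {
  complex_spec(
    submodules = list(
      core = c("protA", "protB"),
      cap = c("protC", "protD"),
      poly = c("protE", "protF", "protG"),
      reg = c("protH", "protI")),
    bait = "protA",
    baseline_abundance = c(protA = 1, protB = 0.8, protC = 0.12,
                           protD = 0.1, protE = 0.3, protF = 0.25,
                           protG = 0.05, protH = 0.04, protI = 0.02),
    backgrounds = list(d_cap = "cap", d_poly = "poly", d_reg = "reg",
                       d_poly_reg = c("poly", "reg")))
}

#' Simulate an iBAQ purification table
#'
#' Proteins of submodules removed by the chosen genetic background get
#' iBAQ 0 and spectral count 0; the others get
#' `iBAQ = bait_iBAQ x baseline_abundance x log-normal noise` (bait
#' itself noise-free so percent-of-bait is anchored). Contaminants are
#' added below the default significance floor.
#'
#' @param spec a [complex_spec()].
#' @param background background name from `spec$backgrounds`, or
#'   `"wild_type"`.
#' @param seed RNG seed.
#' @param noise_sd log2-scale noise sd on member abundances (default 0).
#' @param bait_ibaq iBAQ of the bait (default 1e8).
#' @param purification purification id recorded on the table.
#' @return a `ProteinQuantTable` (see [protein_quant_table()]).
#' @export
simulate_ibaq_table <- function(spec, background = "wild_type", seed = 1,
                                noise_sd = 0, bait_ibaq = 1e8,
                                purification = NULL) {
  if (!identical(background, "wild_type") &&
      !background %in% names(spec$backgrounds))
    stop("unknown background: ", background)
  removed_mods <- if (identical(background, "wild_type")) character()
                  else spec$backgrounds[[background]]
  removed <- unlist(spec$submodules[removed_mods], use.names = FALSE)
  members <- unlist(spec$submodules, use.names = FALSE)
  with_seed(derive_seed(seed, 5), {
    noise <- feature_noise(length(members), noise_sd)
    ibaq <- bait_ibaq * spec$baseline_abundance[members] * noise
    ibaq[members == spec$bait] <- bait_ibaq
    ibaq[members %in% removed] <- 0
    sc <- ifelse(ibaq > 0, pmax(1L, round(ibaq / 5e5)), 0L)
    cont_n <- spec$contaminant_count
    cont <- data.frame(
      protein = sprintf("cont%02d", seq_len(cont_n)),
      ibaq = round(stats::runif(cont_n, spec$contaminant_ibaq_range[1],
                                spec$contaminant_ibaq_range[2])),
      spectral_counts = sample(0:3, cont_n, replace = TRUE))
    df <- rbind(data.frame(protein = members, ibaq = unname(ibaq),
                           spectral_counts = unname(sc)),
                cont)
    protein_quant_table(df,
                        purification = purification %||%
                          paste0(spec$bait, "_", background),
                        bait = spec$bait, background = background)
  })
}

## ---------------------------------------------------------------------
## Writers for the emulated input formats
## ---------------------------------------------------------------------

#' Write a probe-ratio table as TSV
#' @param probe_signal a `ProbeSignal`.
#' @param path output file.
#' @param header character vector of provenance comment lines.
#' @return `path`, invisibly.
#' @export
write_probe_table <- function(probe_signal, path, header = character()) {
  write_tsv_header(probe_signal$probes, path, header)
}

#' Read a probe-ratio table written by [write_probe_table()]
#' @param path TSV with columns chrom, center, strand, value.
#' @param resolution probe design resolution (bp); inferred from probe
#'   spacing when `NULL`.
#' @return a `ProbeSignal`.
#' @export
read_probe_table <- function(path, resolution = NULL) {
  df <- read_tsv_header(path)
  if (!all(c("chrom", "center", "strand", "value") %in% names(df)))
    stop("probe table must have columns chrom, center, strand, value")
  check_strand(df$strand)
  if (is.null(resolution)) {
    d <- diff(sort(df$center[df$chrom == df$chrom[1]]))
    resolution <- if (length(d)) min(d) else 40
  }
  structure(list(probes = df, resolution = resolution,
                 mode = "log2_ratio"),
            class = "ProbeSignal")
}

#' Write a read set as a tab-delimited table
#' @param reads a `ReadSet`.
#' @param path output file.
#' @param header provenance comment lines.
#' @return `path`, invisibly.
#' @export
write_read_table <- function(reads, path, header = character()) {
  write_tsv_header(as.data.frame(reads), path, header)
}

#' Read a read table written by [write_read_table()]
#' @param path tab-delimited file with columns chrom, strand, start1,
#'   end1 and optional start2, end2.
#' @return a `ReadSet`.
#' @export
read_read_table <- function(path) {
  df <- read_tsv_header(path)
  if (!all(c("chrom", "strand", "start1", "end1") %in% names(df)))
    stop("read table must have columns chrom, strand, start1, end1")
  if (is.null(df$start2)) df$start2 <- NA_real_
  if (is.null(df$end2)) df$end2 <- NA_real_
  gapped <- !is.na(df$start2)
  if (any(df$end1[gapped] >= df$start2[gapped]))
    stop("gapped read with non-positive gap")
  structure(df, class = c("ReadSet", "data.frame"))
}
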