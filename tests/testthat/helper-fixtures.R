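# Hand-built fixtures small enough to verify by eye or brute force.

tiny_annotation <- function() {
  genome_annotation(
    chromosomes = c(chrT = 20000),
    genes = data.frame(
      id = c("gf", "gr", "gi", "gn"),
      chrom = "chrT",
      strand = c("+", "-", "+", "+"),
      start = c(1000, 5000, 9000, 13000),
      end = c(3000, 7000, 11500, 14500),
      is_orf = c(TRUE, TRUE, TRUE, TRUE),
      in_mmi1_regulon = c(FALSE, FALSE, FALSE, TRUE)),
    introns = data.frame(
      id = c("gi.i1", "gi.i2"),
      gene = c("gi", "gi"),
      start = c(9500, 10500),
      end = c(9600, 10700)))
}

# Constant-value log2-ratio signal over the whole genome
uniform_ratio_signal <- function(ann, value) {
  sig <- stranded_signal(ann$chromosomes, "log2_ratio")
  for (ch in names(sig$values))
    for (st in c("+", "-"))
      sig$values[[ch]][[st]][] <- value
  sig
}

# Constant coverage over the whole genome
uniform_coverage_signal <- function(ann, value) {
  sig <- stranded_signal(ann$chromosomes, "coverage")
  for (ch in names(sig$values))
    for (st in c("+", "-"))
      sig$values[[ch]][[st]][] <- value
  sig
}

# Reflect an annotation through the chromosome midline and flip strands
mirror_annotation <- function(ann) {
  g <- ann$genes
  len <- ann$chromosomes[g$chrom]
  g2 <- data.frame(id = g$id, chrom = g$chrom,
                   strand = ifelse(g$strand == "+", "-", "+"),
                   start = len - g$end, end = len - g$start,
                   is_orf = g$is_orf, in_mmi1_regulon = g$in_mmi1_regulon)
  i <- ann$introns
  i2 <- if (nrow(i)) {
    ilen <- ann$chromosomes[i$chrom]
    data.frame(id = i$id, gene = i$gene,
               start = ilen - i$end, end = ilen - i$start)
  } else NULL
  genome_annotation(ann$chromosomes, g2, i2)
}

# A small probe set covering one chromosome at fixed pitch on one strand
regular_probes <- function(chrom, centers, strand, values) {
  structure(list(probes = data.frame(chrom = chrom, center = centers,
                                     strand = strand, value = values,
                                     stringsAsFactors = FALSE),
                 resolution = if (length(centers) > 1)
                   min(diff(sort(centers))) else 40,
                 mode = "log2_ratio"),
            class = "ProbeSignal")
}

# Brute-force per-probe binning oracle: for each probe decide its bin by
# scanning the bin bounds, then average per column. Independent of
# bin_gene_row's vectorized path.
oracle_bin_row <- function(gene, probes, n_bins, flank_probes,
                           orientation) {
  strand_used <- if (orientation == "sense") gene$strand
                 else setdiff(c("+", "-"), gene$strand)
  pr <- probes$probes
  pr <- pr[pr$chrom == gene$chrom & pr$strand == strand_used, ]
  pr <- pr[order(pr$center), ]
  bounds <- seq(gene$start, gene$end, length.out = n_bins + 1)
  bins <- rep(NA_real_, n_bins)
  for (b in seq_len(n_bins)) {
    vals <- c()
    for (k in seq_len(nrow(pr))) {
      ctr <- pr$center[k]
      if (ctr < gene$start || ctr >= gene$end) next
      in_bin <- if (b < n_bins) ctr >= bounds[b] && ctr < bounds[b + 1]
                else ctr >= bounds[b] && ctr < gene$end
      if (in_bin) vals <- c(vals, pr$value[k])
    }
    if (length(vals)) bins[b] <- mean(vals)
  }
  pad <- function(v, n, front) {
    if (front) c(rep(NA_real_, n - length(v)), v)
    else c(v, rep(NA_real_, n - length(v)))
  }
  left <- pad(utils::tail(pr$value[pr$center < gene$start], flank_probes),
              flank_probes, front = TRUE)
  right <- pad(utils::head(pr$value[pr$center >= gene$end], flank_probes),
               flank_probes, front = FALSE)
  if (gene$strand == "+") c(left, bins, right)
  else c(rev(right), rev(bins), rev(left))
}
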