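make_coverage <- function(ann, gene_medians) {
  sig <- stranded_signal(ann$chromosomes, "coverage")
  for (i in seq_len(nrow(ann$genes))) {
    g <- ann$genes[i, ]
    sig <- exosurv:::signal_add(sig, g$chrom, g$strand, g$start, g$end,
                                gene_medians[[g$id]])
  }
  sig
}

test_that("coverage normalization anchors intronless medians at 100", {
  ann <- genome_annotation(
    c(chrI = 30000),
    data.frame(id = paste0("g", 1:4), chrom = "chrI", strand = "+",
               start = c(0, 6000, 12000, 18000) + 500,
               end = c(0, 6000, 12000, 18000) + 4500))
  ## per-gene medians {10, 20, 30, 40} -> median 25 -> factor 4
  sig <- make_coverage(ann, c(g1 = 10, g2 = 20, g3 = 30, g4 = 40))
  norm <- normalize_coverage(sig, ann)
  expect_equal(attr(norm, "norm_factor"), 4)
  meds <- intronless_gene_medians(norm, ann)
  expect_equal(unname(stats::median(meds)), 100)
  ## medians already centred at 100 -> factor 1, unchanged signal
  sig2 <- make_coverage(ann, c(g1 = 50, g2 = 100, g3 = 150, g4 = 100))
  norm2 <- normalize_coverage(sig2, ann)
  expect_equal(attr(norm2, "norm_factor"), 1)
  ## idempotence
  norm3 <- normalize_coverage(norm, ann)
  expect_equal(attr(norm3, "norm_factor"), 1)
  expect_equal(norm3$values$chrI[["+"]], norm$values$chrI[["+"]])
})

test_that("normalization requires intronless ORFs with signal", {
  ann <- genome_annotation(
    c(chrI = 10000),
    data.frame(id = "g1", chrom = "chrI", strand = "+",
               start = 1000, end = 3000),
    data.frame(id = "i1", gene = "g1", start = 1500, end = 1600))
  sig <- uniform_coverage_signal(ann, 10)
  expect_error(normalize_coverage(sig, ann), "no intronless")
  ann2 <- genome_annotation(
    c(chrI = 10000),
    data.frame(id = "g1", chrom = "chrI", strand = "+",
               start = 1000, end = 3000))
  zero <- stranded_signal(ann2$chromosomes, "coverage")
  expect_error(normalize_coverage(zero, ann2), "zero")
})

test_that("intron filter applies length bounds inclusively", {
  base <- 2000 * (0:4)
  ann <- genome_annotation(
    c(chrI = 20000),
    data.frame(id = paste0("g", 1:5), chrom = "chrI", strand = "+",
               start = base + 100, end = base + 1900),
    data.frame(id = paste0("i", 1:5), gene = paste0("g", 1:5),
               start = base + 600,
               end = base + 600 + c(19, 20, 400, 401, 100)))
  sig <- uniform_coverage_signal(ann, 100)
  kept <- filter_introns(ann, sig, intron_filter(low_pct = 0,
                                                 high_pct = 0))
  expect_setequal(kept, c("i2", "i3", "i5"))
  ## non-ORF parents are dropped when orf_only
  ann$genes$is_orf[5] <- FALSE
  kept2 <- filter_introns(ann, sig, intron_filter(low_pct = 0,
                                                  high_pct = 0))
  expect_setequal(kept2, c("i2", "i3"))
})

test_that("percentile exclusion drops floor(pct * N) introns per side", {
  n <- 10
  base <- 2000 * (0:(n - 1))
  ann <- genome_annotation(
    c(chrI = 2000 * n + 1000),
    data.frame(id = sprintf("g%02d", 1:n), chrom = "chrI", strand = "+",
               start = base + 100, end = base + 1900),
    data.frame(id = sprintf("i%02d", 1:n), gene = sprintf("g%02d", 1:n),
               start = base + 600, end = base + 700))
  ## distinct proxies 10, 20, ..., 100
  sig <- make_coverage(ann, stats::setNames(10 * (1:n),
                                            sprintf("g%02d", 1:n)))
  kept <- filter_introns(ann, sig, intron_filter())
  ## 10/10% of 10 -> drop exactly the lowest and the highest
  expect_setequal(kept, sprintf("i%02d", 2:9))
  det <- filter_introns(ann, sig, intron_filter(), details = TRUE)
  expect_equal(det$proxy, 10 * (1:n))
})

test_that("ranking scores and upper-quartile selection are exact", {
  ## intron with mut body 30, wt body 10, mut flank 100 -> score 0.2
  ann <- genome_annotation(
    c(chrI = 10000),
    data.frame(id = "g1", chrom = "chrI", strand = "+",
               start = 1000, end = 3000),
    data.frame(id = "i1", gene = "g1", start = 1800, end = 1900))
  wt <- make_coverage(ann, c(g1 = 100))
  wt <- exosurv:::signal_add(wt, "chrI", "+", 1800, 1900, 10 - 100)
  mut <- make_coverage(ann, c(g1 = 100))
  mut <- exosurv:::signal_add(mut, "chrI", "+", 1800, 1900, 30 - 100)
  r <- rank_and_select_introns(ann, "i1", wt, mut)
  expect_equal(r$score, 0.2)
  expect_true(r$selected)
  ## ceil(N/4) property over a range of N
  for (n in c(1:10, 15, 16, 17, 100, 3935)) {
    expect_equal(sum(select_upper_quartile(n)), ceiling(n / 4), info = n)
  }
})

test_that("zero mutant flank coverage drops the intron with a warning", {
  ann <- genome_annotation(
    c(chrI = 10000),
    data.frame(id = c("g1", "g2"), chrom = "chrI", strand = "+",
               start = c(1000, 5000), end = c(3000, 7000)),
    data.frame(id = c("i1", "i2"), gene = c("g1", "g2"),
               start = c(1800, 5800), end = c(1900, 5900)))
  wt <- make_coverage(ann, c(g1 = 100, g2 = 100))
  mut <- make_coverage(ann, c(g1 = 100, g2 = 0))
  expect_warning(r <- rank_and_select_introns(ann, c("i1", "i2"),
                                              wt, mut),
                 "zero mutant flank")
  expect_equal(r$id, "i1")
})

test_that("meta-intron composite matches hand-computed geometric means", {
  ## two introns with uniform coverages 4 and 16: per-column geometric
  ## mean 8 -> log2 = 3
  base <- c(0, 4000)
  ann <- genome_annotation(
    c(chrI = 10000),
    data.frame(id = c("g1", "g2"), chrom = "chrI", strand = "+",
               start = base + 500, end = base + 3500),
    data.frame(id = c("i1", "i2"), gene = c("g1", "g2"),
               start = base + 1500, end = base + 1580))
  sig <- make_coverage(ann, c(g1 = 4, g2 = 16))
  pr <- intron_composite(ann, c("i1", "i2"), sig)
  expect_equal(length(pr$profile), 20 + 40 + 20)
  expect_equal(unname(pr$profile), rep(3, 80))
  ## uniform coverage 100 -> all columns log2(100), no pseudocount shift
  sig100 <- make_coverage(ann, c(g1 = 100, g2 = 100))
  pr100 <- intron_composite(ann, c("i1", "i2"), sig100)
  expect_equal(unname(pr100$profile), rep(log2(100), 80))
})

test_that("meta-intron bins handle introns shorter than 40 bp", {
  ann <- genome_annotation(
    c(chrI = 10000),
    data.frame(id = "g1", chrom = "chrI", strand = "+",
               start = 500, end = 3500),
    data.frame(id = "i1", gene = "g1", start = 1500, end = 1522))
  sig <- make_coverage(ann, c(g1 = 50))
  pr <- intron_composite(ann, "i1", sig)
  expect_equal(unname(pr$profile[sprintf("i%02d", 1:40)]),
               rep(log2(50), 40))
})

test_that("meta-intron elevation recovers the retention fold-change", {
  ann <- make_toy_genome(80, seed = 31)
  eff <- effect_profile(retention_wt = 0.05, retention_mut = 0.15,
                        noise_sd = 0.2, seed = 31)
  sig <- simulate_signals(ann, eff)
  wt <- normalize_coverage(sig$wt, ann)
  mut <- normalize_coverage(sig$mut, ann)
  ids <- filter_introns(ann, wt)
  pw <- intron_composite(ann, ids, wt)
  pm <- intron_composite(ann, ids, mut)
  d <- pm$profile - pw$profile
  intron_cols <- grep("^i", names(d))
  expect_equal(mean(d[intron_cols]), log2(3), tolerance = 0.3)
  exon_cols <- grep("^e", names(d))
  expect_equal(mean(d[exon_cols]), 0, tolerance = 0.1)
})

test_that("read classes partition intron-informative reads", {
  ann <- make_toy_genome(25, seed = 32)
  skip_if(nrow(ann$introns) == 0)
  eff <- effect_profile(retention_mut = 0.3)
  reads <- simulate_reads(ann, eff, 4000, genotype = "mut")
  fl <- intron_flanks(ann)
  df <- as.data.frame(reads)
  for (k in seq_len(nrow(fl))) {
    same <- df$chrom == fl$chrom[k] & df$strand == fl$strand[k]
    contig <- same & is.na(df$start2)
    over <- contig & df$start1 < fl$end[k] & df$end1 > fl$start[k]
    cross <- over & (df$start1 < fl$start[k] | df$end1 > fl$end[k])
    internal <- over & !cross
    q <- quantify_splicing(reads, ann, fl$id[k])
    ## US + intron-internal = all contiguous intron-overlapping reads
    expect_equal(q$unspliced + sum(internal), sum(over), info = fl$id[k])
  }
})

test_that("boundary-span fraction counts reads per the definition", {
  ann <- genome_annotation(
    c(chrI = 10000),
    data.frame(id = "g1", chrom = "chrI", strand = "+",
               start = 1000, end = 3000),
    data.frame(id = "i1", gene = "g1", start = 1800, end = 1900))
  mk_read <- function(s1, e1, s2 = NA, e2 = NA)
    data.frame(chrom = "chrI", strand = "+", start1 = s1, end1 = e1,
               start2 = s2, end2 = e2)
  reads <- structure(rbind(
    mk_read(1750, 1810),        # crosses 5' boundary
    mk_read(1890, 1950),        # crosses 3' boundary
    mk_read(1820, 1870),        # fully inside the intron
    mk_read(1795, 1855),        # crosses 5' boundary
    mk_read(1750, 1800, 1900, 1950),  # spliced exactly: excluded
    mk_read(500, 560)),         # elsewhere
    class = c("ReadSet", "data.frame"))
  expect_equal(boundary_span_fraction(reads, ann), 3 / 4)
  q <- quantify_splicing(reads, ann, "i1")
  expect_equal(q$spliced, 1)
  expect_equal(q$unspliced, 3)
  expect_equal(q$us_ratio, 3)
  ## mis-spliced gap overlapping but not matching the intron
  reads2 <- structure(rbind(mk_read(1700, 1790, 1900, 1950)),
                      class = c("ReadSet", "data.frame"))
  q2 <- quantify_splicing(reads2, ann, "i1")
  expect_equal(q2$misspliced, 1)
  expect_equal(q2$spliced + q2$unspliced, 0)
})

test_that("US/S ratios and WT normalization follow the definitions", {
  ann <- genome_annotation(
    c(chrI = 10000),
    data.frame(id = "g1", chrom = "chrI", strand = "+",
               start = 1000, end = 3000),
    data.frame(id = "i1", gene = "g1", start = 1800, end = 1900))
  mk <- function(n_s, n_us) {
    rows <- list()
    for (i in seq_len(n_s))
      rows[[length(rows) + 1]] <- data.frame(
        chrom = "chrI", strand = "+", start1 = 1750, end1 = 1800,
        start2 = 1900, end2 = 1950)
    for (i in seq_len(n_us))
      rows[[length(rows) + 1]] <- data.frame(
        chrom = "chrI", strand = "+", start1 = 1780, end1 = 1840,
        start2 = NA_real_, end2 = NA_real_)
    structure(do.call(rbind, rows), class = c("ReadSet", "data.frame"))
  }
  q <- quantify_splicing(mk(3, 1), ann, "i1", wt_reads = mk(4, 1))
  expect_equal(q$us_ratio, 1 / 3)
  expect_equal(q$wt_us_ratio, 1 / 4)
  expect_equal(q$normalized_ratio, 4 / 3)
  ## S = 0 -> ratio undefined but counts still reported
  q0 <- quantify_splicing(mk(0, 2), ann, "i1")
  expect_equal(q0$unspliced, 2)
  expect_true(is.na(q0$us_ratio))
})

test_that("the stabilization diagnostic applies the decision rules", {
  ## build coverage pairs realizing the prescribed fold-change triples
  ann <- genome_annotation(
    c(chrI = 30000),
    data.frame(id = c("gi", "gn"), chrom = "chrI", strand = "+",
               start = c(1000, 10000), end = c(5000, 14000)),
    data.frame(id = "i1", gene = "gi", start = 2000, end = 2100))
  build <- function(intron_f, exon_f, intronless_f) {
    wt <- make_coverage(ann, c(gi = 100, gn = 100))
    wt <- exosurv:::signal_add(wt, "chrI", "+", 2000, 2100, 20 - 100)
    mut <- make_coverage(ann, c(gi = 100 * exon_f,
                                gn = 100 * intronless_f))
    mut <- exosurv:::signal_add(mut, "chrI", "+", 2000, 2100,
                                20 * intron_f - 100 * exon_f)
    list(wt = wt, mut = mut)
  }
  s <- build(3, 2.9, 1)
  expect_equal(stabilization_diagnostic(s$wt, s$mut, ann, "i1")$verdict,
               "stabilization")
  s <- build(3, 1, 1)
  expect_equal(stabilization_diagnostic(s$wt, s$mut, ann, "i1")$verdict,
               "splicing defect")
  s <- build(1, 1, 1)
  expect_equal(stabilization_diagnostic(s$wt, s$mut, ann, "i1")$verdict,
               "no change")
  expect_error(stabilization_diagnostic(s$wt, s$mut, ann, character(0)),
               "no introns")
})
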