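test_that("bin values match the brute-force per-probe oracle", {
  ann <- make_toy_genome(5, seed = 21)
  eff <- effect_profile(fold_changes = c(PROMPT = 8, AS = 4, IGT3 = 2),
                        noise_sd = 0.3, retention_mut = 0.05)
  sig <- simulate_signals(ann, eff)
  probes <- simulate_probe_ratios(ann, sig$wt, sig$mut)
  cfg <- profile_config()
  for (i in seq_len(nrow(ann$genes))) {
    g <- ann$genes[i, , drop = FALSE]
    for (orient in c("sense", "antisense")) {
      got <- bin_gene_row(g, probes, cfg, orient)
      want <- oracle_bin_row(g, probes, cfg$n_bins, cfg$flank_probes,
                             orient)
      expect_equal(unname(got), want,
                   info = paste(g$id, orient))
    }
  }
})

test_that("probe partition: every body probe lands in exactly one bin", {
  ann <- make_toy_genome(10, seed = 22)
  sig <- simulate_signals(ann, effect_profile())
  probes <- simulate_probe_ratios(ann, sig$wt, sig$mut)
  cfg <- profile_config()
  for (i in seq_len(nrow(ann$genes))) {
    g <- ann$genes[i, ]
    pr <- probes$probes
    body <- pr[pr$chrom == g$chrom & pr$strand == g$strand &
               pr$center >= g$start & pr$center < g$end, ]
    bounds <- seq(g$start, g$end, length.out = cfg$n_bins + 1)
    counts <- vapply(seq_len(cfg$n_bins), function(b)
      sum(body$center >= bounds[b] &
          (body$center < bounds[b + 1] | b == cfg$n_bins &
             body$center < g$end)), integer(1))
    expect_equal(sum(counts), nrow(body))
  }
})

test_that("geometric column averaging works on the log2 scale", {
  m <- rbind(c(1, 1), c(3, NA))
  colnames(m) <- c("a", "b")
  expect_equal(unname(composite_average(m)), c(2, 1))
  ## ratios {2, 8}: geometric mean 4 -> log2 = 2
  m2 <- cbind(x = log2(c(2, 8)))
  expect_equal(unname(composite_average(m2)),
               log2(sqrt(2 * 8)))
  ## single row passes through unchanged
  m3 <- cbind(a = 1.5, b = -0.5)
  expect_equal(composite_average(m3), c(a = 1.5, b = -0.5))
  ## all-missing column -> NA
  m4 <- cbind(a = c(1, 2), b = c(NA_real_, NA_real_))
  expect_true(is.na(composite_average(m4)["b"]))
})

test_that("uniform signal gives flat rows in both orientations", {
  ann <- tiny_annotation()
  sig <- uniform_ratio_signal(ann, 2)
  cfg <- profile_config()
  for (orient in c("sense", "antisense")) {
    row <- bin_gene_row(ann$genes[1, ], sig, cfg, orient)
    expect_equal(unname(row), rep(2, 35))
  }
})

test_that("a mirrored reverse-strand gene yields the identical row", {
  ## gene lengths divisible by n_bins so bin bounds are integers: the
  ## boundary tie-break is then symmetric under reflection
  ann <- genome_annotation(
    c(chrS = 20000),
    data.frame(id = c("ga", "gb", "gc"), chrom = "chrS",
               strand = c("+", "-", "+"),
               start = c(2000, 7000, 13000),
               end = c(2000 + 1500, 7000 + 2400, 13000 + 3000)))
  eff <- effect_profile(fold_changes = c(PROMPT = 8, AS = 4),
                        noise_sd = 0.2, retention_mut = 0.05)
  sig <- simulate_signals(ann, eff)
  ratio <- log2_ratio_signal(sig$mut, sig$wt)
  mir_ann <- mirror_annotation(ann)
  L <- unname(ann$chromosomes)
  mir_ratio <- stranded_signal(ann$chromosomes, "log2_ratio")
  ch <- names(ann$chromosomes)
  mir_ratio$values[[ch]][["+"]] <- rev(ratio$values[[ch]][["-"]])
  mir_ratio$values[[ch]][["-"]] <- rev(ratio$values[[ch]][["+"]])
  cfg <- profile_config()
  for (i in seq_len(nrow(ann$genes))) {
    row <- bin_gene_row(ann$genes[i, ], ratio, cfg, "sense")
    mrow <- bin_gene_row(mir_ann$genes[i, ], mir_ratio, cfg, "sense")
    expect_equal(mrow, row, info = ann$genes$id[i])
  }
})

test_that("WT normalization zeroes the sense body and is idempotent", {
  cfg <- profile_config(n_bins = 3, flank_probes = 1)
  sense <- c(u01 = 0.1, b01 = 0.4, b02 = 0.3, b03 = 0.2, d01 = 0.5)
  as_p <- c(u01 = 1.1, b01 = 1.4, b02 = 1.3, b03 = 1.2, d01 = 1.5)
  norm <- normalize_to_wt(sense, as_p, cfg)
  expect_equal(norm$offset, 0.3)
  expect_equal(mean(norm$sense[c("b01", "b02", "b03")]), 0)
  ## AS - sense differences are shift-invariant
  expect_equal(norm$antisense - norm$sense, as_p - sense)
  ## already centred profile is unchanged
  norm2 <- normalize_to_wt(norm$sense, norm$antisense, cfg)
  expect_equal(norm2$offset, 0)
  expect_equal(norm2$sense, norm$sense)
  expect_error(normalize_to_wt(c(u01 = 1, b01 = NA, b02 = NA, b03 = NA,
                                 d01 = 1), as_p, cfg), "missing")
})

test_that("expression profiles recover simulated class fold-changes", {
  ann <- make_toy_genome(120, seed = 24)
  eff <- effect_profile(fold_changes = c(PROMPT = 8, AS = 4, IGT3 = 2),
                        noise_sd = 0.2, retention_mut = 0.05, seed = 24)
  sig <- simulate_signals(ann, eff)
  ratio <- log2_ratio_signal(sig$mut, sig$wt)
  comp <- expression_composite(ann, ratio)
  ## plateau columns fully inside the 500-bp class windows (80-bp pitch)
  inw <- floor(eff$w_bp / profile_config()$probe_pitch_bp)
  as_5p <- mean(comp$antisense[sprintf("u%02d", seq_len(inw))])
  expect_equal(as_5p, 3, tolerance = 0.1)
  as_body <- mean(comp$antisense[sprintf("b%02d", 1:15)])
  expect_equal(as_body, 2, tolerance = 0.1)
  sense_3p <- mean(comp$sense[sprintf("d%02d", seq_len(inw))])
  expect_equal(sense_3p, 1, tolerance = 0.1)
  ## sense body is anchored at 0 after WT normalization
  expect_equal(mean(comp$sense[sprintf("b%02d", 1:15)]), 0,
               tolerance = 1e-12)
})

test_that("null simulation gives near-zero profiles", {
  ann <- make_toy_genome(40, seed = 25)
  eff <- effect_profile(retention_mut = 0.05)
  sig <- simulate_signals(ann, eff)
  comp <- expression_composite(ann, log2_ratio_signal(sig$mut, sig$wt))
  expect_true(all(abs(comp$sense) < 1e-9, na.rm = TRUE))
  expect_true(all(abs(comp$antisense) < 1e-9, na.rm = TRUE))
})

test_that("adding a constant shifts raw but not normalized profiles", {
  ann <- make_toy_genome(30, seed = 26)
  eff <- effect_profile(fold_changes = c(AS = 4), noise_sd = 0.1,
                        retention_mut = 0.05)
  sig <- simulate_signals(ann, eff)
  ratio <- log2_ratio_signal(sig$mut, sig$wt)
  shifted <- ratio
  ch <- names(ann$chromosomes)
  for (st in c("+", "-"))
    shifted$values[[ch]][[st]] <- shifted$values[[ch]][[st]] + 0.7
  comp <- expression_composite(ann, ratio)
  comp_s <- expression_composite(ann, shifted)
  expect_equal(comp_s$sense, comp$sense, tolerance = 1e-9)
  expect_equal(comp_s$antisense, comp$antisense, tolerance = 1e-9)
  ## un-normalized RIP machinery shifts by exactly the constant
  rip <- rip_composite(ann, ratio)
  rip_s <- rip_composite(ann, shifted)
  expect_equal(rip_s$sense - rip$sense,
               rep(0.7, length(rip$sense)) |>
                 stats::setNames(names(rip$sense)),
               tolerance = 1e-9)
})

test_that("RIP profiles keep negatives and negate under channel swap", {
  ann <- make_toy_genome(30, seed = 27)
  ip <- simulate_signals(ann, effect_profile(
    fold_changes = c(PROMPT = 4, AS = 4, IGT3 = 4, mRNA = 0.5),
    retention_mut = 0.05))
  enr <- log2_ratio_signal(ip$mut, ip$wt)
  swapped <- log2_ratio_signal(ip$wt, ip$mut)
  r1 <- rip_composite(ann, enr)
  r2 <- rip_composite(ann, swapped)
  expect_equal(r2$sense, -r1$sense, tolerance = 1e-9)
  expect_equal(r2$antisense, -r1$antisense, tolerance = 1e-9)
  ## mRNA depletion shows as negative sense body (no WT normalization)
  expect_lt(mean(r1$sense[sprintf("b%02d", 1:15)]), -0.9)
  expect_gt(mean(r1$antisense[sprintf("b%02d", 1:15)]), 1.9)
  ## positive_only drops the depleted values
  expect_true(all(is.na(positive_only(r1$sense)[sprintf("b%02d", 1:15)])))
})

test_that("regulon report equals the gene-body probe mean", {
  ann <- tiny_annotation()
  sig <- uniform_ratio_signal(ann, 3)
  rep <- regulon_report(ann, c("gn", "gf"), sig)
  expect_equal(rep$mean_log2, c(3, 3))
  expect_error(regulon_report(ann, "nope", sig), "unknown gene")
  expect_error(regulon_report(ann, character(0), sig), "empty")
  ## consistency with bin_gene_row under uniform signal
  row <- bin_gene_row(ann$genes[1, ], sig, profile_config(), "sense")
  expect_equal(mean(row[sprintf("b%02d", 1:15)]), rep$mean_log2[2])
})

test_that("composite tables round-trip the column layout", {
  ann <- make_toy_genome(30, seed = 28)
  sig <- simulate_signals(ann, effect_profile(retention_mut = 0.05))
  comp <- expression_composite(ann, log2_ratio_signal(sig$mut, sig$wt))
  f <- tempfile(fileext = ".tsv")
  write_composite_table(comp, f, header = c("test run"))
  df <- read.table(f, sep = "\t", header = TRUE, comment.char = "#")
  expect_equal(nrow(df), 35)
  expect_equal(df$position[11], "b01")
  expect_true(all(df$n_sense <= comp$n_genes["sense"]))
})
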