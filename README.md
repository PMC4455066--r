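# exosurv

Composite profiling of exosome-targeted transcripts and splicing
surveillance.

## What this package is for

The nuclear exosome, directed by adaptor complexes such as MTREC
(Mtl1–Red1 core), silences two substrate groups in fission yeast:
cryptic unstable transcripts (CUTs) — PROMPTs, antisense (AS)
transcripts and short 3'-intergenic transcripts (3'IGTs) — and
unspliced or mis-spliced pre-mRNAs. `exosurv` provides the genome-scale
analyses used to measure that targeting, for anyone working with
strand-specific expression, RIP-enrichment or RNA-seq coverage data in
compact genomes:

* **CUT classification** from annotation alone: for a gene `[s, e)` on
  the forward strand, PROMPT = reverse strand `[s − w, s)`, AS = reverse
  strand `[s, e)`, 3'IGT = forward strand `[e, e + w)` (mirrored for
  reverse-strand genes), plus intergenic-gap gene selection
  (≥ 600 bp / ≥ 100 bp on the profiled / opposite flank).
* **Composite (metagene) profiles**: each gene body split into 15 bins
  plus 10 flank probes (800 bp) per side; per column the profile is the
  log2 of the geometric mean ratio,
  `profile_j = mean_i log2(ratio_ij)`, with mean sense gene-body
  expression anchored to WT (0 on the log2 scale) for expression data
  and no normalization for RIP (IP/input) data.
* **Intron surveillance**: coverage normalization (median per-gene
  median of intronless ORFs = 100), intron filtering (ORFs, 20–400 bp,
  10–10% expression-percentile trim), retention ranking
  `score = (mut_intron − wt_intron) / mut_flank` with upper-quartile
  (`ceil(N/4)`) selection, 40-bin meta-intron composites with 20-bp
  exonic flanks, junction-level spliced/unspliced counts
  (`US/S`, normalized to WT), and a stabilization-versus-splicing
  diagnostic.
* **Interactome mapping** from iBAQ purification tables: significance
  filter (iBAQ ≥ 50,000 and ≥ 1 spectral count), percent-of-bait
  normalization, black/grey/white tiers (≥ 2.5% / ≥ 0.5%), and
  submodule inference from presence patterns across deletion
  backgrounds.
* A **synthetic-data generator** producing annotation, stranded
  coverage, tiling-probe ratios, gapped/contiguous reads and
  purification tables with configurable effect sizes, so every stage is
  testable end to end without external data.

## Worked example

```r
library(exosurv)

ann <- make_toy_genome(200, seed = 1)
#> GenomeAnnotation: 1 chromosome(s), 200 genes, 175 introns

## CUT-accumulating mutant: PROMPT/AS/3'IGT fold-changes 8/4/2
eff <- effect_profile(fold_changes = c(PROMPT = 8, AS = 4, IGT3 = 2),
                      noise_sd = 0.2, retention_mut = 0.05, seed = 1)
sig <- simulate_signals(ann, eff)
comp <- expression_composite(ann, log2_ratio_signal(sig$mut, sig$wt))
#> Composite profiles: 200 sense / 200 antisense genes, 35 columns;
#> WT offset 0.00253

round(comp$antisense[c("u03", "u02", "u01", "b01", "b02")], 2)
#>  u03  u02  u01  b01  b02
#> 3.00 3.00 3.00 2.00 2.00
round(comp$sense[c("b15", "d01", "d02", "d03")], 2)
#>  b15  d01  d02  d03
#> 0.00 1.03 1.03 1.03
```

The AS profile's 5' flank sits at 3.0 log2 units (the configured 8-fold
PROMPT accumulation), the AS body at 2.0 (4-fold), and the sense 3'
flank at about 1.0 (2-fold 3'IGTs) while the sense body is anchored at
0 after WT normalization.

```r
## Splicing-surveillance mutant: intron retention 0.05 -> 0.15
eff2 <- effect_profile(retention_wt = 0.05, retention_mut = 0.15,
                       noise_sd = 0.2, seed = 1)
sig2 <- simulate_signals(ann, eff2)
wt  <- normalize_coverage(sig2$wt, ann)
mut <- normalize_coverage(sig2$mut, ann)
ids <- filter_introns(ann, wt)          # 141 introns kept
d <- intron_composite(ann, ids, mut)$profile -
     intron_composite(ann, ids, wt)$profile
mean(d[grep("^i", names(d))])
#> 1.539                                  # log2(3) = 1.585

stabilization_diagnostic(wt, mut, ann, ids)
#> Stabilization diagnostic (tau = 0.5 log2):
#>   intron log2FC       1.539
#>   exon-flank log2FC  -0.034
#>   intronless log2FC  -0.025
#>   verdict: splicing defect

reads <- simulate_reads(ann, eff2, 20000, genotype = "mut")
boundary_span_fraction(reads, ann, ids)
#> 0.851
```

The meta-intron profile recovers the simulated 3-fold retention
increase; exonic and intronless coverage are flat, so the diagnostic
calls a splicing defect rather than pre-mRNA stabilization; and 85% of
intron-overlapping reads span an exon–intron boundary, the signature of
unspliced transcripts rather than excised lariats.

The end-to-end pipeline (simulate → profile → introns → interactome)
is available as `cmd_simulate()`, `cmd_profile()`, `cmd_introns()` and
`cmd_interactome()` over a single `run_config()`; every output file
carries the tool version, config hash and seed in its header.

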