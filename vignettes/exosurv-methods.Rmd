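---
title: "Methods: composite profiling and splicing surveillance with exosurv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composite profiling and splicing surveillance with exosurv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exosurv)
```

## Scope and scientific background

In fission yeast, the nuclear exosome — guided by adaptor complexes such
as MTREC (Mtl1–Red1 core) — rapidly degrades two broad substrate groups:
cryptic unstable transcripts (CUTs) and unspliced or mis-spliced
pre-mRNAs. `exosurv` implements the computational analyses by which such
targeting is measured genome-wide, and a synthetic-data generator that
emulates every input those analyses need, so the whole pipeline can be
exercised, validated and benchmarked without any external dataset.

The analyses are:

1. **CUT classification** — deriving PROMPT, antisense (AS) and
   3'-intergenic-transcript (3'IGT) intervals from annotation alone.
2. **Composite (metagene) profiles** — strand-specific, binned averages
   of expression ratios (mutant/WT) or RIP enrichment (IP/input) over
   many genes.
3. **Intron surveillance** — coverage normalization, intron filtering
   and ranking, 40-bin meta-intron profiles, junction-level
   spliced/unspliced quantification, and a diagnostic that separates
   pre-mRNA stabilization from a splicing defect.
4. **Interactome mapping** — iBAQ significance filtering,
   percent-of-bait normalization, abundance tiering and submodule
   inference across deletion-background purifications.

## Coordinate conventions

All coordinates are 0-based half-open internally; GFF3 (1-based closed)
is converted at the boundary by `read_annotation()` /
`write_annotation()`. This removes off-by-one ambiguity from binning
arithmetic. The TSS of a forward-strand gene is its span start; for a
reverse-strand gene it is `end - 1`. "Upstream", "downstream", "5'" and
"3'" are always strand-relative, and every profile row is laid out in
the gene's (or intron's) 5'→3' direction, so forward- and reverse-strand
features are strictly symmetric. Overlapping bedGraph intervals are
rejected rather than summed: per-strand tracks are expected to partition
the covered positions, and silently adding overlaps would hide malformed
input.

## CUT classes and gene selection

For a forward-strand gene `[s, e)` the class intervals are: PROMPT =
reverse strand `[s − w, s)`, AS = reverse strand `[s, e)`, 3'IGT =
forward strand `[e, e + w)`, mirrored for reverse-strand genes and
clipped at chromosome ends. The window `w` defaults to 500 bp: PROMPTs
and 3'IGTs are short transcripts confined to the near vicinity of the
TSS/TTS, and 500 bp keeps the windows of selected genes inside the
600-bp intergenic-gap filter below, i.e. genuinely intergenic. `w` is a
plain argument wherever it matters.

Composite profiles only use genes whose profiled flank is free of
neighbouring transcription: the sense analysis requires at least 600 bp
of intergenic sequence 3' of the gene and 100 bp 5' of it, the AS
analysis the mirror (600 bp 5', 100 bp 3'). Comparisons are inclusive
("at least"). The gap of a gene is measured to the nearest annotated
gene boundary **on either strand** by default — the filter exists to
keep flank signal uncontaminated, and an overlapping neighbour on either
strand contaminates it — but `neighbours = "same"` restricts the
measurement to same-strand neighbours for users who prefer the narrower
convention; with annotated gene sets the two conventions select somewhat
different gene counts and both are exposed because neither is uniquely
standard.

## Composite profiles

Each selected gene body is divided into 15 equal real-valued bins; a bin
averages the log2 ratios of the probes whose centres fall inside it on
the profiled strand (sense = the gene's strand, antisense = opposite).
Ties at a bin boundary go to the downstream (3'-ward in genomic
coordinates) bin; any consistent rule works, and this one makes bins
left-closed like every other interval in the package. Bins containing
no probe are missing, never imputed; column averages use the available
rows. Flank columns take the 10 nearest same-strand probes beyond the
TSS (5' flank) and TTS (3' flank) — at the default 80-bp same-strand
pitch of a 40-bp alternating-strand tiling design, 10 probes cover
800 bp per side. Per-base log2-ratio signals are accepted in place of
probe tables; flank columns then average 80-bp windows.

The per-column profile is the arithmetic mean of the log2 entries —
equivalently the log2 of the geometric mean of the ratios. For
expression profiles (mutant/WT) the grand mean of the *sense body bins*
is then subtracted from every column of both profiles: strong AS and
intergenic accumulation inflates a ratio channel globally, and anchoring
mean sense gene expression at 0 compensates that artefact. The offset is
computed from body bins only (flanks excluded, because flanks carry the
CUT signal being measured) and applied to both orientations equally,
since any global channel imbalance affects both strands of an array
alike. Sense/AS column differences are invariant under this shift. RIP
profiles (IP/input) receive **no** global normalization — enrichment
relative to input is already an internally controlled quantity and no
additional normalization convention is assumed — and negative
(under-enriched) values are kept; `positive_only()` provides the
plotting convention that drops negatives from expression profiles.

## Coverage normalization and intron surveillance

RNA-seq coverage tracks are made comparable by `normalize_coverage()`:
the median per-base sense coverage of every intronless ORF is computed,
and the whole signal is scaled so the median of those per-gene medians
is exactly 100. Intronless genes are used because their coverage cannot
be affected by splicing defects; the operation is idempotent since
scaling commutes with the median.

Introns entering the meta-intron analysis must lie in ORFs and be
20–400 bp long (inclusive bounds). Each intron's expression proxy is the
median WT coverage over the two 20-bp exonic windows abutting it; the
10% lowest- and 10% highest-proxy introns are then excluded. The
percentile exclusion is rank-based — drop `floor(0.10 N)` introns at
each extreme, ties broken by intron id — which is the simplest
deterministic reading of a percentile trim.

Ranking for the retention analysis scores each intron as
`(mean mutant intronic coverage − mean WT intronic coverage) / (mean
mutant flank-exon coverage)`: the absolute intronic gain normalized to
the gene's expression level *in the mutant* (the mutant channel is the
one whose expression level the gain must be compared against). The top
`ceil(N/4)` introns are selected; this rounding is the only convention
under which a ranked set of 3,935 introns yields exactly 984 selected.
Introns with zero mutant flank coverage cannot be scored and are dropped
with a warning.

The meta-intron composite divides each intron into 40 equal bins
(fractional bin widths are handled by length-weighted averaging, so
introns shorter than 40 bp are well-defined) plus one column per exonic
base pair over the 20-bp flanks, sense strand only, 5'→3'. Entries are
log2 of mean coverage; zero-coverage bins are replaced by a pseudocount
(+1 on the normalized scale, configurable) before the log, so columns
remain finite while positive coverage is logged exactly. Columns are
averaged arithmetically on the log2 scale (geometric averaging of
coverages).

Junction-level quantification classifies reads per intron: spliced
support S = gapped reads whose gap equals the intron span *exactly* (no
tolerance; gapped reads with a non-matching overlapping gap are
"mis-spliced" and counted separately, since counting them as either S or
US would misstate both), unspliced support US = contiguous reads
overlapping both the intron and an adjacent exonic flank. Reads fully
inside the intron are informative for the boundary-spanning denominator
but are neither S nor US. The US/S ratio, normalized to the WT US/S
ratio, estimates the retention odds ratio between genotypes — the
read-level window geometry cancels in the double ratio.

The stabilization-versus-splicing diagnostic compares three geometric
mean mutant/WT fold-changes: intron bodies, their exonic flanks, and
intronless gene bodies. Stabilized unspliced pre-mRNA raises intron and
exon coverage *together* while intronless genes stay flat; a splicing
defect raises intronic coverage above the exonic change. The agreement
tolerance τ defaults to 0.5 log2 units — half of the smallest biologically
asserted effect (a two-fold change) — and patterns matching no rule are
reported as "ambiguous" rather than forced into a category.

## Interactome mapping

A protein identification is non-significant when its iBAQ value is below
50,000 or its spectral count is zero (a protein at exactly 50,000 with
at least one spectrum passes). Significant iBAQ values are normalized to
the bait's iBAQ and expressed as percent of bait; replicate tables
sharing a purification id are averaged on the percent scale before
tiering. Tiers follow the conventional colour coding: black ≥ 2.5% of
the bait, grey ≥ 0.5% and < 2.5%, white otherwise (thresholds inclusive
at the lower bound). Complex-level abundance is the arithmetic mean over
member subunits, absent members contributing 0.

Submodules are inferred from presence patterns across purifications:
present = tier other than white (proteins below 0.5% are treated as
absent even if statistically significant, matching the white tier's
definition), and proteins with *identical* presence vectors form one
submodule. Exact vector equality is the strictest machine-checkable
version of grouping subunits by their co-dissociation across deletion
backgrounds; a Hamming-distance tolerance (`hamming_tol = 1`) is
available but off by default, because with few purifications a
single-mismatch merge can collapse genuinely distinct modules.

## The synthetic-data generator

`make_toy_genome()` lays genes with uniform lengths (1.2–3 kb) and
intergenic gaps (0.6–1.6 kb) on one chromosome with random strands; half
the genes carry 1–3 introns. Intron lengths are log-normal with median
60 bp clipped to 20–400 bp, emulating the short-intron statistics of
fission yeast — this matters: only with realistically short introns do
most intron-overlapping short reads also touch an exon boundary, the
read-level signature that distinguishes unspliced transcripts from
excised lariats. The 0.6-kb minimum gap keeps default CUT windows
intergenic, and gene geometry guarantees every gap hosts at most one
CUT window per strand, so class fold-changes are realized without
collisions.

`simulate_signals()` draws per-gene baselines log-normal(log 100, sd 1)
— spread enough for percentile filters to act on — paints sense exonic
coverage, sets intronic coverage to baseline × retention fraction, and
gives each CUT region a WT baseline of 5% of the mean mRNA baseline
(detectable but low, as CUTs are in a WT strain). The mutant channel
multiplies each feature by its class fold-change and by one log-normal
noise factor per (gene, feature) — per-feature rather than per-base, so
noise does not average away within bins and parameter-recovery tests are
honest. With zero noise every realized class fold-change is exact by
construction. Two scenario presets reflect distinct mutant biologies:
CUT-degradation mutants (PROMPT/AS/3'IGT fold-changes 8/4/2, retention
unchanged) and splicing-surveillance mutants (retention 0.05 → 0.15, a
3× increase, CUT classes unchanged).

`simulate_reads()` samples reads from transcript copies that retain each
intron independently with the genotype's retention probability; reads
crossing a spliced junction become gapped reads whose gap equals the
intron exactly. Gene geometry keeps exonic chunks longer than the read
length so no read spans two junctions. `simulate_probe_ratios()` places
40-bp probes alternating strands and reports windowed log2
mutant/WT ratios. `simulate_ibaq_table()` builds purification tables
from a submodule specification: removed submodules get iBAQ 0,
contaminants sit below the significance floor, and with zero noise
percent-of-bait recovers the configured abundances exactly.

All generators are pure functions of their arguments and a seed; each
derives an independent sub-stream from the master seed so adding one
generator never perturbs another's draws.

What the generator does **not** emulate: sequence content (no motifs, no
GC or fragment-length bias), probe melting behaviour and dye bias,
overdispersed count noise, overlapping or nested genes, alternative
splicing beyond single-intron retention, and poly(A)-tail dynamics.
Passing tests therefore demonstrate correctness of the analysis
machinery under the stated generative model, not robustness to every
artefact of real array or sequencing data.

## Numerical choices

* **Zero-protected ratios.** `log2_ratio_signal()` adds its pseudocount
  to both channels only where either is zero: exact ratios are preserved
  wherever both are positive, and 0/0 maps to log2(1) = 0.
* **Pseudocount for logged coverage**: +1 on the normalized scale
  (1% of the intronless-median anchor), configurable.
* **Bin boundaries** are real-valued; probe assignment is left-closed
  with boundary ties going 3'-ward; per-base bins use the same
  convention via ceilings. Exact mirror symmetry of a row holds when
  the gene length is divisible by the bin count (integer boundaries);
  otherwise the tie-break is asymmetric under reflection by at most one
  base per boundary, which is inherent to any fixed convention.
* **Missing values** propagate as NA and are never imputed; profile
  columns average available rows only.
* **Determinism**: ranking ties break by intron id; percentile trims are
  rank-based; submodule grouping sorts by size.

## Problem sizes used by the test-suite

Parameter-recovery checks run on 200-gene toy genomes with noise sd 0.2
(composite plateaus recover fold-changes 8/4/2 within ±0.3 log2 units;
meta-intron elevation recovers the 3× retention increase within ±0.3),
read-level checks on 10,000–30,000 reads against closed-form binomial
oracles with 3-standard-error bands, and exact-arithmetic oracles
(brute-force per-probe binning, hand-computed geometric means,
percentile enumerations) on instances of at most five genes. These sizes
give the stochastic checks comfortable statistical margins while the
suite stays quick to run.

## Known limitations

* Intron discovery from annotation assumes one transcript per gene;
  alternative isoforms are out of scope.
* `quantify_splicing()` assumes reads have at most one gap, matching the
  generator's guarantee; multi-gap reads from other aligners must be
  split upstream.
* The intergenic-gap measurement ignores genes nested entirely inside
  another gene (none are generated); annotations with nested genes
  should be flattened first.
* Submodule inference needs backgrounds that actually separate the
  modules: submodules sharing one presence vector across the supplied
  purifications are indistinguishable by construction.

## Worked example

```{r example, eval = FALSE}
ann <- make_toy_genome(200, seed = 1)
eff <- effect_profile(fold_changes = c(PROMPT = 8, AS = 4, IGT3 = 2),
                      noise_sd = 0.2, retention_mut = 0.05, seed = 1)
sig <- simulate_signals(ann, eff)
comp <- expression_composite(ann, log2_ratio_signal(sig$mut, sig$wt))
plot_composite(comp, drop_negative = TRUE)
```
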