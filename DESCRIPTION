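Package: exosurv
Title: Composite Profiling of Exosome-Targeted Transcripts and Splicing
    Surveillance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for analysing nuclear-exosome RNA surveillance in
    fission yeast and similar compact genomes. Classifies cryptic unstable
    transcript (CUT) regions (PROMPTs, antisense transcripts, 3'
    intergenic transcripts) from a genome annotation, builds
    strand-specific composite (metagene) profiles of expression and
    RIP enrichment ratios, quantifies intron retention with meta-intron
    profiles and junction-level spliced/unspliced read counts, and maps
    protein-complex composition from iBAQ affinity-purification tables.
    Includes a synthetic-data generator that emulates all required inputs
    (annotation, stranded coverage, tiling-probe ratios, gapped reads,
    purification tables) so every analysis stage can be exercised and
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
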