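#' Run configuration for the end-to-end pipeline
#'
#' One declarative configuration drives simulation and every analysis
#' stage. All defaults equal the standard analysis parameters: 15 body
#' bins, 10 flank probes (800 bp at 80-bp pitch), 20-bp exon flanks,
#' 600/100-bp selection gaps, 20-400-bp introns with 10/10 percentile
#' exclusion, upper-quartile ranking, 2.5/0.5% abundance tiers, a 50,000
#' iBAQ significance floor, and median-100 coverage normalization.
#'
#' @param seed master seed recorded in every output header.
#' @param outdir output directory.
#' @param n_genes toy-genome size for simulation runs.
#' @param effect an [effect_profile()] (its seed is overridden by
#'   `seed`).
#' @param config a [profile_config()].
#' @param criteria_sense,criteria_as [selection_criteria()] for the two
#'   composite orientations.
#' @param filter an [intron_filter()].
#' @param w_bp CUT window length.
#' @param n_reads reads per genotype for read simulation.
#' @param complex a [complex_spec()] for purification simulation.
#' @param overrides named list applied over the fields above (e.g. from
#'   a YAML file via [yaml::read_yaml()]).
#' @return a `RunConfig` list.
#' @export
run_config <- function(seed = 1, outdir = tempfile("exosurv_run_"),
                       n_genes = 200,
                       effect = effect_profile(),
                       config = profile_config(),
                       criteria_sense = selection_criteria(600, 100),
                       criteria_as = selection_criteria(100, 600),
                       filter = intron_filter(),
                       w_bp = 500, n_reads = 20000,
                       complex = default_complex_spec(),
                       overrides = NULL) {
  effect$seed <- as.integer(seed)
  rc <- list(seed = as.integer(seed), outdir = outdir, n_genes = n_genes,
             effect = effect, config = config,
             criteria_sense = criteria_sense, criteria_as = criteria_as,
             filter = filter, w_bp = w_bp, n_reads = n_reads,
             complex = complex)
  if (!is.null(overrides)) {
    for (nm in names(overrides)) rc[[nm]] <- overrides[[nm]]
  }
  structure(rc, class = "RunConfig")
}

run_header <- function(rc, stage) {
  c(paste0("exosurv ", as.character(utils::packageVersion("exosurv")),
           " stage=", stage),
    paste0("seed=", rc$seed, " config=", object_md5(unclass(rc))))
}

#' Simulate the full fixture set and write it to disk
#'
#' Generates a toy genome, WT/mutant coverage, probe log2 ratios, WT and
#' mutant read sets and the purification tables, and writes every
#' emulated input format (GFF3, bedGraph pairs, probe table, read tables,
#' iBAQ tables, manifest).
#'
#' @param rc a [run_config()].
#' @return invisibly, a named list of the generated file paths plus the
#'   in-memory objects.
#' @export
cmd_simulate <- function(rc = run_config()) {
  if (rc$n_genes < 1) stop("n_genes must be >= 1")
  dir.create(rc$outdir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(rc$outdir, 2) != 0)
    stop("output directory not writable: ", rc$outdir)
  p <- function(...) file.path(rc$outdir, paste0(...))
  hdr <- run_header(rc, "simulate")

  ann <- make_toy_genome(rc$n_genes, seed = rc$seed)
  write_annotation(ann, p("annotation.gff3"))
  sig <- simulate_signals(ann, rc$effect)
  write_stranded_signal(sig$wt, p("wt_fwd.bedgraph"), p("wt_rev.bedgraph"))
  write_stranded_signal(sig$mut, p("mut_fwd.bedgraph"), p("mut_rev.bedgraph"))
  probes <- simulate_probe_ratios(ann, sig$wt, sig$mut)
  write_probe_table(probes, p("probes.tsv"), hdr)
  reads_wt <- simulate_reads(ann, rc$effect, rc$n_reads, genotype = "wt")
  reads_mut <- simulate_reads(ann, rc$effect, rc$n_reads, genotype = "mut")
  write_read_table(reads_wt, p("reads_wt.tsv"), hdr)
  write_read_table(reads_mut, p("reads_mut.tsv"), hdr)
  backgrounds <- c("wild_type", names(rc$complex$backgrounds))
  quant_paths <- character()
  manifest <- list()
  for (bg in backgrounds) {
    tb <- simulate_ibaq_table(rc$complex, bg, seed = rc$seed)
    fp <- p("ibaq_", bg, ".tsv")
    write_tsv_header(as.data.frame(tb), fp, hdr)
    quant_paths[bg] <- fp
    manifest[[bg]] <- list(purification = attr(tb, "purification"),
                           bait = attr(tb, "bait"), background = bg,
                           path = basename(fp))
  }
  yaml::write_yaml(list(seed = rc$seed,
                        n_genes = rc$n_genes,
                        effect = unclass(rc$effect),
                        purifications = manifest),
                   p("manifest.yaml"))
  message("simulate: wrote ", length(list.files(rc$outdir)),
          " files to ", rc$outdir)
  invisible(list(annotation = p("annotation.gff3"),
                 wt = c(p("wt_fwd.bedgraph"), p("wt_rev.bedgraph")),
                 mut = c(p("mut_fwd.bedgraph"), p("mut_rev.bedgraph")),
                 probes = p("probes.tsv"),
                 reads = c(wt = p("reads_wt.tsv"), mut = p("reads_mut.tsv")),
                 quant = quant_paths, manifest = p("manifest.yaml"),
                 objects = list(ann = ann, wt = sig$wt, mut = sig$mut,
                                probes = probes, reads_wt = reads_wt,
                                reads_mut = reads_mut)))
}

#' Composite expression and RIP profiling stage
#'
#' Builds sense/antisense composite tables from an annotation and a
#' log2-ratio signal and writes them with provenance headers.
#'
#' @param rc a [run_config()].
#' @param ann a `GenomeAnnotation`.
#' @param ratio_signal probe or per-base log2-ratio signal.
#' @param kind `"expression"` (WT-normalized, as in mutant-vs-WT arrays)
#'   or `"rip"` (IP/input enrichment, unnormalized).
#' @return invisibly, the `exosurv_composite` plus the output path.
#' @export
cmd_profile <- function(rc, ann, ratio_signal,
                        kind = c("expression", "rip")) {
  kind <- match.arg(kind)
  dir.create(rc$outdir, showWarnings = FALSE, recursive = TRUE)
  comp <- if (kind == "expression")
    expression_composite(ann, ratio_signal, rc$config,
                         rc$criteria_sense, rc$criteria_as)
  else
    rip_composite(ann, ratio_signal, rc$config,
                  rc$criteria_sense, rc$criteria_as)
  path <- file.path(rc$outdir, paste0("composite_", kind, ".tsv"))
  write_composite_table(comp, path, run_header(rc, paste0("profile_", kind)))
  message("profile: ", kind, " composite over ",
          comp$n_genes["sense"], "/", comp$n_genes["antisense"],
          " sense/AS genes -> ", path)
  invisible(list(composite = comp, path = path))
}

#' Intron-surveillance stage
#'
#' Normalizes WT and mutant coverage, filters and ranks introns, writes
#' the per-intron table, builds WT and mutant meta-intron profiles, and
#' runs the stabilization-versus-splicing diagnostic.
#'
#' @param rc a [run_config()].
#' @param ann a `GenomeAnnotation`.
#' @param wt,mut coverage-mode `StrandedSignal`s (raw; normalized here).
#' @param reads optional mutant `ReadSet` for the boundary-spanning
#'   fraction.
#' @return invisibly, list with the per-intron table, ranking, profiles,
#'   diagnostic and output paths.
#' @export
cmd_introns <- function(rc, ann, wt, mut, reads = NULL) {
  if (is.null(wt)) stop("WT coverage track is required")
  dir.create(rc$outdir, showWarnings = FALSE, recursive = TRUE)
  hdr <- run_header(rc, "introns")
  wt <- normalize_coverage(wt, ann)
  mut <- normalize_coverage(mut, ann)
  det <- filter_introns(ann, wt, rc$filter, details = TRUE)
  ids <- det$id[det$kept]
  ranking <- rank_and_select_introns(ann, ids, wt, mut,
                                     rc$filter$exon_flank_bp)
  per_intron <- merge(det, as.data.frame(ranking), by = "id",
                      all.x = TRUE, sort = TRUE)
  tab_path <- file.path(rc$outdir, "introns.tsv")
  write_tsv_header(per_intron, tab_path, hdr)
  prof_wt <- intron_composite(ann, ids, wt,
                              exon_flank_bp = rc$filter$exon_flank_bp,
                              pseudocount = rc$config$pseudocount)
  prof_mut <- intron_composite(ann, ids, mut,
                               exon_flank_bp = rc$filter$exon_flank_bp,
                               pseudocount = rc$config$pseudocount)
  prof_path <- file.path(rc$outdir, "meta_intron.tsv")
  write_tsv_header(data.frame(position = prof_wt$labels,
                              wt = unname(prof_wt$profile),
                              mut = unname(prof_mut$profile)),
                   prof_path, hdr)
  diag <- stabilization_diagnostic(wt, mut, ann, ids,
                                   pseudocount = rc$config$pseudocount)
  bsf <- if (!is.null(reads))
    boundary_span_fraction(reads, ann, ids, rc$filter$exon_flank_bp)
  else NA_real_
  report_path <- file.path(rc$outdir, "intron_report.yaml")
  yaml::write_yaml(list(seed = rc$seed,
                        n_filtered = length(ids),
                        n_selected = sum(ranking$selected),
                        verdict = diag$verdict,
                        intron_log2fc = diag$intron_log2fc,
                        exon_log2fc = diag$exon_log2fc,
                        intronless_log2fc = diag$intronless_log2fc,
                        boundary_span_fraction = bsf),
                   report_path)
  message("introns: ", length(ids), " filtered, ",
          sum(ranking$selected), " selected; verdict: ", diag$verdict)
  invisible(list(table = per_intron, ranking = ranking,
                 profiles = list(wt = prof_wt, mut = prof_mut),
                 diagnostic = diag, boundary_span_fraction = bsf,
                 paths = c(tab_path, prof_path, report_path)))
}

#' Interactome stage
#'
#' Tiers every purification table, writes the black/grey/white matrix
#' and the inferred submodule listing.
#'
#' @param rc a [run_config()].
#' @param tables list of `ProteinQuantTable`s (>= 1).
#' @return invisibly, list with the `InteractionMap`, submodules and
#'   output paths.
#' @export
cmd_interactome <- function(rc, tables) {
  if (!length(tables)) stop("no purification tables supplied")
  dir.create(rc$outdir, showWarnings = FALSE, recursive = TRUE)
  hdr <- run_header(rc, "interactome")
  map <- interaction_map(tables)
  sub <- infer_submodules(map)
  map_path <- file.path(rc$outdir, "interaction_map.tsv")
  write_interaction_map(map, map_path, hdr)
  sub_path <- file.path(rc$outdir, "submodules.tsv")
  sub_df <- data.frame(
    submodule = rep(names(sub$submodules),
                    lengths(sub$submodules)),
    protein = unlist(sub$submodules, use.names = FALSE),
    pattern = rep(vapply(sub$patterns, function(p)
      paste(as.integer(p), collapse = ""), character(1)),
      lengths(sub$submodules)))
  write_tsv_header(sub_df, sub_path, hdr)
  message("interactome: ", nrow(map$tiers), " proteins, ",
          length(sub$submodules), " submodules")
  invisible(list(map = map, submodules = sub,
                 paths = c(map_path, sub_path)))
}
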