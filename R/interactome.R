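#' Protein quantification table for one purification
#'
#' Per-protein iBAQ intensities and spectral counts from one affinity
#' purification, annotated with the purification id, the bait protein and
#' the genetic background of the strain.
#'
#' @param df data frame with columns `protein`, `ibaq`,
#'   `spectral_counts`.
#' @param purification purification id.
#' @param bait bait protein id (must be present with iBAQ > 0).
#' @param background genetic background label (e.g. `"wild_type"`).
#' @return a `ProteinQuantTable` data frame with metadata attributes.
#' @export
protein_quant_table <- function(df, purification, bait,
                                background = "wild_type") {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!all(c("protein", "ibaq", "spectral_counts") %in% names(df)))
    stop("table must have columns protein, ibaq, spectral_counts")
  if (anyDuplicated(df$protein)) stop("duplicated protein ids")
  if (any(df$spectral_counts < 0)) stop("negative spectral counts")
  b <- df[df$protein == bait, ]
  if (!nrow(b) || b$ibaq <= 0)
    stop("bait ", bait, " missing or with non-positive iBAQ")
  structure(df, purification = purification, bait = bait,
            background = background,
            class = c("ProteinQuantTable", "data.frame"))
}

#' Flag non-significant identifications
#'
#' An identified protein is non-significant if its iBAQ value is below
#' 50,000 or it has zero spectral counts; such rows are excluded from all
#' downstream abundance tiers.
#'
#' @param table a `ProteinQuantTable`.
#' @param min_ibaq significance floor (default 50,000; a protein at
#'   exactly the floor passes).
#' @return the table with a logical `significant` column added.
#' @export
significance_filter <- function(table, min_ibaq = 50000) {
  table$significant <- table$ibaq >= min_ibaq & table$spectral_counts > 0
  table
}

#' iBAQ abundance as percentage of the bait
#'
#' Normalizes iBAQ values to the bait's iBAQ and reports them as a
#' percentage of the bait (the bait itself maps to 100). Non-significant
#' proteins get NA.
#'
#' @param table a `ProteinQuantTable` (filtered or not; the filter is
#'   applied if the `significant` column is absent).
#' @return the table with a `percent` column added.
#' @export
percent_of_bait <- function(table) {
  if (is.null(table$significant)) table <- significance_filter(table)
  bait <- attr(table, "bait")
  b <- table[table$protein == bait, ]
  if (!b$significant) stop("bait ", bait, " fails the significance filter")
  table$percent <- ifelse(table$significant,
                          100 * table$ibaq / b$ibaq, NA_real_)
  table
}

#' Look up percent-of-bait for specific proteins
#'
#' Proteins absent from the table (or non-significant) contribute 0, with
#' an `absent` flag.
#'
#' @param table output of [percent_of_bait()].
#' @param ids protein ids.
#' @return data frame with `protein`, `percent`, `absent`.
#' @export
percent_for <- function(table, ids) {
  idx <- match(ids, table$protein)
  pct <- table$percent[idx]
  absent <- is.na(idx) | is.na(pct)
  pct[absent] <- 0
  data.frame(protein = ids, percent = pct, absent = absent,
             stringsAsFactors = FALSE)
}

#' Abundance tier of a percent-of-bait value
#'
#' Black: at least 2.5% of the bait; grey: at least 0.5% but below 2.5%;
#' white: non-significant or below 0.5% (both thresholds inclusive at the
#' lower bound).
#'
#' @param percent numeric vector of percentages (NA = non-significant).
#' @param black_min,grey_min tier thresholds (defaults 2.5 and 0.5).
#' @return factor with levels `black`, `grey`, `white`.
#' @export
tier_abundance <- function(percent, black_min = 2.5, grey_min = 0.5) {
  stopifnot(black_min > grey_min, grey_min > 0)
  out <- ifelse(is.na(percent) | percent < grey_min, "white",
                ifelse(percent >= black_min, "black", "grey"))
  factor(out, levels = c("black", "grey", "white"))
}

#' Average abundance of a protein group
#'
#' Arithmetic mean percent-of-bait over the members of a complex (e.g.
#' all 12 nuclear exosome subunits); members absent from the purification
#' contribute 0.
#'
#' @param table output of [percent_of_bait()].
#' @param member_ids non-empty vector of member protein ids.
#' @return mean percentage (numeric scalar).
#' @export
complex_abundance <- function(table, member_ids) {
  if (!length(member_ids)) stop("empty member list")
  mean(percent_for(table, member_ids)$percent)
}

#' Tiered interaction map across purifications
#'
#' Builds the proteins x purifications matrix of abundance tiers.
#' Replicate tables sharing a purification id are averaged on the
#' percent-of-bait scale before tiering.
#'
#' @param tables list of `ProteinQuantTable`s.
#' @param black_min,grey_min tier thresholds.
#' @return an `InteractionMap`: list with `tiers` (character matrix),
#'   `percent` (numeric matrix) and `manifest` (purification metadata).
#' @export
interaction_map <- function(tables, black_min = 2.5, grey_min = 0.5) {
  if (!length(tables)) stop("no purification tables")
  tables <- lapply(tables, percent_of_bait)
  ids <- vapply(tables, attr, character(1), "purification")
  prot <- sort(unique(unlist(lapply(tables, `[[`, "protein"))))
  purs <- unique(ids)
  pct <- matrix(0, length(prot), length(purs),
                dimnames = list(prot, purs))
  for (p in purs) {
    reps <- tables[ids == p]
    per_rep <- vapply(reps, function(tb) percent_for(tb, prot)$percent,
                      numeric(length(prot)))
    pct[, p] <- rowMeans(matrix(per_rep, nrow = length(prot)))
  }
  tiers <- matrix(as.character(tier_abundance(pct, black_min, grey_min)),
                  nrow = length(prot), dimnames = dimnames(pct))
  manifest <- data.frame(
    purification = purs,
    bait = vapply(purs, function(p)
      attr(tables[ids == p][[1]], "bait"), character(1)),
    background = vapply(purs, function(p)
      attr(tables[ids == p][[1]], "background"), character(1)),
    stringsAsFactors = FALSE)
  structure(list(tiers = tiers, percent = pct, manifest = manifest),
            class = "InteractionMap")
}

#' @export
print.InteractionMap <- function(x, ...) {
  cat("InteractionMap:", nrow(x$tiers), "proteins x",
      ncol(x$tiers), "purifications\n")
  invisible(x)
}

#' Infer submodules from presence patterns across purifications
#'
#' A protein is present in a purification when its tier is not white.
#' Proteins with identical presence vectors across all purifications are
#' grouped into one submodule -- the strictest machine-checkable version
#' of grouping subunits by their co-dissociation across deletion
#' backgrounds. An optional Hamming tolerance merges near-identical
#' patterns (off by default).
#'
#' @param map an `InteractionMap` (>= 2 purifications; a single
#'   purification degrades to presence/absence grouping with a warning).
#' @param hamming_tol merge groups whose defining vectors differ in at
#'   most this many purifications (default 0 = exact matching).
#' @return list with `submodules` (named list of protein ids) and
#'   `patterns` (the defining presence vector per submodule).
#' @export
infer_submodules <- function(map, hamming_tol = 0) {
  presence <- map$tiers != "white"
  if (ncol(presence) < 2)
    warning("single purification: grouping reflects presence only")
  ## drop proteins never present (contaminants)
  presence <- presence[rowSums(presence) > 0, , drop = FALSE]
  key <- apply(presence, 1, paste, collapse = "")
  groups <- split(rownames(presence), key)
  patterns <- lapply(groups, function(g)
    presence[g[1], , drop = TRUE])
  if (hamming_tol > 0 && length(groups) > 1) {
    ## greedy single-linkage merge of patterns within the tolerance
    repeat {
      merged <- FALSE
      ks <- names(groups)
      for (a in seq_along(ks)) {
        for (b in seq_along(ks)) {
          if (b <= a) next
          d <- sum(patterns[[ks[a]]] != patterns[[ks[b]]])
          if (d <= hamming_tol) {
            groups[[ks[a]]] <- c(groups[[ks[a]]], groups[[ks[b]]])
            groups[[ks[b]]] <- NULL
            patterns[[ks[b]]] <- NULL
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
      if (!merged) break
    }
  }
  ord <- order(vapply(groups, length, integer(1)), decreasing = TRUE)
  groups <- groups[ord]
  patterns <- patterns[names(groups)]
  names(groups) <- names(patterns) <-
    paste0("submodule", seq_along(groups))
  list(submodules = groups, patterns = patterns)
}

#' Read a purification table from TSV
#'
#' @param path TSV with columns `protein`, `ibaq`, `spectral_counts`.
#' @param purification,bait,background metadata for
#'   [protein_quant_table()].
#' @return a `ProteinQuantTable`.
#' @export
read_quant_table <- function(path, purification, bait,
                             background = "wild_type") {
  protein_quant_table(read_tsv_header(path), purification, bait,
                      background)
}

#' Write a tiered interaction map as TSV
#'
#' One row per protein, one column per purification, values
#' black/grey/white mirroring the published colour coding.
#'
#' @param map an `InteractionMap`.
#' @param path output file.
#' @param header provenance comment lines.
#' @return `path`, invisibly.
#' @export
write_interaction_map <- function(map, path, header = character()) {
  df <- data.frame(protein = rownames(map$tiers), map$tiers,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_header(df, path, header)
}
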