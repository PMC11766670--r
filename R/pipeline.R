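# End-to-end orchestration: extract V4 -> consensus fold -> per-taxon
# fold + curation -> Type I/II classification -> CBC matrix -> parsimony
# ancestral reconstruction. Per-taxon failures drop the taxon with a
# logged reason; only global errors abort.

#' Run the V4 structure-evolution pipeline
#'
#' @param seqs Full-length sequence tibble (`id`, `residues`, optional
#'   `clade`), e.g. from [read_rna_fasta()] or [simulate_v4()].
#' @param tree Rooted [ape::phylo] tree whose tip labels match sequence
#'   ids (extra tips are pruned).
#' @param profile An `anchor_profile` for V4 extraction.
#' @param alignment Optional V4 alignment tibble (`id`, `aligned`). When
#'   supplied it drives consensus folding, curation references and the
#'   CBC analysis; without it, those stages are skipped and per-taxon
#'   structures come from [fold_mfe()] alone.
#' @param route How the per-taxon structure entering classification is
#'   chosen. `"reference-guided"` (default, requires an alignment)
#'   curates the consensus structure projected onto each taxon —
#'   mirroring the study workflow in which the consensus is the
#'   reference for every species. `"mfe"` uses [select_structure()]
#'   over the curated free-folded and projected candidates, which
#'   exposes the pair-score folding model directly and is the only
#'   route without an alignment.
#' @param params A [fold_params()] object.
#' @param min_helix_len Minimum helix length (pairs) retained in the
#'   structures that are interpreted topologically; lone pairs are
#'   artifacts of the stacking-free pair-score model and are dropped by
#'   default (see [drop_lone_pairs()]).
#' @param bulge_tol,e23_rule Topology options, see [classify_v4()].
#' @param resolution_rule Ambiguity resolution for the ancestral stage,
#'   see [resolve_asr()].
#' @param cbc_taxa Optional taxon subset for the CBC matrix (default:
#'   all retained taxa present in the alignment).
#' @param max_taxon_mismatch Abort when more than this fraction of
#'   retained taxa is missing from the tree (default 0.5).
#' @return A list of class `v4_run`: `taxa` (per-taxon tibble: V4
#'   coordinates, fold score, structure type, hairpin size, ...),
#'   `structures` (named list of `rna_structure`), `consensus`
#'   (`consensus_fold` or `NULL`), `cbc` (`cbc_matrix` or `NULL`),
#'   `asr` (resolved `fitch_asr`), `dropped` (tibble `id`, `stage`,
#'   `reason`), `provenance`.
#' @export
run_v4_pipeline <- function(seqs, tree, profile, alignment = NULL,
                            route = c("reference-guided", "mfe"),
                            params = fold_params(), min_helix_len = 2L,
                            bulge_tol = 3L,
                            e23_rule = "largest",
                            resolution_rule = "DELTRAN",
                            cbc_taxa = NULL,
                            max_taxon_mismatch = 0.5) {
  route <- match.arg(route)
  if (is.null(alignment)) route <- "mfe"
  stopifnot(is.data.frame(seqs), inherits(tree, "phylo"))
  dropped <- tibble(id = character(0), stage = character(0), reason = character(0))

  hits <- extract_v4(seqs, profile)
  dr <- attr(hits, "v4_dropped")
  if (!is.null(dr) && nrow(dr)) {
    dropped <- dplyr::bind_rows(dropped, dplyr::mutate(dr, stage = "extract"))
  }
  if (!nrow(hits)) stop("no V4 region located in any sequence")

  consensus <- NULL
  references <- list()
  cons_topo <- NULL
  if (!is.null(alignment)) {
    validate_alignment(alignment)
    consensus <- fold_consensus(alignment, params)
    cons_topo <- drop_lone_pairs(consensus$structure, min_helix_len)
    for (id in intersect(hits$id, alignment$id)) {
      references[[id]] <- project_consensus(cons_topo, id, alignment, params)
    }
  }

  structures <- list()
  for (r in seq_len(nrow(hits))) {
    id <- hits$id[r]
    ref <- references[[id]]
    ref_ok <- !is.null(ref) && ref$length == hits$length[r]
    if (route == "reference-guided" && ref_ok) {
      sel <- curate(ref, hits$v4[r], params)
    } else {
      mfe <- fold_mfe(hits$v4[r], params, id = id)
      cands <- list(curate(mfe, hits$v4[r], params))
      if (ref_ok) cands <- c(cands, list(curate(ref, hits$v4[r], params)))
      sel <- select_structure(cands, if (ref_ok) ref else mfe)
    }
    structures[[id]] <- drop_lone_pairs(sel, min_helix_len, params, hits$v4[r])
  }

  topo <- classify_all(structures, bulge_tol = bulge_tol, rule = e23_rule)

  taxa <- dplyr::left_join(hits, topo, by = "id") |>
    dplyr::mutate(
      fold_score = vapply(structures[.data$id], function(s) s$score, numeric(1)),
      n_pairs = vapply(structures[.data$id], function(s) nrow(s$pairs), integer(1))
    ) |>
    dplyr::select(-"v4")
  if ("clade" %in% names(seqs)) {
    taxa <- dplyr::left_join(taxa, seqs[, c("id", "clade")], by = "id")
  }

  cbc <- NULL
  if (!is.null(consensus)) {
    pool <- cbc_taxa %||% intersect(taxa$id, alignment$id)
    if (length(pool) >= 2) {
      cbc <- cbc_matrix(alignment, cons_topo, taxa = pool)
    }
  }

  on_tree <- intersect(taxa$id, tree$tip.label)
  if (length(on_tree) / nrow(taxa) < 1 - max_taxon_mismatch) {
    stop(sprintf("tree/matrix mismatch: only %d of %d classified taxa on the tree",
                 length(on_tree), nrow(taxa)))
  }
  asr <- resolve_asr(fitch_asr(tree, taxa), rule = resolution_rule)

  structure(list(
    taxa = taxa, structures = structures, consensus = consensus,
    cbc = cbc, asr = asr, dropped = dropped,
    provenance = list(
      route = route, params = params, min_helix_len = min_helix_len,
      bulge_tol = bulge_tol, e23_rule = e23_rule,
      resolution_rule = resolution_rule,
      n_input = nrow(seqs), n_retained = nrow(taxa))
  ), class = "v4_run")
}

#' @export
print.v4_run <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<v4_run> %d/%d taxa retained; %d Type I, %d Type II; parsimony length %d (%d reversal(s))\n",
              g$n_retained, g$n_input, g$n_type_i, g$n_type_ii,
              g$n_steps, g$n_reversals))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.v4_run <- function(x, ...) x$taxa

#' @exportS3Method generics::glance
glance.v4_run <- function(x, ...) {
  tibble(
    n_input = x$provenance$n_input,
    n_retained = nrow(x$taxa),
    n_type_i = sum(x$taxa$struct_type == "TYPE_I"),
    n_type_ii = sum(x$taxa$struct_type == "TYPE_II"),
    n_unclassified = sum(x$taxa$struct_type == "UNCLASSIFIED"),
    n_steps = x$asr$n_steps,
    n_gains = sum(x$asr$changes$from == "TYPE_I" & x$asr$changes$to == "TYPE_II"),
    n_reversals = nrow(x$asr$reversals)
  )
}

#' Summarise a pipeline run by clade
#'
#' @param run A `v4_run` object (or its `taxa` tibble).
#' @param clades Optional named character vector mapping taxon id to
#'   clade label, overriding the `clade` column.
#' @return A tibble per clade: taxon count, Type I / Type II counts, and
#'   the min/max terminal hairpin size among Type I members.
#' @export
summarize_by_clade <- function(run, clades = NULL) {
  taxa <- if (inherits(run, "v4_run")) run$taxa else run
  if (!is.null(clades)) taxa$clade <- unname(clades[taxa$id])
  if (!"clade" %in% names(taxa) || all(is.na(taxa$clade))) {
    stop("no clade labels available")
  }
  taxa |>
    dplyr::group_by(.data$clade) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_type_i = sum(.data$struct_type == "TYPE_I"),
      n_type_ii = sum(.data$struct_type == "TYPE_II"),
      hairpin_min = suppressWarnings(min(.data$terminal_hairpin_size, na.rm = TRUE)),
      hairpin_max = suppressWarnings(max(.data$terminal_hairpin_size, na.rm = TRUE)),
      .groups = "drop"
    ) |>
    dplyr::mutate(dplyr::across(c("hairpin_min", "hairpin_max"),
                                ~ ifelse(is.infinite(.x), NA_integer_, .x)))
}
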