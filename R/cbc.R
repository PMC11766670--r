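# Compensatory base change (CBC) counting over the paired columns of a
# shared consensus structure. At a paired column duo, a CBC between two
# taxa means both partners differ while pairing (canonical or wobble) is
# preserved in each taxon; a hemi-CBC (hCBC) changes exactly one partner
# with pairing preserved. Columns where either taxon cannot pair, or
# carrying gaps/N, are skipped, because the statistic is about changes in
# nucleotide bonds, not about unpaired divergence.

cbc_verdict_duo <- function(a1, a2, b1, b2) {
  if (any(c(a1, a2, b1, b2) %in% c("-", "N"))) return("skipped-gap")
  if (!is_canonical_duo(paste0(a1, a2)) || !is_canonical_duo(paste0(b1, b2))) {
    return("skipped-nonpairing")
  }
  d1 <- a1 != b1; d2 <- a2 != b2
  if (d1 && d2) "CBC" else if (d1 || d2) "hCBC" else "same"
}

#' Count compensatory base changes between two taxa
#'
#' For each paired column duo of the consensus structure, compares the
#' residues of taxon A and taxon B and classifies the column as `same`,
#' `CBC`, `hCBC`, `skipped-gap` (any gap or N among the four residues) or
#' `skipped-nonpairing` (either taxon's duo is not a canonical/wobble
#' pair). The report is symmetric in (A, B).
#'
#' @param aln Alignment tibble (`id`, `aligned`).
#' @param pair_columns Two-column integer matrix of column pairs `(k, l)`
#'   (e.g. `$structure$pairs` of a [fold_consensus()] result), or a
#'   `consensus_fold` / `rna_structure` on columns.
#' @param idA,idB Taxon ids present in the alignment.
#' @return A list of class `cbc_report`: `idA`, `idB`, `n_cbc`, `n_hcbc`,
#'   `n_columns_compared` (columns not skipped), and `detail`, a tibble
#'   with one row per column duo (`k`, `l`, residues, `verdict`).
#' @export
count_cbc <- function(aln, pair_columns, idA, idB) {
  validate_alignment(aln)
  pair_columns <- as_pair_columns(pair_columns)
  rowA <- aln$aligned[aln$id == idA]
  rowB <- aln$aligned[aln$id == idB]
  if (length(rowA) != 1) stop("unknown taxon id: ", idA)
  if (length(rowB) != 1) stop("unknown taxon id: ", idB)
  a <- strsplit(rowA, "")[[1]]
  b <- strsplit(rowB, "")[[1]]
  detail <- purrr::map_dfr(seq_len(nrow(pair_columns)), function(r) {
    k <- pair_columns[r, 1]; l <- pair_columns[r, 2]
    tibble(k = k, l = l,
           a1 = a[k], a2 = a[l], b1 = b[k], b2 = b[l],
           verdict = cbc_verdict_duo(a[k], a[l], b[k], b[l]))
  })
  structure(list(
    idA = idA, idB = idB,
    n_cbc = sum(detail$verdict == "CBC"),
    n_hcbc = sum(detail$verdict == "hCBC"),
    n_columns_compared = sum(!startsWith(detail$verdict, "skipped")),
    detail = detail
  ), class = "cbc_report")
}

#' @export
print.cbc_report <- function(x, ...) {
  cat(sprintf("<cbc_report> %s vs %s: %d CBC, %d hCBC over %d compared pair columns\n",
              x$idA, x$idB, x$n_cbc, x$n_hcbc, x$n_columns_compared))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cbc_report <- function(x, ...) x$detail

#' @exportS3Method generics::glance
glance.cbc_report <- function(x, ...) {
  tibble(idA = x$idA, idB = x$idB, n_cbc = x$n_cbc, n_hcbc = x$n_hcbc,
         n_columns_compared = x$n_columns_compared)
}

as_pair_columns <- function(x) {
  if (inherits(x, "consensus_fold")) x <- x$structure
  if (inherits(x, "rna_structure")) x <- x$pairs
  stopifnot(is.matrix(x), ncol(x) == 2)
  x
}

#' Pairwise CBC matrix over a set of taxa
#'
#' @param aln Alignment tibble.
#' @param pair_columns As in [count_cbc()].
#' @param taxa Character vector of taxon ids (default: all rows).
#' @return A list of class `cbc_matrix` with symmetric integer matrices
#'   `cbc` and `hcbc` (zero diagonal) and a long-format `pairs` tibble.
#' @export
cbc_matrix <- function(aln, pair_columns, taxa = aln$id) {
  stopifnot(length(taxa) >= 2, all(taxa %in% aln$id))
  n <- length(taxa)
  cbc <- hcbc <- matrix(0L, n, n, dimnames = list(taxa, taxa))
  rows <- list()
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      rep <- count_cbc(aln, pair_columns, taxa[a], taxa[b])
      cbc[a, b] <- cbc[b, a] <- rep$n_cbc
      hcbc[a, b] <- hcbc[b, a] <- rep$n_hcbc
      rows[[length(rows) + 1]] <- glance(rep)
    }
  }
  structure(list(cbc = cbc, hcbc = hcbc, pairs = dplyr::bind_rows(rows)),
            class = "cbc_matrix")
}

#' @export
print.cbc_matrix <- function(x, ...) {
  cat("<cbc_matrix> CBC counts:\n")
  print(x$cbc)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cbc_matrix <- function(x, ...) x$pairs

#' Restrict consensus pair columns to one labelled stem
#'
#' Utility for running the CBC analysis on a single stem (e.g. E23_8)
#' instead of the whole V4 region.
#'
#' @param consensus A `consensus_fold`.
#' @param label Stem label to keep (default `"E23_8"`).
#' @param bulge_tol,rule Passed to the stem decomposition.
#' @return Two-column matrix of the retained column pairs.
#' @export
restrict_pair_columns <- function(consensus, label = "E23_8",
                                  bulge_tol = 3L, rule = "largest") {
  struct <- consensus$structure
  forest <- find_helices(struct)
  stems <- label_e23(group_stems(forest, bulge_tol), rule)
  keep <- which(vapply(stems$stems, function(s) identical(s$label, label),
                       logical(1)))
  if (!length(keep)) stop("no stem labelled ", label)
  s <- stems$stems[[keep]]
  # the stem plus everything nested inside it
  outer <- s$outer
  p <- struct$pairs
  p[p[, 1] >= outer[1] & p[, 2] <= outer[2], , drop = FALSE]
}
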