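# Structure curation rules, applied after folding:
#   1. close 1x1 bilateral internal loops whose two unpaired residues are
#      G and C (either orientation) by adding that pair;
#   2. remove any helix containing two or more non-canonical pairs
#      (canonical = G:C / A:U, wobble G:U counts as valid pairing);
#   3. among alternative structures, select by score, then base-pair F1
#      against a reference, then lexicographically smallest dot-bracket.
# Rules 1-2 are iterated to a fixed point, which makes curation
# idempotent by construction.

CANONICAL_DUOS <- c("GC", "CG", "AU", "UA", "GU", "UG")

is_canonical_duo <- function(duo) duo %in% CANONICAL_DUOS

# one pass of rule 1: returns possibly augmented pair matrix
close_gc_loops <- function(pairs, chars) {
  if (!nrow(pairs)) return(pairs)
  partner <- integer(length(chars))
  partner[pairs[, 1]] <- pairs[, 2]
  partner[pairs[, 2]] <- pairs[, 1]
  added <- list()
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    # 1x1 internal loop: (i,j) paired, (i+2, j-2) paired together,
    # i+1 and j-1 both unpaired
    if (i + 2 < j - 2 && partner[i + 1] == 0 && partner[j - 1] == 0 &&
        partner[i + 2] == j - 2) {
      duo <- sort(c(chars[i + 1], chars[j - 1]))
      if (identical(duo, c("C", "G"))) {
        added[[length(added) + 1]] <- c(i + 1L, j - 1L)
      }
    }
  }
  if (length(added)) pairs <- rbind(pairs, do.call(rbind, added))
  pairs[order(pairs[, 1]), , drop = FALSE]
}

# one pass of rule 2: drop helices with >= 2 non-canonical pairs
drop_noncanonical_helices <- function(pairs, chars, id, len) {
  if (!nrow(pairs)) return(pairs)
  st <- rna_structure(id, len, pairs)
  hel <- find_helices(st)
  keep <- list()
  for (h in hel$helices) {
    duos <- paste0(chars[h$pairs[, 1]], chars[h$pairs[, 2]])
    if (sum(!is_canonical_duo(duos)) < 2) {
      keep[[length(keep) + 1]] <- h$pairs
    }
  }
  if (!length(keep)) return(matrix(integer(0), ncol = 2))
  do.call(rbind, keep)
}

#' Curate a predicted secondary structure
#'
#' Applies the curation rules: 1x1 bilateral internal loops whose two
#' unpaired residues are G and C are closed into a pair, and any helix
#' carrying two or more non-canonical pairs is removed. The rules are
#' iterated to a fixed point, so `curate()` is idempotent.
#'
#' @param struct An `rna_structure`.
#' @param residues Residue string of matching length.
#' @return A curated `rna_structure` (provenance `"curated"`); its score
#'   is the summed pair score of the retained pairs under `params`.
#' @param params A [fold_params()] object used to re-score the result.
#' @export
curate <- function(struct, residues, params = fold_params()) {
  stopifnot(nchar(residues) == struct$length)
  chars <- strsplit(residues, "")[[1]]
  pairs <- struct$pairs
  repeat {
    before <- pairs
    repeat {
      p2 <- close_gc_loops(pairs, chars)
      if (nrow(p2) == nrow(pairs)) break
      pairs <- p2
    }
    pairs <- drop_noncanonical_helices(pairs, chars, struct$id, struct$length)
    if (nrow(pairs) == nrow(before) && all(pairs == before)) break
  }
  tab <- pair_score_table(params)
  code <- encode_residues(residues)
  score <- if (nrow(pairs)) sum(tab[cbind(code[pairs[, 1]], code[pairs[, 2]])]) else 0
  rna_structure(struct$id, struct$length, pairs, score = score,
                provenance = "curated")
}

#' Base-pair F1 between two structures
#'
#' Harmonic mean of base-pair precision and recall of `x` against
#' `reference`. 1 when pair sets are identical; defined as 1 when both
#' are empty.
#'
#' @param x,reference `rna_structure` objects on sequences of equal length.
#' @return F1 in \[0, 1\].
#' @export
basepair_f1 <- function(x, reference) {
  key <- function(p) paste(p[, 1], p[, 2])
  a <- key(x$pairs); b <- key(reference$pairs)
  if (!length(a) && !length(b)) return(1)
  if (!length(a) || !length(b)) return(0)
  tp <- length(intersect(a, b))
  2 * tp / (length(a) + length(b))
}

#' Select among candidate structures
#'
#' Deterministic total order: highest score first, then highest base-pair
#' F1 against the reference, then lexicographically smallest dot-bracket
#' string. Operationalises "minimum free energy or best compatibility
#' with similar sequences" under the pair-score model.
#'
#' @param candidates List of `rna_structure` objects over the same
#'   sequence.
#' @param reference Reference `rna_structure` (e.g. the projected
#'   consensus).
#' @return The selected `rna_structure`.
#' @export
select_structure <- function(candidates, reference) {
  stopifnot(length(candidates) >= 1)
  scores <- vapply(candidates, function(s) s$score, numeric(1))
  f1 <- vapply(candidates, basepair_f1, numeric(1), reference = reference)
  db <- vapply(candidates, render_dotbracket, character(1))
  ord <- order(-scores, -f1, db, method = "radix")
  candidates[[ord[1]]]
}
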