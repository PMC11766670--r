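#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

# Residue normalisation: DNA -> RNA alphabet, IUPAC ambiguity codes -> N.
# The gene is sequenced as DNA but folded as RNA, so T is silently mapped
# to U; any degenerate code other than N is collapsed to N and N never
# pairs downstream.
normalize_residues <- function(x, id = "?") {
  x <- toupper(x)
  n_t <- sum(stringr::str_count(x, "T"))
  x <- chartr("T", "U", x)
  bad <- stringr::str_count(x, "[^ACGUN]")
  if (any(bad > 0)) {
    message(sprintf("normalising %d degenerate residue(s) to N (e.g. in '%s')",
                    sum(bad), id[which(bad > 0)[1]]))
    x <- stringr::str_replace_all(x, "[^ACGUN]", "N")
  }
  if (n_t > 0) message(sprintf("converted %d T residue(s) to U", n_t))
  x
}

#' Read RNA sequences from a FASTA file
#'
#' Reads a FASTA file and normalises residues to the RNA alphabet
#' `{A, C, G, U, N}`: `T` becomes `U`, lowercase is raised, and IUPAC
#' degenerate codes other than `N` are collapsed to `N` (logged once).
#' Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @param source Optional string recorded in the `source` column
#'   (defaults to the file path).
#' @return A tibble with columns `id`, `residues`, `clade` (always `NA`
#'   on read; set it yourself), and `source`.
#' @export
read_rna_fasta <- function(path, source = path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  ids <- stringr::str_split_i(names(set), "\\s+", 1)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id: ", ids[duplicated(ids)][1])
  }
  res <- as.character(set)
  if (any(nchar(res) == 0)) {
    stop("empty FASTA record: ", ids[nchar(res) == 0][1])
  }
  tibble(
    id = unname(ids),
    residues = unname(normalize_residues(res, ids)),
    clade = NA_character_,
    source = source
  )
}

#' Write RNA sequences to a FASTA file
#'
#' @param seqs A tibble with columns `id` and `residues`.
#' @param path Output path. Sequences are wrapped at 60 columns.
#' @return `path`, invisibly.
#' @export
write_rna_fasta <- function(seqs, path) {
  stopifnot(is.data.frame(seqs), !anyDuplicated(seqs$id))
  set <- Biostrings::BStringSet(stats::setNames(seqs$residues, seqs$id))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a rooted tree in Newick format
#'
#' Thin wrapper around [ape::read.tree()] that validates the result.
#' Trees without branch lengths are accepted (parsimony needs topology
#' only); root polytomies are preserved.
#'
#' @param path Path to a Newick file containing a single tree.
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("Newick parse error: ", conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error: no tree in ", path)
  if (inherits(tr, "multiPhylo")) stop("expected a single tree in ", path)
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate tip label: ", tr$tip.label[duplicated(tr$tip.label)][1])
  }
  tr
}

#' Write a tree in Newick format
#' @param tree An [ape::phylo] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
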