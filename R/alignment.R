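# Alignments are tibbles with columns `id` and `aligned` (gapped residue
# strings over {A,C,G,U,N,-}), all rows the same length. Ungapping a row
# reproduces the corresponding sequence.

#' Read an aligned FASTA file
#'
#' @param path Path to an aligned (gapped) FASTA file.
#' @return A tibble with columns `id` and `aligned`; all rows have equal
#'   length. Residues are normalised as in [read_rna_fasta()]; gap
#'   characters `-` and `.` are unified to `-`.
#' @export
read_rna_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- stringr::str_split_i(names(set), "\\s+", 1)
  if (anyDuplicated(ids)) stop("duplicate alignment id: ", ids[duplicated(ids)][1])
  rows <- chartr(".", "-", toupper(as.character(set)))
  # normalise residues but keep gaps
  rows <- vapply(rows, function(r) {
    parts <- strsplit(r, "")[[1]]
    gap <- parts == "-"
    parts[!gap] <- strsplit(normalize_residues(paste(parts[!gap], collapse = "")), "")[[1]]
    paste(parts, collapse = "")
  }, character(1))
  aln <- tibble(id = unname(ids), aligned = unname(rows))
  validate_alignment(aln)
  aln
}

validate_alignment <- function(aln) {
  stopifnot(is.data.frame(aln), all(c("id", "aligned") %in% names(aln)),
            nrow(aln) >= 1)
  w <- nchar(aln$aligned)
  if (length(unique(w)) != 1) stop("alignment rows differ in length")
  invisible(aln)
}

alignment_width <- function(aln) nchar(aln$aligned[1])

# character matrix, rows = taxa, cols = alignment columns
alignment_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$aligned, ""))
  rownames(m) <- aln$id
  m
}

#' Remove gaps from an aligned row
#' @param x Gapped residue string(s).
#' @return Ungapped string(s).
#' @export
ungap <- function(x) gsub("-", "", x, fixed = TRUE)

#' Write an alignment to aligned FASTA
#' @param aln Alignment tibble (`id`, `aligned`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rna_alignment <- function(aln, path) {
  validate_alignment(aln)
  write_rna_fasta(tibble(id = aln$id, residues = aln$aligned), path)
}
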