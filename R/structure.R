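# Secondary structures are S3 objects of class "rna_structure": a set of
# nested base pairs over a sequence, with a dot-bracket rendering. All
# coordinates are 1-based and intervals closed, the R convention.

#' Construct a secondary structure object
#'
#' @param id Sequence identifier.
#' @param length Sequence length in residues.
#' @param pairs Two-column integer matrix of base pairs `(i, j)`, 1-based,
#'   `i < j`. May have zero rows.
#' @param score Folding score (dimensionless under the pair-score model).
#' @param provenance One of `"mfe"`, `"consensus"`, `"consensus-projected"`,
#'   `"curated"`, `"parsed"`.
#' @return An object of class `rna_structure`.
#' @export
rna_structure <- function(id, length, pairs, score = NA_real_,
                          provenance = "parsed") {
  pairs <- matrix(as.integer(pairs), ncol = 2,
                  dimnames = list(NULL, c("i", "j")))
  if (nrow(pairs)) {
    stopifnot(all(pairs[, 1] < pairs[, 2]),
              all(pairs >= 1L), all(pairs <= length),
              !anyDuplicated(as.vector(pairs)))
    pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
    # nesting check: no crossing pairs
    if (has_crossing(pairs)) stop("pairs are not properly nested (pseudoknot)")
  }
  structure(list(id = id, length = as.integer(length), pairs = pairs,
                 score = score, provenance = provenance),
            class = "rna_structure")
}

has_crossing <- function(pairs) {
  if (nrow(pairs) < 2) return(FALSE)
  o <- order(pairs[, 1])
  i <- pairs[o, 1]; j <- pairs[o, 2]
  for (a in seq_len(length(i) - 1)) {
    b <- (a + 1):length(i)
    if (any(i[b] < j[a] & j[b] > j[a])) return(TRUE)
  }
  FALSE
}

# partner vector: partner[k] = paired index or 0
pair_partner <- function(struct) {
  p <- integer(struct$length)
  if (nrow(struct$pairs)) {
    p[struct$pairs[, 1]] <- struct$pairs[, 2]
    p[struct$pairs[, 2]] <- struct$pairs[, 1]
  }
  p
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(sprintf("<rna_structure> %s: %d nt, %d pairs, score %s (%s)\n",
              x$id, x$length, nrow(x$pairs),
              format(x$score), x$provenance))
  invisible(x)
}

#' Parse a dot-bracket string into a secondary structure
#'
#' Matched parentheses become base pairs; dots are unpaired. The result
#' round-trips through [render_dotbracket()].
#'
#' @param db Dot-bracket string over `".()"`.
#' @param residues Residue string of the same length (used for length
#'   validation and downstream pair typing).
#' @param id Identifier for the resulting structure.
#' @return An `rna_structure`.
#' @export
parse_dotbracket <- function(db, residues = NULL, id = "struct") {
  chars <- strsplit(db, "")[[1]]
  if (!all(chars %in% c(".", "(", ")"))) {
    stop("invalid dot-bracket character at column ",
         which(!chars %in% c(".", "(", ")"))[1])
  }
  if (!is.null(residues) && nchar(residues) != length(chars)) {
    stop("dot-bracket length ", length(chars),
         " != sequence length ", nchar(residues))
  }
  open <- integer(0)
  pairs <- matrix(integer(0), ncol = 2)
  out <- vector("list", length(chars))
  np <- 0L
  for (k in seq_along(chars)) {
    if (chars[k] == "(") {
      open <- c(open, k)
    } else if (chars[k] == ")") {
      if (!length(open)) stop("unbalanced ')' at column ", k)
      np <- np + 1L
      out[[np]] <- c(open[length(open)], k)
      open <- open[-length(open)]
    }
  }
  if (length(open)) stop("unbalanced '(' at column ", open[1])
  pairs <- if (np) do.call(rbind, out[seq_len(np)]) else matrix(integer(0), ncol = 2)
  rna_structure(id, length(chars), pairs, provenance = "parsed")
}

#' Render a secondary structure as a dot-bracket string
#' @param struct An `rna_structure`.
#' @return A dot-bracket string.
#' @export
render_dotbracket <- function(struct) {
  chars <- rep(".", struct$length)
  if (nrow(struct$pairs)) {
    chars[struct$pairs[, 1]] <- "("
    chars[struct$pairs[, 2]] <- ")"
  }
  paste(chars, collapse = "")
}

#' Read a Vienna-format structure file
#'
#' One record: a `>` header line, a sequence line, and a dot-bracket line
#' (an optional trailing energy in parentheses is ignored).
#'
#' @param path Path to a Vienna file.
#' @return A list with elements `id`, `residues` and `structure`
#'   (an `rna_structure`).
#' @export
read_vienna <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(ln)]
  stopifnot(length(ln) >= 3, startsWith(ln[1], ">"))
  id <- sub("^>\\s*", "", ln[1])
  res <- normalize_residues(ln[2], id)
  db <- sub("\\s+\\(.*\\)\\s*$", "", ln[3])
  list(id = id, residues = res,
       structure = parse_dotbracket(db, res, id = id))
}

#' Write a Vienna-format structure file
#' @param struct An `rna_structure`.
#' @param residues Residue string of matching length.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vienna <- function(struct, residues, path) {
  stopifnot(nchar(residues) == struct$length)
  writeLines(c(paste0(">", struct$id), residues, render_dotbracket(struct)),
             path)
  invisible(path)
}

#' Read a connectivity-table (CT) structure file
#'
#' Read-only courtesy support. Only the first structure in the file is
#' read; pair symmetry is validated.
#'
#' @param path Path to a CT file.
#' @return A list with `id`, `residues`, `structure`.
#' @export
read_ct <- function(path) {
  ln <- readLines(path)
  hdr <- strsplit(trimws(ln[1]), "\\s+")[[1]]
  n <- as.integer(hdr[1])
  id <- if (length(hdr) > 1) paste(hdr[-1], collapse = " ") else "ct"
  body <- ln[2:(n + 1)]
  f <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), `[`, 1:5))
  idx <- as.integer(f[, 1]); base <- f[, 2]; partner <- as.integer(f[, 5])
  stopifnot(identical(idx, seq_len(n)))
  bad <- which(partner > 0 & partner[pmax(partner, 1)] != idx)
  if (length(bad)) stop("CT pair table not symmetric at residue ", bad[1])
  keep <- partner > idx
  pairs <- cbind(idx[keep], partner[keep])
  res <- normalize_residues(paste(base, collapse = ""), id)
  list(id = id, residues = res,
       structure = rna_structure(id, n, pairs, provenance = "parsed"))
}

#' Tidy a secondary structure into a tibble of base pairs
#'
#' @param x An `rna_structure`.
#' @param residues Optional residue string; adds residue columns and pair
#'   type (`canonical`, `wobble`, `non-canonical`).
#' @param ... Unused.
#' @return A tibble with columns `i`, `j` and, when residues are given,
#'   `res_i`, `res_j`, `pair_type`.
#' @exportS3Method generics::tidy
tidy.rna_structure <- function(x, residues = NULL, ...) {
  out <- as_tibble(x$pairs)
  if (!is.null(residues) && nrow(out)) {
    ri <- substring(residues, out$i, out$i)
    rj <- substring(residues, out$j, out$j)
    duo <- paste0(ri, rj)
    out$res_i <- ri
    out$res_j <- rj
    out$pair_type <- dplyr::case_when(
      duo %in% c("GC", "CG", "AU", "UA") ~ "canonical",
      duo %in% c("GU", "UG") ~ "wobble",
      TRUE ~ "non-canonical"
    )
  }
  out
}

#' @exportS3Method generics::glance
glance.rna_structure <- function(x, ...) {
  tibble(id = x$id, length = x$length, n_pairs = nrow(x$pairs),
         score = x$score, provenance = x$provenance)
}
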