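# V4 extraction: the hypervariable V4 region is excised from full-length
# SSU rRNA sequences by locating two conserved flanking anchors with an
# ungapped scan. The anchors are derived from a reference alignment in
# which the V4 column interval is known; across-species the V4 flanks are
# highly conserved while V4 itself varies (163-261 nt in Euplotes), which
# is what makes anchor search reliable.

#' Build an anchor profile from a reference alignment
#'
#' Takes a reference alignment with a known V4 column interval and returns
#' the majority-rule consensus of the flanking column blocks as left/right
#' anchors. Gap characters are dropped from the consensus; majority ties
#' are broken alphabetically (A < C < G < U).
#'
#' @param aln Alignment tibble (`id`, `aligned`).
#' @param v4_columns Integer vector `c(first, last)`: 1-based closed
#'   column interval of the V4 region in the alignment.
#' @param anchor_len Number of flanking columns per anchor (default 20).
#' @param max_mismatch_fraction Maximum tolerated mismatch fraction when
#'   the profile is used for search (default 0.2).
#' @return A list of class `anchor_profile` with `left_anchor`,
#'   `right_anchor`, `max_mismatch_fraction`.
#' @export
build_anchor_profile <- function(aln, v4_columns, anchor_len = 20L,
                                 max_mismatch_fraction = 0.2) {
  validate_alignment(aln)
  w <- alignment_width(aln)
  first <- v4_columns[1]; last <- v4_columns[2]
  stopifnot(first >= 1, last <= w, first <= last)
  if (first - 1 < anchor_len || w - last < anchor_len) {
    stop("flank too short for anchor length ", anchor_len)
  }
  m <- alignment_matrix(aln)
  cons <- function(cols) {
    anchor <- vapply(cols, function(k) {
      col <- m[, k]
      col <- col[col != "-"]
      if (!length(col)) return(NA_character_)
      tab <- table(factor(col, levels = c("A", "C", "G", "U", "N")))
      names(tab)[which.max(tab)]  # which.max takes the first max: A<C<G<U tie rule
    }, character(1))
    paste(anchor[!is.na(anchor)], collapse = "")
  }
  structure(list(
    left_anchor = cons((first - anchor_len):(first - 1)),
    right_anchor = cons((last + 1):(last + anchor_len)),
    max_mismatch_fraction = max_mismatch_fraction
  ), class = "anchor_profile")
}

#' @export
print.anchor_profile <- function(x, ...) {
  cat(sprintf("<anchor_profile> left %s (%d nt), right %s (%d nt), max mismatch %.2f\n",
              x$left_anchor, nchar(x$left_anchor),
              x$right_anchor, nchar(x$right_anchor),
              x$max_mismatch_fraction))
  invisible(x)
}

# All ungapped placements of `anchor` in `seq_chars`; returns a tibble of
# start, mismatches, score (match +1 / mismatch -1; N matches nothing).
anchor_scan <- function(seq_chars, anchor) {
  a <- strsplit(anchor, "")[[1]]
  la <- length(a); n <- length(seq_chars)
  if (n < la) return(tibble(start = integer(0), mismatches = integer(0), score = integer(0)))
  starts <- seq_len(n - la + 1)
  mm <- integer(length(starts))
  # column-wise comparison: one pass per anchor position
  for (k in seq_len(la)) {
    sk <- seq_chars[starts + k - 1L]
    mm <- mm + as.integer(sk != a[k] | sk == "N" | a[k] == "N")
  }
  tibble(start = starts, mismatches = mm, score = la - 2L * mm)
}

#' Locate and excise the V4 region from one sequence
#'
#' The left anchor is placed at its best-scoring admissible position (ties
#' broken leftmost); the right anchor at the nearest admissible position
#' downstream of the left anchor (which keeps partial sequences from
#' producing run-on regions). The V4 region is the subsequence strictly
#' between the two anchor matches. A placement is admissible when its
#' mismatch fraction is at most the profile's `max_mismatch_fraction`.
#'
#' @param seq Either a single-row sequence tibble (columns `id`,
#'   `residues`) or a residue string (then `id` is taken from `id`).
#' @param profile An `anchor_profile`.
#' @param id Identifier used when `seq` is a bare string.
#' @return A one-row tibble: `id`, `start`, `end` (1-based closed V4
#'   interval on the ungapped sequence), `length`, `v4` (the excised
#'   residues), `anchor_score` (summed over both anchors).
#' @export
locate_v4 <- function(seq, profile, id = "seq") {
  if (is.data.frame(seq)) {
    stopifnot(nrow(seq) == 1)
    id <- seq$id
    seq <- seq$residues
  }
  chars <- strsplit(seq, "")[[1]]
  la <- nchar(profile$left_anchor); ra <- nchar(profile$right_anchor)
  if (length(chars) <= la + ra) stop("sequence shorter than combined anchors for ", id)

  left <- anchor_scan(chars, profile$left_anchor)
  left_ok <- left[left$mismatches / la <= profile$max_mismatch_fraction, ]
  if (!nrow(left_ok)) {
    stop(sprintf("region not found for %s: best left-anchor score %d (%d mismatches)",
                 id, max(left$score), min(left$mismatches)))
  }
  lbest <- left_ok[which.max(left_ok$score), ]  # which.max: first max = leftmost tie
  lend <- lbest$start + la - 1L

  right <- anchor_scan(chars, profile$right_anchor)
  right_ok <- right[right$start > lend &
                      right$mismatches / ra <= profile$max_mismatch_fraction, ]
  if (!nrow(right_ok)) {
    stop(sprintf("region not found for %s: left anchor at %d, best right-anchor score %d",
                 id, lbest$start, max(right$score)))
  }
  rbest <- right_ok[1, ]  # nearest admissible downstream (shortest V4)

  start <- lend + 1L
  end <- rbest$start - 1L
  if (end < start) stop("region not found for ", id, ": anchors abut, empty V4")
  tibble(
    id = id,
    start = start, end = end, length = end - start + 1L,
    v4 = substr(seq, start, end),
    anchor_score = lbest$score + rbest$score
  )
}

#' Extract the V4 region from a collection of sequences
#'
#' Applies [locate_v4()] to each row; sequences whose region cannot be
#' located are dropped with a warning and reported in the
#' `v4_dropped` attribute.
#'
#' @param seqs Sequence tibble (`id`, `residues`, ...).
#' @param profile An `anchor_profile`.
#' @return A tibble of region hits (one row per located taxon) with a
#'   `v4_dropped` attribute: tibble of `id`, `reason`.
#' @export
extract_v4 <- function(seqs, profile) {
  hits <- vector("list", nrow(seqs))
  dropped <- list()
  for (r in seq_len(nrow(seqs))) {
    hit <- tryCatch(locate_v4(seqs$residues[r], profile, id = seqs$id[r]),
                    error = function(e) conditionMessage(e))
    if (is.character(hit)) {
      dropped[[length(dropped) + 1]] <- tibble(id = seqs$id[r], reason = hit)
    } else {
      hits[[r]] <- hit
    }
  }
  if (length(dropped)) {
    warning(length(dropped), " sequence(s) dropped during V4 extraction")
  }
  out <- dplyr::bind_rows(hits)
  attr(out, "v4_dropped") <- dplyr::bind_rows(dropped)
  out
}
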