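# Helix decomposition and Type I / Type II classification.
#
# A helix is a maximal run of stacked pairs; helices nest into a forest.
# A stem (a "drawn helix" in structure diagrams) chains helices separated
# only by small internal loops/bulges. The V4 classification examines the
# designated variable stem E23_8: if its distal walk ends in a hairpin
# the structure is Type I; if it ends in a multiloop with >= 2 child
# helices (E23_11/E23_12) it is Type II.

#' Decompose a structure into its helix nesting forest
#'
#' Every pair belongs to exactly one helix (a maximal run of stacked
#' pairs `(i,j), (i+1,j-1), ...`). Helices are linked into a nesting
#' forest; roots and children are ordered 5' to 3'.
#'
#' @param struct An `rna_structure`.
#' @return A list of class `helix_forest`: `helices` (list of helix
#'   records with `pairs`, `parent`, `children`, `label`) and `roots`
#'   (indices of top-level helices).
#' @export
find_helices <- function(struct) {
  pairs <- struct$pairs
  if (!nrow(pairs)) {
    return(structure(list(helices = list(), roots = integer(0)),
                     class = "helix_forest"))
  }
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  partner <- integer(struct$length)
  partner[pairs[, 1]] <- pairs[, 2]
  partner[pairs[, 2]] <- pairs[, 1]
  # group into maximal stacked runs
  helices <- list()
  used <- logical(nrow(pairs))
  key <- paste(pairs[, 1], pairs[, 2])
  idx <- stats::setNames(seq_len(nrow(pairs)), key)
  for (r in seq_len(nrow(pairs))) {
    if (used[r]) next
    i <- pairs[r, 1]; j <- pairs[r, 2]
    # walk outward to the helix start (no pair (i-1, j+1))
    while (i - 1 >= 1 && j + 1 <= struct$length && partner[i - 1] == j + 1) {
      i <- i - 1L; j <- j + 1L
    }
    run <- list()
    while (i < j && partner[i] == j) {
      run[[length(run) + 1]] <- c(i, j)
      idx_r <- idx[[paste(i, j)]]
      used[idx_r] <- TRUE
      i <- i + 1L; j <- j - 1L
    }
    helices[[length(helices) + 1]] <- list(
      pairs = do.call(rbind, run), parent = NA_integer_,
      children = integer(0), label = NA_character_)
  }
  # order helices by outer i
  outer_i <- vapply(helices, function(h) h$pairs[1, 1], integer(1))
  helices <- helices[order(outer_i)]
  # parent = nearest enclosing helix (by outer pair containment)
  oi <- vapply(helices, function(h) h$pairs[1, 1], integer(1))
  oj <- vapply(helices, function(h) h$pairs[1, 2], integer(1))
  for (a in seq_along(helices)) {
    enclosing <- which(oi < oi[a] & oj > oj[a])
    if (length(enclosing)) {
      par <- enclosing[which.max(oi[enclosing])]
      helices[[a]]$parent <- par
    }
  }
  for (a in seq_along(helices)) {
    p <- helices[[a]]$parent
    if (!is.na(p)) helices[[p]]$children <- c(helices[[p]]$children, a)
  }
  roots <- which(vapply(helices, function(h) is.na(h$parent), logical(1)))
  structure(list(helices = helices, roots = roots), class = "helix_forest")
}

# inner pair of a helix (closest to the loop)
helix_inner <- function(h) h$pairs[nrow(h$pairs), ]
helix_outer <- function(h) h$pairs[1, ]

#' Remove short isolated helices from a structure
#'
#' Base-pair maximisation has no stacking term, so it happily places
#' isolated pairs wherever two residues happen to be complementary.
#' Thermodynamic folders suppress such lone pairs (they contribute no
#' stacking energy), and published structure models do not draw them.
#' This helper drops every helix shorter than `min_helix` pairs; apply
#' it before interpreting a structure topologically.
#'
#' @param struct An `rna_structure`.
#' @param min_helix Minimum helix length in pairs (default 2 = remove
#'   lone pairs only).
#' @param params A [fold_params()] used to re-score the retained pairs;
#'   `NULL` keeps the original score.
#' @param residues Residue string, required when `params` is given.
#' @return The filtered `rna_structure`.
#' @export
drop_lone_pairs <- function(struct, min_helix = 2L, params = NULL,
                            residues = NULL) {
  f <- find_helices(struct)
  keep <- do.call(rbind, lapply(f$helices, function(h) {
    if (nrow(h$pairs) >= min_helix) h$pairs
  }))
  if (is.null(keep)) keep <- matrix(integer(0), ncol = 2)
  score <- struct$score
  if (!is.null(params)) {
    stopifnot(!is.null(residues))
    tab <- pair_score_table(params)
    code <- encode_residues(residues)
    score <- if (nrow(keep)) sum(tab[cbind(code[keep[, 1]], code[keep[, 2]])]) else 0
  }
  rna_structure(struct$id, struct$length, keep, score = score,
                provenance = struct$provenance)
}

#' Group helices into stems
#'
#' Chains of helices separated only by internal loops/bulges of at most
#' `bulge_tol` unpaired residues per side are merged into one stem;
#' multiloops (two or more child helices) always break stems.
#'
#' @param forest A `helix_forest` from [find_helices()].
#' @param bulge_tol Maximum unpaired residues per side between chained
#'   helices (default 3).
#' @return A list of class `stem_list`; each stem holds `helix_idx`
#'   (indices into `forest$helices`), `n_pairs`, `outer` (the outermost
#'   pair), and `label`.
#' @export
group_stems <- function(forest, bulge_tol = 3L) {
  helices <- forest$helices
  if (!length(helices)) return(structure(list(stems = list(), forest = forest,
                                              bulge_tol = bulge_tol),
                                         class = "stem_list"))
  absorbed <- logical(length(helices))
  stems <- list()
  # candidate chain starts: helices that are not absorbed as a continuation
  continues <- function(p, c) {
    # child c continues parent p when it is the only child and the
    # intervening internal loop is <= bulge_tol per side
    if (length(helices[[p]]$children) != 1) return(FALSE)
    pi <- helix_inner(helices[[p]]); co <- helix_outer(helices[[c]])
    left <- co[1] - pi[1] - 1L
    right <- pi[2] - co[2] - 1L
    left <= bulge_tol && right <= bulge_tol
  }
  is_start <- vapply(seq_along(helices), function(a) {
    p <- helices[[a]]$parent
    is.na(p) || !continues(p, a)
  }, logical(1))
  for (a in which(is_start)) {
    chain <- a
    cur <- a
    repeat {
      ch <- helices[[cur]]$children
      if (length(ch) == 1 && continues(cur, ch)) {
        chain <- c(chain, ch)
        cur <- ch
      } else break
    }
    stems[[length(stems) + 1]] <- list(
      helix_idx = chain,
      n_pairs = sum(vapply(chain, function(k) nrow(helices[[k]]$pairs), integer(1))),
      outer = helix_outer(helices[[chain[1]]]),
      label = NA_character_)
  }
  # order stems 5'->3' by outer start
  ord <- order(vapply(stems, function(s) s$outer[1], integer(1)))
  structure(list(stems = stems[ord], forest = forest, bulge_tol = bulge_tol),
            class = "stem_list")
}

#' Hairpin-loop size of a stem
#'
#' Number of unpaired residues strictly enclosed by the innermost pair of
#' the stem. Errors if the stem's innermost helix branches (ends in a
#' multiloop rather than a hairpin).
#'
#' @param stem One stem record from [group_stems()].
#' @param forest The `helix_forest` (or a `stem_list`, whose forest is
#'   used).
#' @return Integer loop size in nucleotides.
#' @export
hairpin_size <- function(stem, forest) {
  if (inherits(forest, "stem_list")) forest <- forest$forest
  last <- stem$helix_idx[length(stem$helix_idx)]
  h <- forest$helices[[last]]
  if (length(h$children)) stop("not a hairpin: stem ends in a multiloop")
  inner <- helix_inner(h)
  unname(inner[2] - inner[1] - 1L)
}

#' Label the top-level stems of a V4 structure
#'
#' Top-level stems are labelled `H1, H2, ...` in 5' to 3' order. The
#' designated variable stem `E23_8` is, under the default rule, the
#' top-level stem with the greatest total pair count (ties broken
#' 3'-most); its distal children (if the walk ends in a multiloop) are
#' labelled `E23_11`, `E23_12`, ... in 5' to 3' order. The drawn-label
#' to coordinate mapping is not uniquely defined in published models, so
#' the rule is explicit and configurable.
#'
#' @param stems A `stem_list` from [group_stems()].
#' @param rule How to pick E23_8: `"largest"` (default), `"last"`
#'   (3'-most top-level stem), or an integer index among top-level stems.
#' @return The `stem_list` with `label` fields filled and an `e23_8`
#'   element (index of the E23_8 stem, or `NA` if no stems).
#' @export
label_e23 <- function(stems, rule = "largest") {
  ss <- stems$stems
  if (!length(ss)) {
    stems$e23_8 <- NA_integer_
    return(stems)
  }
  # top-level stems: first helix has no parent
  top <- which(vapply(ss, function(s) {
    is.na(stems$forest$helices[[s$helix_idx[1]]]$parent)
  }, logical(1)))
  for (k in seq_along(top)) ss[[top[k]]]$label <- paste0("H", k)
  npairs <- vapply(ss[top], function(s) s$n_pairs, integer(1))
  e23 <- if (identical(rule, "largest")) {
    cand <- which(npairs == max(npairs))
    top[cand[length(cand)]]  # ties: 3'-most
  } else if (identical(rule, "last")) {
    top[length(top)]
  } else if (is.numeric(rule)) {
    top[as.integer(rule)]
  } else stop("unknown E23_8 rule: ", rule)
  ss[[e23]]$label <- "E23_8"
  stems$stems <- ss
  stems$e23_8 <- e23
  stems
}

# walk distally from the last helix of a stem through single-child
# internal loops of any size; return the terminal helix index
distal_walk <- function(forest, start_helix) {
  cur <- start_helix
  repeat {
    ch <- forest$helices[[cur]]$children
    if (length(ch) == 1) cur <- ch else return(cur)
  }
}

#' Classify a V4 structure as Type I or Type II
#'
#' Decomposes the structure, designates the E23_8 stem, and walks
#' distally through internal loops and bulges. A walk ending in a
#' hairpin gives Type I (with the terminal hairpin size); a walk ending
#' in a multiloop with two or more enclosed child helices gives Type II
#' (with the number of distal sub-helices). Structures without pairs are
#' unclassified.
#'
#' @param struct An `rna_structure` spanning the V4 region.
#' @param bulge_tol Bulge tolerance for stem grouping (default 3).
#' @param rule E23_8 designation rule, see [label_e23()].
#' @return A one-row tibble (`topology report`): `id`, `struct_type`
#'   (`"TYPE_I"`, `"TYPE_II"` or `"UNCLASSIFIED"`), `n_top_stems`,
#'   `e23_8_pairs`, `e23_8_terminal` (`"hairpin"`/`"multiloop"`/`NA`),
#'   `terminal_hairpin_size`, `n_distal_subhelices`.
#' @export
classify_v4 <- function(struct, bulge_tol = 3L, rule = "largest") {
  empty <- tibble(id = struct$id, struct_type = "UNCLASSIFIED",
                  n_top_stems = 0L, e23_8_pairs = NA_integer_,
                  e23_8_terminal = NA_character_,
                  terminal_hairpin_size = NA_integer_,
                  n_distal_subhelices = NA_integer_)
  if (!nrow(struct$pairs)) return(empty)
  forest <- find_helices(struct)
  stems <- label_e23(group_stems(forest, bulge_tol), rule)
  if (is.na(stems$e23_8)) return(empty)
  e23 <- stems$stems[[stems$e23_8]]
  n_top <- sum(vapply(stems$stems, function(s) {
    is.na(forest$helices[[s$helix_idx[1]]]$parent)
  }, logical(1)))
  last_h <- e23$helix_idx[length(e23$helix_idx)]
  term <- distal_walk(forest, last_h)
  ch <- forest$helices[[term]]$children
  if (!length(ch)) {
    inner <- helix_inner(forest$helices[[term]])
    tibble(id = struct$id, struct_type = "TYPE_I", n_top_stems = n_top,
           e23_8_pairs = e23$n_pairs, e23_8_terminal = "hairpin",
           terminal_hairpin_size = unname(inner[2] - inner[1] - 1L),
           n_distal_subhelices = 0L)
  } else {
    tibble(id = struct$id, struct_type = "TYPE_II", n_top_stems = n_top,
           e23_8_pairs = e23$n_pairs, e23_8_terminal = "multiloop",
           terminal_hairpin_size = NA_integer_,
           n_distal_subhelices = length(ch))
  }
}

#' Classify a set of structures
#'
#' @param structs List of `rna_structure` objects.
#' @param bulge_tol,rule Passed to [classify_v4()].
#' @return A tibble with one topology-report row per structure.
#' @export
classify_all <- function(structs, bulge_tol = 3L, rule = "largest") {
  dplyr::bind_rows(lapply(structs, classify_v4, bulge_tol = bulge_tol,
                          rule = rule))
}
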