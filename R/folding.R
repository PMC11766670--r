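# Secondary-structure prediction by base-pair maximisation (Nussinov-style
# dynamic programming) with a simple pair-score model, plus consensus
# folding over an alignment with a covariance bonus (RNAalifold-style
# scoring on columns). A full thermodynamic nearest-neighbour model is
# deliberately out of scope: the pair-score surrogate keeps every
# algorithmic property exactly testable, at the cost of model-dependent
# per-species structures.

#' Folding parameters
#'
#' @param pair_scores Named numeric vector of scores per pair type.
#'   Defaults to GC/CG = 3, AU/UA = 2, GU/UG = 1 (dimensionless; the
#'   ordering mirrors pair stability). Must be symmetric.
#' @param min_hairpin Minimum number of unpaired residues enclosed by any
#'   pair (steric minimum, default 3).
#' @param covariance_bonus Consensus folding only: bonus per distinct
#'   canonical pair type beyond the first observed across rows at a
#'   column pair (default 1).
#' @param inconsistency_penalty Consensus folding only: penalty per row
#'   whose residues cannot pair at a column pair; gaps count as
#'   cannot-pair (default 0.5).
#' @return A list of class `fold_params`.
#' @export
fold_params <- function(pair_scores = c(GC = 3, CG = 3, AU = 2, UA = 2,
                                        GU = 1, UG = 1),
                        min_hairpin = 3L,
                        covariance_bonus = 1.0,
                        inconsistency_penalty = 0.5) {
  stopifnot(min_hairpin >= 3)
  rev2 <- function(x) paste0(substr(x, 2, 2), substr(x, 1, 1))
  stopifnot(all(abs(pair_scores[rev2(names(pair_scores))] - pair_scores) < 1e-12))
  structure(list(pair_scores = pair_scores,
                 min_hairpin = as.integer(min_hairpin),
                 covariance_bonus = covariance_bonus,
                 inconsistency_penalty = inconsistency_penalty),
            class = "fold_params")
}

# 6x6 score lookup over the coded alphabet A,C,G,U,N,- (N and gaps never pair)
ALPHABET <- c("A", "C", "G", "U", "N", "-")

pair_score_table <- function(params) {
  tab <- matrix(0, 6, 6, dimnames = list(ALPHABET, ALPHABET))
  for (p in names(params$pair_scores)) {
    tab[substr(p, 1, 1), substr(p, 2, 2)] <- params$pair_scores[[p]]
  }
  tab
}

encode_residues <- function(x) {
  match(strsplit(x, "")[[1]], ALPHABET)
}

# Base-pair maximisation DP over an arbitrary score matrix S (n x n,
# S[i,j] > 0 where pairing i..j is allowed). Returns list(score, pairs).
# Traceback is deterministic: prefer leaving i unpaired, then the
# smallest pairing partner k — one canonical optimum structure.
nussinov_dp <- function(S, min_hairpin) {
  n <- nrow(S)
  h <- min_hairpin
  M <- matrix(0, n, n)
  if (n >= h + 2) {
    for (L in (h + 2):n) {
      ii <- seq_len(n - L + 1)
      for (i in ii) {
        j <- i + L - 1L
        ks <- seq.int(i + h + 1L, j)
        sc <- S[i, ks]
        keep <- sc > 0
        best <- M[i + 1L, j]
        if (any(keep)) {
          ks <- ks[keep]; sc <- sc[keep]
          left <- ifelse(ks - 1L >= i + 1L, M[cbind(i + 1L, pmax(ks - 1L, i + 1L))], 0)
          right <- ifelse(ks + 1L <= j, M[cbind(pmin(ks + 1L, j), j)], 0)
          best <- max(best, max(sc + left + right))
        }
        M[i, j] <- best
      }
    }
  }
  pairs <- matrix(integer(0), ncol = 2)
  if (n >= 2) {
    stack <- list(c(1L, n))
    acc <- list()
    eps <- 1e-9
    while (length(stack)) {
      iv <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      i <- iv[1]; j <- iv[2]
      if (j - i < h + 1L) next
      target <- M[i, j]
      if (target <= eps) next
      if (M[i + 1L, j] >= target - eps) {   # prefer i unpaired
        stack[[length(stack) + 1]] <- c(i + 1L, j)
        next
      }
      ks <- seq.int(i + h + 1L, j)
      found <- FALSE
      for (k in ks) {                        # smallest k first
        if (S[i, k] <= 0) next
        left <- if (k - 1L >= i + 1L) M[i + 1L, k - 1L] else 0
        right <- if (k + 1L <= j) M[k + 1L, j] else 0
        if (abs(S[i, k] + left + right - target) < eps) {
          acc[[length(acc) + 1]] <- c(i, k)
          if (k - 1L >= i + 1L) stack[[length(stack) + 1]] <- c(i + 1L, k - 1L)
          if (k + 1L <= j) stack[[length(stack) + 1]] <- c(k + 1L, j)
          found <- TRUE
          break
        }
      }
      if (!found) stop("traceback failed (internal error)")
    }
    if (length(acc)) pairs <- do.call(rbind, acc)
  }
  list(score = if (n >= 2) M[1, n] else 0, pairs = pairs)
}

#' Fold one sequence by base-pair maximisation
#'
#' Returns a structure maximising the total pair score under the nesting
#' and minimum-hairpin constraints. `N` never pairs. Sequences too short
#' to fold return an empty structure with score 0.
#'
#' @param seq Residue string, or a one-row sequence tibble.
#' @param params A [fold_params()] object.
#' @param id Identifier when `seq` is a bare string.
#' @return An `rna_structure` with provenance `"mfe"`.
#' @export
fold_mfe <- function(seq, params = fold_params(), id = "seq") {
  if (is.data.frame(seq)) {
    stopifnot(nrow(seq) == 1)
    id <- seq$id; seq <- seq$residues
  }
  code <- encode_residues(seq)
  n <- length(code)
  if (n < params$min_hairpin + 2) {
    return(rna_structure(id, n, matrix(integer(0), ncol = 2), score = 0,
                         provenance = "mfe"))
  }
  tab <- pair_score_table(params)
  S <- tab[code, code, drop = FALSE]
  res <- nussinov_dp(S, params$min_hairpin)
  rna_structure(id, n, res$pairs, score = res$score, provenance = "mfe")
}

# column-pair score matrix for consensus folding
consensus_score_matrix <- function(m_codes, params) {
  n <- ncol(m_codes)
  tab <- pair_score_table(params)
  # code each pair of residues as (a-1)*6 + b for pair-type counting
  canon <- c("GC", "CG", "AU", "UA", "GU", "UG")
  canon_code <- vapply(canon, function(p) {
    (match(substr(p, 1, 1), ALPHABET) - 1L) * 6L + match(substr(p, 2, 2), ALPHABET)
  }, integer(1))
  S <- matrix(0, n, n)
  h <- params$min_hairpin
  for (k in seq_len(n - h - 1L)) {
    ls <- seq.int(k + h + 1L, n)
    a <- m_codes[, k]
    for (l in ls) {
      b <- m_codes[, l]
      sc <- tab[cbind(a, b)]
      pairing <- sc > 0
      if (!any(pairing)) next
      types <- unique(((a - 1L) * 6L + b)[pairing])
      total <- sum(sc) +
        params$covariance_bonus * (sum(types %in% canon_code) - 1L) -
        params$inconsistency_penalty * sum(!pairing)
      if (total > 0) S[k, l] <- total
    }
  }
  S
}

#' Fold the consensus structure of an alignment
#'
#' Base-pair maximisation on alignment columns. The score of pairing
#' columns `(k, l)` sums the per-row pair scores, adds a covariance bonus
#' per distinct canonical pair type beyond the first (compensatory
#' substitutions are evidence for a conserved pair), and subtracts a
#' penalty per row whose residues cannot pair (gaps count as
#' cannot-pair). Column pairs with non-positive score are forbidden.
#'
#' @param aln Alignment tibble (`id`, `aligned`).
#' @param params A [fold_params()] object.
#' @return A list of class `consensus_fold`: `structure` (an
#'   `rna_structure` on columns, provenance `"consensus"`), and `stats`,
#'   a tibble of per-column-pair conservation statistics (`k`, `l`,
#'   `score`, `n_pair_types`, `n_inconsistent`).
#' @export
fold_consensus <- function(aln, params = fold_params()) {
  validate_alignment(aln)
  m <- alignment_matrix(aln)
  m_codes <- matrix(match(m, ALPHABET), nrow = nrow(m))
  S <- consensus_score_matrix(m_codes, params)
  res <- nussinov_dp(S, params$min_hairpin)
  struct <- rna_structure("consensus", ncol(m_codes), res$pairs,
                          score = res$score, provenance = "consensus")
  tab <- pair_score_table(params)
  stats <- purrr::map_dfr(seq_len(nrow(struct$pairs)), function(r) {
    k <- struct$pairs[r, 1]; l <- struct$pairs[r, 2]
    sc <- tab[cbind(m_codes[, k], m_codes[, l])]
    duos <- paste0(m[, k], m[, l])
    tibble(k = k, l = l, score = S[k, l],
           n_pair_types = length(unique(duos[sc > 0])),
           n_inconsistent = sum(sc <= 0))
  })
  structure(list(structure = struct, stats = stats, alignment = aln),
            class = "consensus_fold")
}

#' @export
print.consensus_fold <- function(x, ...) {
  cat(sprintf("<consensus_fold> %d columns, %d pairs, score %.2f\n",
              x$structure$length, nrow(x$structure$pairs), x$structure$score))
  invisible(x)
}

#' Project a consensus structure onto one alignment row
#'
#' Column pairs are mapped through the row's gap pattern; pairs with a
#' gapped or non-pairing residue on either side are dropped. The result
#' is a valid per-sequence structure (projection cannot introduce
#' crossings).
#'
#' @param consensus A `consensus_fold` or an `rna_structure` on columns.
#' @param aln Alignment tibble (needed when `consensus` is a bare
#'   structure; otherwise taken from the `consensus_fold`).
#' @param id Row id to project onto.
#' @param params A [fold_params()] object (defines which duos can pair).
#' @return An `rna_structure` over the ungapped row, provenance
#'   `"consensus-projected"`; its score is the summed pair score of the
#'   retained pairs.
#' @export
project_consensus <- function(consensus, id, aln = NULL,
                              params = fold_params()) {
  if (inherits(consensus, "consensus_fold")) {
    if (is.null(aln)) aln <- consensus$alignment
    consensus <- consensus$structure
  }
  validate_alignment(aln)
  row <- aln$aligned[aln$id == id]
  if (length(row) != 1) stop("row not in alignment: ", id)
  chars <- strsplit(row, "")[[1]]
  gap <- chars == "-"
  # ungapped index for each column (NA at gaps)
  up <- cumsum(!gap)
  up[gap] <- NA_integer_
  tab <- pair_score_table(params)
  keep_pairs <- list()
  score <- 0
  for (r in seq_len(nrow(consensus$pairs))) {
    k <- consensus$pairs[r, 1]; l <- consensus$pairs[r, 2]
    if (gap[k] || gap[l]) next
    sc <- tab[chars[k], chars[l]]
    if (sc <= 0) next
    keep_pairs[[length(keep_pairs) + 1]] <- c(up[k], up[l])
    score <- score + sc
  }
  pairs <- if (length(keep_pairs)) do.call(rbind, keep_pairs) else matrix(integer(0), ncol = 2)
  rna_structure(id, sum(!gap), pairs, score = score,
                provenance = "consensus-projected")
}
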