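# Independent oracles used to validate the package's algorithms. These
# deliberately share no code with the implementation: structures are
# enumerated exhaustively, parsimony is minimised over all labellings,
# and CBC verdicts are re-derived from a literal reading of the
# definition.

# --- exhaustive folding oracle -----------------------------------------

# all nested structures over chars[i..j] as lists of pair matrices;
# pairs restricted to duos with positive score and min_hairpin h
enumerate_structures <- function(chars, score_of, h = 3) {
  n <- length(chars)
  rec <- function(i, j) {
    if (i >= j) return(list(matrix(integer(0), ncol = 2)))
    out <- lapply(rec(i + 1, j), identity)  # i unpaired
    for (k in seq.int(i + h + 1, j)) {
      if (k > j) break
      if (score_of(chars[i], chars[k]) <= 0) next
      ins <- rec(i + 1, k - 1)
      outr <- rec(k + 1, j)
      for (x in ins) for (y in outr) {
        out[[length(out) + 1]] <- rbind(c(i, k), x, y)
      }
    }
    out
  }
  rec(1, n)
}

oracle_best_fold_score <- function(residues, params = v4evo::fold_params()) {
  chars <- strsplit(residues, "")[[1]]
  sc <- function(a, b) {
    key <- paste0(a, b)
    if (key %in% names(params$pair_scores)) params$pair_scores[[key]] else 0
  }
  structs <- enumerate_structures(chars, sc, h = params$min_hairpin)
  best <- 0
  for (p in structs) {
    if (!nrow(p)) next
    s <- sum(vapply(seq_len(nrow(p)),
                    function(r) sc(chars[p[r, 1]], chars[p[r, 2]]), numeric(1)))
    if (s > best) best <- s
  }
  best
}

# --- exhaustive parsimony oracle ---------------------------------------

oracle_parsimony_steps <- function(tree, states) {
  ntip <- ape::Ntip(tree)
  nint <- tree$Nnode
  lev <- sort(unique(unname(states)))
  tip_idx <- match(tree$tip.label, names(states))
  grid <- expand.grid(rep(list(lev), nint), stringsAsFactors = FALSE)
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    lab <- c(states[tip_idx], unlist(grid[g, ], use.names = FALSE))
    steps <- sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]])
    if (steps < best) best <- steps
  }
  best
}

# --- independent CBC verdict --------------------------------------------

# literal re-derivation: skip on gap/N; both duos must bond (Watson-Crick
# or G:U); then classify by which sides changed
oracle_cbc_verdict <- function(a1, a2, b1, b2) {
  residues <- c(a1, a2, b1, b2)
  if (any(residues == "-" | residues == "N")) return("skipped-gap")
  bonds <- rbind(c("A", "U"), c("U", "A"), c("G", "C"), c("C", "G"),
                 c("G", "U"), c("U", "G"))
  bonded <- function(x, y) any(bonds[, 1] == x & bonds[, 2] == y)
  if (!bonded(a1, a2) || !bonded(b1, b2)) return("skipped-nonpairing")
  n_diff <- (a1 != b1) + (a2 != b2)
  c("same", "hCBC", "CBC")[n_diff + 1]
}

# --- random generators ---------------------------------------------------

random_rna <- function(n, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# random valid dot-bracket with hairpins >= 3
random_dotbracket <- function(n) {
  rec <- function(m) {
    if (m < 7) return(strrep(".", m))
    if (stats::runif(1) < 0.4) {
      cut <- sample.int(m - 1, 1)
      return(paste0(rec(cut), rec(m - cut)))
    }
    inner <- rec(m - 2)
    paste0("(", inner, ")")
  }
  # ensure any '(' encloses >= 3 characters: rebuild until valid
  repeat {
    db <- rec(n)
    ok <- tryCatch({
      st <- v4evo::parse_dotbracket(db)
      !nrow(st$pairs) || all(st$pairs[, 2] - st$pairs[, 1] > 3)
    }, error = function(e) FALSE)
    if (ok) return(db)
  }
}
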