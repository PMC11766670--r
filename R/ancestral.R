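# Parsimony ancestral-state reconstruction of the binary Type I / Type II
# structural character on a rooted tree, with enumeration of gains
# (TYPE_I -> TYPE_II) and reversals (TYPE_II -> TYPE_I, "reverse
# evolution"). The engine is a unit-cost minimum-change dynamic program
# (Sankoff recursion), which equals Fitch parsimony on binary trees and
# handles polytomies exactly; per-node state sets are the MPR sets (the
# states each node takes in at least one most-parsimonious
# reconstruction).

#' Parsimony ancestral-state reconstruction
#'
#' Computes, for every node of a rooted tree, the set of character
#' states compatible with a most-parsimonious reconstruction (MPR set),
#' and the parsimony length. Tips without a state are pruned with a
#' message. The character is treated as unordered with equal costs.
#'
#' @param tree A rooted [ape::phylo] tree (branch lengths optional;
#'   polytomies allowed).
#' @param states Tip states: a named character vector
#'   (`names = tip labels`), or a tibble with columns `id` and
#'   `struct_type` (rows with `"UNCLASSIFIED"` are excluded with a
#'   warning) — i.e. a topology report from [classify_all()] works
#'   directly.
#' @return An object of class `fitch_asr`: the pruned `tree`, `states`,
#'   `state_levels`, `n_steps` (parsimony length), `down` (per-node
#'   subtree cost matrix) and `node_sets` (per-node MPR sets). Resolve
#'   to a unique labelling with [resolve_asr()].
#' @export
fitch_asr <- function(tree, states) {
  if (is.data.frame(states)) {
    bad <- states$struct_type == "UNCLASSIFIED" | is.na(states$struct_type)
    if (any(bad)) {
      warning("excluding ", sum(bad), " unclassified taxa: ",
              paste(states$id[bad], collapse = ", "))
    }
    states <- stats::setNames(states$struct_type[!bad], states$id[!bad])
  }
  stopifnot(inherits(tree, "phylo"), !is.null(names(states)))
  extra <- setdiff(names(states), tree$tip.label)
  if (length(extra)) stop("states given for taxa absent from tree: ",
                          paste(extra, collapse = ", "))
  missing <- setdiff(tree$tip.label, names(states))
  if (length(missing)) {
    message("pruning ", length(missing), " tip(s) without a state: ",
            paste(missing, collapse = ", "))
    tree <- ape::drop.tip(tree, missing)
    if (is.null(tree) || ape::Ntip(tree) < 2) stop("fewer than 2 tips with states")
  }
  lev <- sort(unique(unname(states)))
  k <- length(lev)
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  ntot <- ntip + nnode
  root <- ntip + 1L
  big <- .Machine$integer.max / 4

  down <- matrix(big, ntot, k, dimnames = list(NULL, lev))
  for (t in seq_len(ntip)) {
    down[t, ] <- big
    down[t, states[[tree$tip.label[t]]]] <- 0
  }
  po <- ape::reorder.phylo(tree, "postorder")
  # postorder fill
  for (e in seq_len(nrow(po$edge))) {
    v <- po$edge[e, 1]; c <- po$edge[e, 2]
    if (all(down[v, ] >= big)) down[v, ] <- 0
    trans <- vapply(seq_len(k), function(s) min(down[c, ] + (seq_len(k) != s)),
                    numeric(1))
    down[v, ] <- ifelse(down[v, ] >= big, trans, down[v, ] + trans)
  }
  # internal nodes never visited as parents keep big; root always visited
  n_steps <- min(down[root, ])

  # up costs by preorder (cost of the rest of the tree given node state)
  up <- matrix(0, ntot, k, dimnames = list(NULL, lev))
  children_of <- split(tree$edge[, 2], tree$edge[, 1])
  pre <- rev(seq_len(nrow(po$edge)))  # reverse postorder edges = preorder
  for (e in pre) {
    v <- po$edge[e, 1]; c <- po$edge[e, 2]
    sibs <- setdiff(children_of[[as.character(v)]], c)
    base <- up[v, ]
    for (b in sibs) {
      base <- base + vapply(seq_len(k), function(s) {
        min(down[b, ] + (seq_len(k) != s))
      }, numeric(1))
    }
    up[c, ] <- vapply(seq_len(k), function(s) {
      min(base + (seq_len(k) != s))
    }, numeric(1))
  }

  node_sets <- lapply(seq_len(ntot), function(v) {
    lev[down[v, ] + up[v, ] <= n_steps + 1e-9]
  })

  structure(list(tree = tree, states = states, state_levels = lev,
                 n_steps = as.integer(round(n_steps)),
                 down = down, up = up, node_sets = node_sets),
            class = "fitch_asr")
}

#' Resolve an ancestral reconstruction to unique node states
#'
#' Resolves ambiguous nodes by a stated rule and derives the list of
#' state-change edges. All rules yield a labelling attaining the
#' parsimony length: each node's state is chosen from the minimisers of
#' (subtree cost + mismatch with the resolved parent state).
#'
#' * `"DELTRAN"` (default): delay transformations — keep the parent's
#'   state whenever it is among the minimisers (changes pushed tipward).
#' * `"ACCTRAN"`: accelerate transformations — prefer a state different
#'   from the parent's whenever the minimum allows (changes pulled
#'   rootward).
#' * `"prefer-ancestral"`: take the parent's state whenever it lies in
#'   the node's MPR set, otherwise fall back to the DELTRAN choice.
#'
#' Ties at the root (and remaining ties elsewhere) are broken by the
#' alphabetically first state, so `TYPE_I` is preferred — the simpler,
#' prokaryote-like condition.
#'
#' @param recon A `fitch_asr` object.
#' @param rule One of `"DELTRAN"`, `"ACCTRAN"`, `"prefer-ancestral"`.
#' @return The `fitch_asr` object augmented with `rule`, `resolved`
#'   (state per node), `changes` (tibble: `parent`, `node`, `from`,
#'   `to`) and `reversals` (the `TYPE_II -> TYPE_I` subset).
#' @export
resolve_asr <- function(recon, rule = c("DELTRAN", "ACCTRAN", "prefer-ancestral")) {
  rule <- match.arg(rule)
  tree <- recon$tree
  lev <- recon$state_levels
  k <- length(lev)
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  down <- recon$down
  resolved <- character(ntip + tree$Nnode)
  resolved[root] <- lev[which.min(down[root, ])]  # which.min: first (alphabetical) tie-break

  po <- ape::reorder.phylo(tree, "postorder")
  pre <- rev(seq_len(nrow(po$edge)))
  for (e in pre) {
    v <- po$edge[e, 1]; c <- po$edge[e, 2]
    p <- resolved[v]
    cond <- down[c, ] + (lev != p)
    cand <- lev[cond <= min(cond) + 1e-9]
    resolved[c] <- switch(
      rule,
      "DELTRAN" = if (p %in% cand) p else cand[1],
      "ACCTRAN" = if (any(cand != p)) cand[cand != p][1] else p,
      "prefer-ancestral" = if (p %in% recon$node_sets[[c]] && p %in% cand) p
                           else if (p %in% cand) p else cand[1]
    )
  }

  edges <- tibble(parent = tree$edge[, 1], node = tree$edge[, 2],
                  from = resolved[tree$edge[, 1]],
                  to = resolved[tree$edge[, 2]])
  changes <- edges[edges$from != edges$to, ]
  recon$rule <- rule
  recon$resolved <- resolved
  recon$changes <- changes
  recon$reversals <- changes[changes$from == "TYPE_II" & changes$to == "TYPE_I", ]
  recon
}

#' Report reversal edges with their descendant clades
#'
#' Lists each `TYPE_II -> TYPE_I` change edge of a resolved
#' reconstruction together with the tip set below it.
#'
#' @param recon A resolved `fitch_asr` (see [resolve_asr()]).
#' @return A tibble: `node`, `from`, `to`, `n_tips_below`, `tips_below`
#'   (semicolon-separated tip labels).
#' @export
reversal_report <- function(recon) {
  if (is.null(recon$resolved)) stop("resolve the reconstruction first (resolve_asr)")
  tree <- recon$tree
  ntip <- ape::Ntip(tree)
  rows <- lapply(seq_len(nrow(recon$reversals)), function(r) {
    node <- recon$reversals$node[r]
    tips <- if (node <= ntip) tree$tip.label[node] else
      tree$tip.label[unlist(phangorn_free_descendants(tree, node))]
    tibble(node = node, from = recon$reversals$from[r],
           to = recon$reversals$to[r],
           n_tips_below = length(tips),
           tips_below = paste(sort(tips), collapse = ";"))
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble(node = integer(0), from = character(0), to = character(0),
                  n_tips_below = integer(0), tips_below = character(0))
  }
  out
}

# tips below an internal node, without extra dependencies
phangorn_free_descendants <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  acc <- integer(0)
  stack <- node
  children_of <- split(tree$edge[, 2], tree$edge[, 1])
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (v <= ntip) {
      acc <- c(acc, v)
    } else {
      stack <- c(stack, children_of[[as.character(v)]])
    }
  }
  list(acc)
}

#' @export
print.fitch_asr <- function(x, ...) {
  cat(sprintf("<fitch_asr> %d tips, parsimony length %d", ape::Ntip(x$tree),
              x$n_steps))
  if (!is.null(x$resolved)) {
    cat(sprintf("; %s: %d change(s), %d reversal(s)", x$rule,
                nrow(x$changes), nrow(x$reversals)))
  }
  cat("\n")
  invisible(x)
}

#' Tidy an ancestral reconstruction into a per-node tibble
#'
#' @param x A `fitch_asr` object.
#' @param ... Unused.
#' @return A tibble with one row per node: `node`, `is_tip`, `label`
#'   (tip label or `NA`), `state_set` (MPR states, pipe-separated) and,
#'   if resolved, `state`.
#' @exportS3Method generics::tidy
tidy.fitch_asr <- function(x, ...) {
  ntip <- ape::Ntip(x$tree)
  n <- ntip + x$tree$Nnode
  out <- tibble(
    node = seq_len(n),
    is_tip = seq_len(n) <= ntip,
    label = c(x$tree$tip.label, rep(NA_character_, x$tree$Nnode)),
    state_set = vapply(x$node_sets, paste, character(1), collapse = "|")
  )
  if (!is.null(x$resolved)) out$state <- x$resolved
  out
}

#' @exportS3Method generics::glance
glance.fitch_asr <- function(x, ...) {
  tibble(
    n_tips = ape::Ntip(x$tree),
    n_steps = x$n_steps,
    rule = x$rule %||% NA_character_,
    n_changes = if (is.null(x$changes)) NA_integer_ else nrow(x$changes),
    n_gains = if (is.null(x$changes)) NA_integer_ else
      sum(x$changes$from == "TYPE_I" & x$changes$to == "TYPE_II"),
    n_reversals = if (is.null(x$reversals)) NA_integer_ else nrow(x$reversals)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
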