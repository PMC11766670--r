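# Seeded simulator for V4 secondary-structure evolution. A hand-designed
# V4 template (four top-level stems, the largest being E23_8 with a
# 21-nt terminal hairpin loop) is embedded in conserved flanks and
# evolved down a Yule tree: unpaired sites mutate freely, stem sites are
# compensated on the partner base with a configured probability, and a
# fixed literal two-helix block (E23_11 + E23_12) inserts into / deletes
# from the E23_8 terminal loop, toggling the structure between Type I
# and Type II. Every event is logged so tips can be replayed from the
# root, and every planted event is recoverable ground truth.

# ---- template ----------------------------------------------------------

rc_gc <- function(x) {
  # reverse complement for GC-only stem strands
  paste(rev(strsplit(chartr("GC", "CG", x), "")[[1]]), collapse = "")
}

#' The designed V4 template
#'
#' Returns the fixed root V4 used by the simulator, in "master"
#' coordinates (the Type II layout; Type I rows gap across the block
#' columns). Four top-level stems; the largest (20 pairs) is E23_8 and
#' ends, in Type I, in a 21-nt hairpin loop; in Type II a fixed literal
#' 31-nt block folding into two hairpins (E23_11, E23_12) sits inside
#' that loop, creating a distal multiloop with two sub-helices.
#'
#' @return A list: `master_seq` and `master_db` (197 columns, Type II),
#'   `block_columns` (integer vector of the 31 block columns),
#'   `type1_seq` and `type1_db` (166 nt), `pairs` (master pair matrix),
#'   `partner` (master partner vector).
#' @export
v4_template <- function() {
  seg <- function(s, d) list(s = s, d = d)
  stem <- function(left, loop) {
    list(seg(left, strrep("(", nchar(left))),
         seg(strrep("A", loop), strrep(".", loop)),
         seg(rc_gc(left), strrep(")", nchar(left))))
  }
  A <- function(n) seg(strrep("A", n), strrep(".", n))
  block_segs <- c(stem("GGCGC", 4), list(A(3)), stem("GCGCG", 4))
  e23_8 <- function(loop_segs) c(
    list(seg("GGCGGCGCG", "((((((((("), A(2), seg("GCGCC", "((((("), A(2),
         seg("GGCCGC", "((((((")),
    loop_segs,
    list(seg("GCGGCC", "))))))"), A(2), seg("GGCGC", ")))))"), A(2),
         seg("CGCGCCGCC", ")))))))))")))
  layout <- function(loop_segs) c(
    list(A(4)), stem("GGCGCG", 12), list(A(6)), stem("GCGGCG", 11),
    list(A(6)), e23_8(loop_segs), list(A(6)), stem("GCGCGG", 12), list(A(4)))
  cat_segs <- function(segs) {
    list(s = paste(vapply(segs, `[[`, character(1), "s"), collapse = ""),
         d = paste(vapply(segs, `[[`, character(1), "d"), collapse = ""))
  }
  t1 <- cat_segs(layout(list(A(21))))
  t2 <- cat_segs(layout(c(list(A(4)), block_segs, list(A(17)))))
  # block columns: residues before the E23_8 terminal loop, plus the 4
  # leading loop As, then the 31-nt block
  left_len <- 4 + 24 + 6 + 23 + 6 + 9 + 2 + 5 + 2 + 6
  block_columns <- seq.int(left_len + 4 + 1, left_len + 4 + 31)
  st <- parse_dotbracket(t2$d, t2$s, id = "template")
  partner <- pair_partner(st)
  list(master_seq = t2$s, master_db = t2$d, block_columns = block_columns,
       type1_seq = t1$s, type1_db = t1$d,
       pairs = st$pairs, partner = partner)
}

# ---- configuration -----------------------------------------------------

#' Simulation configuration
#'
#' Defaults describe the study conditions the simulator emulates: a
#' clock-like Yule tree over a few tens of taxa, a V4 of 166/197 nt
#' (inside the observed 163-261 nt range) embedded in ~800-nt conserved
#' flanks (a full SSU of ~1.8 kb), mostly-compensated stem substitution,
#' and occasional insertion/deletion of the E23_11/E23_12 block.
#'
#' @param n_taxa Number of tips of the Yule tree (ignored when `tree`
#'   is supplied).
#' @param birth Yule birth rate.
#' @param sub_rate Substitutions per site per unit branch length in the
#'   V4 region.
#' @param stem_comp_fraction Probability that a stem substitution is
#'   immediately compensated on the partner base.
#' @param cbc_plant Named integer vector: forced compensatory double
#'   substitutions on the terminal branch of each named tip.
#' @param helix_block_indel_rate Per-branch probability of toggling the
#'   E23_11/E23_12 block (insertion if absent, deletion if present).
#' @param flank_len Length of each conserved flank (nt).
#' @param flank_mut Per-site, per-tip mutation probability in the flanks.
#' @param root_type Root character state, `"TYPE_I"` or `"TYPE_II"`.
#' @param seed Mandatory integer seed; all outputs are reproducible
#'   from it.
#' @param tree Optional fixed [ape::phylo] tree (must have branch
#'   lengths).
#' @param force_toggles Optional list of character vectors of tip
#'   labels; on the edge above the MRCA of each set (the tip edge for a
#'   single label) a block toggle is forced — used to plant gains and
#'   reversals.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 30, birth = 1, sub_rate = 0.02,
                       stem_comp_fraction = 0.8, cbc_plant = NULL,
                       helix_block_indel_rate = 0.05,
                       flank_len = 800, flank_mut = 0.02,
                       root_type = c("TYPE_I", "TYPE_II"), seed,
                       tree = NULL, force_toggles = NULL) {
  root_type <- match.arg(root_type)
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(sub_rate >= 0, stem_comp_fraction >= 0, stem_comp_fraction <= 1,
            helix_block_indel_rate >= 0, helix_block_indel_rate <= 1,
            flank_mut >= 0, flank_mut <= 1)
  structure(list(n_taxa = n_taxa, birth = birth, sub_rate = sub_rate,
                 stem_comp_fraction = stem_comp_fraction,
                 cbc_plant = cbc_plant,
                 helix_block_indel_rate = helix_block_indel_rate,
                 flank_len = flank_len, flank_mut = flank_mut,
                 root_type = root_type, seed = as.integer(seed),
                 tree = tree, force_toggles = force_toggles),
            class = "sim_config")
}

BASES <- c("A", "C", "G", "U")
COMPLEMENTS <- list(A = "U", C = "G", G = c("C", "U"), U = c("A", "G"))

# ---- simulator ---------------------------------------------------------

#' Simulate a V4 cohort down a tree
#'
#' Generates full-length synthetic SSU-like sequences (flank + V4 +
#' flank), the gap-aware V4 alignment, the tree, and a ground-truth
#' record (per-node types, per-branch event log, true V4 coordinates,
#' root pair table). Replaying the event log from the root reproduces
#' every tip sequence exactly.
#'
#' @param config A [sim_config()].
#' @return A list of class `v4_sim`: `sequences` (tibble `id`,
#'   `residues`, `clade`, `source`), `v4_alignment` (tibble `id`,
#'   `aligned`, master coordinates), `tree`, and `truth` (list:
#'   `tip_types`, `node_types`, `events`, `v4_coords`, `template`,
#'   `root_type`, `seed`).
#' @export
simulate_v4 <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tpl <- v4_template()
  tree <- config$tree
  if (is.null(tree)) {
    tree <- ape::rphylo(config$n_taxa, birth = config$birth, death = 0)
    tree$tip.label <- sprintf("t%02d", seq_len(config$n_taxa))
  }
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L

  # forced toggles: map tip sets to edge child nodes
  forced_nodes <- integer(0)
  for (tips in config$force_toggles) {
    node <- if (length(tips) == 1) match(tips, tree$tip.label)
            else ape::getMRCA(tree, tips)
    if (is.na(node) || is.null(node)) stop("force_toggles lineage absent: ",
                                           paste(tips, collapse = ","))
    forced_nodes <- c(forced_nodes, node)
  }
  if (!is.null(config$cbc_plant)) {
    miss <- setdiff(names(config$cbc_plant), tree$tip.label)
    if (length(miss)) stop("cbc_plant lineage absent from tree: ",
                           paste(miss, collapse = ","))
  }

  master <- strsplit(tpl$master_seq, "")[[1]]
  n_master <- length(master)
  partner <- tpl$partner
  block <- tpl$block_columns
  is_block <- seq_len(n_master) %in% block

  flankL <- sample(BASES, config$flank_len, replace = TRUE)
  flankR <- sample(BASES, config$flank_len, replace = TRUE)

  root_state <- list(v4 = master,
                     block_present = config$root_type == "TYPE_II")

  events <- list()
  log_event <- function(node, event, site, from, to) {
    events[[length(events) + 1]] <<- tibble(
      node = node, event = event, site = site, from = from, to = to)
  }

  mutate_site <- function(v4, site, node, comp_allowed) {
    cur <- v4[site]
    newb <- sample(setdiff(BASES, cur), 1)
    p <- partner[site]
    if (p > 0 && comp_allowed && stats::runif(1) < config$stem_comp_fraction) {
      pnew <- sample(COMPLEMENTS[[newb]], 1)
      log_event(node, "comp_sub", site, paste0(cur, v4[p]), paste0(newb, pnew))
      v4[site] <- newb
      v4[p] <- pnew
    } else {
      log_event(node, if (p > 0) "stem_sub" else "sub", site, cur, newb)
      v4[site] <- newb
    }
    v4
  }

  evolve_edge <- function(state, node, brlen) {
    v4 <- state$v4
    present <- state$block_present
    # block toggle: forced on planted edges, otherwise Bernoulli
    toggled <- node %in% forced_nodes ||
      stats::runif(1) < config$helix_block_indel_rate
    if (toggled) {
      if (present) {
        log_event(node, "block_del", NA_integer_, "TYPE_II", "TYPE_I")
        v4[is_block] <- strsplit(tpl$master_seq, "")[[1]][is_block]  # reset literal
        present <- FALSE
      } else {
        log_event(node, "block_ins", NA_integer_, "TYPE_I", "TYPE_II")
        v4[is_block] <- strsplit(tpl$master_seq, "")[[1]][is_block]
        present <- TRUE
      }
    }
    active <- if (present) seq_len(n_master) else which(!is_block)
    n_sub <- stats::rpois(1, config$sub_rate * length(active) * brlen)
    if (n_sub > 0) {
      sites <- active[sample.int(length(active), min(n_sub, length(active)))]
      for (site in sites) {
        p <- partner[site]
        comp_ok <- p > 0 && (p %in% active)
        v4 <- mutate_site(v4, site, node, comp_ok)
      }
    }
    list(v4 = v4, block_present = present)
  }

  # preorder traversal
  states <- vector("list", ntip + tree$Nnode)
  states[[root]] <- root_state
  po <- ape::reorder.phylo(tree, "postorder")
  pre_edges <- rev(seq_len(nrow(po$edge)))
  for (e in pre_edges) {
    v <- po$edge[e, 1]; c <- po$edge[e, 2]
    states[[c]] <- evolve_edge(states[[v]], c, po$edge.length[e])
  }

  # planted CBCs on terminal branches
  for (tip in names(config$cbc_plant)) {
    t_idx <- match(tip, tree$tip.label)
    st <- states[[t_idx]]
    active_pairs <- which(partner > seq_len(n_master))
    if (!st$block_present) {
      active_pairs <- active_pairs[!(active_pairs %in% block) &
                                     !(partner[active_pairs] %in% block)]
    }
    k <- config$cbc_plant[[tip]]
    cols <- active_pairs[sample.int(length(active_pairs), k)]
    for (i5 in cols) {
      i3 <- partner[i5]
      cur <- c(st$v4[i5], st$v4[i3])
      cand <- CANONICAL_DUOS[substr(CANONICAL_DUOS, 1, 1) != cur[1] &
                               substr(CANONICAL_DUOS, 2, 2) != cur[2]]
      newd <- sample(cand, 1)
      log_event(t_idx, "cbc_plant", i5, paste0(cur, collapse = ""), newd)
      st$v4[i5] <- substr(newd, 1, 1)
      st$v4[i3] <- substr(newd, 2, 2)
    }
    states[[t_idx]] <- st
  }

  # materialise tips
  node_types <- vapply(states, function(s) {
    if (is.null(s)) NA_character_
    else if (s$block_present) "TYPE_II" else "TYPE_I"
  }, character(1))
  tip_types <- stats::setNames(node_types[seq_len(ntip)], tree$tip.label)

  rows <- lapply(seq_len(ntip), function(t) {
    st <- states[[t]]
    keep <- if (st$block_present) rep(TRUE, n_master) else !is_block
    v4_chars <- st$v4
    fl <- flankL; fr <- flankR
    if (config$flank_mut > 0) {
      for (nm in c("fl", "fr")) {
        f <- get(nm)
        hit <- which(stats::runif(length(f)) < config$flank_mut)
        if (length(hit)) {
          f[hit] <- vapply(f[hit], function(b) sample(setdiff(BASES, b), 1), character(1))
          assign(nm, f)
        }
      }
    }
    aligned <- v4_chars
    aligned[!keep] <- "-"
    v4_str <- paste(v4_chars[keep], collapse = "")
    tibble(
      id = tree$tip.label[t],
      residues = paste0(paste(fl, collapse = ""), v4_str, paste(fr, collapse = "")),
      aligned = paste(aligned, collapse = ""),
      v4_start = config$flank_len + 1L,
      v4_end = config$flank_len + nchar(v4_str)
    )
  })
  tips <- dplyr::bind_rows(rows)

  # alignment columns: master coordinates; when no tip carries the block
  # the block columns are all-gap and are dropped, so a homogeneous
  # Type I cohort yields a gap-free alignment
  any_block <- any(vapply(seq_len(ntip), function(t) states[[t]]$block_present,
                          logical(1)))
  keep_cols <- if (any_block) seq_len(n_master) else which(!is_block)
  aligned <- vapply(tips$aligned, function(s) {
    paste(strsplit(s, "")[[1]][keep_cols], collapse = "")
  }, character(1), USE.NAMES = FALSE)
  col_map <- match(seq_len(n_master), keep_cols)  # master -> alignment column
  pr <- tpl$pairs
  pr_ok <- !is.na(col_map[pr[, 1]]) & !is.na(col_map[pr[, 2]])
  pair_columns <- cbind(col_map[pr[pr_ok, 1]], col_map[pr[pr_ok, 2]])

  structure(list(
    sequences = tibble(id = tips$id, residues = tips$residues,
                       clade = NA_character_, source = "synthetic"),
    v4_alignment = tibble(id = tips$id, aligned = aligned),
    tree = tree,
    truth = list(
      tip_types = tip_types, node_types = node_types,
      events = if (length(events)) dplyr::bind_rows(events) else
        tibble(node = integer(0), event = character(0), site = integer(0),
               from = character(0), to = character(0)),
      v4_coords = tibble(id = tips$id, start = tips$v4_start, end = tips$v4_end),
      pair_columns = pair_columns, alignment_master_cols = keep_cols,
      template = tpl, root_type = config$root_type, seed = config$seed,
      flankL = paste(flankL, collapse = ""), flankR = paste(flankR, collapse = "")
    )
  ), class = "v4_sim")
}

#' @export
print.v4_sim <- function(x, ...) {
  cat(sprintf("<v4_sim> %d taxa, root %s, %d events (seed %d)\n",
              nrow(x$sequences), x$truth$root_type, nrow(x$truth$events),
              x$truth$seed))
  invisible(x)
}

#' Reference anchor profile for the simulated cohort
#'
#' Builds the extraction anchors from the simulator's unmutated flank
#' consensus — the equivalent of deriving anchors from a reference
#' alignment whose V4 columns are known.
#'
#' @param sim A `v4_sim` object.
#' @param anchor_len Anchor length (default 20).
#' @param max_mismatch_fraction Passed to the profile (default 0.2).
#' @return An `anchor_profile`.
#' @export
sim_anchor_profile <- function(sim, anchor_len = 20L,
                               max_mismatch_fraction = 0.2) {
  fl <- sim$truth$flankL; fr <- sim$truth$flankR
  structure(list(
    left_anchor = substr(fl, nchar(fl) - anchor_len + 1, nchar(fl)),
    right_anchor = substr(fr, 1, anchor_len),
    max_mismatch_fraction = max_mismatch_fraction
  ), class = "anchor_profile")
}

# ---- packaged fixture --------------------------------------------------

#' The 12-taxon mini cohort fixture
#'
#' A deterministic 12-taxon simulated cohort with planted history: root
#' Type I, one block gain on the edge to the `t03..t12` clade, and two
#' planted reversals on the terminal branches of `t07` and `t12` — each
#' nested deep enough inside the Type II clade that every resolution
#' rule recovers it as a reversal rather than trading it for parallel
#' gains. One compensatory base change is planted on the terminal
#' branch of `t12`, mirroring the single deviant taxon of the study's
#' youngest clade. Background substitution is light and uncompensated,
#' flanks carry 1% noise, and no random block toggles occur, so the
#' planted events are the complete structural history.
#'
#' @return A `v4_sim` object with clade labels (`A` = t01-t02,
#'   `B` = t03-t07, `C` = t08-t12) filled in, plus a `planted` element
#'   recording expected tip types, the planted CBC carrier and the
#'   planted reversal clades.
#' @export
fixture_mini_cohort <- function() {
  nwk <- paste0(
    "((t01:0.05,t02:0.05):0.05,((t03:0.05,t04:0.05):0.05,",
    "((t05:0.05,t06:0.05):0.05,(t07:0.1,((t08:0.05,t09:0.05):0.05,",
    "((t10:0.05,t11:0.05):0.05,t12:0.1):0.05):0.05):0.05):0.05):0.05);")
  tree <- ape::read.tree(text = nwk)
  cfg <- sim_config(
    sub_rate = 0.02, stem_comp_fraction = 0, cbc_plant = c(t12 = 1L),
    helix_block_indel_rate = 0, flank_len = 400, flank_mut = 0.01,
    root_type = "TYPE_I", seed = 73901, tree = tree,
    force_toggles = list(
      sprintf("t%02d", 3:12),  # gain on the clade ancestor
      "t07",                   # reversal
      "t12"))                  # reversal
  sim <- simulate_v4(cfg)
  sim$sequences$clade <- c("A", "A", rep("B", 5), rep("C", 5))
  sim$planted <- list(
    tip_types = stats::setNames(
      c("TYPE_I", "TYPE_I", rep("TYPE_II", 4), "TYPE_I",
        rep("TYPE_II", 4), "TYPE_I"),
      sprintf("t%02d", 1:12)),
    cbc_carrier = "t12",
    reversal_clades = list("t07", "t12"))
  sim
}
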