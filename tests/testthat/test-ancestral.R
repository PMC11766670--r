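states_of <- function(tree, x) stats::setNames(x, tree$tip.label)

test_that("a uniform character needs zero steps", {
  tree <- ape::read.tree(text = "((a,b),(c,d));")
  rec <- fitch_asr(tree, states_of(tree, rep("TYPE_I", 4)))
  expect_equal(rec$n_steps, 0)
  rec <- resolve_asr(rec)
  expect_true(all(rec$resolved == "TYPE_I"))
  expect_equal(nrow(rec$changes), 0)
  expect_equal(nrow(reversal_report(rec)), 0)
})

test_that("a balanced split is one step with an ambiguous root", {
  tree <- ape::read.tree(text = "((a,b),(c,d));")
  rec <- fitch_asr(tree, states_of(tree, c("TYPE_I", "TYPE_I",
                                           "TYPE_II", "TYPE_II")))
  expect_equal(rec$n_steps, 1)
  root_set <- rec$node_sets[[ape::Ntip(tree) + 1]]
  expect_setequal(root_set, c("TYPE_I", "TYPE_II"))
  expect_equal(oracle_parsimony_steps(tree, states_of(
    tree, c("TYPE_I", "TYPE_I", "TYPE_II", "TYPE_II"))), 1)
})

test_that("an outgroup tips the root under prefer-ancestral", {
  tree <- ape::read.tree(text = "(((a,b),(c,d)),og);")
  st <- stats::setNames(c("TYPE_I", "TYPE_I", "TYPE_II", "TYPE_II", "TYPE_I"),
                        c("a", "b", "c", "d", "og"))
  rec <- resolve_asr(fitch_asr(tree, st), rule = "prefer-ancestral")
  expect_equal(rec$resolved[ape::Ntip(tree) + 1], "TYPE_I")
  g <- glance(rec)
  expect_equal(g$n_gains, 1)
  expect_equal(g$n_reversals, 0)
})

test_that("step counts equal the exhaustive minimum on random trees", {
  set.seed(67)
  for (i in 1:60) {
    n <- sample(4:8, 1)
    tree <- ape::rtree(n)
    st <- states_of(tree, sample(c("TYPE_I", "TYPE_II"), n, replace = TRUE))
    expect_equal(fitch_asr(tree, st)$n_steps,
                 oracle_parsimony_steps(tree, st),
                 info = ape::write.tree(tree))
  }
})

test_that("step counts agree with an independent parsimony implementation", {
  skip_if_not_installed("phangorn")
  set.seed(97)
  for (i in 1:25) {
    n <- sample(5:20, 1)
    tree <- ape::rtree(n)
    st <- states_of(tree, sample(c("TYPE_I", "TYPE_II"), n, replace = TRUE))
    pd <- phangorn::phyDat(matrix(st[tree$tip.label], ncol = 1,
                                  dimnames = list(tree$tip.label, NULL)),
                           type = "USER", levels = c("TYPE_I", "TYPE_II"))
    expect_equal(fitch_asr(tree, st)$n_steps,
                 phangorn::parsimony(tree, pd))
  }
})

test_that("step count is invariant to tip order and rerooting", {
  set.seed(113)
  tree <- ape::rtree(10)
  st <- states_of(tree, sample(c("TYPE_I", "TYPE_II"), 10, replace = TRUE))
  base <- fitch_asr(tree, st)$n_steps
  for (i in 1:5) {
    perm <- sample(names(st))
    expect_equal(fitch_asr(tree, st[perm])$n_steps, base)
    out <- sample(tree$tip.label, 1)
    rerooted <- ape::root(tree, outgroup = out, resolve.root = TRUE)
    expect_equal(fitch_asr(rerooted, st)$n_steps, base)
  }
})

test_that("every resolution rule attains the parsimony length", {
  set.seed(131)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    tree <- ape::rtree(n)
    st <- states_of(tree, sample(c("TYPE_I", "TYPE_II"), n, replace = TRUE))
    rec <- fitch_asr(tree, st)
    for (rule in c("DELTRAN", "ACCTRAN", "prefer-ancestral")) {
      res <- resolve_asr(rec, rule)
      expect_equal(nrow(res$changes), rec$n_steps, info = rule)
      expect_identical(unname(res$resolved[seq_len(n)]),
                       unname(st[tree$tip.label]))
    }
  }
})

test_that("polytomies are handled exactly", {
  tree <- ape::read.tree(text = "((a,b,c,d),(e,f));")
  st <- stats::setNames(c("TYPE_II", "TYPE_II", "TYPE_II", "TYPE_I",
                          "TYPE_I", "TYPE_I"), letters[1:6])
  rec <- fitch_asr(tree, st)
  expect_equal(rec$n_steps, oracle_parsimony_steps(tree, st))
})

test_that("tips without states are pruned, unknown tips rejected", {
  tree <- ape::read.tree(text = "((a,b),(c,d));")
  st <- stats::setNames(c("TYPE_I", "TYPE_I", "TYPE_II"), c("a", "b", "c"))
  expect_message(rec <- fitch_asr(tree, st), "pruning")
  expect_equal(ape::Ntip(rec$tree), 3)
  expect_error(fitch_asr(tree, c(st, zz = "TYPE_I")), "absent")
  # topology-report input excludes unclassified taxa with a warning
  topo <- tibble::tibble(id = c("a", "b", "c", "d"),
                         struct_type = c("TYPE_I", "TYPE_I", "TYPE_II",
                                         "UNCLASSIFIED"))
  expect_warning(expect_message(rec2 <- fitch_asr(tree, topo), "pruning"),
                 "unclassified")
  expect_equal(ape::Ntip(rec2$tree), 3)
})

test_that("resolved internal states track a simulated low-noise history", {
  # expected changes per edge path well below 1: internal-state recovery
  # should be high
  hits <- 0; tot <- 0
  for (seed in 1:30) {
    sim <- simulate_v4(sim_config(n_taxa = 12, sub_rate = 0, flank_len = 50,
                                  helix_block_indel_rate = 0.04,
                                  seed = 9000 + seed))
    truth <- sim$truth$node_types
    rec <- resolve_asr(fitch_asr(sim$tree, sim$truth$tip_types))
    internal <- (ape::Ntip(sim$tree) + 1):length(truth)
    hits <- hits + sum(rec$resolved[internal] == truth[internal])
    tot <- tot + length(internal)
  }
  expect_gt(hits / tot, 0.9)
})
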