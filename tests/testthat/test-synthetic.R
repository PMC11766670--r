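test_that("the template geometry matches its design", {
  tpl <- v4_template()
  expect_equal(nchar(tpl$type1_seq), 166)
  expect_equal(nchar(tpl$master_seq), 197)
  expect_length(tpl$block_columns, 31)
  # V4 lengths sit inside the observed 163-261 nt range
  expect_true(all(c(166, 197) >= 163 & c(166, 197) <= 261))
  # removing the block columns from the master gives the Type I template
  chars <- strsplit(tpl$master_seq, "")[[1]]
  expect_equal(paste(chars[-tpl$block_columns], collapse = ""), tpl$type1_seq)
})

test_that("zero rates give identical tips, a gap-free alignment, root types", {
  sim <- simulate_v4(sim_config(n_taxa = 6, sub_rate = 0, flank_len = 60,
                                flank_mut = 0, helix_block_indel_rate = 0,
                                seed = 12))
  expect_equal(length(unique(sim$sequences$residues)), 1)
  expect_false(any(grepl("-", sim$v4_alignment$aligned, fixed = TRUE)))
  expect_true(all(sim$truth$tip_types == "TYPE_I"))
  tpl <- v4_template()
  expect_equal(sim$v4_alignment$aligned[1], tpl$type1_seq)
})

test_that("simulation is byte-identical under the same seed", {
  cfg <- sim_config(n_taxa = 10, sub_rate = 0.05, flank_len = 100, seed = 321)
  a <- simulate_v4(cfg)
  b <- simulate_v4(cfg)
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$v4_alignment, b$v4_alignment)
  expect_identical(a$truth$events, b$truth$events)
  c <- simulate_v4(sim_config(n_taxa = 10, sub_rate = 0.05, flank_len = 100,
                              seed = 322))
  expect_false(identical(a$sequences$residues, c$sequences$residues))
})

test_that("replaying the event log reproduces every tip V4 exactly", {
  sim <- simulate_v4(sim_config(n_taxa = 8, sub_rate = 0.2, flank_len = 50,
                                flank_mut = 0, stem_comp_fraction = 0.5,
                                helix_block_indel_rate = 0.1, seed = 55))
  tpl <- sim$truth$template
  tree <- sim$tree
  ev <- sim$truth$events
  master_cols <- sim$truth$alignment_master_cols
  ntip <- ape::Ntip(tree)
  path_to <- function(tip) {
    # node path root -> tip
    anc <- tip
    v <- tip
    parentof <- stats::setNames(tree$edge[, 1], tree$edge[, 2])
    while (!is.na(parentof[as.character(v)])) {
      v <- parentof[[as.character(v)]]
      anc <- c(v, anc)
    }
    anc
  }
  for (t in seq_len(ntip)) {
    v4 <- strsplit(tpl$master_seq, "")[[1]]
    present <- sim$truth$root_type == "TYPE_II"
    for (node in path_to(t)) {
      e <- ev[ev$node == node, ]
      for (r in seq_len(nrow(e))) {
        if (e$event[r] %in% c("block_ins", "block_del")) {
          present <- e$event[r] == "block_ins"
          v4[tpl$block_columns] <- strsplit(tpl$master_seq, "")[[1]][tpl$block_columns]
        } else if (e$event[r] == "comp_sub" || e$event[r] == "cbc_plant") {
          i5 <- e$site[r]; i3 <- tpl$partner[i5]
          v4[i5] <- substr(e$to[r], 1, 1)
          v4[i3] <- substr(e$to[r], 2, 2)
        } else {
          v4[e$site[r]] <- e$to[r]
        }
      }
    }
    expected <- v4
    if (!present) expected[tpl$block_columns] <- "-"
    got <- strsplit(sim$v4_alignment$aligned[t], "")[[1]]
    expect_identical(got, expected[master_cols],
                     info = tree$tip.label[t])
    expect_identical(sim$truth$tip_types[[tree$tip.label[t]]],
                     if (present) "TYPE_II" else "TYPE_I")
  }
})

test_that("full compensation keeps every stem duo pairable at every tip", {
  sim <- simulate_v4(sim_config(n_taxa = 10, sub_rate = 0.3, flank_len = 50,
                                stem_comp_fraction = 1,
                                helix_block_indel_rate = 0, seed = 77))
  pc <- sim$truth$pair_columns
  for (row in sim$v4_alignment$aligned) {
    chars <- strsplit(row, "")[[1]]
    duos <- paste0(chars[pc[, 1]], chars[pc[, 2]])
    expect_true(all(duos %in% c("GC", "CG", "AU", "UA", "GU", "UG")))
  }
})

test_that("contradictory configurations are rejected", {
  expect_error(sim_config(n_taxa = 4, sub_rate = 0.1), "seed")
  tree <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  expect_error(simulate_v4(sim_config(tree = tree, seed = 1,
                                      cbc_plant = c(zz = 1))), "absent")
  expect_error(simulate_v4(sim_config(tree = tree, seed = 1,
                                      force_toggles = list("zz"))), "absent")
})

test_that("the packaged fixture is stable and matches its planted truth", {
  fx <- fixture_mini_cohort()
  expect_equal(nrow(fx$sequences), 12)
  expect_identical(fx$truth$tip_types, fx$planted$tip_types)
  expect_identical(fixture_mini_cohort()$sequences, fx$sequences)
  # planted events are the complete structural history
  ev <- fx$truth$events
  expect_equal(sum(ev$event == "block_ins"), 1)
  expect_equal(sum(ev$event == "block_del"), 2)
  expect_equal(sum(ev$event == "cbc_plant"), 1)
})
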