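test_that("helix decomposition finds stacked runs and multiloops", {
  f <- find_helices(parse_dotbracket("(((...)))"))
  expect_length(f$helices, 1)
  expect_equal(nrow(f$helices[[1]]$pairs), 3)

  f <- find_helices(parse_dotbracket("((..((...))..((...))..))"))
  expect_length(f$helices, 3)
  expect_length(f$roots, 1)
  expect_length(f$helices[[f$roots]]$children, 2)
})

test_that("helices partition the pair set exactly", {
  set.seed(83)
  for (i in 1:100) {
    st <- parse_dotbracket(random_dotbracket(sample(20:80, 1)))
    f <- find_helices(st)
    got <- do.call(rbind, lapply(f$helices, `[[`, "pairs"))
    if (is.null(got)) got <- matrix(integer(0), ncol = 2)
    expect_equal(nrow(got), nrow(st$pairs))
    key <- function(m) sort(paste(m[, 1], m[, 2]))
    expect_identical(key(got), key(st$pairs))
  }
})

test_that("stem grouping respects the bulge tolerance", {
  st <- parse_dotbracket("(((..(((...))))))")
  f <- find_helices(st)
  expect_length(group_stems(f, bulge_tol = 2)$stems, 1)
  expect_length(group_stems(f, bulge_tol = 1)$stems, 2)
  # multiloops always break stems, whatever the tolerance
  st2 <- parse_dotbracket("((((...))((...))))")
  expect_length(group_stems(find_helices(st2), bulge_tol = 10)$stems, 3)
})

test_that("hairpin sizes count enclosed unpaired residues", {
  sizes <- function(db) {
    stems <- group_stems(find_helices(parse_dotbracket(db)))
    vapply(stems$stems, hairpin_size, integer(1), forest = stems)
  }
  expect_equal(sizes("((...))"), 3L)
  expect_equal(sizes("(((....)))"), 4L)
  ml <- group_stems(find_helices(parse_dotbracket("((..((...))..((...))..))")))
  expect_error(hairpin_size(ml$stems[[1]], ml), "not a hairpin")
})

test_that("E23_8 is the largest top-level stem, ties 3'-most", {
  db <- "((...))..(((((.....)))))..((...))"
  stems <- label_e23(group_stems(find_helices(parse_dotbracket(db))))
  expect_equal(stems$stems[[stems$e23_8]]$n_pairs, 5)
  # tie between two 3-pair stems: the 3'-most wins
  db2 <- "(((...)))..(((...)))"
  stems2 <- label_e23(group_stems(find_helices(parse_dotbracket(db2))))
  expect_equal(stems2$stems[[stems2$e23_8]]$outer[[1]], 12)
  # single-stem structure: it is E23_8
  db3 <- "(((...)))"
  stems3 <- label_e23(group_stems(find_helices(parse_dotbracket(db3))))
  expect_equal(stems3$e23_8, 1L)
  # the "last" rule picks the 3'-most regardless of size
  stems4 <- label_e23(group_stems(find_helices(parse_dotbracket(db))), rule = "last")
  expect_equal(stems4$stems[[stems4$e23_8]]$n_pairs, 2)
})

test_that("classification separates terminal hairpins from distal multiloops", {
  t2 <- classify_v4(parse_dotbracket("((((((....((...))..((...))..))))))"))
  expect_equal(t2$struct_type, "TYPE_II")
  expect_equal(t2$n_distal_subhelices, 2)

  t1 <- classify_v4(parse_dotbracket(
    paste0("((((((", strrep(".", 21), "))))))")))
  expect_equal(t1$struct_type, "TYPE_I")
  expect_equal(t1$terminal_hairpin_size, 21)

  expect_equal(classify_v4(parse_dotbracket("......"))$struct_type,
               "UNCLASSIFIED")
})

test_that("classification is invariant to unpaired padding outside E23_8", {
  core <- "((((((....((...))..((...))..))))))"
  base <- classify_v4(parse_dotbracket(core))
  padded <- classify_v4(parse_dotbracket(paste0("....", core, "......")))
  expect_equal(padded$struct_type, base$struct_type)
  expect_equal(padded$n_distal_subhelices, base$n_distal_subhelices)
})

test_that("the designed templates classify to their planted types", {
  tpl <- v4_template()
  r1 <- classify_v4(fold_mfe(tpl$type1_seq, id = "t1"))
  expect_equal(r1$struct_type, "TYPE_I")
  expect_equal(r1$terminal_hairpin_size, 21)
  expect_equal(r1$n_top_stems, 4)
  r2 <- classify_v4(fold_mfe(tpl$master_seq, id = "t2"))
  expect_equal(r2$struct_type, "TYPE_II")
  expect_equal(r2$n_distal_subhelices, 2)
  # the E23_11/E23_12 labels land on the two distal children of E23_8
  st <- parse_dotbracket(tpl$master_db, tpl$master_seq)
  expect_equal(classify_v4(st)$struct_type, "TYPE_II")
})

test_that("type recovery is exact on a mutation-free planted cohort", {
  for (root in c("TYPE_I", "TYPE_II")) {
    sim <- simulate_v4(sim_config(n_taxa = 5, sub_rate = 0, flank_len = 50,
                                  flank_mut = 0, helix_block_indel_rate = 0,
                                  root_type = root, seed = 211))
    hits <- extract_v4(sim$sequences, sim_anchor_profile(sim))
    types <- vapply(seq_len(nrow(hits)), function(r) {
      classify_v4(fold_mfe(hits$v4[r], id = hits$id[r]))$struct_type
    }, character(1))
    expect_true(all(types == root))
  }
})

test_that("lone pairs are dropped and longer helices kept", {
  st <- parse_dotbracket("((((...))))..(.....).", id = "x")
  out <- drop_lone_pairs(st)
  expect_equal(nrow(out$pairs), 4)
  expect_true(all(out$pairs[, 1] <= 4))
  # rescoring against the residues
  seq <- "GGGGAAACCCCAAGAAAAACA"
  out2 <- drop_lone_pairs(parse_dotbracket("((((...))))..(.....).", seq, id = "x"),
                          params = fold_params(), residues = seq)
  expect_equal(out2$score, 12)
  # min_helix = 1 is the identity
  expect_identical(drop_lone_pairs(st, min_helix = 1)$pairs, st$pairs)
})
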