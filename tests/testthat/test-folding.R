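test_that("sequences without complementary residues yield no pairs", {
  st <- fold_mfe("AAAAAA")
  expect_equal(nrow(st$pairs), 0)
  expect_equal(st$score, 0)
})

test_that("a perfect GC hairpin folds to the full stem", {
  st <- fold_mfe("GGGAAACCC")
  expect_equal(unname(st$pairs[, 1]), 1:3)
  expect_equal(unname(st$pairs[, 2]), c(9, 8, 7))
  expect_equal(st$score, 9)
  expect_equal(oracle_best_fold_score("GGGAAACCC"), 9)
})

test_that("DP score equals the exhaustive optimum on random short RNAs", {
  set.seed(31)
  for (i in 1:40) {
    s <- random_rna(sample(8:14, 1))
    expect_equal(fold_mfe(s)$score, oracle_best_fold_score(s), info = s)
  }
})

test_that("short sequences return an empty structure, not an error", {
  st <- fold_mfe("GCU")
  expect_equal(nrow(st$pairs), 0)
  expect_equal(st$score, 0)
})

test_that("N never pairs", {
  st <- fold_mfe("NNNAAANNN")
  expect_equal(nrow(st$pairs), 0)
})

test_that("folding is deterministic", {
  set.seed(59)
  for (i in 1:20) {
    s <- random_rna(40)
    expect_identical(render_dotbracket(fold_mfe(s)),
                     render_dotbracket(fold_mfe(s)))
  }
})

test_that("single-row consensus folding reduces to per-sequence folding", {
  s <- "GGCGCAAAAGCGCCAAAGGGAAACCC"
  aln <- tibble::tibble(id = "a", aligned = s)
  cons <- fold_consensus(aln)
  expect_equal(cons$structure$pairs, fold_mfe(s)$pairs,
               ignore_attr = TRUE)
})

test_that("covariant rows earn the covariance bonus", {
  aln <- tibble::tibble(id = c("a", "b"),
                        aligned = c("GGGAAACCC", "CCCAAAGGG"))
  cons <- fold_consensus(aln, fold_params(covariance_bonus = 1))
  expect_equal(unname(cons$structure$pairs[, 1]), 1:3)
  expect_equal(unname(cons$structure$pairs[, 2]), c(9, 8, 7))
  # each column pair: 3 + 3 per-row score, two distinct pair types -> +1
  expect_equal(cons$stats$score, rep(7, 3))
  expect_equal(cons$stats$n_pair_types, rep(2, 3))
  expect_error(fold_consensus(tibble::tibble(id = character(0),
                                             aligned = character(0))))
})

test_that("gap rows are penalised as unable to pair", {
  aln <- tibble::tibble(id = c("a", "b"),
                        aligned = c("GGGAAACCC", "--GAAAC--"))
  cons <- fold_consensus(aln, fold_params(inconsistency_penalty = 0.5))
  inner <- cons$stats[cons$stats$k == 3, ]
  expect_equal(inner$n_inconsistent, 0)
  outer <- cons$stats[cons$stats$k %in% c(1, 2), ]
  if (nrow(outer)) expect_true(all(outer$n_inconsistent == 1))
})

test_that("projection maps column pairs through the gap pattern", {
  aln <- tibble::tibble(id = c("a", "b"),
                        aligned = c("GGGAAACCC", "G--AAAC--"))
  cons <- fold_consensus(aln)
  pa <- project_consensus(cons, "a")
  expect_equal(pa$pairs, cons$structure$pairs, ignore_attr = TRUE)
  pb <- project_consensus(cons, "b")
  # only the outermost column pair survives b's gaps, at ungapped coords
  expect_true(all(pb$pairs[, 1] >= 1 & pb$pairs[, 2] <= 5))
  expect_error(project_consensus(cons, "zz"), "not in alignment")
})

test_that("projection never produces crossing pairs on simulated cohorts", {
  for (seed in c(3, 14, 15)) {
    sim <- simulate_v4(sim_config(n_taxa = 8, flank_len = 50,
                                  sub_rate = 0.05, seed = seed))
    cons <- fold_consensus(sim$v4_alignment)
    for (id in sim$v4_alignment$id) {
      st <- project_consensus(cons, id)   # rna_structure() validates nesting
      expect_s3_class(st, "rna_structure")
    }
  }
})
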