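test_that("FASTA reading normalises residues and preserves order", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x", "acgt", ">y some description", "GGRRCC"), f)
  seqs <- suppressMessages(read_rna_fasta(f))
  expect_equal(seqs$id, c("x", "y"))
  expect_equal(seqs$residues[1], "ACGU")
  expect_equal(seqs$residues[2], "GGNNCC")
})

test_that("FASTA reading rejects duplicate ids and empty records", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x", "ACGU", ">x", "GGGG"), f)
  expect_error(read_rna_fasta(f), "duplicate.*x")
  writeLines(c(">x", "", ">y", "ACGU"), f)
  expect_error(suppressMessages(read_rna_fasta(f)), "empty")
})

test_that("write/read FASTA round-trips normalized records", {
  set.seed(11)
  seqs <- tibble::tibble(
    id = sprintf("s%03d", 1:100),
    residues = vapply(sample(1:200, 100, replace = TRUE), random_rna, character(1)),
    clade = NA_character_, source = "synthetic")
  f <- withr::local_tempfile(fileext = ".fasta")
  write_rna_fasta(seqs, f)
  back <- read_rna_fasta(f)
  expect_equal(back$id, seqs$id)
  expect_equal(back$residues, seqs$residues)
})

test_that("empty and single-residue FASTA writing are well-formed", {
  f <- withr::local_tempfile(fileext = ".fasta")
  write_rna_fasta(tibble::tibble(id = character(0), residues = character(0)), f)
  expect_identical(readLines(f), character(0))
  write_rna_fasta(tibble::tibble(id = "a", residues = "G"), f)
  expect_identical(readLines(f), c(">a", "G"))
})

test_that("Newick reading keeps topology, including root trifurcations", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((a,b),c);", f)
  tr <- read_newick(f)
  expect_equal(ape::Ntip(tr), 3)
  expect_equal(tr$Nnode, 2)
  writeLines("(a,b,c);", f)
  tr <- read_newick(f)
  expect_equal(tr$Nnode, 1)  # trifurcation preserved
  writeLines("((a,b,c);", f)
  expect_error(read_newick(f))
})

test_that("Newick round-trips random tree topologies", {
  set.seed(7)
  f <- withr::local_tempfile(fileext = ".nwk")
  for (i in 1:50) {
    tr <- ape::rtree(sample(4:40, 1))
    write_newick(tr, f)
    back <- read_newick(f)
    expect_true(ape::all.equal.phylo(tr, back, use.edge.length = FALSE))
  }
})

test_that("dot-bracket parsing matches brackets and flags imbalance", {
  st <- parse_dotbracket("(((...)))", "GGGAAACCC")
  expect_equal(unname(st$pairs[, 1]), 1:3)
  expect_equal(unname(st$pairs[, 2]), c(9, 8, 7))
  expect_equal(nrow(parse_dotbracket(".........")$pairs), 0)
  expect_error(parse_dotbracket("((...)"), "column 1")
  expect_error(parse_dotbracket("(...))"), "column 6")
  expect_error(parse_dotbracket("(...)", "GGGGGG"), "length")
})

test_that("parse and render are mutual inverses on random structures", {
  set.seed(23)
  for (i in 1:200) {
    db <- random_dotbracket(sample(10:60, 1))
    expect_identical(render_dotbracket(parse_dotbracket(db)), db)
  }
})

test_that("Vienna files round-trip and CT files read symmetrically", {
  f <- withr::local_tempfile(fileext = ".vienna")
  st <- parse_dotbracket("((((...))))", "GGGGAAACCCC", id = "v1")
  write_vienna(st, "GGGGAAACCCC", f)
  back <- read_vienna(f)
  expect_equal(back$id, "v1")
  expect_equal(back$residues, "GGGGAAACCCC")
  expect_equal(back$structure$pairs, st$pairs)

  ct <- withr::local_tempfile(fileext = ".ct")
  writeLines(c("7 hairpin",
               "1 G 0 2 7 1", "2 G 1 3 6 2", "3 A 2 4 0 3", "4 A 3 5 0 4",
               "5 A 4 6 0 5", "6 C 5 7 2 6", "7 C 6 8 1 7"), ct)
  got <- read_ct(ct)
  expect_equal(unname(got$structure$pairs[, 1]), 1:2)
  expect_equal(unname(got$structure$pairs[, 2]), c(7, 6))
})
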