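test_that("FASTA records parse, normalize and validate", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">pk1", "GGGGAAAACCCCUUUU", ">x", "acgt"), f)
  sq <- read_fasta(f)
  expect_equal(sq$id, c("pk1", "x"))
  expect_equal(sq$length, c(16L, 4L))
  expect_equal(sq$residues[2], "ACGU")  # lowercase uppercased, T -> U

  writeLines(c(">x", "ACGX"), f)
  expect_error(read_fasta(f), "position 4", class = "knotfold_validation_error")
  writeLines(c(">x", "ACGN"), f)
  expect_error(read_fasta(f), "invalid residue 'N'")
  writeLines(c("ACGU", ">x", "ACGU"), f)
  expect_error(read_fasta(f), "line 1")
  writeLines(c(">multi", "GGGG", "aaaa", "CCCC"), f)
  expect_equal(read_fasta(f)$residues, "GGGGAAAACCCC")
})

test_that("dot-bracket rendering uses greedy first-fit layers", {
  expect_equal(pairs_to_dotbracket(NULL, 4), "....")
  expect_equal(pairs_to_dotbracket(cbind(c(1, 2, 3), c(10, 9, 8)), 10),
               "(((....)))")
  pk <- cbind(c(1, 2, 3, 4, 5, 6, 7, 8), c(12, 11, 10, 9, 16, 15, 14, 13))
  expect_equal(pairs_to_dotbracket(pk, 16), "(((([[[[))))]]]]")
  # five mutually crossing pairs exceed the 4-layer capacity
  deep <- cbind(1:5, 10:14)
  expect_error(pairs_to_dotbracket(deep, 14), "4 bracket layers")
})

test_that("dot-bracket round-trips and always has length n", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(6:24, 1)
    fold <- predict_structure(random_rna(n))
    db <- fold$dotbracket
    expect_equal(nchar(db), n)
    expect_equal(dotbracket_to_pairs(db), fold$structure$pairs)
  }
})

test_that("CT output follows the column convention and round-trips", {
  f <- withr::local_tempfile(fileext = ".ct")
  write_ct(NULL, "ACGU", f, id = "bare")
  lines <- readLines(f)
  expect_length(lines, 5)
  expect_match(lines[1], "^4 bare$")
  fields <- strsplit(lines[-1], " ")
  expect_true(all(vapply(fields, `[[`, character(1), 5) == "0"))

  pm <- cbind(c(1, 2, 3), c(10, 9, 8))
  write_ct(pm, "GGGAAAACCC", f, id = "hp")
  lines <- readLines(f)
  expect_equal(strsplit(lines[2], " ")[[1]][5], "10")  # partner of pair (1,10)
  back <- read_ct(f)
  expect_equal(back$residues, "GGGAAAACCC")
  expect_equal(unname(back$pairs), unname(pm))
  expect_equal(back$id, "hp")
})

test_that("pair matrices reject overlapping or inverted pairs", {
  expect_error(pairs_to_dotbracket(cbind(5, 2), 6), "i < j")
  expect_error(pairs_to_dotbracket(cbind(c(1, 1), c(5, 6)), 6), "disjoint")
  expect_error(pairs_to_dotbracket(cbind(1, 9), 6), "exceeds")
})
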