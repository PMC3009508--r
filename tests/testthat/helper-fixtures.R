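# Shared helpers for the test suite.  Everything is generated in code.

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# Exhaustive enumeration of nested structures by direct recursion (no
# memoization): independent cross-check for the Nussinov oracle at tiny n.
nested_enum_max <- function(seq, scorer = pair_scorer()) {
  b <- strsplit(toupper(seq), "")[[1]]
  S <- knotfold:::score_matrix(scorer, paste(b, collapse = ""))
  rec <- function(i, j) {
    if (j <= i) return(0)
    best <- rec(i + 1L, j)                # i unpaired
    for (jp in (i + 1L):j) {
      if (is.finite(S[i, jp]))            # i pairs jp
        best <- max(best, S[i, jp] + rec(i + 1L, jp - 1L) + rec(jp + 1L, j))
    }
    best
  }
  rec(1L, length(b))
}

# Structure validity: disjoint pairs, allowed classes, min-loop respected.
expect_valid_structure <- function(struct, residues, scorer = pair_scorer()) {
  pm <- struct$pairs
  expect_true(anyDuplicated(c(pm)) == 0)
  if (nrow(pm)) {
    b <- strsplit(residues, "")[[1]]
    cls <- paste0(pmin(b[pm[, 1]], b[pm[, 2]]), pmax(b[pm[, 1]], b[pm[, 2]]))
    expect_true(all(cls %in% names(scorer$weights)))
    expect_true(all(pm[, 2] - pm[, 1] > scorer$min_loop))
  }
  invisible(struct)
}
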