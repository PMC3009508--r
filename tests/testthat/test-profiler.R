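test_that("operation counts match an independent closed-form summation", {
  # Expected counts derived by direct summation over the cell enumeration,
  # written independently of the fill's own counters.
  expected_ops <- function(n, gap_gap = TRUE) {
    ops <- c(VX = 0, WX = 0, WHX = 0, VHX = 0, ZHX = 0, YHX = 0)
    for (d in 1:(n - 1)) for (i in seq_len(n - d)) {
      j <- i + d
      ops["VX"] <- ops["VX"] + 1
      pk_cnt <- 0
      if (d >= 3) for (a in i:(j - 3)) for (b in (a + 2):(j - 1))
        pk_cnt <- pk_cnt + (j - b)
      ops["WX"] <- ops["WX"] + 3 + (j - i) + pk_cnt
      if (d >= 2) for (hole in 1:(d - 1)) for (k in i:(j - hole - 1)) {
        l <- k + hole + 1
        ops["WHX"] <- ops["WHX"] + 7 + 2 * (k - i) + 2 * (j - l) +
          if (gap_gap) (k - i + 1) * (j - l + 1) - 1 else 0
        ops["VHX"] <- ops["VHX"] + 1
        ops["ZHX"] <- ops["ZHX"] + 1
        ops["YHX"] <- ops["YHX"] + 1
      }
    }
    ops
  }
  set.seed(21)
  for (n in c(6, 9)) {
    s <- random_rna(n)
    for (gg in c(TRUE, FALSE)) {
      p <- profile_run(s, options = dp_options(gap_gap = gg))
      expect_equal(stats::setNames(p$ops, p$family), expected_ops(n, gg))
    }
  }
})

test_that("the WHX family dominates the operation count", {
  set.seed(22)
  p <- profile_run(random_rna(10))
  shares <- stats::setNames(p$share, p$family)
  expect_true(all(shares["WHX"] > shares[names(shares) != "WHX"]))
  expect_equal(sum(p$share), 1, tolerance = 1e-9)
  expect_true(all(p$ops >= 0))
})

test_that("gap families count nothing when pseudoknots are off", {
  p <- profile_run("GGGGAAAACCCC", options = dp_options(pseudoknots = FALSE))
  gap <- p$ops[p$family %in% c("WHX", "VHX", "ZHX", "YHX")]
  expect_equal(unname(gap), rep(0, 4))
})

test_that("profiling is deterministic in the counts", {
  s <- fixture_sequences("random", n = 11, seed = 12)$residues
  p1 <- profile_run(s)
  p2 <- profile_run(s)
  expect_equal(p1$ops, p2$ops)
  expect_equal(p1$cells, p2$cells)
  expect_error(profile_run("ACG"), "n >= 4")
})

test_that("the WHX share grows with sequence length", {
  tr <- share_trend(c(8, 10, 12, 14))
  whx <- tr$share[tr$family == "WHX"]
  expect_equal(length(whx), 4)
  expect_true(all(diff(whx) >= 0))
  one <- share_trend(10)
  expect_equal(unique(one$n), 10L)
  off <- share_trend(c(8, 10), options = dp_options(pseudoknots = FALSE))
  expect_equal(unique(off$share[off$family == "WHX"]), 0)
})
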