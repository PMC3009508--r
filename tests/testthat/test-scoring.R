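test_that("elementary pair scores follow class, weight and min-loop rules", {
  sc <- pair_scorer()
  expect_equal(pair_score(sc, "G", "C", 1, 10), 1)
  expect_equal(pair_score(sc, "G", "U", 1, 9), 1)    # wobble on by default
  expect_identical(pair_score(sc, "A", "U", 3, 6), -Inf)  # j - i = 3, not > h
  expect_equal(pair_score(sc, "A", "U", 3, 7), 1)
  expect_identical(pair_score(sc, "A", "G", 1, 11), -Inf) # not an allowed class

  up <- pair_scorer(weights = c(AU = 1, CG = 3, GU = 0.5))
  expect_equal(pair_score(up, "C", "G", 1, 8), 3)
  expect_equal(pair_score(up, "U", "G", 1, 8), 0.5)

  nog <- pair_scorer(allowed_pairs = c("AU", "CG"))
  expect_identical(pair_score(nog, "G", "U", 1, 9), -Inf)

  h0 <- pair_scorer(min_loop = 0)
  expect_equal(pair_score(h0, "A", "U", 1, 2), 1)
})

test_that("pair score is symmetric in the two bases", {
  sc <- pair_scorer(weights = c(AU = 2, CG = 1, GU = 0.25))
  bases <- c("A", "C", "G", "U")
  for (a in bases) for (b in bases)
    expect_identical(pair_score(sc, a, b, 1, 10), pair_score(sc, b, a, 1, 10))
})

test_that("scorer constructor rejects bad input", {
  expect_error(pair_scorer(allowed_pairs = c("AU", "UA")), "duplicated")
  expect_error(pair_scorer(allowed_pairs = "AX"), "two bases")
  expect_error(pair_scorer(weights = -1), "positive")
  expect_error(pair_scorer(min_loop = -2), ">= 0")
  expect_error(pair_scorer(weights = c(AU = 1, CG = 1)),
               "cover exactly")
})

test_that("raising the min-loop separation never raises the optimum", {
  set.seed(301)
  for (rep in 1:8) {
    n <- sample(6:14, 1)
    s <- random_rna(n)
    scores <- vapply(c(0L, 3L, 5L), function(h) {
      st <- fill_dp(s, pair_scorer(min_loop = h))
      wx_value(st, 1, n)
    }, numeric(1))
    expect_true(all(diff(scores) <= 0))
  }
})
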