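# Reference sequences used throughout: a hairpin whose nested optimum is 3,
# and the 16-mer whose unique optimum is an H-type pseudoknot of 8 pairs.
HAIRPIN <- "GGGAAAACCC"
PK16 <- "GGGGAAAACCCCUUUU"

test_that("vx cells assert the closing pair", {
  st <- fill_dp(HAIRPIN)
  expect_equal(vx_value(st, 1, 10), 3)           # delta + wx(2, 9) = 1 + 2
  expect_equal(wx_value(st, 2, 9), 2)
  st2 <- fill_dp("AAAA")
  expect_identical(vx_value(st2, 1, 4), -Inf)    # A-A cannot pair
  expect_identical(vx_value(st, 3, 6), -Inf)     # j - i <= h
})

test_that("wx cells take the best of all scenarios", {
  st <- fill_dp("AAAAAAAA")
  expect_equal(wx_value(st, 1, 8), 0)
  expect_equal(wx_value(fill_dp(HAIRPIN), 1, 10), 3)
  expect_equal(wx_value(fill_dp(PK16), 1, 16), 8)  # the n/2 bound, attained
})

test_that("pseudoknot composition pairs two interleaving gapped pieces", {
  st <- fill_dp(PK16)
  expect_equal(pk_compose(st, 1, 16), 8)
  expect_equal(whx_value(st, 1, 12, 4, 9) + whx_value(st, 5, 16, 8, 13), 8)
  expect_identical(pk_compose(st, 3, 5), -Inf)   # no admissible (a, b, c)
  sth <- fill_dp(HAIRPIN)
  expect_lte(pk_compose(sth, 1, 10), 3)          # never beats the nested optimum
})

test_that("gap closures score the hole-flanking and outer pairs", {
  st <- fill_dp(PK16)
  gc <- gap_closures(st, 1, 12, 4, 9)
  expect_equal(gc$vhx, 1 + 1 + whx_value(st, 2, 11, 3, 10))
  expect_equal(gc$vhx, 4)
  # forced by the empty-segment conventions
  expect_equal(gap_closures(st, 4, 9, 4, 9)$yhx, 1)
  # unpairable outer ends propagate the forbidden score
  expect_identical(gap_closures(st, 5, 8, 5, 7)$zhx, -Inf)
})

test_that("whx cells honor the boundary conventions and the oracle values", {
  st <- fill_dp(PK16)
  for (k in c(3, 7, 10))   # empty hole collapses to wx over the full interval
    expect_equal(whx_value(st, 2, 14, k, k + 1), wx_value(st, 2, 14))
  expect_equal(whx_value(st, 1, 12, 0, 5), wx_value(st, 5, 12))  # left empty
  expect_equal(whx_value(st, 1, 12, 4, 13), wx_value(st, 1, 4))  # right empty
  expect_equal(whx_value(st, 1, 12, 4, 9), 4)   # four G-C pairs span the hole
  expect_equal(whx_value(st, 5, 16, 8, 13), 4)  # four A-U pairs span the hole
})

test_that("degenerate and guarded inputs are handled", {
  st <- fill_dp("A")
  expect_equal(wx_value(st, 1, 1), 0)
  expect_null(st$whx)  # no gap cells exist for a single residue
  expect_error(fill_dp(strrep("A", 61)), "O\\(n\\^6\\)")
  expect_equal(wx_value(fill_dp(strrep("A", 61),
                                options = dp_options(max_n = 61)), 1, 61), 0)
})

test_that("the fill only ever reads written cells, in Table-ledger channels", {
  set.seed(77)
  st <- fill_dp(random_rna(12), options = dp_options(audit = TRUE))
  log <- audit_log(st)
  expect_gt(nrow(log), 1000)
  expect_equal(sum(log$n_unwritten), 0)  # zero read-before-write violations
  sanctioned <- list(
    VX = "WX",                  # interior region (the WBX alias of WX)
    WX = c("VX", "WX", "WHX"),  # trims, bifurcation, pseudoknot composition
    WHX = c("WX", "WHX"),
    VHX = "WHX", ZHX = "WHX", YHX = "WHX")
  reads <- unique(log[log$op == "read", c("ctx", "target")])
  for (r in seq_len(nrow(reads)))
    expect_true(reads$target[r] %in% sanctioned[[reads$ctx[r]]],
                label = paste(reads$ctx[r], "->", reads$target[r]))
})

test_that("dependencies are non-serial and polyadic (reads reach back >= 2 spans)", {
  set.seed(78)
  st <- fill_dp(random_rna(10), options = dp_options(audit = TRUE))
  log <- audit_log(st)
  rr <- log[log$op == "read" & log$target == "WHX" & !is.na(log$ctx_i), ]
  span_delta <- (rr$ctx_j - rr$ctx_i) - (rr$tj - rr$ti)
  expect_true(any(span_delta >= 2))
})

test_that("traceback recovers an optimal structure deterministically", {
  expect_equal(nrow(predict_structure("AAAA")$structure$pairs), 0)
  hp <- predict_structure(HAIRPIN)
  expect_equal(unname(hp$structure$pairs), cbind(c(1, 2, 3), c(10, 9, 8)))
  expect_equal(hp$dotbracket, "(((....)))")
  pk <- predict_structure(PK16)
  expect_equal(nrow(pk$structure$pairs), 8)
  expect_equal(pk$dotbracket, "(((([[[[))))]]]]")
  # self-consistency on a random batch: traceback score equals the optimum,
  # and the structure is always valid
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(5:16, 1)
    s <- random_rna(n)
    fold <- predict_structure(s)
    expect_valid_structure(fold$structure, s)
    expect_equal(nrow(fold$structure$pairs), fold$score)  # unit weights
  }
})

test_that("prediction without pseudoknots reduces to the nested optimum", {
  off <- predict_structure(PK16, options = dp_options(pseudoknots = FALSE))
  expect_equal(off$score, 4)
  expect_equal(max(off$structure$layers), 1)  # nested: a single bracket layer
  expect_equal(predict_structure("AAAAAAAA")$score, 0)
})

test_that("wx agrees with the independent oracles on random sequences", {
  set.seed(90)
  for (rep in 1:25) {
    n <- sample(4:24, 1)
    s <- random_rna(n)
    off <- fill_dp(s, options = dp_options(pseudoknots = FALSE))
    expect_equal(wx_value(off, 1, n), nussinov_max_pairs(s), label = s)
  }
  for (rep in 1:10) {
    n <- sample(4:10, 1)
    s <- random_rna(n)
    st <- fill_dp(s)
    expect_equal(wx_value(st, 1, n), enumerate_grammar_max(s), label = s)
  }
})

test_that("table invariants hold on a filled random state", {
  set.seed(91)
  s <- random_rna(14)
  st <- fill_dp(s)
  n <- st$n
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    wij <- wx_value(st, i, j)
    vij <- vx_value(st, i, j)
    if (is.finite(vij)) expect_lte(vij, wij)
    expect_gte(wij, 0)
    expect_lte(wij, floor((j - i + 1) / 2))       # unit weights
    if (i > 1) expect_lte(wij, wx_value(st, i - 1, j))  # interval monotone
    if (j < n) expect_lte(wij, wx_value(st, i, j + 1))
  }
  expect_gte(wx_value(st, 1, n),
             wx_value(fill_dp(s, options = dp_options(pseudoknots = FALSE)),
                      1, n))
})
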