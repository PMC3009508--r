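test_that("a whx cell decomposes into six independent blocks", {
  b <- decompose_blocks(c(2, 14, 5, 9))
  expect_equal(b$block_id, paste0("B", 1:6))
  expect_equal(b$size[b$block_id == "B1"], 0L)   # loop-free
  expect_equal(b$size[b$block_id == "B2"], 3L)   # r in i..k-1
  expect_equal(b$size[b$block_id == "B4"], 5L)   # r in l+1..j
  expect_equal(b$size[b$block_id == "B6"], 4L * 6L)
  # no split room in the left segment
  b0 <- decompose_blocks(c(2, 14, 2, 9))
  expect_equal(b0$size[b0$block_id %in% c("B2", "B3")], c(0L, 0L))
  expect_equal(nrow(decompose_blocks(c(2, 14, 5, 9), gap_gap = FALSE)), 5)
})

test_that("the threshold scheduler follows the five-iterations/two-workers rule", {
  expect_equal(schedule_iterations(9)$mode, "serial")
  d10 <- schedule_iterations(10)
  expect_equal(d10$mode, "parallel")
  expect_equal(d10$chunks$size, c(5L, 5L))
  d30 <- schedule_iterations(30)
  expect_equal(d30$chunks$size, rep(5L, 6))      # full six-worker utilization
  expect_equal(schedule_iterations(32)$chunks$size, c(6L, 6L, 5L, 5L, 5L, 5L))
  expect_equal(schedule_iterations(0)$mode, "serial")
  expect_error(schedule_iterations(30, workers = 0), ">= 1")
  # purity: same inputs, same decision
  expect_identical(schedule_iterations(47, 4, 7, 3),
                   schedule_iterations(47, 4, 7, 3))
  # every chunk meets the per-worker minimum and chunks partition the range
  d <- schedule_iterations(53)
  expect_true(all(d$chunks$size >= 5))
  expect_equal(d$chunks$from[1], 1L)
  expect_equal(d$chunks$to[nrow(d$chunks)], 53L)
  expect_true(all(d$chunks$from[-1] == head(d$chunks$to, -1) + 1L))
})

test_that("worker pools start, serve and shut down cleanly", {
  pool <- worker_pool(4)
  counts <- pool_stop(pool)
  expect_equal(counts$tasks, rep(1L, 4))   # shutdown message only
  expect_false(pool$started)
  # a 30-iteration block over 6 workers: exactly one 5-iteration chunk each
  st <- fill_dp("GGGGGGGAAAACCCCCCC")
  cell <- c(1L, 18L, 5L, 13L)
  expect_equal(decompose_blocks(cell)$size[6], 30L)
  dec <- schedule_iterations(30)
  pool <- worker_pool(6)
  replies <- purrr::map_dbl(seq_len(nrow(dec$chunks)), function(w) {
    msg <- knotfold:::make_task(pool, st, cell, "B6",
                                dec$chunks$from[w], dec$chunks$to[w])
    knotfold:::pool_submit(pool, w, msg)$max
  })
  tasks <- pool_stop(pool)
  expect_equal(tasks$tasks, rep(2L, 6))    # one compute + one shutdown
  full <- max(knotfold:::block_candidates(st, 1L, 18L, 5L, 13L, "B6"))
  expect_equal(max(replies), full)
  expect_error(worker_pool(0), "startup")
})

test_that("all engines produce identical tables, scores and tracebacks", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(6:14, 1)
    s <- random_rna(n)
    ref <- fill_dp(s)
    ref_db <- predict_structure(s)$dotbracket
    for (mk in list(engine_cpar, engine_dpar, engine_hpar)) {
      for (w in c(1L, 2L, 6L)) {
        st <- fill_dp(s, engine = mk(w))
        expect_identical(st$wx, ref$wx)
        expect_identical(st$whx, ref$whx)
        expect_identical(predict_structure(s, engine = mk(w))$dotbracket,
                         ref_db)
      }
    }
  }
})

test_that("chunk boundaries never change a block's maximum", {
  set.seed(43)
  s <- random_rna(14)
  st <- fill_dp(s)
  cell <- c(2L, 13L, 4L, 8L)
  blocks <- decompose_blocks(cell)
  for (bid in c("B2", "B4", "B6")) {
    sz <- blocks$size[blocks$block_id == bid]  # iteration-space size
    full <- knotfold:::block_candidates(st, cell[1], cell[2], cell[3],
                                        cell[4], bid, 1L, sz)
    for (rep in 1:5) {
      cuts <- sort(unique(c(0L, sample(sz - 1, sample(0:(sz - 1), 1)), sz)))
      parts <- purrr::map_dbl(seq_len(length(cuts) - 1), function(q) {
        v <- knotfold:::block_candidates(st, cell[1], cell[2], cell[3],
                                         cell[4], bid,
                                         cuts[q] + 1L, cuts[q + 1L])
        if (length(v)) max(v) else -Inf
      })
      expect_equal(max(parts), max(full))
    }
  }
  # the same through whole engines with odd worker counts
  for (w in c(3L, 5L, 7L))
    expect_equal(whx_cell_score(st, cell, engine_dpar(w)),
                 whx_cell_score(st, cell))
})

test_that("packaged-value tasks equal snapshot tasks", {
  set.seed(44)
  s <- random_rna(12)
  ref <- fill_dp(s)
  for (mk in list(engine_cpar, engine_hpar)) {
    st <- fill_dp(s, engine = mk(6, payload = "package"))
    expect_identical(st$whx, ref$whx)
  }
})

test_that("the hybrid engine engages workers only above the threshold", {
  # below 10 iterations for every cell: everything stays with the coordinator
  s5 <- "GCGCA"
  st5 <- fill_dp(s5, pair_scorer(min_loop = 1), engine = engine_hpar())
  sm <- sched_summary(st5)
  expect_equal(sm$cells[sm$mode == "parallel"], 0L)
  # a longer sequence mixes both modes, and the split is reproducible
  s <- fixture_sequences("random", n = 16, seed = 9)$residues
  a <- sched_summary(fill_dp(s, engine = engine_hpar()))
  b <- sched_summary(fill_dp(s, engine = engine_hpar()))
  expect_identical(a, b)
  expect_gt(a$cells[a$mode == "parallel"], 0L)
  expect_gt(a$cells[a$mode == "serial"], 0L)
  # raising min_iters pushes cells back to the coordinator
  c6 <- sched_summary(fill_dp(s, engine = engine_hpar(min_iters = 50L)))
  expect_equal(c6$cells[c6$mode == "parallel"], 0L)
})
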