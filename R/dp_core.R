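#' Dynamic-programming options
#'
#' @param pseudoknots logical; fill the four one-hole gap matrices and allow
#'   the crossing (pseudoknot) composition in WX.  When `FALSE` only the
#'   nested VX/WX recursion runs.
#' @param gap_gap logical; include the gap-gap work block (B6) in the WHX
#'   recursion.  B6 is what raises the fill to O(n^6) time; switching it off
#'   restricts the structure class but keeps all other blocks.
#' @param max_n refuse sequences longer than this (the fill is O(n^6) time
#'   and O(n^4) space; 60 is a desk-scale ceiling).
#' @param audit record an ordered log of every table read and write during
#'   the fill, including read-before-write violations and which matrix family
#'   read which.  Costly; intended for small `n`.
#' @param timing accumulate wall time per matrix family (used by the
#'   profiler; informative only).
#' @return a list of class `dp_options`.
#' @export
dp_options <- function(pseudoknots = TRUE, gap_gap = TRUE, max_n = 60L,
                       audit = FALSE, timing = FALSE) {
  structure(list(pseudoknots = isTRUE(pseudoknots),
                 gap_gap = isTRUE(gap_gap),
                 max_n = as.integer(max_n),
                 audit = isTRUE(audit),
                 timing = isTRUE(timing)),
            class = "dp_options")
}

FAMILIES <- c("VX", "WX", "WHX", "VHX", "ZHX", "YHX")

# ---------------------------------------------------------------------------
# DP state: an environment holding the triangular tables vx/wx, the one-hole
# gap table whx (vhx/zhx/yhx are evaluated on demand as thin closures over
# whx but are first-class families for auditing and profiling), operation
# counters, and the audit trail.  whx(i,j:k,l) scores the two-segment region
# [i,k] u [l,j]; the hole [k+1,l-1] is left for an interleaving partner.
# Storage uses index k+1 on the third axis so the boundary column k = i-1
# fits; the fourth axis runs to l = j+1 for the right-empty boundary.
# ---------------------------------------------------------------------------
new_dp_state <- function(seq, scorer, options, engine_name = "serial") {
  residues <- normalize_residues(seq)
  n <- nchar(residues)
  st <- new.env(parent = emptyenv())
  st$n <- n
  st$residues <- residues
  st$scorer <- scorer
  st$opts <- options
  st$S <- score_matrix(scorer, residues)
  # During the fill the tables live inside a closure so element writes are
  # in-place (a complex assignment on an env-stored array copies the whole
  # O(n^4) table on every write); they are materialized onto the state once
  # the fill seals.
  st$tbl <- make_tables(n, options$pseudoknots && n >= 2)
  st$wx <- NULL
  st$vx <- NULL
  st$whx <- NULL
  st$ops <- stats::setNames(numeric(6), FAMILIES)
  st$cells <- stats::setNames(numeric(6), FAMILIES)
  st$timers <- stats::setNames(numeric(6), FAMILIES)
  st$ctx <- "WX"
  st$ctx_cell <- c(NA_integer_, NA_integer_)
  st$closure_acc <- 0
  st$sealed <- FALSE
  st$engine_name <- engine_name
  st$sched <- new.env(parent = emptyenv())
  st$sched$serial <- 0L
  st$sched$parallel <- 0L
  if (options$audit) {
    st$aud <- new.env(parent = emptyenv())
    st$aud$rows <- vector("list", 256L)
    st$aud$cnt <- 0L
    st$aud$violations <- 0L
  }
  class(st) <- "dp_state"
  st
}

make_tables <- function(n, pk) {
  wx <- matrix(NA_real_, n, n)
  wx[lower.tri(wx, diag = FALSE)] <- 0  # empty/negative-width regions
  vx <- matrix(NA_real_, n, n)
  whx <- if (pk) array(NA_real_, dim = c(n, n, n + 1L, n + 1L)) else NULL
  list(wx_g = function(i, j) wx[cbind(i, j)],
       wx_s = function(i, j, v) wx[cbind(i, j)] <<- v,
       vx_g = function(i, j) vx[cbind(i, j)],
       vx_s = function(i, j, v) vx[cbind(i, j)] <<- v,
       whx_g = function(i, j, k, l) whx[cbind(i, j, k + 1L, l)],
       whx_s = function(i, j, k, l, v) whx[cbind(i, j, k + 1L, l)] <<- v,
       export = function() list(wx = wx, vx = vx, whx = whx))
}

# Materialize the closure-held tables onto the state (end of fill).
seal_state <- function(st) {
  ex <- st$tbl$export()
  st$wx <- ex$wx
  st$vx <- ex$vx
  st$whx <- ex$whx
  st$tbl <- NULL
  st$sealed <- TRUE
  invisible(st)
}

aud_push <- function(st, op, target, ti, tj, tk = NA_integer_, tl = NA_integer_,
                     n_cells = 1L, n_unwritten = 0L) {
  a <- st$aud
  a$cnt <- a$cnt + 1L
  if (a$cnt > length(a$rows)) a$rows <- c(a$rows, vector("list", length(a$rows)))
  a$rows[[a$cnt]] <- list(step = a$cnt, op = op, ctx = st$ctx,
                          ctx_i = st$ctx_cell[1], ctx_j = st$ctx_cell[2],
                          target = target,
                          ti = as.integer(ti[1]), tj = as.integer(tj[1]),
                          tk = as.integer(tk[1]), tl = as.integer(tl[1]),
                          n_cells = as.integer(n_cells),
                          n_unwritten = as.integer(n_unwritten))
  if (n_unwritten > 0L) a$violations <- a$violations + 1L
  invisible(NULL)
}

rd_wx <- function(st, i, j) {
  v <- if (is.null(st$tbl)) st$wx[cbind(i, j)] else st$tbl$wx_g(i, j)
  if (!st$sealed && st$opts$audit)
    aud_push(st, "read", "WX", i, j, n_cells = length(v),
             n_unwritten = sum(is.na(v)))
  v
}

rd_vx <- function(st, i, j) {
  v <- if (is.null(st$tbl)) st$vx[cbind(i, j)] else st$tbl$vx_g(i, j)
  if (!st$sealed && st$opts$audit)
    aud_push(st, "read", "VX", i, j, n_cells = length(v),
             n_unwritten = sum(is.na(v)))
  v
}

rd_whx <- function(st, i, j, k, l) {
  v <- if (is.null(st$tbl)) st$whx[cbind(i, j, k + 1L, l)]
       else st$tbl$whx_g(i, j, k, l)
  if (!st$sealed && st$opts$audit)
    aud_push(st, "read", "WHX", i, j, k, l, n_cells = length(v),
             n_unwritten = sum(is.na(v)))
  v
}

wr_wx <- function(st, i, j, v) {
  st$tbl$wx_s(i, j, v)
  if (!st$sealed && st$opts$audit)
    aud_push(st, "write", "WX", i, j, n_cells = length(v))
  invisible(NULL)
}

wr_vx <- function(st, i, j, v) {
  st$tbl$vx_s(i, j, v)
  if (!st$sealed && st$opts$audit)
    aud_push(st, "write", "VX", i, j, n_cells = length(v))
  invisible(NULL)
}

wr_whx <- function(st, i, j, k, l, v) {
  st$tbl$whx_s(i, j, k, l, v)
  if (!st$sealed && st$opts$audit)
    aud_push(st, "write", "WHX", i, j, k, l, n_cells = length(v))
  invisible(NULL)
}

# Unlogged raw wx read (used when the value is semantically a WHX boundary).
wx_raw <- function(st, i, j) {
  if (is.null(st$tbl)) st$wx[i, j] else st$tbl$wx_g(i, j)
}

# Convention-aware scalar lookup of whx(i,j:k,l):
#   k = i-1 (left segment empty)  -> wx(l, j), or 0 if also l = j+1
#   l = j+1 (right segment empty) -> wx(i, k)
#   l = k+1 (empty hole)          -> wx(i, j)
# Convention values ARE WHX values, so the audit logs them as WHX reads.
whx_lookup_int <- function(st, i, j, k, l) {
  if (k >= i && l <= j && l != k + 1L) return(rd_whx(st, i, j, k, l))
  v <- if (k < i) {
    if (l > j) 0 else wx_raw(st, l, j)
  } else if (l > j) {
    wx_raw(st, i, k)
  } else {
    wx_raw(st, i, j)
  }
  if (!st$sealed && st$opts$audit)
    aud_push(st, "read", "WHX", i, j, k, l, n_cells = 1L,
             n_unwritten = sum(is.na(v)))
  v
}

# --- gap closures: thin, named per-cell evaluations over whx ---------------
# zhx: the outer ends (i, j) pair; yhx: the hole-flanking ends (k, l) pair
# across the hole; vhx: both.  -Inf propagates when the pair is forbidden.
closure_enter <- function(st, fam) {
  if (!st$sealed) {
    st$ops[[fam]] <- st$ops[[fam]] + 1
    st$cells[[fam]] <- st$cells[[fam]] + 1
  }
}

closure_time <- function(st, fam, t0) {
  dt <- proc.time()[[3]] - t0
  st$timers[[fam]] <- st$timers[[fam]] + dt
  st$closure_acc <- st$closure_acc + dt
}

zhx_value_int <- function(st, i, j, k, l) {
  oc <- st$ctx; st$ctx <- "ZHX"; on.exit(st$ctx <- oc)
  closure_enter(st, "ZHX")
  if (st$opts$timing) { t0 <- proc.time()[[3]]; on.exit(closure_time(st, "ZHX", t0), add = TRUE) }
  st$S[i, j] + whx_lookup_int(st, i + 1L, j - 1L, k, l)
}

yhx_value_int <- function(st, i, j, k, l) {
  oc <- st$ctx; st$ctx <- "YHX"; on.exit(st$ctx <- oc)
  closure_enter(st, "YHX")
  if (st$opts$timing) { t0 <- proc.time()[[3]]; on.exit(closure_time(st, "YHX", t0), add = TRUE) }
  st$S[k, l] + whx_lookup_int(st, i, j, k - 1L, l + 1L)
}

vhx_value_int <- function(st, i, j, k, l) {
  oc <- st$ctx; st$ctx <- "VHX"; on.exit(st$ctx <- oc)
  closure_enter(st, "VHX")
  if (st$opts$timing) { t0 <- proc.time()[[3]]; on.exit(closure_time(st, "VHX", t0), add = TRUE) }
  # both end pairs need four distinct positions: k > i and l < j
  if (k <= i || l >= j) return(-Inf)
  st$S[i, j] + st$S[k, l] + whx_lookup_int(st, i + 1L, j - 1L, k - 1L, l + 1L)
}

#' Evaluate the gap-matrix closures of a cell
#'
#' For a filled state, returns the VHX, ZHX and YHX values of the gap cell
#' `(i, j : k, l)`: respectively both end pairs formed, only the outer ends
#' `(i, j)` paired, and only the hole-flanking ends `(k, l)` paired across
#' the hole.  `-Inf` marks a forbidden closing pair.
#'
#' @param state a filled `dp_state` from [fill_dp()] (pseudoknots enabled).
#' @param i,j,k,l 1-based indices with `i <= k < l <= j`.
#' @return a named list with elements `vhx`, `zhx`, `yhx`.
#' @export
gap_closures <- function(state, i, j, k, l) {
  stopifnot(inherits(state, "dp_state"), !is.null(state$whx),
            i <= k, k < l, l <= j)
  list(vhx = vhx_value_int(state, i, j, k, l),
       zhx = zhx_value_int(state, i, j, k, l),
       yhx = yhx_value_int(state, i, j, k, l))
}

# --- work blocks -----------------------------------------------------------

block_sizes_int <- function(i, j, k, l, gap_gap = TRUE) {
  s <- c(B1 = 0L, B2 = max(0L, k - i), B3 = max(0L, k - i),
         B4 = j - l, B5 = j - l,
         B6 = if (gap_gap) (k - i + 1L) * (j - l + 1L) else NA_integer_)
  s[!is.na(s)]
}

#' Decompose a WHX cell into its work blocks
#'
#' The WHX recursion of a cell splits into six mutually independent blocks:
#' B1 holds the loop-free alternatives (four hole/span trims plus the three
#' closures), B2-B5 are single loops splitting one segment against a WX
#' region, and B6 (the gap-gap block) is the doubly indexed split of the cell
#' into two gapped pieces.  Blocks share no data dependency, so they can be
#' evaluated in any order or concurrently and combined by max.
#'
#' @param cell integer vector `c(i, j, k, l)` of a valid gap cell
#'   (`i <= k < l - 1`, `l <= j`).
#' @param gap_gap include B6 (default `TRUE`); when `FALSE` only five blocks
#'   are returned.
#' @return a tibble with columns `block_id`, `i`, `j`, `k`, `l`, `from`,
#'   `to`, `size`; B1 has an empty iteration range.
#' @export
decompose_blocks <- function(cell, gap_gap = TRUE) {
  stopifnot(length(cell) == 4)
  i <- cell[1]; j <- cell[2]; k <- cell[3]; l <- cell[4]
  stopifnot(i <= k, k + 1L < l, l <= j)
  sz <- block_sizes_int(i, j, k, l, gap_gap)
  tibble::tibble(block_id = names(sz),
                 i = as.integer(i), j = as.integer(j),
                 k = as.integer(k), l = as.integer(l),
                 from = 1L,
                 to = as.integer(sz),
                 size = as.integer(sz))
}

# Candidate values of one block (or a contiguous chunk [from, to] of its
# iteration range).  Every loop block is an elementwise sum of two stored
# value vectors, which is what lets chunks be shipped to workers either as
# index ranges over a read-only snapshot or as packaged value vectors.
block_candidates <- function(st, i, j, k, l, block_id, from = 1L, to = NULL) {
  switch(block_id,
    B1 = c(whx_lookup_int(st, i + 1L, j, k, l),
           whx_lookup_int(st, i, j - 1L, k, l),
           whx_lookup_int(st, i, j, k - 1L, l),
           whx_lookup_int(st, i, j, k, l + 1L),
           zhx_value_int(st, i, j, k, l),
           yhx_value_int(st, i, j, k, l),
           vhx_value_int(st, i, j, k, l)),
    B2 = {
      sz <- max(0L, k - i); if (is.null(to)) to <- sz
      if (to < from) return(numeric(0))
      r <- (i:(k - 1L))[from:to]
      rd_wx(st, i, r) + rd_whx(st, r + 1L, j, k, l)
    },
    B3 = {
      sz <- max(0L, k - i); if (is.null(to)) to <- sz
      if (to < from) return(numeric(0))
      r <- (i:(k - 1L))[from:to]
      rd_whx(st, i, j, r, l) + rd_wx(st, r + 1L, k)
    },
    B4 = {
      sz <- j - l; if (is.null(to)) to <- sz
      if (to < from) return(numeric(0))
      r <- ((l + 1L):j)[from:to]
      rd_whx(st, i, r - 1L, k, l) + rd_wx(st, r, j)
    },
    B5 = {
      sz <- j - l; if (is.null(to)) to <- sz
      if (to < from) return(numeric(0))
      r <- (l:(j - 1L))[from:to]
      rd_wx(st, l, r) + rd_whx(st, i, j, k, r + 1L)
    },
    B6 = {
      w2 <- j - l + 1L
      sz <- (k - i + 1L) * w2; if (is.null(to)) to <- sz
      if (to < from) return(numeric(0))
      t <- from:to
      r <- i + (t - 1L) %/% w2
      s <- l + (t - 1L) %% w2
      keep <- !(r == i & s == j)  # identity split excluded before any read
      if (!any(keep)) return(numeric(0))
      r <- r[keep]; s <- s[keep]
      rd_whx(st, i, j, r - 1L, s + 1L) + rd_whx(st, r, s, k, l)
    },
    stop("unknown block id: ", block_id))
}

# Fill one WHX cell: decompose into blocks, let the engine evaluate them,
# combine by max.  Operation counts are a function of (n, options) only and
# are identical for every engine.
compute_whx_cell_int <- function(st, i, j, k, l, engine) {
  st$ctx <- "WHX"
  st$ctx_cell <- c(i, j)
  if (st$opts$timing) { t0 <- proc.time()[[3]]; st$closure_acc <- 0 }
  cell <- c(i, j, k, l)
  sz <- block_sizes_int(i, j, k, l, st$opts$gap_gap)
  st$cells[["WHX"]] <- st$cells[["WHX"]] + 1
  st$ops[["WHX"]] <- st$ops[["WHX"]] + 7 +
    sum(sz[c("B2", "B3", "B4", "B5")]) +
    if (st$opts$gap_gap) max(0L, sz[["B6"]] - 1L) else 0L
  val <- engine_eval(engine, st, cell, sz)
  st$ctx <- "WHX"
  wr_whx(st, i, j, k, l, val)
  if (st$opts$timing)
    st$timers[["WHX"]] <- st$timers[["WHX"]] +
      (proc.time()[[3]] - t0) - st$closure_acc
  val
}

# Crossing composition feeding WX: two interleaving gapped pieces, piece one
# on [i,a] u [b,c], piece two on [a+1,b-1] u [c+1,j]; each piece's hole is
# exactly the other's material.
pk_compose_int <- function(st, i, j) {
  best <- -Inf
  cnt <- 0L
  if (j - i >= 3L) {
    for (a in i:(j - 3L)) {
      for (b in (a + 2L):(j - 1L)) {
        cv <- b:(j - 1L)
        v <- rd_whx(st, i, cv, a, b) + rd_whx(st, a + 1L, j, b - 1L, cv + 1L)
        m <- max(v)
        if (m > best) best <- m
        cnt <- cnt + length(cv)
      }
    }
  }
  list(score = best, count = cnt)
}

#' Pseudoknot composition score of an interval
#'
#' The crossing alternative of WX(i, j): the best sum of two interleaving
#' gapped pieces `whx(i, c : a, b) + whx(a+1, j : b-1, c+1)` over all
#' admissible `(a, b, c)`.  Returns `-Inf` when no admissible split exists
#' (interval shorter than 4) or no piece scores.
#'
#' @param state a filled `dp_state` with pseudoknots enabled.
#' @param i,j 1-based interval bounds.
#' @return a numeric score.
#' @export
pk_compose <- function(state, i, j) {
  stopifnot(inherits(state, "dp_state"), !is.null(state$whx), i <= j)
  pk_compose_int(state, i, j)$score
}

# ---------------------------------------------------------------------------
# Fill driver.  Cell order (normative): outer span d = j - i ascending;
# within a span all (i, j); within one (i, j), gap cells by hole size
# descending (B1's k-1 / l+1 alternatives, the closures, and B6's outer
# factor all reference larger holes at the same (i, j)); vx before wx; wx
# last because its pseudoknot composition reads only smaller-span whx cells.
# ---------------------------------------------------------------------------

#' Fill all DP matrices for a sequence
#'
#' Runs the gap-matrix dynamic program: the triangular VX/WX tables and, with
#' pseudoknots enabled, the one-hole WHX gap table (VHX/ZHX/YHX are evaluated
#' per cell as closures over WHX).  The engine decides who evaluates the work
#' blocks of each WHX cell, never the order of cells, so every engine yields
#' bit-identical tables.
#'
#' @param seq a residue string (A/C/G/U; T tolerated and mapped to U).
#' @param scorer a [pair_scorer()].
#' @param options a [dp_options()].
#' @param engine an execution engine, e.g. [engine_serial()] or
#'   [engine_hpar()].
#' @return a `dp_state` whose `wx[1, n]` holds the optimal score.
#' @examples
#' st <- fill_dp("GGGAAAACCC")
#' wx_value(st, 1, 10)  # 3
#' @export
fill_dp <- function(seq, scorer = pair_scorer(), options = dp_options(),
                    engine = engine_serial()) {
  stopifnot(inherits(scorer, "pair_scorer"), inherits(options, "dp_options"))
  st <- new_dp_state(seq, scorer, options, engine_name(engine))
  n <- st$n
  if (n > options$max_n)
    stop("sequence length ", n, " exceeds the guard (max_n = ", options$max_n,
         "): the gap-matrix fill is O(n^6) time / O(n^4) space; raise max_n ",
         "deliberately if you accept the cost")
  engine_begin(engine, st)
  on.exit(engine_end(engine, st), add = TRUE)
  pk <- options$pseudoknots && n >= 2
  for (d in 0:(n - 1L)) {
    for (i in seq_len(n - d)) {
      j <- i + d
      st$ctx_cell <- c(i, j)
      if (d == 0L) { st$ctx <- "WX"; wr_wx(st, i, i, 0); next }
      if (pk) {
        # boundary conventions stored so vectorized block slices can read
        # them: left-empty column k = i-1 and right-empty column l = j+1
        st$ctx <- "WHX"
        lv <- (i + 1L):j
        wr_whx(st, i, j, i - 1L, lv, rd_wx(st, lv, j))
        wr_whx(st, i, j, i - 1L, j + 1L, 0)
        kv <- i:(j - 1L)
        wr_whx(st, i, j, kv, j + 1L, rd_wx(st, i, kv))
      }
      st$ctx <- "VX"
      if (st$opts$timing) t0 <- proc.time()[[3]]
      st$cells[["VX"]] <- st$cells[["VX"]] + 1
      st$ops[["VX"]] <- st$ops[["VX"]] + 1
      interior <- if (j - 1L >= i + 1L) rd_wx(st, i + 1L, j - 1L) else 0
      wr_vx(st, i, j, st$S[i, j] + interior)
      if (st$opts$timing)
        st$timers[["VX"]] <- st$timers[["VX"]] + (proc.time()[[3]] - t0)
      if (pk && d >= 2L) {
        for (hole in (d - 1L):1L) {
          for (k in i:(j - hole - 1L)) {
            compute_whx_cell_int(st, i, j, k, k + hole + 1L, engine)
          }
        }
      }
      st$ctx <- "WX"
      if (st$opts$timing) t0 <- proc.time()[[3]]
      st$cells[["WX"]] <- st$cells[["WX"]] + 1
      rv <- i:(j - 1L)
      cands <- c(rd_vx(st, i, j),
                 rd_wx(st, i + 1L, j),
                 rd_wx(st, i, j - 1L),
                 rd_wx(st, i, rv) + rd_wx(st, rv + 1L, j))
      nops <- 3 + length(rv)
      if (pk) {
        pkres <- pk_compose_int(st, i, j)
        cands <- c(cands, pkres$score)
        nops <- nops + pkres$count
      }
      st$ops[["WX"]] <- st$ops[["WX"]] + nops
      wr_wx(st, i, j, max(cands))
      if (st$opts$timing)
        st$timers[["WX"]] <- st$timers[["WX"]] + (proc.time()[[3]] - t0)
    }
  }
  seal_state(st)
  st
}

#' @export
print.dp_state <- function(x, ...) {
  cat("<dp_state> n =", x$n, " engine =", x$engine_name,
      " pseudoknots =", x$opts$pseudoknots,
      " gap_gap =", x$opts$gap_gap, "\n")
  cat("  optimal score wx(1, n) =", x$wx[1, x$n], "\n")
  invisible(x)
}

#' Read a WX cell
#'
#' Best score of the subinterval `[i, j]` with no assertion on the ends.
#' Empty or negative-width intervals score 0.
#' @param state a filled `dp_state`.
#' @param i,j 1-based interval bounds.
#' @export
wx_value <- function(state, i, j) {
  stopifnot(inherits(state, "dp_state"))
  if (j <= i - 1L) return(0)
  state$wx[i, j]
}

#' Read a VX cell
#'
#' Best score of `[i, j]` under the assertion that `(i, j)` itself pairs;
#' `-Inf` when that pair is forbidden.
#' @inheritParams wx_value
#' @export
vx_value <- function(state, i, j) {
  stopifnot(inherits(state, "dp_state"), i < j)
  state$vx[i, j]
}

#' Read a WHX gap cell (convention-aware)
#'
#' Value of `whx(i, j : k, l)`, the best score of the two-segment region
#' `[i,k] u [l,j]` whose hole `[k+1, l-1]` is left unfilled.  The boundary
#' conventions apply: `k = i-1` gives `wx(l, j)`, `l = j+1` gives
#' `wx(i, k)`, both give 0, and an empty hole (`l = k+1`) gives `wx(i, j)`.
#' @inheritParams wx_value
#' @param k,l hole-flank indices, `i-1 <= k < l <= j+1`.
#' @export
whx_value <- function(state, i, j, k, l) {
  stopifnot(inherits(state, "dp_state"), k < l, k >= i - 1L, l <= j + 1L)
  if (is.null(state$whx)) stop("state was filled without pseudoknots; no gap tables")
  whx_lookup_int(state, as.integer(i), as.integer(j),
                 as.integer(k), as.integer(l))
}

#' Scheduling decision counts of a filled state
#'
#' How many WHX cells the engine evaluated serially versus in parallel
#' (meaningful for [engine_hpar()]; other engines count every cell in the
#' mode they always use).
#' @param state a `dp_state`.
#' @return a tibble with columns `mode` and `cells`.
#' @export
sched_summary <- function(state) {
  stopifnot(inherits(state, "dp_state"))
  tibble::tibble(mode = c("serial", "parallel"),
                 cells = c(state$sched$serial, state$sched$parallel))
}

#' Audit trail of a filled state
#'
#' The ordered log of table reads and writes recorded when the state was
#' filled with `dp_options(audit = TRUE)`: the acting matrix family and its
#' cell, the target family and first target cell, how many cells the access
#' touched, and how many of them were unwritten at read time (any non-zero
#' count is a dependency-order violation).
#' @param state a `dp_state` filled with auditing on.
#' @return a tibble, one row per access, in fill order.
#' @export
audit_log <- function(state) {
  stopifnot(inherits(state, "dp_state"))
  if (is.null(state$aud)) stop("state was filled without audit = TRUE")
  rows <- state$aud$rows[seq_len(state$aud$cnt)]
  dplyr::bind_rows(lapply(rows, tibble::as_tibble))
}

# ---------------------------------------------------------------------------
# Traceback: replay the recursions from wx(1, n), always taking the first
# alternative (fixed order below) whose value equals the stored cell value.
# The replay recomputes candidates with the same arithmetic as the fill, so
# exact equality is sound.  Deterministic regardless of the fill engine.
# ---------------------------------------------------------------------------

#' Trace back one optimal structure
#'
#' @param state a filled `dp_state` from [fill_dp()].
#' @return a `secondary_structure`; its total pair weight equals the DP
#'   optimum (checked; a mismatch aborts with an internal-consistency error).
#' @export
traceback_structure <- function(state) {
  stopifnot(inherits(state, "dp_state"), state$sealed)
  acc <- new.env(parent = emptyenv())
  acc$pairs <- list()
  tb_wx(state, acc, 1L, state$n)
  pm <- if (length(acc$pairs)) do.call(rbind, acc$pairs) else
    matrix(integer(0), 0, 2)
  struct <- secondary_structure(pm, state$n)
  got <- if (nrow(struct$pairs)) sum(state$S[struct$pairs]) else 0
  want <- wx_value(state, 1L, state$n)
  if (!isTRUE(all.equal(got, want)))
    stop("internal-consistency error: traceback recovered score ", got,
         " but the DP optimum is ", want)
  struct
}

tb_pair <- function(acc, i, j) {
  acc$pairs[[length(acc$pairs) + 1L]] <- c(as.integer(i), as.integer(j))
}

tb_wx <- function(st, acc, i, j) {
  if (j <= i) return(invisible(NULL))
  v <- st$wx[i, j]
  if (identical(st$vx[i, j], v)) { tb_vx(st, acc, i, j); return(invisible(NULL)) }
  if (identical(st$wx[i + 1L, j], v)) { tb_wx(st, acc, i + 1L, j); return(invisible(NULL)) }
  if (identical(st$wx[i, j - 1L], v)) { tb_wx(st, acc, i, j - 1L); return(invisible(NULL)) }
  for (r in i:(j - 1L)) {
    if (identical(st$wx[i, r] + st$wx[r + 1L, j], v)) {
      tb_wx(st, acc, i, r); tb_wx(st, acc, r + 1L, j)
      return(invisible(NULL))
    }
  }
  if (st$opts$pseudoknots && !is.null(st$whx) && j - i >= 3L) {
    for (a in i:(j - 3L)) for (b in (a + 2L):(j - 1L)) for (cc in b:(j - 1L)) {
      if (identical(whx_lookup_int(st, i, cc, a, b) +
                    whx_lookup_int(st, a + 1L, j, b - 1L, cc + 1L), v)) {
        tb_whx(st, acc, i, cc, a, b)
        tb_whx(st, acc, a + 1L, j, b - 1L, cc + 1L)
        return(invisible(NULL))
      }
    }
  }
  stop("internal-consistency error: no WX alternative matches cell (",
       i, ",", j, ")")
}

tb_vx <- function(st, acc, i, j) {
  tb_pair(acc, i, j)
  if (j - 1L >= i + 1L) tb_wx(st, acc, i + 1L, j - 1L)
  invisible(NULL)
}

tb_whx <- function(st, acc, i, j, k, l) {
  if (k < i) {
    if (l <= j) tb_wx(st, acc, l, j)
    return(invisible(NULL))
  }
  if (l > j) { tb_wx(st, acc, i, k); return(invisible(NULL)) }
  if (l == k + 1L) { tb_wx(st, acc, i, j); return(invisible(NULL)) }
  v <- st$whx[i, j, k + 1L, l]
  # B1 alternatives in listed order
  if (identical(whx_lookup_int(st, i + 1L, j, k, l), v))
    return(invisible(tb_whx(st, acc, i + 1L, j, k, l)))
  if (identical(whx_lookup_int(st, i, j - 1L, k, l), v))
    return(invisible(tb_whx(st, acc, i, j - 1L, k, l)))
  if (identical(whx_lookup_int(st, i, j, k - 1L, l), v))
    return(invisible(tb_whx(st, acc, i, j, k - 1L, l)))
  if (identical(whx_lookup_int(st, i, j, k, l + 1L), v))
    return(invisible(tb_whx(st, acc, i, j, k, l + 1L)))
  if (identical(st$S[i, j] + whx_lookup_int(st, i + 1L, j - 1L, k, l), v)) {
    tb_pair(acc, i, j)
    return(invisible(tb_whx(st, acc, i + 1L, j - 1L, k, l)))
  }
  if (identical(st$S[k, l] + whx_lookup_int(st, i, j, k - 1L, l + 1L), v)) {
    tb_pair(acc, k, l)
    return(invisible(tb_whx(st, acc, i, j, k - 1L, l + 1L)))
  }
  if (k > i && l < j &&
      identical(st$S[i, j] + st$S[k, l] +
                whx_lookup_int(st, i + 1L, j - 1L, k - 1L, l + 1L), v)) {
    tb_pair(acc, i, j); tb_pair(acc, k, l)
    return(invisible(tb_whx(st, acc, i + 1L, j - 1L, k - 1L, l + 1L)))
  }
  if (k > i) {
    for (r in i:(k - 1L)) {  # B2
      if (identical(st$wx[i, r] + whx_lookup_int(st, r + 1L, j, k, l), v)) {
        tb_wx(st, acc, i, r)
        return(invisible(tb_whx(st, acc, r + 1L, j, k, l)))
      }
    }
    for (r in i:(k - 1L)) {  # B3
      if (identical(whx_lookup_int(st, i, j, r, l) + st$wx[r + 1L, k], v)) {
        tb_whx(st, acc, i, j, r, l)
        return(invisible(tb_wx(st, acc, r + 1L, k)))
      }
    }
  }
  if (l < j) {
    for (r in (l + 1L):j) {  # B4
      if (identical(whx_lookup_int(st, i, r - 1L, k, l) + st$wx[r, j], v)) {
        tb_whx(st, acc, i, r - 1L, k, l)
        return(invisible(tb_wx(st, acc, r, j)))
      }
    }
    for (r in l:(j - 1L)) {  # B5
      if (identical(st$wx[l, r] + whx_lookup_int(st, i, j, k, r + 1L), v)) {
        tb_wx(st, acc, l, r)
        return(invisible(tb_whx(st, acc, i, j, k, r + 1L)))
      }
    }
  }
  if (st$opts$gap_gap) {
    for (r in i:k) for (s in l:j) {  # B6, ascending flattened (r, s)
      if (r == i && s == j) next
      if (identical(whx_lookup_int(st, i, j, r - 1L, s + 1L) +
                    whx_lookup_int(st, r, s, k, l), v)) {
        tb_whx(st, acc, i, j, r - 1L, s + 1L)
        return(invisible(tb_whx(st, acc, r, s, k, l)))
      }
    }
  }
  stop("internal-consistency error: no WHX alternative matches cell (",
       i, ",", j, ":", k, ",", l, ")")
}

#' Predict the optimal secondary structure of one sequence
#'
#' Fills the DP tables and traces back one optimal structure.
#'
#' @inheritParams fill_dp
#' @param id identifier attached to the result.
#' @param keep_state keep the filled tables on the result (`$state`); off by
#'   default since the gap table is O(n^4) numbers.
#' @return an object of class `knot_fold` with the optimal `score`, the
#'   `structure` (a `secondary_structure`), its `dotbracket` rendering, and
#'   scheduling counts.  Supports [generics::tidy()] (one row per pair) and
#'   [generics::glance()] (one summary row).
#' @examples
#' fold <- predict_structure("GGGGAAAACCCCUUUU")
#' fold$score        # 8
#' fold$dotbracket   # "(((([[[[))))]]]]"
#' @export
predict_structure <- function(seq, scorer = pair_scorer(),
                              options = dp_options(),
                              engine = engine_serial(),
                              id = "seq", keep_state = FALSE) {
  st <- fill_dp(seq, scorer, options, engine)
  struct <- traceback_structure(st)
  out <- structure(list(id = id,
                        residues = st$residues,
                        n = st$n,
                        score = wx_value(st, 1L, st$n),
                        structure = struct,
                        dotbracket = pairs_to_dotbracket(struct),
                        engine = st$engine_name,
                        options = st$opts,
                        sched = sched_summary(st),
                        state = if (keep_state) st else NULL),
                   class = "knot_fold")
  out
}

#' @export
print.knot_fold <- function(x, ...) {
  cat("<knot_fold>", x$id, " n =", x$n, " score =", x$score,
      " engine =", x$engine, "\n")
  cat("  ", x$residues, "\n  ", x$dotbracket, "\n")
  invisible(x)
}

#' Predict structures for a table of sequences
#'
#' Data-frame-first wrapper over [predict_structure()]: takes the tibble
#' shape produced by [read_fasta()] / [fixture_sequences()] and returns one
#' row per sequence.
#'
#' @param seqs a data frame with columns `id` and `residues`.
#' @inheritParams predict_structure
#' @return a tibble with columns `id`, `n`, `score`, `n_pairs`,
#'   `pseudoknotted` (does the structure contain crossing pairs),
#'   `dotbracket`, and a list-column `structure`.
#' @export
predict_structures <- function(seqs, scorer = pair_scorer(),
                               options = dp_options(),
                               engine = engine_serial()) {
  stopifnot(is.data.frame(seqs), all(c("id", "residues") %in% names(seqs)))
  folds <- purrr::map2(seqs$residues, seqs$id,
                       ~predict_structure(.x, scorer, options, engine, id = .y))
  tibble::tibble(
    id = seqs$id,
    n = vapply(folds, `[[`, integer(1), "n"),
    score = vapply(folds, `[[`, numeric(1), "score"),
    n_pairs = vapply(folds, function(f) nrow(f$structure$pairs), integer(1)),
    pseudoknotted = vapply(folds, function(f) length(f$structure$layers) > 0 &&
                             max(f$structure$layers) > 1L, logical(1)),
    dotbracket = vapply(folds, `[[`, character(1), "dotbracket"),
    structure = lapply(folds, `[[`, "structure"))
}
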