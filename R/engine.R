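#' Threshold scheduler for loop iterations
#'
#' Decides whether a unit of `total_iters` loop iterations is worth
#' parallelizing.  The rule: run serially unless there is enough work for at
#' least `min_workers` workers to receive at least `min_iters` iterations
#' each; otherwise use `w = min(workers, floor(total_iters / min_iters))`
#' workers with balanced contiguous chunks whose sizes differ by at most 1.
#' Under the defaults (6 workers, 5 iterations minimum, 2 workers minimum) a
#' unit of 30 iterations is exactly six chunks of five — full utilization.
#'
#' @param total_iters non-negative iteration count of the unit of work.
#' @param workers number of available workers (default 6).
#' @param min_iters minimum iterations a worker must receive (default 5).
#' @param min_workers minimum workers that must be engageable (default 2).
#' @return a `schedule_decision`: a list with `mode` (`"serial"` or
#'   `"parallel"`), `chunks` (tibble `worker`, `from`, `to`, `size`) and a
#'   human-readable `reason`.
#' @examples
#' schedule_iterations(9)$mode    # "serial"
#' schedule_iterations(30)$chunks # six chunks of five
#' @export
schedule_iterations <- function(total_iters, workers = 6L, min_iters = 5L,
                                min_workers = 2L) {
  workers <- as.integer(workers)
  if (is.na(workers) || workers < 1L) stop("`workers` must be >= 1")
  min_iters <- as.integer(min_iters); min_workers <- as.integer(min_workers)
  if (min_iters < 1L || min_workers < 1L)
    stop("`min_iters` and `min_workers` must be >= 1")
  total_iters <- as.integer(total_iters)
  stopifnot(total_iters >= 0L)
  dec <- schedule_fast(total_iters, workers, min_iters, min_workers)
  if (dec$mode == "serial") {
    return(structure(list(
      mode = "serial",
      chunks = tibble::tibble(worker = integer(0), from = integer(0),
                              to = integer(0), size = integer(0)),
      reason = sprintf(
        "%d iterations < %d x %d: not enough work for %d workers of %d iterations each",
        total_iters, min_iters, min_workers, min_workers, min_iters)),
      class = "schedule_decision"))
  }
  structure(list(mode = "parallel",
                 chunks = tibble::tibble(worker = seq_along(dec$size),
                                         from = dec$from, to = dec$to,
                                         size = dec$size),
                 reason = sprintf(
                   "%d iterations across %d workers (>= %d each)",
                   total_iters, length(dec$size), min_iters)),
            class = "schedule_decision")
}

# Allocation-light core of the scheduling rule, called once per WHX cell by
# the hybrid engine.
schedule_fast <- function(total_iters, workers, min_iters, min_workers) {
  if (total_iters < min_iters * min_workers) return(list(mode = "serial"))
  w <- min(workers, total_iters %/% min_iters)
  base <- total_iters %/% w
  extra <- total_iters %% w
  size <- base + as.integer(seq_len(w) <= extra)
  to <- cumsum(size)
  list(mode = "parallel", from = to - size + 1L, to = to, size = size)
}

#' @export
print.schedule_decision <- function(x, ...) {
  cat("<schedule_decision>", x$mode, "-", x$reason, "\n")
  if (nrow(x$chunks)) print(x$chunks)
  invisible(x)
}

# ---------------------------------------------------------------------------
# Worker pool: persistent in-process workers exchanging task/reply messages
# with the coordinator.  Workers either read a shared read-only snapshot of
# the tables ("snapshot" payload) or receive the candidate values packaged
# into the message ("package" payload); both modes return the same partial
# maxima, since every work block reduces to max over an elementwise sum of
# two stored value vectors.
# ---------------------------------------------------------------------------

#' Start a pool of persistent workers
#'
#' Workers are started once, before any cell is processed, stay alive across
#' cells, and are dismissed with an explicit shutdown message by
#' [pool_stop()].
#'
#' @param workers number of workers (default 6).
#' @param payload `"snapshot"`: tasks reference a read-only snapshot of the
#'   tables; `"package"`: the coordinator packages the candidate values into
#'   each task and workers never touch the tables.
#' @return a `worker_pool`.
#' @export
worker_pool <- function(workers = 6L, payload = c("snapshot", "package")) {
  payload <- match.arg(payload)
  workers <- as.integer(workers)
  if (is.na(workers) || workers < 1L) stop("pool startup error: `workers` must be >= 1")
  pool <- new.env(parent = emptyenv())
  pool$payload <- payload
  pool$started <- TRUE
  pool$workers <- lapply(seq_len(workers), function(w) {
    we <- new.env(parent = emptyenv())
    we$id <- w
    we$n_tasks <- 0L
    we$alive <- TRUE
    we
  })
  class(pool) <- "worker_pool"
  pool
}

#' @export
print.worker_pool <- function(x, ...) {
  cat("<worker_pool>", length(x$workers), "workers,",
      if (x$started) "running" else "stopped",
      sprintf("(payload = %s)\n", x$payload))
  invisible(x)
}

# Deliver one TaskMessage to a worker and collect the reply (partial max and
# argmax loop index).  A worker failure aborts the run: no silent partials.
pool_submit <- function(pool, worker_id, msg) {
  stopifnot(inherits(pool, "worker_pool"))
  if (!pool$started) stop("worker pool is stopped")
  we <- pool$workers[[worker_id]]
  if (!we$alive) stop("worker ", worker_id, " is not alive")
  we$n_tasks <- we$n_tasks + 1L
  if (identical(msg$kind, "shutdown")) {
    we$alive <- FALSE
    return(invisible(NULL))
  }
  reply <- tryCatch({
    vals <- if (!is.null(msg$values)) msg$values
            else block_candidates(msg$state, msg$i, msg$j, msg$k, msg$l,
                                  msg$block_id, msg$from, msg$to)
    if (length(vals)) list(max = max(vals), argmax = which.max(vals))
    else list(max = -Inf, argmax = NA_integer_)
  }, error = function(e) e)
  if (inherits(reply, "error"))
    stop("worker ", worker_id, " failed on ", msg$block_id, " of cell (",
         msg$i, ",", msg$j, ":", msg$k, ",", msg$l, "): ",
         conditionMessage(reply))
  reply
}

#' Stop a worker pool
#'
#' Sends a shutdown message to every worker and returns the per-worker task
#' counts (shutdown included).
#' @param pool a [worker_pool()].
#' @return a tibble with columns `worker` and `tasks`, invisibly.
#' @export
pool_stop <- function(pool) {
  stopifnot(inherits(pool, "worker_pool"))
  if (pool$started) {
    for (we in pool$workers)
      if (we$alive) pool_submit(pool, we$id, list(kind = "shutdown"))
    pool$started <- FALSE
  }
  invisible(tibble::tibble(worker = vapply(pool$workers, `[[`, integer(1), "id"),
                           tasks = vapply(pool$workers, `[[`, integer(1), "n_tasks")))
}

make_task <- function(pool, st, cell, block_id, from, to,
                      group = NA_character_) {
  msg <- list(kind = "compute", group = group, block_id = block_id,
              i = cell[1], j = cell[2], k = cell[3], l = cell[4],
              from = from, to = to)
  if (pool$payload == "package") {
    msg$values <- block_candidates(st, cell[1], cell[2], cell[3], cell[4],
                                   block_id, from, to)
  } else {
    msg$state <- st
  }
  msg
}

# Map a global [gfrom, gto] range over the flattened union of the loop
# blocks (a named size vector, B1 excluded) to per-block local subranges.
flatten_segments <- function(sizes, gfrom, gto) {
  segs <- list()
  off <- 0L
  for (b in seq_along(sizes)) {
    sz <- sizes[[b]]
    lo <- max(gfrom - off, 1L)
    hi <- min(gto - off, sz)
    if (sz > 0L && lo <= hi)
      segs[[length(segs) + 1L]] <- list(block_id = names(sizes)[b],
                                        from = lo, to = hi)
    off <- off + sz
  }
  segs
}

# --- engine classes --------------------------------------------------------

new_engine <- function(class, ...) {
  e <- new.env(parent = emptyenv())
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  class(e) <- c(class, "dp_engine")
  e
}

#' Execution engines for the WHX work blocks
#'
#' Engines decide who evaluates the work blocks of each WHX cell; they never
#' change the cell order, and all of them produce bit-identical tables.
#'
#' * `engine_serial()` — the coordinator evaluates every block itself.
#' * `engine_cpar()` — code parallelism (function offloading): each of the up
#'   to six blocks of a cell is handed whole to one worker.
#' * `engine_dpar()` — data (loop) parallelism: the union of all loop blocks'
#'   iteration spaces is flattened and chunked evenly across the workers
#'   regardless of block membership; tasks are submitted per cell to a fresh
#'   logical task group.  The loop-free B1 stays with the coordinator.
#' * `engine_hpar()` — hybrid: per cell, [schedule_iterations()] decides
#'   between coordinator-side evaluation and chunked dispatch to the
#'   persistent pool; below the threshold no worker is invoked.
#'
#' @param workers number of workers (default 6).
#' @param payload see [worker_pool()].
#' @param min_iters,min_workers threshold parameters of the scheduler
#'   (H-Par only).
#' @return an engine object usable as the `engine` argument of [fill_dp()]
#'   and [predict_structure()].
#' @name engines
NULL

#' @rdname engines
#' @export
engine_serial <- function() new_engine("engine_serial", workers = 0L)

#' @rdname engines
#' @export
engine_cpar <- function(workers = 6L, payload = c("snapshot", "package"))
  new_engine("engine_cpar", workers = as.integer(workers),
             payload = match.arg(payload), pool = NULL)

#' @rdname engines
#' @export
engine_dpar <- function(workers = 6L, payload = c("snapshot", "package"))
  new_engine("engine_dpar", workers = as.integer(workers),
             payload = match.arg(payload), pool = NULL)

#' @rdname engines
#' @export
engine_hpar <- function(workers = 6L, min_iters = 5L, min_workers = 2L,
                        payload = c("snapshot", "package"))
  new_engine("engine_hpar", workers = as.integer(workers),
             min_iters = as.integer(min_iters),
             min_workers = as.integer(min_workers),
             payload = match.arg(payload), pool = NULL)

engine_name <- function(engine) UseMethod("engine_name")
#' @export
engine_name.engine_serial <- function(engine) "serial"
#' @export
engine_name.engine_cpar <- function(engine) "cpar"
#' @export
engine_name.engine_dpar <- function(engine) "dpar"
#' @export
engine_name.engine_hpar <- function(engine) "hpar"

engine_begin <- function(engine, st) UseMethod("engine_begin")
#' @export
engine_begin.dp_engine <- function(engine, st) {
  if (!is.null(engine$workers) && engine$workers > 0L)
    engine$pool <- worker_pool(engine$workers, engine$payload)
  invisible(NULL)
}
#' @export
engine_begin.engine_serial <- function(engine, st) invisible(NULL)

engine_end <- function(engine, st) UseMethod("engine_end")
#' @export
engine_end.dp_engine <- function(engine, st) {
  if (!is.null(engine$pool)) {
    pool_stop(engine$pool)
    engine$pool <- NULL
  }
  invisible(NULL)
}
#' @export
engine_end.engine_serial <- function(engine, st) invisible(NULL)

# Evaluate all blocks of one cell and return the combined max.  `cell` is
# c(i, j, k, l); `sizes` the named iteration counts from block_sizes_int().
engine_eval <- function(engine, st, cell, sizes) UseMethod("engine_eval")

eval_blocks_here <- function(st, cell, sizes) {
  best <- -Inf
  for (bid in names(sizes)) {
    v <- block_candidates(st, cell[1], cell[2], cell[3], cell[4], bid)
    if (length(v)) best <- max(best, max(v))
  }
  best
}

#' @export
engine_eval.engine_serial <- function(engine, st, cell, sizes) {
  st$sched$serial <- st$sched$serial + 1L
  eval_blocks_here(st, cell, sizes)
}

#' @export
engine_eval.engine_cpar <- function(engine, st, cell, sizes) {
  st$sched$parallel <- st$sched$parallel + 1L
  nw <- length(engine$pool$workers)
  best <- -Inf
  for (b in seq_along(sizes)) {
    msg <- make_task(engine$pool, st, cell, names(sizes)[b], 1L,
                     max(sizes[[b]], 0L))
    reply <- pool_submit(engine$pool, (b - 1L) %% nw + 1L, msg)
    best <- max(best, reply$max)
  }
  best
}

#' @export
engine_eval.engine_dpar <- function(engine, st, cell, sizes) {
  st$sched$parallel <- st$sched$parallel + 1L
  loop_sizes <- sizes[names(sizes) != "B1"]
  total <- sum(loop_sizes)
  best <- max(block_candidates(st, cell[1], cell[2], cell[3], cell[4], "B1"))
  if (total > 0L) {
    nw <- length(engine$pool$workers)
    w <- min(nw, total)
    base <- total %/% w; extra <- total %% w
    size <- base + as.integer(seq_len(w) <= extra)
    to <- cumsum(size)
    group <- paste0("cell-", paste(cell, collapse = "-"))
    for (cw in seq_len(w)) {
      for (seg in flatten_segments(loop_sizes, to[cw] - size[cw] + 1L, to[cw])) {
        msg <- make_task(engine$pool, st, cell, seg$block_id,
                         seg$from, seg$to, group)
        reply <- pool_submit(engine$pool, cw, msg)
        best <- max(best, reply$max)
      }
    }
  }
  best
}

#' @export
engine_eval.engine_hpar <- function(engine, st, cell, sizes) {
  loop_sizes <- sizes[names(sizes) != "B1"]
  total <- sum(loop_sizes)
  dec <- schedule_fast(total, engine$workers, engine$min_iters,
                       engine$min_workers)
  if (dec$mode == "serial") {
    st$sched$serial <- st$sched$serial + 1L
    return(eval_blocks_here(st, cell, sizes))
  }
  st$sched$parallel <- st$sched$parallel + 1L
  best <- max(block_candidates(st, cell[1], cell[2], cell[3], cell[4], "B1"))
  for (cw in seq_along(dec$size)) {
    for (seg in flatten_segments(loop_sizes, dec$from[cw], dec$to[cw])) {
      msg <- make_task(engine$pool, st, cell, seg$block_id,
                       seg$from, seg$to)
      reply <- pool_submit(engine$pool, cw, msg)
      best <- max(best, reply$max)
    }
  }
  best
}

#' Re-evaluate one WHX cell under a given engine
#'
#' Recomputes the value of a gap cell from a filled state by decomposing it
#' into work blocks and running them through the engine.  Intended for
#' engine-equivalence checks; the state is not modified.
#'
#' @param state a filled `dp_state` (pseudoknots enabled).
#' @param cell integer vector `c(i, j, k, l)`.
#' @param engine an engine from [engines].
#' @return the cell's score.
#' @export
whx_cell_score <- function(state, cell, engine = engine_serial()) {
  stopifnot(inherits(state, "dp_state"), !is.null(state$whx))
  sizes <- block_sizes_int(cell[1], cell[2], cell[3], cell[4],
                           state$opts$gap_gap)
  engine_begin(engine, state)
  on.exit(engine_end(engine, state), add = TRUE)
  engine_eval(engine, state, as.integer(cell), sizes)
}
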