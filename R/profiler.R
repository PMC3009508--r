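#' Profile one fill: work attribution per matrix family
#'
#' Runs the serial engine with counting instrumentation and reports, per
#' matrix family (VX, WX, WHX, VHX, ZHX, YHX): the number of cells
#' evaluated, the number of elementary operations (candidate values entering
#' a maximization; the closure families count one per evaluation), the
#' accumulated wall time, and each family's share of the total operation
#' count.  Operation counts are a deterministic function of `(n, options)`;
#' the times are informative only.
#'
#' @param seq residue string (at least 4 residues).
#' @param scorer a [pair_scorer()].
#' @param options a [dp_options()]; `audit`/`timing` flags are overridden.
#' @return a tibble of class `knot_profile` with columns `family`, `cells`,
#'   `ops`, `seconds`, `share`, plus attributes `n` and `elapsed`.
#' @export
profile_run <- function(seq, scorer = pair_scorer(), options = dp_options()) {
  opts <- dp_options(pseudoknots = options$pseudoknots,
                     gap_gap = options$gap_gap,
                     max_n = options$max_n,
                     audit = FALSE, timing = TRUE)
  residues <- normalize_residues(seq)
  if (nchar(residues) < 4L) stop("profiling needs n >= 4")
  t0 <- proc.time()[[3]]
  st <- fill_dp(residues, scorer, opts, engine_serial())
  elapsed <- proc.time()[[3]] - t0
  total <- sum(st$ops)
  rep <- tibble::tibble(family = FAMILIES,
                        cells = as.integer(st$cells[FAMILIES]),
                        ops = st$ops[FAMILIES],
                        seconds = st$timers[FAMILIES],
                        share = if (total > 0) st$ops[FAMILIES] / total
                                else rep(0, length(FAMILIES)))
  attr(rep, "n") <- st$n
  attr(rep, "pseudoknots") <- opts$pseudoknots
  attr(rep, "gap_gap") <- opts$gap_gap
  attr(rep, "elapsed") <- elapsed
  class(rep) <- c("knot_profile", class(rep))
  rep
}

#' Operation-count shares across sequence lengths
#'
#' Profiles one sequence per requested length and tabulates each matrix
#' family's share of the elementary-operation count.  Because the counts
#' depend only on `(n, options)` — every candidate is evaluated whether or
#' not it wins — the trend is deterministic; the WHX family's share grows
#' with `n` (its cell count is Theta(n^4) with up to Theta(n^2) work per
#' cell, against Theta(n^2) cells elsewhere), which is the operation-count
#' analogue of the wall-clock bottleneck at the WHX fill.
#'
#' @param lengths ascending integer sequence lengths (each >= 4).
#' @inheritParams profile_run
#' @param seed seed for the (irrelevant to the counts) sequence content.
#' @return a tibble with columns `n`, `family`, `cells`, `ops`, `share`.
#' @export
share_trend <- function(lengths, scorer = pair_scorer(),
                        options = dp_options(), seed = 1L) {
  stopifnot(length(lengths) >= 1, !is.unsorted(lengths))
  purrr::map_dfr(as.integer(lengths), function(n) {
    s <- fixture_sequences("random", n = n, count = 1, seed = seed)$residues
    p <- profile_run(s, scorer, options)
    tibble::tibble(n = n, family = p$family, cells = p$cells,
                   ops = p$ops, share = p$share)
  })
}

#' @export
print.knot_profile <- function(x, ...) {
  cat("<knot_profile> n =", attr(x, "n"),
      " pseudoknots =", attr(x, "pseudoknots"),
      " elapsed =", sprintf("%.3fs", attr(x, "elapsed")), "\n")
  NextMethod()
}

#' @importFrom ggplot2 autoplot
#' @method autoplot knot_profile
#' @export
autoplot.knot_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$family <- factor(df$family, levels = FAMILIES)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$family, y = .data$share)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "share of elementary operations",
                  title = sprintf("Per-matrix work attribution (n = %d)",
                                  attr(object, "n"))) +
    ggplot2::theme_minimal()
}
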