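#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a predicted fold: one row per base pair
#'
#' @param x a `knot_fold` from [predict_structure()].
#' @param ... unused.
#' @return a tibble with columns `i`, `j`, `bases` (e.g. `"G-C"`), `span`
#'   and `layer` (bracket layer of the dot-bracket rendering; layers above 1
#'   mark crossing pairs).
#' @method tidy knot_fold
#' @export
tidy.knot_fold <- function(x, ...) {
  pm <- x$structure$pairs
  b <- strsplit(x$residues, "")[[1]]
  tibble::tibble(i = pm[, 1], j = pm[, 2],
                 bases = if (nrow(pm)) paste0(b[pm[, 1]], "-", b[pm[, 2]])
                         else character(0),
                 span = pm[, 2] - pm[, 1],
                 layer = x$structure$layers)
}

#' One-row summary of a predicted fold
#'
#' @inheritParams tidy.knot_fold
#' @return a tibble with `id`, `n`, `score`, `n_pairs`, `n_layers`,
#'   `pseudoknotted`, `engine`.
#' @method glance knot_fold
#' @export
glance.knot_fold <- function(x, ...) {
  tibble::tibble(id = x$id, n = x$n, score = x$score,
                 n_pairs = nrow(x$structure$pairs),
                 n_layers = if (length(x$structure$layers))
                   max(x$structure$layers) else 0L,
                 pseudoknotted = length(x$structure$layers) > 0 &&
                   max(x$structure$layers) > 1L,
                 engine = x$engine)
}

#' Arc diagram of a predicted fold
#'
#' Draws the sequence on a line with one arc per base pair; crossing layers
#' are colored separately, so a pseudoknot shows as arcs of two colors that
#' interleave.
#'
#' @param object a `knot_fold`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot knot_fold
#' @export
autoplot.knot_fold <- function(object, ...) {
  td <- tidy(object)
  b <- strsplit(object$residues, "")[[1]]
  base_df <- tibble::tibble(x = seq_along(b), base = b)
  p <- ggplot2::ggplot() +
    ggplot2::geom_text(data = base_df,
                       ggplot2::aes(x = .data$x, y = 0, label = .data$base),
                       size = 3) +
    ggplot2::coord_fixed(ylim = c(-0.5, object$n / 2 + 1)) +
    ggplot2::theme_void() +
    ggplot2::labs(title = sprintf("%s  score = %g", object$id, object$score))
  if (nrow(td)) {
    arcs <- purrr::pmap_dfr(td, function(i, j, bases, span, layer) {
      t <- seq(0, pi, length.out = 32)
      tibble::tibble(x = (i + j) / 2 + (j - i) / 2 * cos(t),
                     y = (j - i) / 2 * sin(t),
                     grp = paste(i, j), layer = factor(layer))
    })
    p <- p + ggplot2::geom_path(
      data = arcs,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$grp,
                   color = .data$layer))
  }
  p
}

#' @rdname autoplot.knot_fold
#' @param fold a `knot_fold`.
#' @export
plot_structure <- function(fold, ...) autoplot(fold, ...)
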