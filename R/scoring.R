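#' Build a base-pair scorer
#'
#' A scorer defines which nucleotide pairs are allowed to form, the score each
#' pair class contributes, and the minimum hairpin loop separation `h`.  Under
#' base-pair maximization every admissible pair contributes its (positive)
#' class weight and the optimum maximizes the total; positions `i < j` may
#' pair only when `j - i > h`, so at least `h` unpaired residues can sit
#' inside a hairpin loop.
#'
#' Pairs that are not allowed score `FORBIDDEN`, represented as `-Inf`.
#' `-Inf` is absorbing under addition, so a forbidden elementary score can
#' never win a maximization nor leak into a reported total.
#'
#' @param allowed_pairs character vector of unordered pair classes, each two
#'   bases from `A,C,G,U` (order within a class does not matter).  The default
#'   allows Watson-Crick pairs plus the G-U wobble.
#' @param weights positive numeric, either length 1 (recycled) or named by
#'   pair class, giving the score of each allowed class.  Default 1 for all,
#'   i.e. plain pair counting.
#' @param min_loop minimum loop separation `h` (non-negative integer);
#'   positions pair only when `j - i > min_loop`.
#' @return an object of class `pair_scorer`.
#' @examples
#' sc <- pair_scorer()
#' pair_score(sc, "G", "C", 1, 10)   # 1
#' pair_score(sc, "A", "U", 3, 6)    # -Inf: separation 3 violates min_loop
#' @export
pair_scorer <- function(allowed_pairs = c("AU", "CG", "GU"),
                        weights = 1,
                        min_loop = 3L) {
  stopifnot(length(allowed_pairs) >= 1)
  cls <- vapply(allowed_pairs, canonical_pair_class, character(1))
  if (anyDuplicated(cls)) stop("duplicated pair class in `allowed_pairs`")
  if (is.null(names(weights))) {
    if (!length(weights) %in% c(1L, length(cls)))
      stop("`weights` must be length 1 or one per allowed pair class")
    w <- rep_len(as.numeric(weights), length(cls))
    names(w) <- cls
  } else {
    nm <- vapply(names(weights), canonical_pair_class, character(1))
    if (!setequal(nm, cls))
      stop("named `weights` must cover exactly the allowed pair classes")
    w <- as.numeric(weights)[match(cls, nm)]
    names(w) <- cls
  }
  if (any(!is.finite(w)) || any(w <= 0))
    stop("pair weights must be finite and positive")
  min_loop <- as.integer(min_loop)
  if (is.na(min_loop) || min_loop < 0) stop("`min_loop` must be >= 0")
  structure(list(weights = w, min_loop = min_loop),
            class = "pair_scorer")
}

canonical_pair_class <- function(p) {
  p <- toupper(gsub("[^A-Za-z]", "", p))
  b <- strsplit(p, "")[[1]]
  if (length(b) != 2 || !all(b %in% c("A", "C", "G", "U")))
    stop("pair class must be two bases from A,C,G,U: got '", p, "'")
  paste(sort(b), collapse = "")
}

#' @export
print.pair_scorer <- function(x, ...) {
  cat("<pair_scorer> min_loop =", x$min_loop, "\n")
  cat("  weights:",
      paste(sprintf("%s=%g", names(x$weights), x$weights), collapse = ", "),
      "\n")
  invisible(x)
}

#' Elementary pair score
#'
#' Score of pairing bases `a` (at position `i`) and `b` (at position `j > i`).
#' Returns the class weight when `{a,b}` is an allowed pair and `j - i >
#' min_loop`, otherwise `-Inf` (FORBIDDEN).  Symmetric in `(a, b)`.
#'
#' @param scorer a [pair_scorer()].
#' @param a,b single bases (characters from A,C,G,U).
#' @param i,j 1-based positions with `i < j`.
#' @return a numeric score, `-Inf` if the pair may not form.
#' @export
pair_score <- function(scorer, a, b, i, j) {
  stopifnot(inherits(scorer, "pair_scorer"), i < j)
  if (j - i <= scorer$min_loop) return(-Inf)
  cls <- paste(sort(c(toupper(a), toupper(b))), collapse = "")
  w <- scorer$weights[cls]
  if (is.na(w)) -Inf else unname(w)
}

# Precompute the n x n elementary score matrix S[i, j] = delta(i, j) for a
# residue string; -Inf marks forbidden pairs (wrong class or j - i <= h).
# Only the upper triangle (i < j) is meaningful.
score_matrix <- function(scorer, residues) {
  b <- strsplit(residues, "")[[1]]
  n <- length(b)
  S <- matrix(-Inf, n, n)
  if (n < 2) return(S)
  idx <- which(upper.tri(S), arr.ind = TRUE)
  idx <- idx[idx[, 2] - idx[, 1] > scorer$min_loop, , drop = FALSE]
  if (nrow(idx)) {
    cls <- paste0(pmin(b[idx[, 1]], b[idx[, 2]]),
                  pmax(b[idx[, 1]], b[idx[, 2]]))
    w <- scorer$weights[cls]
    w[is.na(w)] <- -Inf
    S[idx] <- w
  }
  S
}
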