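#' Nussinov maximum base pairing (nested structures only)
#'
#' Classic O(n^3) dynamic program over nested structures: every admissible
#' pair contributes its weight, crossings are not allowed.  Implemented
#' independently of the gap-matrix fill (its own table, its own recursion)
#' so it can serve as a reference for the pseudoknot-free configuration.
#'
#' @param seq residue string.
#' @param scorer a [pair_scorer()].
#' @return the optimal nested score.
#' @examples
#' nussinov_max_pairs("GGGAAAACCC")  # 3
#' @export
nussinov_max_pairs <- function(seq, scorer = pair_scorer()) {
  residues <- normalize_residues(seq)
  n <- nchar(residues)
  if (n < 2) return(0)
  b <- strsplit(residues, "")[[1]]
  h <- scorer$min_loop
  w <- scorer$weights
  N <- matrix(0, n, n)
  for (d in 1:(n - 1L)) {
    for (i in seq_len(n - d)) {
      j <- i + d
      best <- max(N[i + 1L, j], N[i, j - 1L])
      if (j - i > h) {
        cls <- paste0(min(b[i], b[j]), max(b[i], b[j]))
        if (!is.na(w[cls])) {
          inner <- if (j - 1L >= i + 1L) N[i + 1L, j - 1L] else 0
          best <- max(best, w[[cls]] + inner)
        }
      }
      if (d >= 2L) for (r in (i + 1L):(j - 1L))
        best <- max(best, N[i, r] + N[r + 1L, j])
      N[i, j] <- best
    }
  }
  N[1, n]
}

#' Exhaustive evaluation of the gap-matrix grammar
#'
#' Independent authority for small sequences: evaluates the same recursion
#' rules the gap-matrix fill implements — trims, closures, segment splits,
#' the gap-gap split and the crossing composition — by direct top-down
#' recursion with scalar loops and a per-cell cache, sharing no code with
#' the table fill.  Exponential state space bounds its use to `n <= 12`.
#'
#' @param seq residue string (at most 12 residues).
#' @param scorer a [pair_scorer()].
#' @param options a [dp_options()]; `pseudoknots` and `gap_gap` are honored.
#' @return the optimal score derivable by the grammar.
#' @export
enumerate_grammar_max <- function(seq, scorer = pair_scorer(),
                                  options = dp_options()) {
  residues <- normalize_residues(seq)
  n <- nchar(residues)
  if (n > 12L)
    stop("enumerate_grammar_max is exponential; refusing n = ", n, " > 12")
  if (n < 2) return(0)
  S <- score_matrix(scorer, residues)
  pk <- options$pseudoknots
  gg <- options$gap_gap
  mwx <- matrix(NA_real_, n, n)
  mwhx <- if (pk) array(NA_real_, dim = c(n, n, n, n)) else NULL

  ewx <- function(i, j) {
    if (j <= i) return(0)
    if (!is.na(mwx[i, j])) return(mwx[i, j])
    best <- max(ewx(i + 1L, j), ewx(i, j - 1L))
    vin <- if (j - 1L >= i + 1L) ewx(i + 1L, j - 1L) else 0
    best <- max(best, S[i, j] + vin)
    if (j - i >= 2L) for (r in (i + 1L):(j - 1L))
      best <- max(best, ewx(i, r) + ewx(r + 1L, j))
    if (pk && j - i >= 3L) {
      for (a in i:(j - 3L)) for (bb in (a + 2L):(j - 1L)) for (cc in bb:(j - 1L))
        best <- max(best, ewhx(i, cc, a, bb) +
                          ewhx(a + 1L, j, bb - 1L, cc + 1L))
    }
    mwx[i, j] <<- best
    best
  }

  ewhx <- function(i, j, k, l) {
    if (k < i) return(if (l > j) 0 else ewx(l, j))
    if (l > j) return(ewx(i, k))
    if (l == k + 1L) return(ewx(i, j))
    if (!is.na(mwhx[i, j, k, l])) return(mwhx[i, j, k, l])
    best <- max(ewhx(i + 1L, j, k, l), ewhx(i, j - 1L, k, l),
                ewhx(i, j, k - 1L, l), ewhx(i, j, k, l + 1L))
    best <- max(best, S[i, j] + ewhx(i + 1L, j - 1L, k, l))          # zhx
    best <- max(best, S[k, l] + ewhx(i, j, k - 1L, l + 1L))          # yhx
    if (k > i && l < j)                                              # vhx
      best <- max(best, S[i, j] + S[k, l] +
                        ewhx(i + 1L, j - 1L, k - 1L, l + 1L))
    if (k > i) for (r in i:(k - 1L)) {
      best <- max(best, ewx(i, r) + ewhx(r + 1L, j, k, l))
      best <- max(best, ewhx(i, j, r, l) + ewx(r + 1L, k))
    }
    if (l < j) for (r in (l + 1L):j)
      best <- max(best, ewhx(i, r - 1L, k, l) + ewx(r, j))
    if (l < j) for (r in l:(j - 1L))
      best <- max(best, ewx(l, r) + ewhx(i, j, k, r + 1L))
    if (gg) for (r in i:k) for (s in l:j) {
      if (r == i && s == j) next
      best <- max(best, ewhx(i, j, r - 1L, s + 1L) + ewhx(r, s, k, l))
    }
    mwhx[i, j, k, l] <<- best
    best
  }

  ewx(1L, n)
}

#' Brute-force maximum matching upper bound
#'
#' The best total weight of ANY set of disjoint admissible pairs under the
#' min-loop constraint, with no topological restriction at all — every
#' structure the grammar can build is such a matching, so this value bounds
#' the DP optimum from above.  Exhaustive branch-on-first-position search;
#' refuses `n > 14`.
#'
#' @inheritParams nussinov_max_pairs
#' @return the maximum matching weight.
#' @export
max_matching_upper_bound <- function(seq, scorer = pair_scorer()) {
  residues <- normalize_residues(seq)
  n <- nchar(residues)
  if (n > 14L)
    stop("max_matching_upper_bound is exponential; refusing n = ", n, " > 14")
  if (n < 2) return(0)
  S <- score_matrix(scorer, residues)
  rec <- function(pos) {
    if (length(pos) < 2L) return(0)
    i <- pos[1]
    rest <- pos[-1]
    best <- rec(rest)
    for (idx in seq_along(rest)) {
      j <- rest[idx]
      if (is.finite(S[i, j]))
        best <- max(best, S[i, j] + rec(rest[-idx]))
    }
    best
  }
  rec(seq_len(n))
}
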