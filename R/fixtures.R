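#' Generate synthetic test sequences
#'
#' Three families of fixtures:
#' * `"random"` — residues drawn uniformly from A/C/G/U; no structural
#'   signal, used for property suites and oracle comparisons.
#' * `"hairpin"` — `G^m A^4 C^m`: one stem of `m` G-C pairs around a
#'   four-residue loop; its optimal score is `m` and the structure is
#'   nested.
#' * `"pseudoknot"` — `G^m A^m C^m U^m`: an H-type pseudoknot by
#'   construction (the G run pairs the C run across the A run, and the A run
#'   pairs the U run across the C run), with `2m` interleaving pairs when
#'   the min-loop constraint permits.
#'
#' @param kind one of `"random"`, `"hairpin"`, `"pseudoknot"`.
#' @param n target length (random: exact; hairpin: `2m + 4` so `n - 4` must
#'   be a positive even number; pseudoknot: `4m` so `n` must be a positive
#'   multiple of 4).  Ignored when `m` is given for the structured kinds.
#' @param m stem/run length for the structured kinds (overrides `n`).
#' @param count how many sequences.
#' @param seed optional seed; the caller's RNG state is left untouched.
#' @return a tibble with columns `id`, `residues`, `length`.
#' @examples
#' fixture_sequences("pseudoknot", m = 4)$residues  # "GGGGAAAACCCCUUUU"
#' @export
fixture_sequences <- function(kind = c("random", "hairpin", "pseudoknot"),
                              n = NULL, m = NULL, count = 1L, seed = NULL) {
  kind <- match.arg(kind)
  count <- as.integer(count)
  stopifnot(count >= 1L)
  make_one <- function(idx) {
    switch(kind,
      random = {
        if (is.null(n) || n < 1) stop("random fixtures need n >= 1")
        paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
      },
      hairpin = {
        mm <- if (!is.null(m)) as.integer(m) else {
          if (is.null(n) || n < 6 || (n - 4) %% 2 != 0)
            stop("hairpin fixtures need m >= 1, i.e. n = 2m + 4 >= 6 and even n - 4")
          as.integer((n - 4) / 2)
        }
        if (mm < 1) stop("hairpin fixtures need m >= 1")
        paste0(strrep("G", mm), "AAAA", strrep("C", mm))
      },
      pseudoknot = {
        mm <- if (!is.null(m)) as.integer(m) else {
          if (is.null(n) || n < 4 || n %% 4 != 0)
            stop("pseudoknot fixtures need m >= 1, i.e. n a positive multiple of 4")
          as.integer(n / 4)
        }
        if (mm < 1) stop("pseudoknot fixtures need m >= 1")
        paste0(strrep("G", mm), strrep("A", mm), strrep("C", mm), strrep("U", mm))
      })
  }
  res <- with_preserved_seed(seed, vapply(seq_len(count), make_one, character(1)))
  tibble::tibble(id = paste0(kind, seq_len(count)),
                 residues = res,
                 length = nchar(res))
}

# Evaluate `code` under `set.seed(seed)` (when given) and restore the
# caller's RNG state afterwards.
with_preserved_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}
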