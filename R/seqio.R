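#' Read RNA sequences from a FASTA file
#'
#' Residues are uppercased and DNA-style `T` is mapped to `U`; any character
#' outside `A,C,G,U,T` (either case) is a hard error naming the record and
#' position.  Record order is preserved.
#'
#' @param path path to a FASTA file.
#' @return a tibble with columns `id`, `residues` (normalized A/C/G/U string)
#'   and `length`.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">pk1", "GGGGAAAACCCCUUUU"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  ids <- character(0)
  seqs <- character(0)
  cur <- NULL
  for (ln in seq_along(lines)) {
    x <- trimws(lines[[ln]])
    if (x == "") next
    if (startsWith(x, ">")) {
      id <- trimws(sub("^>", "", x))
      if (id == "") id <- paste0("seq", length(ids) + 1L)
      ids <- c(ids, id)
      seqs <- c(seqs, "")
      cur <- length(ids)
    } else {
      if (is.null(cur))
        stop(validation_error(sprintf(
          "malformed FASTA: line %d holds sequence data before any '>' header",
          ln)))
      seqs[cur] <- paste0(seqs[cur], gsub("[[:space:]]", "", x))
    }
  }
  if (length(ids) == 0)
    stop(validation_error("malformed FASTA: no records found"))
  res <- mapply(function(id, s) normalize_residues(s, id), ids, seqs,
                USE.NAMES = FALSE)
  tibble::tibble(id = ids, residues = res, length = nchar(res))
}

# Uppercase, map T -> U, reject anything outside the RNA alphabet (including
# N: the matrix system scores concrete bases only).
normalize_residues <- function(residues, id = "seq") {
  stopifnot(is.character(residues), length(residues) == 1)
  s <- toupper(residues)
  s <- gsub("T", "U", s, fixed = TRUE)
  bad <- regexpr("[^ACGU]", s)
  if (bad > 0)
    stop(validation_error(sprintf(
      "record '%s' position %d: invalid residue '%s' (alphabet is A,C,G,U with T tolerated)",
      id, bad, substr(s, bad, bad))))
  if (nchar(s) == 0)
    stop(validation_error(sprintf("record '%s' is empty", id)))
  s
}

validation_error <- function(msg) {
  structure(class = c("knotfold_validation_error", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Write sequences to a FASTA file
#'
#' @param seqs a data frame with columns `id` and `residues` (as returned by
#'   [read_fasta()] or [fixture_sequences()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(all(c("id", "residues") %in% names(seqs)))
  writeLines(rbind(paste0(">", seqs$id), seqs$residues), path)
  invisible(path)
}

#' Render base pairs as layered dot-bracket notation
#'
#' Pairs are sorted by `(i, j)` and assigned bracket layers greedily
#' (first-fit): each pair takes the lowest layer in which it crosses no pair
#' already placed there.  Layer 1 uses `()`, then `[]`, `{}`, `<>`; unpaired
#' positions print `.`.  Crossing pairs (pseudoknots) therefore end up in
#' different bracket alphabets.  More than 4 layers is a capacity error.
#'
#' @param pairs a two-column matrix or data frame of 1-based pair indices
#'   `(i, j)` with `i < j`, or a `secondary_structure`.
#' @param n sequence length (ignored when `pairs` is a `secondary_structure`).
#' @return a string of length `n`.
#' @examples
#' pairs_to_dotbracket(cbind(c(1, 2, 3), c(10, 9, 8)), 10)
#' @export
pairs_to_dotbracket <- function(pairs, n = NULL) {
  if (inherits(pairs, "secondary_structure")) {
    n <- pairs$n
    pairs <- pairs$pairs
  }
  pm <- as_pair_matrix(pairs)
  stopifnot(is.numeric(n), n >= 0)
  out <- rep(".", n)
  if (nrow(pm)) {
    if (max(pm) > n) stop("pair index exceeds sequence length")
    lay <- assign_layers(pm)
    if (max(lay) > 4L)
      stop("structure needs more than 4 bracket layers; dot-bracket capacity exceeded")
    open <- c("(", "[", "{", "<")
    close <- c(")", "]", "}", ">")
    out[pm[, 1]] <- open[lay]
    out[pm[, 2]] <- close[lay]
  }
  paste(out, collapse = "")
}

# Greedy first-fit layering over pairs sorted by (i, j): a pair joins the
# lowest layer where it crosses nothing already placed.
assign_layers <- function(pm) {
  ord <- order(pm[, 1], pm[, 2])
  pm <- pm[ord, , drop = FALSE]
  lay <- integer(nrow(pm))
  for (p in seq_len(nrow(pm))) {
    i <- pm[p, 1]; j <- pm[p, 2]
    q <- 1L
    repeat {
      prior <- which(lay[seq_len(p - 1L)] == q)
      crosses <- any((pm[prior, 1] < i & i < pm[prior, 2] & pm[prior, 2] < j) |
                     (i < pm[prior, 1] & pm[prior, 1] < j & j < pm[prior, 2]))
      if (!crosses) break
      q <- q + 1L
    }
    lay[p] <- q
  }
  lay[order(ord)] <- lay
  lay
}

#' Parse layered dot-bracket notation into base pairs
#'
#' Inverse of [pairs_to_dotbracket()] for the four supported bracket layers.
#'
#' @param db a dot-bracket string.
#' @return a two-column integer matrix of 1-based pairs sorted by `(i, j)`.
#' @export
dotbracket_to_pairs <- function(db) {
  ch <- strsplit(db, "")[[1]]
  open <- c("(", "[", "{", "<")
  close <- c(")", "]", "}", ">")
  pairs <- list()
  for (q in 1:4) {
    stack <- integer(0)
    for (p in seq_along(ch)) {
      if (ch[p] == open[q]) stack <- c(stack, p)
      else if (ch[p] == close[q]) {
        if (!length(stack)) stop("unbalanced '", close[q], "' at position ", p)
        pairs[[length(pairs) + 1L]] <- c(stack[length(stack)], p)
        stack <- stack[-length(stack)]
      }
    }
    if (length(stack)) stop("unbalanced '", open[q], "'")
  }
  bad <- setdiff(unique(ch), c(open, close, "."))
  if (length(bad)) stop("unknown structure character: ", bad[1])
  pm <- if (length(pairs)) do.call(rbind, pairs) else
    matrix(integer(0), 0, 2)
  pm <- pm[order(pm[, 1], pm[, 2]), , drop = FALSE]
  storage.mode(pm) <- "integer"
  colnames(pm) <- c("i", "j")
  pm
}

#' Write a structure in CT format
#'
#' Standard connectivity-table output: a header line with the length and
#' identifier, then one line per residue with 1-based index, base, previous
#' index, next index, pairing partner (0 if unpaired) and the index again.
#'
#' @param structure a `secondary_structure` or a two-column pair matrix.
#' @param residues the residue string the structure belongs to.
#' @param path output file path.
#' @param id record identifier for the header.
#' @return `path`, invisibly.
#' @export
write_ct <- function(structure, residues, path, id = "seq") {
  pm <- as_pair_matrix(structure)
  b <- strsplit(residues, "")[[1]]
  n <- length(b)
  if (nrow(pm) && max(pm) > n) stop("pair index exceeds sequence length")
  partner <- integer(n)
  partner[pm[, 1]] <- pm[, 2]
  partner[pm[, 2]] <- pm[, 1]
  idx <- seq_len(n)
  lines <- c(sprintf("%d %s", n, id),
             sprintf("%d %s %d %d %d %d",
                     idx, b, idx - 1L, ifelse(idx < n, idx + 1L, 0L),
                     partner, idx))
  writeLines(lines, path)
  invisible(path)
}

#' Read a CT file back into pairs and residues
#'
#' @param path a CT file written by [write_ct()] (or compatible).
#' @return a list with `id`, `residues`, and `pairs` (two-column matrix).
#' @export
read_ct <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty CT file")
  head <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
  n <- as.integer(head[1])
  id <- if (length(head) > 1) paste(head[-1], collapse = " ") else "seq"
  if (is.na(n) || length(lines) < n + 1) stop("malformed CT header")
  fields <- strsplit(trimws(lines[2:(n + 1)]), "[[:space:]]+")
  base <- vapply(fields, `[[`, character(1), 2)
  partner <- vapply(fields, function(f) as.integer(f[5]), integer(1))
  i <- which(partner > seq_len(n))
  pm <- cbind(i = i, j = partner[i])
  storage.mode(pm) <- "integer"
  list(id = id, residues = paste(base, collapse = ""), pairs = pm)
}

as_pair_matrix <- function(pairs) {
  if (inherits(pairs, "secondary_structure")) pairs <- pairs$pairs
  if (is.data.frame(pairs)) pairs <- as.matrix(pairs[, 1:2])
  if (is.null(pairs) || length(pairs) == 0)
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j"))))
  pm <- matrix(as.integer(pairs), ncol = 2)
  if (any(pm[, 1] >= pm[, 2])) stop("pairs must satisfy i < j")
  if (anyDuplicated(c(pm))) stop("pairs must be disjoint (each index once)")
  pm <- pm[order(pm[, 1], pm[, 2]), , drop = FALSE]
  colnames(pm) <- c("i", "j")
  pm
}

# Constructor for the structure container: disjoint 1-based pairs plus the
# greedy layer assignment used for dot-bracket rendering.
secondary_structure <- function(pairs, n) {
  pm <- as_pair_matrix(pairs)
  if (nrow(pm) && max(pm) > n) stop("pair index exceeds sequence length")
  structure(list(pairs = pm,
                 layers = if (nrow(pm)) assign_layers(pm) else integer(0),
                 n = as.integer(n)),
            class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat("<secondary_structure> n =", x$n, "with", nrow(x$pairs), "pairs\n")
  cat(" ", pairs_to_dotbracket(x), "\n")
  invisible(x)
}
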