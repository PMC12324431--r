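# RNA sequence encoding and secondary-structure representations.
#
# Sequence sets travel as tibbles with `id` and `seq` columns (plus an
# optional `structure` dot-bracket column).  Internally a sequence is a
# 0-based integer code vector (A=0, C=1, G=2, U=3) and a structure is an
# integer matrix with columns `i`, `j` (1-based, i < j).

#' Encode an RNA sequence
#'
#' Uppercases, maps T to U, and converts to 0-based integer codes
#' (A=0, C=1, G=2, U=3).  Characters outside A,C,G,U,T are rejected:
#' degenerate IUPAC codes carry no emission probability under these
#' grammars.
#'
#' @param seq A single character string.
#' @return An integer vector of codes.
#' @export
encode_rna <- function(seq) {
  if (length(seq) != 1 || !is.character(seq) || is.na(seq) || nchar(seq) < 1)
    abort("`seq` must be a single nonempty character string")
  chars <- strsplit(toupper(seq), "")[[1]]
  chars[chars == "T"] <- "U"
  codes <- match(chars, RNA_ALPHABET) - 1L
  if (anyNA(codes)) {
    bad <- unique(chars[is.na(codes)])
    abort(paste0("sequence contains non-ACGU residue(s): ",
                 paste(bad, collapse = ", ")))
  }
  codes
}

#' @rdname encode_rna
#' @param codes An integer code vector as returned by `encode_rna()`.
#' @export
decode_rna <- function(codes) paste(RNA_ALPHABET[codes + 1L], collapse = "")

#' Construct a tibble of RNA sequences
#'
#' The standard sequence-set container used throughout the package:
#' one row per sequence, with `id` and `seq` (and optionally
#' `structure`) columns.  Input T residues are mapped to U.
#'
#' @param seq Character vector of sequences.
#' @param id Character vector of identifiers (defaults to `seq1`,
#'   `seq2`, ...).
#' @param structure Optional character vector of dot-bracket strings.
#' @return A tibble.
#' @export
rna_tbl <- function(seq, id = NULL, structure = NULL) {
  if (is.null(id)) id <- paste0("seq", seq_along(seq))
  if (anyDuplicated(id)) abort("sequence ids must be unique")
  seq <- vapply(seq, function(s) decode_rna(encode_rna(s)), character(1),
                USE.NAMES = FALSE)
  out <- tibble(id = as.character(id), seq = seq)
  if (!is.null(structure)) {
    stopifnot(length(structure) == length(seq))
    purrr::walk2(structure, seq, function(db, s) db_to_pairs(db))
    out$structure <- structure
  }
  out
}

check_seq_tbl <- function(data, need_structure = FALSE) {
  if (!is.data.frame(data) || !all(c("id", "seq") %in% names(data)))
    abort("`data` must be a data frame with `id` and `seq` columns")
  if (nrow(data) == 0) abort("`data` has no sequences")
  if (need_structure && !"structure" %in% names(data))
    abort("`data` must have a `structure` column of dot-bracket strings")
  invisible(data)
}

# --------------------------------------------------------- structures --

#' Convert between dot-bracket strings and base-pair tables
#'
#' `db_to_pairs()` parses a dot-bracket string into an integer matrix
#' with columns `i`, `j` (1-based, `i < j`).  Only `(`, `)` and `.` are
#' accepted; pseudoknot bracket layers (`[`, `{`, `<`) are rejected
#' because context-free grammars cannot represent crossing pairs.
#' `pairs_to_db()` is the inverse.
#'
#' @param db A dot-bracket string.
#' @return For `db_to_pairs()`, an integer matrix of pairs; for
#'   `pairs_to_db()`, a dot-bracket string.
#' @export
db_to_pairs <- function(db) {
  chars <- strsplit(db, "")[[1]]
  if (any(chars %in% c("[", "]", "{", "}", "<", ">")))
    abort("pseudoknot bracket layers ([, {, <) are not representable by these grammars")
  bad <- setdiff(unique(chars), c("(", ")", "."))
  if (length(bad) > 0)
    abort(paste0("invalid dot-bracket character(s): ", paste(bad, collapse = ", ")))
  open <- integer(0)
  pairs <- matrix(integer(0), 0, 2)
  for (pos in seq_along(chars)) {
    if (chars[pos] == "(") open <- c(open, pos)
    else if (chars[pos] == ")") {
      if (length(open) == 0)
        abort(paste0("unbalanced ')' at position ", pos))
      pairs <- rbind(pairs, c(open[length(open)], pos))
      open <- open[-length(open)]
    }
  }
  if (length(open) > 0)
    abort(paste0("unbalanced '(' at position ", open[1]))
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  colnames(pairs) <- c("i", "j")
  storage.mode(pairs) <- "integer"
  pairs
}

#' @rdname db_to_pairs
#' @param pairs An integer matrix of 1-based pairs (columns i, j).
#' @param n Sequence length.
#' @export
pairs_to_db <- function(pairs, n) {
  chars <- rep(".", n)
  if (length(pairs) > 0) {
    validate_structure(pairs, n)
    chars[pairs[, 1]] <- "("
    chars[pairs[, 2]] <- ")"
  }
  paste(chars, collapse = "")
}

#' Validate a base-pair set
#'
#' Checks that indices lie in `[1, n]`, each position appears in at most
#' one pair, and pairs are nested (no crossing `i < k < j < l`).
#'
#' @param pairs Integer matrix of 1-based pairs.
#' @param n Sequence length.
#' @return `pairs` (with i < j enforced), invisibly; errors otherwise.
#' @export
validate_structure <- function(pairs, n) {
  if (length(pairs) == 0) return(invisible(matrix(integer(0), 0, 2)))
  pairs <- matrix(as.integer(pairs), ncol = 2)
  pairs <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  if (any(pairs < 1) || any(pairs > n))
    abort(paste0("pair index out of range 1..", n))
  if (any(pairs[, 1] == pairs[, 2]))
    abort("a position cannot pair with itself")
  idx <- as.vector(pairs)
  if (anyDuplicated(idx))
    abort(paste0("position ", idx[duplicated(idx)][1],
                 " appears in more than one pair"))
  if (nrow(pairs) > 1) {
    for (r in seq_len(nrow(pairs) - 1)) {
      a <- pairs[r, ]
      rest <- pairs[(r + 1):nrow(pairs), , drop = FALSE]
      crossing <- (rest[, 1] < a[1] & a[1] < rest[, 2] & rest[, 2] < a[2]) |
                  (a[1] < rest[, 1] & rest[, 1] < a[2] & a[2] < rest[, 2])
      if (any(crossing))
        abort(paste0("pairs (", a[1], ",", a[2], ") and (",
                     rest[crossing, 1][1], ",", rest[crossing, 2][1],
                     ") cross; structure is not nested"))
    }
  }
  invisible(pairs)
}
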