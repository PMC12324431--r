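# File I/O: FASTA (via Biostrings), dot-bracket, and CT.

#' Read and write FASTA sequence files
#'
#' `read_fasta()` parses a FASTA file into the package's standard
#' sequence tibble, mapping T to U.  Records containing degenerate
#' IUPAC codes (N, R, Y, ...) are dropped with a warning by default,
#' since the grammars assign them no emission probability; set
#' `degenerate = "error"` to fail instead.  Duplicate ids are an error.
#'
#' @param path File path.
#' @param degenerate `"drop"` (default) or `"error"`.
#' @return A tibble with `id` and `seq` columns.
#' @export
read_fasta <- function(path, degenerate = c("drop", "error")) {
  degenerate <- match.arg(degenerate)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) abort(paste0("no FASTA records in ", path))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    abort(paste0("duplicate FASTA id: ", ids[duplicated(ids)][1]))
  seqs <- toupper(as.character(set))
  seqs <- chartr("T", "U", seqs)
  ok <- !grepl("[^ACGU]", seqs)
  if (any(!ok)) {
    if (degenerate == "error")
      abort(paste0("record '", ids[!ok][1], "' contains non-ACGU residues"))
    warn(paste0("dropping ", sum(!ok),
                " record(s) with degenerate residues: ",
                paste(utils::head(ids[!ok], 5), collapse = ", ")))
    seqs <- seqs[ok]; ids <- ids[ok]
    if (length(seqs) == 0) abort("all records were degenerate")
  }
  rna_tbl(unname(seqs), id = ids)
}

#' @rdname read_fasta
#' @param data A data frame with `id` and `seq` columns.
#' @export
write_fasta <- function(data, path) {
  check_seq_tbl(data)
  set <- Biostrings::BStringSet(data$seq)
  names(set) <- data$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read and write dot-bracket structure files
#'
#' The dot-bracket format used here is FASTA-like: a `>id` header line,
#' the sequence line, then the structure line of equal length using
#' only `(`, `)` and `.`.  Unbalanced brackets, pseudoknot bracket
#' layers, length mismatches and duplicate ids are errors reported with
#' the offending line number.
#'
#' @param path File path.
#' @return A tibble with `id`, `seq` and `structure` columns.
#' @export
read_dotbracket <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0 || length(lines) %% 3 != 0)
    abort(paste0(path, ": expected records of 3 lines (>id / seq / structure)"))
  ids <- character(0); seqs <- character(0); dbs <- character(0)
  for (r in seq_len(length(lines) / 3)) {
    ln <- (r - 1) * 3 + 1
    hdr <- lines[ln]
    if (!startsWith(hdr, ">"))
      abort(paste0(path, " line ", ln, ": expected '>' header, got: ", hdr))
    id <- sub("\\s.*$", "", sub("^>", "", hdr))
    sq <- toupper(trimws(lines[ln + 1]))
    db <- trimws(lines[ln + 2])
    if (nchar(sq) != nchar(db))
      abort(paste0(path, " line ", ln + 2, ": structure length ", nchar(db),
                   " does not match sequence length ", nchar(sq)))
    tryCatch(db_to_pairs(db), error = function(e) {
      abort(paste0(path, " line ", ln + 2, ": ", conditionMessage(e)))
    })
    ids <- c(ids, id); seqs <- c(seqs, sq); dbs <- c(dbs, db)
  }
  if (anyDuplicated(ids))
    abort(paste0(path, ": duplicate id: ", ids[duplicated(ids)][1]))
  rna_tbl(seqs, id = ids, structure = dbs)
}

#' @rdname read_dotbracket
#' @param data A data frame with `id`, `seq` and `structure` columns.
#' @export
write_dotbracket <- function(data, path) {
  check_seq_tbl(data, need_structure = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  for (r in seq_len(nrow(data)))
    writeLines(c(paste0(">", data$id[r]), data$seq[r], data$structure[r]),
               con)
  invisible(path)
}

#' Read and write CT (connectivity table) structure files
#'
#' The classic 6-column, 1-based CT layout: a header line
#' `<n> <id>` followed by n rows of
#' `index base index-1 index+1 pairing-partner index` (partner 0 for
#' unpaired).  Multiple concatenated records are supported.  Index
#' inconsistencies and non-reciprocal partners are errors with line
#' numbers.
#'
#' @param path File path.
#' @return A tibble with `id`, `seq` and `structure` columns.
#' @export
read_ct <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  ids <- character(0); seqs <- character(0); dbs <- character(0)
  ln <- 1L
  while (ln <= length(lines)) {
    hdr <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    n <- suppressWarnings(as.integer(hdr[1]))
    if (is.na(n) || n < 1)
      abort(paste0(path, " line ", ln, ": expected record header '<n> <id>'"))
    id <- if (length(hdr) >= 2) hdr[2] else paste0("ct", length(ids) + 1)
    if (ln + n > length(lines))
      abort(paste0(path, " line ", ln, ": record claims ", n,
                   " residues but file ends early"))
    base <- character(n); partner <- integer(n)
    for (k in seq_len(n)) {
      row <- strsplit(trimws(lines[ln + k]), "\\s+")[[1]]
      if (length(row) < 6)
        abort(paste0(path, " line ", ln + k, ": expected 6 CT columns"))
      idx <- as.integer(row[1])
      if (is.na(idx) || idx != k)
        abort(paste0(path, " line ", ln + k, ": residue index ", row[1],
                     " out of order (expected ", k, ")"))
      base[k] <- row[2]
      partner[k] <- as.integer(row[5])
    }
    if (any(partner < 0 | partner > n))
      abort(paste0(path, ": pairing partner out of range in record '", id, "'"))
    for (k in seq_len(n))
      if (partner[k] != 0 && partner[partner[k]] != k)
        abort(paste0(path, ": non-reciprocal pair ", k, "-", partner[k],
                     " in record '", id, "'"))
    pr <- which(partner > seq_len(n))
    pairs <- cbind(pr, partner[pr])
    ids <- c(ids, id)
    seqs <- c(seqs, paste(base, collapse = ""))
    dbs <- c(dbs, pairs_to_db(pairs, n))
    ln <- ln + n + 1L
  }
  if (anyDuplicated(ids))
    abort(paste0(path, ": duplicate id: ", ids[duplicated(ids)][1]))
  rna_tbl(seqs, id = ids, structure = dbs)
}

#' @rdname read_ct
#' @param data A data frame with `id`, `seq` and `structure` columns.
#' @export
write_ct <- function(data, path) {
  check_seq_tbl(data, need_structure = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  for (r in seq_len(nrow(data))) {
    sq <- strsplit(data$seq[r], "")[[1]]
    n <- length(sq)
    pairs <- db_to_pairs(data$structure[r])
    partner <- integer(n)
    if (length(pairs) > 0) {
      partner[pairs[, 1]] <- pairs[, 2]
      partner[pairs[, 2]] <- pairs[, 1]
    }
    writeLines(paste(n, data$id[r]), con)
    for (k in seq_len(n))
      writeLines(sprintf("%d %s %d %d %d %d", k, sq[k], k - 1L,
                         if (k == n) 0L else k + 1L, partner[k], k), con)
  }
  invisible(path)
}

#' @rdname read_dotbracket
#' @param format `"dotbracket"` or `"ct"`.
#' @export
read_structures <- function(path, format = c("dotbracket", "ct")) {
  format <- match.arg(format)
  if (format == "dotbracket") read_dotbracket(path) else read_ct(path)
}
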