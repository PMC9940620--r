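#' Read sequence pairs from a seq-pair text file
#'
#' The seq-pair format stores one pair per two lines: a query line
#' prefixed `>` immediately followed by a text line prefixed `<`. Line
#' terminators (LF or CRLF) are stripped; everything after the prefix is
#' the sequence, byte-exact.
#'
#' @param path Path to a seq-pair file.
#' @return A tibble with columns `id` (`pair_1`, `pair_2`, ...), `query`
#'   and `text`.
#' @examples
#' f <- tempfile()
#' writeLines(c(">TCTAGCG", "<TGGAAAG"), f)
#' read_seq_pairs(f)
#' @export
read_seq_pairs <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("seq-pair file '%s' does not exist", path), call. = FALSE)
  }
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  n <- length(lines)
  if (n %% 2L != 0L) {
    stop(sprintf("seq-pair file '%s': odd number of lines (%d); the last query line %d has no '<' line",
                 path, n, n), call. = FALSE)
  }
  if (n == 0L) {
    return(tibble(id = character(0), query = character(0), text = character(0)))
  }
  odd <- lines[seq(1L, n, by = 2L)]
  even <- lines[seq(2L, n, by = 2L)]
  bad_q <- which(substr(odd, 1L, 1L) != ">")
  if (length(bad_q) > 0L) {
    stop(sprintf("seq-pair file '%s': line %d must start with '>'",
                 path, 2L * bad_q[1L] - 1L), call. = FALSE)
  }
  bad_t <- which(substr(even, 1L, 1L) != "<")
  if (length(bad_t) > 0L) {
    stop(sprintf("seq-pair file '%s': line %d must start with '<'",
                 path, 2L * bad_t[1L]), call. = FALSE)
  }
  tibble(
    id = sprintf("pair_%d", seq_len(n %/% 2L)),
    query = substring(odd, 2L),
    text = substring(even, 2L)
  )
}

#' Write sequence pairs in seq-pair format
#'
#' @param pairs A data frame with columns `query` and `text` (e.g. from
#'   [generate_pairs()] or [read_seq_pairs()]).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_seq_pairs <- function(pairs, path) {
  stopifnot(is.data.frame(pairs), all(c("query", "text") %in% names(pairs)))
  lines <- character(2L * nrow(pairs))
  if (nrow(pairs) > 0L) {
    lines[seq(1L, length(lines), by = 2L)] <- paste0(">", pairs$query)
    lines[seq(2L, length(lines), by = 2L)] <- paste0("<", pairs$text)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read record-paired sequences from two FASTA files
#'
#' Record `i` of the query FASTA is paired with record `i` of the text
#' FASTA; multi-line sequences are concatenated and LF/CRLF both parse.
#' The two files must contain the same number of records.
#'
#' @param query_path,text_path Paths to the two FASTA files.
#' @return A tibble with columns `id` (query record header), `query`,
#'   `text`.
#' @export
read_fasta_pairs <- function(query_path, text_path) {
  q <- read_fasta(query_path)
  t <- read_fasta(text_path)
  if (nrow(q) != nrow(t)) {
    stop(sprintf("record count mismatch: '%s' has %d records but '%s' has %d",
                 query_path, nrow(q), text_path, nrow(t)), call. = FALSE)
  }
  tibble(id = q$id, query = q$seq, text = t$seq)
}

# Minimal FASTA reader via Biostrings when available, plain text otherwise.
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    set <- Biostrings::readBStringSet(path)
    return(tibble(id = names(set), seq = unname(as.character(set))))
  }
  lines <- sub("\r$", "", readLines(path))
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (length(lines) > 0L && !hdr[1L]) {
    stop(sprintf("FASTA file '%s': first line is not a header", path), call. = FALSE)
  }
  rec <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  seqs <- vapply(split(lines[!hdr], rec[!hdr]),
                 paste, collapse = "", FUN.VALUE = character(1))
  # records with no sequence lines
  out <- character(length(ids))
  out[as.integer(names(seqs))] <- seqs
  tibble(id = ids, seq = out)
}

#' Align a table of sequence pairs
#'
#' Applies an aligner to every row of a pairs table and returns a tidy
#' result table; designed to chain: `read_seq_pairs(f) |> align_pairs(pen)`.
#'
#' @param pairs A data frame with columns `query` and `text` (and
#'   optionally `id`).
#' @inheritParams wfa_align
#' @param mode `"biwfa"` (linear-space alignment, the default), `"wfa"`
#'   (full-memory unidirectional alignment) or `"score"` (bidirectional
#'   score only; no CIGAR).
#' @param oracle_check Re-align each pair with the Gotoh oracle and stop
#'   on any disagreement (quadratic memory; small inputs only).
#' @param antidiag_skip Passed to [biwfa_align()].
#' @return A tibble with one row per pair: `id`, `n`, `m`, `score`,
#'   `cigar`, `cells_computed`, `peak_live_cells`, `max_depth`.
#' @examples
#' pairs <- generate_pairs(3, 40, mutation_profile(0.1), seed = 1)
#' align_pairs(pairs, affine_penalties(4, 5, 1))
#' @export
align_pairs <- function(pairs, penalties, mode = c("biwfa", "wfa", "score"),
                        oracle_check = FALSE, antidiag_skip = TRUE) {
  stopifnot(is.data.frame(pairs), all(c("query", "text") %in% names(pairs)))
  mode <- match.arg(mode)
  penalties <- as_penalties(penalties)
  ids <- if ("id" %in% names(pairs)) as.character(pairs$id) else sprintf("pair_%d", seq_len(nrow(pairs)))
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    q <- pairs$query[[i]]
    t <- pairs$text[[i]]
    a <- switch(mode,
      biwfa = biwfa_align(q, t, penalties, antidiag_skip = antidiag_skip),
      wfa = wfa_align(q, t, penalties),
      score = new_alignment(biwfa_score(q, t, penalties, antidiag_skip = antidiag_skip),
                            "", list(cells_computed = NA_real_,
                                     peak_live_cells = NA_real_,
                                     max_depth = NA_integer_),
                            q, t, method = "biwfa.score")
    )
    if (oracle_check) {
      ref <- gotoh_align(q, t, penalties)
      if (ref$score != a$score) {
        stop(sprintf("oracle disagreement on pair '%s': %d (aligner) vs %d (Gotoh)",
                     ids[i], a$score, ref$score), call. = FALSE)
      }
    }
    tibble(
      id = ids[i], n = nchar(q), m = nchar(t),
      score = a$score, cigar = a$cigar,
      cells_computed = as.numeric(a$stats$cells_computed),
      peak_live_cells = as.numeric(a$stats$peak_live_cells),
      max_depth = if (is.null(a$stats$max_depth)) NA_integer_ else a$stats$max_depth
    )
  })
  if (length(rows) == 0L) {
    return(tibble(id = character(0), n = integer(0), m = integer(0),
                  score = integer(0), cigar = character(0),
                  cells_computed = numeric(0), peak_live_cells = numeric(0),
                  max_depth = integer(0)))
  }
  do.call(rbind, rows)
}

#' Write alignment results as TSV
#'
#' One row per pair with `id`, `score` and `cigar`; `verbose = TRUE` adds
#' the instrumentation counters. A header row is always included.
#'
#' @param results A result tibble from [align_pairs()].
#' @param path Output file path.
#' @param verbose Include counter columns?
#' @return The path, invisibly.
#' @export
write_alignment_tsv <- function(results, path, verbose = FALSE) {
  stopifnot(is.data.frame(results), all(c("id", "score", "cigar") %in% names(results)))
  cols <- c("id", "n", "m", "score", "cigar")
  if (verbose) cols <- c(cols, intersect(c("cells_computed", "peak_live_cells", "max_depth"), names(results)))
  cols <- intersect(cols, names(results))
  utils::write.table(results[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read back an alignment TSV, optionally re-checking scores
#'
#' @param path Path written by [write_alignment_tsv()].
#' @param penalties If supplied, every row with a non-empty CIGAR is
#'   re-scored with [score_of_cigar()] and a mismatch raises an error.
#' @return A tibble of the file's columns.
#' @export
read_alignment_tsv <- function(path, penalties = NULL) {
  df <- as_tibble(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                                    colClasses = "character"))
  if ("score" %in% names(df)) df$score <- as.integer(df$score)
  for (col in intersect(c("n", "m", "max_depth"), names(df))) df[[col]] <- as.integer(df[[col]])
  for (col in intersect(c("cells_computed", "peak_live_cells"), names(df))) df[[col]] <- as.numeric(df[[col]])
  if (!is.null(penalties) && all(c("score", "cigar") %in% names(df))) {
    penalties <- as_penalties(penalties)
    for (i in seq_len(nrow(df))) {
      if (!is.na(df$cigar[i]) && nzchar(df$cigar[i])) {
        rescored <- score_of_cigar(df$cigar[i], penalties)
        if (rescored != df$score[i]) {
          stop(sprintf("self-check failed at row %d ('%s'): score %d but CIGAR re-scores to %d",
                       i, df$id[i], df$score[i], rescored), call. = FALSE)
        }
      }
    }
  }
  df
}
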