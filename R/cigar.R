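#' CIGAR strings
#'
#' Alignments are reported as extended-CIGAR strings over the operations
#' `=` (match), `X` (mismatch), `I` (insertion: consumes one query
#' character per column) and `D` (deletion: consumes one text character
#' per column) — the SAM convention with the query playing the role of the
#' read and the text the reference. A canonical CIGAR has no zero-length
#' runs and no two adjacent runs with the same operation.
#'
#' @param cigar A single CIGAR string, e.g. `"1=2X1=2X1="`. The empty
#'   string is the CIGAR of the empty alignment.
#' @return `cigar_runs()` returns a tibble with columns `op` (character,
#'   one of `=`, `X`, `I`, `D`) and `length` (integer).
#' @examples
#' cigar_runs("1=2X1=2X1=")
#' score_of_cigar("1=2X1=2X1=", affine_penalties(4, 5, 1))
#' cigar_consumed("3=2I1D")
#' @name cigar
NULL

#' @rdname cigar
#' @export
cigar_runs <- function(cigar) {
  stopifnot(is.character(cigar), length(cigar) == 1L, !is.na(cigar))
  if (!nzchar(cigar)) {
    return(tibble(op = character(0), length = integer(0)))
  }
  tokens <- regmatches(cigar, gregexpr("[0-9]+[=XID]", cigar))[[1]]
  if (sum(nchar(tokens)) != nchar(cigar)) {
    stop("malformed CIGAR string: ", cigar, call. = FALSE)
  }
  tibble(
    op = substr(tokens, nchar(tokens), nchar(tokens)),
    length = as.integer(substr(tokens, 1L, nchar(tokens) - 1L))
  )
}

#' Assemble a CIGAR string from runs
#'
#' @param op Character vector of operations (`=`, `X`, `I`, `D`).
#' @param length Integer vector of run lengths (same length as `op`).
#' @return A single CIGAR string (not canonicalized).
#' @examples
#' cigar_string(c("=", "X"), c(3, 1))
#' @export
cigar_string <- function(op, length) {
  stopifnot(length(op) == length(length))
  if (length(op) == 0L) return("")
  stopifnot(all(op %in% c("=", "X", "I", "D")), all(length >= 0))
  paste0(as.integer(length), op, collapse = "")
}

#' Canonicalize a CIGAR string
#'
#' Drops zero-length runs and merges adjacent runs with the same
#' operation. Idempotent.
#'
#' @inheritParams cigar
#' @return A canonical CIGAR string.
#' @examples
#' canonicalize_cigar("1=2=0X3I3I")  # "3=6I"
#' @export
canonicalize_cigar <- function(cigar) {
  runs <- cigar_runs(cigar)
  runs <- runs[runs$length > 0L, ]
  if (nrow(runs) == 0L) return("")
  grp <- cumsum(c(TRUE, runs$op[-1L] != runs$op[-nrow(runs)]))
  op <- runs$op[!duplicated(grp)]
  len <- as.integer(tapply(runs$length, grp, sum))
  cigar_string(op, len)
}

#' Gap-affine score of a CIGAR string
#'
#' Sums `x` per mismatch column and `o + l * e` per maximal gap run of
#' length `l`; match columns are free. The CIGAR is canonicalized first so
#' that split gap runs are charged a single open.
#'
#' @inheritParams cigar
#' @param penalties An [affine_penalties()] object (or `(x, o, e)` triple).
#' @return A single integer score (>= 0).
#' @examples
#' score_of_cigar("1=2X1=2X1=", affine_penalties(4, 5, 1))  # 16
#' @export
score_of_cigar <- function(cigar, penalties) {
  penalties <- as_penalties(penalties)
  runs <- cigar_runs(canonicalize_cigar(cigar))
  if (nrow(runs) == 0L) return(0L)
  per_run <- ifelse(
    runs$op == "X", runs$length * penalties$x,
    ifelse(runs$op %in% c("I", "D"), penalties$o + runs$length * penalties$e, 0L)
  )
  as.integer(sum(per_run))
}

#' Query and text consumption of a CIGAR string
#'
#' `=` and `X` consume one character of each sequence per column; `I`
#' consumes query only; `D` consumes text only.
#'
#' @inheritParams cigar
#' @return A named integer vector `c(query = , text = )`.
#' @examples
#' cigar_consumed("3=2I1D")  # query 5, text 4
#' @export
cigar_consumed <- function(cigar) {
  runs <- cigar_runs(cigar)
  c(
    query = as.integer(sum(runs$length[runs$op %in% c("=", "X", "I")])),
    text = as.integer(sum(runs$length[runs$op %in% c("=", "X", "D")]))
  )
}
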