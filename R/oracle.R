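#' Gotoh dynamic-programming oracle
#'
#' Classical three-matrix dynamic program for gap-affine alignment
#' (quadratic time and memory). It is an independent implementation that
#' shares no code with the wavefront engines and serves as the ground
#' truth in the package's test suite; keep inputs modest (hundreds of
#' characters).
#'
#' Boundary components have the same meaning as in [wfa_align()]: an
#' alignment beginning at `I`/`D` starts inside a gap whose open cost is
#' already paid; ending at `I`/`D` reads the score off that matrix at
#' `(n, m)`. Traceback ties prefer the diagonal move over `I` over `D`.
#'
#' @inheritParams wfa_align
#' @return A `gotoh_alignment` object (also `wfa_alignment`) with `score`
#'   and `cigar`.
#' @examples
#' gotoh_align("TCTAGCG", "TGGAAAG", affine_penalties(4, 5, 1))$score  # 16
#' @export
gotoh_align <- function(query, text, penalties, begin = "M", end = "M") {
  query <- check_sequence(query, "query")
  text <- check_sequence(text, "text")
  penalties <- as_penalties(penalties)
  begin <- match.arg(begin, c("M", "I", "D"))
  end <- match.arg(end, c("M", "I", "D"))
  r <- .cpp_gotoh_align(query, text, penalties$x, penalties$o, penalties$e,
                        begin, end)
  new_alignment(r$score, r$cigar,
                stats = list(cells_computed = (nchar(query) + 1) * (nchar(text) + 1) * 3,
                             peak_live_cells = (nchar(query) + 1) * (nchar(text) + 1) * 3,
                             peak_live_wavefronts = NA_integer_),
                query, text, method = "gotoh", begin = begin, end = end,
                class = "gotoh_alignment")
}

#' Full Gotoh score matrices
#'
#' Returns the three `(n + 1) x (m + 1)` state matrices (`M`, `I`, `D`)
#' after closure, with `NA` for unreachable states — useful for visual
#' diffing against wavefront states on small instances.
#'
#' @inheritParams gotoh_align
#' @return A named list of three integer matrices.
#' @examples
#' gotoh_score_matrix("A", "C", affine_penalties(4, 5, 1))$M
#' @export
gotoh_score_matrix <- function(query, text, penalties, begin = "M") {
  query <- check_sequence(query, "query")
  text <- check_sequence(text, "text")
  penalties <- as_penalties(penalties)
  m <- .cpp_gotoh_matrices(query, text, penalties$x, penalties$o, penalties$e,
                           match.arg(begin, c("M", "I", "D")))
  dn <- list(
    c("", strsplit(query, "")[[1]]),
    c("", strsplit(text, "")[[1]])
  )
  lapply(m, function(M) { dimnames(M) <- dn; M })
}
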