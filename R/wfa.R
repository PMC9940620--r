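new_alignment <- function(score, cigar, stats, query, text, method,
                          begin = "M", end = "M", breakpoints = NULL,
                          class = character(0)) {
  structure(
    list(
      score = as.integer(score),
      cigar = cigar,
      stats = stats,
      query = query,
      text = text,
      method = method,
      begin = begin,
      end = end,
      breakpoints = breakpoints
    ),
    class = c(class, "wfa_alignment")
  )
}

#' Unidirectional wavefront alignment
#'
#' Standard wavefront alignment (WFA): computes partial optimal alignments
#' of increasing score `s` until one reaches the end of both sequences.
#' With `traceback = TRUE` every wavefront is retained (memory grows with
#' the square of the optimal score) and an optimal CIGAR is recovered by
#' backtrace; [biwfa_align()] produces the same result in memory
#' proportional to the score.
#'
#' The `begin` and `end` components select boundary conditions used by the
#' recursive bidirectional aligner: an alignment beginning (ending) at `I`
#' or `D` starts (ends) inside a gap whose open cost is accounted for on
#' the other side of the breakpoint.
#'
#' @param query,text Character scalars (any single-byte alphabet;
#'   comparison is byte-exact, no case folding).
#' @param penalties An [affine_penalties()] object or `(x, o, e)` triple.
#' @param begin,end Boundary component, one of `"M"`, `"I"`, `"D"`.
#' @param traceback Retain all wavefronts and emit a CIGAR?
#'
#' @return A `wfa_alignment` object: a list with `score` (integer), `cigar`
#'   (extended CIGAR string, `""` when `traceback = FALSE`), and `stats`
#'   (instrumentation counters: wavefront cells computed, peak live cells,
#'   peak simultaneously-live wavefronts).
#' @examples
#' pen <- affine_penalties(4, 5, 1)
#' wfa_align("TCTAGCG", "TGGAAAG", pen)
#' @seealso [biwfa_align()], [wfa_score()], [gotoh_align()]
#' @export
wfa_align <- function(query, text, penalties, begin = "M", end = "M",
                      traceback = TRUE) {
  query <- check_sequence(query, "query")
  text <- check_sequence(text, "text")
  penalties <- as_penalties(penalties)
  begin <- match.arg(begin, c("M", "I", "D"))
  end <- match.arg(end, c("M", "I", "D"))
  r <- .cpp_wfa_align(query, text, penalties$x, penalties$o, penalties$e,
                      comp_code(begin), comp_code(end), traceback)
  new_alignment(r$score, r$cigar, r$stats, query, text,
                method = "wfa", begin = begin, end = end)
}

#' Wavefront alignment score in O(s) memory per direction
#'
#' Same optimal score as [wfa_align()] but retaining only the last
#' `scope(penalties)` wavefronts; no traceback is possible.
#'
#' @inheritParams wfa_align
#' @return A single integer score.
#' @examples
#' wfa_score("TCTAGCG", "TGGAAAG", affine_penalties(4, 5, 1))  # 16
#' @export
wfa_score <- function(query, text, penalties, begin = "M", end = "M") {
  query <- check_sequence(query, "query")
  text <- check_sequence(text, "text")
  penalties <- as_penalties(penalties)
  r <- .cpp_wfa_score(query, text, penalties$x, penalties$o, penalties$e,
                      comp_code(match.arg(begin, c("M", "I", "D"))),
                      comp_code(match.arg(end, c("M", "I", "D"))))
  as.integer(r$score)
}

#' Greedy diagonal extension of wavefront offsets
#'
#' `wf_extend_forward()` advances each reachable offset by the length of
#' the longest common prefix of the remaining suffixes of `query` (from
#' `offset - k`) and `text` (from `offset`); `wf_extend_reverse()` pulls
#' each offset back by the longest common suffix of the prefixes up to the
#' offset. Offsets are given for consecutive diagonals `k = lo, lo + 1,
#' ...`; `NA` marks an unreachable diagonal and is left untouched.
#'
#' These are the extension primitives of the wavefront engines, exposed
#' for inspection and testing.
#'
#' @inheritParams wfa_align
#' @param offsets Integer vector of M-component offsets (`NA` =
#'   unreachable).
#' @param lo Diagonal of `offsets[1]`.
#' @return Integer vector of extended offsets.
#' @examples
#' wf_extend_forward("TCTAGCG", "TGGAAAG", offsets = 0L, lo = 0L)  # 1
#' @export
wf_extend_forward <- function(query, text, offsets, lo = 0L) {
  query <- check_sequence(query, "query")
  text <- check_sequence(text, "text")
  .cpp_wf_extend_forward(query, text, as.integer(lo), as.integer(offsets))
}

#' @rdname wf_extend_forward
#' @export
wf_extend_reverse <- function(query, text, offsets, lo = 0L) {
  query <- check_sequence(query, "query")
  text <- check_sequence(text, "text")
  .cpp_wf_extend_reverse(query, text, as.integer(lo), as.integer(offsets))
}

#' Inspect successive wavefronts
#'
#' Computes and returns every wavefront of a unidirectional run (forward
#' from the alignment start, or reverse from its end), each as a list of
#' components `M`, `I`, `D` with a diagonal range `[lo, hi]` and an offset
#' vector (`NA` = unreachable). Intended for step-level testing and
#' teaching; the aligners do not keep this structure.
#'
#' @inheritParams wfa_align
#' @param max_score Stop after this score even if the end was not reached
#'   (`-1` = run to completion).
#' @return A list of wavefronts, element `s + 1` holding score `s`.
#' @examples
#' w <- wavefronts_forward("TCTAGCG", "TGGAAAG", affine_penalties(4, 5, 1))
#' w[[1]]$M  # score-0 M component after extension
#' @export
wavefronts_forward <- function(query, text, penalties, begin = "M", end = "M",
                               max_score = -1L) {
  query <- check_sequence(query, "query")
  text <- check_sequence(text, "text")
  penalties <- as_penalties(penalties)
  .cpp_wavefronts_forward(query, text, penalties$x, penalties$o, penalties$e,
                          comp_code(match.arg(begin, c("M", "I", "D"))),
                          comp_code(match.arg(end, c("M", "I", "D"))),
                          as.integer(max_score))
}

#' @rdname wavefronts_forward
#' @export
wavefronts_reverse <- function(query, text, penalties, begin = "M", end = "M",
                               max_score = -1L) {
  query <- check_sequence(query, "query")
  text <- check_sequence(text, "text")
  penalties <- as_penalties(penalties)
  .cpp_wavefronts_reverse(query, text, penalties$x, penalties$o, penalties$e,
                          comp_code(match.arg(begin, c("M", "I", "D"))),
                          comp_code(match.arg(end, c("M", "I", "D"))),
                          as.integer(max_score))
}

#' @export
print.wfa_alignment <- function(x, ...) {
  cat(sprintf("<%s alignment>\n", x$method))
  cat(sprintf("  query: %d chars, text: %d chars\n", nchar(x$query), nchar(x$text)))
  cat(sprintf("  score: %d\n", x$score))
  if (nzchar(x$cigar) || (nchar(x$query) == 0 && nchar(x$text) == 0)) {
    cat(sprintf("  cigar: %s\n", if (nzchar(x$cigar)) x$cigar else "(empty)"))
  }
  cat(sprintf("  cells computed: %s, peak live cells: %s\n",
              format(x$stats$cells_computed, big.mark = ","),
              format(x$stats$peak_live_cells, big.mark = ",")))
  invisible(x)
}
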