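#' Bidirectional wavefront alignment (linear-space)
#'
#' Runs wavefronts forward from the alignment start and reverse from its
#' end, strictly alternating single score increments and keeping only the
#' last `p = scope(penalties)` wavefronts per direction. When the two
#' searches overlap on a diagonal, the meeting cell is a breakpoint of an
#' optimal alignment with total score `sf + sr` (`sf + sr - o` when the
#' breakpoint lies on an indel component, since both directions pay the
#' open of the same gap). The problem is then split at the breakpoint and
#' both halves are solved recursively; sub-problems below a small size (or
#' score) threshold are solved directly by [wfa_align()] with traceback.
#' Working memory is proportional to the optimal score.
#'
#' @inheritParams wfa_align
#' @param antidiag_skip Skip overlap checks while the farthest forward
#'   antidiagonal lies strictly before the farthest-back reverse
#'   antidiagonal (a conservative shortcut; results are identical).
#'
#' @return A `biwfa_alignment` object (also of class `wfa_alignment`):
#'   `score`, `cigar`, `stats` (cells computed, peak live cells, peak live
#'   wavefronts per direction, overlap-call counters, recursion depth),
#'   and `breakpoints` — a tibble with one row per recursion node holding
#'   `depth`, `sf`, `sr`, `total` and `component`.
#' @examples
#' pen <- affine_penalties(4, 5, 1)
#' aln <- biwfa_align("TCTAGCG", "TGGAAAG", pen)
#' aln$score          # 16
#' aln$cigar          # "1=2X1=2X1="
#' @seealso [biwfa_score()], [find_breakpoint()], [wfa_align()]
#' @export
biwfa_align <- function(query, text, penalties, antidiag_skip = TRUE) {
  query <- check_sequence(query, "query")
  text <- check_sequence(text, "text")
  penalties <- as_penalties(penalties)
  r <- .cpp_biwfa_align(query, text, penalties$x, penalties$o, penalties$e,
                        isTRUE(antidiag_skip))
  comps <- c("M", "I", "D")
  bp <- tibble(
    depth = r$nodes$depth,
    sf = r$nodes$sf,
    sr = r$nodes$sr,
    total = as.integer(r$nodes$total),
    component = comps[r$nodes$component + 1L]
  )
  new_alignment(r$score, r$cigar, r$stats, query, text,
                method = "biwfa", breakpoints = bp, class = "biwfa_alignment")
}

#' Optimal score via the bidirectional search only
#'
#' Runs a single breakpoint search and returns its total; no recursion and
#' no CIGAR. Memory is bounded by the two wavefront windows.
#'
#' @inheritParams biwfa_align
#' @return A single integer score.
#' @examples
#' biwfa_score("TCTAGCG", "TGGAAAG", affine_penalties(4, 5, 1))  # 16
#' @export
biwfa_score <- function(query, text, penalties, antidiag_skip = TRUE) {
  query <- check_sequence(query, "query")
  text <- check_sequence(text, "text")
  penalties <- as_penalties(penalties)
  r <- .cpp_biwfa_score(query, text, penalties$x, penalties$o, penalties$e,
                        isTRUE(antidiag_skip))
  as.integer(r$score)
}

#' Find a score-balanced breakpoint of an optimal alignment
#'
#' The core of the bidirectional aligner, exposed directly: alternate
#' forward and reverse wavefronts until an overlap proves a breakpoint of
#' minimum total score. The returned breakpoint satisfies
#' `abs(sf - sr) <= scope(penalties)` and `total == sf + sr` on the M
#' component or `total == sf + sr - o` on I/D.
#'
#' @inheritParams wfa_align
#' @inheritParams biwfa_align
#' @return A list of class `wfa_breakpoint`: `sf`, `sr`, `k` (diagonal),
#'   `offset` (text position; the cell is `(offset - k, offset)`),
#'   `component`, `total`, and `stats` from the search.
#' @examples
#' find_breakpoint("TCTAGCG", "TGGAAAG", affine_penalties(4, 5, 1))
#' @export
find_breakpoint <- function(query, text, penalties, begin = "M", end = "M",
                            antidiag_skip = TRUE) {
  query <- check_sequence(query, "query")
  text <- check_sequence(text, "text")
  if (nchar(query) + nchar(text) == 0L) {
    stop("breakpoint search requires at least one non-empty sequence", call. = FALSE)
  }
  penalties <- as_penalties(penalties)
  r <- .cpp_find_breakpoint(query, text, penalties$x, penalties$o, penalties$e,
                            comp_code(match.arg(begin, c("M", "I", "D"))),
                            comp_code(match.arg(end, c("M", "I", "D"))),
                            isTRUE(antidiag_skip))
  r$total <- as.integer(r$total)
  structure(r, class = "wfa_breakpoint")
}

#' @export
print.wfa_breakpoint <- function(x, ...) {
  cat(sprintf(
    "<breakpoint> total %d = sf %d + sr %d%s at component %s, cell (%d, %d) [diagonal %d]\n",
    x$total, x$sf, x$sr,
    if (x$component == "M") "" else " - o",
    x$component, x$offset - x$k, x$offset, x$k
  ))
  invisible(x)
}
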