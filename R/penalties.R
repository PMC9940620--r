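#' Gap-affine penalty set
#'
#' Scoring model in which a match costs 0, a mismatch costs `x`, and a gap
#' of length `l` costs `o + l * e`. All penalties are non-negative
#' integers; `x` and `e` must be strictly positive so that every non-match
#' operation has positive cost.
#'
#' @param x Mismatch cost (integer, >= 1).
#' @param o Gap-open cost (integer, >= 0).
#' @param e Gap-extend cost, per gap character (integer, >= 1).
#'
#' @return An object of class `affine_penalties`: a named list with fields
#'   `x`, `o`, `e`.
#' @examples
#' pen <- affine_penalties(x = 4, o = 5, e = 1)
#' scope(pen)  # max(x, o + e) = 6
#' @export
affine_penalties <- function(x, o, e) {
  check_count <- function(v, name, min) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v != as.integer(v) || v < min) {
      stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
    }
    as.integer(v)
  }
  structure(
    list(
      x = check_count(x, "x", 1L),
      o = check_count(o, "o", 0L),
      e = check_count(e, "e", 1L)
    ),
    class = "affine_penalties"
  )
}

#' Wavefront scope of a penalty set
#'
#' The scope `p = max(x, o + e)` is the number of previous wavefronts a new
#' wavefront depends on, and the width (in score) of the window used when
#' testing forward/reverse overlaps in the bidirectional search.
#'
#' @param penalties An [affine_penalties()] object.
#' @return A single integer, `max(x, o + e)`.
#' @examples
#' scope(affine_penalties(4, 5, 1))
#' @export
scope <- function(penalties) {
  penalties <- as_penalties(penalties)
  max(penalties$x, penalties$o + penalties$e)
}

# Accept an affine_penalties object or a plain length-3 vector/list (x, o, e).
as_penalties <- function(penalties) {
  if (inherits(penalties, "affine_penalties")) return(penalties)
  if (is.numeric(penalties) && length(penalties) == 3L) {
    return(affine_penalties(penalties[[1]], penalties[[2]], penalties[[3]]))
  }
  if (is.list(penalties) && all(c("x", "o", "e") %in% names(penalties))) {
    return(affine_penalties(penalties$x, penalties$o, penalties$e))
  }
  stop("`penalties` must be an affine_penalties object or a numeric (x, o, e) triple",
       call. = FALSE)
}

#' @export
print.affine_penalties <- function(x, ...) {
  cat(sprintf(
    "Gap-affine penalties: mismatch x = %d, gap open o = %d, gap extend e = %d (scope p = %d)\n",
    x$x, x$o, x$e, scope(x)
  ))
  invisible(x)
}

check_sequence <- function(s, name) {
  if (!is.character(s) || length(s) != 1L || is.na(s)) {
    stop(sprintf("`%s` must be a single (possibly empty) string", name), call. = FALSE)
  }
  if (grepl("[\r\n]", s)) {
    stop(sprintf("`%s` must not contain newline characters", name), call. = FALSE)
  }
  s
}

comp_code <- function(component) {
  component <- match.arg(component, c("M", "I", "D"))
  c(M = 0L, I = 1L, D = 2L)[[component]]
}
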