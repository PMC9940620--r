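#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an alignment into per-run coordinates
#'
#' One row per CIGAR run with its operation, length and 0-based start
#' positions in query (`v`) and text (`h`).
#'
#' @param x A `wfa_alignment` (from [wfa_align()], [biwfa_align()] or
#'   [gotoh_align()]).
#' @param ... Unused.
#' @return A tibble with columns `op`, `length`, `v`, `h`.
#' @export
tidy.wfa_alignment <- function(x, ...) {
  runs <- cigar_runs(x$cigar)
  dq <- ifelse(runs$op %in% c("=", "X", "I"), runs$length, 0L)
  dt <- ifelse(runs$op %in% c("=", "X", "D"), runs$length, 0L)
  runs$v <- as.integer(cumsum(c(0L, dq))[seq_len(nrow(runs))])
  runs$h <- as.integer(cumsum(c(0L, dt))[seq_len(nrow(runs))])
  runs
}

#' One-row summary of an alignment
#'
#' @inheritParams tidy.wfa_alignment
#' @return A one-row tibble: `method`, `n`, `m`, `score`, `n_runs`,
#'   `cells_computed`, `peak_live_cells`, `max_depth`.
#' @export
glance.wfa_alignment <- function(x, ...) {
  tibble(
    method = x$method,
    n = nchar(x$query),
    m = nchar(x$text),
    score = x$score,
    n_runs = nrow(cigar_runs(x$cigar)),
    cells_computed = as.numeric(x$stats$cells_computed),
    peak_live_cells = as.numeric(x$stats$peak_live_cells),
    max_depth = if (is.null(x$stats$max_depth)) NA_integer_ else x$stats$max_depth
  )
}

#' Plot an alignment path through the dynamic-programming grid
#'
#' Draws the optimal alignment as a path from cell `(0, 0)` to `(n, m)`
#' with the text on the horizontal axis and the query (reversed) on the
#' vertical axis; segments are coloured by operation.
#'
#' @param object A `wfa_alignment` with a non-empty CIGAR.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wfa_alignment <- function(object, ...) {
  runs <- tidy(object)
  if (nrow(runs) == 0L) {
    stop("alignment has no CIGAR to plot (score-only result?)", call. = FALSE)
  }
  dq <- ifelse(runs$op %in% c("=", "X", "I"), runs$length, 0L)
  dt <- ifelse(runs$op %in% c("=", "X", "D"), runs$length, 0L)
  seg <- tibble(
    h = runs$h, v = runs$v,
    hend = runs$h + dt, vend = runs$v + dq,
    op = factor(runs$op, levels = c("=", "X", "I", "D"))
  )
  ggplot2::ggplot(seg) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$h, y = .data$v, xend = .data$hend, yend = .data$vend,
      colour = .data$op
    ), linewidth = 1) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_colour_manual(
      values = c(`=` = "grey40", X = "#d7301f", I = "#2b8cbe", D = "#31a354"),
      drop = FALSE
    ) +
    ggplot2::labs(
      x = "text position (h)", y = "query position (v)",
      colour = "op",
      title = sprintf("%s alignment, score %d", object$method, object$score)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
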