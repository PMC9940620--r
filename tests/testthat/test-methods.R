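test_that("tidy() lays out runs with cumulative coordinates", {
  a <- biwfa_align(fig_pair$q, fig_pair$t, fig_pen)
  td <- tidy(a)
  expect_identical(td$op, c("=", "X", "=", "X", "="))
  expect_identical(td$v, c(0L, 1L, 3L, 4L, 6L))
  expect_identical(td$h, td$v)  # no gaps in this alignment
})

test_that("glance() summarises score and instrumentation in one row", {
  a <- wfa_align(fig_pair$q, fig_pair$t, fig_pen)
  g <- glance(a)
  expect_identical(nrow(g), 1L)
  expect_identical(g$score, 16L)
  expect_identical(g$n, 7L)
  expect_identical(g$m, 7L)
  expect_gt(g$cells_computed, 0)
})

test_that("autoplot() builds a path plot over the DP grid", {
  a <- biwfa_align("TCTAGCG", "TGGAG", fig_pen)
  p <- autoplot(a)
  expect_s3_class(p, "ggplot")
  # a score-only result has no CIGAR to draw
  sc <- structure(list(cigar = "", score = 0L, method = "biwfa.score"),
                  class = "wfa_alignment")
  expect_error(autoplot(sc), "no CIGAR")
})
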