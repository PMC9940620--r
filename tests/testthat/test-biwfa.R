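test_that("the worked example yields the balanced 8 + 8 breakpoint", {
  bp <- find_breakpoint(fig_pair$q, fig_pair$t, fig_pen)
  expect_identical(bp$total, 16L)
  expect_identical(bp$sf, 8L)
  expect_identical(bp$sr, 8L)
  expect_identical(bp$component, "M")
  expect_lte(abs(bp$sf - bp$sr), scope(fig_pen))
  # the breakpoint cell lies inside the matrix
  v <- bp$offset - bp$k
  expect_true(v >= 0 && v <= nchar(fig_pair$q))
  expect_true(bp$offset >= 0 && bp$offset <= nchar(fig_pair$t))
})

test_that("identical sequences meet immediately with total 0", {
  bp <- find_breakpoint("ACGTACGT", "ACGTACGT", fig_pen)
  expect_identical(bp$total, 0L)
  expect_identical(bp$sf + bp$sr, 0L)
})

test_that("breakpoint totals equal the oracle score on tiny exhaustive instances", {
  strings <- all_strings(3)
  for (p in list(c(1, 1, 1), c(4, 5, 1))) {
    pen <- affine_penalties(p[1], p[2], p[3])
    for (q in strings) {
      for (t in strings) {
        if (nchar(q) + nchar(t) == 0) next
        expect_identical(
          find_breakpoint(q, t, pen)$total,
          gotoh_align(q, t, pen)$score
        )
      }
    }
  }
})

test_that("antidiagonal pruning is conservative: identical results with it on or off", {
  set.seed(301)
  for (i in 1:60) {
    pr <- random_pair(max_len = 150)
    p <- test_penalty_sets[[sample(length(test_penalty_sets), 1)]]
    pen <- affine_penalties(p[1], p[2], p[3])
    on <- find_breakpoint(pr$query, pr$text, pen, antidiag_skip = TRUE)
    off <- find_breakpoint(pr$query, pr$text, pen, antidiag_skip = FALSE)
    expect_identical(on$total, off$total)
    # the shortcut actually skips work on divergent pairs
    expect_lte(on$stats$overlap_calls, off$stats$overlap_calls)
  }
})

test_that("antidiagonal bounds of the first wavefronts match hand values", {
  # forward s=0 of the worked example reaches cell (1,1): antidiagonal 2;
  # reverse s=0 reaches cell (6,6): antidiagonal 12
  w <- wavefronts_forward(fig_pair$q, fig_pair$t, fig_pen, max_score = 0)
  expect_identical(2L * w[[1]]$M$offset - w[[1]]$M$lo, 2L)
  wr <- wavefronts_reverse(fig_pair$q, fig_pair$t, fig_pen, max_score = 0)
  expect_identical(2L * wr[[1]]$M$offset - wr[[1]]$M$lo, 12L)
})

test_that("biwfa_align solves the worked example and degenerate pairs", {
  a <- biwfa_align(fig_pair$q, fig_pair$t, fig_pen)
  expect_identical(a$score, 16L)
  expect_identical(a$cigar, "1=2X1=2X1=")
  expect_identical(biwfa_align("", "", fig_pen)$score, 0L)
  expect_identical(biwfa_align("", "", fig_pen)$cigar, "")
  expect_identical(biwfa_align("", "AAA", fig_pen)$score, 8L)
  expect_identical(biwfa_score("", "AAA", fig_pen), 8L)
})

test_that("biwfa agrees with oracle and full WFA on seeded random pairs", {
  set.seed(302)
  for (i in 1:120) {
    pr <- random_pair(max_len = 250)
    p <- test_penalty_sets[[sample(length(test_penalty_sets), 1)]]
    pen <- affine_penalties(p[1], p[2], p[3])
    g <- gotoh_align(pr$query, pr$text, pen)
    b <- biwfa_align(pr$query, pr$text, pen)
    expect_identical(b$score, g$score)
    expect_identical(biwfa_score(pr$query, pr$text, pen), g$score)
    expect_identical(score_of_cigar(b$cigar, pen), g$score)
    expect_identical(
      unname(cigar_consumed(b$cigar)),
      c(nchar(pr$query), nchar(pr$text))
    )
  }
})

test_that("a meeting inside a long gap applies the gap-open correction", {
  pen <- affine_penalties(4, 12, 1)
  q <- strrep("A", 30)
  t <- paste0(strrep("A", 15), strrep("T", 40), strrep("A", 15))
  g <- gotoh_align(q, t, pen)
  bp <- find_breakpoint(q, t, pen)
  # both directions pay the open of the same long insertion, so the
  # breakpoint must land on the I component and subtract o once
  expect_identical(bp$component, "I")
  expect_identical(bp$total, g$score)
  expect_identical(bp$total, bp$sf + bp$sr - 12L)
  b <- biwfa_align(q, t, pen)
  expect_identical(b$score, g$score)
  expect_identical(score_of_cigar(b$cigar, pen), g$score)
})

test_that("every recursion node is balanced and decays geometrically", {
  set.seed(303)
  n_nodes <- 0
  for (i in 1:40) {
    pr <- random_pair(max_len = 300)
    p <- test_penalty_sets[[sample(length(test_penalty_sets), 1)]]
    pen <- affine_penalties(p[1], p[2], p[3])
    b <- biwfa_align(pr$query, pr$text, pen)
    bps <- b$breakpoints
    n_nodes <- n_nodes + nrow(bps)
    if (nrow(bps) > 0) {
      expect_true(all(abs(bps$sf - bps$sr) <= scope(pen)))
      expect_true(all(pmax(bps$sf, bps$sr) <= 2 * bps$total / 3 + scope(pen)))
    }
    expect_lte(b$stats$max_depth, 4 * log2(b$score + 2) + 1)
  }
  expect_gt(n_nodes, 50)  # the recursion was actually exercised
})

test_that("the bidirectional search keeps at most scope + 1 wavefronts per direction", {
  set.seed(304)
  for (i in 1:20) {
    pr <- random_pair(max_len = 200)
    p <- test_penalty_sets[[sample(length(test_penalty_sets), 1)]]
    pen <- affine_penalties(p[1], p[2], p[3])
    bp <- find_breakpoint(pr$query, pr$text, pen)
    expect_lte(bp$stats$peak_live_wavefronts, scope(pen) + 1L)
  }
})
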