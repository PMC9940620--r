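test_that("Gotoh oracle solves the worked example and trivial cases", {
  expect_identical(gotoh_align(fig_pair$q, fig_pair$t, fig_pen)$score, 16L)
  expect_identical(gotoh_align("ACGT", "ACGT", fig_pen)$score, 0L)
  expect_identical(gotoh_align("AC", "", fig_pen)$score, 7L)  # o + 2e
  expect_identical(gotoh_align("", "", fig_pen)$score, 0L)
})

test_that("oracle CIGARs re-score to the oracle score and conserve lengths", {
  set.seed(101)
  for (i in 1:40) {
    pr <- random_pair(max_len = 120)
    p <- test_penalty_sets[[sample(length(test_penalty_sets), 1)]]
    pen <- affine_penalties(p[1], p[2], p[3])
    a <- gotoh_align(pr$query, pr$text, pen)
    expect_identical(score_of_cigar(a$cigar, pen), a$score)
    expect_identical(
      unname(cigar_consumed(a$cigar)),
      c(nchar(pr$query), nchar(pr$text))
    )
  }
})

test_that("oracle score is symmetric under swapping query and text", {
  set.seed(102)
  for (i in 1:25) {
    pr <- random_pair(max_len = 80)
    p <- test_penalty_sets[[sample(length(test_penalty_sets), 1)]]
    pen <- affine_penalties(p[1], p[2], p[3])
    expect_identical(
      gotoh_align(pr$query, pr$text, pen)$score,
      gotoh_align(pr$text, pr$query, pen)$score
    )
  }
})

test_that("score matrices expose the textbook state closure", {
  pen <- affine_penalties(4, 5, 1)
  m <- gotoh_score_matrix("A", "C", pen)
  expect_identical(m$M[2, 2], 4L)  # single mismatch
  expect_identical(m$M[1, 1], 0L)
  # after closure M <= I and M <= D wherever those states are reachable
  set.seed(103)
  for (i in 1:10) {
    pr <- random_pair(max_len = 40)
    mm <- gotoh_score_matrix(pr$query, pr$text, pen)
    ok_i <- is.na(mm$I) | mm$M <= mm$I
    ok_d <- is.na(mm$D) | mm$M <= mm$D
    expect_true(all(ok_i, na.rm = TRUE))
    expect_true(all(ok_d, na.rm = TRUE))
  }
})

test_that("matrix cell scores match the worked example's shaded values", {
  # recomputed: the optimal path of the worked example alternates matches
  # and mismatch pairs along the main diagonal
  m <- gotoh_score_matrix(fig_pair$q, fig_pair$t, fig_pen)
  diag_scores <- vapply(1:8, function(i) m$M[i, i], integer(1))
  expect_identical(diag_scores, c(0L, 0L, 4L, 8L, 8L, 12L, 16L, 16L))
})

test_that("boundary components steer the oracle's begin and end states", {
  pen <- affine_penalties(4, 5, 1)
  # beginning inside a gap pays extension only
  expect_identical(gotoh_align("", "AAA", pen, begin = "I")$score, 3L)
  # ending inside a gap still pays that gap's open
  expect_identical(gotoh_align("", "AAA", pen, end = "I")$score, 8L)
  expect_identical(gotoh_align("AAA", "", pen, begin = "D")$score, 3L)
  # infeasible boundary combination errors out
  expect_error(gotoh_align("", "", pen, end = "I"), "boundary")
})
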