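test_that("forward extension advances offsets by the LCP of the suffixes", {
  expect_identical(wf_extend_forward(fig_pair$q, fig_pair$t, 0L, lo = 0L), 1L)
  expect_identical(wf_extend_forward("ACGT", "ACGT", 0L, lo = 0L), 4L)
  expect_identical(wf_extend_forward("A", "C", 0L, lo = 0L), 0L)
  # NA marks an unreachable diagonal and is left untouched
  expect_identical(
    wf_extend_forward("ACGT", "ACGT", c(NA, 0L), lo = -1L),
    c(NA, 4L)
  )
})

test_that("reverse extension pulls offsets back by the LCS of the prefixes", {
  expect_identical(wf_extend_reverse(fig_pair$q, fig_pair$t, 7L, lo = 0L), 6L)
  expect_identical(wf_extend_reverse("ACGT", "ACGT", 4L, lo = 0L), 0L)
  expect_identical(wf_extend_reverse("A", "C", 1L, lo = 0L), 1L)
})

test_that("extension is idempotent", {
  set.seed(201)
  for (i in 1:20) {
    pr <- random_pair(max_len = 60)
    off <- wf_extend_forward(pr$query, pr$text, 0L, lo = 0L)
    expect_identical(wf_extend_forward(pr$query, pr$text, off, lo = 0L), off)
    m <- nchar(pr$text)
    offr <- wf_extend_reverse(pr$query, pr$text, m,
                              lo = m - nchar(pr$query))
    expect_identical(
      wf_extend_reverse(pr$query, pr$text, offr, lo = m - nchar(pr$query)),
      offr
    )
  }
})

test_that("successive wavefronts follow the base case and gap recurrences", {
  pen <- affine_penalties(4, 5, 1)
  # scores below min(x, o + e) have no reachable cell beyond the base
  w <- wavefronts_forward("A", "C", pen)
  expect_length(w, 5)  # scores 0..4
  for (s in 2:4) expect_true(is.na(w[[s]]$M$lo))
  # the mismatch at s = x resolves the 1x1 instance
  expect_identical(w[[5]]$M$offset, 1L)
  expect_identical(wfa_score("A", "C", pen), 4L)
  # an empty query is closed by a text gap at s = o + l*e through the I
  # component (the text-consuming wavefront component)
  w2 <- wavefronts_forward("", "A", pen)
  expect_length(w2, 7)  # scores 0..6 = o + e
  expect_identical(w2[[7]]$I$offset, 1L)
  expect_identical(wfa_score("", "A", pen), 6L)
})

test_that("full WFA reproduces the worked example with its CIGAR", {
  a <- wfa_align(fig_pair$q, fig_pair$t, fig_pen)
  expect_identical(a$score, 16L)
  expect_identical(a$cigar, "1=2X1=2X1=")
  expect_identical(wfa_align("ACGTACGT", "ACGTACGT", fig_pen)$cigar, "8=")
  expect_identical(wfa_align("", "AAA", fig_pen)$score, 8L)
  expect_identical(wfa_align("", "", fig_pen)$score, 0L)
  expect_identical(wfa_align("", "", fig_pen)$cigar, "")
})

test_that("score-only mode matches full WFA while keeping scope wavefronts", {
  set.seed(202)
  for (i in 1:30) {
    pr <- random_pair(max_len = 150)
    p <- test_penalty_sets[[sample(length(test_penalty_sets), 1)]]
    pen <- affine_penalties(p[1], p[2], p[3])
    a <- wfa_align(pr$query, pr$text, pen, traceback = FALSE)
    s <- wfa_score(pr$query, pr$text, pen)
    expect_identical(s, a$score)
  }
  # the windowed engine never keeps more than scope + 1 wavefronts
  pr <- generate_pair(400, mutation_profile(0.2), seed = 7)
  st <- biwfa:::.cpp_wfa_score(pr$query, pr$text, 4L, 5L, 1L, 0L, 0L)$stats
  expect_lte(st$peak_live_wavefronts, scope(fig_pen) + 1L)
})

test_that("reverse/forward duality: reversing both sequences preserves scores", {
  set.seed(203)
  for (i in 1:50) {
    pr <- random_pair(max_len = 120)
    p <- test_penalty_sets[[sample(length(test_penalty_sets), 1)]]
    pen <- affine_penalties(p[1], p[2], p[3])
    rev1 <- paste(rev(strsplit(pr$query, "")[[1]]), collapse = "")
    rev2 <- paste(rev(strsplit(pr$text, "")[[1]]), collapse = "")
    expect_identical(wfa_score(pr$query, pr$text, pen), wfa_score(rev1, rev2, pen))
  }
})

test_that("reverse wavefronts realize the reverse recurrences' base case", {
  pen <- affine_penalties(4, 5, 1)
  # base X_{0, m-n} = m; after the longest-common-suffix extension of the
  # worked example (common 'G') the offset drops to 6
  w <- wavefronts_reverse(fig_pair$q, fig_pair$t, pen)
  expect_identical(w[[1]]$M$lo, 0L)
  expect_identical(w[[1]]$M$offset, 6L)
  # identical strings collapse to the origin at score 0
  w2 <- wavefronts_reverse("ACGT", "ACGT", pen)
  expect_identical(w2[[1]]$M$offset, 0L)
  # the 1x1 mismatch instance resolves in reverse at s = x
  w3 <- wavefronts_reverse("A", "C", pen)
  expect_length(w3, 5)
  expect_identical(w3[[5]]$M$offset, 0L)
})

test_that("unit-cost offsets are monotone across scores within a diagonal", {
  # with x = e = 1 every wavefront cell has a same-diagonal predecessor one
  # score back, so forward offsets never decrease (and reverse never
  # increase) as s grows; for x > 1 exact-score wavefronts may legally dip
  pen <- affine_penalties(1, 1, 1)
  set.seed(204)
  for (i in 1:10) {
    pr <- random_pair(max_len = 60)
    wfs <- wavefronts_forward(pr$query, pr$text, pen)
    best <- list()
    for (w in wfs) {
      b <- w$M
      if (is.na(b$lo)) next
      for (j in seq_along(b$offset)) {
        if (is.na(b$offset[j])) next
        key <- as.character(b$lo + j - 1L)
        if (!is.null(best[[key]])) expect_gte(b$offset[j], best[[key]])
        best[[key]] <- max(b$offset[j], best[[key]] %||% -1L)
      }
    }
  }
})

test_that("boundary components change begin/end states consistently with the oracle", {
  set.seed(205)
  comps <- c("M", "I", "D")
  n_checked <- 0
  for (i in 1:60) {
    pr <- random_pair(max_len = 60)
    p <- test_penalty_sets[[sample(length(test_penalty_sets), 1)]]
    pen <- affine_penalties(p[1], p[2], p[3])
    b <- sample(comps, 1)
    e <- sample(comps, 1)
    g <- tryCatch(gotoh_align(pr$query, pr$text, pen, begin = b, end = e),
                  error = function(err) NULL)
    if (is.null(g)) next
    n_checked <- n_checked + 1
    a <- wfa_align(pr$query, pr$text, pen, begin = b, end = e)
    expect_identical(a$score, g$score)
    expect_identical(
      unname(cigar_consumed(a$cigar)),
      c(nchar(pr$query), nchar(pr$text))
    )
  }
  expect_gt(n_checked, 30)
})
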