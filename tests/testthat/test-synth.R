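test_that("profile validation rejects inconsistent mixes", {
  expect_error(mutation_profile(0.1, mismatch = 0.5, insertion = 0.5, deletion = 0.5),
               "sum to 1")
  expect_error(mutation_profile(1.5), "error_rate")
  expect_error(mutation_profile(0.1, indel_mean = 0.5), "indel_mean")
})

test_that("degenerate profiles behave as documented", {
  p0 <- generate_pair(0, mutation_profile(0.5), seed = 1)
  expect_identical(p0$query, "")
  expect_identical(p0$text, "")
  # error rate 0: query is the text and the alignment is free
  p <- generate_pair(200, mutation_profile(0), seed = 2)
  expect_identical(p$query, p$text)
  expect_identical(p$n_events, 0L)
  expect_identical(gotoh_align(p$query, p$text, fig_pen)$score, 0L)
})

test_that("identical seed and profile give byte-identical pairs", {
  prof <- mutation_profile(0.15)
  a <- generate_pair(300, prof, seed = 42)
  b <- generate_pair(300, prof, seed = 42)
  expect_identical(a, b)
  d <- generate_pair(300, prof, seed = 43)
  expect_false(identical(a$query, d$query))
})

test_that("event counts track the binomial expectation", {
  prof <- mutation_profile(0.1)
  set.seed(401)
  counts <- vapply(1:40, function(i) generate_pair(1000, prof)$n_events, integer(1))
  # n_events ~ Binomial(1000, 0.1) less a small deletion-shadowing loss
  expect_gt(mean(counts), 100 - 4 * sqrt(1000 * 0.1 * 0.9))
  expect_lt(mean(counts), 100 + 4 * sqrt(1000 * 0.1 * 0.9))
})

test_that("mismatch-only error rate maps onto the expected alignment score", {
  # error 10%, mismatch-only, unit mismatch cost: oracle score per base
  # approaches the error rate (a mismatch can occasionally be beaten by a
  # gap pairing, so the score is at most the event count)
  prof <- mutation_profile(0.10, mismatch = 1, insertion = 0, deletion = 0)
  set.seed(402)
  L <- 1000
  scores <- vapply(1:50, function(i) {
    pr <- generate_pair(L, prof)
    gotoh_align(pr$query, pr$text, affine_penalties(1, 1, 1))$score
  }, integer(1))
  expected <- L * 0.10
  se <- sqrt(L * 0.10 * 0.90)
  expect_lt(abs(mean(scores) - expected), 3 * se / sqrt(50) + 0.01 * L)
  expect_lte(max(scores), expected + 5 * se)
})

test_that("generate_dataset writes deterministic, round-trippable seq-pair files", {
  prof <- mutation_profile(0.2)
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  generate_dataset(3, 50, prof, f1, seed = 9)
  generate_dataset(3, 50, prof, f2, seed = 9)
  expect_identical(readLines(f1), readLines(f2))
  lines <- readLines(f1)
  expect_length(lines, 6L)
  expect_true(all(substr(lines[c(1, 3, 5)], 1, 1) == ">"))
  expect_true(all(substr(lines[c(2, 4, 6)], 1, 1) == "<"))
  back <- read_seq_pairs(f1)
  pairs <- generate_pairs(3, 50, prof, seed = 9)
  expect_identical(back$query, pairs$query)
  expect_identical(back$text, pairs$text)
})
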