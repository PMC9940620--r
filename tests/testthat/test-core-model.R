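test_that("scope is max(x, o + e)", {
  expect_identical(scope(affine_penalties(4, 5, 1)), 6L)
  expect_identical(scope(affine_penalties(1, 0, 1)), 1L)
  expect_identical(scope(affine_penalties(2, 3, 2)), 5L)
})

test_that("penalty validation rejects non-positive mismatch/extend costs", {
  expect_error(affine_penalties(0, 5, 1), "x")
  expect_error(affine_penalties(4, -1, 1), "o")
  expect_error(affine_penalties(4, 5, 0), "e")
  expect_error(affine_penalties(1.5, 5, 1), "x")
})

test_that("score_of_cigar charges x per mismatch and o + l*e per gap run", {
  pen <- affine_penalties(4, 5, 1)
  expect_identical(score_of_cigar("1=2X1=2X1=", pen), 16L)
  expect_identical(score_of_cigar("500=", pen), 0L)
  expect_identical(score_of_cigar("3D", pen), 8L)   # o + 3e
  expect_identical(score_of_cigar("", pen), 0L)
  # a split gap is merged before scoring (one open)
  expect_identical(score_of_cigar("1I1I", pen), score_of_cigar("2I", pen))
})

test_that("canonicalize_cigar merges runs, drops zero runs and is idempotent", {
  expect_identical(canonicalize_cigar("1=2="), "3=")
  expect_identical(canonicalize_cigar(""), "")
  expect_identical(canonicalize_cigar("1I1D1I"), "1I1D1I")
  expect_identical(canonicalize_cigar("1=2=0X3I3I"), "3=6I")
  c1 <- canonicalize_cigar("2=0D2=5X0I5X")
  expect_identical(canonicalize_cigar(c1), c1)
})

test_that("score_of_cigar is invariant under canonicalization", {
  pen <- affine_penalties(3, 4, 2)
  for (cig in c("1=1=2X", "2=2X", "3I0D2I1=", "10D10D")) {
    expect_identical(score_of_cigar(cig, pen),
                     score_of_cigar(canonicalize_cigar(cig), pen))
  }
})

test_that("cigar_consumed splits query/text consumption by op", {
  expect_identical(cigar_consumed("3=2I1D"), c(query = 5L, text = 4L))
  expect_identical(cigar_consumed(""), c(query = 0L, text = 0L))
  expect_identical(cigar_consumed("2X"), c(query = 2L, text = 2L))
})

test_that("malformed CIGAR strings are rejected", {
  expect_error(cigar_runs("12"), "malformed")
  expect_error(cigar_runs("=3"), "malformed")
  expect_error(cigar_runs("3M"), "malformed")
})
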