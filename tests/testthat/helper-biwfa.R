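# Shared fixtures: the worked-example pair, the penalty sets used across
# the suite, and a seeded random-pair helper.

fig_pair <- list(q = "TCTAGCG", t = "TGGAAAG")
fig_pen <- affine_penalties(x = 4, o = 5, e = 1)

test_penalty_sets <- list(
  c(1, 1, 1),
  c(4, 5, 1),
  c(2, 0, 1),
  c(3, 4, 2)
)

# All strings over `alphabet` with lengths 0..max_len.
all_strings <- function(max_len, alphabet = c("A", "C")) {
  out <- ""
  for (L in seq_len(max_len)) {
    grid <- expand.grid(rep(list(alphabet), L), stringsAsFactors = FALSE)
    out <- c(out, apply(grid, 1, paste, collapse = ""))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_pair <- function(max_len = 300, max_error = 0.4) {
  L <- sample(10:max_len, 1)
  generate_pair(L, mutation_profile(stats::runif(1, 0, max_error)))
}
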