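#' Mutation profile for synthetic sequence pairs
#'
#' Describes how a query is derived from a random text: at each text
#' position an edit event occurs with probability `error_rate`; the event
#' is a mismatch, an insertion or a deletion according to the mix, and
#' indel lengths follow a geometric distribution with the given mean
#' (support >= 1). The defaults — half mismatches, a quarter insertions,
#' a quarter deletions, mean indel length 2 — emulate a generic
#' moderately indel-rich read simulator.
#'
#' @param error_rate Per-base event probability in `[0, 1]`.
#' @param mismatch,insertion,deletion Event mix; must sum to 1.
#' @param indel_mean Mean indel length (>= 1); lengths are
#'   `1 + Geometric(1 / indel_mean)`.
#' @param alphabet Character vector of single characters.
#' @return A `mutation_profile` object.
#' @examples
#' mutation_profile(0.10)
#' @export
mutation_profile <- function(error_rate, mismatch = 0.5, insertion = 0.25,
                             deletion = 0.25, indel_mean = 2,
                             alphabet = c("A", "C", "G", "T")) {
  stopifnot(
    is.numeric(error_rate), length(error_rate) == 1L,
    error_rate >= 0, error_rate <= 1
  )
  mix <- c(mismatch = mismatch, insertion = insertion, deletion = deletion)
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8) {
    stop("mismatch, insertion and deletion probabilities must be >= 0 and sum to 1",
         call. = FALSE)
  }
  stopifnot(is.numeric(indel_mean), indel_mean >= 1)
  stopifnot(is.character(alphabet), length(alphabet) >= 2L, all(nchar(alphabet) == 1L))
  structure(
    list(error_rate = error_rate, mix = mix, indel_mean = indel_mean,
         alphabet = alphabet),
    class = "mutation_profile"
  )
}

#' @export
print.mutation_profile <- function(x, ...) {
  cat(sprintf(
    "Mutation profile: error rate %.3g (mismatch %.2f, insertion %.2f, deletion %.2f), mean indel length %.3g, alphabet {%s}\n",
    x$error_rate, x$mix[["mismatch"]], x$mix[["insertion"]], x$mix[["deletion"]],
    x$indel_mean, paste(x$alphabet, collapse = ",")
  ))
  invisible(x)
}

# Run code under a temporary RNG state seeded with `seed` (NULL = use the
# current stream).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      stats::runif(1)
    }
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  code
}

#' Generate one mutated sequence pair
#'
#' Draws a uniform random text of the requested length over the profile's
#' alphabet, then applies the profile's edits to derive the query.
#' Mismatches substitute a different character (so they are guaranteed to
#' be mismatches); insertions add random characters to the query before
#' the current text position; deletions skip a run of text characters. An
#' event whose text was removed by an earlier deletion is dropped. The
#' number of applied events is recorded.
#'
#' @param length Text length (>= 0).
#' @param profile A [mutation_profile()].
#' @param seed Optional integer; identical seed and profile give
#'   byte-identical output.
#' @return A `seq_pair` object: list with `query`, `text`, `n_events`.
#' @examples
#' p <- generate_pair(50, mutation_profile(0.1), seed = 1)
#' nchar(p$text)
#' @export
generate_pair <- function(length, profile, seed = NULL) {
  stopifnot(is.numeric(length), length(length) == 1L, length >= 0)
  stopifnot(inherits(profile, "mutation_profile"))
  length <- as.integer(length)
  with_seed(seed, {
    t_chars <- if (length > 0L) sample(profile$alphabet, length, replace = TRUE) else character(0)
    text <- paste(t_chars, collapse = "")
    if (length == 0L) {
      return(structure(list(query = "", text = "", n_events = 0L),
                       class = "seq_pair"))
    }
    ev <- which(stats::runif(length) < profile$error_rate)
    types <- if (length(ev) > 0L) {
      sample(names(profile$mix), length(ev), replace = TRUE, prob = profile$mix)
    } else {
      character(0)
    }
    geom_len <- function() 1L + stats::rgeom(1L, prob = 1 / profile$indel_mean)
    pieces <- character(0)
    cursor <- 1L  # next text position not yet consumed
    applied <- 0L
    for (i in seq_along(ev)) {
      pos <- ev[i]
      if (pos < cursor) next  # swallowed by an earlier deletion
      if (pos > cursor) {
        pieces <- c(pieces, substr(text, cursor, pos - 1L))
      }
      applied <- applied + 1L
      if (types[i] == "mismatch") {
        orig <- substr(text, pos, pos)
        pieces <- c(pieces, sample(setdiff(profile$alphabet, orig), 1L))
        cursor <- pos + 1L
      } else if (types[i] == "insertion") {
        ins <- paste(sample(profile$alphabet, geom_len(), replace = TRUE),
                     collapse = "")
        pieces <- c(pieces, ins, substr(text, pos, pos))
        cursor <- pos + 1L
      } else {  # deletion
        cursor <- pos + geom_len()
      }
    }
    if (cursor <= length) {
      pieces <- c(pieces, substr(text, cursor, length))
    }
    structure(
      list(query = paste(pieces, collapse = ""), text = text,
           n_events = applied),
      class = "seq_pair"
    )
  })
}

#' @export
print.seq_pair <- function(x, ...) {
  trunc60 <- function(s) if (nchar(s) > 60) paste0(substr(s, 1, 57), "...") else s
  cat(sprintf("<seq_pair> query %d chars, text %d chars, %d edit events\n",
              nchar(x$query), nchar(x$text), x$n_events))
  cat(" query:", trunc60(x$query), "\n", "text: ", trunc60(x$text), "\n", sep = "")
  invisible(x)
}

#' Generate a table of mutated pairs
#'
#' @param count Number of pairs.
#' @inheritParams generate_pair
#' @return A tibble with columns `id`, `query`, `text`, `n_events`.
#' @examples
#' generate_pairs(3, 20, mutation_profile(0.2), seed = 7)
#' @export
generate_pairs <- function(count, length, profile, seed = NULL) {
  stopifnot(is.numeric(count), length(count) == 1L, count >= 0)
  count <- as.integer(count)
  with_seed(seed, {
    rows <- lapply(seq_len(count), function(i) {
      p <- generate_pair(length, profile)
      tibble(id = sprintf("pair_%d", i), query = p$query, text = p$text,
             n_events = p$n_events)
    })
    if (count == 0L) {
      tibble(id = character(0), query = character(0), text = character(0),
             n_events = integer(0))
    } else {
      do.call(rbind, rows)
    }
  })
}

#' Write a generated dataset in seq-pair format
#'
#' Generates `count` pairs and writes them to `path` in the two-line
#' seq-pair text format (`>` query line, `<` text line); deterministic for
#' a given seed.
#'
#' @inheritParams generate_pairs
#' @param path Output file path.
#' @return The path, invisibly.
#' @examples
#' f <- tempfile()
#' generate_dataset(2, 30, mutation_profile(0.1), f, seed = 3)
#' readLines(f)
#' @export
generate_dataset <- function(count, length, profile, path, seed = NULL) {
  pairs <- generate_pairs(count, length, profile, seed = seed)
  write_seq_pairs(pairs, path)
  invisible(path)
}
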