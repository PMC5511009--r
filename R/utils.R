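# Internal helpers: reproducible substreams and small numeric utilities.

#' Stable 31-bit hash of a character string
#'
#' Polynomial rolling hash over UTF-8 code points, modulo 2^31 - 1. Used to
#' derive per-group random-number substreams from the root seed, so adding or
#' removing groups does not reshuffle the draws of existing groups.
#'
#' @param x character scalar.
#' @return non-negative integer below 2^31 - 1.
#' @keywords internal
#' @noRd
stable_hash <- function(x) {
  codes <- utf8ToInt(x)
  h <- 0
  for (k in codes) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}

# Derive a substream seed from a root seed and a string label, kept < 2^31.
substream_seed <- function(seed, label) {
  as.integer((as.double(seed) * 48271 + stable_hash(label)) %% 2147483647)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is untouched.
with_substream <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Minimal data-frame constructor for hot loops: no name repair, no coercion.
fast_df <- function(lst) {
  n <- if (length(lst)) length(lst[[1]]) else 0L
  structure(lst, class = "data.frame", row.names = c(NA_integer_, -n))
}

# Draw one element from a set, safe for length-1 numeric sets (avoids
# sample()'s 1:n expansion).
sample1 <- function(v) if (length(v) == 1L) v else sample(v, 1L)

# Round to the nearest 0.5 (egg-mass lengths are recorded to half millimetres).
round_half_mm <- function(x) round(x * 2) / 2

# stopifnot with a custom message naming the offending field.
check_field <- function(ok, field, msg) {
  if (!isTRUE(ok)) stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}
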