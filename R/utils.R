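#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed family percentages follow
#' the conventional half-up rule instead (0.125 -> 0.13 at two decimals).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up.
#' @examples
#' round_half_up(63.2224, 2)
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Stop unless all sequence characters belong to the declared alphabet.
check_aa_alphabet <- function(sequence, id, alphabet = AA_ALPHABET_OK) {
  chars <- unique(strsplit(sequence, "", fixed = TRUE)[[1]])
  bad <- setdiff(chars, alphabet)
  if (length(bad) > 0) {
    abort(sprintf(
      "sequence '%s' contains characters outside the amino-acid alphabet: %s",
      id, paste(bad, collapse = ", ")
    ))
  }
  invisible(TRUE)
}

# Split a vector of sequences into a list of character vectors.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)

# Deterministic RNG scope: run `code` under a fixed seed and restore the
# caller's RNG state afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
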