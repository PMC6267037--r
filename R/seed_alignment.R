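#' Toy seed alignment of synthetic bHLH domains
#'
#' A small, fully synthetic eight-row alignment of 60-residue domains used
#' as the packaged default seed for [build_consensus()]. Its helix-loop-
#' helix block is strongly conserved (41 of 43 columns at or above the 50%
#' threshold, three of them exactly at it) while every basic-region column
#' is variable, so consensus matching — like the family-membership
#' criterion it implements — reads the HLH consensus and leaves the basic
#' region free to vary with DNA-binding category. A copy ships as
#' `inst/extdata/seed_alignment.fasta`.
#'
#' @return Alignment tibble (`id`, `aligned`) of 8 rows x 60 columns.
#' @export
toy_seed_alignment <- function() {
  canon <- canonical_domain(6L)
  rows <- matrix(rep(seq_chars(canon)[[1]], each = 8), nrow = 8)
  # basic region (columns 1-17): rotate an 8-residue pool so every column
  # holds 8 distinct residues (conservation 1/8)
  pool <- c("A", "D", "E", "K", "N", "Q", "R", "S")
  for (j in 1:17) {
    rows[, j] <- pool[((seq_len(8) - 1 + j) %% 8) + 1]
  }
  # three HLH columns at exactly the 50% threshold (4 canonical + 2 + 2)
  for (j in c(20L, 40L, 55L)) {
    alt <- setdiff(c("G", "P", "W"), rows[1, j])[1:2]
    rows[5:6, j] <- alt[1]
    rows[7:8, j] <- alt[2]
  }
  # two HLH columns below threshold (3 canonical + 2 + 2 + 1)
  for (j in c(25L, 50L)) {
    alt <- setdiff(c("G", "P", "W", "C"), rows[1, j])[1:3]
    rows[4:5, j] <- alt[1]
    rows[6:7, j] <- alt[2]
    rows[8, j] <- alt[3]
  }
  tibble::tibble(
    id = sprintf("seed%02d", 1:8),
    aligned = apply(rows, 1, paste, collapse = "")
  )
}

#' Default consensus profile from the packaged seed alignment
#'
#' Convenience wrapper: [build_consensus()] on [toy_seed_alignment()].
#'
#' @inheritParams build_consensus
#' @return A `consensus_profile`.
#' @export
default_profile <- function(threshold = 0.5) {
  build_consensus(toy_seed_alignment(), threshold = threshold)
}
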