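#' Build a position-specific consensus profile from a seed domain alignment
#'
#' For every alignment column the modal non-gap residue is recorded together
#' with its conservation fraction. Columns whose fraction meets `threshold`
#' become *consensus positions*: only these carry a consensus residue that
#' candidate domains are compared against during scanning. The bHLH region
#' template (basic / helix 1 / loop / helix 2) is laid over the ungapped
#' consensus coordinate: the basic region and the helices have fixed lengths
#' and the loop absorbs the remainder.
#'
#' @param alignment Tibble with columns `id` and `aligned`
#'   (see [read_alignment()]); at least two rows.
#' @param threshold Conservation fraction at or above which a column is a
#'   consensus position. Default 0.5: a residue shared by at least half the
#'   seed domains.
#' @param region_lengths Named integer vector with elements `basic`,
#'   `helix1`, `helix2`. The loop length is whatever remains of the ungapped
#'   consensus; defaults 17/15/22 reflect the canonical domain architecture
#'   (~17-residue basic region, ~60-residue domain).
#' @param gap_denominator `"exclude"` (default): the fraction denominator is
#'   the number of non-gap characters in the column. `"include"`: all rows
#'   count, so a mostly-gap column can never be conserved.
#' @return An object of class `consensus_profile`: see [tidy()] and
#'   [glance()] methods for tabular views.
#' @export
build_consensus <- function(alignment, threshold = 0.5,
                            region_lengths = c(basic = 17L, helix1 = 15L, helix2 = 22L),
                            gap_denominator = c("exclude", "include")) {
  gap_denominator <- match.arg(gap_denominator)
  stopifnot(is.data.frame(alignment), all(c("id", "aligned") %in% names(alignment)))
  if (nrow(alignment) < 2) abort("consensus requires at least 2 alignment rows")
  widths <- nchar(alignment$aligned)
  if (length(unique(widths)) != 1) abort("alignment rows have unequal lengths")
  stopifnot(all(c("basic", "helix1", "helix2") %in% names(region_lengths)))

  mat <- do.call(rbind, seq_chars(toupper(alignment$aligned)))
  n_rows <- nrow(mat)
  cols <- purrr::map(seq_len(ncol(mat)), function(j) {
    ch <- mat[, j]
    nongap <- ch[ch != "-"]
    if (length(nongap) == 0) {
      return(list(residue = "-", fraction = 0))
    }
    tab <- table(nongap)
    top <- max(tab)
    # ties broken by alphabetical order of residue
    residue <- sort(names(tab)[tab == top])[1]
    denom <- if (gap_denominator == "exclude") length(nongap) else n_rows
    list(residue = residue, fraction = unname(top) / denom)
  })

  columns <- tibble::tibble(
    column = seq_along(cols),
    residue = purrr::map_chr(cols, "residue"),
    fraction = purrr::map_dbl(cols, "fraction")
  )
  # ungapped consensus coordinate: all-gap sentinel columns carry no position
  columns$position <- NA_integer_
  real <- columns$residue != "-"
  columns$position[real] <- seq_len(sum(real))
  columns$is_consensus <- real & columns$fraction >= threshold

  L <- sum(real)
  fixed <- sum(region_lengths[c("basic", "helix1", "helix2")])
  if (L < fixed + 1) {
    abort(sprintf(
      "ungapped consensus length %d too short for region template (need > %d)",
      L, fixed
    ))
  }
  b <- unname(region_lengths[["basic"]])
  h1 <- unname(region_lengths[["helix1"]])
  h2 <- unname(region_lengths[["helix2"]])
  loop_len <- L - fixed
  regions <- tibble::tibble(
    region = c("basic", "helix1", "loop", "helix2"),
    start = c(1L, b + 1L, b + h1 + 1L, b + h1 + loop_len + 1L),
    end = c(b, b + h1, b + h1 + loop_len, L)
  )
  columns$region <- NA_character_
  idx <- findInterval(columns$position[real], regions$start)
  columns$region[real] <- regions$region[idx]

  structure(
    list(
      columns = columns,
      threshold = threshold,
      region_lengths = c(basic = b, helix1 = h1, loop = loop_len, helix2 = h2),
      regions = regions,
      consensus = paste(columns$residue[real], collapse = ""),
      length = L,
      n_rows = n_rows,
      gap_denominator = gap_denominator
    ),
    class = "consensus_profile"
  )
}

#' @export
print.consensus_profile <- function(x, ...) {
  cat(sprintf(
    "<consensus_profile> %d rows, %d columns (%d ungapped), %d consensus positions at threshold %.2f\n",
    x$n_rows, nrow(x$columns), x$length, sum(x$columns$is_consensus), x$threshold
  ))
  cat(sprintf(
    "  regions: basic %d | helix1 %d | loop %d | helix2 %d\n",
    x$region_lengths[["basic"]], x$region_lengths[["helix1"]],
    x$region_lengths[["loop"]], x$region_lengths[["helix2"]]
  ))
  cat("  consensus:", x$consensus, "\n")
  invisible(x)
}

#' Tidy a consensus profile into its per-column table
#'
#' @param x A `consensus_profile`.
#' @param ... Unused.
#' @return Tibble with one row per alignment column: `column`, `position`
#'   (ungapped coordinate, `NA` for all-gap columns), `residue`, `fraction`,
#'   `is_consensus`, `region`.
#' @export
tidy.consensus_profile <- function(x, ...) {
  x$columns[, c("column", "position", "residue", "fraction", "is_consensus", "region")]
}

#' One-row summary of a consensus profile
#'
#' @param x A `consensus_profile`.
#' @param ... Unused.
#' @return One-row tibble: seed rows, column counts, domain length, loop
#'   length, consensus-position count and threshold.
#' @export
glance.consensus_profile <- function(x, ...) {
  tibble::tibble(
    n_seed_rows = x$n_rows,
    n_columns = nrow(x$columns),
    domain_length = x$length,
    loop_length = x$region_lengths[["loop"]],
    n_consensus_positions = sum(x$columns$is_consensus),
    threshold = x$threshold
  )
}
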