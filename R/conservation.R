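#' Column-wise conservation of a domain alignment
#'
#' For each column, the fraction of sequences carrying the modal non-gap
#' residue. By default gaps count in the denominator — a mostly-gap column
#' cannot be conserved in at least half the domains — which differs from
#' [build_consensus()], whose default denominator is gap-excluded; both
#' behaviours are available here through `gap_denominator`.
#'
#' @param alignment Tibble with columns `id` and `aligned`; at least two
#'   rows.
#' @param gap_denominator `"include"` (default): denominator is the number
#'   of rows. `"exclude"`: the number of non-gap characters in the column.
#' @return Tibble `column`, `residue` (modal non-gap residue, `-` for an
#'   all-gap column), `fraction`.
#' @export
column_conservation <- function(alignment, gap_denominator = c("include", "exclude")) {
  gap_denominator <- match.arg(gap_denominator)
  stopifnot(is.data.frame(alignment), all(c("id", "aligned") %in% names(alignment)))
  if (nrow(alignment) < 2) abort("conservation requires at least 2 alignment rows")
  widths <- nchar(alignment$aligned)
  if (length(unique(widths)) != 1) abort("alignment rows have unequal lengths")
  mat <- do.call(rbind, seq_chars(toupper(alignment$aligned)))
  n <- nrow(mat)
  res <- purrr::map(seq_len(ncol(mat)), function(j) {
    ch <- mat[, j]
    nongap <- ch[ch != "-"]
    if (length(nongap) == 0) return(list(residue = "-", fraction = 0))
    tab <- table(nongap)
    top <- max(tab)
    denom <- if (gap_denominator == "include") n else length(nongap)
    list(residue = sort(names(tab)[tab == top])[1], fraction = unname(top) / denom)
  })
  tibble::tibble(
    column = seq_along(res),
    residue = purrr::map_chr(res, "residue"),
    fraction = purrr::map_dbl(res, "fraction")
  )
}

#' Alignment columns conserved at or above a threshold
#'
#' @inheritParams column_conservation
#' @param threshold Minimum conservation fraction; the 50% convention
#'   identifies the residues shared by at least half the family.
#' @return Ascending integer vector of column indices.
#' @export
conserved_positions <- function(alignment, threshold = 0.5,
                                gap_denominator = c("include", "exclude")) {
  cc <- column_conservation(alignment, gap_denominator = gap_denominator)
  cc$column[cc$fraction >= threshold]
}

#' Conserved-position counts per domain region
#'
#' Buckets conserved alignment columns into the basic/helix1/loop/helix2
#' regions using a consensus profile's column-to-region mapping. The
#' canonical plant bHLH expectation is a 5/6/2/12 split over 25 conserved
#' residues.
#'
#' @inheritParams conserved_positions
#' @param profile A [consensus_profile][build_consensus] built from the
#'   same alignment (provides the region template on the ungapped consensus
#'   coordinate).
#' @return Tibble `region`, `n_conserved`, in domain order; counts sum to
#'   the number of conserved positions.
#' @export
region_conservation_summary <- function(alignment, profile, threshold = 0.5,
                                        gap_denominator = c("include", "exclude")) {
  stopifnot(inherits(profile, "consensus_profile"))
  cols <- conserved_positions(alignment, threshold = threshold,
                              gap_denominator = gap_denominator)
  map <- profile$columns
  if (nrow(map) != nchar(alignment$aligned[1])) {
    abort("profile was not built from this alignment (column count differs)")
  }
  reg <- map$region[match(cols, map$column)]
  if (any(is.na(reg))) {
    abort(sprintf(
      "conserved column(s) outside the region template (all-gap in profile): %s",
      paste(cols[is.na(reg)], collapse = ", ")
    ))
  }
  tibble::tibble(region = c("basic", "helix1", "loop", "helix2")) |>
    dplyr::left_join(
      tibble::tibble(region = reg) |> dplyr::count(.data$region, name = "n_conserved"),
      by = "region"
    ) |>
    tidyr::replace_na(list(n_conserved = 0L)) |>
    dplyr::mutate(n_conserved = as.integer(.data$n_conserved))
}
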