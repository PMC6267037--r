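#' Locate the best-matching bHLH domain placement in one protein
#'
#' Exhaustively scans every start offset and every loop length in
#' `loop_range`, counting mismatches at the profile's consensus positions
#' only. The loop is elastic: when candidate and consensus loop lengths
#' differ, consensus loop positions are compared to the first
#' `min(candidate, consensus)` loop residues and surplus residues are left
#' uncounted. The placement minimizing total mismatches wins; ties are
#' broken by smaller deviation of the loop length from `loop_mode`, then
#' smaller start, then smaller loop length. `X` (and a consensus sentinel)
#' never match.
#'
#' @param sequence Amino-acid string.
#' @param profile A [consensus_profile][build_consensus].
#' @param loop_range Integer vector `c(min, max)` of candidate loop lengths.
#' @param loop_mode Most typical loop length, used only for tie-breaking.
#' @return One-row tibble (`start`, `end`, `domain_length`, `loop_length`,
#'   `mm_basic`, `mm_helix1`, `mm_loop`, `mm_helix2`, `total_mismatches`)
#'   or `NULL` when the protein is shorter than the minimal domain.
#' @export
locate_domain <- function(sequence, profile, loop_range = c(5L, 15L), loop_mode = 6L) {
  stopifnot(inherits(profile, "consensus_profile"))
  pc <- seq_chars(toupper(sequence))[[1]]
  n <- length(pc)
  b <- profile$region_lengths[["basic"]]
  h1 <- profile$region_lengths[["helix1"]]
  h2 <- profile$region_lengths[["helix2"]]
  cl <- profile$region_lengths[["loop"]]
  pre <- b + h1
  cons <- profile$columns[profile$columns$is_consensus, c("position", "residue", "region")]
  loops <- seq.int(loop_range[1], loop_range[2])
  min_len <- pre + min(loops) + h2
  if (n < min_len) return(NULL)

  best <- NULL
  regions <- c("basic", "helix1", "loop", "helix2")
  for (l in loops) {
    D <- pre + l + h2
    if (n < D) next
    starts <- seq_len(n - D + 1L)
    # map each consensus position to a 0-based offset within the placement
    p <- cons$position
    loop_j <- p - pre
    counted <- p <= pre | (loop_j >= 1 & loop_j <= min(l, cl)) | p > pre + cl
    rel <- ifelse(p <= pre + cl, p - 1L, p - cl + l - 1L)
    per_region <- matrix(0L, nrow = length(starts), ncol = 4L,
                         dimnames = list(NULL, regions))
    for (k in which(counted)) {
      z <- cons$residue[k]
      ch <- pc[starts + rel[k]]
      mism <- (ch != z) | ch == "X" | z == "X"
      per_region[, cons$region[k]] <- per_region[, cons$region[k]] + mism
    }
    totals <- rowSums(per_region)
    i <- which.min(totals) # earliest start among equals
    cand <- list(
      start = starts[i], loop = l, dev = abs(l - loop_mode),
      total = totals[i], mm = per_region[i, ]
    )
    if (is.null(best) ||
        cand$total < best$total ||
        (cand$total == best$total && cand$dev < best$dev) ||
        (cand$total == best$total && cand$dev == best$dev && cand$start < best$start) ||
        (cand$total == best$total && cand$dev == best$dev &&
         cand$start == best$start && cand$loop < best$loop)) {
      best <- cand
    }
  }
  if (is.null(best)) return(NULL)
  D <- pre + best$loop + h2
  tibble::tibble(
    start = best$start,
    end = best$start + D - 1L,
    domain_length = D,
    loop_length = best$loop,
    mm_basic = unname(best$mm[["basic"]]),
    mm_helix1 = unname(best$mm[["helix1"]]),
    mm_loop = unname(best$mm[["loop"]]),
    mm_helix2 = unname(best$mm[["helix2"]]),
    total_mismatches = unname(best$total)
  )
}

#' Scan a set of proteins for bHLH domains
#'
#' Applies [locate_domain()] to every record and flags acceptance under the
#' mismatch budget (12 mismatches from the consensus by default, the
#' low-stringency criterion used for family membership).
#'
#' @param proteins Tibble with columns `id` and `sequence`
#'   (see [read_protein_fasta()]).
#' @param profile A [consensus_profile][build_consensus].
#' @param max_mismatches Whole-domain mismatch budget; a hit is accepted
#'   when `total_mismatches <= max_mismatches`.
#' @param per_region_caps Optional named vector of additional per-region
#'   mismatch caps (`basic`, `helix1`, `loop`, `helix2`); when supplied a
#'   hit must also satisfy every cap.
#' @inheritParams locate_domain
#' @return Tibble of hits, one row per protein with a locatable domain:
#'   the [locate_domain()] columns plus `protein_id` and `accepted`.
#'   Proteins shorter than the minimal domain are dropped.
#' @export
scan_domains <- function(proteins, profile, loop_range = c(5L, 15L),
                         max_mismatches = 12L, loop_mode = 6L,
                         per_region_caps = NULL) {
  stopifnot(is.data.frame(proteins), all(c("id", "sequence") %in% names(proteins)))
  hits <- purrr::map2(proteins$id, proteins$sequence, function(id, s) {
    h <- locate_domain(s, profile, loop_range = loop_range, loop_mode = loop_mode)
    if (is.null(h)) NULL else dplyr::mutate(h, protein_id = id, .before = 1)
  })
  hits <- dplyr::bind_rows(hits)
  if (nrow(hits) == 0) {
    return(tibble::tibble(
      protein_id = character(), start = integer(), end = integer(),
      domain_length = integer(), loop_length = integer(),
      mm_basic = numeric(), mm_helix1 = numeric(), mm_loop = numeric(),
      mm_helix2 = numeric(), total_mismatches = numeric(), accepted = logical()
    ))
  }
  accept_candidate(hits, max_mismatches = max_mismatches,
                   per_region_caps = per_region_caps)
}

#' Apply the mismatch acceptance rule to domain hits
#'
#' @param hits Tibble of domain hits (see [scan_domains()]).
#' @inheritParams scan_domains
#' @return `hits` with an `accepted` column:
#'   `total_mismatches <= max_mismatches` (and within every per-region cap,
#'   when caps are given).
#' @export
accept_candidate <- function(hits, max_mismatches = 12L, per_region_caps = NULL) {
  ok <- hits$total_mismatches <= max_mismatches
  if (!is.null(per_region_caps)) {
    for (r in names(per_region_caps)) {
      col <- paste0("mm_", r)
      if (!col %in% names(hits)) abort(sprintf("unknown region cap: %s", r))
      ok <- ok & hits[[col]] <= per_region_caps[[r]]
    }
  }
  dplyr::mutate(hits, accepted = ok)
}

#' Region spans of located domains in protein coordinates
#'
#' @param hits Tibble of domain hits.
#' @param profile The [consensus_profile][build_consensus] the hits were
#'   scanned against (provides the fixed basic/helix lengths).
#' @return Long tibble: `protein_id`, `region`, `start`, `end` (1-based
#'   inclusive protein coordinates).
#' @export
domain_regions <- function(hits, profile) {
  b <- profile$region_lengths[["basic"]]
  h1 <- profile$region_lengths[["helix1"]]
  purrr::pmap_dfr(
    hits[, c("protein_id", "start", "loop_length", "domain_length")],
    function(protein_id, start, loop_length, domain_length) {
      s0 <- start
      tibble::tibble(
        protein_id = protein_id,
        region = c("basic", "helix1", "loop", "helix2"),
        start = s0 + c(0L, b, b + h1, b + h1 + loop_length),
        end = s0 - 1L + c(b, b + h1, b + h1 + loop_length, domain_length)
      )
    }
  )
}

#' Distribution of accepted domain lengths
#'
#' @param hits Tibble of domain hits with an `accepted` column.
#' @return Tibble (`domain_length`, `count`, `percentage`), percentages
#'   rounded half-up to two decimals and summing to 100 within rounding.
#' @export
domain_length_distribution <- function(hits) {
  acc <- dplyr::filter(hits, .data$accepted)
  if (nrow(acc) == 0) {
    return(tibble::tibble(domain_length = integer(), count = integer(),
                          percentage = numeric()))
  }
  acc |>
    dplyr::count(.data$domain_length, name = "count") |>
    dplyr::mutate(percentage = round_half_up(100 * .data$count / sum(.data$count), 2))
}

#' Distribution of accepted loop lengths
#'
#' @inheritParams domain_length_distribution
#' @return Tibble (`loop_length`, `count`, `percentage`) as in
#'   [domain_length_distribution()].
#' @export
loop_length_distribution <- function(hits) {
  acc <- dplyr::filter(hits, .data$accepted)
  if (nrow(acc) == 0) {
    return(tibble::tibble(loop_length = integer(), count = integer(),
                          percentage = numeric()))
  }
  acc |>
    dplyr::count(.data$loop_length, name = "count") |>
    dplyr::mutate(percentage = round_half_up(100 * .data$count / sum(.data$count), 2))
}
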