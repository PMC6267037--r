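INTRONLESS_LABEL <- "intronless"

# CDS pieces of each transcript in transcription order, with cumulative
# coding length before and after each piece.
transcript_cds <- function(models) {
  models |>
    dplyr::filter(.data$type == "CDS") |>
    dplyr::group_by(.data$gene_id, .data$transcript_id) |>
    dplyr::mutate(
      piece = dplyr::row_number(),
      width = .data$end - .data$start + 1L,
      cds_after = cumsum(.data$width),
      cds_before = .data$cds_after - .data$width
    ) |>
    dplyr::ungroup()
}

#' CDS-nucleotide interval occupied by a located domain
#'
#' Converts 1-based protein coordinates of each accepted hit into the
#' 1-based interval on the spliced CDS: residues `start..end` occupy CDS
#' nucleotides `3*(start-1)+1 .. 3*end`.
#'
#' @param models Gene-model feature tibble (see [read_gtf()]).
#' @param hits Tibble of domain hits; `protein_id` must match
#'   `transcript_id` in `models`.
#' @return Tibble `transcript_id`, `cds_length`, `cds_start`, `cds_end`.
#' @export
domain_cds_interval <- function(models, hits) {
  acc <- dplyr::filter(hits, .data$accepted)
  cds_len <- transcript_cds(models) |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(cds_length = sum(.data$width), .groups = "drop")
  out <- dplyr::inner_join(acc, cds_len, by = c(protein_id = "transcript_id"))
  bad <- out$end * 3L > out$cds_length
  if (any(bad)) {
    abort(sprintf(
      "domain extends beyond CDS for transcript(s): %s",
      paste(out$protein_id[bad], collapse = ", ")
    ))
  }
  tibble::tibble(
    transcript_id = out$protein_id,
    cds_length = out$cds_length,
    cds_start = 3L * (out$start - 1L) + 1L,
    cds_end = 3L * out$end
  )
}

#' Map introns into domain-relative codon coordinates with phase
#'
#' Every junction between consecutive CDS-bearing pieces of a transcript is
#' an intron; its CDS offset `c` is the number of coding nucleotides 5' of
#' it. Introns interior to the domain's CDS interval are reported as
#' events: `domain_codon` is the amino-acid position whose codon the intron
#' interrupts (or, at phase 0, follows), and `phase` is the number of
#' nucleotides of that codon lying 5' of the intron (0 = between codons).
#' Strand is handled by transcription-order traversal, so plus- and
#' minus-strand genes with the same coding structure yield identical
#' events.
#'
#' @inheritParams domain_cds_interval
#' @param region_lengths Basic/helix1 lengths used to assign each event to
#'   a domain region (the loop length comes from the hit).
#' @return Tibble `transcript_id`, `cds_offset`, `domain_codon`, `phase`,
#'   `region`, events ordered 5' to 3' within each transcript. Transcripts
#'   whose domain contains no intron contribute no rows.
#' @export
map_introns_to_domain <- function(models, hits,
                                  region_lengths = c(basic = 17L, helix1 = 15L)) {
  acc <- dplyr::filter(hits, .data$accepted)
  intervals <- domain_cds_interval(models, hits)
  cds <- transcript_cds(models) |>
    dplyr::filter(.data$transcript_id %in% acc$protein_id)
  junctions <- cds |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::filter(dplyr::row_number() < dplyr::n()) |>
    dplyr::ungroup() |>
    dplyr::select("transcript_id", cds_offset = "cds_after")
  ev <- junctions |>
    dplyr::inner_join(intervals, by = "transcript_id") |>
    dplyr::inner_join(
      acc[, c("protein_id", "loop_length", "domain_length")],
      by = c(transcript_id = "protein_id")
    ) |>
    dplyr::mutate(d = .data$cds_offset - .data$cds_start + 1L) |>
    dplyr::filter(.data$d >= 1L, .data$d <= 3L * .data$domain_length - 1L) |>
    dplyr::mutate(
      domain_codon = as.integer(ceiling(.data$d / 3)),
      phase = .data$d %% 3L
    )
  b <- region_lengths[["basic"]]
  h1 <- region_lengths[["helix1"]]
  ev |>
    dplyr::mutate(region = dplyr::case_when(
      .data$domain_codon <= b ~ "basic",
      .data$domain_codon <= b + h1 ~ "helix1",
      .data$domain_codon <= b + h1 + .data$loop_length ~ "loop",
      .default = "helix2"
    )) |>
    dplyr::arrange(.data$transcript_id, .data$cds_offset) |>
    dplyr::select("transcript_id", "cds_offset", "domain_codon", "phase", "region")
}

new_registry <- function() {
  structure(
    tibble::tibble(
      label = character(), n_introns = integer(),
      positions = list(), phases = list()
    ),
    class = c("intron_registry", "tbl_df", "tbl", "data.frame")
  )
}

registry_letters <- function(i) {
  # A..Z, then AA, AB, ...
  if (i <= 26) return(LETTERS[i])
  paste0(LETTERS[(i - 27) %/% 26 + 1], LETTERS[(i - 27) %% 26 + 1])
}

#' Assign intron-pattern signatures and registry labels
#'
#' Each domain's intron events are normalized onto a 60-residue scale and
#' matched against a pattern registry: two signatures are the same pattern
#' when they have the same intron count, equal phases, and every position
#' pairs within `tolerance` residues. Unmatched signatures found a new
#' registry entry; labels (`A`, `B`, ...) are issued in first-encounter
#' order over lexicographically sorted transcript ids, so the labelling is
#' independent of input order. Intronless domains take the reserved
#' `intronless` label.
#'
#' @param events Intron events (see [map_introns_to_domain()]).
#' @param hits Tibble of domain hits; every accepted hit is labelled, with
#'   or without events.
#' @param registry Optional existing registry to extend (from a previous
#'   call's `pattern_registry()`).
#' @param tolerance Matching tolerance in residues on the 60-residue scale.
#' @param max_introns Hard cap on events per domain; more is an error.
#' @return Tibble `transcript_id`, `n_introns`, `signature`, `label`, with
#'   the updated registry attached (retrieve via [pattern_registry()]).
#' @export
assign_patterns <- function(events, hits, registry = NULL, tolerance = 2,
                            max_introns = 3L) {
  acc <- dplyr::filter(hits, .data$accepted)
  registry <- registry %||% new_registry()
  stopifnot(inherits(registry, "intron_registry"))
  ids <- sort(acc$protein_id)
  dl <- setNames(acc$domain_length, acc$protein_id)
  events <- dplyr::arrange(events, .data$transcript_id, .data$cds_offset)
  ev_by_id <- split(events, events$transcript_id)
  over <- names(ev_by_id)[vapply(ev_by_id, nrow, integer(1)) > max_introns]
  if (length(over) > 0) {
    abort(sprintf("more than %d domain introns in transcript(s): %s",
                  max_introns, paste(over, collapse = ", ")))
  }
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    e <- ev_by_id[[id]]
    if (is.null(e) || nrow(e) == 0) {
      rows[[i]] <- tibble::tibble(
        transcript_id = id, n_introns = 0L, signature = "",
        label = INTRONLESS_LABEL
      )
      next
    }
    pos <- e$domain_codon * 60 / dl[[id]]
    ph <- e$phase
    match_i <- which(purrr::map_lgl(seq_len(nrow(registry)), function(k) {
      registry$n_introns[k] == length(pos) &&
        all(registry$phases[[k]] == ph) &&
        all(abs(registry$positions[[k]] - pos) <= tolerance)
    }))
    if (length(match_i) == 0) {
      lab <- registry_letters(nrow(registry) + 1L)
      registry <- dplyr::bind_rows(
        registry,
        tibble::tibble(label = lab, n_introns = length(pos),
                       positions = list(pos), phases = list(as.integer(ph)))
      )
      class(registry) <- c("intron_registry", class(tibble::tibble()))
    } else {
      lab <- registry$label[match_i[1]]
    }
    rows[[i]] <- tibble::tibble(
      transcript_id = id, n_introns = length(pos),
      signature = paste(sprintf("%.2f.%d", pos, ph), collapse = ";"),
      label = lab
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "registry") <- registry
  out
}

#' Retrieve the pattern registry attached to [assign_patterns()] output
#'
#' @param patterns Tibble returned by [assign_patterns()].
#' @return The `intron_registry` tibble (`label`, `n_introns`, `positions`,
#'   `phases`).
#' @export
pattern_registry <- function(patterns) {
  reg <- attr(patterns, "registry")
  if (is.null(reg)) abort("no registry attached; was this made by assign_patterns()?")
  reg
}

#' Tidy an intron-pattern registry into long format
#'
#' @param x An `intron_registry`.
#' @param ... Unused.
#' @return Tibble `label`, `intron`, `position` (60-residue scale), `phase`.
#' @export
tidy.intron_registry <- function(x, ...) {
  if (nrow(x) == 0) {
    return(tibble::tibble(label = character(), intron = integer(),
                          position = numeric(), phase = integer()))
  }
  tibble::tibble(
    label = rep(x$label, x$n_introns),
    intron = unlist(purrr::map(x$n_introns, seq_len)),
    position = unlist(x$positions),
    phase = unlist(x$phases)
  )
}

#' Pattern counts and percentages per group
#'
#' @param patterns Tibble from [assign_patterns()].
#' @param grouping Named character vector or tibble (`id`, `group`) mapping
#'   each transcript to a group (species, subfamily, ...). Omit to report a
#'   single overall group.
#' @return Tibble `label`, `group`, `count`, `percentage`; percentages sum
#'   to 100 within each group up to two-decimal half-up rounding.
#' @export
pattern_distribution <- function(patterns, grouping = NULL) {
  p <- dplyr::as_tibble(patterns)
  if (is.null(grouping)) {
    p$group <- "all"
  } else {
    if (is.data.frame(grouping)) grouping <- setNames(grouping$group, grouping$id)
    unknown <- setdiff(p$transcript_id, names(grouping))
    if (length(unknown) > 0) {
      abort(sprintf("no group for transcript(s): %s",
                    paste(unknown, collapse = ", ")))
    }
    p$group <- unname(grouping[p$transcript_id])
  }
  p |>
    dplyr::count(.data$group, .data$label, name = "count") |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(percentage = round_half_up(100 * .data$count / sum(.data$count), 2)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$group, dplyr::desc(.data$count), .data$label)
}

#' Per-transcript gene-structure statistics
#'
#' Exon counts, intronless status (a single CDS-bearing piece) and
#' symmetric phase-zero exons: an internal CDS exon whose flanking introns
#' both fall between codons (phase 0), the configuration that favours exon
#' shuffling.
#'
#' @param models Gene-model feature tibble (see [read_gtf()]).
#' @return Tibble `gene_id`, `transcript_id`, `n_exons`, `n_cds_exons`,
#'   `intronless`, `n_internal_exons`, `n_symmetric_phase0`.
#' @export
gene_structure_stats <- function(models) {
  exons <- models |>
    dplyr::filter(.data$type == "exon") |>
    dplyr::count(.data$gene_id, .data$transcript_id, name = "n_exons")
  cds <- transcript_cds(models) |>
    dplyr::group_by(.data$gene_id, .data$transcript_id) |>
    dplyr::summarise(
      n_cds_exons = dplyr::n(),
      n_internal_exons = max(dplyr::n() - 2L, 0L),
      n_symmetric_phase0 = {
        ph <- .data$cds_after[-dplyr::n()] %% 3L # phases of the introns, 5'->3'
        if (length(ph) < 2) 0L else sum(ph[-length(ph)] == 0L & ph[-1] == 0L)
      },
      .groups = "drop"
    )
  dplyr::left_join(exons, cds, by = c("gene_id", "transcript_id")) |>
    dplyr::mutate(intronless = .data$n_cds_exons == 1L, .after = "n_cds_exons")
}
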