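BINDING_CATEGORIES <- c(
  "G_binder", "E_non_G", "non_E_binder",
  "potential_E_box", "potential_G_box", "non_binder"
)

#' Count basic residues in a basic-region sequence
#'
#' @param basic_region Residue string, one per region (the N-terminal ~17
#'   residues of the domain).
#' @param min_length Minimum accepted region length; shorter input errors.
#' @param basic_set Residues counted as basic; Arg/Lys/His by default.
#' @return Integer vector of basic-residue counts.
#' @export
count_basic_residues <- function(basic_region, min_length = 17L,
                                 basic_set = BASIC_RESIDUES) {
  short <- nchar(basic_region) < min_length
  if (any(short)) {
    abort(sprintf(
      "basic region shorter than %d residues (got %s)",
      min_length, paste(nchar(basic_region)[short], collapse = ", ")
    ))
  }
  vapply(seq_chars(basic_region), function(ch) sum(ch %in% basic_set), integer(1))
}

# Decision tree over the basic-region evidence. At least five basic residues
# marks a DNA binder; Glu-13 + Arg-16 mark E-box recognition; His/Lys-9 +
# Arg-17 add G-box specificity. Below five basics the same residue motifs
# rescue a domain as a *potential* E-box / G-box binder.
binding_category <- function(basic_count, has_E13, has_R16, has_HK9, has_R17) {
  ebox <- has_E13 & has_R16
  gbox <- has_HK9 & has_R17
  dplyr::case_when(
    basic_count >= 5 & ebox & gbox ~ "G_binder",
    basic_count >= 5 & ebox ~ "E_non_G",
    basic_count >= 5 ~ "non_E_binder",
    ebox & gbox ~ "potential_G_box",
    ebox ~ "potential_E_box",
    .default = "non_binder"
  )
}

#' Classify DNA-binding ability of accepted bHLH domains
#'
#' Extracts each accepted domain from its protein, inspects the basic
#' region (domain positions 1 to `basic_length`) and the four diagnostic
#' residues — Glu-13, Arg-16 (E-box recognition) and His/Lys-9, Arg-17
#' (G-box specificity) — and assigns one of six categories:
#' `G_binder`, `E_non_G`, `non_E_binder` (at least five basic residues) or
#' `potential_E_box`, `potential_G_box`, `non_binder` (fewer than five).
#' A non-standard residue (`X`) at a rule position counts as a non-match.
#'
#' @param hits Tibble of domain hits (see [scan_domains()]); only accepted
#'   hits are classified.
#' @param proteins Tibble with `id` and `sequence` covering every hit.
#' @param basic_length Length of the basic region; rule positions are
#'   1-based within the located domain.
#' @param rule_positions Named integer vector giving the diagnostic
#'   positions (`E = 13`, `R1 = 16`, `HK = 9`, `R2 = 17` by default).
#' @param basic_set Residues counted as basic.
#' @return Tibble with one row per accepted hit: `protein_id`,
#'   `basic_count`, `has_E13`, `has_R16`, `has_HK9`, `has_R17`, `category`
#'   (factor over the six categories).
#' @export
classify_binding <- function(hits, proteins, basic_length = 17L,
                             rule_positions = c(E = 13L, R1 = 16L, HK = 9L, R2 = 17L),
                             basic_set = BASIC_RESIDUES) {
  stopifnot(is.data.frame(hits), is.data.frame(proteins))
  acc <- dplyr::filter(hits, .data$accepted)
  missing <- setdiff(acc$protein_id, proteins$id)
  if (length(missing) > 0) {
    abort(sprintf("hit protein(s) absent from `proteins`: %s",
                  paste(missing, collapse = ", ")))
  }
  acc <- dplyr::left_join(acc, proteins[, c("id", "sequence")],
                          by = c(protein_id = "id"))
  domain <- substr(acc$sequence, acc$start, acc$end)
  short <- nchar(domain) < max(basic_length, rule_positions)
  if (any(short)) {
    abort(sprintf("domain too short to classify for protein(s): %s",
                  paste(acc$protein_id[short], collapse = ", ")))
  }
  at <- function(pos) substr(domain, pos, pos)
  r_E <- at(rule_positions[["E"]])
  r_R1 <- at(rule_positions[["R1"]])
  r_HK <- at(rule_positions[["HK"]])
  r_R2 <- at(rule_positions[["R2"]])
  nonstd <- !(c(r_E, r_R1, r_HK, r_R2) %in% AA_STANDARD)
  if (any(nonstd)) {
    warn(sprintf(
      "%d non-standard residue(s) at rule positions treated as non-matching",
      sum(nonstd)
    ))
  }
  calls <- tibble::tibble(
    protein_id = acc$protein_id,
    basic_count = count_basic_residues(substr(domain, 1L, basic_length),
                                       min_length = basic_length,
                                       basic_set = basic_set),
    has_E13 = r_E == "E",
    has_R16 = r_R1 == "R",
    has_HK9 = r_HK %in% c("H", "K"),
    has_R17 = r_R2 == "R"
  )
  calls$category <- factor(
    binding_category(calls$basic_count, calls$has_E13, calls$has_R16,
                     calls$has_HK9, calls$has_R17),
    levels = BINDING_CATEGORIES
  )
  calls
}

#' Tabulate binding categories per species
#'
#' Builds the species-by-category contingency table in the conventional
#' printed order (G binder, E non G, non E binder | potential E-box,
#' potential G-box, non DNA binder | Total), with a grand-total row.
#'
#' @param calls Tibble of binding calls (see [classify_binding()]).
#' @param species_of Named character vector or tibble (`id`, `species`)
#'   mapping every `protein_id` to a species label; may be omitted when
#'   `calls` already carries a `species` column.
#' @return Tibble: one row per species plus a `Total` row; columns are the
#'   six category counts and `Total`.
#' @export
tabulate_categories <- function(calls, species_of = NULL) {
  calls <- dplyr::as_tibble(calls)
  if (!"species" %in% names(calls)) {
    if (is.null(species_of)) abort("supply `species_of` or a `species` column")
    if (is.data.frame(species_of)) {
      species_of <- setNames(species_of$species, species_of$id)
    }
    unknown <- setdiff(calls$protein_id, names(species_of))
    if (length(unknown) > 0) {
      abort(sprintf("no species label for protein(s): %s",
                    paste(unknown, collapse = ", ")))
    }
    calls$species <- unname(species_of[calls$protein_id])
  }
  if (any(is.na(calls$species) | calls$species == "")) {
    abort("missing species label in `calls`")
  }
  wide <- calls |>
    dplyr::count(.data$species, .data$category, .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "category", values_from = "n",
                       values_fill = 0L) |>
    dplyr::arrange(.data$species)
  for (cat in BINDING_CATEGORIES) {
    if (!cat %in% names(wide)) wide[[cat]] <- 0L
  }
  wide <- wide[, c("species", BINDING_CATEGORIES)]
  wide$Total <- as.integer(rowSums(wide[, BINDING_CATEGORIES]))
  total_row <- dplyr::summarise(
    wide,
    species = "Total",
    dplyr::across(dplyr::all_of(c(BINDING_CATEGORIES, "Total")),
                  \(x) as.integer(sum(x)))
  )
  dplyr::bind_rows(wide, total_row)
}

#' Aggregate binding groups per species
#'
#' DNA binders are the three categories with at least five basic residues;
#' E-box binders are G binders plus E-non-G binders; the non-binder group
#' collects the potential binders and the non DNA binders.
#'
#' @param table Family table from [tabulate_categories()].
#' @return Tibble with per-species `dna_binders`, `e_box_binders`,
#'   `g_box_binders`, `non_e_binders`, `non_binder_group` and `total`.
#' @export
derive_aggregates <- function(table) {
  stopifnot(all(c("species", BINDING_CATEGORIES) %in% names(table)))
  table |>
    dplyr::transmute(
      species = .data$species,
      dna_binders = .data$G_binder + .data$E_non_G + .data$non_E_binder,
      e_box_binders = .data$G_binder + .data$E_non_G,
      g_box_binders = .data$G_binder,
      non_e_binders = .data$non_E_binder,
      non_binder_group = .data$potential_E_box + .data$potential_G_box +
        .data$non_binder,
      total = .data$dna_binders + .data$non_binder_group
    )
}
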