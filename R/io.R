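#' Read a protein FASTA file
#'
#' Headers are parsed as an identifier followed by optional whitespace-
#' separated `key=value` metadata fields (`species`, `chromosome`,
#' `subgenome`). Sequences are uppercased and checked against the 20-letter
#' amino-acid alphabet plus `X`.
#'
#' @param path Path to a FASTA file of protein sequences.
#' @return A tibble with columns `id`, `sequence`, `species`, `chromosome`,
#'   `subgenome` (empty string where a field is absent), one row per record
#'   in file order.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) abort(sprintf("empty FASTA file: %s", path))
  headers <- names(aa)
  parts <- strsplit(headers, "\\s+")
  ids <- vapply(parts, `[[`, character(1), 1)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate FASTA id(s): %s", paste(unique(dup), collapse = ", ")))
  }
  meta_field <- function(p, key) {
    hit <- grep(paste0("^", key, "="), p, value = TRUE)
    if (length(hit) == 0) "" else sub(paste0("^", key, "="), "", hit[1])
  }
  seqs <- toupper(as.character(aa))
  purrr::walk2(seqs, ids, check_aa_alphabet)
  tibble::tibble(
    id = ids,
    sequence = unname(seqs),
    species = vapply(parts, meta_field, character(1), key = "species"),
    chromosome = vapply(parts, meta_field, character(1), key = "chromosome"),
    subgenome = vapply(parts, meta_field, character(1), key = "subgenome")
  )
}

#' Write protein records to FASTA
#'
#' Inverse of [read_protein_fasta()]: non-empty `species`, `chromosome` and
#' `subgenome` fields are serialized as `key=value` tokens in the header.
#'
#' @param records Tibble with at least `id` and `sequence` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  meta_cols <- intersect(c("species", "chromosome", "subgenome"), names(records))
  headers <- purrr::pmap_chr(records, function(...) {
    row <- list(...)
    extras <- purrr::map_chr(meta_cols, function(k) {
      v <- row[[k]] %||% ""
      if (is.na(v) || v == "") "" else paste0(k, "=", v)
    })
    paste(c(row$id, extras[extras != ""]), collapse = " ")
  })
  aa <- Biostrings::AAStringSet(setNames(records$sequence, headers))
  Biostrings::writeXStringSet(aa, path, width = 70)
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Parses `exon` and `CDS` features of a GTF 2.2 file into a flat feature
#' table. Features are returned in transcription order within each
#' transcript: ascending genomic coordinate on the plus strand, descending
#' on the minus strand. Coordinates are 1-based closed, per GTF convention.
#'
#' @param path Path to a GTF file.
#' @return A tibble with columns `gene_id`, `transcript_id`, `chromosome`,
#'   `strand`, `type` (`exon` or `CDS`), `start`, `end`, `frame` (integer,
#'   `NA` for exons).
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  gr <- rtracklayer::import(path, format = "gtf")
  feats <- tibble::tibble(
    gene_id = gr$gene_id,
    transcript_id = gr$transcript_id,
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    frame = as.integer(gr$phase)
  ) |>
    dplyr::filter(.data$type %in% c("exon", "CDS"))
  validate_gene_models(feats)
}

# Shared validation + transcription-order sorting for gene-model feature
# tables, used by both the GTF reader and the synthetic generator.
validate_gene_models <- function(feats) {
  if (nrow(feats) == 0) abort("no exon/CDS features found")
  bad_strand <- setdiff(unique(feats$strand), c("+", "-"))
  if (length(bad_strand) > 0) {
    abort(sprintf("unknown strand value(s): %s", paste(bad_strand, collapse = ", ")))
  }
  no_cds <- feats |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(has_cds = any(.data$type == "CDS"), .groups = "drop") |>
    dplyr::filter(!.data$has_cds)
  if (nrow(no_cds) > 0) {
    abort(sprintf(
      "transcript(s) without CDS features: %s",
      paste(no_cds$transcript_id, collapse = ", ")
    ))
  }
  # every CDS interval must lie inside some exon of its transcript
  orphans <- feats |>
    dplyr::filter(.data$type == "CDS") |>
    dplyr::rowwise() |>
    dplyr::mutate(contained = {
      ex <- feats[feats$transcript_id == .data$transcript_id & feats$type == "exon", ]
      any(ex$start <= .data$start & ex$end >= .data$end)
    }) |>
    dplyr::ungroup() |>
    dplyr::filter(!.data$contained)
  if (nrow(orphans) > 0) {
    abort(sprintf(
      "CDS outside any exon in transcript(s): %s",
      paste(unique(orphans$transcript_id), collapse = ", ")
    ))
  }
  feats |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::arrange(
      dplyr::if_else(.data$strand == "+", .data$start, -.data$start),
      .by_group = TRUE
    ) |>
    dplyr::ungroup()
}

#' Write gene models to a GTF file
#'
#' @param models Feature tibble as returned by [read_gtf()].
#' @param path Output path.
#' @param source Value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path, source = "bhlhfamily") {
  stopifnot(is.data.frame(models))
  gr <- GenomicRanges::GRanges(
    seqnames = models$chromosome,
    ranges = IRanges::IRanges(start = models$start, end = models$end),
    strand = models$strand,
    source = source,
    type = models$type,
    phase = as.integer(models$frame),
    gene_id = models$gene_id,
    transcript_id = models$transcript_id
  )
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read an aligned FASTA file of domain sequences
#'
#' @param path Path to an aligned FASTA file (equal row lengths; gaps `-`).
#' @return A tibble with columns `id` and `aligned`, plus attribute
#'   `alignment_length`. Rows consisting entirely of gaps are accepted with
#'   a warning.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) abort(sprintf("empty alignment file: %s", path))
  ids <- vapply(strsplit(names(aa), "\\s+"), `[[`, character(1), 1)
  rows <- toupper(as.character(aa))
  widths <- nchar(rows)
  if (length(unique(widths)) != 1) {
    off <- ids[widths != widths[1]]
    abort(sprintf(
      "ragged alignment rows (width differs from first row) for id(s): %s",
      paste(off, collapse = ", ")
    ))
  }
  purrr::walk2(gsub("-", "", rows, fixed = TRUE), ids, function(s, id) {
    if (nchar(s) > 0) check_aa_alphabet(s, id)
  })
  all_gap <- ids[!grepl("[^-]", rows)]
  if (length(all_gap) > 0) {
    warn(sprintf("alignment row(s) consisting entirely of gaps: %s",
                 paste(all_gap, collapse = ", ")))
  }
  out <- tibble::tibble(id = ids, aligned = unname(rows))
  attr(out, "alignment_length") <- unname(widths[1])
  out
}

#' Write an alignment to aligned FASTA
#'
#' @param alignment Tibble with columns `id` and `aligned`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path) {
  stopifnot(is.data.frame(alignment), all(c("id", "aligned") %in% names(alignment)))
  aa <- Biostrings::AAStringSet(setNames(alignment$aligned, alignment$id))
  Biostrings::writeXStringSet(aa, path, width = 70)
  invisible(path)
}

#' Write a rectangular table as TSV
#'
#' Deterministic column order (as supplied), UTF-8, newline-terminated;
#' the file always carries a header line even for an empty body.
#'
#' @param rows A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  if (!is.data.frame(rows)) abort("`rows` must be a data frame")
  readr::write_tsv(rows, path, progress = FALSE)
  invisible(path)
}

#' Read a TSV table written by [write_table()]
#'
#' @param path Path to a TSV file with a header line.
#' @return A tibble.
#' @export
read_table_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
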