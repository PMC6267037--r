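#' Family share of the protein-coding gene complement
#'
#' @param n_family Number of family members.
#' @param n_coding Number of protein-coding genes in the genome (> 0).
#' @return Percentage `100 * n_family / n_coding`, rounded half-up to two
#'   decimals.
#' @export
genome_fraction <- function(n_family, n_coding) {
  if (any(n_coding <= 0)) abort("`n_coding` must be positive")
  round_half_up(100 * n_family / n_coding, 2)
}

#' Chromosome and subgenome distribution of family members
#'
#' @param records Tibble with `chromosome` and `subgenome` columns (e.g.
#'   [read_protein_fasta()] output); subgenome `none` or a
#'   `scaffold`-prefixed chromosome marks an unplaced gene.
#' @return List of tibbles: `per_chromosome` (`chromosome`, `subgenome`,
#'   `count`) and `per_subgenome` (marginals over `A`, `B`, `D` plus a
#'   `scaffold` bucket; counts sum to `nrow(records)`).
#' @export
chromosome_distribution <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("chromosome", "subgenome") %in% names(records)))
  r <- records |>
    dplyr::mutate(bucket = dplyr::if_else(
      .data$subgenome %in% c("A", "B", "D"), .data$subgenome, "scaffold"
    ))
  per_chromosome <- r |>
    dplyr::count(.data$chromosome, .data$subgenome, name = "count") |>
    dplyr::arrange(.data$chromosome)
  per_subgenome <- tibble::tibble(subgenome = c("A", "B", "D", "scaffold")) |>
    dplyr::left_join(
      dplyr::count(r, .data$bucket, name = "count"),
      by = c(subgenome = "bucket")
    ) |>
    tidyr::replace_na(list(count = 0L)) |>
    dplyr::mutate(count = as.integer(.data$count))
  list(per_chromosome = per_chromosome, per_subgenome = per_subgenome)
}

#' Select one representative transcript per gene
#'
#' The representative is the transcript with the fewest consensus
#' mismatches; ties go to the longest protein, then to the
#' lexicographically smallest transcript id. Genes with no accepted
#' transcript are excluded with a warning.
#'
#' @param hits Tibble of domain hits with an `accepted` column;
#'   `protein_id` is the transcript id.
#' @param transcript_genes Tibble (`transcript_id`, `gene_id`) mapping
#'   transcripts to genes.
#' @param proteins Tibble (`id`, `sequence`) supplying protein lengths.
#' @return Tibble `gene_id`, `transcript_id` of representatives, one row
#'   per gene with at least one accepted hit.
#' @export
select_representative <- function(hits, transcript_genes, proteins) {
  acc <- dplyr::filter(hits, .data$accepted)
  lengths <- tibble::tibble(
    protein_id = proteins$id,
    protein_length = nchar(proteins$sequence)
  )
  joined <- acc |>
    dplyr::inner_join(transcript_genes, by = c(protein_id = "transcript_id")) |>
    dplyr::left_join(lengths, by = "protein_id")
  dropped <- setdiff(transcript_genes$gene_id, joined$gene_id)
  if (length(dropped) > 0) {
    warn(sprintf("gene(s) without an accepted transcript excluded: %s",
                 paste(sort(dropped), collapse = ", ")))
  }
  joined |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::arrange(.data$total_mismatches, dplyr::desc(.data$protein_length),
                   .data$protein_id, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select("gene_id", transcript_id = "protein_id") |>
    dplyr::arrange(.data$gene_id)
}

#' Expression-threshold filter
#'
#' Selects genes whose maximum value across samples meets the unit's
#' inclusion threshold. The conventional thresholds carry deliberately
#' mixed comparison semantics: strictly greater than 10 for TPM, at least
#' 5 for FPKM/RPKM.
#'
#' @param matrix Expression tibble with a `gene` column and one numeric
#'   column per sample (attribute `unit` set by [generate_expression()],
#'   or pass `unit`).
#' @param min_value Threshold; defaults to 10 (TPM) or 5 (FPKM/RPKM).
#' @param unit One of `"TPM"`, `"FPKM"`, `"RPKM"`; read from the matrix
#'   attribute when omitted.
#' @return Character vector of genes passing the filter, in input order.
#' @export
expression_filter <- function(matrix, min_value = NULL, unit = NULL) {
  stopifnot(is.data.frame(matrix), "gene" %in% names(matrix))
  unit <- unit %||% attr(matrix, "unit") %||% "TPM"
  unit <- match.arg(unit, c("TPM", "FPKM", "RPKM"))
  min_value <- min_value %||% if (unit == "TPM") 10 else 5
  vals <- as.matrix(matrix[, setdiff(names(matrix), "gene"), drop = FALSE])
  maxv <- apply(vals, 1, max)
  keep <- if (unit == "TPM") maxv > min_value else maxv >= min_value
  matrix$gene[keep]
}

#' Select differentially expressed genes per contrast
#'
#' A gene is differentially expressed when `|log2fc| >= log2(fc_cutoff)`
#' and `padj <= padj_cutoff` (both boundaries inclusive). Genes with a
#' missing adjusted p are skipped with a warning.
#'
#' @param de_stats Tibble with columns `gene`, `contrast`, `log2fc`,
#'   `padj`.
#' @param fc_cutoff Fold-change cutoff on the linear scale (default 2,
#'   i.e. `|log2fc| >= 1`).
#' @param padj_cutoff Adjusted-p cutoff.
#' @return Tibble `gene`, `contrast`, `log2fc`, `padj`, `direction`
#'   (`up`/`down`), one row per selected gene and contrast.
#' @export
select_degs <- function(de_stats, fc_cutoff = 2, padj_cutoff = 0.05) {
  stopifnot(is.data.frame(de_stats),
            all(c("gene", "contrast", "log2fc", "padj") %in% names(de_stats)))
  missing_p <- is.na(de_stats$padj)
  if (any(missing_p)) {
    warn(sprintf("%d gene(s) with missing adjusted p skipped", sum(missing_p)))
    de_stats <- de_stats[!missing_p, ]
  }
  de_stats |>
    dplyr::filter(abs(.data$log2fc) >= log2(fc_cutoff),
                  .data$padj <= padj_cutoff) |>
    dplyr::mutate(direction = dplyr::if_else(.data$log2fc > 0, "up", "down")) |>
    dplyr::select("gene", "contrast", "log2fc", "padj", "direction") |>
    dplyr::arrange(.data$contrast, .data$gene)
}

#' Assemble the family report bundle
#'
#' Writes every stage output plus a YAML run-configuration snapshot and a
#' plain-text log into one directory. Output bytes are a deterministic
#' function of the inputs, so re-running an identical configuration
#' reproduces the bundle exactly.
#'
#' @param stages Named list with mandatory elements `table1`,
#'   `pattern_distribution`, `conservation`, `chromosome`,
#'   `expression_sets` (each a data frame) and `config` (a list).
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
assemble_report <- function(stages, out_dir) {
  mandatory <- c("table1", "pattern_distribution", "conservation",
                 "chromosome", "expression_sets", "config")
  missing <- setdiff(mandatory, names(stages))
  if (length(missing) > 0) {
    abort(sprintf("missing mandatory stage output(s): %s",
                  paste(missing, collapse = ", ")))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tables <- setdiff(mandatory, "config")
  files <- character(0)
  log_lines <- c("bhlhfamily report bundle")
  for (nm in tables) {
    f <- file.path(out_dir, paste0(nm, ".tsv"))
    write_table(stages[[nm]], f)
    files[nm] <- f
    log_lines <- c(log_lines, sprintf("wrote %s.tsv: %d rows", nm, nrow(stages[[nm]])))
  }
  cfg <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(stages$config, cfg)
  files["config"] <- cfg
  log_file <- file.path(out_dir, "report.log")
  writeLines(log_lines, log_file)
  files["log"] <- log_file
  invisible(files)
}
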