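NONBASIC_RESIDUES <- setdiff(AA_STANDARD, BASIC_RESIDUES)

# Canonical synthetic bHLH domain used as the generator's backbone and as
# the seed for the packaged toy alignment. Architecture: basic 17 aa,
# helix1 15 aa, elastic loop (6 at the mode), helix2 22 aa.
CANON_BASIC <- "ANRRERNRHRMNERNRR"
CANON_HELIX1 <- "VERNRRMKLNDSLHD"
CANON_LOOP <- "GSLPKT"
CANON_HELIX2 <- "AQVLSEAARYIKFLQDQVEKLR"

canonical_domain <- function(loop_length = 6L) {
  loop <- CANON_LOOP
  extend <- "STGNAPQDVM"
  while (nchar(loop) < loop_length) loop <- paste0(loop, extend)
  paste0(CANON_BASIC, CANON_HELIX1, substr(loop, 1, loop_length), CANON_HELIX2)
}

# Allowed basic-residue counts per binding category given the residues the
# category itself forces (R-16/R-17 and His/Lys-9 are basic).
BASIC_COUNT_RANGES <- list(
  G_binder = c(5L, 11L), E_non_G = c(5L, 11L), non_E_binder = c(5L, 11L),
  potential_E_box = c(1L, 4L), potential_G_box = c(3L, 4L), non_binder = c(0L, 4L)
)

default_blueprints <- function() {
  list(
    list(label = "intronless", positions = integer(0), phases = integer(0), weight = 0.20),
    list(label = "loop_p0", positions = 33L, phases = 0L, weight = 0.35),
    list(label = "triple_p0", positions = c(16L, 33L, 48L), phases = c(0L, 0L, 0L), weight = 0.20),
    list(label = "helix1_p1", positions = 24L, phases = 1L, weight = 0.15),
    list(label = "basic_p2_helix2_p0", positions = c(10L, 44L), phases = c(2L, 0L), weight = 0.10)
  )
}

#' Specify a synthetic bHLH gene family
#'
#' Bundles and validates all generator parameters. The defaults emulate the
#' hexaploid-wheat family structure: subgenome proportions and the
#' binding-category mix follow the family's observed contingency row, loop
#' lengths centre on six residues (domain mode 60 aa), and the intron
#' blueprints cover the recurrent pattern types (intronless, a single
#' phase-0 loop intron, three phase-0 introns, plus two rarer signatures).
#'
#' @param n_genes Number of genes to generate.
#' @param species Species label attached to every record.
#' @param subgenome_fractions Simplex over subgenomes `A`, `B`, `D`.
#' @param scaffold_fraction Probability that a gene sits on an unplaced
#'   scaffold (subgenome `none`).
#' @param binding_category_mix Simplex over the six binding categories.
#' @param basic_counts Optional named integer vector fixing the basic-
#'   residue count per category; must be achievable (at least 5 for the
#'   binder categories, below 5 — and at least the category's forced
#'   residues — otherwise), or generation refuses up front.
#' @param intron_blueprints List of blueprints, each
#'   `list(label, positions, phases, weight)` with domain-relative codon
#'   positions and phases in 0..2.
#' @param loop_length_distribution Named probability vector over loop
#'   lengths 5..15.
#' @param noise_rate Per-position substitution probability applied to the
#'   helix1/loop/helix2 part of the planted domain (the basic region and
#'   its rule positions are never mutated, so truth categories stay
#'   consistent with the emitted residues).
#' @param expression_class_mix Simplex over `tissue_specific`, `broad`,
#'   `silent`.
#' @param tissues Tissue panel for expression classes.
#' @param seed Integer seed; a fixed seed makes generation byte-identical.
#' @return A validated `family_spec` object.
#' @export
family_spec <- function(n_genes = 200L,
                        species = "wheat",
                        subgenome_fractions = c(A = 176, B = 193, D = 183) / 552,
                        scaffold_fraction = 19 / 571,
                        binding_category_mix = c(
                          G_binder = 291, E_non_G = 85, non_E_binder = 84,
                          potential_E_box = 8, potential_G_box = 3, non_binder = 100
                        ) / 571,
                        basic_counts = NULL,
                        intron_blueprints = default_blueprints(),
                        loop_length_distribution = c(
                          "5" = 0.08, "6" = 0.64, "7" = 0.12, "8" = 0.07,
                          "9" = 0.04, "10" = 0.02, "11" = 0.01, "12" = 0.01,
                          "13" = 0.005, "14" = 0.0025, "15" = 0.0025
                        ),
                        noise_rate = 0,
                        expression_class_mix = c(
                          tissue_specific = 0.35, broad = 0.45, silent = 0.20
                        ),
                        tissues = c("root", "stem", "leaf", "spike", "grain"),
                        seed = 1L) {
  check_simplex <- function(x, what) {
    if (abs(sum(x) - 1) > 1e-9) {
      abort(sprintf("%s must sum to 1 (got %.12f)", what, sum(x)))
    }
    if (any(x < 0)) abort(sprintf("%s must be non-negative", what))
  }
  check_simplex(subgenome_fractions, "subgenome_fractions")
  check_simplex(binding_category_mix, "binding_category_mix")
  check_simplex(loop_length_distribution, "loop_length_distribution")
  check_simplex(expression_class_mix, "expression_class_mix")
  stopifnot(
    all(names(subgenome_fractions) == c("A", "B", "D")),
    all(names(binding_category_mix) == BINDING_CATEGORIES),
    scaffold_fraction >= 0, scaffold_fraction < 1,
    n_genes >= 1, noise_rate >= 0, noise_rate <= 1,
    length(tissues) >= 1
  )
  loops <- as.integer(names(loop_length_distribution))
  if (any(is.na(loops)) || any(loops < 5L) || any(loops > 15L)) {
    abort("loop_length_distribution must be keyed by loop lengths 5..15")
  }
  max_domain_all_loops <- 54L + min(loops[loop_length_distribution > 0])
  w <- vapply(intron_blueprints, `[[`, numeric(1), "weight")
  check_simplex(w, "intron blueprint weights")
  for (bp in intron_blueprints) {
    stopifnot(length(bp$positions) == length(bp$phases))
    if (length(bp$positions) > 0) {
      if (any(bp$phases < 0L | bp$phases > 2L)) {
        abort(sprintf("blueprint '%s': phases must be in 0..2", bp$label))
      }
      if (any(bp$positions < 1L | bp$positions > max_domain_all_loops)) {
        abort(sprintf(
          "blueprint '%s': positions must lie in 1..%d (shortest generated domain)",
          bp$label, max_domain_all_loops
        ))
      }
      if (is.unsorted(bp$positions, strictly = FALSE)) {
        abort(sprintf("blueprint '%s': positions must be ascending", bp$label))
      }
    }
  }
  if (!is.null(basic_counts)) {
    for (cat in names(basic_counts)) {
      rng <- BASIC_COUNT_RANGES[[cat]]
      if (is.null(rng)) abort(sprintf("unknown category in basic_counts: %s", cat))
      if (basic_counts[[cat]] < rng[1] || basic_counts[[cat]] > rng[2]) {
        abort(sprintf(
          "impossible spec: category %s requires %d..%d basic residues, got %d",
          cat, rng[1], rng[2], basic_counts[[cat]]
        ))
      }
    }
  }
  structure(
    list(
      n_genes = as.integer(n_genes), species = species,
      subgenome_fractions = subgenome_fractions,
      scaffold_fraction = scaffold_fraction,
      binding_category_mix = binding_category_mix,
      basic_counts = basic_counts,
      intron_blueprints = intron_blueprints,
      loop_length_distribution = loop_length_distribution,
      noise_rate = noise_rate,
      expression_class_mix = expression_class_mix,
      tissues = tissues,
      seed = as.integer(seed)
    ),
    class = "family_spec"
  )
}

# Build a 17-residue basic region that forces `category`, with exactly
# `target` basic residues (drawn from the category's allowed range when
# target is NULL). Rule positions: His/Lys-9, Glu-13, Arg-16, Arg-17.
build_basic_region <- function(category, target = NULL) {
  ch <- sample(NONBASIC_RESIDUES, 17, replace = TRUE)
  rule <- switch(category,
    G_binder = c(`9` = sample(c("H", "K"), 1), `13` = "E", `16` = "R", `17` = "R"),
    E_non_G = c(`9` = "N", `13` = "E", `16` = "R", `17` = "S"),
    non_E_binder = c(`9` = "N", `13` = "S", `16` = "A", `17` = "T"),
    potential_G_box = c(`9` = sample(c("H", "K"), 1), `13` = "E", `16` = "R", `17` = "R"),
    potential_E_box = c(`9` = "N", `13` = "E", `16` = "R", `17` = "S"),
    non_binder = c(`9` = "N", `13` = "A", `16` = "S", `17` = "A"),
    abort(sprintf("unknown binding category: %s", category))
  )
  ch[as.integer(names(rule))] <- unname(rule)
  forced <- sum(ch %in% BASIC_RESIDUES)
  rng <- BASIC_COUNT_RANGES[[category]]
  if (is.null(target)) {
    target <- sample(seq.int(max(rng[1], forced), rng[2]), 1)
  }
  extra <- target - forced
  if (extra < 0) {
    abort(sprintf("impossible spec: category %s cannot have %d basic residues (rule residues alone give %d)",
                  category, target, forced))
  }
  free <- setdiff(seq_len(17), c(9L, 13L, 16L, 17L))
  if (extra > length(free)) abort("basic-residue target exceeds region capacity")
  if (extra > 0) {
    slots <- sample(free, extra)
    ch[slots] <- sample(BASIC_RESIDUES, extra, replace = TRUE)
  }
  list(region = paste(ch, collapse = ""), basic_count = target)
}

# Lexicographically first codon per amino acid: a fixed slice of the
# standard genetic code so back-translation is reproducible.
codon_for_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  split_codons <- split(names(gc), unname(gc))
  vapply(split_codons, function(x) sort(x)[1], character(1))
}

back_translate <- function(protein, codon_map = codon_for_aa()) {
  aa <- seq_chars(protein)[[1]]
  paste(codon_map[aa], collapse = "")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

# Substitute each position with probability `rate`, drawing a different
# standard residue.
apply_noise <- function(chars, rate) {
  if (rate <= 0) return(chars)
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(a) {
      sample(setdiff(AA_STANDARD, a), 1)
    }, character(1))
  }
  chars
}

#' Generate a synthetic bHLH gene family with ground truth
#'
#' Every generated protein contains exactly one planted domain whose
#' location, loop length, binding category, basic-residue count and intron
#' signature are recorded in the truth table. Gene models back-translate
#' the protein through a fixed codon slice (stop codon excluded from the
#' CDS), introns are inserted at blueprint positions with their declared
#' phases (lengths uniform 60-300 nt), flanking protein sequence and UTRs
#' are random, and strands are mixed. A fixed spec seed reproduces the
#' output exactly.
#'
#' @param spec A [family_spec()].
#' @return List with elements `proteins` (tibble `id`, `sequence`,
#'   `species`, `chromosome`, `subgenome`), `models` (gene-model feature
#'   tibble as from [read_gtf()]), `cds` (tibble `id`, `sequence` of
#'   spliced CDS nucleotides), `truth` (one row per gene) and `spec`.
#' @export
generate_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  codon_map <- codon_for_aa()
  with_seed(spec$seed, {
    n <- spec$n_genes
    categories <- sample(BINDING_CATEGORIES, n, replace = TRUE,
                         prob = spec$binding_category_mix)
    loop_support <- as.integer(names(spec$loop_length_distribution))
    loops <- loop_support[sample.int(length(loop_support), n, replace = TRUE,
                                     prob = spec$loop_length_distribution)]
    bp_idx <- sample(seq_along(spec$intron_blueprints), n, replace = TRUE,
                     prob = vapply(spec$intron_blueprints, `[[`, numeric(1), "weight"))
    on_scaffold <- runif(n) < spec$scaffold_fraction
    subg <- sample(names(spec$subgenome_fractions), n, replace = TRUE,
                   prob = spec$subgenome_fractions)
    classes <- sample(names(spec$expression_class_mix), n, replace = TRUE,
                      prob = spec$expression_class_mix)

    proteins <- vector("list", n)
    models <- vector("list", n)
    cds_rows <- vector("list", n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      gene_id <- sprintf("SYNG%04d", i)
      tx_id <- paste0(gene_id, ".1")
      cat_i <- categories[i]
      l <- loops[i]
      target_basics <- if (!is.null(spec$basic_counts) && cat_i %in% names(spec$basic_counts)) {
        spec$basic_counts[[cat_i]]
      } else {
        NULL
      }
      basic <- build_basic_region(cat_i, target_basics)
      rest <- seq_chars(substr(canonical_domain(l), 18L, 54L + l))[[1]]
      rest <- apply_noise(rest, spec$noise_rate)
      domain <- paste0(basic$region, paste(rest, collapse = ""))
      D <- nchar(domain)
      flank5 <- paste(sample(AA_STANDARD, sample(15:60, 1), replace = TRUE), collapse = "")
      flank3 <- paste(sample(AA_STANDARD, sample(15:60, 1), replace = TRUE), collapse = "")
      protein <- paste0(flank5, domain, flank3)
      domain_start <- nchar(flank5) + 1L
      domain_end <- domain_start + D - 1L

      chrom <- if (on_scaffold[i]) sprintf("scaffold_%04d", i) else
        paste0(sample(1:7, 1), subg[i])
      sg <- if (on_scaffold[i]) "none" else subg[i]

      bp <- spec$intron_blueprints[[bp_idx[i]]]
      keep <- bp$positions <= D
      positions <- bp$positions[keep]
      phases <- bp$phases[keep]

      cds_nt <- back_translate(protein, codon_map)
      cds_len <- nchar(cds_nt)
      dstart_nt <- 3L * (domain_start - 1L) # coding nt upstream of the domain
      cut_offsets <- dstart_nt +
        ifelse(phases == 0L, 3L * positions, 3L * (positions - 1L) + phases)
      strand <- sample(c("+", "-"), 1)
      models[[i]] <- build_gene_model(
        gene_id, tx_id, chrom, strand, cds_len, cut_offsets,
        utr5 = sample(20:60, 1), utr3 = sample(20:60, 1)
      )
      proteins[[i]] <- tibble::tibble(
        id = tx_id, sequence = protein, species = spec$species,
        chromosome = chrom, subgenome = sg
      )
      cds_rows[[i]] <- tibble::tibble(id = tx_id, sequence = cds_nt)
      tissue <- if (classes[i] == "tissue_specific") sample(spec$tissues, 1) else NA_character_
      truth[[i]] <- tibble::tibble(
        gene_id = gene_id, transcript_id = tx_id, species = spec$species,
        chromosome = chrom, subgenome = sg,
        domain_start = domain_start, domain_end = domain_end,
        domain_length = D, loop_length = l,
        binding_category = cat_i, basic_residue_count = basic$basic_count,
        blueprint = bp$label,
        intron_signature = paste(sprintf("%d.%d", positions, phases), collapse = ";"),
        n_introns = length(positions),
        expression_class = if (is.na(tissue)) classes[i] else
          paste0("tissue-specific:", tissue)
      )
    }
    list(
      proteins = dplyr::bind_rows(proteins),
      models = validate_gene_models(dplyr::bind_rows(models)),
      cds = dplyr::bind_rows(cds_rows),
      truth = dplyr::bind_rows(truth),
      spec = spec
    )
  })
}

# Exon/CDS feature rows for one transcript. `cut_offsets` are coding-
# nucleotide offsets (nt upstream of each intron); UTRs extend the first
# and last exon. Minus-strand genes are built by mirroring the plus-strand
# layout, so transcription order is descending genomic coordinate.
build_gene_model <- function(gene_id, tx_id, chrom, strand, cds_len,
                             cut_offsets, utr5, utr3, gene_start = NULL) {
  stopifnot(all(cut_offsets >= 1L), all(cut_offsets <= cds_len - 1L),
            !anyDuplicated(cut_offsets))
  gene_start <- gene_start %||% sample(1000:2000000, 1)
  bounds <- c(0L, sort(as.integer(cut_offsets)), cds_len)
  piece_len <- diff(bounds) # coding nt per exon, transcription order
  n_pieces <- length(piece_len)
  intron_len <- if (n_pieces > 1) sample(60:300, n_pieces - 1, replace = TRUE) else integer(0)

  # transcript-order exon lengths including UTRs
  exon_len <- piece_len
  exon_len[1] <- exon_len[1] + utr5
  exon_len[n_pieces] <- exon_len[n_pieces] + utr3
  # plus-strand style layout in transcription order
  ex_start <- integer(n_pieces)
  ex_end <- integer(n_pieces)
  pos <- gene_start
  for (k in seq_len(n_pieces)) {
    ex_start[k] <- pos
    ex_end[k] <- pos + exon_len[k] - 1L
    pos <- ex_end[k] + (if (k < n_pieces) intron_len[k] else 0L) + 1L
  }
  cds_start <- ex_start
  cds_end <- ex_end
  cds_start[1] <- cds_start[1] + utr5
  cds_end[n_pieces] <- cds_end[n_pieces] - utr3
  frame <- (3L - (c(0L, cumsum(piece_len))[seq_len(n_pieces)] %% 3L)) %% 3L

  if (strand == "-") {
    span_end <- ex_end[n_pieces]
    mirror <- function(s, e) {
      list(start = gene_start + (span_end - e), end = gene_start + (span_end - s))
    }
    me <- mirror(ex_start, ex_end)
    mc <- mirror(cds_start, cds_end)
    ex_start <- me$start; ex_end <- me$end
    cds_start <- mc$start; cds_end <- mc$end
  }
  dplyr::bind_rows(
    tibble::tibble(
      gene_id = gene_id, transcript_id = tx_id, chromosome = chrom,
      strand = strand, type = "exon", start = ex_start, end = ex_end,
      frame = NA_integer_
    ),
    tibble::tibble(
      gene_id = gene_id, transcript_id = tx_id, chromosome = chrom,
      strand = strand, type = "CDS", start = cds_start, end = cds_end,
      frame = as.integer(frame)
    )
  )
}

#' Generate expression and differential-expression tables for a family
#'
#' Values are constructed so the family's inclusion thresholds separate
#' the classes exactly: tissue-specific genes exceed 10 units only in
#' their tissue (elsewhere below 5), broad genes exceed 10 everywhere,
#' silent genes stay below 5 everywhere. The DE table carries each gene's
#' true log2 fold change plus Gaussian noise and adjusted-p placeholders
#' consistent with effect direction.
#'
#' @param truth Truth table from [generate_family()].
#' @param n_samples_per_tissue Replicates per tissue.
#' @param tissues Tissue panel (non-empty).
#' @param fold_changes Named vector of true absolute log2 fold changes per
#'   contrast.
#' @param dispersion Standard deviation of the log2-fold-change noise;
#'   must be non-negative.
#' @param deg_fraction Fraction of non-silent genes that are differentially
#'   expressed per contrast (half up, half down).
#' @param seed Integer seed.
#' @return List: `expression` (tibble, genes x samples, attribute `unit` =
#'   `"TPM"`), `samples` (tibble `sample`, `tissue`), `de_stats` (tibble
#'   `gene`, `contrast`, `true_log2fc`, `log2fc`, `padj`).
#' @export
generate_expression <- function(truth, n_samples_per_tissue = 2L,
                                tissues = c("root", "stem", "leaf", "spike", "grain"),
                                fold_changes = c(drought = 2),
                                dispersion = 0.15, deg_fraction = 0.25,
                                seed = 1L) {
  if (length(tissues) == 0) abort("`tissues` must be non-empty")
  if (dispersion < 0) abort("`dispersion` must be non-negative")
  stopifnot(is.data.frame(truth), "expression_class" %in% names(truth))
  with_seed(seed, {
    samples <- tibble::tibble(
      tissue = rep(tissues, each = n_samples_per_tissue),
      sample = paste0(rep(tissues, each = n_samples_per_tissue), "_",
                      rep(seq_len(n_samples_per_tissue), length(tissues)))
    )
    genes <- truth$transcript_id
    cls <- truth$expression_class
    own_tissue <- ifelse(startsWith(cls, "tissue-specific:"),
                         sub("^tissue-specific:", "", cls), NA_character_)
    expr <- matrix(0, nrow = length(genes), ncol = nrow(samples),
                   dimnames = list(genes, samples$sample))
    for (j in seq_len(nrow(samples))) {
      tis <- samples$tissue[j]
      v <- numeric(length(genes))
      silent <- cls == "silent"
      broad <- cls == "broad"
      spec_on <- !is.na(own_tissue) & own_tissue == tis
      spec_off <- !is.na(own_tissue) & own_tissue != tis
      v[silent] <- runif(sum(silent), 0, 4.5)
      v[broad] <- 12 + rlnorm(sum(broad), 2, 0.5)
      v[spec_on] <- 10.5 + rlnorm(sum(spec_on), 2.5, 0.6)
      v[spec_off] <- runif(sum(spec_off), 0, 4.5)
      expr[, j] <- round(v, 3)
    }
    expression <- tibble::as_tibble(expr, rownames = "gene")
    attr(expression, "unit") <- "TPM"

    de <- purrr::imap(fold_changes, function(lfc, contrast) {
      eligible <- genes[cls != "silent"]
      n_deg <- ceiling(deg_fraction * length(eligible))
      deg <- sample(eligible, n_deg)
      sign <- rep(c(1, -1), length.out = n_deg)
      true_lfc <- setNames(numeric(length(genes)), genes)
      true_lfc[deg] <- sign * lfc
      tibble::tibble(
        gene = genes,
        contrast = contrast,
        true_log2fc = unname(true_lfc),
        log2fc = unname(true_lfc) + rnorm(length(genes), 0, dispersion),
        padj = ifelse(genes %in% deg, runif(length(genes), 1e-6, 0.01),
                      runif(length(genes), 0.2, 1))
      )
    })
    list(expression = expression, samples = samples,
         de_stats = dplyr::bind_rows(de))
  })
}

#' Write a generated family to disk
#'
#' Emits `proteins.fasta`, `genes.gtf`, `cds.fasta` and `truth.tsv` into
#' `dir`; with expression output also `expr.tsv`, `samples.tsv` and
#' `de_stats.tsv`.
#'
#' @param family List from [generate_family()].
#' @param dir Output directory (created if needed).
#' @param expression Optional list from [generate_expression()].
#' @return `dir`, invisibly.
#' @export
write_family <- function(family, dir, expression = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_protein_fasta(family$proteins, file.path(dir, "proteins.fasta"))
  write_gtf(family$models, file.path(dir, "genes.gtf"))
  dna <- Biostrings::DNAStringSet(setNames(family$cds$sequence, family$cds$id))
  Biostrings::writeXStringSet(dna, file.path(dir, "cds.fasta"), width = 70)
  write_table(family$truth, file.path(dir, "truth.tsv"))
  if (!is.null(expression)) {
    write_table(expression$expression, file.path(dir, "expr.tsv"))
    write_table(expression$samples, file.path(dir, "samples.tsv"))
    write_table(expression$de_stats, file.path(dir, "de_stats.tsv"))
  }
  invisible(dir)
}
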