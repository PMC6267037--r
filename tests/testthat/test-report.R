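profile <- default_profile()

test_that("genome fraction reproduces printed two-decimal percentages", {
  expect_equal(genome_fraction(0, 1000), 0)
  expect_equal(genome_fraction(1, 800), 0.13) # 0.125 rounds half-up
  expect_error(genome_fraction(10, 0), "positive")
})

test_that("chromosome distribution marginals sum to the record count", {
  fam <- generate_family(family_spec(n_genes = 120, seed = 67))
  cd <- chromosome_distribution(fam$proteins)
  expect_equal(sum(cd$per_subgenome$count), 120L)
  expect_equal(sum(cd$per_chromosome$count), 120L)
  expect_equal(
    cd$per_subgenome$count[cd$per_subgenome$subgenome == "scaffold"],
    sum(fam$proteins$subgenome == "none")
  )
  # counting oracle per subgenome
  for (sg in c("A", "B", "D")) {
    expect_equal(cd$per_subgenome$count[cd$per_subgenome$subgenome == sg],
                 sum(fam$proteins$subgenome == sg))
  }
  one <- chromosome_distribution(tibble::tibble(chromosome = "1A", subgenome = "A"))
  expect_equal(nrow(one$per_chromosome), 1)
})

test_that("representative selection follows mismatches, then length, then id", {
  proteins <- tibble::tibble(
    id = c("t1", "t2", "t3", "t4"),
    sequence = c(strrep("A", 400), strrep("A", 350), strrep("A", 350),
                 strrep("A", 350))
  )
  tg <- tibble::tibble(transcript_id = c("t1", "t2", "t3", "t4"),
                       gene_id = c("g1", "g1", "g2", "g2"))
  hits <- dplyr::bind_rows(
    dplyr::mutate(manual_hit("t1", 1), total_mismatches = 3),
    dplyr::mutate(manual_hit("t2", 1), total_mismatches = 5),
    dplyr::mutate(manual_hit("t3", 1), total_mismatches = 2),
    dplyr::mutate(manual_hit("t4", 1), total_mismatches = 2)
  )
  rep <- select_representative(hits, tg, proteins)
  expect_equal(rep$transcript_id[rep$gene_id == "g1"], "t1") # fewer mismatches
  expect_equal(rep$transcript_id[rep$gene_id == "g2"], "t3") # id tie-break
  # tie on mismatches -> longest protein
  hits2 <- dplyr::mutate(hits, total_mismatches = 2)
  rep2 <- select_representative(hits2, tg, proteins)
  expect_equal(rep2$transcript_id[rep2$gene_id == "g1"], "t1")
  # gene with no accepted transcript is excluded with a warning
  hits3 <- dplyr::mutate(hits, accepted = c(TRUE, TRUE, FALSE, FALSE))
  expect_warning(rep3 <- select_representative(hits3, tg, proteins), "g2")
  expect_equal(rep3$gene_id, "g1")
})

test_that("representative selection agrees with a sort-based oracle", {
  set.seed(71)
  for (i in 1:20) {
    n <- sample(2:5, 1)
    cand <- tibble::tibble(
      id = sprintf("tx%02d", sample(99, n)),
      mm = sample(0:6, n, replace = TRUE),
      len = sample(200:400, n, replace = TRUE)
    )
    proteins <- tibble::tibble(id = cand$id,
                               sequence = vapply(cand$len, strrep, "", x = "A"))
    tg <- tibble::tibble(transcript_id = cand$id, gene_id = "g")
    hits <- dplyr::bind_rows(lapply(seq_len(n), function(j) {
      dplyr::mutate(manual_hit(cand$id[j], 1), total_mismatches = cand$mm[j])
    }))
    want <- cand[order(cand$mm, -cand$len, cand$id), ]$id[1]
    expect_equal(select_representative(hits, tg, proteins)$transcript_id, want)
  }
})

test_that("expression thresholds keep the documented boundary semantics", {
  m <- tibble::tibble(
    gene = c("at9.99", "at10", "just_over", "at5", "under5"),
    s1 = c(9.99, 10, 10.01, 5, 4.99),
    s2 = c(1, 1, 1, 1, 1)
  )
  # strict > for TPM-10
  expect_equal(expression_filter(m, unit = "TPM"), "just_over")
  # inclusive >= for FPKM-5
  expect_equal(expression_filter(m, unit = "FPKM"),
               c("at9.99", "at10", "just_over", "at5"))
  # synthetic recovery: filter equals the non-silent classes
  fam <- generate_family(family_spec(n_genes = 50, seed = 83))
  ex <- generate_expression(fam$truth, seed = 83)
  got <- expression_filter(ex$expression)
  want <- fam$truth$transcript_id[fam$truth$expression_class != "silent"]
  expect_equal(sort(got), sort(want))
})

test_that("DEG selection pins both boundaries and mirrors reversed contrasts", {
  de <- tibble::tibble(
    gene = c("a", "b", "c", "d"),
    contrast = "drought",
    log2fc = c(1.0, 0.9, -1.2, 2.0),
    padj = c(0.05, 0.001, 0.01, NA)
  )
  expect_warning(sel <- select_degs(de), "missing adjusted p")
  expect_equal(sel$gene, c("a", "c"))
  expect_equal(sel$direction, c("up", "down"))
  # reversed contrast: up and down swap
  rev <- dplyr::mutate(de[1:3, ], log2fc = -log2fc, contrast = "drought_rev")
  sel_rev <- select_degs(rev)
  expect_equal(sel_rev$gene, sel$gene)
  expect_equal(sel_rev$direction, c("down", "up"))
  # synthetic recovery of planted signs at |log2FC| = 2
  fam <- generate_family(family_spec(n_genes = 60, seed = 3))
  hitrate <- purrr::map_dbl(1:20, function(s) {
    de <- generate_expression(fam$truth, fold_changes = c(drought = 2),
                              seed = s)$de_stats
    sel <- select_degs(de)
    truth_up <- de$gene[de$true_log2fc > 0]
    truth_dn <- de$gene[de$true_log2fc < 0]
    got_up <- sel$gene[sel$direction == "up"]
    got_dn <- sel$gene[sel$direction == "down"]
    (sum(truth_up %in% got_up) + sum(truth_dn %in% got_dn)) /
      (length(truth_up) + length(truth_dn))
  })
  expect_gte(mean(hitrate), 0.95)
})

test_that("the report bundle is complete and byte-deterministic", {
  fam <- generate_family(family_spec(n_genes = 30, seed = 11))
  hits <- scan_domains(fam$proteins, profile)
  calls <- classify_binding(hits, fam$proteins)
  tab <- tabulate_categories(calls, setNames(fam$proteins$species, fam$proteins$id))
  ev <- map_introns_to_domain(fam$models, hits)
  pats <- assign_patterns(ev, hits)
  ex <- generate_expression(fam$truth, seed = 11)
  stages <- list(
    table1 = tab,
    pattern_distribution = pattern_distribution(pats),
    conservation = column_conservation(toy_seed_alignment()),
    chromosome = chromosome_distribution(fam$proteins)$per_subgenome,
    expression_sets = tibble::tibble(gene = expression_filter(ex$expression)),
    config = list(seed = 11, n_genes = 30, threshold = 0.5, max_mismatches = 12)
  )
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  assemble_report(stages, d1)
  assemble_report(stages, d2)
  files <- c("table1.tsv", "pattern_distribution.tsv", "conservation.tsv",
             "chromosome.tsv", "expression_sets.tsv", "config.yaml", "report.log")
  expect_setequal(list.files(d1), files)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  expect_error(assemble_report(stages[-1], d1), "table1")
})
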