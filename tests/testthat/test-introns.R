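profile <- default_profile()

test_that("domain CDS interval arithmetic is exact", {
  # 100-aa protein, domain residues 10..69 -> CDS nucleotides 28..207
  gene <- manual_gene("g", "g.1", "chr1", "+", list(c(101, 400, 101, 400)))
  hit <- manual_hit("g.1", 10)
  iv <- domain_cds_interval(gene, hit)
  expect_equal(iv$cds_start, 28L)
  expect_equal(iv$cds_end, 207L)
  # domain starting at residue 1 begins at CDS nucleotide 1
  iv2 <- domain_cds_interval(gene, manual_hit("g.1", 1))
  expect_equal(iv2$cds_start, 1L)
  # domain extending beyond the CDS is an error
  short <- manual_gene("g", "g.1", "chr1", "+", list(c(101, 190, 101, 190)))
  expect_error(domain_cds_interval(short, hit), "beyond CDS.*g\\.1")
})

test_that("an intron after the first nucleotide of domain codon 30 maps to (30, 1)", {
  # domain at residues 10..69: cut after CDS nt 27 + 3*29 + 1 = 115
  gene <- manual_gene("g", "g.1", "chr1", "+",
                      list(c(101, 215, 101, 215), c(316, 500, 316, 500)))
  hit <- manual_hit("g.1", 10)
  ev <- map_introns_to_domain(gene, hit)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$domain_codon, 30L)
  expect_equal(ev$phase, 1L)
  expect_equal(ev$region, "helix1")
})

test_that("a mirrored minus-strand gene yields identical intron events", {
  plus <- manual_gene("g", "g.1", "chr1", "+",
                      list(c(101, 215, 101, 215), c(316, 500, 316, 500)))
  # mirror the layout across the gene span [101, 500]
  mirror <- function(s, e) c(101 + (500 - e), 101 + (500 - s))
  minus <- manual_gene("g", "g.1", "chr1", "-",
                       list(c(mirror(101, 215), mirror(101, 215)),
                            c(mirror(316, 500), mirror(316, 500))))
  hit <- manual_hit("g.1", 10)
  expect_equal(map_introns_to_domain(minus, hit),
               map_introns_to_domain(plus, hit))
})

test_that("single-exon genes produce no events", {
  gene <- manual_gene("g", "g.1", "chr1", "+", list(c(1, 300, 1, 300)))
  ev <- map_introns_to_domain(gene, manual_hit("g.1", 10))
  expect_equal(nrow(ev), 0)
})

test_that("planted (codon, phase) round-trips exhaustively through the generator", {
  # one gene per (codon, phase); a phase-0 cut after codon 60 falls on the
  # domain's 3' boundary and must not be reported as interior
  set.seed(1)
  cases <- expand.grid(k = seq(1, 60, by = 1), p = 0:2)
  boundary <- cases$k == 60 & cases$p == 0
  for (i in seq_len(nrow(cases))) {
    k <- cases$k[i]; p <- cases$p[i]
    bp <- list(list(label = "t", positions = as.integer(k),
                    phases = as.integer(p), weight = 1))
    fam <- generate_family(family_spec(
      n_genes = 1, seed = 1000 + i, intron_blueprints = bp,
      loop_length_distribution = c("6" = 1)
    ))
    hit <- manual_hit(fam$truth$transcript_id, fam$truth$domain_start)
    ev <- map_introns_to_domain(fam$models, hit)
    if (boundary[i]) {
      expect_equal(nrow(ev), 0)
    } else {
      expect_equal(nrow(ev), 1)
      expect_equal(ev$domain_codon, k)
      expect_equal(ev$phase, p)
    }
  }
})

test_that("strand choice in the generator never changes mapped events", {
  fam <- generate_family(family_spec(n_genes = 40, seed = 77))
  hits <- scan_domains(fam$proteins, profile)
  ev <- map_introns_to_domain(fam$models, hits)
  sig <- ev |>
    dplyr::group_by(transcript_id) |>
    dplyr::summarise(sig = paste(sprintf("%d.%d", domain_codon, phase),
                                 collapse = ";"), .groups = "drop")
  cmp <- fam$truth |>
    dplyr::left_join(sig, by = "transcript_id") |>
    dplyr::mutate(sig = dplyr::coalesce(sig, ""))
  expect_equal(cmp$sig, cmp$intron_signature)
  expect_true(all(c("+", "-") %in% fam$models$strand))
})

test_that("pattern registry labels deterministically and ignores input order", {
  fam <- generate_family(family_spec(n_genes = 30, seed = 41))
  hits <- scan_domains(fam$proteins, profile)
  ev <- map_introns_to_domain(fam$models, hits)
  p1 <- assign_patterns(ev, hits)
  p2 <- assign_patterns(ev[sample(nrow(ev)), ], hits[sample(nrow(hits)), ])
  expect_equal(p1, p2, ignore_attr = TRUE)
  # count conservation: every accepted gene gets exactly one label
  expect_equal(nrow(p1), sum(hits$accepted))
  # intronless genes take the reserved label
  zero <- fam$truth$transcript_id[fam$truth$n_introns == 0]
  expect_equal(sort(p1$transcript_id[p1$label == "intronless"]), sort(zero))
})

test_that("signatures differing in phase or position get distinct labels", {
  hits <- dplyr::bind_rows(manual_hit("a", 1), manual_hit("b", 1),
                           manual_hit("c", 1), manual_hit("d", 1))
  ev <- tibble::tibble(
    transcript_id = c("a", "b", "c", "d"),
    cds_offset = 1L,
    domain_codon = c(30L, 30L, 30L, 45L),
    phase = c(1L, 1L, 2L, 1L),
    region = "helix1"
  )
  pats <- assign_patterns(ev, hits)
  lab <- setNames(pats$label, pats$transcript_id)
  expect_equal(lab[["a"]], lab[["b"]]) # identical signatures share a label
  expect_false(lab[["a"]] == lab[["c"]]) # phase differs
  expect_false(lab[["a"]] == lab[["d"]]) # position beyond tolerance
  reg <- pattern_registry(pats)
  expect_equal(sort(reg$label), c("A", "B", "C"))
  long <- tidy(reg)
  expect_equal(nrow(long), 3)
})

test_that("nearby positions within tolerance merge into one pattern", {
  hits <- dplyr::bind_rows(manual_hit("a", 1), manual_hit("b", 1))
  ev <- tibble::tibble(
    transcript_id = c("a", "b"), cds_offset = 1L,
    domain_codon = c(30L, 31L), phase = c(0L, 0L), region = "helix1"
  )
  pats <- assign_patterns(ev, hits, tolerance = 2)
  expect_equal(length(unique(pats$label)), 1)
  pats0 <- assign_patterns(ev, hits, tolerance = 0.5)
  expect_equal(length(unique(pats0$label)), 2)
})

test_that("pattern distribution percentages are per group and half-up", {
  pats <- tibble::tibble(
    transcript_id = sprintf("g%02d", 1:93),
    n_introns = 1L, signature = "x",
    label = c(rep("A", 87), rep("B", 6))
  )
  dist <- pattern_distribution(pats, setNames(rep("XII", 93), pats$transcript_id))
  expect_equal(dist$percentage[dist$label == "A"], 93.55)
  expect_equal(sum(dist$count), 93)
  one <- pattern_distribution(pats[1, ])
  expect_equal(one$percentage, 100)
})

test_that("gene-structure statistics match a brute-force recomputation", {
  fam <- generate_family(family_spec(n_genes = 40, seed = 53))
  stats <- gene_structure_stats(fam$models)
  # independent recomputation straight from the feature table
  for (tx in sample(stats$transcript_id, 10)) {
    cds <- fam$models[fam$models$transcript_id == tx & fam$models$type == "CDS", ]
    ord <- order(if (cds$strand[1] == "+") cds$start else -cds$start)
    w <- (cds$end - cds$start + 1)[ord]
    phases <- cumsum(w)[-length(w)] %% 3
    sym <- if (length(phases) < 2) 0 else
      sum(phases[-length(phases)] == 0 & phases[-1] == 0)
    row <- stats[stats$transcript_id == tx, ]
    expect_equal(row$n_cds_exons, length(w))
    expect_equal(row$intronless, length(w) == 1)
    expect_equal(row$n_symmetric_phase0, sym)
  }
  # definitional cases
  one <- gene_structure_stats(manual_gene("g", "g.1", "c", "+", list(c(1, 30, 1, 30))))
  expect_true(one$intronless)
  # exon flanked by two phase-0 introns is symmetric: cuts at 90 and 180
  sym_gene <- manual_gene("g2", "g2.1", "c", "+", list(
    c(1, 90, 1, 90), c(191, 280, 191, 280), c(381, 500, 381, 500)
  ))
  s2 <- gene_structure_stats(sym_gene)
  expect_equal(s2$n_symmetric_phase0, 1L)
  expect_false(s2$intronless)
})
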