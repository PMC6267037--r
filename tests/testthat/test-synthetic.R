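profile <- default_profile()

test_that("family generation is byte-deterministic under a fixed seed", {
  spec <- family_spec(n_genes = 12, seed = 101)
  f1 <- generate_family(spec)
  f2 <- generate_family(spec)
  expect_identical(f1$proteins, f2$proteins)
  expect_identical(f1$models, f2$models)
  expect_identical(f1$truth, f2$truth)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  e1 <- generate_expression(f1$truth, seed = 101)
  write_family(f1, d1, expression = e1)
  write_family(f2, d2, expression = generate_expression(f2$truth, seed = 101))
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # a different seed changes the output
  f3 <- generate_family(family_spec(n_genes = 12, seed = 102))
  expect_false(identical(f1$proteins$sequence, f3$proteins$sequence))
})

test_that("a clean family is fully recovered by the scan", {
  fam <- generate_family(family_spec(n_genes = 10, seed = 1))
  expect_equal(nrow(fam$proteins), 10)
  hits <- scan_domains(fam$proteins, profile)
  expect_true(all(hits$accepted))
  expect_true(all(hits$total_mismatches == 0))
  cmp <- dplyr::inner_join(hits, fam$truth, by = c(protein_id = "transcript_id"))
  expect_equal(cmp$start, cmp$domain_start)
})

test_that("forcing a category plants the rule residues", {
  mix <- c(G_binder = 1, E_non_G = 0, non_E_binder = 0,
           potential_E_box = 0, potential_G_box = 0, non_binder = 0)
  fam <- generate_family(family_spec(n_genes = 8, seed = 9,
                                     binding_category_mix = mix))
  for (i in 1:8) {
    dom <- substr(fam$proteins$sequence[i], fam$truth$domain_start[i],
                  fam$truth$domain_end[i])
    basic <- substr(dom, 1, 17)
    expect_gte(count_basic_residues(basic), 5)
    expect_equal(substr(dom, 13, 13), "E")
    expect_equal(substr(dom, 16, 16), "R")
    expect_true(substr(dom, 9, 9) %in% c("H", "K"))
    expect_equal(substr(dom, 17, 17), "R")
  }
})

test_that("impossible binding specifications are refused before generation", {
  expect_error(family_spec(basic_counts = c(G_binder = 3)), "impossible spec")
  expect_error(family_spec(basic_counts = c(non_binder = 7)), "impossible spec")
  expect_error(
    family_spec(subgenome_fractions = c(A = 0.5, B = 0.4, D = 0.2)),
    "sum to 1"
  )
  expect_error(
    family_spec(intron_blueprints = list(
      list(label = "bad", positions = 70L, phases = 0L, weight = 1)
    )),
    "positions"
  )
  expect_error(
    family_spec(intron_blueprints = list(
      list(label = "bad", positions = 10L, phases = 3L, weight = 1)
    )),
    "phases"
  )
})

test_that("expression classes respect the unit thresholds by construction", {
  fam <- generate_family(family_spec(n_genes = 60, seed = 19))
  ex <- generate_expression(fam$truth, seed = 19)
  vals <- as.matrix(ex$expression[, -1])
  rownames(vals) <- ex$expression$gene
  cls <- setNames(fam$truth$expression_class, fam$truth$transcript_id)
  for (g in rownames(vals)) {
    if (cls[[g]] == "silent") {
      expect_true(all(vals[g, ] < 5))
    } else if (cls[[g]] == "broad") {
      expect_true(all(vals[g, ] > 10))
    } else {
      tis <- sub("^tissue-specific:", "", cls[[g]])
      own <- ex$samples$sample[ex$samples$tissue == tis]
      expect_true(all(vals[g, own] > 10))
      expect_true(all(vals[g, setdiff(colnames(vals), own)] < 5))
    }
  }
  expect_error(generate_expression(fam$truth, tissues = character(0)), "non-empty")
  expect_error(generate_expression(fam$truth, dispersion = -1), "non-negative")
})

test_that("true log2 fold changes are recovered from the DE table", {
  fam <- generate_family(family_spec(n_genes = 30, seed = 3))
  disp <- 0.15
  errs <- purrr::map_dbl(1:100, function(s) {
    de <- generate_expression(fam$truth, fold_changes = c(drought = 2),
                              dispersion = disp, seed = s)$de_stats
    deg <- de[de$true_log2fc != 0, ]
    mean(deg$log2fc - deg$true_log2fc)
  })
  n_deg <- sum(generate_expression(fam$truth, seed = 1)$de_stats$true_log2fc != 0)
  se <- disp / sqrt(n_deg)
  # per-replicate mean error within 3 standard errors, grand mean near zero
  expect_true(mean(abs(errs) <= 3 * se) > 0.95)
  expect_lt(abs(mean(errs)), 3 * se / sqrt(100))
})

test_that("recovery degrades monotonically with substitution noise", {
  rates <- c(0, 0.05, 0.15)
  rec <- purrr::map_dbl(rates, function(r) {
    acc <- purrr::map_dbl(1:3, function(s) {
      fam <- generate_family(family_spec(n_genes = 25, seed = 400 + s,
                                         noise_rate = r))
      hits <- scan_domains(fam$proteins, profile)
      calls <- classify_binding(hits, fam$proteins)
      cmp <- dplyr::inner_join(calls, fam$truth,
                               by = c(protein_id = "transcript_id"))
      mean(as.character(cmp$category) == cmp$binding_category) *
        nrow(cmp) / 25
    })
    mean(acc)
  })
  expect_equal(rec[1], 1)
  expect_true(all(diff(rec) <= 0))
})
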