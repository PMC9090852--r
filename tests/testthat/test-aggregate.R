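test_that("mean tpm per locus averages over the selected samples", {
  records <- data.frame(
    locus_raw_id = rep(c("TraesCS1A02G100000", "TraesCS1B02G100100"), each = 2),
    sample_id = rep(c("s1", "s2"), 2),
    tpm = c(2, 4, 10, 0))
  meta <- data.frame(sample_id = c("s1", "s2"), study = "st",
                     tissue = "leaf", condition = "control")
  mat <- expression_matrix(records, meta)

  mt <- mean_tpm_per_locus(mat, list(tissue = "leaf"))
  expect_equal(mt[["TraesCS1A02G100000"]], 3)
  expect_equal(mt[["TraesCS1B02G100100"]], 5)

  # single sample: identity
  one <- mean_tpm_per_locus(mat, function(m) m$sample_id == "s1")
  expect_equal(one[["TraesCS1A02G100000"]], 2)

  # empty selection is an error, not an empty result
  expect_error(mean_tpm_per_locus(mat, list(tissue = "root")),
               "no samples")
})

test_that("expression matrix construction validates its invariants", {
  meta <- data.frame(sample_id = "s1", study = "st", tissue = "leaf",
                     condition = "control")
  rec <- data.frame(locus_raw_id = "L1", sample_id = "s1", tpm = 1)
  expect_s3_class(expression_matrix(rec, meta), "expression_matrix")
  expect_error(expression_matrix(transform(rec, tpm = -1), meta),
               "non-negative")
  expect_error(expression_matrix(rbind(rec, rec), meta), "duplicate")
  expect_error(
    expression_matrix(transform(rec, sample_id = "ghost"), meta),
    "missing metadata")
})

test_that("dense matrices reject missing cells; sparse ones fill them", {
  meta <- data.frame(sample_id = c("s1", "s2"), study = "st",
                     tissue = "leaf", condition = "control")
  rec <- data.frame(locus_raw_id = c("L1", "L1", "L2"),
                    sample_id = c("s1", "s2", "s1"), tpm = c(2, 4, 6))
  dense <- expression_matrix(rec, meta, dense = TRUE)
  expect_error(mean_tpm_per_locus(dense, list(tissue = "leaf")), "L2")

  sparse <- expression_matrix(rec, meta, dense = FALSE, fill = 0)
  mt <- mean_tpm_per_locus(sparse, list(tissue = "leaf"))
  expect_equal(mt[["L2"]], 3)  # (6 + 0) / 2
})

test_that("subgenome totals sum the gene's loci within each subgenome", {
  reg <- tiny_registry()
  # GeneTwo: two loci per subgenome
  mt <- c(TraesCS1A02G100000 = 1, TraesCS1B02G100100 = 2,
          TraesCS1D02G100200 = 3,
          TraesCS2A02G200000 = 3, TraesCS2A02G200100 = 5,
          TraesCS2B02G200200 = 1, TraesCS2B02G200300 = 1,
          TraesCS2D02G200400 = 0, TraesCS2D02G200500 = 7,
          TraesCS3A02G300000 = 2, TraesCS3B02G300100 = 2,
          TraesCSU02G300200 = 2)
  expect_equal(subgenome_totals(mt, reg, "GeneTwo"),
               c(A = 8, B = 2, D = 7))
  # single-locus gene: totals are the loci means themselves
  expect_equal(subgenome_totals(mt, reg, "GeneOne"), c(A = 1, B = 2, D = 3))
  # the override routes the unplaced locus into D
  expect_equal(subgenome_totals(mt, reg, "GeneUn"), c(A = 2, B = 2, D = 2))
  # missing locus is an error listing the ID
  expect_error(subgenome_totals(mt[-1], reg, "GeneOne"),
               "TraesCS1A02G100000")
})

test_that("relative fractions and log2 total follow their formulas", {
  expect_equal(relative_fractions(c(10, 10, 10)),
               c(A = 1, B = 1, D = 1) / 3)
  expect_equal(relative_fractions(c(0, 5, 5)), c(A = 0, B = 0.5, D = 0.5))
  expect_equal(relative_fractions(c(22, 23, 55)),
               c(A = 0.22, B = 0.23, D = 0.55))
  expect_error(relative_fractions(c(0, 0, 0)), "undefined")
  expect_error(relative_fractions(c(-1, 1, 1)), "non-negative")

  expect_equal(log2_total(c(1, 1, 2)), 2)
  expect_equal(log2_total(c(1024, 0, 0)), 10)
  expect_error(log2_total(c(0, 0, 0)), "undefined")

  # hand computation on random non-negative triples
  set.seed(41)
  for (k in 1:1000) {
    t3 <- stats::runif(3, 0, 100)
    fr <- relative_fractions(t3)
    expect_true(abs(sum(fr) - 1) <= 1e-9)
    expect_equal(unname(fr),
                 c(t3[1], t3[2], t3[3]) / (t3[1] + t3[2] + t3[3]))
    expect_equal(log2_total(t3), log(sum(t3), base = 2))
  }
})

test_that("analyze_gene_set matches a brute-force double loop", {
  set.seed(7)
  reg <- tiny_registry()
  for (rep in 1:10) {
    samples <- paste0("s", seq_len(sample(2:5, 1)))
    records <- expand.grid(locus_raw_id = reg$raw_id, sample_id = samples,
                           stringsAsFactors = FALSE)
    records$tpm <- round(stats::runif(nrow(records), 0, 50), 3)
    meta <- data.frame(sample_id = samples, study = "st", tissue = "leaf",
                       condition = "control")
    mat <- expression_matrix(records, meta)
    res <- analyze_gene_set(mat, reg, list(ctl = list(condition = "control")))

    for (g in unique(reg$gene_name)) {
      # independent oracle: explicit loops over the raw records
      tot <- c(A = 0, B = 0, D = 0)
      for (r in seq_len(nrow(reg))) {
        if (reg$gene_name[r] != g) next
        vals <- c()
        for (i in seq_len(nrow(records)))
          if (records$locus_raw_id[i] == reg$raw_id[r])
            vals <- c(vals, records$tpm[i])
        tot[reg$effective_subgenome[r]] <-
          tot[reg$effective_subgenome[r]] + mean(vals)
      }
      row <- res[res$gene_name == g, ]
      expect_equal(c(row$total_A, row$total_B, row$total_D), unname(tot))
      expect_equal(c(row$frac_A, row$frac_B, row$frac_D),
                   unname(tot / sum(tot)))
      expect_equal(row$log2_total, log2(sum(tot)))
      expect_equal(row$n_samples, length(samples))
    }
  }
})

test_that("totals are linear in tpm and fractions scale-invariant", {
  reg <- tiny_registry()
  tpm <- stats::setNames(seq(1, 12) * 1.5, reg$raw_id)
  mat1 <- constant_matrix(tpm)
  mat2 <- constant_matrix(tpm * 7)
  ctx <- list(ctl = list(condition = "control"))
  r1 <- analyze_gene_set(mat1, reg, ctx)
  r2 <- analyze_gene_set(mat2, reg, ctx)
  expect_equal(r2$total_A, 7 * r1$total_A)
  expect_equal(r2$total_B, 7 * r1$total_B)
  expect_equal(r2$total_D, 7 * r1$total_D)
  expect_equal(r2$frac_A, r1$frac_A)
  expect_equal(r2$frac_B, r1$frac_B)
  expect_equal(r2$frac_D, r1$frac_D)
})

test_that("relabelling subgenomes A and B swaps the fractions exactly", {
  tab <- tiny_registry_table()[1:9, ]  # the two complete triads
  swapped <- tab
  swapped$gene_id <- chartr("AB", "BA", tab$gene_id)
  reg <- load_registry(tab)
  reg_sw <- load_registry(swapped)
  tpm <- stats::setNames(c(5, 1, 3, 2, 4, 8, 1, 6, 9), tab$gene_id)
  tpm_sw <- stats::setNames(unname(tpm), swapped$gene_id)
  r <- analyze_gene_set(constant_matrix(tpm), reg,
                        list(ctl = list(condition = "control")))
  r_sw <- analyze_gene_set(constant_matrix(tpm_sw), reg_sw,
                           list(ctl = list(condition = "control")))
  expect_equal(r_sw$frac_A, r$frac_B)
  expect_equal(r_sw$frac_B, r$frac_A)
  expect_equal(r_sw$frac_D, r$frac_D)
})

test_that("zero-total gene-context pairs are reported, not dropped silently", {
  reg <- tiny_registry()
  tpm <- stats::setNames(rep(1, 12), reg$raw_id)
  tpm[reg$raw_id[reg$gene_name == "GeneOne"]] <- 0
  res <- analyze_gene_set(constant_matrix(tpm), reg,
                          list(ctl = list(condition = "control")))
  expect_false("GeneOne" %in% res$gene_name)
  dropped <- attr(res, "dropped")
  expect_equal(dropped$gene_name, "GeneOne")
  expect_equal(dropped$context, "ctl")
})

test_that("expression TSV round-trips through the readers", {
  reg <- tiny_registry()
  tpm <- stats::setNames(seq_len(12), reg$raw_id)
  mat <- constant_matrix(tpm)
  d <- withr::local_tempdir()
  expr_path <- file.path(d, "expr.tsv")
  meta_path <- file.path(d, "meta.tsv")
  rec <- mat$records
  names(rec)[1] <- "gene_id"
  utils::write.table(rec, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(mat$sample_meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  mat2 <- read_expression(expr_path, meta_path)
  res <- analyze_gene_set(mat2, reg, list(ctl = list(condition = "control")))
  expect_equal(nrow(res), 3)
  expect_equal(res$total_A[res$gene_name == "GeneTwo"], 4 + 5)

  # wide CSV route agrees with the long route
  wide <- data.frame(gene_id = names(tpm), s1 = unname(tpm),
                     s2 = unname(tpm), check.names = FALSE)
  wide_path <- file.path(d, "expr_wide.csv")
  utils::write.csv(wide, wide_path, row.names = FALSE, quote = FALSE)
  mat3 <- read_expression_wide(wide_path, meta_path)
  res3 <- analyze_gene_set(mat3, reg, list(ctl = list(condition = "control")))
  expect_equal(res3$total_A, res$total_A)
})

test_that("study-stratified means weight studies, not samples", {
  # study1 has two samples (tpm 1, 1), study2 has one (tpm 10):
  # pooled mean = 4, stratified mean = (1 + 10) / 2 = 5.5
  records <- data.frame(locus_raw_id = "L1",
                        sample_id = c("a1", "a2", "b1"),
                        tpm = c(1, 1, 10))
  meta <- data.frame(sample_id = c("a1", "a2", "b1"),
                     study = c("study1", "study1", "study2"),
                     tissue = "leaf", condition = "control")
  mat <- expression_matrix(records, meta)
  expect_equal(mean_tpm_per_locus(mat, list(tissue = "leaf"))[["L1"]], 4)
  expect_equal(mean_tpm_per_locus(mat, list(tissue = "leaf"),
                                  stratify_by_study = TRUE)[["L1"]], 5.5)
})
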