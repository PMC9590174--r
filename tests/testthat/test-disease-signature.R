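make_groups <- function(seed = 31, lfc_range = NULL, n_case = 10,
                        batch_strength = 0) {
  spec <- small_spec(seed = seed, batch_strength = batch_strength,
                     n_genes = 800, tissues = c(brain = 30, liver = 10))
  cmp <- simulate_compendium(spec)
  planted <- if (is.null(lfc_range)) NULL else {
    simulate_planted_signature(spec, n_up = 40, n_down = 40, n_up_tail = 0,
                               n_down_tail = 0, n_control = 100,
                               lfc_range = lfc_range)
  }
  coh <- simulate_disease_cohort(cmp, planted, n = n_case, seed = seed + 1)
  ctrl_batch <- if (batch_strength > 0) {
    cmp$meta$batch[cmp$meta$tissue == "brain"][1:10]
  }
  list(case = coh$counts, case_batch = coh$truth$batch,
       control = cmp$counts[, cmp$meta$tissue == "brain"][, 1:10],
       control_batch = ctrl_batch, planted = planted)
}

test_that("empirical controls exclude planted signature genes", {
  g <- make_groups(seed = 33, lfc_range = c(2, 3))
  emp <- select_empirical_controls(g$case, g$control, n = 500)
  expect_length(emp, 500)
  planted_genes <- names(g$planted$effect_log2fc)
  expect_gte(mean(!planted_genes %in% emp), 0.99)
  # n = n_genes returns every gene
  all_genes <- select_empirical_controls(g$case, g$control,
                                         n = nrow(g$case))
  expect_setequal(all_genes, rownames(g$case))
  expect_error(select_empirical_controls(g$case, g$control,
                                         n = nrow(g$case) + 1), "exceeds")
})

test_that("unwanted-variation factors are recovered and k = 0 is the identity", {
  g <- make_groups(seed = 35, lfc_range = c(1, 2), batch_strength = 1)
  combined <- cbind(g$case, g$control)
  emp <- select_empirical_controls(g$case, g$control, n = 300)
  grp <- rep(c("case", "control"), c(ncol(g$case), ncol(g$control)))
  ruv <- remove_unwanted_variation(combined, emp, k_factors = 1, groups = grp)
  truth <- c(g$case_batch, g$control_batch)
  expect_gt(abs(cor(ruv$w[, 1], truth)), 0.9)

  r0 <- remove_unwanted_variation(combined, emp, k_factors = 0)
  expect_equal(r0$adjusted, norm_center_log(combined))
  expect_equal(ncol(r0$w), 0)

  # control genes constant in the working (normalized) matrix carry no
  # factor signal; data pass through
  set.seed(36)
  const <- matrix(rep(rpois(100, 20) + 1L, 10), nrow = 100,
                  dimnames = list(sprintf("c%03d", 1:100),
                                  sprintf("s%02d", 1:10)))
  rc <- remove_unwanted_variation(const, rownames(const)[1:50], k_factors = 1)
  expect_true(all(rc$w == 0))
  expect_equal(rc$adjusted, norm_center_log(const))

  expect_error(remove_unwanted_variation(combined, emp,
                                         k_factors = ncol(combined)),
               "n_samples")
  expect_error(remove_unwanted_variation(combined, c("nope", emp)), "absent")
})

test_that("differential expression recovers planted effects and is null-safe", {
  g <- make_groups(seed = 37, lfc_range = c(2, 2))
  de <- compute_de(g$case, g$control)
  expect_s3_class(de, "de_table")
  expect_true(all(de$padj >= de$pvalue - 1e-12))
  hits <- de$gene[de$padj < 0.05]
  planted_genes <- names(g$planted$effect_log2fc)
  expect_gte(mean(planted_genes %in% hits), 0.8)
  expect_lte(mean(!hits %in% planted_genes), 0.1)
  # planted direction is recovered
  up_lfc <- de$log2fc[match(g$planted$up_genes, de$gene)]
  expect_gt(min(up_lfc, na.rm = TRUE), 0)
})

test_that("identical groups give zero fold changes and an empty signature", {
  g <- make_groups(seed = 39)
  dup <- g$control
  colnames(dup) <- paste0(colnames(dup), "_dup")
  de <- suppressMessages(compute_de(g$control, dup))
  expect_lt(max(abs(de$log2fc)), 1e-6)
  sig <- suppressMessages(threshold_signature(de))
  expect_equal(nrow(sig), 0)
})

test_that("count input is validated", {
  g <- make_groups(seed = 41)
  expect_error(compute_de(g$case[, 1, drop = FALSE], g$control),
               "at least 2 samples")
  tpm_like <- g$case * 1.5
  expect_error(compute_de(tpm_like, g$control), "TPM")
})

test_that("signature thresholds are strict on both criteria", {
  de <- tibble::tibble(gene = c("a", "b", "c", "d", "e"),
                       log2fc = c(1.2, 1.2, -1.5, 0.9, 3),
                       pvalue = c(0.001, 0.02, 1e-4, 1e-4, 0.3),
                       padj = c(0.03, 0.06, 0.001, 0.001, 0.4),
                       mean_expr = 5)
  sig <- threshold_signature(de)
  expect_equal(sig$gene[sig$direction == "up"], "a")
  expect_equal(sig$gene[sig$direction == "down"], "c")
  expect_false("b" %in% sig$gene)   # padj 0.06 fails
  expect_false("d" %in% sig$gene)   # |lfc| 0.9 fails
  expect_false("e" %in% sig$gene)   # padj 0.4 fails
  # ordering by |lfc| descending
  sig2 <- threshold_signature(dplyr::mutate(de, padj = 0.01, pvalue = 0.001))
  expect_equal(sig2$gene[1], "e")
})

test_that("single-cell signature reproduces the pooled t-test by hand", {
  # log(values + 0.1) is exactly [1,2,3] vs [4,5,6] for the test gene
  vals <- rbind(exp(matrix(c(1, 2, 3, 4, 5, 6), nrow = 1)) - 0.1,
                matrix(5, nrow = 1, ncol = 6),          # constant: removed
                exp(matrix(c(5, 1, 3, 2, 6, 4), nrow = 1)) - 0.1)
  rownames(vals) <- c("target", "flat", "filler")
  labels <- rep(c("malignant", "oligodendrocyte"), each = 3)
  sig <- suppressMessages(sc_signature(vals, labels))
  de <- attr(sig, "de")
  expect_false("flat" %in% de$gene)               # variance 0 < 0.1
  row <- de[de$gene == "target", ]
  expect_equal(row$log2fc, -3 / log(2), tolerance = 1e-8)
  # pooled-variance t = -3.674 on 4 df -> p = 0.02131
  expect_equal(row$pvalue, 2 * pt(3.6742346, 4, lower.tail = FALSE),
               tolerance = 1e-6)
  expect_error(sc_signature(vals, c("malignant", rep("oligodendrocyte", 5))),
               "at least 2 cells")
})

test_that("identical cell groups yield zero log fold change", {
  set.seed(43)
  half <- matrix(rlnorm(50 * 4), nrow = 50,
                 dimnames = list(sprintf("g%02d", 1:50), NULL))
  vals <- cbind(half, half)
  labels <- rep(c("malignant", "oligodendrocyte"), each = 4)
  sig <- suppressMessages(sc_signature(vals, labels))
  expect_equal(nrow(sig), 0)
  expect_true(all(abs(attr(sig, "de")$log2fc) < 1e-10))
})

test_that("meta-signature combination follows the stated rules", {
  sig_a <- threshold_signature(tibble::tibble(
    gene = c("a", "b", "c"), log2fc = c(2, 1.5, -2),
    pvalue = 0.001, padj = 0.01, mean_expr = 5))
  sig_b <- threshold_signature(tibble::tibble(
    gene = c("a", "c", "d"), log2fc = c(1.2, -1.8, 2.5),
    pvalue = 0.001, padj = 0.01, mean_expr = 5))
  meta <- combine_signatures(sig_a, sig_b)
  expect_equal(meta$log2fc[meta$gene == "a"], 1.6)     # mean of 2 and 1.2
  expect_false("b" %in% meta$gene)                     # absent from b
  expect_false("d" %in% meta$gene)
  expect_true("c" %in% meta$gene)
  expect_identical(attr(meta, "provenance"), "meta")
  # idempotence
  expect_equal(as.data.frame(combine_signatures(sig_a, sig_a))[c("gene", "log2fc")],
               as.data.frame(sig_a)[c("gene", "log2fc")])
  # direction conflict is excluded with a message
  sig_c <- threshold_signature(tibble::tibble(
    gene = "a", log2fc = -2, pvalue = 0.001, padj = 0.01, mean_expr = 5))
  expect_message(meta2 <- combine_signatures(sig_a, sig_c), "conflict")
  expect_false("a" %in% meta2$gene)
  # union keeps one-sided genes
  expect_true("b" %in% combine_signatures(sig_a, sig_b, rule = "union")$gene)
})

test_that("signature round-trips through its TSV format", {
  sig <- threshold_signature(tibble::tibble(
    gene = c("g1", "g2"), log2fc = c(2.25, -1.5),
    pvalue = 0.001, padj = 0.01, mean_expr = 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_signature(sig, path, seed = 1)
  back <- read_signature(path, provenance = "bulk")
  expect_equal(as.data.frame(back), as.data.frame(sig))
  writeLines(c("gene\tdirection\tlog2fc", "g1\tsideways\t2"), path)
  expect_error(read_signature(path), "sideways")
})

test_that("signature evaluation harness rejects degenerate inputs", {
  spec <- small_spec(seed = 45)
  planted <- simulate_planted_signature(spec, n_up = 20, n_down = 20,
                                        n_up_tail = 0, n_down_tail = 0,
                                        n_control = 40)
  sig <- truth_signature(planted)
  cpds <- simulate_compounds(n = 10, n_strong = 3, seed = 46)
  landmark <- sprintf("g%05d", 1:200)
  lib <- simulate_drug_library(planted, cpds, landmark, seed = 47)
  sens <- simulate_sensitivity(cpds, seed = 48)
  expect_error(evaluate_signature(sig[0, ], lib, sens), "empty")
  expect_error(evaluate_signature(sig, lib, sens[0, ]), "empty")
  ev <- evaluate_signature(sig, lib, sens, srges_cutoff = NULL)
  expect_s3_class(ev, "reversal_correlation")
  expect_true(is.finite(ev$r) && ev$n == 10)
})
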