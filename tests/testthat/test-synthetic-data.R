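test_that("compendium spec validates its invariants", {
  expect_error(compendium_spec(n_genes = 100, n_landmark = 200),
               class = "sigreverse_config_error")
  expect_error(compendium_spec(tissues = c(brain = 1, liver = 10)),
               "at least 2 samples", class = "sigreverse_config_error")
  expect_error(compendium_spec(source_tissue = "kidney"),
               "kidney", class = "sigreverse_config_error")
  expect_error(compendium_spec(nb_dispersion = -1),
               "nb_dispersion", class = "sigreverse_config_error")
})

test_that("compendium generation is deterministic and well-formed", {
  spec <- small_spec(seed = 7)
  a <- simulate_compendium(spec)
  b <- simulate_compendium(spec)
  expect_identical(a$counts, b$counts)
  expect_identical(a$tpm, b$tpm)
  expect_true(all(a$counts >= 0))
  expect_true(all(a$counts == floor(a$counts)))
  expect_equal(unname(colSums(a$tpm)), rep(1e6, ncol(a$tpm)),
               tolerance = 1e-6)
  expect_false("batch" %in% names(a$meta))      # batch_strength = 0
  expect_true(all(a$truth$batch_loadings == 0))
})

test_that("tissues are more correlated within than between", {
  cmp <- simulate_compendium(small_spec(seed = 5))
  lt <- log2(cmp$tpm + 1)
  brain <- lt[, cmp$meta$tissue == "brain"]
  liver <- lt[, cmp$meta$tissue == "liver"]
  within <- mean(cor(brain)[upper.tri(diag(ncol(brain)))])
  between <- mean(cor(brain, liver))
  expect_gt(within, between)
})

test_that("batch strength adds a covariate with planted loadings", {
  cmp <- simulate_compendium(small_spec(seed = 9, batch_strength = 1))
  expect_true("batch" %in% names(cmp$meta))
  expect_gt(sum(cmp$truth$batch_loadings != 0), 0)
})

test_that("disease cohort carries the planted fold changes", {
  spec <- small_spec(seed = 11, tissues = c(brain = 60, liver = 30))
  cmp <- simulate_compendium(spec)
  planted <- simulate_planted_signature(spec, n_up = 20, n_down = 20,
                                        n_up_tail = 0, n_down_tail = 0,
                                        n_control = 40,
                                        lfc_range = c(2, 2))
  coh <- simulate_disease_cohort(cmp, planted, n = 40, seed = 12)
  brain <- cmp$counts[, cmp$meta$tissue == "brain"]
  # normalize by library size before comparing group means
  rate_coh <- rowMeans(sweep(coh$counts, 2, colSums(coh$counts), "/"))
  rate_ctl <- rowMeans(sweep(brain, 2, colSums(brain), "/"))
  # compare against control genes to cancel the compositional shift the
  # up-regulated mass induces on per-library rates
  ratio_up <- rate_coh[planted$up_genes] / rate_ctl[planted$up_genes]
  ratio_ctl <- rate_coh[planted$control_genes] / rate_ctl[planted$control_genes]
  expect_equal(mean(ratio_up) / mean(ratio_ctl), 4, tolerance = 0.25)
  # control genes behave like every other unplanted gene
  other <- setdiff(rownames(brain),
                   c(names(planted$effect_log2fc), planted$control_genes))
  ratio_other <- rate_coh[other] / rate_ctl[other]
  expect_lt(abs(mean(log(ratio_ctl)) - mean(log(ratio_other))), 0.05)
})

test_that("a zero-effect cohort matches the source tissue distribution", {
  spec <- small_spec(seed = 13)
  cmp <- simulate_compendium(spec)
  coh <- simulate_disease_cohort(cmp, planted = NULL, n = 25, seed = 14)
  brain <- cmp$counts[, cmp$meta$tissue == "brain"]
  lr <- log1p(rowMeans(sweep(coh$counts, 2, colSums(coh$counts), "/")) * 1e6) -
    log1p(rowMeans(sweep(brain, 2, colSums(brain), "/")) * 1e6)
  expect_lt(abs(mean(lr)), 0.05)
})

test_that("cohort edge cases: empty cohort and unknown genes", {
  spec <- small_spec(seed = 15)
  cmp <- simulate_compendium(spec)
  empty <- simulate_disease_cohort(cmp, NULL, n = 0)
  expect_equal(dim(empty$counts), c(spec$n_genes, 0))
  expect_identical(rownames(empty$counts), rownames(cmp$counts))
  bad <- simulate_planted_signature(spec, n_up = 2, n_down = 2,
                                    n_up_tail = 0, n_down_tail = 0,
                                    n_control = 2)
  names(bad$effect_log2fc)[1] <- "not_a_gene"
  expect_error(simulate_disease_cohort(cmp, bad, n = 3), "not_a_gene")
})

test_that("drug profiles encode planted reversal strength", {
  spec <- small_spec(seed = 17)
  planted <- simulate_planted_signature(spec, n_up = 20, n_down = 20,
                                        n_up_tail = 0, n_down_tail = 0,
                                        n_control = 40)
  landmark <- sort(unique(c(names(planted$effect_log2fc),
                            sprintf("g%05d", 1:100))))
  cond <- tibble::tibble(cell_line = "L1", dose_um = 10, duration_h = 24)
  cpd <- function(id, theta) tibble::tibble(
    compound = id, theta = theta, moa_class = "null",
    clinical_phase = "Launched", n_profiles = 1L, conditions = list(cond))

  # theta = 1, no noise, reference condition: every up gene ranks below
  # every non-signature gene
  lib1 <- simulate_drug_library(planted, cpd("strong", 1), landmark,
                                noise_sd = 0, seed = 18)
  vals <- setNames(lib1$value, lib1$gene)
  nonsig <- setdiff(landmark, names(planted$effect_log2fc))
  expect_true(max(vals[planted$up_genes]) < min(vals[nonsig]))

  # theta scaling: mean up-gene value twice as negative for theta = 1 vs 0.5
  lib_half <- simulate_drug_library(planted, cpd("half", 0.5), landmark,
                                    noise_sd = 0, seed = 18)
  m1 <- mean(vals[planted$up_genes])
  m05 <- mean(setNames(lib_half$value, lib_half$gene)[planted$up_genes])
  expect_equal(m1 / m05, 2, tolerance = 1e-8)

  # theta = 0 is pure noise: mean RGES over replicate profiles near zero
  cpd0 <- cpd("nul", 0)
  cpd0$conditions <- list(cond[rep(1, 30), ])
  cpd0$n_profiles <- 30L
  lib0 <- simulate_drug_library(planted, cpd0, landmark, noise_sd = 0.5,
                                seed = 19)
  scores <- score_library(lib0, truth_signature(planted),
                          same_sign_zero = FALSE)
  expect_lt(abs(mean(scores$rges)), 0.2)

  expect_error(simulate_drug_library(planted, cpd("x", 1), landmark,
                                     noise_sd = -1),
               class = "sigreverse_config_error")
  expect_error(simulate_drug_library(planted, cpd("x", 1)[0, ], landmark),
               "nonempty")
})

test_that("sensitivity follows the stated AC50 model", {
  cond <- tibble::tibble(cell_line = "L1", dose_um = 10, duration_h = 24)
  cpds <- tibble::tibble(compound = sprintf("c%d", 1:5),
                         theta = c(0, 0.25, 0.5, 0.75, 1),
                         moa_class = "null", clinical_phase = "Launched",
                         n_profiles = 1L,
                         conditions = rep(list(cond), 5))
  sens <- simulate_sensitivity(cpds, cell_lines = "L1", a = -4, b = 2,
                               eps_sd = 0, lowq_frac = 0, seed = 20)
  sens <- sens[order(sens$compound), ]
  expect_true(all(diff(sens$ac50) < 0))          # strictly decreasing in theta
  expect_equal(sens$ac50[sens$compound == "c5"], 1e-6)
  expect_equal(nrow(filter_sensitivity(sens)), nrow(sens))
  expect_error(simulate_sensitivity(cpds[0, ]), "nonempty")
  expect_error(simulate_sensitivity(cpds, b = -1),
               class = "sigreverse_config_error")
})

test_that("single-cell matrix has the documented default shape", {
  spec <- small_spec(seed = 21, n_genes = 300)
  planted <- simulate_planted_signature(spec, n_up = 15, n_down = 15,
                                        n_up_tail = 0, n_down_tail = 0,
                                        n_control = 30)
  genes <- rownames(simulate_compendium(spec)$counts)
  sc <- simulate_sc_matrix(planted, genes, seed = 22)
  expect_equal(dim(sc$values), c(300, 2259 + 232))
  expect_equal(sum(sc$labels$cell_type == "malignant"), 2259)
  expect_equal(sum(sc$labels$cell_type == "oligodendrocyte"), 232)
  expect_true(all(!is.na(sc$labels$program[sc$labels$cell_type == "malignant"])))
})

test_that("single-cell generator honours dropout and null effects", {
  spec <- small_spec(seed = 23, n_genes = 300)
  genes <- sprintf("g%05d", 1:300)
  null_sig <- simulate_planted_signature(spec, n_up = 10, n_down = 10,
                                         n_up_tail = 0, n_down_tail = 0,
                                         n_control = 20,
                                         lfc_range = c(0, 0))
  sc <- simulate_sc_matrix(null_sig, genes, n_malignant = 60, n_oligo = 40,
                           programs = "Cell cycle", module_size = 0,
                           dropout = 0, seed = 24)
  expect_true(all(sc$values > 0))
  logv <- log(sc$values)
  d <- rowMeans(logv[, sc$labels$cell_type == "malignant"]) -
    rowMeans(logv[, sc$labels$cell_type == "oligodendrocyte"])
  expect_lt(abs(mean(d)), 0.1)
  sc2 <- simulate_sc_matrix(null_sig, genes, n_malignant = 30, n_oligo = 20,
                            dropout = 0.4, seed = 25)
  expect_equal(mean(sc2$values == 0), 0.4, tolerance = 0.05)
  expect_error(simulate_sc_matrix(null_sig, genes, n_malignant = -1),
               "nonnegative")
  expect_error(simulate_sc_matrix(null_sig, genes, dropout = 1),
               class = "sigreverse_config_error")
})

test_that("generators return their planted ground truth", {
  spec <- small_spec(seed = 27)
  cmp <- simulate_compendium(spec)
  expect_named(cmp$truth, c("tissue_profiles", "batch_loadings",
                            "library_sizes"))
  cpds <- simulate_compounds(n = 12, n_strong = 3, seed = 28)
  expect_true(all(cpds$theta >= 0 & cpds$theta <= 1))
  expect_equal(cpds$n_profiles,
               vapply(cpds$conditions, nrow, integer(1)))
  planted <- simulate_planted_signature(spec, n_up = 40, n_down = 40,
                                        n_up_tail = 20, n_down_tail = 20,
                                        n_control = 100)
  expect_length(intersect(planted$up_genes, planted$down_genes), 0)
  expect_length(intersect(planted$control_genes,
                          c(planted$up_genes, planted$down_genes)), 0)
})
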