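#' Select empirical negative-control genes for unwanted-variation estimation
#'
#' Runs a first-pass case/control differential test and returns the `n` genes
#' least associated with the contrast (largest p-values). These act as
#' negative controls in the factor-analysis adjustment: genes whose variation
#' is assumed to reflect technical rather than disease signal. Weakly
#' expressed genes are filtered before the first pass (they are too noisy to
#' be useful controls) and are appended only when `n` exceeds the number of
#' expressed genes.
#'
#' @param counts_case,counts_control Integer count matrices (genes x samples)
#'   sharing a gene index.
#' @param n Number of control genes to return (default 5000, capped at the
#'   number of genes).
#' @param min_cpm Weak-expression filter for the first-pass test.
#' @return Character vector of gene ids.
#' @export
select_empirical_controls <- function(counts_case, counts_control, n = 5000,
                                      min_cpm = 1) {
  genes <- rownames(counts_case)
  if (!identical(genes, rownames(counts_control))) {
    abort("case and control matrices must share a gene index")
  }
  if (n > length(genes)) {
    abort(sprintf("`n` (%d) exceeds the number of genes (%d)", n,
                  length(genes)))
  }
  de <- compute_de(counts_case, counts_control, min_cpm = min_cpm)
  ranked <- de |> arrange(desc(.data$pvalue), .data$gene)
  untested <- setdiff(genes, de$gene)
  head(c(ranked$gene, sort(untested)), n)
}

#' Remove unwanted variation via factor analysis on control genes
#'
#' Counts are first brought to a common library size (each sample scaled to
#' the geometric-mean total), then log2-transformed and row-centered.
#' `k` nuisance factors are estimated from the centered log values of the
#' negative control genes (singular value decomposition of the control-gene
#' rows; the top `k` right singular vectors form `W`, samples x k) and their
#' contribution is regressed out of every gene. Without the depth
#' normalization the leading factor simply recovers sequencing depth.
#' `k = 0` returns the centered normalized log matrix unchanged. Control
#' genes that are constant across samples carry no signal, and when all of
#' them are constant `W` is zero and the data pass through untouched.
#'
#' When the case/control grouping is supplied, the control-gene matrix is
#' centered within each group before the decomposition so the estimated
#' factors cannot absorb the biological contrast of interest (the
#' residual-based recipe of the RUV family); the returned `adjusted` matrix
#' is always the globally centered data with `W`'s contribution removed.
#'
#' @param counts Integer count matrix (genes x samples).
#' @param control_genes Gene ids used to estimate the factors.
#' @param k_factors Number of unwanted-variation factors (>= 0).
#' @param pseudocount Added before the log2 transform.
#' @param groups Optional vector (length = samples) of group labels whose
#'   contribution is projected out before factor estimation.
#' @return List: `adjusted` (genes x samples, row-centered log2 scale) and
#'   `w` (samples x k factor matrix; 0 columns when `k_factors = 0`).
#' @export
remove_unwanted_variation <- function(counts, control_genes, k_factors = 1,
                                      pseudocount = 1, groups = NULL) {
  missing <- setdiff(control_genes, rownames(counts))
  if (length(missing) > 0) {
    abort(sprintf("control gene(s) absent from `counts`: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  if (k_factors > ncol(counts) - 1) {
    abort(sprintf("`k_factors` (%d) must be <= n_samples - 1 (%d)",
                  k_factors, ncol(counts) - 1))
  }
  lib <- colSums(counts)
  sf <- lib / exp(mean(log(pmax(lib, 1))))
  sf[sf == 0] <- 1
  logy <- log2(sweep(counts, 2, sf, "/") + pseudocount)
  centered <- logy - rowMeans(logy)
  w <- matrix(0, nrow = ncol(counts), ncol = k_factors,
              dimnames = list(colnames(counts), NULL))
  if (k_factors == 0) {
    return(list(adjusted = centered, w = w))
  }
  ctrl <- centered[control_genes, , drop = FALSE]
  if (!is.null(groups)) {
    stopifnot(length(groups) == ncol(counts))
    for (g in unique(groups)) {
      idx <- which(groups == g)
      ctrl[, idx] <- ctrl[, idx, drop = FALSE] -
        rowMeans(ctrl[, idx, drop = FALSE])
    }
  }
  sv <- svd(ctrl, nu = 0, nv = k_factors)
  keep <- sv$d[seq_len(k_factors)] > 1e-8
  if (any(keep)) {
    w[, keep] <- sv$v[, keep, drop = FALSE]
    beta <- centered %*% w %*% solve(crossprod(w) + diag(1e-12, k_factors))
    adjusted <- centered - beta %*% t(w)
  } else {
    adjusted <- centered
  }
  list(adjusted = adjusted, w = w)
}

#' Negative-binomial differential expression between case and control
#'
#' Library sizes are normalized with trimmed-mean-of-M-values scale factors,
#' weakly expressed genes are removed (fewer than `min_cpm` counts-per-million
#' in at least the smaller group's number of samples), per-gene NB dispersion
#' is estimated with a trend-shrunk tagwise estimator, and each gene is
#' tested with a likelihood-ratio test on the case/control coefficient, with
#' optional nuisance covariates (e.g. unwanted-variation factors) in the
#' model. P-values are Benjamini-Hochberg adjusted over the tested genes.
#' The edgeR framework supplies the normalization, dispersion, and GLM
#' machinery.
#'
#' @param counts_case,counts_control Integer count matrices (genes x samples).
#' @param covariates Optional numeric matrix (samples x k, cases first then
#'   controls) of nuisance covariates, e.g. `w` from
#'   [remove_unwanted_variation()] on the combined matrix.
#' @param min_cpm Weak-expression filter threshold (counts-per-million);
#'   0 keeps every gene with any count.
#' @return A `de_table` tibble: gene, log2fc (case vs control), pvalue, padj,
#'   mean_expr (average log2 CPM).
#' @export
compute_de <- function(counts_case, counts_control, covariates = NULL,
                       min_cpm = 1) {
  if (ncol(counts_case) < 2 || ncol(counts_control) < 2) {
    abort("each group needs at least 2 samples")
  }
  if (!identical(rownames(counts_case), rownames(counts_control))) {
    abort("case and control matrices must share a gene index")
  }
  combined <- cbind(counts_case, counts_control)
  if (any(combined < 0) || any(combined != floor(combined))) {
    abort(paste("counts must be nonnegative integers; a non-integer matrix",
                "suggests TPM was passed where raw counts are required"))
  }
  group <- factor(rep(c("case", "control"),
                      c(ncol(counts_case), ncol(counts_control))),
                  levels = c("control", "case"))
  design <- if (is.null(covariates)) {
    model.matrix(~group)
  } else {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == ncol(combined))
    model.matrix(~ group + covariates)
  }
  dge <- edgeR::DGEList(counts = combined, group = group)
  if (min_cpm > 0) {
    keep <- rowSums(edgeR::cpm(dge) >= min_cpm) >=
      min(ncol(counts_case), ncol(counts_control))
  } else {
    keep <- rowSums(combined) > 0
  }
  dge <- dge[keep, , keep.lib.sizes = FALSE]
  dge <- edgeR::calcNormFactors(dge, method = "TMM")
  dge <- edgeR::estimateDisp(dge, design)
  fit <- edgeR::glmFit(dge, design)
  lrt <- edgeR::glmLRT(fit, coef = "groupcase")
  tab <- lrt$table
  out <- tibble(gene = rownames(tab), log2fc = tab$logFC,
                pvalue = tab$PValue,
                padj = p.adjust(tab$PValue, method = "BH"),
                mean_expr = tab$logCPM) |>
    arrange(.data$gene)
  class(out) <- c("de_table", class(out))
  out
}

#' Threshold a differential-expression table into a disease signature
#'
#' Up genes satisfy `log2fc > lfc_min` and `padj < padj_max` (both strict);
#' down genes mirror with `log2fc < -lfc_min`. Genes are ordered by |log2FC|
#' descending, ties by gene id. An empty signature is permitted and flagged
#' with a message.
#'
#' @param de A `de_table`.
#' @param lfc_min,padj_max Effect-size and FDR thresholds (defaults 1, 0.05).
#' @param provenance Tag recorded on the signature (e.g. "bulk", "sc",
#'   "meta", "published").
#' @return A `disease_signature` tibble: gene, direction ("up"/"down"),
#'   log2fc.
#' @export
threshold_signature <- function(de, lfc_min = 1, padj_max = 0.05,
                                provenance = "bulk") {
  hits <- de |>
    filter(.data$padj < padj_max, abs(.data$log2fc) > lfc_min) |>
    mutate(direction = ifelse(.data$log2fc > 0, "up", "down")) |>
    arrange(desc(abs(.data$log2fc)), .data$gene) |>
    select("gene", "direction", "log2fc")
  if (nrow(hits) == 0) inform("thresholding produced an empty signature")
  new_signature(hits, provenance)
}

new_signature <- function(tbl, provenance) {
  tbl <- as_tibble(tbl)
  attr(tbl, "provenance") <- provenance
  class(tbl) <- unique(c("disease_signature", class(tbl)))
  tbl
}

#' Single-cell disease signature from malignant vs oligodendrocyte cells
#'
#' Works on `log(RSEM + 0.1)` values: genes whose variance across all cells
#' falls below `var_min` are removed, each remaining gene is tested with an
#' equal-variance two-sample Student's t-test (malignant vs oligodendrocyte),
#' the mean natural-log difference is rescaled to log2, p-values are BH
#' adjusted, and the usual thresholds are applied.
#'
#' @param values RSEM-like value matrix (genes x cells).
#' @param labels Character vector per cell: "malignant" or "oligodendrocyte".
#' @param var_min Variance filter on log values (default 0.1).
#' @param lfc_min,padj_max Signature thresholds.
#' @return A `disease_signature` tibble (provenance "sc"); the full test
#'   table is attached as `attr(, "de")`.
#' @export
sc_signature <- function(values, labels, var_min = 0.1, lfc_min = 1,
                         padj_max = 0.05) {
  stopifnot(length(labels) == ncol(values))
  if (is.null(rownames(values))) abort("`values` needs gene rownames")
  is_mal <- labels == "malignant"
  is_oli <- labels == "oligodendrocyte"
  if (sum(is_mal) < 2 || sum(is_oli) < 2) {
    abort("each cell class needs at least 2 cells")
  }
  logv <- log(values + 0.1)
  keep <- apply(logv, 1, var) >= var_min
  logv <- logv[keep, , drop = FALSE]
  tt <- row_t_equalvar(logv[, is_mal, drop = FALSE],
                       logv[, is_oli, drop = FALSE])
  de <- tibble(gene = rownames(logv),
               log2fc = unname(tt$mean_diff) / log(2),
               pvalue = unname(tt$pvalue),
               padj = p.adjust(unname(tt$pvalue), method = "BH"),
               mean_expr = unname(rowMeans(logv)))
  class(de) <- c("de_table", class(de))
  sig <- threshold_signature(de, lfc_min = lfc_min, padj_max = padj_max,
                             provenance = "sc")
  attr(sig, "de") <- de
  sig
}

# Vectorized equal-variance (pooled) two-sample t-test over matrix rows.
row_t_equalvar <- function(x, y) {
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
  se <- sqrt(sp2 * (1 / nx + 1 / ny))
  tstat <- (mx - my) / se
  df <- nx + ny - 2
  p <- 2 * pt(abs(tstat), df = df, lower.tail = FALSE)
  p[se == 0] <- ifelse(abs(mx - my)[se == 0] < .Machine$double.eps^0.5, 1, 0)
  tstat[se == 0 & abs(mx - my) < .Machine$double.eps^0.5] <- 0
  list(statistic = tstat, df = df, pvalue = p, mean_diff = mx - my)
}

#' Combine two disease signatures into a meta-signature
#'
#' Default rule: direction-consistent intersection — a gene enters the meta
#' up (down) set only if it is up (down) in both signatures, with the mean of
#' the two log2 fold changes. Genes with conflicting directions are excluded
#' and reported. Alternatives: `"union"` keeps genes present in either
#' signature (mean lfc where both, own lfc otherwise), and
#' `"average-rethreshold"` averages lfc over the shared gene universe and
#' re-applies the |log2FC| threshold.
#'
#' @param sig_a,sig_b `disease_signature` tibbles over a shared gene universe.
#' @param rule One of "intersection", "union", "average-rethreshold".
#' @param lfc_min Threshold used by the rethresholding rule.
#' @return A `disease_signature` (provenance "meta").
#' @export
combine_signatures <- function(sig_a, sig_b,
                               rule = c("intersection", "union",
                                        "average-rethreshold"),
                               lfc_min = 1) {
  rule <- match.arg(rule)
  merged <- dplyr::full_join(
    as_tibble(sig_a)[c("gene", "direction", "log2fc")],
    as_tibble(sig_b)[c("gene", "direction", "log2fc")],
    by = "gene", suffix = c("_a", "_b"))
  conflict <- merged |>
    filter(!is.na(.data$direction_a), !is.na(.data$direction_b),
           .data$direction_a != .data$direction_b)
  if (nrow(conflict) > 0) {
    inform(sprintf("%d gene(s) with conflicting direction excluded: %s",
                   nrow(conflict),
                   paste(head(conflict$gene, 5), collapse = ", ")))
  }
  merged <- anti_join(merged, conflict, by = "gene")
  out <- switch(rule,
    intersection = merged |>
      filter(!is.na(.data$direction_a), !is.na(.data$direction_b)) |>
      mutate(direction = .data$direction_a,
             log2fc = (.data$log2fc_a + .data$log2fc_b) / 2),
    union = merged |>
      mutate(log2fc = dplyr::coalesce((.data$log2fc_a + .data$log2fc_b) / 2,
                                      .data$log2fc_a, .data$log2fc_b),
             direction = dplyr::coalesce(.data$direction_a, .data$direction_b)),
    `average-rethreshold` = merged |>
      mutate(log2fc = dplyr::coalesce((.data$log2fc_a + .data$log2fc_b) / 2,
                                      .data$log2fc_a, .data$log2fc_b)) |>
      filter(abs(.data$log2fc) > lfc_min) |>
      mutate(direction = ifelse(.data$log2fc > 0, "up", "down"))
  )
  out <- out |>
    select("gene", "direction", "log2fc") |>
    arrange(desc(abs(.data$log2fc)), .data$gene)
  new_signature(out, "meta")
}

#' Evaluate one signature end-to-end against sensitivity data
#'
#' Scores the profile library with the signature, summarizes to sRGES, and
#' correlates predicted reversal with drug sensitivity — the harness used to
#' compare alternative signatures (bulk, single-cell, meta, or published
#' signatures read from TSV).
#'
#' @param signature A `disease_signature`.
#' @param library A `profile_library`.
#' @param sensitivity Sensitivity tibble (compound, cell_line, ac50, cclass,
#'   cclass2); quality-filtered internally.
#' @param top_n,srges_cutoff Passed through to scoring and correlation.
#' @return A `reversal_correlation` object (see [correlate_efficacy()]).
#' @export
evaluate_signature <- function(signature, library, sensitivity, top_n = 100,
                               srges_cutoff = -0.1) {
  if (nrow(signature) == 0) abort("`signature` is empty")
  if (nrow(sensitivity) == 0) abort("`sensitivity` is empty")
  srges <- summarize_srges(score_library(library, signature, top_n = top_n))
  correlate_efficacy(srges, filter_sensitivity(sensitivity),
                     srges_cutoff = srges_cutoff)
}
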