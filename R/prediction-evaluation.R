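#' Keep high-quality drug-sensitivity records
#'
#' Retains records whose dose-response curve classes satisfy
#' `cclass < max_cclass` and `cclass2 < max_cclass` (both strict): a strong,
#' reliable viability signal.
#'
#' @param records Sensitivity tibble (compound, cell_line, ac50, cclass,
#'   cclass2).
#' @param max_cclass Strict upper bound on both quality classes (default 4).
#' @return The filtered tibble.
#' @export
filter_sensitivity <- function(records, max_cclass = 4) {
  records[records$cclass < max_cclass & records$cclass2 < max_cclass, ,
          drop = FALSE]
}

#' Correlate predicted reversal potency with drug sensitivity
#'
#' For each compound passing the sRGES cutoff, AC50 is summarized as the
#' median over cell lines and log10-transformed; the statistic is the Pearson
#' correlation of (sRGES, log10 AC50) over those compounds, with a two-sided
#' p-value from the t distribution. A positive correlation means stronger
#' predicted reversers (lower sRGES) are more potent (lower AC50).
#'
#' @param srges An `srges_table`.
#' @param sensitivity Quality-filtered sensitivity records.
#' @param srges_cutoff Strict sRGES cutoff (default -0.1); `NULL` correlates
#'   over all overlapping compounds.
#' @return A `reversal_correlation` list: `r`, `p`, `n`, and the per-compound
#'   `data` tibble (compound, srges, log10_ac50).
#' @export
correlate_efficacy <- function(srges, sensitivity, srges_cutoff = -0.1) {
  if (!is.null(srges_cutoff)) srges <- reversal_threshold(srges, srges_cutoff)
  per_cpd <- sensitivity |>
    group_by(.data$compound) |>
    summarise(log10_ac50 = log10(median(.data$ac50)), .groups = "drop")
  merged <- inner_join(as_tibble(srges)[c("compound", "srges")], per_cpd,
                       by = "compound")
  if (nrow(merged) < 3) {
    abort(sprintf(paste("need at least 3 compounds with both sRGES and",
                        "sensitivity after the cutoff; got %d"), nrow(merged)),
          class = "sigreverse_too_few")
  }
  ct <- cor.test(merged$srges, merged$log10_ac50, method = "pearson")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = nrow(merged),
                 data = merged),
            class = "reversal_correlation")
}

#' @export
print.reversal_correlation <- function(x, ...) {
  cat(sprintf("sRGES vs log10(AC50): Pearson r = %.3f, p = %.3g, n = %d\n",
              x$r, x$p, x$n))
  invisible(x)
}

#' Enrichment of drug target/MOA classes among the top predictions
#'
#' Ranks compounds by sRGES ascending (best reversers first) and, for each
#' annotation class with at least two member compounds, computes the KS
#' enrichment of its members in that ranking. Significance is a one-sided
#' permutation test: the fraction of random same-size compound sets with
#' enrichment at least as large, with the +1 correction on numerator and
#' denominator so p is never exactly zero.
#'
#' @param srges An `srges_table`.
#' @param annotations Tibble with `compound` and `moa_class`.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed for the permutations.
#' @return Tibble: moa_class, n_members, es, p_perm. Classes with fewer than
#'   2 members (or spanning all compounds) are skipped with a message.
#' @export
target_class_enrichment <- function(srges, annotations, n_perm = 1000,
                                    seed = 1) {
  ranked <- arrange(as_tibble(srges), .data$srges, .data$compound)$compound
  ann <- annotations |>
    filter(.data$compound %in% ranked, !is.na(.data$moa_class),
           .data$moa_class != "null")
  classes <- split(ann$compound, ann$moa_class)
  withr::with_seed(seed, {
    rows <- imap(classes, function(members, cls) {
      members <- unique(members)
      if (length(members) < 2 || length(members) >= length(ranked)) {
        inform(sprintf("class '%s' skipped (%d member(s) of %d compounds)",
                       cls, length(members), length(ranked)))
        return(NULL)
      }
      es <- ks_enrichment(ranked, members)
      perm <- vapply(seq_len(n_perm), function(i) {
        ks_enrichment(ranked, sample(ranked, length(members)))
      }, numeric(1))
      tibble(moa_class = cls, n_members = length(members), es = es,
             p_perm = (1 + sum(perm >= es)) / (n_perm + 1))
    })
    out <- bind_rows(rows)
    if (nrow(out) == 0) {
      out <- tibble(moa_class = character(), n_members = integer(),
                    es = numeric(), p_perm = numeric())
    }
    arrange(out, .data$p_perm, .data$moa_class)
  })
}

#' Filter sRGES predictions to the final hit table
#'
#' Drops compounds that (1) fail the sRGES cutoff, (2) belong to excluded
#' mechanism-of-action classes — by default the known or non-specific
#' chemotherapy classes (topoisomerase, CDK, HDAC, and DNA inhibitors), (3)
#' have fewer than `min_profiles` perturbation profiles (low-confidence
#' predictions), or (4) optionally are preclinical. Unannotated compounds are
#' kept and reported. The result is sorted by sRGES ascending.
#'
#' @param srges An `srges_table` (with `n_profiles`).
#' @param annotations Tibble: compound, moa_class, clinical_phase.
#' @param srges_cutoff Strict sRGES cutoff (default -0.1).
#' @param exclude_moa MOA classes to drop (case-insensitive match).
#' @param min_profiles Minimum profile count (default 3).
#' @param exclude_preclinical Drop compounds with phase "Preclinical".
#' @return Hit tibble: compound, srges, n_profiles, n_cell_lines, moa_class,
#'   clinical_phase.
#' @export
filter_hits <- function(srges, annotations, srges_cutoff = -0.1,
                        exclude_moa = c("TOP inhibitor", "CDK inhibitor",
                                        "HDAC inhibitor", "DNA inhibitor"),
                        min_profiles = 3, exclude_preclinical = FALSE) {
  tbl <- left_join(as_tibble(srges),
                   annotations[c("compound", "moa_class", "clinical_phase")],
                   by = "compound")
  unann <- tbl$compound[is.na(tbl$moa_class)]
  if (length(unann) > 0) {
    inform(sprintf("%d unannotated compound(s) kept: %s", length(unann),
                   paste(head(unann, 5), collapse = ", ")))
  }
  keep <- tbl$srges < srges_cutoff &
    tbl$n_profiles >= min_profiles &
    (is.na(tbl$moa_class) |
       !tolower(tbl$moa_class) %in% tolower(exclude_moa))
  if (exclude_preclinical) {
    keep <- keep & (is.na(tbl$clinical_phase) |
                      tbl$clinical_phase != "Preclinical")
  }
  tbl[keep, , drop = FALSE] |> arrange(.data$srges, .data$compound)
}

#' Check whether a drug treatment reversed the disease signature
#'
#' Ranks genes by the treatment's log2 fold change (drug vs vehicle,
#' descending) and computes the signature's enrichment difference
#' `es_up - es_down` in that ranking — the same bidirectional KS machinery
#' as RGES, without the same-sign zeroing so the statistic stays continuous
#' under the permutation null. Negative values mean the treatment pushed
#' disease-up genes down and disease-down genes up. Significance is a
#' one-sided (toward reversal) permutation test over gene-label permutations
#' with the +1 correction.
#'
#' @param treatment_de A `de_table` for drug vs vehicle.
#' @param signature A `disease_signature`.
#' @param n_perm Permutations (default 1000).
#' @param top_n Signature truncation per direction.
#' @param min_coverage Minimum fraction of signature genes present in the
#'   treatment table (default 0.5).
#' @param seed Integer seed.
#' @return List: `statistic`, `p`, `coverage`, `n_perm`.
#' @export
reversal_check <- function(treatment_de, signature, n_perm = 1000,
                           top_n = 100, min_coverage = 0.5, seed = 1) {
  covered <- mean(signature$gene %in% treatment_de$gene)
  if (covered < min_coverage) {
    abort(sprintf("treatment table covers only %.0f%% of signature genes (< %.0f%%)",
                  100 * covered, 100 * min_coverage),
          class = "sigreverse_low_coverage")
  }
  values <- setNames(treatment_de$log2fc, treatment_de$gene)
  ranking <- rank_genes(values)
  stat_of <- function(rk) {
    rec <- compute_rges(rk, signature, top_n = top_n, same_sign_zero = FALSE)
    rec$rges
  }
  observed <- stat_of(ranking)
  withr::with_seed(seed, {
    perm <- vapply(seq_len(n_perm), function(i) stat_of(sample(ranking)),
                   numeric(1))
  })
  list(statistic = observed,
       p = (1 + sum(perm <= observed)) / (n_perm + 1),
       coverage = covered, n_perm = n_perm)
}
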