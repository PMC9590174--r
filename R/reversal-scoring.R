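#' Bidirectional Kolmogorov-Smirnov enrichment score
#'
#' Measures whether a gene set concentrates at the top (positive score) or
#' bottom (negative score) of a ranked gene list, using the classic
#' connectivity-map running-sum statistic. With universe size `n`, set size
#' `t` (after intersection with the universe) and sorted set positions
#' `V(1) < ... < V(t)`:
#' \deqn{a = \max_j (j/t - V_j/n), \quad b = \max_j (V_j/n - (j-1)/t)}
#' and the score is `a` if `a > b`, else `-b`. Scores lie in \[-1, 1\]; the
#' extreme -1 arises only for a singleton set at the very bottom.
#'
#' @param ranking Character vector of gene ids in rank order (rank 1 = most
#'   up-regulated by the perturbation).
#' @param gene_set Character vector of genes to test.
#' @return A single enrichment score.
#' @examples
#' ks_enrichment(letters[1:10], c("a", "b"))   #  0.8 (set at the top)
#' ks_enrichment(letters[1:10], c("i", "j"))   # -0.9 (set at the bottom)
#' @export
ks_enrichment <- function(ranking, gene_set) {
  if (length(gene_set) == 0) {
    abort("`gene_set` is empty", class = "sigreverse_empty_set")
  }
  if (anyDuplicated(ranking)) {
    abort("`ranking` contains duplicate genes; it must be a total order")
  }
  n <- length(ranking)
  v <- sort(match(gene_set, ranking))
  v <- v[!is.na(v)]
  t_size <- length(v)
  if (t_size == 0) {
    abort("`gene_set` has no overlap with the ranking universe",
          class = "sigreverse_no_overlap")
  }
  j <- seq_len(t_size)
  a <- max(j / t_size - v / n)
  b <- max(v / n - (j - 1) / t_size)
  if (a > b) a else -b
}

# Rank a named differential vector: most up-regulated first, ties broken by
# gene id so scoring is deterministic.
rank_genes <- function(values) {
  ord <- order(-values, names(values), method = "radix")
  names(values)[ord]
}

#' Reversal gene expression score (RGES) for one drug profile
#'
#' Scores how strongly a ranked drug profile reverses a disease signature:
#' `rges = es_up - es_down` where `es_up`/`es_down` are the KS enrichment of
#' the signature's up/down sets in the profile ranking. A reversing drug
#' pushes disease-up genes to the bottom (`es_up < 0`) and disease-down genes
#' to the top (`es_down > 0`), giving a negative RGES. When both enrichment
#' scores share a sign the profile neither reverses nor mimics the signature
#' coherently and the score is set to 0 (the connectivity-map convention;
#' disable with `same_sign_zero = FALSE`). When the up or down set exceeds
#' `top_n` genes it is truncated to the `top_n` largest |log2FC| before
#' scoring.
#'
#' @param ranking Character vector: profile gene ranking (rank 1 = most
#'   up-regulated by the drug), over the landmark universe.
#' @param signature A [disease_signature] tibble (gene, direction, log2fc).
#' @param top_n Maximum signature genes per direction (default 100).
#' @param same_sign_zero Zero the score when es_up and es_down agree in sign.
#' @return One-row tibble: es_up, es_down, rges.
#' @export
compute_rges <- function(ranking, signature, top_n = 100,
                         same_sign_zero = TRUE) {
  up <- signature_direction(signature, "up", top_n)
  down <- signature_direction(signature, "down", top_n)
  up <- intersect(up, ranking)
  down <- intersect(down, ranking)
  if (length(up) == 0 && length(down) == 0) {
    abort("signature has no overlap with the profile's gene universe",
          class = "sigreverse_no_overlap")
  }
  es_up <- if (length(up)) ks_enrichment(ranking, up) else 0
  es_down <- if (length(down)) ks_enrichment(ranking, down) else 0
  rges <- if (same_sign_zero && sign(es_up) == sign(es_down) &&
              es_up != 0 && es_down != 0) 0 else es_up - es_down
  tibble(es_up = es_up, es_down = es_down, rges = rges)
}

# Top-n genes of one signature direction, ranked by |log2FC| descending with
# gene-id tie-break; truncation applies only when the set exceeds top_n.
signature_direction <- function(signature, direction, top_n = Inf) {
  rows <- signature[signature$direction == direction, , drop = FALSE]
  rows <- rows[order(-abs(rows$log2fc), rows$gene, method = "radix"), ]
  if (nrow(rows) > top_n) rows <- rows[seq_len(top_n), ]
  rows$gene
}

#' Score every profile of a perturbation library against a signature
#'
#' Ranks each profile's landmark differential values (most up-regulated
#' first, gene-id tie-break) and computes its RGES.
#'
#' @param library A `profile_library` long tibble ([simulate_drug_library()]
#'   or [read_profile_library()]).
#' @param signature A disease signature tibble.
#' @inheritParams compute_rges
#' @return Tibble of RGES records: profile_id, compound, cell_line, dose_um,
#'   duration_h, es_up, es_down, rges.
#' @export
score_library <- function(library, signature, top_n = 100,
                          same_sign_zero = TRUE) {
  stopifnot(all(c("profile_id", "compound", "gene", "value") %in%
                  names(library)))
  meta_cols <- intersect(c("profile_id", "compound", "cell_line", "dose_um",
                           "duration_h"), names(library))
  meta <- distinct(library[meta_cols])
  scores <- library |>
    group_by(.data$profile_id) |>
    dplyr::group_map(function(df, key) {
      values <- setNames(df$value, df$gene)
      dplyr::bind_cols(key, compute_rges(rank_genes(values), signature,
                                         top_n = top_n,
                                         same_sign_zero = same_sign_zero))
    }) |>
    bind_rows()
  left_join(meta, scores, by = "profile_id")
}

#' Summarize per-profile RGES into one sRGES per compound
#'
#' Profiles of one compound span cell lines, concentrations, and durations.
#' Each RGES is first adjusted to the 10 uM / 24 h reference condition by
#' subtracting additive dose and duration offsets fitted globally (one
#' ordinary least squares of RGES on `log10(dose/10)` and `duration - 24`,
#' pooled over all compounds; offsets are zero when the metadata columns are
#' absent). Adjusted scores are then averaged within cell line, and sRGES is
#' the mean over cell lines. The table is sorted ascending (most reversing
#' first), ties by compound id.
#'
#' @param rges RGES record tibble from [score_library()].
#' @param reference Named numeric: reference `dose_um` and `duration_h`.
#' @param adjust Apply the pooled dose/duration correction (default TRUE);
#'   FALSE gives the plain per-compound mean-of-cell-line-means.
#' @return `srges_table` tibble: compound, srges, n_profiles, n_cell_lines.
#' @export
summarize_srges <- function(rges, reference = c(dose_um = 10, duration_h = 24),
                            adjust = TRUE) {
  if (nrow(rges) == 0) abort("`rges` is empty; nothing to summarize")
  if (!"compound" %in% names(rges) || anyNA(rges$compound)) {
    abort("every RGES record needs a compound id")
  }
  adj <- rges$rges
  has_meta <- all(c("dose_um", "duration_h") %in% names(rges)) &&
    !anyNA(rges$dose_um) && !anyNA(rges$duration_h)
  if (adjust && has_meta) {
    d <- log10(rges$dose_um / reference[["dose_um"]])
    t <- rges$duration_h - reference[["duration_h"]]
    has_var <- function(v) length(v) > 1 && sd(v) > 0
    if (has_var(d) || has_var(t)) {
      fit <- lm(adj ~ d + t)
      beta <- coef(fit)
      adj <- adj - ifelse(is.na(beta["d"]), 0, beta["d"]) * d -
        ifelse(is.na(beta["t"]), 0, beta["t"]) * t
    }
  }
  rges$rges_adj <- adj
  if (!"cell_line" %in% names(rges)) rges$cell_line <- "unknown"
  out <- rges |>
    group_by(.data$compound, .data$cell_line) |>
    summarise(line_mean = mean(.data$rges_adj), n = n(), .groups = "drop") |>
    group_by(.data$compound) |>
    summarise(srges = mean(.data$line_mean), n_profiles = sum(.data$n),
              n_cell_lines = n(), .groups = "drop") |>
    arrange(.data$srges, .data$compound)
  class(out) <- c("srges_table", class(out))
  out
}

#' Keep compounds that effectively reverse the signature
#'
#' Subsets an sRGES table to rows with `srges < cutoff` (strict), preserving
#' order. The default cutoff of -0.1 is the operating threshold for calling
#' a compound an effective signature reverser.
#'
#' @param srges An `srges_table`.
#' @param cutoff Strict upper bound on sRGES.
#' @return The filtered `srges_table`.
#' @export
reversal_threshold <- function(srges, cutoff = -0.1) {
  out <- srges[srges$srges < cutoff, , drop = FALSE]
  class(out) <- unique(c("srges_table", class(out)))
  out
}
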