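#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end analysis under one list
#' with documented defaults: autoencoder settings, number of surrogate
#' controls, unwanted-variation factors, differential-expression thresholds,
#' signature truncation, the sRGES reversal cutoff, sensitivity quality
#' bound, and hit-filtering rules. Values can come from a YAML file via
#' `yaml::read_yaml()` and be passed here as arguments.
#'
#' @param seed Global seed fanned out to per-stage seeds.
#' @param autoencoder An [autoencoder_config()].
#' @param k_controls Surrogate controls selected from the compendium.
#' @param ruv_k Unwanted-variation factors regressed out (0 disables).
#' @param n_empirical Empirical negative-control genes for the factor fit.
#' @param lfc_min,padj_max Signature thresholds.
#' @param top_n Signature genes per direction used in scoring.
#' @param srges_cutoff Reversal cutoff on sRGES.
#' @param max_cclass Sensitivity curve-quality bound.
#' @param min_profiles,exclude_moa,exclude_preclinical Hit-filtering rules.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1,
                            autoencoder = autoencoder_config(seed = seed),
                            k_controls = 100, ruv_k = 1, n_empirical = 1000,
                            lfc_min = 1, padj_max = 0.05, top_n = 100,
                            srges_cutoff = -0.1, max_cclass = 4,
                            min_profiles = 3,
                            exclude_moa = c("TOP inhibitor", "CDK inhibitor",
                                            "HDAC inhibitor", "DNA inhibitor"),
                            exclude_preclinical = FALSE) {
  assert_positive_int(k_controls, "k_controls")
  if (ruv_k < 0) abort("`ruv_k` must be >= 0",
                       class = "sigreverse_config_error")
  structure(list(seed = as.integer(seed), autoencoder = autoencoder,
                 k_controls = k_controls, ruv_k = ruv_k,
                 n_empirical = n_empirical, lfc_min = lfc_min,
                 padj_max = padj_max, top_n = top_n,
                 srges_cutoff = srges_cutoff, max_cclass = max_cclass,
                 min_profiles = min_profiles, exclude_moa = exclude_moa,
                 exclude_preclinical = exclude_preclinical),
            class = "pipeline_config")
}

#' Validate pipeline inputs before any computation
#'
#' Checks gene-universe overlaps (signature-relevant genes vs the landmark
#' universe, sRGES compounds vs sensitivity compounds), duplicate ids, and
#' unit sanity (positive AC50s), and reports overlap percentages. Report
#' only — nothing is modified and nothing errors.
#'
#' @param library A `profile_library` (or NULL to skip).
#' @param sensitivity Sensitivity tibble (or NULL).
#' @param annotations Annotation tibble (or NULL).
#' @param compendium_genes Gene ids of the expression compendium (or NULL).
#' @return Tibble of checks: check, status ("ok"/"warn"), detail.
#' @export
validate_inputs <- function(library = NULL, sensitivity = NULL,
                            annotations = NULL, compendium_genes = NULL) {
  checks <- list()
  note <- function(check, ok, detail) {
    checks[[length(checks) + 1]] <<- tibble(
      check = check, status = if (ok) "ok" else "warn", detail = detail)
  }
  if (!is.null(library) && !is.null(compendium_genes)) {
    landmark <- unique(library$gene)
    ov <- mean(landmark %in% compendium_genes)
    note("landmark-compendium overlap", ov > 0,
         sprintf("%.1f%% of %d landmark genes in compendium", 100 * ov,
                 length(landmark)))
  }
  if (!is.null(library) && !is.null(sensitivity)) {
    cpds <- unique(library$compound)
    ov <- mean(cpds %in% sensitivity$compound)
    note("compound-sensitivity overlap", ov > 0,
         sprintf("%.1f%% of %d library compounds have sensitivity data",
                 100 * ov, length(cpds)))
  }
  if (!is.null(sensitivity)) {
    note("AC50 positivity", all(sensitivity$ac50 > 0),
         sprintf("%d records, min AC50 = %.3g", nrow(sensitivity),
                 suppressWarnings(min(sensitivity$ac50))))
  }
  if (!is.null(annotations)) {
    dups <- annotations$compound[duplicated(annotations$compound)]
    note("annotation ids unique", length(dups) == 0,
         if (length(dups) == 0) "no duplicates" else
           sprintf("duplicated: %s", paste(unique(dups), collapse = ", ")))
  }
  out <- bind_rows(checks)
  for (i in seq_len(nrow(out))) {
    if (out$status[i] == "warn") {
      warn(sprintf("%s: %s", out$check[i], out$detail[i]))
    }
  }
  out
}

#' Run the full repurposing analysis end-to-end
#'
#' Stages, in order: surrogate-control selection (autoencoder embedding of
#' the TPM compendium plus disease cohort, median-correlation top-k),
#' disease-signature construction (empirical negative controls,
#' unwanted-variation factors, NB differential expression, thresholding),
#' library scoring (RGES, sRGES), evaluation against sensitivity, and hit
#' filtering. Outputs are written to `out_dir` as stamped TSVs together with
#' a JSON manifest (package version, config hash, seed, per-stage row
#' counts). Re-running with the same inputs, config, and seed reproduces the
#' output files byte for byte.
#'
#' @param compendium An `expr_compendium` (normal samples + TPM).
#' @param cohort Disease cohort list (`counts`, `meta`) as from
#'   [simulate_disease_cohort()].
#' @param library A `profile_library`.
#' @param sensitivity Sensitivity tibble.
#' @param annotations Annotation tibble (compound, moa_class, clinical_phase).
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed); NULL skips writing.
#' @return List: controls, signature, srges, evaluation, hits, manifest.
#' @export
run_pipeline <- function(compendium, cohort, library, sensitivity,
                         annotations, config = pipeline_config(),
                         out_dir = NULL) {
  t0 <- Sys.time()
  cfg_hash <- rlang::hash(config)
  stage <- function(name, expr) {
    inform(sprintf("[%s] starting", name))
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            parent = e)
    })
  }

  controls <- stage("controls", {
    cohort_tpm <- sweep(cohort$counts, 2,
                        pmax(colSums(cohort$counts), 1), "/") * 1e6
    model <- train_autoencoder(cbind(compendium$tpm, cohort_tpm),
                               config$autoencoder)
    disease_emb <- encode_samples(model, cohort_tpm)
    normal_emb <- encode_samples(model, compendium$tpm)
    select_controls(disease_emb, normal_emb,
                    k = min(config$k_controls, nrow(normal_emb)))
  })

  signature <- stage("signature", {
    ctrl_counts <- compendium$counts[, controls$sample_id, drop = FALSE]
    emp <- select_empirical_controls(
      cohort$counts, ctrl_counts,
      n = min(config$n_empirical, nrow(cohort$counts)))
    combined <- cbind(cohort$counts, ctrl_counts)
    w <- NULL
    if (config$ruv_k > 0) {
      grp <- rep(c("case", "control"),
                 c(ncol(cohort$counts), ncol(ctrl_counts)))
      w <- remove_unwanted_variation(combined, emp, config$ruv_k,
                                     groups = grp)$w
    }
    de <- compute_de(cohort$counts, ctrl_counts, covariates = w)
    threshold_signature(de, lfc_min = config$lfc_min,
                        padj_max = config$padj_max)
  })

  srges <- stage("score", {
    summarize_srges(score_library(library, signature, top_n = config$top_n))
  })

  evaluation <- stage("evaluate", {
    evaluate_signature(signature, library,
                       filter_sensitivity(sensitivity,
                                          max_cclass = config$max_cclass),
                       top_n = config$top_n,
                       srges_cutoff = config$srges_cutoff)
  })

  hits <- stage("hits", {
    filter_hits(srges, annotations, srges_cutoff = config$srges_cutoff,
                exclude_moa = config$exclude_moa,
                min_profiles = config$min_profiles,
                exclude_preclinical = config$exclude_preclinical)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("sigreverse")),
    config_hash = cfg_hash, seed = config$seed,
    rows = list(controls = nrow(controls), signature = nrow(signature),
                srges = nrow(srges), hits = nrow(hits)),
    evaluation = list(r = evaluation$r, p = evaluation$p, n = evaluation$n),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    stamp <- list(seed = config$seed, config_hash = cfg_hash)
    write_tsv_stamped(controls, file.path(out_dir, "controls.tsv"),
                      stamp$seed, stamp$config_hash)
    write_signature(signature, file.path(out_dir, "signature.tsv"),
                    stamp$seed, stamp$config_hash)
    write_tsv_stamped(as_tibble(srges), file.path(out_dir, "srges.tsv"),
                      stamp$seed, stamp$config_hash)
    write_tsv_stamped(hits, file.path(out_dir, "hits.tsv"),
                      stamp$seed, stamp$config_hash)
    manifest_out <- manifest
    manifest_out$elapsed_s <- NULL   # timing is not part of reproducible output
    jsonlite::write_json(manifest_out, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  list(controls = controls, signature = signature, srges = srges,
       evaluation = evaluation, hits = hits, manifest = manifest)
}

#' Demo: the whole analysis on synthetic data
#'
#' Generates the default synthetic study ([simulate_repurposing_scenario()])
#' and runs [run_pipeline()] on it with a reduced autoencoder (for quick
#' turnaround) unless a full config is supplied.
#'
#' @param seed Global seed.
#' @param out_dir Optional output directory for the stamped result files.
#' @param config Optional [pipeline_config()] override.
#' @return The [run_pipeline()] result list, plus `scenario`.
#' @export
sigreverse_demo <- function(seed = 42, out_dir = NULL, config = NULL) {
  scenario <- simulate_repurposing_scenario(seed = seed)
  config <- config %||% pipeline_config(
    seed = seed,
    autoencoder = autoencoder_config(n_encoded = 32, hidden_widths = c(128),
                                     epochs = 15, batch_size = 128,
                                     seed = stage_seed(seed, "controls")))
  res <- run_pipeline(scenario$compendium, scenario$cohort, scenario$library,
                      scenario$sensitivity, scenario$annotations,
                      config = config, out_dir = out_dir)
  res$scenario <- scenario
  res
}
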