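#' Specification for a synthetic expression compendium
#'
#' Describes the healthy-tissue RNA-seq compendium plus a disease cohort that
#' the generators emulate: negative-binomial counts with tissue-specific mean
#' profiles, optional batch structure, and a disease cohort drawn from one
#' source tissue. Defaults mirror the study conditions the pipeline targets:
#' a 978-gene landmark scoring universe and a 22-sample disease cohort.
#'
#' @param n_genes Number of genes simulated.
#' @param n_landmark Number of landmark (directly scored) genes; the first
#'   `n_landmark` gene ids form the scoring universe.
#' @param tissues Named integer vector of samples per tissue.
#' @param n_disease_samples Disease cohort size.
#' @param source_tissue Tissue the disease cohort derives from.
#' @param nb_dispersion Negative-binomial dispersion phi (variance
#'   `mu + phi * mu^2`).
#' @param library_size_range Min/max expected library size (total counts).
#' @param batch_strength Log2-scale weight of a batch covariate loaded onto a
#'   random 20% of genes; 0 disables batch structure.
#' @param tissue_sd SD of per-tissue log2 deviations from the shared gene mean.
#' @param seed Integer seed; generation is bit-reproducible given the spec.
#'
#' @return A `compendium_spec` list.
#' @export
compendium_spec <- function(n_genes = 2000, n_landmark = 978,
                            tissues = c(brain = 200, liver = 150, muscle = 150),
                            n_disease_samples = 22, source_tissue = "brain",
                            nb_dispersion = 0.1,
                            library_size_range = c(5e5, 2e6),
                            batch_strength = 0, tissue_sd = 1, seed = 1) {
  assert_positive_int(n_genes, "n_genes")
  assert_positive_int(n_landmark, "n_landmark")
  if (n_landmark > n_genes) {
    abort("`n_landmark` must be <= `n_genes`", class = "sigreverse_config_error")
  }
  if (is.null(names(tissues)) || any(!nzchar(names(tissues)))) {
    abort("`tissues` must be a named vector of sample counts",
          class = "sigreverse_config_error")
  }
  if (any(tissues < 2)) {
    abort("`tissues`: every tissue needs at least 2 samples",
          class = "sigreverse_config_error")
  }
  if (!source_tissue %in% names(tissues)) {
    abort(sprintf("`source_tissue` '%s' is not among tissues (%s)",
                  source_tissue, paste(names(tissues), collapse = ", ")),
          class = "sigreverse_config_error")
  }
  if (!is.numeric(nb_dispersion) || nb_dispersion <= 0) {
    abort("`nb_dispersion` must be a positive real",
          class = "sigreverse_config_error")
  }
  if (length(library_size_range) != 2 || any(library_size_range <= 0) ||
      diff(library_size_range) < 0) {
    abort("`library_size_range` must be increasing positive (min, max)",
          class = "sigreverse_config_error")
  }
  if (!is.numeric(batch_strength) || batch_strength < 0) {
    abort("`batch_strength` must be nonnegative",
          class = "sigreverse_config_error")
  }
  structure(
    list(n_genes = as.integer(n_genes), n_landmark = as.integer(n_landmark),
         tissues = tissues, n_disease_samples = as.integer(n_disease_samples),
         source_tissue = source_tissue, nb_dispersion = nb_dispersion,
         library_size_range = library_size_range,
         batch_strength = batch_strength, tissue_sd = tissue_sd,
         seed = as.integer(seed)),
    class = "compendium_spec"
  )
}

gene_ids <- function(n) sprintf("g%05d", seq_len(n))

#' Simulate a healthy-tissue expression compendium
#'
#' Draws NB counts `NB(mu = s_j * q_{g,t(j)}, size = 1/phi)` where `q_{g,t}`
#' is a tissue-specific relative-abundance profile and `s_j` a per-sample
#' library size. With `batch_strength > 0` a standard-normal batch covariate
#' multiplies the mean of a random 20% gene subset by
#' `2^(batch_strength * loading * covariate)`. TPM assumes fixed 1 kb gene
#' lengths, so each TPM column is `count / library_size * 1e6` and sums to
#' one million.
#'
#' @param spec A [compendium_spec()].
#' @return An `expr_compendium` list: `counts` and `tpm` (gene x sample
#'   matrices), `meta` (tibble: sample_id, tissue, disease, cohort, and
#'   `batch` when simulated), and `truth` (tissue mean profiles, batch
#'   loadings) for downstream ground-truth checks.
#' @export
simulate_compendium <- function(spec) {
  if (!inherits(spec, "compendium_spec")) {
    abort("`spec` must be created by compendium_spec()",
          class = "sigreverse_config_error")
  }
  withr::with_seed(spec$seed, {
    genes <- gene_ids(spec$n_genes)
    base_log2 <- rnorm(spec$n_genes, mean = 5, sd = 2)
    q <- sapply(names(spec$tissues), function(t) {
      w <- 2^(base_log2 + rnorm(spec$n_genes, 0, spec$tissue_sd))
      w / sum(w)
    })
    rownames(q) <- genes

    tissue_of <- rep(names(spec$tissues), times = spec$tissues)
    n_samp <- length(tissue_of)
    sample_id <- sprintf("%s_%03d", tissue_of,
                         unlist(lapply(spec$tissues, seq_len)))
    lib <- runif(n_samp, spec$library_size_range[1], spec$library_size_range[2])

    batch <- NULL
    loadings <- rep(0, spec$n_genes)
    if (spec$batch_strength > 0) {
      batch <- rnorm(n_samp)
      members <- sample.int(spec$n_genes, size = ceiling(0.2 * spec$n_genes))
      loadings[members] <- rnorm(length(members))
    }

    mu <- q[, tissue_of, drop = FALSE] * rep(lib, each = spec$n_genes)
    if (!is.null(batch)) {
      mu <- mu * 2^(spec$batch_strength * outer(loadings, batch))
    }
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / spec$nb_dispersion),
                     nrow = spec$n_genes,
                     dimnames = list(genes, sample_id))
    tpm <- sweep(counts, 2, colSums(counts), "/") * 1e6

    meta <- tibble(sample_id = sample_id, tissue = tissue_of,
                   disease = FALSE, cohort = "compendium")
    if (!is.null(batch)) meta$batch <- batch

    structure(
      list(counts = counts, tpm = tpm, meta = meta,
           truth = list(tissue_profiles = q, batch_loadings = loadings,
                        library_sizes = lib),
           spec = spec),
      class = "expr_compendium"
    )
  })
}

#' Plant a ground-truth disease signature
#'
#' Chooses disjoint up/down gene sets with log2 fold changes of at least 1 in
#' magnitude, plus a set of unaffected negative-control genes used to test
#' empirical-control selection. By default most signature genes fall inside
#' the landmark universe so reversal scoring has material to work with.
#'
#' @param spec A [compendium_spec()] giving the gene universe.
#' @param n_up,n_down Signature genes inside the landmark set.
#' @param n_up_tail,n_down_tail Additional signature genes outside it.
#' @param n_control Unaffected negative-control genes.
#' @param lfc_range Magnitude range of planted log2 fold changes.
#' @param seed Integer seed.
#' @return A `planted_signature` list: `up_genes`, `down_genes`,
#'   `control_genes`, and named `effect_log2fc` over all signature genes.
#' @export
simulate_planted_signature <- function(spec, n_up = 100, n_down = 100,
                                       n_up_tail = 50, n_down_tail = 50,
                                       n_control = 500, lfc_range = c(1, 3),
                                       seed = spec$seed + 1L) {
  genes <- gene_ids(spec$n_genes)
  landmark <- genes[seq_len(spec$n_landmark)]
  tail_pool <- setdiff(genes, landmark)
  withr::with_seed(seed, {
    in_lm <- sample(landmark, n_up + n_down)
    in_tail <- if (n_up_tail + n_down_tail > 0) {
      sample(tail_pool, n_up_tail + n_down_tail)
    } else character()
    up <- c(in_lm[seq_len(n_up)], in_tail[seq_len(n_up_tail)])
    down <- c(in_lm[n_up + seq_len(n_down)],
              in_tail[n_up_tail + seq_len(n_down_tail)])
    ctrl <- sample(setdiff(genes, c(up, down)), n_control)
    eff <- c(runif(length(up), lfc_range[1], lfc_range[2]),
             -runif(length(down), lfc_range[1], lfc_range[2]))
    names(eff) <- c(up, down)
    structure(list(up_genes = up, down_genes = down, control_genes = ctrl,
                   effect_log2fc = eff),
              class = "planted_signature")
  })
}

#' Simulate a disease cohort carrying a planted signature
#'
#' Draws `n` samples from the compendium's source-tissue NB model with gene
#' means multiplied by `2^effect_log2fc` on the planted signature genes;
#' control genes (and all other genes) keep their source-tissue means. When
#' the compendium carries batch structure the cohort samples receive fresh
#' batch covariate values under the same gene loadings.
#'
#' @param compendium An `expr_compendium`.
#' @param planted A `planted_signature` (or NULL for a signature-free cohort).
#' @param n Cohort size; defaults to the spec's `n_disease_samples`.
#' @param seed Integer seed.
#' @return List with `counts` (genes x n), `meta`, and `truth` (batch values).
#' @export
simulate_disease_cohort <- function(compendium, planted = NULL,
                                    n = compendium$spec$n_disease_samples,
                                    seed = compendium$spec$seed + 2L) {
  spec <- compendium$spec
  genes <- rownames(compendium$counts)
  if (!is.null(planted)) {
    sig_genes <- names(planted$effect_log2fc)
    missing <- setdiff(sig_genes, genes)
    if (length(missing) > 0) {
      abort(sprintf("planted gene id(s) not in compendium: %s",
                    paste(head(missing, 5), collapse = ", ")))
    }
  }
  withr::with_seed(seed, {
    q <- compendium$truth$tissue_profiles[, spec$source_tissue]
    if (!is.null(planted)) {
      q[names(planted$effect_log2fc)] <-
        q[names(planted$effect_log2fc)] * 2^planted$effect_log2fc
    }
    sample_id <- sprintf("DIPG_%03d", seq_len(n))
    if (n == 0) {
      counts <- matrix(integer(), nrow = length(genes), ncol = 0,
                       dimnames = list(genes, NULL))
      return(list(counts = counts,
                  meta = tibble(sample_id = character(), tissue = character(),
                                disease = logical(), cohort = character()),
                  truth = list(batch = numeric())))
    }
    lib <- runif(n, spec$library_size_range[1], spec$library_size_range[2])
    mu <- outer(q, lib)
    batch <- NULL
    if (spec$batch_strength > 0) {
      batch <- rnorm(n)
      mu <- mu * 2^(spec$batch_strength *
                      outer(compendium$truth$batch_loadings, batch))
    }
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / spec$nb_dispersion),
                     nrow = length(genes), dimnames = list(genes, sample_id))
    meta <- tibble(sample_id = sample_id, tissue = spec$source_tissue,
                   disease = TRUE, cohort = "disease")
    if (!is.null(batch)) meta$batch <- batch
    list(counts = counts, meta = meta, truth = list(batch = batch %||% numeric()))
  })
}

#' Simulate a panel of perturbagen compounds with planted reversal strengths
#'
#' Each compound carries a ground-truth reversal strength theta in \[0, 1\]
#' (the fraction of the disease signature its profiles undo), a
#' mechanism-of-action class, a clinical phase, and a set of assay conditions
#' (cell line, concentration, duration) — one profile per condition,
#' mirroring perturbation libraries where compounds are measured repeatedly
#' across cell lines, doses, and durations.
#'
#' @param n Total compounds.
#' @param n_strong Compounds with theta drawn from U(0.75, 1); the rest draw
#'   from U(0, 0.7).
#' @param cell_lines Candidate cell lines for assay conditions.
#' @param n_profile_range Range of profiles (conditions) per compound.
#' @param seed Integer seed.
#' @return A tibble (class `planted_compounds`): compound, theta, moa_class,
#'   clinical_phase, n_profiles, and a `conditions` list-column.
#' @export
simulate_compounds <- function(n = 100, n_strong = 10,
                               cell_lines = c("SU-DIPG-IV", "JHH-DIPG-1",
                                              "SU-DIPG-XIII", "SU-DIPG-VI"),
                               n_profile_range = c(3, 8), seed = 100) {
  assert_positive_int(n, "n")
  if (n_strong > n) abort("`n_strong` must be <= `n`",
                          class = "sigreverse_config_error")
  withr::with_seed(seed, {
    theta <- c(runif(n_strong, 0.75, 1), runif(n - n_strong, 0, 0.7))
    compound <- sprintf("cpd_%03d", seq_len(n))
    excluded_pool <- c("TOP inhibitor", "CDK inhibitor", "HDAC inhibitor",
                       "DNA inhibitor")
    other_pool <- c("IMPDH inhibitor", "glucocorticoid receptor agonist",
                    "EGFR inhibitor", "sodium channel blocker", "null")
    moa <- c(sample(c("IMPDH inhibitor", "null"), n_strong, replace = TRUE,
                    prob = c(0.7, 0.3)),
             sample(c(excluded_pool, other_pool), n - n_strong, replace = TRUE))
    phase <- c(rep("Launched", n_strong),
               sample(c("Launched", "Phase 3", "Phase 2", "Preclinical"),
                      n - n_strong, replace = TRUE))
    n_prof <- sample(seq(n_profile_range[1], n_profile_range[2]), n,
                     replace = TRUE)
    conditions <- lapply(n_prof, function(k) {
      tibble(cell_line = sample(cell_lines, k, replace = TRUE),
             dose_um = sample(c(0.5, 1, 5, 10, 20), k, replace = TRUE),
             duration_h = sample(c(6, 24, 48), k, replace = TRUE))
    })
    out <- tibble(compound = compound, theta = theta, moa_class = moa,
                  clinical_phase = phase, n_profiles = n_prof,
                  conditions = conditions)
    class(out) <- c("planted_compounds", class(out))
    out
  })
}

# Dose/time modulation of effective reversal strength: 1 at the 10 uM / 24 h
# reference condition, linear in log10(dose/10) and duration/24, clamped.
dose_time_modulation <- function(dose_um, duration_h) {
  m <- 1 + 0.3 * log10(dose_um / 10) + 0.3 * (duration_h / 24 - 1)
  pmin(pmax(m, 0.25), 1.5)
}

#' Simulate a drug-perturbation profile library over the landmark genes
#'
#' Each profile is a landmark-gene differential vector: on signature genes it
#' equals `-theta_eff * effect_log2fc` (the drug pushes disease-up genes down
#' and disease-down genes up, in proportion to the compound's planted
#' strength), plus Gaussian noise everywhere. `theta_eff` is theta scaled by
#' a dose/duration modulation that equals 1 at the 10 uM / 24 h reference.
#'
#' @param planted A `planted_signature`.
#' @param compounds A `planted_compounds` tibble ([simulate_compounds()]).
#' @param landmark_genes Character vector: the scoring universe.
#' @param noise_sd Gaussian noise SD added to every landmark value.
#' @param seed Integer seed.
#' @return A long tibble (class `profile_library`): profile_id, compound,
#'   cell_line, dose_um, duration_h, gene, value. The compounds table (with
#'   ground-truth theta) is attached as `attr(, "truth")`; the landmark
#'   universe as `attr(, "landmark")`.
#' @export
simulate_drug_library <- function(planted, compounds, landmark_genes,
                                  noise_sd = 0.5, seed = 200) {
  if (nrow(compounds) == 0) abort("`compounds` must be nonempty")
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    abort("`noise_sd` must be nonnegative", class = "sigreverse_config_error")
  }
  eff <- planted$effect_log2fc
  eff_lm <- eff[names(eff) %in% landmark_genes]
  withr::with_seed(seed, {
    rows <- pmap(list(compounds$compound, compounds$theta, compounds$conditions),
                 function(cpd, theta, cond) {
      cond$profile <- seq_len(nrow(cond))
      pmap(cond[c("cell_line", "dose_um", "duration_h", "profile")],
           function(cell_line, dose_um, duration_h, profile) {
        theta_eff <- theta * dose_time_modulation(dose_um, duration_h)
        value <- rnorm(length(landmark_genes), 0, noise_sd)
        names(value) <- landmark_genes
        value[names(eff_lm)] <- value[names(eff_lm)] - theta_eff * eff_lm
        tibble(profile_id = sprintf("%s_p%02d", cpd, profile),
               compound = cpd, cell_line = cell_line, dose_um = dose_um,
               duration_h = duration_h, gene = landmark_genes,
               value = unname(value))
      })
    })
    out <- bind_rows(purrr::flatten(rows))
    attr(out, "truth") <- compounds
    attr(out, "landmark") <- landmark_genes
    class(out) <- c("profile_library", class(out))
    out
  })
}

#' Simulate drug-sensitivity records (AC50 with curve-quality classes)
#'
#' AC50 follows `10^(a - b * theta + eps)` molar with `eps ~ N(0, eps_sd)`
#' per (compound, cell line): potency is lognormal and monotone decreasing in
#' the planted reversal strength in expectation. A configurable fraction of
#' records receives a low-quality curve class (CCLASS or CCLASS2 >= 4) so the
#' quality filter has something to remove.
#'
#' @param compounds A `planted_compounds` tibble.
#' @param cell_lines Cell lines assayed.
#' @param a,b Intercept and slope of log10 AC50 on theta; `b >= 0`.
#' @param eps_sd Lognormal noise SD (log10 scale).
#' @param lowq_frac Fraction of records flagged low quality.
#' @param seed Integer seed.
#' @return Tibble: compound, cell_line, ac50 (molar), cclass, cclass2.
#' @export
simulate_sensitivity <- function(compounds,
                                 cell_lines = c("SU-DIPG-IV", "JHH-DIPG-1",
                                                "SU-DIPG-XIII", "SU-DIPG-VI"),
                                 a = -4, b = 2, eps_sd = 0.5,
                                 lowq_frac = 0.1, seed = 300) {
  if (nrow(compounds) == 0) abort("`compounds` must be nonempty")
  if (b < 0) abort("`b` must be >= 0", class = "sigreverse_config_error")
  assert_fraction(lowq_frac, "lowq_frac", allow_one = TRUE)
  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(
      compounds[c("compound", "theta")], cell_line = cell_lines)
    eps <- rnorm(nrow(grid), 0, eps_sd)
    lowq <- runif(nrow(grid)) < lowq_frac
    grid |>
      mutate(ac50 = 10^(a - b * .data$theta + eps),
             cclass = ifelse(lowq & runif(n()) < 0.5,
                             sample(4:5, n(), replace = TRUE),
                             sample(1:3, n(), replace = TRUE)),
             cclass2 = ifelse(lowq & .data$cclass < 4,
                              sample(4:5, n(), replace = TRUE),
                              sample(1:3, n(), replace = TRUE))) |>
      select("compound", "cell_line", "ac50", "cclass", "cclass2")
  })
}

#' Simulate a single-cell RSEM-like matrix with malignant and oligodendrocyte cells
#'
#' Values are lognormal per gene; malignant cells carry the planted disease
#' signature (gene means multiplied by `2^effect_log2fc`) plus one of several
#' disjoint program modules (cell cycle, OPC-like, AC-like, OC-like) with
#' lognormal activation; dropout injects exact zeros at the given rate.
#' Defaults emulate a cohort of 2259 malignant and 232 oligodendrocyte cells.
#'
#' @param planted A `planted_signature` over the gene universe.
#' @param genes Character vector of gene ids.
#' @param n_malignant,n_oligo Cell counts per class.
#' @param programs Program names; disjoint gene modules of `module_size` genes
#'   are planted for each.
#' @param module_size Genes per program module.
#' @param dropout Zero-injection rate in \[0, 1).
#' @param seed Integer seed.
#' @return List: `values` (genes x cells), `labels` (tibble: cell_id,
#'   cell_type, program), `truth` (program module gene sets).
#' @export
simulate_sc_matrix <- function(planted, genes, n_malignant = 2259,
                               n_oligo = 232,
                               programs = c("Cell cycle", "OPC like",
                                            "AC like", "OC like"),
                               module_size = 50, dropout = 0.3, seed = 400) {
  if (n_malignant < 0 || n_oligo < 0) abort("cell counts must be nonnegative")
  assert_fraction(dropout, "dropout")
  withr::with_seed(seed, {
    n_cells <- n_malignant + n_oligo
    cell_type <- c(rep("malignant", n_malignant), rep("oligodendrocyte", n_oligo))
    cell_id <- sprintf("cell_%04d", seq_len(n_cells))
    program <- rep(NA_character_, n_cells)
    if (n_malignant > 0) {
      program[seq_len(n_malignant)] <- sample(programs, n_malignant,
                                              replace = TRUE)
    }
    pool <- setdiff(genes, names(planted$effect_log2fc))
    modules <- if (module_size > 0) {
      split(sample(pool, module_size * length(programs)),
            rep(programs, each = module_size))
    } else {
      setNames(rep(list(character()), length(programs)), programs)
    }
    base_mu <- rnorm(length(genes), mean = 1, sd = 1)
    names(base_mu) <- genes
    logv <- matrix(rnorm(length(genes) * n_cells, mean = base_mu, sd = 1),
                   nrow = length(genes), dimnames = list(genes, cell_id))
    eff <- planted$effect_log2fc * log(2)
    if (n_malignant > 0) {
      logv[names(eff), seq_len(n_malignant)] <-
        logv[names(eff), seq_len(n_malignant), drop = FALSE] + eff
      for (p in programs) {
        cells <- which(program == p)
        if (module_size == 0 || length(cells) == 0) next
        act <- rnorm(length(cells), mean = 1.5, sd = 0.3)
        logv[modules[[p]], cells] <-
          logv[modules[[p]], cells, drop = FALSE] +
          rep(act, each = module_size)
      }
    }
    values <- exp(logv)
    if (dropout > 0) {
      values[matrix(runif(length(values)) < dropout, nrow = nrow(values))] <- 0
    }
    list(values = values,
         labels = tibble(cell_id = cell_id, cell_type = cell_type,
                         program = program),
         truth = list(modules = modules))
  })
}

#' Simulate the full default repurposing study
#'
#' Bundles every synthetic input the pipeline consumes under one seed:
#' a multi-tissue compendium, a planted disease signature, a disease cohort,
#' a perturbation profile library over the landmark genes, drug-sensitivity
#' records, and a drug-annotation table derived from the planted compounds.
#'
#' @param seed Global integer seed fanned out to per-stage seeds.
#' @param spec Optional [compendium_spec()] override.
#' @param n_compounds,n_strong Compound panel composition.
#' @return List: compendium, planted, cohort, compounds, library, sensitivity,
#'   annotations.
#' @export
simulate_repurposing_scenario <- function(seed = 1, spec = NULL,
                                          n_compounds = 100, n_strong = 10) {
  spec <- spec %||% compendium_spec(batch_strength = 0.5,
                                    seed = stage_seed(seed, "simulate"))
  compendium <- simulate_compendium(spec)
  # planted sizes scale down with small gene universes
  n_in <- min(100L, spec$n_landmark %/% 4L)
  n_tail <- min(50L, (spec$n_genes - spec$n_landmark) %/% 4L)
  n_ctrl <- min(500L, (spec$n_genes - 2L * (n_in + n_tail)) %/% 2L)
  planted <- simulate_planted_signature(spec, n_up = n_in, n_down = n_in,
                                        n_up_tail = n_tail,
                                        n_down_tail = n_tail,
                                        n_control = n_ctrl,
                                        seed = stage_seed(seed, "signature"))
  cohort <- simulate_disease_cohort(compendium, planted,
                                    seed = stage_seed(seed, "sc"))
  compounds <- simulate_compounds(n = n_compounds, n_strong = n_strong,
                                  seed = stage_seed(seed, "library"))
  landmark <- gene_ids(spec$n_genes)[seq_len(spec$n_landmark)]
  library <- simulate_drug_library(planted, compounds, landmark,
                                   seed = stage_seed(seed, "score"))
  sensitivity <- simulate_sensitivity(compounds,
                                      seed = stage_seed(seed, "sensitivity"))
  annotations <- compounds |>
    mutate(targets = stringr::str_remove(.data$moa_class,
                                         " (inhibitor|agonist|blocker)$")) |>
    select("compound", "moa_class", "targets", "clinical_phase")
  list(compendium = compendium, planted = planted, cohort = cohort,
       compounds = compounds, library = library, sensitivity = sensitivity,
       annotations = annotations)
}
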