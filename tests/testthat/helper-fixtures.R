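# Shared fixture builders. Everything is generated in code under fixed seeds;
# sizes are kept small so the default run stays fast.

small_spec <- function(seed = 3, batch_strength = 0, n_genes = 400,
                       tissues = c(brain = 30, liver = 30)) {
  compendium_spec(n_genes = n_genes, n_landmark = min(200, n_genes),
                  tissues = tissues, n_disease_samples = 8,
                  source_tissue = "brain",
                  library_size_range = c(1e5, 3e5),
                  batch_strength = batch_strength, seed = seed)
}

# Disease signature straight from planted truth (bypasses DE).
truth_signature <- function(planted) {
  new_sig <- tibble::tibble(
    gene = names(planted$effect_log2fc),
    direction = ifelse(planted$effect_log2fc > 0, "up", "down"),
    log2fc = unname(planted$effect_log2fc))
  structure(new_sig, class = c("disease_signature", class(new_sig)))
}

# Signature placing `up` and `down` gene sets with unit fold changes.
set_signature <- function(up, down) {
  tibble::tibble(gene = c(up, down),
                 direction = rep(c("up", "down"), c(length(up), length(down))),
                 log2fc = rep(c(2, -2), c(length(up), length(down))))
}

# Independent running-sum oracle for the bidirectional KS score: walks the
# ranking once, tracking the set's empirical CDF against the uniform CDF.
ks_oracle <- function(n, positions) {
  member <- seq_len(n) %in% positions
  t_size <- sum(member)
  f <- cumsum(member) / t_size
  i <- seq_len(n)
  a <- max(f - i / n)
  b <- max(i / n - c(0, f[-n]))
  if (a > b) a else -b
}

tiny_ae_config <- function(seed = 2, epochs = 8) {
  autoencoder_config(n_encoded = 16, hidden_widths = c(64), epochs = epochs,
                     batch_size = 32, seed = seed)
}

# The depth-normalized, row-centered log2 transform the unwanted-variation
# step works on, recomputed independently for identity checks.
norm_center_log <- function(counts, pseudocount = 1) {
  lib <- colSums(counts)
  sf <- lib / exp(mean(log(pmax(lib, 1))))
  sf[sf == 0] <- 1
  logy <- log2(sweep(counts, 2, sf, "/") + pseudocount)
  logy - rowMeans(logy)
}

tpm_of <- function(counts) {
  sweep(counts, 2, pmax(colSums(counts), 1), "/") * 1e6
}
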