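# Internal helpers shared across modules.

# Derive a reproducible per-stage seed from a global seed. Keeps results
# inside the 32-bit integer range R requires for set.seed().
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offsets <- c(
    simulate = 11L, controls = 23L, signature = 37L, score = 47L,
    evaluate = 59L, hits = 67L, sc = 71L, library = 83L, sensitivity = 97L
  )
  off <- offsets[[stage]] %||% (sum(utf8ToInt(stage)) %% 101L)
  as.integer((as.numeric(seed) * 127L + off) %% 2147483647)
}

assert_positive_int <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 1 || x != floor(x)) {
    abort(sprintf("`%s` must be a positive integer, got %s", name,
                  paste(format(x), collapse = ", ")),
          class = "sigreverse_config_error")
  }
  invisible(as.integer(x))
}

assert_fraction <- function(x, name, allow_one = FALSE) {
  hi_ok <- if (allow_one) x <= 1 else x < 1
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || !hi_ok) {
    abort(sprintf("`%s` must lie in [0, 1%s), got %s", name,
                  if (allow_one) "]" else "", format(x)),
          class = "sigreverse_config_error")
  }
  invisible(as.numeric(x))
}

# Write a tibble as TSV with a provenance comment header; readers skip '#'.
write_tsv_stamped <- function(x, path, seed = NULL, config_hash = NULL) {
  header <- sprintf("# sigreverse %s | seed=%s | config=%s",
                    as.character(utils::packageVersion("sigreverse")),
                    seed %||% "NA", config_hash %||% "NA")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(c(header, sub("\n+$", "", readr::format_tsv(x))), con)
  invisible(path)
}

read_tsv_stamped <- function(path, col_types = NULL) {
  readr::read_tsv(path, comment = "#", col_types = col_types %||% readr::cols(),
                  progress = FALSE)
}

# log2(TPM + 1), the transform used throughout embedding and QC.
log2_tpm <- function(tpm) log2(tpm + 1)
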