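#' Read and write disease signatures as 3-column TSV
#'
#' The on-disk format is `gene`, `direction` (up/down), `log2fc` — the same
#' format used to ingest externally published signatures. Lines starting
#' with `#` are ignored.
#'
#' @param path File path.
#' @param signature A `disease_signature` tibble.
#' @param provenance Tag recorded on the signature when reading.
#' @param ... Passed to [write_tsv_stamped()] (seed, config hash).
#' @return `read_signature()` returns a `disease_signature`;
#'   `write_signature()` returns the path invisibly.
#' @export
read_signature <- function(path, provenance = "published") {
  tbl <- read_tsv_stamped(path, readr::cols(gene = "c", direction = "c",
                                            log2fc = "d"))
  bad <- setdiff(unique(tbl$direction), c("up", "down"))
  if (length(bad) > 0) {
    abort(sprintf("invalid direction value(s): %s", paste(bad, collapse = ", ")))
  }
  new_signature(tbl, provenance)
}

#' @rdname read_signature
#' @export
write_signature <- function(signature, path, ...) {
  write_tsv_stamped(as_tibble(signature)[c("gene", "direction", "log2fc")],
                    path, ...)
}

#' Read and write a profile library as long-format TSV
#'
#' Columns: profile_id, compound, cell_line, dose_um, duration_h, gene,
#' value. The landmark universe is taken as the union of genes present.
#'
#' @param path File path (plain or gzip TSV).
#' @param library A `profile_library` tibble.
#' @param ... Passed to [write_tsv_stamped()].
#' @export
read_profile_library <- function(path) {
  tbl <- read_tsv_stamped(path)
  needed <- c("profile_id", "compound", "gene", "value")
  if (!all(needed %in% names(tbl))) {
    abort(sprintf("profile library must have columns: %s",
                  paste(needed, collapse = ", ")))
  }
  attr(tbl, "landmark") <- sort(unique(tbl$gene))
  class(tbl) <- c("profile_library", class(tbl))
  tbl
}

#' @rdname read_profile_library
#' @export
write_profile_library <- function(library, path, ...) {
  cols <- intersect(c("profile_id", "compound", "cell_line", "dose_um",
                      "duration_h", "gene", "value"), names(library))
  write_tsv_stamped(as_tibble(library)[cols], path, ...)
}

#' Read and write drug-sensitivity tables
#'
#' Columns: compound, cell_line, ac50, cclass, cclass2.
#'
#' @param path File path.
#' @param sensitivity Sensitivity tibble.
#' @param ... Passed to [write_tsv_stamped()].
#' @export
read_sensitivity <- function(path) {
  tbl <- read_tsv_stamped(path)
  needed <- c("compound", "cell_line", "ac50", "cclass", "cclass2")
  if (!all(needed %in% names(tbl))) {
    abort(sprintf("sensitivity table must have columns: %s",
                  paste(needed, collapse = ", ")))
  }
  if (any(tbl$ac50 <= 0)) abort("AC50 values must be positive")
  tbl
}

#' @rdname read_sensitivity
#' @export
write_sensitivity <- function(sensitivity, path, ...) {
  write_tsv_stamped(sensitivity, path, ...)
}

#' Write an expression matrix with metadata as TSV
#'
#' Genes x samples matrix written with the gene id as first column; the
#' metadata tibble goes to a sibling `*.meta.tsv`.
#'
#' @param mat Numeric matrix with gene rownames and sample colnames.
#' @param path Output TSV path (a `.gz` suffix enables compression via
#'   readr).
#' @param meta Optional sample metadata tibble.
#' @param ... Passed to [write_tsv_stamped()].
#' @export
write_expression <- function(mat, path, meta = NULL, ...) {
  tbl <- as_tibble(mat, rownames = "gene")
  write_tsv_stamped(tbl, path, ...)
  if (!is.null(meta)) {
    write_tsv_stamped(meta, sub("\\.tsv(\\.gz)?$", ".meta.tsv", path), ...)
  }
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  tbl <- read_tsv_stamped(path)
  mat <- as.matrix(tbl[-1])
  rownames(mat) <- tbl$gene
  mat
}
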