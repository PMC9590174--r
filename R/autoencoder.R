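#' Autoencoder configuration for compendium embedding
#'
#' Defaults follow the embedding recipe the pipeline targets: 64 encoded
#' features, mini-batches of 128, 100 epochs, and a learning rate of 0.0002,
#' with rectified-linear activations, dropout, and batch normalization
#' between layers. The encoder narrows through `hidden_widths` to
#' `n_encoded`; the decoder mirrors it.
#'
#' @param n_encoded Width of the embedding (bottleneck) layer.
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs; 0 leaves the model at initialization.
#' @param learning_rate Adam step size.
#' @param hidden_widths Encoder hidden-layer widths, input to bottleneck.
#' @param dropout_rate Dropout probability on hidden activations, in \[0, 1).
#' @param seed Integer seed controlling initialization, shuffling, dropout.
#' @return An `autoencoder_config` list.
#' @export
autoencoder_config <- function(n_encoded = 64, batch_size = 128, epochs = 100,
                               learning_rate = 2e-4,
                               hidden_widths = c(512, 128),
                               dropout_rate = 0.1, seed = 1) {
  assert_positive_int(n_encoded, "n_encoded")
  assert_positive_int(batch_size, "batch_size")
  if (epochs < 0) abort("`epochs` must be >= 0",
                        class = "sigreverse_config_error")
  assert_fraction(dropout_rate, "dropout_rate")
  structure(list(n_encoded = as.integer(n_encoded),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 hidden_widths = as.integer(hidden_widths),
                 dropout_rate = dropout_rate, seed = as.integer(seed)),
            class = "autoencoder_config")
}

relu <- function(x) pmax(x, 0)
bn_eps <- 1e-5

ae_init_layer <- function(n_in, n_out, hidden) {
  list(w = matrix(rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out),
       b = rep(0, n_out), hidden = hidden,
       run_mean = rep(0, n_out), run_var = rep(1, n_out))
}

# Forward pass. Hidden layers: linear -> batch normalization -> ReLU ->
# (inverted) dropout; the bottleneck and output layers are plain linear.
ae_forward <- function(layers, x, dropout_rate = 0, training = FALSE,
                       momentum = 0.9, upto = length(layers)) {
  caches <- vector("list", upto)
  for (l in seq_len(upto)) {
    ly <- layers[[l]]
    z <- sweep(x %*% ly$w, 2, ly$b, "+")
    if (ly$hidden) {
      if (training) {
        mu <- colMeans(z)
        vr <- colMeans(sweep(z, 2, mu)^2)
        layers[[l]]$run_mean <- momentum * ly$run_mean + (1 - momentum) * mu
        layers[[l]]$run_var <- momentum * ly$run_var + (1 - momentum) * vr
      } else {
        mu <- ly$run_mean
        vr <- ly$run_var
      }
      zhat <- sweep(sweep(z, 2, mu), 2, sqrt(vr + bn_eps), "/")
      a <- relu(zhat)
      mask <- NULL
      if (training && dropout_rate > 0) {
        mask <- matrix(runif(length(a)) >= dropout_rate, nrow(a)) /
          (1 - dropout_rate)
        a <- a * mask
      }
      caches[[l]] <- list(x = x, zhat = zhat, mu = mu, vr = vr, mask = mask)
      x <- a
    } else {
      caches[[l]] <- list(x = x)
      x <- z
    }
  }
  list(out = x, caches = caches, layers = layers)
}

ae_backward <- function(layers, caches, delta, dropout_rate) {
  grads <- vector("list", length(layers))
  for (l in rev(seq_along(layers))) {
    ly <- layers[[l]]
    ca <- caches[[l]]
    if (ly$hidden) {
      if (!is.null(ca$mask)) delta <- delta * ca$mask
      dzhat <- delta * (ca$zhat > 0)
      m <- nrow(dzhat)
      inv_sd <- 1 / sqrt(ca$vr + bn_eps)
      # batch-normalization backward (no learned affine)
      dz <- sweep(
        dzhat - matrix(colMeans(dzhat), m, ncol(dzhat), byrow = TRUE) -
          ca$zhat * matrix(colMeans(dzhat * ca$zhat), m, ncol(dzhat),
                           byrow = TRUE),
        2, inv_sd, "*")
    } else {
      dz <- delta
    }
    grads[[l]] <- list(dw = crossprod(ca$x, dz) / nrow(dz),
                       db = colMeans(dz))
    delta <- dz %*% t(ly$w)
  }
  grads
}

#' Train an autoencoder on a TPM compendium
#'
#' The input is `log2(TPM + 1)`, standardized per gene on the training set
#' (constant genes get unit scale). The encoder narrows through the
#' configured hidden widths to the bottleneck; the decoder mirrors it.
#' Hidden layers apply batch normalization, rectified-linear activation, and
#' dropout; optimization is Adam on the mean squared reconstruction error.
#' Training is deterministic under the config seed.
#'
#' @param tpm Gene x sample TPM matrix (nonnegative, finite).
#' @param config An [autoencoder_config()].
#' @return A `sigreverse_autoencoder` model holding the layers, the gene
#'   index and standardization parameters, and the reconstruction MSE on the
#'   `log2(TPM + 1)` scale at initialization and after training.
#' @export
train_autoencoder <- function(tpm, config = autoencoder_config()) {
  if (!all(is.finite(tpm))) abort("`tpm` contains non-finite values")
  if (ncol(tpm) < 2) abort("need at least 2 samples to train")
  if (config$n_encoded > nrow(tpm)) {
    abort(sprintf("`n_encoded` (%d) exceeds the number of genes (%d)",
                  config$n_encoded, nrow(tpm)),
          class = "sigreverse_config_error")
  }
  x_log <- t(log2_tpm(tpm))              # samples x genes
  center <- colMeans(x_log)
  scale <- apply(x_log, 2, sd)
  scale[scale == 0] <- 1
  x <- sweep(sweep(x_log, 2, center), 2, scale, "/")

  dims <- c(ncol(x), config$hidden_widths, config$n_encoded,
            rev(config$hidden_widths), ncol(x))
  n_code <- length(config$hidden_widths) + 1L   # index of bottleneck layer
  withr::with_seed(config$seed, {
    layers <- lapply(seq_len(length(dims) - 1), function(l) {
      hidden <- l != n_code && l != length(dims) - 1
      ae_init_layer(dims[l], dims[l + 1], hidden)
    })

    mse_raw <- function(lys) {
      recon_std <- ae_forward(lys, x, training = FALSE)$out
      recon <- sweep(sweep(recon_std, 2, scale, "*"), 2, center, "+")
      mean((recon - x_log)^2)
    }
    loss_init <- mse_raw(layers)

    adam <- lapply(layers, function(ly) {
      list(mw = ly$w * 0, vw = ly$w * 0, mb = ly$b * 0, vb = ly$b * 0)
    })
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0
    n <- nrow(x)
    if (config$epochs > 0) {
      for (epoch in seq_len(config$epochs)) {
        idx <- sample.int(n)
        starts <- seq(1, n, by = config$batch_size)
        for (s in starts) {
          rows <- idx[s:min(s + config$batch_size - 1, n)]
          if (length(rows) < 2) next   # batch statistics need >= 2 samples
          xb <- x[rows, , drop = FALSE]
          fw <- ae_forward(layers, xb, dropout_rate = config$dropout_rate,
                           training = TRUE)
          layers <- fw$layers          # running batch-norm statistics
          delta <- 2 * (fw$out - xb) / length(xb)
          grads <- ae_backward(layers, fw$caches, delta, config$dropout_rate)
          step <- step + 1
          for (l in seq_along(layers)) {
            g <- grads[[l]]
            adam[[l]]$mw <- b1 * adam[[l]]$mw + (1 - b1) * g$dw
            adam[[l]]$vw <- b2 * adam[[l]]$vw + (1 - b2) * g$dw^2
            adam[[l]]$mb <- b1 * adam[[l]]$mb + (1 - b1) * g$db
            adam[[l]]$vb <- b2 * adam[[l]]$vb + (1 - b2) * g$db^2
            mw_hat <- adam[[l]]$mw / (1 - b1^step)
            vw_hat <- adam[[l]]$vw / (1 - b2^step)
            mb_hat <- adam[[l]]$mb / (1 - b1^step)
            vb_hat <- adam[[l]]$vb / (1 - b2^step)
            layers[[l]]$w <- layers[[l]]$w -
              config$learning_rate * mw_hat / (sqrt(vw_hat) + eps)
            layers[[l]]$b <- layers[[l]]$b -
              config$learning_rate * mb_hat / (sqrt(vb_hat) + eps)
          }
        }
      }
    }
    loss_final <- mse_raw(layers)
    structure(list(layers = layers, n_code = n_code, genes = rownames(tpm),
                   center = center, scale = scale, config = config,
                   loss_init = loss_init, loss_final = loss_final),
              class = "sigreverse_autoencoder")
  })
}

#' Embed samples with a trained autoencoder
#'
#' Applies the stored `log2(TPM + 1)` transform and per-gene standardization,
#' then runs the encoder (inference mode: running batch-norm statistics, no
#' dropout) to the bottleneck layer. A pure function of its inputs.
#'
#' @param model A `sigreverse_autoencoder`.
#' @param tpm Gene x sample TPM matrix over the training gene index.
#' @return Samples x `n_encoded` embedding matrix, rownames = sample ids.
#' @export
encode_samples <- function(model, tpm) {
  missing <- setdiff(model$genes, rownames(tpm))
  if (length(missing) > 0) {
    abort(sprintf("matrix is missing %d training gene(s): %s",
                  length(missing), paste(head(missing, 5), collapse = ", ")))
  }
  tpm <- tpm[model$genes, , drop = FALSE]
  if (ncol(tpm) == 0) {
    return(matrix(numeric(), nrow = 0, ncol = model$config$n_encoded,
                  dimnames = list(NULL, NULL)))
  }
  x <- sweep(sweep(t(log2_tpm(tpm)), 2, model$center), 2, model$scale, "/")
  emb <- ae_forward(model$layers, x, training = FALSE, upto = model$n_code)$out
  rownames(emb) <- colnames(tpm)
  emb
}

#' @export
print.sigreverse_autoencoder <- function(x, ...) {
  dims <- vapply(x$layers, function(l) ncol(l$w), integer(1))
  cat(sprintf("autoencoder: %d genes -> %s (bottleneck %d)\n",
              length(x$genes), paste(dims, collapse = " -> "),
              x$config$n_encoded))
  cat(sprintf("reconstruction MSE (log2 TPM+1): %.4f (init) -> %.4f\n",
              x$loss_init, x$loss_final))
  invisible(x)
}

#' @rdname train_autoencoder
#' @param x A `sigreverse_autoencoder`.
#' @param ... Unused.
#' @export
glance.sigreverse_autoencoder <- function(x, ...) {
  tibble(n_genes = length(x$genes), n_encoded = x$config$n_encoded,
         epochs = x$config$epochs, loss_init = x$loss_init,
         loss_final = x$loss_final)
}

#' @rdname train_autoencoder
#' @export
tidy.sigreverse_autoencoder <- function(x, ...) {
  tibble(layer = seq_along(x$layers),
         n_in = vapply(x$layers, function(l) nrow(l$w), integer(1)),
         n_out = vapply(x$layers, function(l) ncol(l$w), integer(1)),
         type = ifelse(vapply(x$layers, `[[`, logical(1), "hidden"),
                       "hidden", "linear"))
}

#' Select surrogate normal controls by embedding correlation
#'
#' For each normal sample, computes the Pearson (or Spearman) correlation of
#' its embedding with every disease sample's embedding, aggregates across
#' disease samples by the median, and returns the top `k` normals by
#' aggregated correlation (descending, ties broken by sample id).
#'
#' @param disease_emb,normal_emb Embedding matrices (samples x n_encoded)
#'   from [encode_samples()], sharing the feature dimension.
#' @param k Number of controls to select (default 100).
#' @param method Correlation method: "pearson" (default) or "spearman".
#' @return Tibble: sample_id, correlation — sorted non-increasing.
#' @export
select_controls <- function(disease_emb, normal_emb, k = 100,
                            method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (ncol(disease_emb) != ncol(normal_emb)) {
    abort("embeddings must share the encoded dimension")
  }
  if (k > nrow(normal_emb)) {
    abort(sprintf("k (%d) exceeds available normal samples (%d)", k,
                  nrow(normal_emb)))
  }
  cors <- cor(t(normal_emb), t(disease_emb), method = method)
  agg <- unname(apply(cors, 1, median))
  out <- tibble(sample_id = rownames(normal_emb), correlation = agg) |>
    arrange(desc(.data$correlation), .data$sample_id)
  head(out, k)
}
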