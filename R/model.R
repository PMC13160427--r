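# The disentangling network: one classifier encoder per factor, a residual
# encoder, learned per-category code embeddings, and a shared decoder that
# reconstructs expression from the concatenated factor codes and the (noised)
# residual.

#' Model configuration
#'
#' @param spec A [factor_spec()] defining factors, code dimensions and the
#'   residual dimension.
#' @param encoder_hidden Hidden layer sizes of every factor / residual encoder.
#' @param decoder_hidden Hidden layer sizes of the decoder.
#' @param reconstruction `"mse"` (expects a lognorm layer) or `"nb"` (expects
#'   raw counts; the decoder emits per-gene negative binomial means and a
#'   learned per-gene dispersion, both softplus-positive).
#' @param seed Integer seed for weight initialization.
#' @return An object of class `scd_model_config`.
#' @export
model_config <- function(spec, encoder_hidden = c(128L, 64L),
                         decoder_hidden = c(64L, 128L),
                         reconstruction = c("mse", "nb"), seed = 0L) {
  stopifnot(inherits(spec, "factor_spec"))
  reconstruction <- match.arg(reconstruction)
  structure(list(spec = spec,
                 encoder_hidden = as.integer(encoder_hidden),
                 decoder_hidden = as.integer(decoder_hidden),
                 reconstruction = reconstruction, seed = as.integer(seed)),
            class = "scd_model_config")
}

#' Initialize an untrained model
#'
#' @param config A [model_config()].
#' @param n_genes Number of genes the model consumes and reconstructs.
#' @return An object of class `scd_model` holding the parameter tree and
#'   architecture metadata.
#' @export
scd_model <- function(config, n_genes) {
  stopifnot(inherits(config, "scd_model_config"))
  spec <- config$spec
  d <- as.integer(n_genes)
  K <- n_categories(spec)
  with_seed(config$seed, {
    enc <- lapply(seq_along(K), function(j)
      nn_init(c(d, config$encoder_hidden, K[j])))
    names(enc) <- names(spec$factors)
    res <- nn_init(c(d, config$encoder_hidden, spec$residual_dim))
    emb <- lapply(seq_along(K), function(j) {
      lim <- sqrt(6 / (K[j] + spec$code_dims[j]))
      matrix(stats::runif(K[j] * spec$code_dims[j], -lim, lim),
             K[j], spec$code_dims[j])
    })
    names(emb) <- names(spec$factors)
    latent_dim <- sum(spec$code_dims) + spec$residual_dim
    dec <- nn_init(c(latent_dim, config$decoder_hidden, d))
    par <- list(enc = enc, res = res, emb = emb, dec = dec)
    if (config$reconstruction == "nb") par$theta <- numeric(d)  # softplus(0)
    structure(list(par = par, config = config, spec = spec, n_genes = d),
              class = "scd_model")
  })
}

#' @export
print.scd_model <- function(x, ...) {
  cat(sprintf("scd_model: %d genes -> %d factors + residual(%d), %s reconstruction\n",
              x$n_genes, length(x$spec$factors), x$spec$residual_dim,
              x$config$reconstruction))
  invisible(x)
}

# The encoders always consume log-scale input: raw counts are log1p'ed.
encoder_input <- function(model, ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (ncol(ds$matrix) != model$n_genes)
    stop("gene-space mismatch: dataset has ", ncol(ds$matrix),
         " genes, model expects ", model$n_genes)
  if (ds$layer == "raw_counts") log1p(ds$matrix) else ds$matrix
}

#' Encode cells into factor logits, probabilities and a residual
#'
#' Runs every factor encoder and the residual encoder. In training mode the
#' residual additionally carries standard Gaussian noise
#' (`residual_noised`); in eval mode encoding is a pure deterministic
#' function of the input.
#'
#' @param model An [scd_model()].
#' @param ds An [expression_dataset()] on the model's gene space (raw counts
#'   are log1p-transformed before encoding).
#' @param training Populate `residual_noised` with noise-injected residuals.
#' @return A list of class `latent_code`: `logits` and `probs` (per-factor
#'   cells x categories matrices), `residual`, and `residual_noised`
#'   (training mode only).
#' @export
encode <- function(model, ds, training = FALSE) {
  stopifnot(inherits(model, "scd_model"))
  X <- encoder_input(model, ds)
  logits <- lapply(model$par$enc, function(net) nn_output(net, X))
  probs <- lapply(logits, row_softmax)
  residual <- nn_output(model$par$res, X)
  structure(list(logits = logits, probs = probs, residual = residual,
                 residual_noised = if (training)
                   inject_noise(residual, training = TRUE) else NULL),
            class = "latent_code")
}

#' Compose a factor code from probabilities or a hard label
#'
#' The decoder receives, per factor, a probability-weighted sum of learned
#' per-category embedding rows. When the true label is known it replaces the
#' predicted distribution with a one-hot weighting (i.e. the embedding row of
#' the label); otherwise the softmax prediction weights the rows.
#'
#' @param probs Probability vector over the factor's categories (simplex).
#' @param label Integer 0-based category, or `NA`/`NULL` when unknown.
#' @param embedding categories x code_dim embedding matrix.
#' @return A code vector of length `code_dim`.
#' @export
compose_factor_code <- function(probs, label, embedding) {
  K <- nrow(embedding)
  if (!is.null(label) && !is.na(label) && label >= 0) {
    if (label >= K) stop("label out of range")
    return(as.numeric(embedding[label + 1L, ]))
  }
  if (length(probs) != K) stop("probs length must match embedding rows")
  as.numeric(crossprod(embedding, probs))
}

# Matrix version used internally: probs (n x K), labels (n, -1 = missing).
compose_codes_matrix <- function(probs, labels, embedding) {
  w <- probs
  lab <- !is.na(labels) & labels >= 0
  if (any(lab)) {
    w[lab, ] <- 0
    w[cbind(which(lab), labels[lab] + 1L)] <- 1
  }
  w %*% embedding
}

#' Inject standard Gaussian noise into the residual
#'
#' Training-time regularization: `r' = r + eps`, `eps ~ N(0, I)`. In eval mode
#' the residual is returned unchanged.
#'
#' @param residual Numeric vector or cells x residual_dim matrix.
#' @param training Apply noise (TRUE) or pass through (FALSE).
#' @return Same shape as `residual`.
#' @export
inject_noise <- function(residual, training = FALSE) {
  if (!training) return(residual)
  residual + stats::rnorm(length(residual))
}

#' Decode factor codes and a residual into an expression reconstruction
#'
#' Concatenates all factor code blocks with the residual and runs the decoder
#' network. In `"mse"` mode the output is the predicted lognorm profile; in
#' `"nb"` mode it is a list with strictly positive per-gene negative binomial
#' `mean` and `dispersion` (softplus-bounded).
#'
#' @param model An [scd_model()].
#' @param codes List of per-factor code matrices (cells x code_dim), in spec
#'   order, or a single pre-concatenated matrix.
#' @param residual cells x residual_dim matrix.
#' @return cells x genes matrix (`mse`) or `list(mean, dispersion)` (`nb`).
#' @export
decode <- function(model, codes, residual) {
  stopifnot(inherits(model, "scd_model"))
  if (is.list(codes)) codes <- do.call(cbind, lapply(codes, rbind))
  codes <- rbind(codes)  # promote a vector to one row
  residual <- rbind(residual)
  Z <- cbind(codes, residual)
  if (ncol(Z) != sum(model$spec$code_dims) + model$spec$residual_dim)
    stop("latent dimension mismatch")
  O <- nn_output(model$par$dec, Z)
  if (model$config$reconstruction == "mse") return(O)
  list(mean = softplus(O) + 1e-8,
       dispersion = softplus(model$par$theta) + 1e-8)
}

#' Save / load a trained model
#'
#' The checkpoint is a single self-describing archive holding the parameter
#' tree, the model configuration and the factor specification; loading
#' validates the embedded spec before the model is used for inference.
#'
#' @param model An [scd_model()].
#' @param path Checkpoint file path.
#' @return `path` (save) or the restored [scd_model()] (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "scd_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @param expect_spec Optional [factor_spec()]; loading fails if the
#'   checkpointed spec differs.
#' @export
load_model <- function(path, expect_spec = NULL) {
  model <- readRDS(path)
  if (!inherits(model, "scd_model")) stop("not a model checkpoint: ", path)
  if (!is.null(expect_spec) && !identical(unclass(model$spec),
                                          unclass(expect_spec)))
    stop("checkpoint factor specification does not match the expected spec")
  model
}
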