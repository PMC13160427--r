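# The four training objectives and their weighted sum.
#
# All terms are per-(cell, factor)-pair or per-cell MEANS rather than sums,
# so the weighting hyperparameters are independent of dataset size; this is a
# positive rescaling of the summed objective with identical minimizers for a
# fixed label mask. Entropies and cross-entropies are in nats.

#' Semi-supervised classification loss
#'
#' Mean, over labeled (cell, factor) pairs, of the cross-entropy between each
#' factor encoder's softmax prediction and the true category. Unlabeled pairs
#' do not contribute; with no labeled pair at all the loss is 0.
#'
#' @param logits List of per-factor cells x categories logit matrices.
#' @param labels A [label_table()] (or plain integer matrix with -1
#'   sentinels) aligned with `logits`.
#' @return Non-negative scalar (nats).
#' @export
classification_loss <- function(logits, labels) {
  lt <- as_labels(labels)
  total <- 0
  npairs <- 0L
  for (j in seq_along(logits)) {
    lab <- lt$labels[, j]
    sel <- lt$mask[, j] == 1L
    if (!any(sel)) next
    if (any(lab[sel] >= ncol(logits[[j]])))
      stop("label index exceeds the factor's category count")
    p <- row_softmax(logits[[j]][sel, , drop = FALSE])
    total <- total - sum(log(pmax(
      p[cbind(seq_len(sum(sel)), lab[sel] + 1L)], 1e-300)))
    npairs <- npairs + sum(sel)
  }
  if (npairs == 0L) 0 else total / npairs
}

#' Entropy regularization on unlabeled predictions
#'
#' Mean, over unlabeled (cell, factor) pairs, of the Shannon entropy (nats)
#' of the encoder's softmax prediction. Driving this term down pushes
#' unlabeled predictions toward confident, near-one-hot distributions. 0 when
#' every pair is labeled.
#'
#' @param logits List of per-factor cells x categories logit matrices.
#' @param mask cells x factors availability matrix (1 = labeled).
#' @return Scalar in `[0, log(max categories)]`.
#' @export
entropy_loss <- function(logits, mask) {
  mask <- as_mask(mask)
  total <- 0
  npairs <- 0L
  for (j in seq_along(logits)) {
    sel <- mask[, j] == 0L
    if (!any(sel)) next
    p <- row_softmax(logits[[j]][sel, , drop = FALSE])
    pl <- p * log(pmax(p, 1e-300))
    total <- total - sum(pl)
    npairs <- npairs + sum(sel)
  }
  if (npairs == 0L) 0 else total / npairs
}

#' Residual magnitude penalty
#'
#' Mean over cells of the squared l2 norm of the residual latent vector,
#' keeping the residual compact so named factors are not under-used.
#'
#' @param residuals cells x residual_dim matrix (or a single vector).
#' @return Non-negative scalar.
#' @export
residual_loss <- function(residuals) {
  residuals <- rbind(residuals)
  mean(rowSums(residuals^2))
}

#' Negative binomial negative log-likelihood
#'
#' Parameterized by mean `mu` and dispersion `theta` (variance
#' `mu + mu^2 / theta`). Vectorized with recycling.
#'
#' @param x Non-negative integer counts.
#' @param mu Positive means.
#' @param theta Positive dispersions.
#' @return Element-wise negative log-likelihood.
#' @export
nb_nll <- function(x, mu, theta) {
  if (!is_wholenumber(x) || any(x < 0))
    stop("negative binomial likelihood requires non-negative integer counts")
  -stats::dnbinom(x, size = theta, mu = mu, log = TRUE)
}

#' Reconstruction loss
#'
#' `"mse"`: mean over cells of the mean-over-genes squared error between the
#' decoded and observed lognorm profiles. `"nb"`: mean over cells and genes
#' of the negative binomial negative log-likelihood of the observed counts
#' under the decoder's mean and dispersion.
#'
#' @param x Observed cells x genes matrix (lognorm for mse, counts for nb).
#' @param xhat Decoder output: a matrix (mse) or `list(mean, dispersion)`
#'   (nb; `dispersion` may be a per-gene vector).
#' @param mode `"mse"` or `"nb"`.
#' @return Scalar loss.
#' @export
reconstruction_loss <- function(x, xhat, mode = c("mse", "nb")) {
  mode <- match.arg(mode)
  x <- rbind(x)
  if (mode == "mse") {
    xhat <- rbind(xhat)
    if (!identical(dim(x), dim(xhat))) stop("dimension mismatch")
    return(mean((x - xhat)^2))
  }
  mu <- rbind(xhat$mean)
  theta <- xhat$dispersion
  if (!identical(dim(x), dim(mu))) stop("dimension mismatch")
  if (is.null(dim(theta))) theta <- rep(theta, each = nrow(mu))
  mean(nb_nll(x, mu, theta))
}

#' Weighted total loss
#'
#' `total = cls + lambda1 * ent + lambda2 * res + lambda3 * rec`, with every
#' component reported alongside the weighted sum.
#'
#' @param cls,ent,res,rec The four component losses (mean-scaled).
#' @param lambda1,lambda2,lambda3 Non-negative weights of the entropy,
#'   residual and reconstruction terms.
#' @return A list of class `loss_breakdown` with fields `cls`, `ent`, `res`,
#'   `rec`, `total`.
#' @export
total_loss <- function(cls, ent, res, rec, lambda1, lambda2, lambda3) {
  if (any(c(lambda1, lambda2, lambda3) < 0))
    stop("loss weights must be non-negative")
  structure(list(cls = cls, ent = ent, res = res, rec = rec,
                 total = cls + lambda1 * ent + lambda2 * res + lambda3 * rec),
            class = "loss_breakdown")
}

# Accept a label_table or a bare labels matrix with -1 sentinels.
as_labels <- function(x) {
  if (inherits(x, "label_table")) return(x)
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  list(labels = x, mask = (x >= 0L) * 1L)
}

# Accept a label_table or a bare binary availability matrix.
as_mask <- function(x) {
  if (inherits(x, "label_table")) return(x$mask)
  x <- as.matrix(x)
  if (!all(x %in% c(0, 1))) stop("mask must be binary")
  x
}
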