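# Semi-supervised mini-batch training, prediction, and latent extraction.

#' Training configuration
#'
#' Defaults: Adam with learning rate 1e-3, batch size 128, 200 epochs, and
#' loss weights lambda1 = 0.5 (entropy), lambda2 = 0.01 (residual),
#' lambda3 = 1 (reconstruction) on the mean-scaled objectives, which balances
#' the four terms to the same order of magnitude on the bundled simulation.
#'
#' @param epochs Number of passes over the data.
#' @param batch_size Mini-batch size (must not exceed the cell count).
#' @param learning_rate Adam step size.
#' @param lambda1,lambda2,lambda3 Non-negative weights of the entropy,
#'   residual and reconstruction losses.
#' @param seed Integer seed driving shuffling and residual noise.
#' @param early_stop_patience Stop after this many epochs without improvement
#'   of the total loss; 0 (default) disables early stopping so runs are
#'   fully length-deterministic.
#' @return An object of class `scd_train_config`.
#' @export
train_config <- function(epochs = 200L, batch_size = 128L,
                         learning_rate = 1e-3, lambda1 = 0.5,
                         lambda2 = 0.01, lambda3 = 1.0, seed = 0L,
                         early_stop_patience = 0L) {
  if (any(c(lambda1, lambda2, lambda3) < 0))
    stop("loss weights must be non-negative")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, lambda1 = lambda1,
                 lambda2 = lambda2, lambda3 = lambda3,
                 seed = as.integer(seed),
                 early_stop_patience = as.integer(early_stop_patience)),
            class = "scd_train_config")
}

# One mini-batch forward/backward pass. Returns the gradient tree (mirroring
# model$par), the component losses, and the pair counts used for averaging.
train_step <- function(model, Xb, Tb, labb, maskb, tcfg) {
  par <- model$par
  spec <- model$spec
  kf <- length(spec$factors)
  cdims <- spec$code_dims
  rdim <- spec$residual_dim
  B <- nrow(Xb)
  d <- model$n_genes

  encH <- lapply(par$enc, function(net) nn_forward(net, Xb))
  logits <- lapply(encH, function(H) H[[length(H)]])
  probs <- lapply(logits, row_softmax)

  w <- vector("list", kf)
  for (j in seq_len(kf)) {
    wj <- probs[[j]]
    sel <- maskb[, j] == 1L
    if (any(sel)) {
      wj[sel, ] <- 0
      wj[cbind(which(sel), labb[sel, j] + 1L)] <- 1
    }
    w[[j]] <- wj
  }
  C <- mapply(function(wj, ej) wj %*% ej, w, par$emb, SIMPLIFY = FALSE)

  resH <- nn_forward(par$res, Xb)
  r <- resH[[length(resH)]]
  noise <- matrix(stats::rnorm(B * rdim), B, rdim)
  rp <- r + noise

  Z <- cbind(do.call(cbind, C), rp)
  decH <- nn_forward(par$dec, Z)
  O <- decH[[length(decH)]]

  # component losses ---------------------------------------------------
  n_lab <- sum(maskb == 1L)
  n_unl <- length(maskb) - n_lab
  cls <- 0
  ent <- 0
  H_ent <- vector("list", kf)
  for (j in seq_len(kf)) {
    p <- probs[[j]]
    lp <- log(pmax(p, 1e-300))
    sel <- maskb[, j] == 1L
    if (any(sel))
      cls <- cls - sum(lp[cbind(which(sel), labb[sel, j] + 1L)])
    Hrow <- -rowSums(p * lp)
    H_ent[[j]] <- Hrow
    if (any(!sel)) ent <- ent + sum(Hrow[!sel])
  }
  if (n_lab > 0L) cls <- cls / n_lab
  if (n_unl > 0L) ent <- ent / n_unl
  res <- mean(rowSums(r^2))

  if (model$config$reconstruction == "mse") {
    rec <- mean((O - Tb)^2)
    dO <- tcfg$lambda3 * 2 * (O - Tb) / (B * d)
    gtheta <- NULL
  } else {
    theta <- rep(softplus(par$theta) + 1e-8, each = B)
    mu <- softplus(O) + 1e-8
    rec <- mean(nb_nll(Tb, mu, theta))
    dmu <- ((theta + Tb) / (theta + mu) - Tb / mu) / (B * d)
    dO <- tcfg$lambda3 * dmu * sigmoid(O)
    dtheta <- -(digamma(Tb + theta) - digamma(theta) + log(theta) + 1 -
                  log(theta + mu) - (theta + Tb) / (theta + mu)) / (B * d)
    gtheta <- unname(tcfg$lambda3 * colSums(dtheta) * sigmoid(par$theta))
  }

  # backward ------------------------------------------------------------
  decb <- nn_backward(par$dec, decH, dO)
  dZ <- decb$dX
  offs <- c(0L, cumsum(cdims))
  genc <- vector("list", kf)
  gemb <- vector("list", kf)
  for (j in seq_len(kf)) {
    dC <- dZ[, (offs[j] + 1L):offs[j + 1L], drop = FALSE]
    gemb[[j]] <- crossprod(w[[j]], dC)
    dw <- tcrossprod(dC, par$emb[[j]])
    sel <- maskb[, j] == 1L
    if (any(sel)) dw[sel, ] <- 0  # hard labels block decoder gradients
    p <- probs[[j]]
    dz <- p * (dw - rowSums(dw * p))
    if (n_lab > 0L && any(sel)) {
      y <- matrix(0, sum(sel), ncol(p))
      y[cbind(seq_len(sum(sel)), labb[sel, j] + 1L)] <- 1
      dz[sel, ] <- dz[sel, ] + (p[sel, , drop = FALSE] - y) / n_lab
    }
    if (n_unl > 0L && any(!sel)) {
      pu <- p[!sel, , drop = FALSE]
      lpu <- log(pmax(pu, 1e-300))
      dz[!sel, ] <- dz[!sel, ] - tcfg$lambda1 *
        pu * (lpu + H_ent[[j]][!sel]) / n_unl
    }
    genc[[j]] <- nn_backward(par$enc[[j]], encH[[j]], dz)[c("W", "b")]
  }
  names(genc) <- names(par$enc)
  names(gemb) <- names(par$emb)

  drp <- dZ[, (offs[kf + 1L] + 1L):ncol(dZ), drop = FALSE]
  dr <- drp + tcfg$lambda2 * 2 * r / B
  gres <- nn_backward(par$res, resH, dr)[c("W", "b")]

  grads <- list(enc = genc, res = gres, emb = gemb,
                dec = decb[c("W", "b")])
  if (!is.null(gtheta)) grads$theta <- gtheta

  list(grads = grads,
       parts = c(cls = cls, ent = ent, res = res, rec = rec),
       counts = c(lab = n_lab, unl = n_unl, cells = B))
}

#' Fit the semi-supervised disentangling model
#'
#' Minimizes the weighted objective (classification + entropy + residual +
#' reconstruction) by mini-batch Adam. Labeled and unlabeled cells are mixed
#' in every shuffled batch; residual noise injection is active throughout
#' training. Fully reproducible given the model and training seeds.
#'
#' @param ds An [expression_dataset()]; its layer must match the model's
#'   reconstruction mode (`lognorm` for mse, `raw_counts` for nb).
#' @param labels A [label_table()] with the (partially) observed labels.
#' @param model_cfg A [model_config()]; defaults to `model_config(spec)`.
#' @param train_cfg A [train_config()].
#' @param spec A [factor_spec()]; defaults to `model_cfg$spec`.
#' @param verbose Print the loss breakdown every 10 epochs.
#' @return An object of class `scd_fit`: `model` (trained [scd_model()]),
#'   `history` (one [total_loss()] breakdown row per epoch), and the configs.
#' @export
scd_fit <- function(ds, labels, model_cfg = NULL, train_cfg = train_config(),
                    spec = NULL, verbose = FALSE) {
  stopifnot(inherits(ds, "expression_dataset"),
            inherits(labels, "label_table"))
  if (is.null(model_cfg)) {
    if (is.null(spec)) stop("provide model_cfg or spec")
    model_cfg <- model_config(spec)
  }
  spec <- model_cfg$spec
  need <- if (model_cfg$reconstruction == "mse") "lognorm" else "raw_counts"
  if (ds$layer != need)
    stop(sprintf("%s reconstruction requires a %s layer (got %s)",
                 model_cfg$reconstruction, need, ds$layer))
  n <- nrow(ds$matrix)
  if (train_cfg$batch_size > n) stop("batch_size exceeds the cell count")
  if (ncol(labels$labels) != length(spec$factors))
    stop("label table and factor spec disagree on the factor count")

  K <- n_categories(spec)
  for (j in seq_along(K)) {
    seen <- unique(labels$labels[labels$mask[, j] == 1L, j])
    absent <- setdiff(0:(K[j] - 1L), seen)
    if (length(absent))
      warning(sprintf(
        "factor '%s': categor%s %s ha%s no labeled cell and cannot receive supervised signal",
        names(spec$factors)[j], if (length(absent) > 1) "ies" else "y",
        paste(absent, collapse = ","), if (length(absent) > 1) "ve" else "s"),
        call. = FALSE)
  }

  model <- scd_model(model_cfg, ncol(ds$matrix))
  X <- encoder_input(model, ds)
  Tmat <- if (model_cfg$reconstruction == "mse") ds$matrix else ds$matrix
  lab <- labels$labels
  msk <- labels$mask

  history <- vector("list", train_cfg$epochs)
  best <- Inf
  stale <- 0L
  model$par <- with_seed(train_cfg$seed, {
    par <- model$par
    st <- adam_init(par)
    for (ep in seq_len(train_cfg$epochs)) {
      perm <- sample.int(n)
      sums <- c(cls = 0, ent = 0, res = 0, rec = 0)
      cnts <- c(lab = 0, unl = 0, cells = 0)
      for (b0 in seq(1L, n, by = train_cfg$batch_size)) {
        idx <- perm[b0:min(b0 + train_cfg$batch_size - 1L, n)]
        model$par <- par
        stp <- train_step(model, X[idx, , drop = FALSE],
                          Tmat[idx, , drop = FALSE],
                          lab[idx, , drop = FALSE],
                          msk[idx, , drop = FALSE], train_cfg)
        upd <- adam_step(par, stp$grads, st, train_cfg$learning_rate)
        par <- upd$par
        st <- upd$state
        wgt <- c(stp$counts[["lab"]], stp$counts[["unl"]],
                 stp$counts[["cells"]], stp$counts[["cells"]])
        sums <- sums + stp$parts * wgt[c(1, 2, 3, 4)]
        cnts <- cnts + stp$counts
      }
      parts <- c(
        cls = if (cnts[["lab"]] > 0) sums[["cls"]] / cnts[["lab"]] else 0,
        ent = if (cnts[["unl"]] > 0) sums[["ent"]] / cnts[["unl"]] else 0,
        res = sums[["res"]] / cnts[["cells"]],
        rec = sums[["rec"]] / cnts[["cells"]])
      lb <- total_loss(parts[["cls"]], parts[["ent"]], parts[["res"]],
                       parts[["rec"]], train_cfg$lambda1, train_cfg$lambda2,
                       train_cfg$lambda3)
      history[[ep]] <- lb
      if (verbose && (ep %% 10L == 0L || ep == 1L))
        message(sprintf(
          "epoch %3d  cls %.4f  ent %.4f  res %.4f  rec %.4f  total %.4f",
          ep, lb$cls, lb$ent, lb$res, lb$rec, lb$total))
      if (train_cfg$early_stop_patience > 0L) {
        if (lb$total < best - 1e-8) {
          best <- lb$total
          stale <- 0L
        } else {
          stale <- stale + 1L
          if (stale >= train_cfg$early_stop_patience) break
        }
      }
    }
    par
  })

  history <- history[!vapply(history, is.null, TRUE)]
  hist_df <- do.call(rbind, lapply(seq_along(history), function(i)
    data.frame(epoch = i, cls = history[[i]]$cls, ent = history[[i]]$ent,
               res = history[[i]]$res, rec = history[[i]]$rec,
               total = history[[i]]$total)))
  structure(list(model = model, history = hist_df,
                 model_config = model_cfg, train_config = train_cfg),
            class = "scd_fit")
}

#' @export
print.scd_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("scd_fit: %d epochs, final total loss %.4f (cls %.4f, ent %.4f, res %.4f, rec %.4f)\n",
              nrow(h), h$total[nrow(h)], h$cls[nrow(h)], h$ent[nrow(h)],
              h$res[nrow(h)], h$rec[nrow(h)]))
  invisible(x)
}

#' Predict factor labels for every cell
#'
#' Per cell and factor, the argmax of the encoder's softmax prediction; exact
#' ties resolve to the lowest category index.
#'
#' @param model An [scd_model()] or [scd_fit()].
#' @param ds An [expression_dataset()] on the model's gene space.
#' @return A fully observed [label_table()] of predictions.
#' @export
predict_factors <- function(model, ds) {
  if (inherits(model, "scd_fit")) model <- model$model
  code <- encode(model, ds, training = FALSE)
  pred <- vapply(code$logits, function(z)
    max.col(z, ties.method = "first") - 1L, integer(nrow(ds$matrix)))
  pred <- matrix(as.integer(pred), nrow = nrow(ds$matrix),
                 dimnames = list(ds$cell_ids, names(model$spec$factors)))
  label_table(pred, factor_names = names(model$spec$factors),
              cell_ids = ds$cell_ids, n_cats = n_categories(model$spec))
}

#' Extract the disentangled latent matrix
#'
#' Concatenates the composed factor code blocks and the residual (noise off)
#' into an n x (sum of code dims + residual dim) matrix, together with a
#' column map naming which factor owns which columns. When `use_labels` is
#' given, cells with an available label compose their code from the hard
#' label instead of the softmax prediction.
#'
#' @param model An [scd_model()] or [scd_fit()].
#' @param ds An [expression_dataset()].
#' @param use_labels Optional [label_table()]; masked-available entries use
#'   the true label in the code composition.
#' @return `list(latent, column_map)`: `latent` has named columns, and
#'   `column_map` maps each factor name (plus `"residual"`) to its column
#'   indices.
#' @export
extract_latent <- function(model, ds, use_labels = NULL) {
  if (inherits(model, "scd_fit")) model <- model$model
  code <- encode(model, ds, training = FALSE)
  spec <- model$spec
  n <- nrow(ds$matrix)
  lab <- if (is.null(use_labels)) NULL else {
    stopifnot(inherits(use_labels, "label_table"))
    l <- use_labels$labels
    l[use_labels$mask == 0L] <- -1L
    l
  }
  blocks <- lapply(seq_along(spec$factors), function(j)
    compose_codes_matrix(code$probs[[j]],
                         if (is.null(lab)) rep(-1L, n) else lab[, j],
                         model$par$emb[[j]]))
  latent <- cbind(do.call(cbind, blocks), code$residual)
  nms <- unlist(c(
    lapply(names(spec$factors), function(f)
      paste0(f, "_", seq_len(spec$code_dims[[f]]))),
    list(paste0("residual_", seq_len(spec$residual_dim)))))
  colnames(latent) <- nms
  rownames(latent) <- ds$cell_ids
  offs <- c(0L, cumsum(spec$code_dims))
  column_map <- stats::setNames(
    lapply(seq_along(spec$factors), function(j)
      (offs[j] + 1L):offs[j + 1L]),
    names(spec$factors))
  column_map$residual <- (offs[length(offs)] + 1L):ncol(latent)
  list(latent = latent, column_map = column_map)
}
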