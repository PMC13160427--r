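# Classification, clustering, and disentanglement evaluation.

#' Macro-averaged F1 score
#'
#' Unweighted mean over categories of the per-category F1 (harmonic mean of
#' precision and recall). Categories absent from both vectors are excluded; a
#' category with no true or predicted positives at all contributes 0.
#'
#' @param true,pred Equal-length label vectors (integer, character or factor).
#' @return Scalar in [0, 1].
#' @export
macro_f1 <- function(true, pred) {
  if (length(true) == 0L) stop("empty input")
  if (length(true) != length(pred)) stop("length mismatch")
  cats <- sort(unique(c(true, pred)))
  f1 <- vapply(cats, function(cl) {
    tp <- sum(true == cl & pred == cl)
    fp <- sum(true != cl & pred == cl)
    fn <- sum(true == cl & pred != cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, 1.0)
  mean(f1)
}

#' Adjusted Rand index
#'
#' Chance-corrected pair-counting agreement between two partitions, from the
#' closed form on the contingency table. Identical labelings (up to category
#' renaming) score 1. When the chance-correction denominator vanishes -- both
#' partitions a single cluster, or both all singletons -- the partitions are
#' identical and the index is defined as 1.
#'
#' @param a,b Equal-length label vectors.
#' @return Scalar, at most 1; 0 expected under random agreement.
#' @export
ari <- function(a, b) {
  if (length(a) == 0L) stop("empty input")
  if (length(a) != length(b)) stop("length mismatch")
  tab <- table(a, b)
  n <- length(a)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  exp_ <- sa * sb / choose(n, 2)
  denom <- (sa + sb) / 2 - exp_
  if (denom == 0) return(1)
  (sij - exp_) / denom
}

#' Spearman correlation between latent dimensions and factors
#'
#' For every (latent dimension, factor) pair, Spearman's rho between the
#' dimension's values and the integer-coded factor labels. Integer coding
#' makes multi-class correlations order-dependent, so a second matrix is
#' returned holding, per pair, the maximum absolute rho over one-vs-rest
#' binary indicators of the factor's categories -- the recommended summary
#' for factors with more than two categories. Constant latent dimensions get
#' rho = 0 (with a message).
#'
#' @param latent n x D latent matrix.
#' @param labels Fully observed [label_table()] (or integer label matrix).
#' @return `list(rho, rho_ovr)`, both D x factors matrices.
#' @export
spearman_matrix <- function(latent, labels) {
  lab <- as_labels(labels)$labels
  latent <- as.matrix(latent)
  const <- apply(latent, 2, function(x) stats::sd(x) == 0)
  if (any(const))
    message(sum(const), " constant latent dimension(s); rho set to 0")
  rho <- suppressWarnings(
    stats::cor(latent, lab, method = "spearman"))
  rho[is.na(rho)] <- 0
  rho_ovr <- matrix(0, ncol(latent), ncol(lab), dimnames = dimnames(rho))
  for (k in seq_len(ncol(lab))) {
    cats <- sort(unique(lab[, k]))
    for (cl in cats) {
      r <- suppressWarnings(
        stats::cor(latent, (lab[, k] == cl) * 1, method = "spearman"))
      r[is.na(r)] <- 0
      rho_ovr[, k] <- pmax(rho_ovr[, k], abs(r))
    }
  }
  list(rho = rho, rho_ovr = rho_ovr)
}

# Quantile-bin a continuous vector into at most n_bins levels (scale-free).
# Vectors that are already discrete (few unique values) keep their values as
# categories; quantile cuts on such vectors can merge or drop levels.
quantile_bin <- function(x, n_bins) {
  u <- sort(unique(x))
  if (length(u) <= n_bins) return(match(x, u))
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 2L) return(rep(1L, length(x)))
  br[1] <- -Inf
  br[length(br)] <- Inf
  as.integer(cut(x, br))
}

# Empirical mutual information (nats) between two discrete vectors.
discrete_mi <- function(a, b) {
  tab <- table(a, b) / length(a)
  pa <- rowSums(tab)
  pb <- colSums(tab)
  idx <- tab > 0
  sum(tab[idx] * log(tab[idx] / outer(pa, pb)[idx]))
}

#' Mutual information gap
#'
#' Every latent dimension is discretized by quantile binning; for each factor
#' the mutual information with every dimension is estimated from the
#' empirical joint, and the gap between the two most informative dimensions,
#' normalized by the factor's entropy, is averaged over factors and clamped
#' to [0, 1]. Factors with a single category are excluded with a warning.
#'
#' @param latent n x D latent matrix (D >= 2).
#' @param labels Fully observed [label_table()] or integer label matrix.
#' @param n_bins Number of quantile bins per dimension (default 20).
#' @return Scalar in [0, 1].
#' @export
mig <- function(latent, labels, n_bins = 20L) {
  latent <- as.matrix(latent)
  if (ncol(latent) < 2L) stop("mig needs at least 2 latent dimensions")
  lab <- as_labels(labels)$labels
  bins <- apply(latent, 2, quantile_bin, n_bins = n_bins)
  gaps <- c()
  for (k in seq_len(ncol(lab))) {
    v <- lab[, k]
    Hv <- shannon_entropy(table(v) / length(v))
    if (Hv == 0) {
      warning("factor ", k, " has a single category; excluded from MIG")
      next
    }
    mi <- apply(bins, 2, discrete_mi, b = v)
    top <- sort(mi, decreasing = TRUE)[1:2]
    gaps <- c(gaps, (top[1] - top[2]) / Hv)
  }
  if (!length(gaps)) stop("no usable factor for MIG")
  min(max(mean(gaps), 0), 1)
}

# Best single-threshold stump balanced accuracy for a binary target, max over
# cut points and both orientations. Chance level is 0.5.
stump_bacc <- function(x, y) {
  n1 <- sum(y)
  n0 <- length(y) - n1
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  o <- order(x)
  xs <- x[o]
  ys <- y[o]
  cum1 <- cumsum(ys)
  cum0 <- cumsum(!ys)
  valid <- xs[-length(xs)] < xs[-1]  # cuts only between distinct values
  if (!any(valid)) return(0.5)
  i <- which(valid)
  # predict positive on the right of the cut
  bacc_r <- ((n1 - cum1[i]) / n1 + cum0[i] / n0) / 2
  # predict positive on the left of the cut
  bacc_l <- (cum1[i] / n1 + (n0 - cum0[i]) / n0) / 2
  max(bacc_r, bacc_l, 0.5)
}

#' Attribute predictability score
#'
#' Score `S[j, k]` is the balanced accuracy of the best single-threshold
#' stump predicting factor k from latent dimension j alone (averaged
#' one-vs-rest for multi-class factors). SAP is the mean over factors of the
#' gap between the best and second-best dimension of that factor's score
#' column, so duplicated informative dimensions force the gap to zero.
#'
#' @param latent n x D latent matrix (D >= 2).
#' @param labels Fully observed [label_table()] or integer label matrix.
#' @return Scalar in [0, 1].
#' @export
sap <- function(latent, labels) {
  latent <- as.matrix(latent)
  if (ncol(latent) < 2L) stop("sap needs at least 2 latent dimensions")
  lab <- as_labels(labels)$labels
  S <- matrix(0, ncol(latent), ncol(lab))
  for (k in seq_len(ncol(lab))) {
    cats <- sort(unique(lab[, k]))
    for (j in seq_len(ncol(latent))) {
      vals <- vapply(cats, function(cl)
        stump_bacc(latent[, j], lab[, k] == cl), 1.0)
      S[j, k] <- mean(vals, na.rm = TRUE)
    }
  }
  gaps <- apply(S, 2, function(col) {
    top <- sort(col, decreasing = TRUE)[1:2]
    top[1] - top[2]
  })
  min(max(mean(gaps), 0), 1)
}

#' Disentanglement / completeness from an importance matrix
#'
#' Given a dims x factors importance matrix with columns normalized to sum
#' one: disentanglement is the importance-weighted mean over dimensions of
#' one minus the normalized entropy of the dimension's row (entropy base =
#' number of factors); completeness is the mean over factors of one minus the
#' normalized entropy of the column (base = number of dimensions). An
#' identity matrix scores 1/1, a uniform matrix 0/0; a single-dimension
#' latent has disentanglement defined as 1.
#'
#' @param R dims x factors non-negative importance matrix.
#' @return `list(disentanglement, completeness)`.
#' @export
dci_from_importance <- function(R) {
  R <- as.matrix(R)
  cs <- colSums(R)
  cs[cs == 0] <- 1
  R <- sweep(R, 2, cs, "/")
  D <- nrow(R)
  Kf <- ncol(R)
  dis <- if (Kf <= 1L) 1 else {
    rs <- rowSums(R)
    dj <- vapply(seq_len(D), function(j) {
      if (rs[j] == 0) return(0)
      1 - shannon_entropy(R[j, ] / rs[j]) / log(Kf)
    }, 1.0)
    wj <- if (sum(rs) == 0) rep(1 / D, D) else rs / sum(rs)
    sum(wj * dj)
  }
  comp <- if (D <= 1L) 1 else
    mean(vapply(seq_len(Kf), function(k)
      1 - shannon_entropy(R[, k]) / log(D), 1.0))
  list(disentanglement = dis, completeness = comp)
}

#' DCI: disentanglement, completeness, informativeness
#'
#' Fits one random-forest classifier per factor on a 50/50 train/held-out
#' split of the latent matrix (100 trees, impurity importance, fixed seed).
#' Gini importances form the dims x factors matrix fed to
#' [dci_from_importance()]; informativeness is the mean held-out balanced
#' accuracy over factors.
#'
#' @param latent n x D latent matrix (D >= 2).
#' @param labels Fully observed [label_table()] or integer label matrix.
#' @param n_trees Trees per forest.
#' @param seed Seed for the split and the forests.
#' @return `list(informativeness, disentanglement, completeness, importance)`.
#' @export
dci <- function(latent, labels, n_trees = 100L, seed = 0L) {
  latent <- as.matrix(latent)
  if (ncol(latent) < 2L) stop("dci needs at least 2 latent dimensions")
  lab <- as_labels(labels)$labels
  n <- nrow(latent)
  tr <- with_seed(seed, sample.int(n, floor(n / 2)))
  df <- as.data.frame(latent)
  names(df) <- paste0("z", seq_len(ncol(latent)))
  R <- matrix(0, ncol(latent), ncol(lab))
  info <- numeric(ncol(lab))
  for (k in seq_len(ncol(lab))) {
    dtr <- df[tr, , drop = FALSE]
    dtr$.y <- factor(lab[tr, k])
    rf <- ranger::ranger(stats::as.formula(".y ~ ."), data = dtr,
                         num.trees = n_trees, importance = "impurity",
                         seed = seed, num.threads = 1)
    R[, k] <- rf$variable.importance[names(df)]
    pred <- stats::predict(rf, df[-tr, , drop = FALSE])$predictions
    truth <- factor(lab[-tr, k], levels = levels(dtr$.y))
    recalls <- vapply(levels(dtr$.y), function(cl) {
      sel <- truth == cl
      if (!any(sel)) return(NA_real_)
      mean(pred[sel] == cl)
    }, 1.0)
    info[k] <- mean(recalls, na.rm = TRUE)
  }
  dc <- dci_from_importance(R)
  list(informativeness = mean(info),
       disentanglement = dc$disentanglement,
       completeness = dc$completeness,
       importance = R)
}

#' Optimal block-to-factor alignment score
#'
#' Solves the assignment problem maximizing the total association score over
#' one-to-one pairings of latent blocks (rows) and factors (columns), by
#' exact dynamic programming over factor subsets, and returns the mean
#' matched score. Requires at least as many blocks as factors and score
#' entries in [0, 1].
#'
#' @param score blocks x factors matrix of association scores (for example
#'   per-block maximum absolute Spearman rho, or normalized MI).
#' @return Scalar in [0, 1].
#' @export
hungarian_alignment <- function(score) {
  score <- rbind(score)
  B <- nrow(score)
  Kf <- ncol(score)
  if (Kf > B) stop("more factors than blocks: no one-to-one assignment")
  if (any(score < -1e-9) || any(score > 1 + 1e-9))
    stop("score entries must lie in [0, 1]")
  if (Kf > 20L) stop("assignment over more than 20 factors is unsupported")
  full <- bitwShiftL(1L, Kf) - 1L
  dp <- rep(-Inf, full + 1L)
  dp[1L] <- 0
  for (i in seq_len(B)) {
    new <- dp
    for (k in seq_len(Kf)) {
      bit <- bitwShiftL(1L, k - 1L)
      masks <- which(bitwAnd(seq_len(full), bit) != 0L)
      cand <- dp[masks - bit + 1L] + score[i, k]
      new[masks + 1L] <- pmax(new[masks + 1L], cand)
    }
    dp <- new
  }
  dp[full + 1L] / Kf
}
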