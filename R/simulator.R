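# Factorial synthetic scRNA-seq generator with ground-truth factors.
#
# Counts are negative binomial around cell-type-specific mean profiles that
# are shifted, in log space, by additive level effects for each non-cell-type
# factor. The batch factor scales every gene (gene-wise multiplicative batch
# effect); condition factors touch only a subset of genes. Cells of each type
# are allocated deterministically and near-evenly across all combinations of
# the non-cell-type factor levels ("subsets"), so per-type totals are exact.

#' Simulator configuration
#'
#' @param n_genes Number of genes.
#' @param factors List of factor descriptors `list(name, n_levels,
#'   effect_gene_fraction, effect_logfc_sd)`. The factor named `"cell_type"`
#'   defines the cell populations; its per-type marker fraction and log-fold
#'   -change sd come from its descriptor.
#' @param cell_type_counts Integer vector, one entry per cell type.
#' @param batch_factor_name Name of the factor treated as the technical batch;
#'   its effects hit every gene regardless of `effect_gene_fraction`.
#' @param depth_mean Expected total counts per cell.
#' @param nb_dispersion Negative binomial size parameter theta (var = mu +
#'   mu^2 / theta).
#' @param seed Integer seed; identical configurations reproduce identical
#'   datasets bit for bit.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes, factors, cell_type_counts,
                       batch_factor_name = "batch", depth_mean = 2000,
                       nb_dispersion = 1.0, seed = 0L) {
  nms <- vapply(factors, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("factor names must be unique")
  if (!"cell_type" %in% nms) stop("one factor must be named 'cell_type'")
  if (!batch_factor_name %in% nms)
    stop("batch_factor_name must name one of the factors")
  if (batch_factor_name == "cell_type")
    stop("the batch factor cannot be the cell_type factor")
  ct <- factors[[which(nms == "cell_type")]]
  cell_type_counts <- as.integer(cell_type_counts)
  if (length(cell_type_counts) != ct$n_levels)
    stop("cell_type_counts length must equal the cell_type level count")
  if (any(cell_type_counts < 1L)) stop("all cell type counts must be >= 1")
  for (f in factors) {
    if (f$n_levels < 2L) stop("every factor needs >= 2 levels")
    if (f$effect_gene_fraction <= 0 || f$effect_gene_fraction > 1)
      stop("effect_gene_fraction must lie in (0, 1]")
    if (f$effect_logfc_sd < 0) stop("effect_logfc_sd must be >= 0")
  }
  structure(list(n_genes = as.integer(n_genes), factors = factors,
                 cell_type_counts = cell_type_counts,
                 batch_factor_name = batch_factor_name,
                 depth_mean = depth_mean, nb_dispersion = nb_dispersion,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default benchmark configuration
#'
#' The factorial benchmark design: 2 batches x 2 condition-1 levels
#' (Ctrl/Stim) x 2 condition-2 levels (Healthy/Severe) x 16 cell types over
#' 500 genes; every cell type has 660 cells except type 2, a rare population
#' of 200 cells (10 100 cells in total, eight batch-condition subsets).
#'
#' @return A [sim_config()].
#' @export
default_sim_config <- function() {
  sim_config(
    n_genes = 500L,
    factors = list(
      list(name = "batch", n_levels = 2L,
           effect_gene_fraction = 1.0, effect_logfc_sd = 0.3),
      list(name = "condition1", n_levels = 2L,
           effect_gene_fraction = 0.1, effect_logfc_sd = 1.0),
      list(name = "condition2", n_levels = 2L,
           effect_gene_fraction = 0.1, effect_logfc_sd = 1.0),
      list(name = "cell_type", n_levels = 16L,
           effect_gene_fraction = 0.2, effect_logfc_sd = 1.0)
    ),
    cell_type_counts = replace(rep(660L, 16L), 3L, 200L),
    batch_factor_name = "batch",
    depth_mean = 2000, nb_dispersion = 5.0, seed = 0L
  )
}

#' Reduced configuration for fast experiments
#'
#' Same factorial structure as [default_sim_config()] at desk scale: 8 cell
#' types of 250 cells (2000 cells) over 200 genes.
#'
#' @param seed Integer seed.
#' @return A [sim_config()].
#' @export
tiny_sim_config <- function(seed = 0L) {
  sim_config(
    n_genes = 200L,
    factors = list(
      list(name = "batch", n_levels = 2L,
           effect_gene_fraction = 1.0, effect_logfc_sd = 0.3),
      list(name = "condition1", n_levels = 2L,
           effect_gene_fraction = 0.1, effect_logfc_sd = 1.0),
      list(name = "condition2", n_levels = 2L,
           effect_gene_fraction = 0.1, effect_logfc_sd = 1.0),
      list(name = "cell_type", n_levels = 8L,
           effect_gene_fraction = 0.2, effect_logfc_sd = 1.0)
    ),
    cell_type_counts = rep(250L, 8L),
    batch_factor_name = "batch",
    depth_mean = 2000, nb_dispersion = 5.0, seed = seed
  )
}

# Deterministic near-even split of n cells over s slots: the first n %% s
# slots get one extra cell.
allocate_even <- function(n, s) {
  base <- n %/% s
  extra <- n %% s
  base + c(rep(1L, extra), rep(0L, s - extra))
}

#' Simulate a factorial scRNA-seq dataset
#'
#' Draws, once per run: a shared baseline log-mean per gene; per cell type a
#' shift on a random marker subset; per non-cell-type factor level (level 0 is
#' the reference) additive log-fold-changes on a random gene subset (all genes
#' for the batch factor). Each cell's expected profile is the exponentiated
#' log-mean renormalized to `depth_mean` total counts; counts are negative
#' binomial with dispersion `nb_dispersion`.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_output`: `dataset` (raw counts), `truth`
#'   (fully observed [label_table()]), `spec` ([factor_spec()]),
#'   `gene_effects` (baseline plus per-factor genes x levels log-fold-change
#'   matrices), and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    G <- config$n_genes
    nms <- vapply(config$factors, `[[`, "", "name")
    other <- config$factors[nms != "cell_type"]
    ct_idx <- which(nms == "cell_type")
    ctf <- config$factors[[ct_idx]]
    n_types <- ctf$n_levels

    baseline <- stats::rnorm(G, 0, 1)

    type_shift <- matrix(0, G, n_types,
                         dimnames = list(NULL, paste0("type", 0:(n_types - 1))))
    n_marker <- max(1L, round_half_up(ctf$effect_gene_fraction * G))
    for (t in seq_len(n_types)) {
      idx <- sample.int(G, n_marker)
      type_shift[idx, t] <- stats::rnorm(n_marker, 0, ctf$effect_logfc_sd)
    }

    lfc <- vector("list", length(other))
    names(lfc) <- vapply(other, `[[`, "", "name")
    for (i in seq_along(other)) {
      f <- other[[i]]
      frac <- if (f$name == config$batch_factor_name) 1.0
              else f$effect_gene_fraction
      m <- matrix(0, G, f$n_levels,
                  dimnames = list(NULL, paste0("level", 0:(f$n_levels - 1))))
      n_eff <- max(1L, round_half_up(frac * G))
      for (l in 2:f$n_levels) {  # level 0 is the reference
        idx <- sample.int(G, n_eff)
        m[idx, l] <- stats::rnorm(n_eff, 0, f$effect_logfc_sd)
      }
      lfc[[i]] <- m
    }

    subsets <- as.matrix(expand.grid(lapply(other, function(f)
      0:(f$n_levels - 1L))))
    colnames(subsets) <- names(lfc)
    S <- nrow(subsets)

    n_total <- sum(config$cell_type_counts)
    counts <- matrix(0, n_total, G)
    lab <- matrix(0L, n_total, length(config$factors))
    colnames(lab) <- nms
    row0 <- 0L
    for (t in seq_len(n_types)) {
      alloc <- allocate_even(config$cell_type_counts[t], S)
      if (any(alloc == 0L))
        message(sprintf(
          "cell type %d has fewer cells (%d) than subsets (%d); some subsets empty",
          t - 1L, config$cell_type_counts[t], S))
      for (s in seq_len(S)) {
        nc <- alloc[s]
        if (nc == 0L) next
        lm <- baseline + type_shift[, t]
        for (i in seq_along(lfc)) lm <- lm + lfc[[i]][, subsets[s, i] + 1L]
        mu <- exp(lm)
        mu <- mu * (config$depth_mean / sum(mu))
        block <- matrix(
          stats::rnbinom(nc * G, size = config$nb_dispersion,
                         mu = rep(mu, each = nc)),
          nrow = nc, ncol = G)
        rows <- row0 + seq_len(nc)
        counts[rows, ] <- block
        lab[rows, ct_idx] <- t - 1L
        for (i in seq_along(lfc))
          lab[rows, names(lfc)[i]] <- subsets[s, i]
        row0 <- row0 + nc
      }
    }

    gene_ids <- sprintf("gene_%03d", seq_len(G))
    cell_ids <- sprintf("cell_%05d", seq_len(n_total))
    ds <- expression_dataset(counts, cell_ids, gene_ids, layer = "raw_counts")
    vocab <- c(
      stats::setNames(lapply(other, function(f)
        paste0(f$name, 0:(f$n_levels - 1L))), names(lfc)),
      list(cell_type = paste0("type", 0:(n_types - 1L)))
    )
    # keep the configured factor order
    vocab <- vocab[nms]
    spec <- factor_spec(vocab)
    truth <- label_table(lab, factor_names = nms, cell_ids = cell_ids,
                         n_cats = n_categories(spec))
    structure(list(dataset = ds, truth = truth, spec = spec,
                   gene_effects = c(list(baseline = baseline,
                                         cell_type = type_shift), lfc),
                   subsets = subsets, config = config),
              class = "sim_output")
  })
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf("sim_output: %d cells x %d genes, %d factors, %d subsets\n",
              nrow(x$dataset$matrix), ncol(x$dataset$matrix),
              length(x$spec$factors), nrow(x$subsets)))
  invisible(x)
}

#' Tabulate simulated cells by subset and cell type
#'
#' Rows are the (batch x condition...) subsets, columns the cell types; column
#' sums reproduce the configured per-type cell counts exactly.
#'
#' @param sim A [simulate_dataset()] result.
#' @return An integer matrix, subsets x cell types.
#' @export
summarize_sim <- function(sim) {
  stopifnot(inherits(sim, "sim_output"))
  lab <- sim$truth$labels
  nms <- colnames(lab)
  other <- setdiff(nms, "cell_type")
  subset_id <- apply(lab[, other, drop = FALSE], 1, paste, collapse = "|")
  tab <- table(subset_id, cell_type = lab[, "cell_type"])
  out <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                dimnames = list(rownames(tab),
                                paste0("type", colnames(tab))))
  out
}
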