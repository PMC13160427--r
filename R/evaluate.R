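# Assembled disentanglement report and the end-to-end benchmark pipeline.

#' Full disentanglement report for a latent matrix
#'
#' Computes the Spearman factor-correlation matrices, MIG, SAP, DCI, and the
#' Hungarian block alignment for a latent matrix whose columns are grouped
#' into factor blocks by a column map (as produced by [extract_latent()]).
#' The Hungarian score matrix is built at the block level: each block's score
#' for a factor is the maximum one-vs-rest absolute Spearman rho over the
#' block's columns; the residual block competes like any other, so the
#' assignment can reveal a factor that leaked into the residual.
#'
#' @param latent n x D latent matrix.
#' @param column_map Named list mapping factor names (and optionally
#'   `"residual"`) to column index vectors.
#' @param labels Fully observed [label_table()] of ground-truth factors.
#' @param n_bins Quantile bins for the MIG estimator.
#' @param seed Seed for the DCI forests.
#' @return An object of class `disentanglement_report` with fields
#'   `spearman`, `spearman_ovr`, `block_scores`, `mig`, `sap`, `hungarian`,
#'   `dci_informativeness`, `dci_disentanglement`, `dci_completeness`.
#' @export
evaluate_latent <- function(latent, column_map, labels, n_bins = 20L,
                            seed = 0L) {
  latent <- as.matrix(latent)
  sp <- spearman_matrix(latent, labels)
  lab <- as_labels(labels)$labels
  block_scores <- do.call(rbind, lapply(column_map, function(cols)
    apply(sp$rho_ovr[cols, , drop = FALSE], 2, max)))
  colnames(block_scores) <- colnames(lab)
  d <- dci(latent, labels, seed = seed)
  structure(list(
    spearman = sp$rho,
    spearman_ovr = sp$rho_ovr,
    block_scores = block_scores,
    mig = mig(latent, labels, n_bins = n_bins),
    sap = sap(latent, labels),
    hungarian = hungarian_alignment(pmin(block_scores, 1)),
    dci_informativeness = d$informativeness,
    dci_disentanglement = d$disentanglement,
    dci_completeness = d$completeness
  ), class = "disentanglement_report")
}

#' @export
print.disentanglement_report <- function(x, ...) {
  cat("disentanglement_report\n")
  cat(sprintf("  MIG %.3f  SAP %.3f  Hungarian %.3f\n",
              x$mig, x$sap, x$hungarian))
  cat(sprintf("  DCI info %.3f  dis %.3f  comp %.3f\n",
              x$dci_informativeness, x$dci_disentanglement,
              x$dci_completeness))
  if (!is.null(x$per_factor_f1)) {
    cat("  macro-F1:",
        paste(sprintf("%s %.3f", names(x$per_factor_f1), x$per_factor_f1),
              collapse = "  "), "\n")
  }
  if (!is.null(x$ari)) cat(sprintf("  cell-type ARI %.3f\n", x$ari))
  invisible(x)
}

#' Plot a Spearman factor-correlation heatmap
#'
#' @param report A [evaluate_latent()] result (or a plain dims x factors
#'   matrix).
#' @param one_vs_rest Plot the one-vs-rest matrix instead of the integer
#'   -coded one.
#' @param ... Passed to [pheatmap::pheatmap()].
#' @export
plot_spearman <- function(report, one_vs_rest = TRUE, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("plot_spearman needs the pheatmap package")
  m <- if (inherits(report, "disentanglement_report")) {
    if (one_vs_rest) report$spearman_ovr else report$spearman
  } else as.matrix(report)
  pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE, ...)
}

#' End-to-end simulated benchmark
#'
#' Simulates a factorial dataset, hides all but a fraction of the labels,
#' trains the model, and evaluates factor recovery (macro-F1 on cells whose
#' labels were hidden, cell-type ARI) plus the disentanglement metric suite
#' on the extracted latent. The simulated dataset is fixed by the preset;
#' each seed in `seeds` draws a different labeled subset and re-trains, and
#' per-seed results are averaged.
#'
#' @param preset `"tiny"` (2000 cells, 200 genes, 8 cell types) or `"full"`
#'   (10 100 cells, 500 genes, 16 cell types).
#' @param seeds Integer vector of masking/training seeds.
#' @param label_fraction Fraction of cells whose labels stay visible.
#' @param epochs Training epochs per run.
#' @param out Optional directory: writes `report.json`, per-seed history and
#'   prediction CSVs, and a run manifest.
#' @param verbose Print per-seed progress.
#' @return A list with per-seed results (`runs`), averaged per-factor F1
#'   (`f1_mean`), averaged ARI, and the last seed's
#'   [evaluate_latent()] report.
#' @export
run_benchmark <- function(preset = c("tiny", "full"), seeds = 0:2,
                          label_fraction = 0.05, epochs = 60L, out = NULL,
                          verbose = FALSE) {
  preset <- match.arg(preset)
  cfg <- if (preset == "tiny") tiny_sim_config() else default_sim_config()
  sim <- simulate_dataset(cfg)
  ds <- normalize_counts(sim$dataset)
  runs <- lapply(seeds, function(s) {
    masked <- mask_labels(sim$truth, label_fraction, seed = s)
    fit <- scd_fit(ds, masked,
                   model_cfg = model_config(sim$spec, seed = s),
                   train_cfg = train_config(epochs = epochs, seed = s))
    pred <- predict_factors(fit, ds)
    unl <- masked$mask[, 1] == 0L
    f1 <- vapply(seq_along(sim$spec$factors), function(j)
      macro_f1(sim$truth$labels[unl, j], pred$labels[unl, j]), 1.0)
    names(f1) <- names(sim$spec$factors)
    ari_ct <- ari(sim$truth$labels[unl, "cell_type"],
                  pred$labels[unl, "cell_type"])
    lat <- extract_latent(fit, ds)
    rep <- evaluate_latent(lat$latent, lat$column_map, sim$truth, seed = s)
    rep$per_factor_f1 <- f1
    rep$ari <- ari_ct
    if (verbose)
      message(sprintf("seed %d: F1 [%s], ARI %.3f, MIG %.3f", s,
                      paste(sprintf("%.3f", f1), collapse = " "),
                      ari_ct, rep$mig))
    list(seed = s, fit = fit, report = rep, latent = lat, masked = masked)
  })
  f1_mat <- do.call(rbind, lapply(runs, function(r) r$report$per_factor_f1))
  res <- list(
    preset = preset, seeds = seeds, label_fraction = label_fraction,
    runs = runs,
    f1_mean = colMeans(f1_mat),
    ari_mean = mean(vapply(runs, function(r) r$report$ari, 1.0)),
    report = runs[[length(runs)]]$report
  )
  if (!is.null(out)) write_benchmark(res, sim, out)
  res
}

write_benchmark <- function(res, sim, out) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (r in res$runs) {
    f <- file.path(out, sprintf("history_seed%d.csv", r$seed))
    utils::write.csv(r$fit$history, f, row.names = FALSE)
    files <- c(files, f)
  }
  last <- res$runs[[length(res$runs)]]
  latf <- file.path(out, "latent.csv")
  utils::write.csv(
    data.frame(cell_id = rownames(last$latent$latent), last$latent$latent,
               check.names = FALSE),
    latf, row.names = FALSE)
  mapf <- file.path(out, "column_map.json")
  jsonlite::write_json(last$latent$column_map, mapf)
  rep <- res$report
  repf <- file.path(out, "report.json")
  jsonlite::write_json(list(
    schema = "disentanglement_report/1",
    preset = res$preset, seeds = res$seeds,
    label_fraction = res$label_fraction,
    f1_mean = as.list(res$f1_mean), ari_mean = res$ari_mean,
    mig = rep$mig, sap = rep$sap, hungarian = rep$hungarian,
    dci_informativeness = rep$dci_informativeness,
    dci_disentanglement = rep$dci_disentanglement,
    dci_completeness = rep$dci_completeness
  ), repf, auto_unbox = TRUE, digits = NA)
  write_manifest(out, seeds = res$seeds,
                 config = list(preset = res$preset,
                               label_fraction = res$label_fraction),
                 files = c(files, latf, mapf, repf))
  invisible(out)
}

# Every run directory gets exactly one manifest recording configs, seeds,
# package version, input checksums and the output file list.
write_manifest <- function(out, seeds, config, files, inputs = character(0)) {
  manifest <- list(
    package = "scdisent",
    version = as.character(utils::packageVersion("scdisent")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seeds = seeds,
    config = config,
    input_checksums = as.list(tools::md5sum(inputs)),
    outputs = basename(files)
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
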