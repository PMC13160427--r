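# Shared fixtures. Everything is generated in code at test time; the heavier
# trained runs are memoized so several test files can share them.

fixture_cache <- new.env(parent = emptyenv())

# The tiny-preset simulation used across training / evaluation tests.
tiny_sim <- function() {
  if (is.null(fixture_cache$sim))
    fixture_cache$sim <- simulate_dataset(tiny_sim_config())
  fixture_cache$sim
}

tiny_lognorm <- function() {
  if (is.null(fixture_cache$ds))
    fixture_cache$ds <- normalize_counts(tiny_sim()$dataset)
  fixture_cache$ds
}

# One semi-supervised training run on the tiny preset, memoized by
# (seed, label fraction). 60 epochs: the loss plateaus well before that on
# this problem size.
tiny_run <- function(seed, fraction = 0.05, epochs = 60L) {
  key <- sprintf("run_%d_%s", seed, fraction)
  if (!is.null(fixture_cache[[key]])) return(fixture_cache[[key]])
  sim <- tiny_sim()
  ds <- tiny_lognorm()
  masked <- mask_labels(sim$truth, fraction, seed = seed)
  fit <- scd_fit(ds, masked,
                 model_cfg = model_config(sim$spec, seed = seed),
                 train_cfg = train_config(epochs = epochs, seed = seed))
  pred <- predict_factors(fit, ds)
  unl <- masked$mask[, 1] == 0L
  f1 <- vapply(seq_along(sim$spec$factors), function(j)
    macro_f1(sim$truth$labels[unl, j], pred$labels[unl, j]), 1.0)
  names(f1) <- names(sim$spec$factors)
  lat <- extract_latent(fit, ds)
  res <- list(seed = seed, fraction = fraction, fit = fit, masked = masked,
              pred = pred, unlabeled = unl, f1 = f1, latent = lat)
  fixture_cache[[key]] <- res
  res
}

# A small deterministic expression fixture for I/O tests.
small_counts <- function(n = 6L, d = 4L, seed = 42L) {
  m <- with_seed(seed, matrix(rpois(n * d, 5) + 0, n, d))
  m[1, 1] <- 0
  expression_dataset(m, paste0("c", seq_len(n)), paste0("g", seq_len(d)),
                     layer = "raw_counts")
}

# A fully observed label table over two factors.
small_labels <- function(n = 6L) {
  lab <- cbind(batch = rep(0:1, length.out = n),
               cell_type = rep(0:2, length.out = n))
  label_table(lab, factor_names = colnames(lab),
              cell_ids = paste0("c", seq_len(n)))
}

# A tiny model on random data for forward-pass tests.
toy_model <- function(reconstruction = "mse", seed = 7L, d = 12L) {
  spec <- factor_spec(list(batch = c("a", "b"),
                           cell_type = c("x", "y", "z")),
                      code_dims = c(2L, 2L), residual_dim = 3L)
  scd_model(model_config(spec, encoder_hidden = 8L, decoder_hidden = 8L,
                         reconstruction = reconstruction, seed = seed), d)
}

toy_dataset <- function(n = 10L, d = 12L, seed = 5L, layer = "lognorm") {
  m <- with_seed(seed, if (layer == "lognorm")
    matrix(abs(rnorm(n * d)), n, d) else matrix(rpois(n * d, 4) + 0, n, d))
  expression_dataset(m, layer = layer)
}
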