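make_toy_problem <- function(n = 120L, seed = 21L) {
  # two well-separated groups per factor on 15 genes
  with_seed(seed, {
    g1 <- rep(0:1, each = n / 2)
    g2 <- rep(rep(0:1, each = n / 4), 2)
    m <- matrix(rnorm(n * 15, 5), n, 15)
    m[g1 == 1, 1:5] <- m[g1 == 1, 1:5] + 3
    m[g2 == 1, 6:10] <- m[g2 == 1, 6:10] + 3
    ds <- expression_dataset(abs(m), layer = "lognorm")
    spec <- factor_spec(list(grp1 = c("a", "b"), grp2 = c("x", "y")),
                        code_dims = 2L, residual_dim = 2L)
    truth <- label_table(cbind(grp1 = g1, grp2 = g2))
    list(ds = ds, spec = spec, truth = truth)
  })
}

test_that("training reduces the total loss and is seed-deterministic", {
  prob <- make_toy_problem()
  masked <- mask_labels(prob$truth, 0.25, seed = 2L)
  tcfg <- train_config(epochs = 15L, batch_size = 40L, seed = 3L)
  fit1 <- scd_fit(prob$ds, masked, model_cfg = model_config(
    prob$spec, encoder_hidden = 16L, decoder_hidden = 16L, seed = 3L),
    train_cfg = tcfg)
  expect_lt(fit1$history$total[nrow(fit1$history)], fit1$history$total[1])
  fit2 <- scd_fit(prob$ds, masked, model_cfg = model_config(
    prob$spec, encoder_hidden = 16L, decoder_hidden = 16L, seed = 3L),
    train_cfg = tcfg)
  expect_identical(fit1$history, fit2$history)
})

test_that("lambda3 = 0 still reports the reconstruction component", {
  prob <- make_toy_problem()
  masked <- mask_labels(prob$truth, 0.5, seed = 1L)
  tcfg <- train_config(epochs = 3L, batch_size = 40L, lambda3 = 0, seed = 1L)
  fit <- scd_fit(prob$ds, masked, model_cfg = model_config(
    prob$spec, encoder_hidden = 8L, decoder_hidden = 8L, seed = 1L),
    train_cfg = tcfg)
  h <- fit$history
  expect_true(all(h$rec > 0))
  expect_equal(h$total, h$cls + 0.5 * h$ent + 0.01 * h$res, tolerance = 1e-9)
})

test_that("training mixes supervision contracts and warnings", {
  prob <- make_toy_problem()
  # a category never labeled -> warning
  lab <- prob$truth$labels
  lab[lab[, 1] == 1L, 1] <- -1L
  part <- label_table(lab)
  expect_warning(
    scd_fit(prob$ds, part, model_cfg = model_config(
      prob$spec, encoder_hidden = 8L, decoder_hidden = 8L, seed = 1L),
      train_cfg = train_config(epochs = 1L, batch_size = 40L, seed = 1L)),
    "no labeled cell")
  # layer / mode mismatch
  counts <- expression_dataset(matrix(1:20, 4), layer = "raw_counts")
  expect_error(
    scd_fit(counts, label_table(cbind(rep(0:1, 2), rep(0:1, 2))),
            model_cfg = model_config(prob$spec, reconstruction = "mse")),
    "requires a lognorm layer")
  expect_error(
    scd_fit(prob$ds, prob$truth,
            model_cfg = model_config(prob$spec),
            train_cfg = train_config(batch_size = 4000L)),
    "batch_size")
})

test_that("semi-supervised training on separable data recovers held-out labels", {
  prob <- make_toy_problem()
  masked <- mask_labels(prob$truth, 0.25, seed = 5L)
  fit <- scd_fit(prob$ds, masked, model_cfg = model_config(
    prob$spec, encoder_hidden = 16L, decoder_hidden = 16L, seed = 5L),
    train_cfg = train_config(epochs = 300L, batch_size = 40L, seed = 5L))
  pred <- predict_factors(fit, prob$ds)
  unl <- masked$mask[, 1] == 0L
  expect_gte(macro_f1(prob$truth$labels[unl, 1], pred$labels[unl, 1]), 0.9)
  expect_gte(macro_f1(prob$truth$labels[unl, 2], pred$labels[unl, 2]), 0.9)
  # labeled training cells with saturated cls loss reproduce their labels
  labc <- masked$mask[, 1] == 1L
  expect_equal(unname(pred$labels[labc, ]), unname(masked$labels[labc, ]))
})

test_that("prediction ties resolve to the lowest category index", {
  model <- toy_model()
  for (net in c("batch", "cell_type")) {
    model$par$enc[[net]]$W <- lapply(model$par$enc[[net]]$W, function(w) w * 0)
    model$par$enc[[net]]$b <- lapply(model$par$enc[[net]]$b, function(b) b * 0)
  }
  pred <- predict_factors(model, toy_dataset())
  expect_true(all(pred$labels == 0L))
})

test_that("extract_latent lays out factor blocks per the column map", {
  sim <- tiny_sim()
  model <- scd_model(model_config(sim$spec, encoder_hidden = 8L,
                                  decoder_hidden = 8L, seed = 1L),
                     ncol(sim$dataset$matrix))
  ds <- tiny_lognorm()
  lat <- extract_latent(model, ds)
  # 3 binary factors (dim 2) + cell type (dim 8) + residual (10)
  expect_equal(ncol(lat$latent), 2L + 2L + 2L + 8L + 10L)
  expect_equal(lat$column_map$batch, 1:2)
  expect_equal(lat$column_map$residual, 15:24)
  expect_equal(nrow(lat$latent), nrow(ds$matrix))
  # hard labels switch the composition for labeled cells only
  masked <- mask_labels(sim$truth, 0.05, seed = 1L)
  lab <- extract_latent(model, ds, use_labels = masked)
  labc <- masked$mask[, 1] == 1L
  expect_false(isTRUE(all.equal(lab$latent[labc, 1:2],
                                lat$latent[labc, 1:2])))
  expect_equal(lab$latent[!labc, ], lat$latent[!labc, ])
  emb <- model$par$emb$batch
  expect_equal(unname(lab$latent[labc, 1:2]),
               unname(emb[masked$labels[labc, "batch"] + 1L, ]))
})
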