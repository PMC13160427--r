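test_that("classification loss matches closed forms on labeled pairs", {
  # empty mask: the sum has no terms
  expect_equal(classification_loss(list(matrix(rnorm(4), 2)),
                                   matrix(-1L, 2, 1)), 0)
  # uniform binary logits, true label 0
  expect_equal(classification_loss(list(matrix(0, 1, 2)), matrix(0L, 1, 1)),
               log(2), tolerance = 1e-12)
  # saturated correct prediction
  expect_lt(classification_loss(list(matrix(c(20, -20), 1)),
                                matrix(0L, 1, 1)), 1e-8)
  expect_error(classification_loss(list(matrix(0, 1, 2)), matrix(5L, 1, 1)),
               "exceeds")
})

test_that("classification loss falls as the correct-class logit grows", {
  prev <- Inf
  for (z in seq(-2, 6, by = 1)) {
    cur <- classification_loss(list(matrix(c(z, 1, -1), 1)),
                               matrix(0L, 1, 1))
    expect_lt(cur, prev)
    prev <- cur
  }
})

test_that("entropy loss matches closed forms on unlabeled pairs", {
  expect_equal(entropy_loss(list(matrix(rnorm(6), 2)), matrix(1L, 2, 1)), 0)
  expect_equal(entropy_loss(list(matrix(0, 1, 4)), matrix(0L, 1, 1)),
               log(4), tolerance = 1e-12)
  expect_lt(entropy_loss(list(matrix(c(30, -30), 1)), matrix(0L, 1, 1)),
            1e-8)
})

test_that("entropy loss is bounded by log of the category count", {
  for (i in 1:20) {
    K <- sample(2:6, 1)
    z <- matrix(rnorm(5 * K, sd = 3), 5)
    e <- entropy_loss(list(z), matrix(0L, 5, 1))
    expect_gte(e, 0)
    expect_lte(e, log(K) + 1e-12)
  }
})

test_that("residual loss is the mean squared l2 norm", {
  expect_equal(residual_loss(matrix(0, 4, 3)), 0)
  expect_equal(residual_loss(matrix(c(3, 4), 1)), 25)
  u <- matrix(rnorm(50), 10)
  u <- u / sqrt(rowSums(u^2))
  expect_equal(residual_loss(u), 1, tolerance = 1e-12)
})

test_that("reconstruction loss covers both modes with exact values", {
  expect_equal(reconstruction_loss(matrix(1:4, 2), matrix(1:4, 2), "mse"), 0)
  expect_equal(reconstruction_loss(rbind(c(0, 2)), rbind(c(1, 1)), "mse"), 1)
  expect_equal(reconstruction_loss(matrix(0), list(mean = matrix(1),
                                                   dispersion = 1), "nb"),
               log(2), tolerance = 1e-12)
  expect_error(reconstruction_loss(matrix(0.5), list(mean = matrix(1),
                                                     dispersion = 1), "nb"),
               "integer")
})

test_that("nb likelihood at fixed dispersion peaks at mu = x", {
  for (x in c(1, 3, 10)) {
    grid <- seq(max(0.1, x - 2), x + 2, by = 0.01)
    nll <- nb_nll(x, grid, theta = 2)
    expect_equal(grid[which.min(nll)], x, tolerance = 0.011)
  }
})

test_that("total loss is the weighted sum identity", {
  lb <- total_loss(1, 2, 3, 4, 0.5, 0.01, 1)
  expect_equal(lb$total, 1 + 1 + 0.03 + 4, tolerance = 1e-9)
  expect_equal(total_loss(5, 2, 3, 4, 0, 0, 0)$total, 5)
  expect_equal(total_loss(0, 0, 0, 0, 0.5, 0.01, 1)$total, 0)
  expect_error(total_loss(1, 1, 1, 1, -1, 0, 0), "non-negative")
})

test_that("backpropagated gradients match finite differences", {
  # deterministic loss given a fixed noise seed; central differences over a
  # sample of coordinates from every parameter leaf
  for (mode in c("mse", "nb")) {
    model <- toy_model(mode, d = 6L)
    ds <- toy_dataset(n = 5L, d = 6L,
                      layer = if (mode == "mse") "lognorm" else "raw_counts")
    X <- if (mode == "mse") ds$matrix else log1p(ds$matrix)
    Tb <- ds$matrix
    labb <- cbind(c(0L, 1L, -1L, -1L, -1L), c(2L, -1L, -1L, 0L, -1L))
    maskb <- (labb >= 0L) * 1L
    tcfg <- train_config(lambda1 = 0.5, lambda2 = 0.01, lambda3 = 1)
    loss_at <- function(par) {
      m <- model
      m$par <- par
      stp <- with_seed(77L, train_step(m, X, Tb, labb, maskb, tcfg))
      total_loss(stp$parts[["cls"]], stp$parts[["ent"]], stp$parts[["res"]],
                 stp$parts[["rec"]], 0.5, 0.01, 1)$total
    }
    grads <- with_seed(77L, train_step(model, X, Tb, labb, maskb,
                                       tcfg))$grads
    get_path <- function(x, path) Reduce(`[[`, path, x)
    set_path <- function(x, path, val) {
      if (length(path) == 1L) x[[path[[1L]]]] <- val
      else x[[path[[1L]]]] <- set_path(x[[path[[1L]]]], path[-1L], val)
      x
    }
    leaves <- list(
      list("enc", "batch", "W", 1L), list("enc", "cell_type", "W", 2L),
      list("res", "W", 1L), list("emb", "batch"), list("emb", "cell_type"),
      list("dec", "W", 1L), list("dec", "b", 2L))
    if (mode == "nb") leaves <- c(leaves, list(list("theta")))
    for (path in leaves) {
      p <- get_path(model$par, path)
      g <- get_path(grads, path)
      idx <- with_seed(3L, sample.int(length(p), min(4L, length(p))))
      for (i in idx) {
        h <- 1e-5
        pu <- p
        pu[i] <- p[i] + h
        pd <- p
        pd[i] <- p[i] - h
        fd <- (loss_at(set_path(model$par, path, pu)) -
                 loss_at(set_path(model$par, path, pd))) / (2 * h)
        expect_equal(g[i], fd, tolerance = 1e-4)
      }
    }
  }
})
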