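test_that("macro_f1 matches hand contingency computations", {
  expect_equal(macro_f1(c(0, 1, 1, 0), c(0, 1, 1, 0)), 1)
  expect_equal(macro_f1(c(0, 0, 1, 1), c(1, 1, 0, 0)), 0)
  # F1(class 0) = 2/3, F1(class 1) = 4/5
  expect_equal(macro_f1(c(0, 0, 1, 1), c(0, 1, 1, 1)), 11 / 15)
  # category renaming leaves the score unchanged
  expect_equal(macro_f1(c(2, 2, 7, 7), c(2, 7, 7, 7)), 11 / 15)
  expect_error(macro_f1(integer(0), integer(0)), "empty")
})

brute_force_ari <- function(a, b) {
  # pair-counting definition: agreement over all unordered pairs
  n <- length(a)
  s_ab <- 0; s_a <- 0; s_b <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]
    sb <- b[i] == b[j]
    s_ab <- s_ab + (sa && sb)
    s_a <- s_a + sa
    s_b <- s_b + sb
  }
  np <- choose(n, 2)
  expected <- s_a * s_b / np
  (s_ab - expected) / ((s_a + s_b) / 2 - expected)
}

test_that("ari agrees with pair counting and handles degenerate partitions", {
  expect_equal(ari(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(ari(c(0, 0, 1, 1), c(5, 5, 2, 2)), 1)  # permutation invariance
  set.seed(4)
  for (i in 1:10) {
    a <- sample(0:2, 12, replace = TRUE)
    b <- sample(0:2, 12, replace = TRUE)
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    expect_equal(ari(a, b), brute_force_ari(a, b), tolerance = 1e-12)
    if (requireNamespace("mclust", quietly = TRUE))
      expect_equal(ari(a, b), mclust::adjustedRandIndex(a, b),
                   tolerance = 1e-12)
  }
  expect_equal(ari(c(0, 0, 1, 1), c(0, 1, 0, 1)),
               brute_force_ari(c(0, 0, 1, 1), c(0, 1, 0, 1)))
  expect_equal(ari(rep(1, 5), rep(2, 5)), 1)  # both single-cluster
})

test_that("spearman_matrix flags perfect monotone and null associations", {
  set.seed(11)
  codes <- rep(0:3, each = 500)
  noise <- rnorm(2000)
  sp <- spearman_matrix(cbind(codes, -codes, noise), cbind(f = codes))
  expect_equal(sp$rho[1, 1], 1)
  expect_equal(sp$rho[2, 1], -1)
  expect_lt(abs(sp$rho[3, 1]), 0.08)  # ~3/sqrt(n) null bound
  expect_true(all(sp$rho_ovr >= 0 & sp$rho_ovr <= 1))
  expect_message(
    sp0 <- spearman_matrix(cbind(rep(1, 10), 1:10), cbind(rep(0:1, 5))),
    "constant")
  expect_equal(sp0$rho[1, 1], 0)
})

test_that("empirical mutual information matches a brute-force oracle", {
  brute_mi <- function(a, b) {
    mi <- 0
    for (x in unique(a)) for (y in unique(b)) {
      pxy <- mean(a == x & b == y)
      if (pxy > 0) mi <- mi + pxy * log(pxy / (mean(a == x) * mean(b == y)))
    }
    mi
  }
  set.seed(9)
  for (i in 1:10) {
    a <- sample(1:3, 40, replace = TRUE)
    b <- sample(1:4, 40, replace = TRUE)
    expect_equal(discrete_mi(a, b), brute_mi(a, b), tolerance = 1e-12)
  }
})

test_that("mig is 1 on exact factor copies and ~0 on independent noise", {
  f1 <- rep(0:1, each = 1000)
  f2 <- rep(rep(0:1, each = 500), 2)  # balanced and independent of f1
  expect_equal(mig(cbind(f1 + 0, f2 + 0), cbind(f1, f2)), 1)
  set.seed(12)
  expect_lt(mig(matrix(rnorm(6000), 2000), cbind(f1, f2)), 0.05)
  expect_error(mig(matrix(rnorm(10)), cbind(f1 = rep(0:1, 5))), "at least 2")
  expect_warning(mig(cbind(f1, rnorm(2000)), cbind(f1, rep(0L, 2000))),
                 "single category")
})

test_that("sap scores stump separability gaps", {
  set.seed(13)
  y <- rep(0:1, each = 1000)
  x <- c(rnorm(1000, -3), rnorm(1000, 3))
  noise <- matrix(rnorm(6000), 2000)
  expect_lt(abs(sap(cbind(x, noise), cbind(y)) - 0.5), 0.05)
  # duplicating the best dimension forces the gap to zero
  expect_equal(sap(cbind(x, x, noise), cbind(y)), 0)
  expect_equal(sap(cbind(x, x, x), cbind(y)), 0)
})

test_that("dci entropies match hand-computed importance summaries", {
  id <- dci_from_importance(diag(3))
  expect_equal(id$disentanglement, 1)
  expect_equal(id$completeness, 1)
  un <- dci_from_importance(matrix(1 / 4, 4, 4))
  expect_equal(un$disentanglement, 0)
  expect_equal(un$completeness, 0)
  hand <- dci_from_importance(rbind(c(0.9, 0.1), c(0.1, 0.9)))
  want <- 1 - shannon_entropy(c(0.9, 0.1)) / log(2)
  expect_equal(hand$disentanglement, want, tolerance = 1e-12)
  expect_equal(hand$completeness, want, tolerance = 1e-12)
  one <- dci_from_importance(matrix(c(0.6, 0.4), 1))
  expect_equal(one$completeness, 1)  # single-dim latent
})

test_that("hungarian alignment equals the brute-force permutation maximum", {
  expect_equal(hungarian_alignment(diag(3)), 1)
  expect_equal(hungarian_alignment(diag(3)[, c(3, 1, 2)]), 1)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  set.seed(14)
  for (i in 1:20) {
    m <- matrix(runif(9), 3)
    brute <- max(vapply(perms, function(p) mean(m[cbind(p, 1:3)]), 1.0))
    expect_equal(hungarian_alignment(m), brute, tolerance = 1e-12)
  }
  # rectangular: more blocks than factors is fine, the reverse errors
  m <- matrix(runif(8), 4, 2)
  pairs <- expand.grid(i = 1:4, j = 1:4)
  pairs <- pairs[pairs$i != pairs$j, ]
  brute <- max(mapply(function(i, j) (m[i, 1] + m[j, 2]) / 2,
                      pairs$i, pairs$j))
  expect_equal(hungarian_alignment(m), brute, tolerance = 1e-12)
  expect_error(hungarian_alignment(matrix(runif(8), 2, 4)), "more factors")
  expect_error(hungarian_alignment(matrix(2, 2, 2)), "\\[0, 1\\]")
})

test_that("metrics are invariant to category relabeling and dim permutation", {
  set.seed(15)
  lab <- cbind(a = sample(0:1, 400, TRUE), b = sample(0:2, 400, TRUE))
  latent <- cbind(lab[, 1] + rnorm(400, sd = 0.1),
                  lab[, 2] + rnorm(400, sd = 0.1),
                  matrix(rnorm(800), 400))
  relab <- cbind(a = 1 - lab[, 1], b = (lab[, 2] + 1) %% 3)
  expect_equal(mig(latent, lab), mig(latent, relab), tolerance = 1e-10)
  expect_equal(sap(latent, lab), sap(latent, relab), tolerance = 1e-10)
  perm <- c(3, 1, 4, 2)
  expect_equal(mig(latent[, perm], lab), mig(latent, lab), tolerance = 1e-10)
  expect_equal(sap(latent[, perm], lab), sap(latent, lab), tolerance = 1e-10)
})

test_that("the oracle latent achieves near-ideal disentanglement scores", {
  # ground-truth factor codes injected directly as latent dims, plus noise:
  # the ceiling every learned latent is compared against
  sim <- tiny_sim()
  lab <- sim$truth$labels
  set.seed(16)
  latent <- cbind(lab + 0, matrix(rnorm(nrow(lab) * 4), nrow(lab)))
  t0 <- Sys.time()
  m <- mig(latent, sim$truth)
  s <- sap(latent, sim$truth)
  d <- dci(latent, sim$truth, seed = 1L)
  elapsed <- as.numeric(Sys.time() - t0, units = "secs")
  expect_gte(m, 0.9)
  expect_gte(s, 0.35)
  expect_gte(d$informativeness, 0.95)
  # impurity importance never reaches exactly zero on noise dims, which caps
  # disentanglement/completeness slightly below 1 even at the oracle
  expect_gte(d$disentanglement, 0.75)
  expect_gte(d$completeness, 0.6)
  expect_lt(elapsed, 60)
})
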