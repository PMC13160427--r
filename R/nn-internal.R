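# Minimal dense feed-forward machinery with manual backpropagation.
# tanh hidden units, linear outputs, Glorot-uniform initialization, Adam
# updates over arbitrarily nested parameter trees. Internal only.

nn_init <- function(sizes) {
  L <- length(sizes) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    lim <- sqrt(6 / (sizes[l] + sizes[l + 1L]))
    W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1L], -lim, lim),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  list(W = W, b = b)
}

# Returns the list of layer inputs H (H[[1]] = X) plus the linear output.
nn_forward <- function(net, X) {
  L <- length(net$W)
  H <- vector("list", L + 1L)
  H[[1L]] <- X
  for (l in seq_len(L)) {
    A <- H[[l]] %*% net$W[[l]]
    A <- A + rep(net$b[[l]], each = nrow(A))
    H[[l + 1L]] <- if (l < L) tanh(A) else A
  }
  H
}

nn_output <- function(net, X) nn_forward(net, X)[[length(net$W) + 1L]]

# dOut: gradient w.r.t. the linear output. Returns parameter gradients in the
# same shape as the net plus the gradient w.r.t. the input X.
nn_backward <- function(net, H, dOut) {
  L <- length(net$W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  delta <- dOut
  dX <- NULL
  for (l in rev(seq_len(L))) {
    gW[[l]] <- unname(crossprod(H[[l]], delta))
    gb[[l]] <- unname(colSums(delta))
    dX <- tcrossprod(delta, net$W[[l]])
    if (l > 1L) delta <- dX * (1 - H[[l]]^2)
  }
  list(W = gW, b = gb, dX = dX)
}

# ---- Adam over nested lists of numeric arrays ----

tree_zero <- function(par) {
  if (is.numeric(par)) return(par * 0)
  lapply(par, tree_zero)
}

tree_add <- function(a, b) {
  if (is.numeric(a)) return(a + b)
  mapply(tree_add, a, b, SIMPLIFY = FALSE)
}

adam_init <- function(par) list(m = tree_zero(par), v = tree_zero(par), t = 0L)

adam_step <- function(par, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  rec <- function(p, g, m, v) {
    if (is.numeric(p)) {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      p <- p - lr * (m / (1 - beta1^t)) / (sqrt(v / (1 - beta2^t)) + eps)
      return(list(p = p, m = m, v = v))
    }
    out <- mapply(rec, p, g, m, v, SIMPLIFY = FALSE)
    list(p = lapply(out, `[[`, "p"),
         m = lapply(out, `[[`, "m"),
         v = lapply(out, `[[`, "v"))
  }
  r <- rec(par, grad, state$m, state$v)
  list(par = r$p, state = list(m = r$m, v = r$v, t = t))
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
sigmoid <- function(x) 1 / (1 + exp(-x))
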