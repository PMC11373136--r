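# Multilayer perceptron: hidden layers with ReLU, sigmoid output, binary
# cross-entropy, full-batch Adam. Small enough that plain BLAS-backed matrix
# code is fast; no compiled code needed.

.mlp_fit <- function(x, y, hidden = c(100, 50), max_iter = 500, lr = 0.001,
                     seed = 1, tol = 1e-5, n_iter_no_change = 10) {
  sizes <- c(ncol(x), hidden, 1L)
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  with_seed(seed, {
    for (l in seq_len(L)) {
      r <- sqrt(6 / (sizes[l] + sizes[l + 1]))   # Glorot uniform
      W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1], -r, r),
                       sizes[l], sizes[l + 1])
      b[[l]] <- rep(0, sizes[l + 1])
    }
  })
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(v) v * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  n <- nrow(x)
  loss_log <- numeric(0)
  best <- Inf; stale <- 0L
  for (it in seq_len(max_iter)) {
    # forward
    a <- vector("list", L + 1L); a[[1]] <- x
    for (l in seq_len(L)) {
      z <- sweep(a[[l]] %*% W[[l]], 2, b[[l]], "+")
      a[[l + 1]] <- if (l < L) pmax(z, 0) else 1 / (1 + exp(-z))
    }
    p <- pmin(pmax(a[[L + 1]][, 1], 1e-12), 1 - 1e-12)
    loss <- -mean(y * log(p) + (1 - y) * log(1 - p))
    loss_log <- c(loss_log, loss)
    # backward
    delta <- matrix((p - y) / n, ncol = 1)
    for (l in rev(seq_len(L))) {
      gW <- crossprod(a[[l]], delta)
      gb <- colSums(delta)
      if (l > 1) {
        delta <- (delta %*% t(W[[l]])) * (a[[l]] > 0)
      }
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
      corr1 <- 1 - beta1^it; corr2 <- 1 - beta2^it
      W[[l]] <- W[[l]] - lr * (mW[[l]] / corr1) / (sqrt(vW[[l]] / corr2) + eps)
      b[[l]] <- b[[l]] - lr * (mb[[l]] / corr1) / (sqrt(vb[[l]] / corr2) + eps)
    }
    if (best - loss > tol) { best <- loss; stale <- 0L } else stale <- stale + 1L
    if (stale >= n_iter_no_change) break
  }
  if (length(loss_log) == max_iter && stale < n_iter_no_change)
    warning(sprintf("MLP did not converge within %d iterations", max_iter))
  list(W = W, b = b, loss = loss_log)
}

.mlp_predict <- function(state, x) {
  L <- length(state$W)
  a <- x
  for (l in seq_len(L)) {
    z <- sweep(a %*% state$W[[l]], 2, state$b[[l]], "+")
    a <- if (l < L) pmax(z, 0) else 1 / (1 + exp(-z))
  }
  as.numeric(a)
}
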