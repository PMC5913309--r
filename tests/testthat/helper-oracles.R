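# Independent oracles used to cross-check the package implementation.

`%||%` <- function(x, y) if (is.null(x)) y else x

# SIMPLS (de Jong 1993): an SVD-based PLS algorithm that shares no code path
# with the NIPALS implementation. For a univariate response its coefficients
# coincide with PLS1/NIPALS, which makes it a cross-implementation oracle.
simpls_oracle <- function(x, y, ncomp) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  cx <- colMeans(x)
  cy <- mean(y)
  x0 <- sweep(x, 2, cx)
  y0 <- y - cy
  s <- crossprod(x0, y0) # p x 1
  R <- matrix(0, p, ncomp)
  V <- matrix(0, p, ncomp)
  for (a in seq_len(ncomp)) {
    r <- svd(s)$u[, 1, drop = FALSE] # dominant left singular vector
    t_a <- x0 %*% r
    t_a <- t_a - mean(t_a)
    normt <- sqrt(sum(t_a^2))
    t_a <- t_a / normt
    r <- r / normt
    p_a <- crossprod(x0, t_a)
    v <- p_a
    if (a > 1) {
      Vp <- V[, seq_len(a - 1), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, p_a)
    }
    v <- v / sqrt(sum(v^2))
    s <- s - v %*% crossprod(v, s)
    R[, a] <- r
    V[, a] <- v
  }
  q <- crossprod(y0, x0 %*% R) # 1 x ncomp
  b <- R %*% t(q)
  list(coefficients = as.numeric(b),
       intercept = cy - sum(b * cx))
}

# Explicit leave-one-out loop, written independently of loocv_rmsep's
# internals: refit with the exported fitting functions and accumulate
# held-out errors by hand.
loo_loop_oracle <- function(x, y, determinants, ncomp, scale = FALSE) {
  x <- as.matrix(x)[, determinants, drop = FALSE]
  n <- length(y)
  errs <- numeric(n)
  for (i in seq_len(n)) {
    fit <- fit_pls1(x[-i, , drop = FALSE], y[-i], ncomp = ncomp, scale = scale)
    errs[i] <- y[i] - predict(fit, x[i, , drop = FALSE])
  }
  sqrt(mean(errs^2))
}

# Brute-force VIP from a model's stored weights, scores and y-loadings.
vip_bruteforce <- function(fit) {
  p <- nrow(fit$weights)
  A <- fit$ncomp
  ss <- numeric(A)
  for (a in seq_len(A)) {
    ss[a] <- fit$y_loadings[a]^2 * sum(fit$x_scores[, a]^2)
  }
  out <- numeric(p)
  for (j in seq_len(p)) {
    acc <- 0
    for (a in seq_len(A)) {
      wnorm <- sqrt(sum(fit$weights[, a]^2))
      acc <- acc + ss[a] * (fit$weights[j, a] / wnorm)^2
    }
    out[j] <- sqrt(p * acc / sum(ss))
  }
  out
}

# Random small regression instance for property-style loops.
random_instance <- function(seed, n = NULL, p = NULL) {
  set.seed(seed)
  n <- n %||% sample(6:15, 1)
  p <- p %||% sample(2:8, 1)
  x <- matrix(rnorm(n * p), n, p)
  colnames(x) <- paste0("v", seq_len(p))
  beta <- rnorm(p)
  y <- as.numeric(x %*% beta) + rnorm(n, 0, 0.5)
  list(x = x, y = y, n = n, p = p, beta = beta)
}
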