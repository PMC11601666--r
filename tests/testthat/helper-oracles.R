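# Independent reference implementations used as oracles. These are written
# against the textbook definitions (explicit loops, eigendecompositions,
# normal equations) and deliberately share no code with the package.

# PCA of the z-scored matrix via eigendecomposition of the covariance,
# with the same sign convention (largest-magnitude loading positive).
pca_eigen_oracle <- function(X, d) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2, mu, "-"), 2, sdv, "/")
  C <- stats::cov(Z)
  eig <- eigen(C, symmetric = TRUE)
  evr <- eig$values / sum(eig$values)
  L <- eig$vectors[, seq_len(d), drop = FALSE]
  for (j in seq_len(d)) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  list(loadings = L, evr = evr[seq_len(d)], mean = mu, scale = sdv)
}

# Optimal rank-r reconstruction residual (Frobenius) of the z-scored matrix.
pca_residual_oracle <- function(X, r) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2, mu, "-"), 2, sdv, "/")
  Zc <- sweep(Z, 2, colMeans(Z), "-")
  sv <- svd(Zc)
  r <- min(r, length(sv$d))
  Zr <- sv$u[, seq_len(r), drop = FALSE] %*%
    diag(sv$d[seq_len(r)], r) %*% t(sv$v[, seq_len(r), drop = FALSE])
  sqrt(sum((Zc - Zr)^2))
}

# Plain NIPALS PLS1: keeps all score vectors and predicts a new row by
# passing it through the same deflation sequence, never forming the
# composite coefficient vector the package uses.
nipals_oracle <- function(X, y, A) {
  X <- as.matrix(X)
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  E <- sweep(X, 2, x_mean, "-")
  f <- y - y_mean
  Ws <- Ps <- list()
  qs <- numeric(A)
  for (a in 1:A) {
    w <- drop(t(E) %*% f)
    w <- w / sqrt(sum(w * w))
    t_a <- drop(E %*% w)
    p_a <- drop(t(E) %*% t_a) / sum(t_a * t_a)
    q_a <- sum(t_a * f) / sum(t_a * t_a)
    E <- E - outer(t_a, p_a)
    f <- f - q_a * t_a
    Ws[[a]] <- w; Ps[[a]] <- p_a; qs[a] <- q_a
  }
  predict_fn <- function(Xnew) {
    Xnew <- as.matrix(Xnew)
    out <- numeric(nrow(Xnew))
    for (i in seq_len(nrow(Xnew))) {
      e <- Xnew[i, ] - x_mean
      yhat <- y_mean
      for (a in 1:A) {
        t_a <- sum(e * Ws[[a]])
        yhat <- yhat + qs[a] * t_a
        e <- e - t_a * Ps[[a]]
      }
      out[i] <- yhat
    }
    out
  }
  list(predict = predict_fn)
}

# Ordinary least squares through the normal equations, with intercept.
ols_oracle <- function(X, y) {
  X1 <- cbind(1, as.matrix(X))
  beta <- solve(t(X1) %*% X1, t(X1) %*% y)
  function(Xnew) drop(cbind(1, as.matrix(Xnew)) %*% beta)
}
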