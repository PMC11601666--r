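# Single-response partial least squares via NIPALS with X-deflation.
# Components are latent directions maximising covariance between projected
# features and the response; the regression coefficients are recomposed as
# beta = W (P'W)^{-1} q, so prediction is (x - x_mean) . beta + y_mean.

#' Fit a partial least squares regression (NIPALS, single response)
#'
#' @param X Numeric matrix, n x p.
#' @param y Numeric response of length n.
#' @param ncomp Number of latent components A, \code{1 <= A <= min(p, n-1)}.
#' @return A \code{pls_model}: list with \code{ncomp}, \code{x_mean},
#'   \code{y_mean}, \code{weights} (p x A), \code{x_loadings} (p x A),
#'   \code{y_loadings} (length A), and \code{coefficients} (length p).
#' @examples
#' X <- matrix(rnorm(60), 20, 3)
#' y <- X %*% c(1, -2, 0.5) + rnorm(20, sd = 0.1)
#' m <- fit_pls(X, y, ncomp = 3)
#' head(predict(m, X))
#' @export
fit_pls <- function(X, y, ncomp = 3L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  if (anyNA(X) || anyNA(y) || any(!is.finite(X)) || any(!is.finite(y)))
    stop("X and y must be finite", call. = FALSE)
  if (stats::var(y) == 0) stop("response y has zero variance", call. = FALSE)
  A <- as.integer(ncomp)
  if (A < 1L || A > min(p, n - 1L))
    stop(sprintf("ncomp = %d out of range [1, min(p, n-1)] = [1, %d]",
                 A, min(p, n - 1L)), call. = FALSE)

  x_mean <- colMeans(X)
  y_mean <- mean(y)
  E <- sweep(X, 2, x_mean, "-")
  f <- y - y_mean

  W <- matrix(0, p, A)
  P <- matrix(0, p, A)
  q <- numeric(A)
  used <- 0L
  for (a in seq_len(A)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break  # residual X carries no covariance with y left
    w <- w / nw
    t_scores <- as.vector(E %*% w)
    tt <- sum(t_scores^2)
    if (tt < 1e-12) break
    p_a <- as.vector(crossprod(E, t_scores)) / tt
    q_a <- sum(t_scores * f) / tt
    E <- E - tcrossprod(t_scores, p_a)
    f <- f - t_scores * q_a
    W[, a] <- w
    P[, a] <- p_a
    q[a] <- q_a
    used <- a
  }
  if (used == 0L) stop("no usable PLS component (X carries no signal)", call. = FALSE)
  W <- W[, seq_len(used), drop = FALSE]
  P <- P[, seq_len(used), drop = FALSE]
  q <- q[seq_len(used)]
  beta <- as.vector(W %*% solve(crossprod(P, W), q))
  structure(list(ncomp = used, requested_ncomp = A, x_mean = x_mean,
                 y_mean = y_mean, weights = W, x_loadings = P, y_loadings = q,
                 coefficients = beta),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("pls_model: %d component(s), %d predictors\n",
              x$ncomp, length(x$coefficients)))
  invisible(x)
}

#' Predict from a fitted PLS model
#'
#' @param object A \code{pls_model}.
#' @param newdata Numeric matrix (or single row) with the training column
#'   count.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1L) else as.matrix(newdata)
  if (ncol(X) != length(object$coefficients))
    stop(sprintf("newdata has %d columns; model expects %d",
                 ncol(X), length(object$coefficients)), call. = FALSE)
  as.vector(sweep(X, 2, object$x_mean, "-") %*% object$coefficients) + object$y_mean
}

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - \sum(y - \hat y)^2 / \sum(y - \bar y)^2}; can be negative
#' for predictions worse than the mean.
#'
#' @param y Observed values (length >= 2, non-constant).
#' @param y_hat Predicted values.
#' @return Scalar R-squared.
#' @export
r_squared <- function(y, y_hat) {
  check_metric_args(y, y_hat)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("R-squared undefined for zero-variance y", call. = FALSE)
  1 - sum((y - y_hat)^2) / ss_tot
}

#' Root mean square error
#'
#' @inheritParams r_squared
#' @return Scalar RMSE, \code{>= 0}.
#' @export
rmse <- function(y, y_hat) {
  check_metric_args(y, y_hat)
  sqrt(mean((y - y_hat)^2))
}

check_metric_args <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("y and y_hat lengths differ", call. = FALSE)
  if (length(y) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (anyNA(y) || anyNA(y_hat) || any(!is.finite(y)) || any(!is.finite(y_hat)))
    stop("metric inputs must be finite", call. = FALSE)
  invisible(NULL)
}
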