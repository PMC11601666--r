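# k-fold cross-validation, the PLS component sweep, and the comparator
# benchmark. Metrics are computed per fold on the held-out set and then
# averaged (not pooled over concatenated out-of-fold predictions). All
# stochastic learners draw their randomness from a seed derived from the CV
# seed and fold index, so identical calls reproduce identical tables.

with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Assign samples to cross-validation folds
#'
#' Uniform shuffle with an explicit seed, split into k near-equal folds
#' (no stratification). The folds partition \code{1..n}.
#'
#' @param n Sample count.
#' @param k Fold count, \code{2 <= k <= n}.
#' @param seed Integer shuffle seed.
#' @return List of k integer index vectors.
#' @export
make_folds <- function(n, k = 5L, seed = 0L) {
  n <- as.integer(n); k <- as.integer(k)
  if (k < 2L) stop("need k >= 2 folds", call. = FALSE)
  if (k > n) stop(sprintf("k = %d folds exceed n = %d samples", k, n), call. = FALSE)
  idx <- with_local_seed(seed, sample.int(n))
  unname(split(idx, rep(seq_len(k), length.out = n)))  # sizes differ by <= 1
}

#' Cross-validate a regressor
#'
#' For each fold the model is fitted on the complement and scored (R-squared
#' and RMSE) on the held-out fold; the report carries per-fold and mean
#' metrics. Deterministic given \code{(X, y, k, seed, model_factory)}.
#'
#' @param X Feature matrix.
#' @param y Response vector.
#' @param k Fold count (default 5).
#' @param model_factory Function \code{(X, y) -> fitted model}; predictions
#'   are obtained with \code{predict}. See [pls_factory()] and friends.
#' @param seed Fold-assignment seed (default 0).
#' @param folds Optional pre-computed fold list (overrides \code{k}/seed
#'   assignment but is still recorded against them).
#' @return A \code{cv_report}: list with \code{k}, \code{seed},
#'   \code{per_fold} (data.frame r2/rmse), \code{mean_r2}, \code{mean_rmse},
#'   \code{folds}, and \code{predictions} (data.frame index/actual/
#'   predicted/fold).
#' @export
cross_validate <- function(X, y, k = 5L, model_factory = pls_factory(3L),
                           seed = 0L, folds = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%04d", seq_len(ncol(X)))
  y <- as.numeric(y)
  n <- nrow(X)
  if (is.null(folds)) folds <- make_folds(n, k, seed)
  k <- length(folds)
  per_fold <- data.frame(fold = seq_len(k), r2 = NA_real_, rmse = NA_real_)
  preds <- vector("list", k)
  for (i in seq_len(k)) {
    test_i <- folds[[i]]
    train_i <- setdiff(seq_len(n), test_i)
    fit <- with_local_seed(fold_seed(seed, i),
                           model_factory(X[train_i, , drop = FALSE], y[train_i]))
    y_hat <- predict_regressor(fit, X[test_i, , drop = FALSE])
    per_fold$r2[i] <- r_squared(y[test_i], y_hat)
    per_fold$rmse[i] <- rmse(y[test_i], y_hat)
    preds[[i]] <- data.frame(index = test_i, actual = y[test_i],
                             predicted = y_hat, fold = i)
  }
  predictions <- do.call(rbind, preds)
  predictions <- predictions[order(predictions$index), ]
  rownames(predictions) <- NULL
  structure(list(k = k, seed = seed, per_fold = per_fold,
                 mean_r2 = mean(per_fold$r2), mean_rmse = mean(per_fold$rmse),
                 folds = folds, predictions = predictions),
            class = "cv_report")
}

fold_seed <- function(seed, fold) (as.integer(seed) %% 1000000L) * 1009L + fold

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: %d-fold (seed %d)  mean R2 = %.4f  mean RMSE = %.4f\n",
              x$k, x$seed, x$mean_r2, x$mean_rmse))
  invisible(x)
}

#' Sweep the PLS component count
#'
#' Runs one cross-validation per component count with identical folds and
#' selects the count maximising mean held-out R-squared (ties broken toward
#' fewer components).
#'
#' @inheritParams cross_validate
#' @param A_range Integer vector of component counts (default 2:10).
#' @return A \code{sweep_table}: data.frame with columns \code{ncomp},
#'   \code{r2}, \code{rmse}; attributes \code{selected_A}, \code{k},
#'   \code{seed}.
#' @export
component_sweep <- function(X, y, A_range = 2:10, k = 5L, seed = 0L) {
  folds <- make_folds(nrow(as.matrix(X)), k, seed)
  rows <- lapply(A_range, function(A) {
    rep <- cross_validate(X, y, model_factory = pls_factory(A),
                          seed = seed, folds = folds)
    data.frame(ncomp = A, r2 = rep$mean_r2, rmse = rep$mean_rmse)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  selected <- tab$ncomp[which.max(tab$r2)]  # which.max takes the first maximum
  structure(tab, selected_A = selected, k = k, seed = seed,
            class = c("sweep_table", "data.frame"))
}

#' Benchmark the standard comparator regressors
#'
#' Evaluates partial least squares, support-vector regression,
#' random-forest regression, extremely-randomized-trees regression and
#' adaptive-boosting regression on identical folds at library/standard
#' default settings, sorted by mean held-out R-squared (descending). An
#' algorithm failing on a fold is recorded as a failed row without
#' affecting the others.
#'
#' @inheritParams cross_validate
#' @param ncomp PLS component count (default 3; capped at what the feature
#'   matrix supports).
#' @return A \code{benchmark_table} data.frame with columns
#'   \code{algorithm}, \code{r2}, \code{rmse}, \code{status}.
#' @export
benchmark <- function(X, y, k = 5L, seed = 0L, ncomp = 3L) {
  X <- as.matrix(X)
  folds <- make_folds(nrow(X), k, seed)
  ncomp <- min(ncomp, ncol(X), nrow(X) - max(lengths(folds)) - 1L)
  algos <- list(
    `Partial Least Squares` = pls_factory(ncomp),
    `SVR` = svr_factory(),
    `Random Forest` = rf_factory(),
    `Extra Trees` = extra_trees_factory(),
    `AdaBoost` = adaboost_factory()
  )
  rows <- lapply(names(algos), function(nm) {
    res <- tryCatch(cross_validate(X, y, model_factory = algos[[nm]],
                                   seed = seed, folds = folds),
                    error = function(e) e)
    if (inherits(res, "error"))
      data.frame(algorithm = nm, r2 = NA_real_, rmse = NA_real_,
                 status = paste("failed:", conditionMessage(res)))
    else
      data.frame(algorithm = nm, r2 = res$mean_r2, rmse = res$mean_rmse,
                 status = "ok")
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$r2, na.last = TRUE), ]
  rownames(tab) <- NULL
  structure(tab, k = k, seed = seed, class = c("benchmark_table", "data.frame"))
}

# ---- regressor factories ---------------------------------------------------

#' Regressor factories for cross-validation and benchmarking
#'
#' Each factory returns a function \code{(X, y) -> fitted model} usable as
#' the \code{model_factory} of [cross_validate()]. Comparators run at their
#' library defaults; stochastic learners pick up the RNG state the CV loop
#' seeds per fold.
#'
#' @param ncomp PLS component count.
#' @return A function of \code{(X, y)}.
#' @name regressor_factories
NULL

#' @rdname regressor_factories
#' @export
pls_factory <- function(ncomp = 3L) {
  force(ncomp)
  function(X, y) fit_pls(X, y, ncomp = ncomp)
}

#' @rdname regressor_factories
#' @export
svr_factory <- function() {
  function(X, y) e1071::svm(x = X, y = y, type = "eps-regression")
}

#' @rdname regressor_factories
#' @export
rf_factory <- function() {
  function(X, y) randomForest::randomForest(x = X, y = y)
}

#' @rdname regressor_factories
#' @export
extra_trees_factory <- function() {
  function(X, y) {
    df <- as.data.frame(X)
    df$.response <- y
    fit <- ranger::ranger(dependent.variable.name = ".response", data = df,
                          splitrule = "extratrees", num.random.splits = 1L,
                          replace = FALSE, sample.fraction = 1,
                          seed = sample.int(.Machine$integer.max, 1L))
    structure(list(fit = fit, features = colnames(X)), class = "ranger_regressor")
  }
}

#' @rdname regressor_factories
#' @export
adaboost_factory <- function() {
  function(X, y) fit_adaboost_r2(X, y)
}

predict_regressor <- function(model, X) {
  if (inherits(model, "ranger_regressor")) {
    df <- as.data.frame(X)
    as.numeric(stats::predict(model$fit, data = df)$predictions)
  } else {
    as.numeric(stats::predict(model, X))
  }
}

# ---- AdaBoost.R2 (Drucker 1997) over regression trees ----------------------

#' Adaptive-boosting regression (AdaBoost.R2)
#'
#' Boosted shallow regression trees with the linear loss: each round fits a
#' depth-limited tree on a weight-resampled training set, converts absolute
#' errors to a confidence \eqn{\beta_t}, and reweights; prediction is the
#' weighted median of the rounds' predictions with weights
#' \eqn{\log(1/\beta_t)}.
#'
#' @param X Feature matrix.
#' @param y Response.
#' @param n_rounds Maximum boosting rounds (default 50).
#' @param max_depth Tree depth limit (default 3).
#' @return An \code{adaboost_r2} model.
#' @export
fit_adaboost_r2 <- function(X, y, n_rounds = 50L, max_depth = 3L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%04d", seq_len(ncol(X)))
  n <- nrow(X)
  w <- rep(1 / n, n)
  trees <- list()
  betas <- numeric(0)
  df_all <- as.data.frame(X)
  df_all$.response <- y
  ctrl <- rpart::rpart.control(maxdepth = max_depth, minsplit = 2L,
                               minbucket = 1L, cp = 0, xval = 0L)
  for (t in seq_len(n_rounds)) {
    idx <- sample.int(n, n, replace = TRUE, prob = w)
    fit <- rpart::rpart(.response ~ ., data = df_all[idx, , drop = FALSE],
                        method = "anova", control = ctrl)
    pred <- stats::predict(fit, df_all)
    err <- abs(y - pred)
    d_max <- max(err)
    if (d_max == 0) {  # perfect learner: keep it with full confidence, stop
      trees[[length(trees) + 1L]] <- fit
      betas <- c(betas, 1e-10)
      break
    }
    loss <- err / d_max
    ebar <- sum(w * loss)
    if (ebar >= 0.5) break
    beta <- ebar / (1 - ebar)
    trees[[length(trees) + 1L]] <- fit
    betas <- c(betas, beta)
    w <- w * beta^(1 - loss)
    w <- w / sum(w)
  }
  if (length(trees) == 0L) {  # fall back to a single unweighted tree
    fit <- rpart::rpart(.response ~ ., data = df_all, method = "anova",
                        control = ctrl)
    trees <- list(fit)
    betas <- 1 - 1e-10
  }
  structure(list(trees = trees, betas = betas, features = colnames(X)),
            class = "adaboost_r2")
}

#' @export
predict.adaboost_r2 <- function(object, newdata, ...) {
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1L) else as.matrix(newdata)
  colnames(X) <- object$features
  df <- as.data.frame(X)
  preds <- vapply(object$trees, function(tr) stats::predict(tr, df),
                  numeric(nrow(df)))
  preds <- matrix(preds, nrow = nrow(df))
  wts <- log(1 / object$betas)
  apply(preds, 1, weighted_median, w = wts)
}

weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w)
  x[which(cw >= sum(w) / 2)[1]]
}
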