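test_that("folds partition the sample indices into near-equal parts", {
  for (cfg in list(c(20, 5), c(23, 5), c(10, 2), c(7, 7))) {
    folds <- make_folds(cfg[1], cfg[2], seed = 1)
    expect_length(folds, cfg[2])
    all_idx <- sort(unlist(folds))
    expect_equal(all_idx, seq_len(cfg[1]))          # disjoint + exhaustive
    expect_lte(diff(range(lengths(folds))), 1L)     # near-equal sizes
  }
  expect_error(make_folds(4, 5), "exceed")
  expect_error(make_folds(10, 1), "k >= 2")
})

test_that("cross-validation is exact on noiseless linear data", {
  set.seed(20)
  X <- matrix(rnorm(300), 60, 5)
  y <- drop(X %*% c(1, -2, 0.5, 3, -1))
  rep <- cross_validate(X, y, k = 5, model_factory = pls_factory(5), seed = 0)
  expect_gte(rep$mean_r2, 0.999)
  expect_lte(rep$mean_rmse, 1e-6)
})

test_that("cross-validation reports are deterministic and internally consistent", {
  cohort <- shared_cohort()
  X <- cohort$enc$X; y <- cohort$enc$y
  a <- cross_validate(X, y, k = 5, model_factory = pls_factory(3), seed = 42)
  b <- cross_validate(X, y, k = 5, model_factory = pls_factory(3), seed = 42)
  expect_identical(a, b)
  expect_equal(a$mean_r2, mean(a$per_fold$r2), tolerance = 1e-12)
  expect_equal(a$mean_rmse, mean(a$per_fold$rmse), tolerance = 1e-12)
  expect_equal(nrow(a$per_fold), 5L)
  expect_equal(sort(a$predictions$index), seq_len(nrow(X)))
  # a different seed shuffles differently
  c_rep <- cross_validate(X, y, k = 5, model_factory = pls_factory(3), seed = 43)
  expect_false(identical(a$folds, c_rep$folds))
})

test_that("the component sweep selects the generative rank on noiseless data", {
  set.seed(21)
  basis <- matrix(rnorm(20), 10, 2)
  X <- matrix(rnorm(120), 60, 2) %*% t(basis)    # exact rank-2 features
  y <- drop(X %*% rnorm(10))
  sw <- component_sweep(X, y, A_range = 2:8, k = 5, seed = 0)
  expect_equal(nrow(sw), 7L)
  expect_equal(attr(sw, "selected_A"), 2L)       # ties break to fewer comps
})

test_that("the benchmark runs all five regressors on identical folds", {
  # low-dimensional so the piecewise-constant tree learners can also track
  # the noiseless linear surface well
  set.seed(22)
  X <- matrix(rnorm(1000), 500, 2)
  y <- drop(X %*% c(3, -2))
  tab <- benchmark(X, y, k = 5, seed = 1)
  expect_setequal(tab$algorithm,
                  c("Partial Least Squares", "SVR", "Random Forest",
                    "Extra Trees", "AdaBoost"))
  expect_true(all(tab$status == "ok"))
  expect_true(all(tab$r2 >= 0.9))                # easy-problem sanity floor
  expect_true(!is.unsorted(rev(tab$r2)))         # sorted by R2 descending
  tab2 <- benchmark(X, y, k = 5, seed = 1)
  expect_equal(as.data.frame(tab), as.data.frame(tab2))
})

test_that("adaptive boosting fits and predicts deterministically under a seed", {
  set.seed(23)
  X <- matrix(rnorm(200), 100, 2)
  y <- drop(X %*% c(1, 2)) + rnorm(100, sd = 0.2)
  set.seed(99); m1 <- fit_adaboost_r2(X, y)
  set.seed(99); m2 <- fit_adaboost_r2(X, y)
  expect_identical(predict(m1, X), predict(m2, X))
  expect_gte(r_squared(y, predict(m1, X)), 0.8)
})

test_that("held-out accuracy approaches the generative R-squared as n grows", {
  # y = x . beta + noise with var(signal) = var(noise) => generative R2 = 0.5;
  # a 3-component PLS on p = 6 features should approach it from below.
  r2_at <- function(n) {
    mean(sapply(1:5, function(s) {
      set.seed(1000 + s)
      X <- matrix(rnorm(n * 6), n, 6)
      beta <- rnorm(6)
      signal <- drop(X %*% beta)
      y <- signal + rnorm(n, sd = sd(signal))
      cross_validate(X, y, k = 5, model_factory = pls_factory(3),
                     seed = s)$mean_r2
    }))
  }
  r2_small <- r2_at(200)
  r2_large <- r2_at(2000)
  expect_gt(r2_small, 0.5 - 0.15)
  expect_gt(r2_large, 0.5 - 0.05)
  expect_lt(abs(r2_large - 0.5), abs(r2_small - 0.5) + 0.02)
})
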