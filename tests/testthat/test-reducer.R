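test_that("rank-1 input concentrates all variance in the first component", {
  set.seed(3)
  direction <- rnorm(40)
  X <- outer(rnorm(30), direction)  # 30 points on a line in 40-space
  red <- fit_reducer(X, d = 3)
  expect_equal(red$explained_variance_ratio[1], 1, tolerance = 1e-10)
})

test_that("explained variance ratios are a valid, ordered decomposition", {
  X <- random_matrix(30, 15, seed = 4)
  red <- fit_reducer(X, d = 10)
  evr <- red$explained_variance_ratio
  expect_true(all(evr >= 0 & evr <= 1))
  expect_true(all(diff(evr) <= 1e-12))
  expect_lte(sum(evr), 1 + 1e-8)
})

test_that("loadings and variance ratios match a covariance eigendecomposition", {
  for (s in 1:3) {
    X <- random_matrix(30, 12, seed = 100 + s)
    red <- fit_reducer(X, d = 5)
    oracle <- pca_eigen_oracle(X, d = 5)
    expect_equal(unname(red$loadings), unname(oracle$loadings), tolerance = 1e-8)
    expect_equal(red$explained_variance_ratio, oracle$evr, tolerance = 1e-8)
    # orthonormal loading columns
    G <- crossprod(red$loadings)
    expect_equal(unname(G), diag(5), tolerance = 1e-8)
  }
})

test_that("reduction refuses more components than rows support", {
  X <- random_matrix(8, 12, seed = 5)
  expect_error(fit_reducer(X, d = 10), "smaller d")
})

test_that("the d-component reconstruction is as good as the optimal low-rank oracle", {
  X <- random_matrix(25, 12, seed = 6)
  d <- 4
  red <- fit_reducer(X, d = d)
  Z <- sweep(sweep(X, 2, red$mean, "-"), 2, red$scale, "/")
  scores <- Z %*% red$loadings
  resid_d <- sqrt(sum((Z - scores %*% t(red$loadings))^2))
  expect_equal(resid_d, pca_residual_oracle(X, d), tolerance = 1e-8)
  expect_lte(resid_d, pca_residual_oracle(X, d - 1) + 1e-10)
})

test_that("a row at the training mean projects to the zero vector", {
  X <- random_matrix(20, 12, seed = 7)
  red <- fit_reducer(X, d = 4)
  z <- reduce_descriptors(red, colMeans(X))
  expect_equal(unname(as.vector(z)), rep(0, 4), tolerance = 1e-10)
})

test_that("the token map covers the registry with d-vectors", {
  reg <- make_registry(n_ncaa = 28, seed = 1)
  expect_equal(nrow(reg), 48L)  # 20 canonical + 28 NCAA
  desc <- token_descriptor_matrix(reg)
  expect_equal(dim(desc), c(48L, 208L))
  red <- fit_reducer(desc, d = 10)
  map <- build_token_map(reg, red)
  expect_setequal(rownames(map), reg$token)
  expect_equal(ncol(map), 10L)
})

test_that("peptide encoding concatenates and zero-pads to the fixed length", {
  map <- matrix(seq_len(50) / 10, nrow = 5, ncol = 10,
                dimnames = list(c("A", "C", "D", "E", "F"), NULL))
  v9 <- encode_peptide(rep(c("A", "C", "D"), 3), map, L_max = 10)
  expect_length(v9, 100L)
  expect_equal(attr(v9, "n_residues"), 9L)
  expect_equal(v9[91:100], rep(0, 10))
  expect_true(all(v9[1:10] == map["A", ]))

  v10 <- encode_peptide(rep(c("A", "C"), 5), map, L_max = 10)
  expect_length(v10, 100L)
  expect_false(all(v10[91:100] == 0))

  zero_map <- matrix(0, 2, 10, dimnames = list(c("A", "C"), NULL))
  expect_equal(as.vector(encode_peptide(c("A", "C"), zero_map))[1:100],
               rep(0, 100))

  expect_error(encode_peptide(c("A", "Z"), map), "Z")
  expect_error(encode_peptide(rep("A", 11), map, L_max = 10), "L_max")
})

test_that("stripping and re-padding a 9-mer vector reproduces it exactly", {
  map <- matrix(rnorm(80), nrow = 8, ncol = 10,
                dimnames = list(LETTERS[1:8], NULL))
  tokens <- sample(LETTERS[1:8], 9, replace = TRUE)
  v <- encode_peptide(tokens, map, L_max = 10)
  informative <- v[1:90]
  repadded <- c(informative, rep(0, 10))
  expect_identical(unname(repadded), as.numeric(v))
})

test_that("dataset encoding aligns rows, pads 9-mers, and is deterministic", {
  reg <- make_registry(n_ncaa = 5, seed = 2)
  ncaa <- reg$token[is_ncaa_token(reg$token)][1]
  parent <- substr(ncaa, 1, 1)
  code <- sub("^[A-Z]-", "", ncaa)
  name9 <- paste0(paste(rep(parent, 9), collapse = ""), " + ", code, "(", parent, "9)")
  name10 <- paste0(paste(rep(parent, 10), collapse = ""), " + ", code, "(", parent, "1)")
  rec <- data.frame(name = c(name9, name10), qualitative = "Positive",
                    quantitative = c(10, 100), response_measured = "IC50",
                    hla = "HLA-A*02:01", stringsAsFactors = FALSE)
  ds <- affinity_dataset(rec)
  enc <- encode_dataset(ds, reg)
  expect_equal(dim(enc$X), c(2L, 100L))
  expect_equal(unname(enc$X[1, 91:100]), rep(0, 10))  # 9-mer padded
  expect_false(all(enc$X[2, 91:100] == 0))            # 10-mer not padded
  enc2 <- encode_dataset(ds, reg)
  expect_identical(enc$X, enc2$X)

  bad <- rec
  bad$name[1] <- paste0(paste(rep("K", 9), collapse = ""), " + FOO(K3)")
  expect_error(encode_dataset(affinity_dataset(bad), reg), "K-FOO")
})
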