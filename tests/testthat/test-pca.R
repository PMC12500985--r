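test_that("eigenvalues match an independent SVD oracle and sum to p", {
  set.seed(101)
  for (i in 1:15) {
    n <- sample(6:12, 1)
    p <- sample(2:min(n - 1, 10), 1)
    X <- matrix(rnorm(n * p), n, p)
    fit <- fit_pca(X)
    # oracle: squared singular values of the standardized matrix / sqrt(n-1)
    Z <- scale(X) / sqrt(n - 1)
    expect_equal(fit$eigenvalues, sort(svd(Z)$d^2, decreasing = TRUE),
                 tolerance = 1e-8)
    expect_equal(sum(fit$eigenvalues), p, tolerance = 1e-8)
    expect_true(all(diff(fit$eigenvalues) < 1e-12))
    expect_equal(fit$contribution, 100 * fit$eigenvalues / p)
    expect_equal(fit$cumulative[p], 100, tolerance = 1e-8)
  }
})

test_that("uncorrelated columns give near-unit eigenvalues", {
  set.seed(7)
  X <- matrix(rnorm(4000 * 5), 4000, 5)
  fit <- fit_pca(X)
  expect_equal(fit$eigenvalues, rep(1, 5), tolerance = 0.1)
  expect_equal(fit$contribution, rep(20, 5), tolerance = 2)
})

test_that("component scores: centering, variance identity, permutation", {
  set.seed(5)
  X <- matrix(rnorm(30 * 6), 30, 6, dimnames = list(paste0("g", 1:30), NULL))
  fit <- fit_pca(X)
  S <- component_scores(X, fit, m = 6, convention = "eigenvector")
  expect_equal(colMeans(S), setNames(rep(0, 6), paste0("PC", 1:6)),
               tolerance = 1e-12)
  # raw-eigenvector convention: score column j has variance lambda_j
  expect_equal(unname(apply(S, 2, var)), fit$eigenvalues, tolerance = 1e-8)
  # loadings convention scales each column by sqrt(lambda)
  L <- component_scores(X, fit, m = 6, convention = "loadings")
  expect_equal(L, sweep(S, 2, sqrt(fit$eigenvalues), `*`), tolerance = 1e-10)
  # row permutation permutes scores identically
  perm <- sample(30)
  expect_equal(component_scores(X[perm, ], fit, m = 3),
               component_scores(X, fit, m = 3)[perm, ])
  expect_error(component_scores(X, fit, m = 7), "parameter error")
})

test_that("sign convention is deterministic and correlation-invariant", {
  set.seed(12)
  X <- matrix(rnorm(20 * 4), 20, 4)
  f1 <- fit_pca(X); f2 <- fit_pca(X)
  expect_identical(f1$eigenvectors, f2$eigenvectors)
  # each column's largest-magnitude coefficient is positive
  expect_true(all(apply(f1$eigenvectors, 2,
                        function(v) v[which.max(abs(v))] > 0)))
  # positive affine transform of one column leaves eigenvalues unchanged
  Y <- X; Y[, 2] <- 3.7 * X[, 2] + 11
  expect_equal(fit_pca(Y)$eigenvalues, f1$eigenvalues, tolerance = 1e-10)
})

test_that("degenerate inputs are rejected with context", {
  X <- cbind(a = rnorm(10), b = rep(2, 10))
  expect_error(fit_pca(X), "constant column: b")
  expect_error(fit_pca(matrix(1:4, 1)), "at least 2 genotypes")
})

test_that("retention rules: fixed, kaiser on reference eigenvalues, threshold", {
  lam <- hemerocallis_eigenvalues()$eigenvalue
  expect_equal(retain_components(lam, "kaiser"), 4)  # lambda4 = 1.017 > 1
  expect_equal(retain_components(lam, "fixed_m", m = 3), 3)
  expect_equal(retain_components(lam, "cumulative_threshold", threshold = 100),
               13)
  expect_equal(retain_components(lam, "cumulative_threshold", threshold = 74),
               3)
  expect_error(retain_components(lam, "cumulative_threshold", threshold = 0),
               "parameter error")
  expect_error(retain_components(lam, "fixed_m", m = 14), "parameter error")
})

test_that("pca_report writes a parseable JSON bundle", {
  set.seed(2)
  fit <- fit_pca(matrix(rnorm(40), 10, 4,
                        dimnames = list(NULL, letters[1:4])))
  path <- withr::local_tempfile(fileext = ".json")
  pca_report(fit, path)
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(rep$eigenvalues, fit$eigenvalues, tolerance = 1e-12)
  expect_equal(names(rep$loadings), paste0("PC", 1:4))
  expect_equal(rep$index, letters[1:4])
})
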