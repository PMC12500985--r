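test_that("component weights: both denominators and edge cases", {
  lam <- c(4.278, 3.109, 2.241)
  # extracted-sum mode always sums to 1
  expect_equal(sum(component_weights(lam, 3, "extracted_sum")), 1)
  expect_equal(component_weights(lam, 1, "extracted_sum"), 1)
  # total-variance mode is lambda/p
  expect_equal(component_weights(lam, 3, "total_variance_p", p = 13),
               lam / 13)
  expect_error(component_weights(lam, 4), "parameter error")
  expect_error(component_weights(c(0, 0), 2, "extracted_sum"),
               "degenerate error")
})

test_that("composite F is the eigenvalue-weighted mean of component scores", {
  S <- matrix(c(1, 2, 3, 4, 5, 6), 2, 3)
  # equal eigenvalues -> arithmetic mean
  expect_equal(composite_f(S, c(2, 2, 2)), rowMeans(S))
  # single component -> identity
  expect_equal(composite_f(S[, 1, drop = FALSE], 5), S[, 1])
  expect_error(composite_f(S, c(1, 2)), "parameter error")
  expect_error(composite_f(S, c(0, 0, 0)), "degenerate error")

  # reference rows S10 and S15 give near-equal composites (~1.51), by an
  # independent weighted-mean hand computation
  F <- table6_scores()
  lam <- hemerocallis_eigenvalues()$eigenvalue[1:3]
  f10 <- sum(lam * F["S10", ]) / sum(lam)
  f15 <- sum(lam * F["S15", ]) / sum(lam)
  expect_equal(composite_f(F, lam)[c("S10", "S15")],
               c(S10 = f10, S15 = f15))
  expect_equal(round(f10, 2), 1.51)
  expect_equal(round(f15, 2), 1.51)
})

test_that("d_values: membership weighting, ranking and tie handling", {
  S <- rbind(A = c(3, 1), B = c(1, 3), C = c(2, 2), D = c(3, 3))
  st <- d_values(S, weights = c(0.6, 0.4))
  # a genotype maximal on every component reaches D = sum of weights
  expect_equal(st$D[st$genotype == "D"], 1.0)
  expect_equal(st$rank[st$genotype == "D"], 1)
  expect_equal(sort(st$rank), 1:4)
  expect_equal(st$D, as.numeric(cbind(st$mu1, st$mu2) %*% c(0.6, 0.4)))
  # D is non-increasing along rank order
  expect_true(all(diff(st$D[order(st$rank)]) <= 0))

  # exact ties keep input order and are flagged
  S2 <- rbind(A = c(1, 2), B = c(2, 1), C = c(0, 0))
  st2 <- d_values(S2, c(0.5, 0.5))
  expect_equal(st2$rank[1:2], c(1, 2))
  expect_true(all(st2$tied[1:2]))

  # rescaling all weights by a positive constant preserves the order
  st3 <- d_values(S, weights = c(6, 4))
  expect_equal(st3$rank, st$rank)
  expect_equal(st3$D, 10 * st$D)

  expect_error(d_values(S[1, , drop = FALSE], c(1, 1)), "at least 2")
  expect_error(d_values(S, c(-1, 1)), "non-negative")
  # constant score column errors unless the mid policy is chosen
  Sc <- rbind(A = c(1, 5), B = c(2, 5), C = c(3, 5))
  expect_error(d_values(Sc, c(0.5, 0.5)), "degenerate-range")
  stc <- suppressWarnings(d_values(Sc, c(0.5, 0.5), degenerate = "mid"))
  expect_equal(stc$mu2, rep(0.5, 3))
})

test_that("non-extremal dominated genotype leaves existing D values intact", {
  S <- rbind(A = c(3, 1), B = c(1, 3), C = c(2, 2))
  w <- c(0.6, 0.4)
  st <- d_values(S, w)
  # add a genotype inside the per-column ranges: minima/maxima unchanged
  S4 <- rbind(S, Z = c(1.5, 1.5))
  st4 <- d_values(S4, w)
  expect_equal(st4$D[match(rownames(S), st4$genotype)], st$D)
})

test_that("write_score_table emits a rounded report plus raw companion", {
  st <- d_values(rbind(A = c(1.23456, 2), B = c(2, 1)), c(0.329, 0.239))
  path <- withr::local_tempfile(fileext = ".csv")
  write_score_table(st, path)
  rep <- utils::read.csv(path)
  expect_equal(nrow(rep), 3)  # 2 genotypes + weights footer
  expect_equal(rep$genotype[3], "Weights")
  expect_equal(rep$F1[3], 0.329)
  raw <- utils::read.csv(sub("\\.csv$", "_raw.csv", path))
  expect_equal(raw$F1[1], 1.23456)
})
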