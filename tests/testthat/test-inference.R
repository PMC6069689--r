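# Correlation, TOM, partial-correlation and regression methods against
# independent brute-force oracles, plus their documented edge cases.

test_that("correlation scores match the covariance-formula oracle", {
  expr <- expr_fixture(20, 5, seed = 21)
  x <- as.matrix(expr[, -1])
  sc <- infer_correlation(expr, "pearson")
  expected <- oracle_pearson(x)
  diag(expected) <- 0
  expect_equal(unname(score_matrix(sc)), expected, tolerance = 1e-10)

  # spearman = pearson on average ranks
  scs <- infer_correlation(expr, "spearman")
  expected_s <- oracle_pearson(apply(x, 2, rank))
  diag(expected_s) <- 0
  expect_equal(unname(score_matrix(scs)), expected_s, tolerance = 1e-10)
})

test_that("duplicated and negated columns give correlation +1 / -1", {
  x <- withr::with_seed(3, matrix(rnorm(30), 10, 3))
  x <- cbind(x, x[, 1], -x[, 2])
  expr <- expr_from_matrix(x)
  s <- score_matrix(infer_correlation(expr, "pearson"))
  expect_equal(s[1, 4], 1)
  expect_equal(s[2, 5], -1)
  expect_error(infer_correlation(expr_from_matrix(cbind(x, 0)), "pearson"),
               "Zero-variance")
})

test_that("TOM similarity equals the naive triple-loop oracle", {
  expr <- expr_fixture(30, 6, seed = 31)
  sc <- infer_wgcna_tom(expr, beta = 6)
  expected <- oracle_tom(as.matrix(expr[, -1]), beta = 6)
  expect_equal(unname(score_matrix(sc)), expected, tolerance = 1e-10)
  expect_true(all(score_matrix(sc) >= 0 & score_matrix(sc) <= 1))

  # mutually (near) uncorrelated columns: TOM stays small
  big <- expr_fixture(2000, 5, seed = 32)
  expect_lt(max(score_matrix(infer_wgcna_tom(big))), 0.02)
})

test_that("simple partial correlation matches the residual-regression oracle", {
  expr <- expr_fixture(40, 5, seed = 41)
  sc <- infer_partial_correlation(expr, "spc")
  expected <- oracle_pcor_residuals(as.matrix(expr[, -1]))
  expect_equal(unname(score_matrix(sc)), expected, tolerance = 1e-8)
})

test_that("partial correlation separates direct from chain-induced association", {
  # chain x1 -> x2 -> x3: the marginal cor(1,3) is large but vanishes once
  # conditioned on the mediator
  x <- withr::with_seed(42, {
    x1 <- rnorm(500)
    x2 <- x1 + rnorm(500, sd = 0.4)
    cbind(x1, x2, x2 + rnorm(500, sd = 0.4))
  })
  sc <- score_matrix(infer_partial_correlation(expr_from_matrix(x), "spc"))
  marg <- cor(x)
  expect_gt(abs(sc[1, 2]), 0.6)
  expect_gt(abs(sc[2, 3]), 0.6)
  expect_gt(abs(marg[1, 3]), 0.6)
  expect_lt(abs(sc[1, 3]), 0.15)
  expect_lt(abs(sc[1, 3]), abs(marg[1, 3]))
})

test_that("shrinkage partial correlation matches the analytic-lambda oracle", {
  expr <- expr_fixture(25, 6, seed = 51)
  sc <- infer_partial_correlation(expr, "genenet")
  oracle <- oracle_genenet(as.matrix(expr[, -1]))
  expect_equal(unname(score_matrix(sc)), oracle$pcor, tolerance = 1e-8)
  expect_equal(sc$params$lambda, oracle$lambda, tolerance = 1e-8)
})

test_that("graphical lasso satisfies its optimality conditions and limits", {
  expr <- expr_fixture(30, 6, seed = 61)
  x <- scale(as.matrix(expr[, -1]))
  s <- cor(x)
  for (rho in c(0.05, 0.2)) {
    theta <- ppinet:::glasso_fit(s, rho)
    expect_lt(glasso_kkt_gap(s, theta, rho), 1e-4)
  }
  # full-penalization limit: all off-diagonal scores zero
  sc_big <- infer_partial_correlation(expr, "glasso", rho = 2)
  expect_true(all(score_matrix(sc_big) == 0))
  # unpenalized limit with n >> p equals simple partial correlation
  big <- expr_fixture(800, 5, seed = 62)
  g0 <- score_matrix(infer_partial_correlation(big, "glasso", rho = 0))
  spc <- score_matrix(infer_partial_correlation(big, "spc"))
  expect_equal(g0, spc, tolerance = 1e-4)
})

test_that("glmnet-based regression coefficients match a naive coordinate-descent oracle", {
  expr <- expr_fixture(20, 6, seed = 71)
  x <- standardized <- scale(as.matrix(expr[, -1]),
                             scale = apply(as.matrix(expr[, -1]), 2, sd))
  lambda <- 0.1
  for (variant in c("ridge", "lasso", "elasticnet")) {
    alpha <- switch(variant, ridge = 0, lasso = 1, elasticnet = 0.5)
    sc <- infer_regression(expr, variant, lambda = lambda, seed = 1)
    # rebuild the coefficient matrix with the oracle and symmetrize by hand
    p <- ncol(x)
    b <- matrix(0, p, p)
    for (j in seq_len(p)) b[-j, j] <- oracle_enet(x[, -j], x[, j], lambda, alpha)
    s <- matrix(0, p, p)
    for (i in seq_len(p)) for (j in seq_len(p)) {
      if (i != j && sign(b[i, j]) == sign(b[j, i]) && b[i, j] != 0) {
        s[i, j] <- sign(b[i, j]) * sqrt(b[i, j] * b[j, i])
      }
    }
    expect_equal(unname(score_matrix(sc)), s, tolerance = 1e-6,
                 label = paste("symmetrized", variant, "scores"))
  }
})

test_that("PLS coefficients match the Krylov-subspace characterization", {
  expr <- expr_fixture(20, 6, seed = 81)
  x <- scale(as.matrix(expr[, -1]), scale = apply(as.matrix(expr[, -1]), 2, sd))
  for (nc in c(1, 2, 3)) {
    b_pkg <- ppinet:::pls1_coefficients(x[, -1], x[, 1], nc)
    b_oracle <- oracle_pls_krylov(x[, -1], x[, 1], nc)
    expect_equal(b_pkg, b_oracle, tolerance = 1e-8, label = paste("ncomp", nc))
  }
  sc <- infer_regression(expr, "pls", ncomp = 2, seed = 1)
  expect_true(isSymmetric(score_matrix(sc)))
})

test_that("symmetrization zeroes sign-disagreeing coefficient pairs", {
  b <- matrix(0, 3, 3)
  b[1, 2] <- 0.4; b[2, 1] <- -0.3
  b[1, 3] <- 0.5; b[3, 1] <- 0.2
  s <- ppinet:::symmetrize_coefficients(b)
  expect_equal(s[1, 2], 0)
  expect_equal(s[1, 3], sqrt(0.5 * 0.2))
  expect_equal(s[3, 1], s[1, 3])
})

test_that("regression scores vanish across independent blocks and find planted signal", {
  x <- withr::with_seed(91, {
    a <- matrix(rnorm(500 * 2), 500, 2)
    a <- cbind(a, a[, 1] + a[, 2] + rnorm(500, sd = 0.5)) # block 1 with structure
    cbind(a, matrix(rnorm(500 * 2), 500, 2))              # block 2 independent
  })
  sc <- score_matrix(infer_regression(expr_from_matrix(x), "lasso", seed = 2))
  cross <- sc[1:3, 4:5]
  expect_true(all(abs(cross) < 0.05))

  y <- withr::with_seed(92, { x1 <- rnorm(100); cbind(x1, 2 * x1, rnorm(100)) })
  s2 <- score_matrix(infer_regression(expr_from_matrix(y), "ridge", seed = 2))
  expect_gt(s2[1, 2], max(abs(s2[1, 3]), abs(s2[2, 3])))
})

test_that("cross-validated hyperparameters are deterministic given the seed", {
  expr <- expr_fixture(30, 5, seed = 101)
  a <- infer_regression(expr, "elasticnet", seed = 7)
  b <- infer_regression(expr, "elasticnet", seed = 7)
  expect_identical(score_matrix(a), score_matrix(b))
  expect_error(infer_regression(expr, "lasso", folds = 31), "folds")
})

test_that("sample permutation leaves scores unchanged; variable permutation permutes them", {
  expr <- expr_fixture(25, 5, seed = 111)
  perm <- withr::with_seed(1, sample(nrow(expr)))
  for (m in c("PEARSON", "WGCNA", "SPC", "GENENET")) {
    s1 <- score_matrix(infer_network(expr, m))
    s2 <- score_matrix(infer_network(expr[perm, ], m))
    expect_equal(s1, s2, tolerance = 1e-12, label = paste(m, "sample permutation"))
    vp <- c(1, 3, 2, 5, 4)
    s3 <- score_matrix(infer_network(expr[, c(1, 1 + vp)], m))
    expect_equal(unname(s3), unname(s1[vp, vp]), tolerance = 1e-12,
                 label = paste(m, "variable permutation"))
  }
})
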