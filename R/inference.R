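# Correlation, partial-correlation and regression inference methods.
#
# Every method standardizes columns to zero mean / unit variance first and
# returns a ppi_scores object: an exactly symmetric p x p matrix of edge
# scores with a zero diagonal, on (or rescalable to) the correlation scale.

#' Infer an edge-score matrix with one of the fourteen methods
#'
#' Dispatcher over the full method catalogue (see [ppi_methods()]).
#' Mutual-information methods estimate an MI matrix first (see
#' [estimate_mi()]) and then apply their pruning/normalization rule.
#'
#' @param expr Expression tibble (first column sample ids, remaining columns
#'   numeric antibody/protein measurements).
#' @param method One of the identifiers returned by [ppi_methods()].
#' @param seed Integer seed for methods with cross-validated hyperparameters.
#' @param ... Passed on to the method-specific function
#'   ([infer_correlation()], [infer_wgcna_tom()],
#'   [infer_partial_correlation()], [infer_regression()], [estimate_mi()] +
#'   [aracne()]/[clr()]/[mrnet()]).
#' @return A `ppi_scores` object.
#' @export
#' @examples
#' study <- generate_study(p = 10, n = 30, n_conditions = 1, seed = 1)
#' sc <- infer_network(study$expressions[[1]], "PEARSON")
#' dplyr::arrange(tidy(sc), dplyr::desc(abs(score)))
infer_network <- function(expr, method, seed = 1L, ...) {
  method <- toupper(method)
  category <- method_category(method)
  switch(
    category,
    correlation = if (method == "WGCNA") infer_wgcna_tom(expr, ...)
                  else infer_correlation(expr, variant = tolower(method)),
    partial_correlation = infer_partial_correlation(expr, variant = tolower(method), ...),
    regression = infer_regression(expr, variant = tolower(method), seed = seed, ...),
    mutual_information = {
      mi <- estimate_mi(expr, ...)
      switch(method,
             ARACNEA = aracne(mi, mode = "additive"),
             ARACNEM = aracne(mi, mode = "multiplicative"),
             CLR = clr(mi),
             MRNET = mrnet(mi))
    }
  )
}

#' Pairwise correlation scores
#'
#' @param expr Expression tibble.
#' @param variant `"pearson"` or `"spearman"` (Pearson on average ranks).
#' @return A `ppi_scores` object with scores in \[-1, 1\].
#' @export
infer_correlation <- function(expr, variant = c("pearson", "spearman")) {
  variant <- match.arg(variant)
  x <- expr_matrix(expr)
  x <- standardize_cols(x)
  if (variant == "spearman") x <- apply(x, 2L, rank, ties.method = "average")
  r <- cor(x)
  new_ppi_scores(r, toupper(variant), nrow(x))
}

#' Topological overlap (TOM) similarity scores
#'
#' Soft-thresholds the absolute Pearson correlation into an unsigned
#' adjacency `a_ij = |r_ij|^beta` and computes the topological overlap
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k_i = sum_{u != i} a_iu`. Scores lie in \[0, 1\].
#'
#' @param expr Expression tibble.
#' @param beta Soft-threshold exponent (default 6, the usual unsigned
#'   network default).
#' @return A `ppi_scores` object (method id `WGCNA`).
#' @export
infer_wgcna_tom <- function(expr, beta = 6) {
  if (beta <= 0) config_error("`beta` must be positive.")
  x <- standardize_cols(expr_matrix(expr))
  a <- abs(cor(x))^beta
  diag(a) <- 0
  k <- colSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  new_ppi_scores(tom, "WGCNA", nrow(x), params = list(beta = beta))
}

# partial correlations from a precision (or precision-proportional) matrix
prec_to_pcor <- function(omega) {
  d <- sqrt(diag(omega))
  pc <- -omega / tcrossprod(d)
  diag(pc) <- 0
  pc
}

#' Partial-correlation scores (simple, shrunken, graphical lasso)
#'
#' Three estimators of the partial-correlation matrix:
#' * `spc` — plain inversion of the sample correlation matrix (Moore-Penrose
#'   pseudo-inverse when singular and `pseudo_inverse = TRUE`).
#' * `genenet` — Schaefer-Strimmer shrinkage of the correlation matrix
#'   (`r* = (1 - lambda*) r` with the analytic optimal `lambda*`) before
#'   inversion, via \pkg{corpcor}.
#' * `glasso` — L1-penalized maximum-likelihood precision matrix (graphical
#'   lasso); the penalty `rho` defaults to the BIC minimizer over
#'   `c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5)`.
#'
#' @param expr Expression tibble.
#' @param variant `"spc"`, `"genenet"` or `"glasso"`.
#' @param rho Graphical-lasso penalty; `NULL` selects by BIC.
#' @param pseudo_inverse Allow a pseudo-inverse for a singular correlation
#'   matrix under `spc` (an error is raised otherwise).
#' @return A `ppi_scores` object with partial correlations in \[-1, 1\].
#' @export
infer_partial_correlation <- function(expr, variant = c("spc", "genenet", "glasso"),
                                      rho = NULL, pseudo_inverse = TRUE) {
  variant <- match.arg(variant)
  x <- standardize_cols(expr_matrix(expr))
  n <- nrow(x)
  r <- cor(x)
  if (variant == "spc") {
    omega <- tryCatch(solve(r), error = function(e) NULL)
    if (is.null(omega)) {
      if (!pseudo_inverse) {
        numeric_error("Singular correlation matrix; set pseudo_inverse = TRUE to use the Moore-Penrose inverse.")
      }
      omega <- MASS::ginv(r)
      dimnames(omega) <- dimnames(r)
    }
    pc <- prec_to_pcor(omega)
    return(new_ppi_scores(pc, "SPC", n))
  }
  if (variant == "genenet") {
    pc <- suppressWarnings(corpcor::pcor.shrink(x, verbose = FALSE))
    lambda <- attr(pc, "lambda")
    pc <- as.matrix(pc[, ])
    dimnames(pc) <- dimnames(r)
    return(new_ppi_scores(pc, "GENENET", n, params = list(lambda = lambda)))
  }
  # graphical lasso
  grid <- c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5)
  if (is.null(rho)) {
    fits <- lapply(grid, function(g) glasso_fit(r, g))
    bic <- vapply(seq_along(grid), function(i) {
      th <- fits[[i]]
      df <- sum(th[upper.tri(th)] != 0)
      ll <- determinant(th, logarithm = TRUE)$modulus - sum(diag(r %*% th))
      -n * as.numeric(ll) + log(n) * df
    }, numeric(1L))
    best <- which.min(bic)
    theta <- fits[[best]]
    rho <- grid[best]
  } else {
    if (rho < 0) config_error("`rho` must be non-negative.")
    theta <- glasso_fit(r, rho)
  }
  dimnames(theta) <- dimnames(r)
  pc <- prec_to_pcor(theta)
  new_ppi_scores(pc, "GLASSO", n, params = list(rho = rho))
}

# Graphical lasso: maximize log det(Theta) - tr(S Theta) - rho ||Theta||_1
# (off-diagonal penalty), by block coordinate descent on the covariance
# estimate W (Friedman et al. 2008). rho = 0 falls back to plain inversion.
glasso_fit <- function(s, rho, tol = 1e-7, maxit = 200L) {
  p <- ncol(s)
  if (rho <= 0) return(solve(s))
  w <- s + rho * diag(p)
  b <- matrix(0, p, p)
  off <- mean(abs(s[upper.tri(s)]))
  if (!is.finite(off) || off == 0) off <- 1
  for (it in seq_len(maxit)) {
    w_prev <- w
    for (j in seq_len(p)) {
      idx <- setdiff(seq_len(p), j)
      w11 <- w[idx, idx, drop = FALSE]
      s12 <- s[idx, j]
      beta <- b[idx, j]
      # lasso subproblem: min 1/2 b' W11 b - s12' b + rho |b|_1
      repeat {
        delta <- 0
        for (k in seq_along(idx)) {
          zk <- s12[k] - sum(w11[k, ] * beta) + w11[k, k] * beta[k]
          new <- soft_threshold(zk, rho) / w11[k, k]
          delta <- max(delta, abs(new - beta[k]))
          beta[k] <- new
        }
        if (delta < tol) break
      }
      b[idx, j] <- beta
      w12 <- drop(w11 %*% beta)
      w[idx, j] <- w12
      w[j, idx] <- w12
    }
    if (mean(abs(w - w_prev)) < tol * off) break
  }
  theta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- setdiff(seq_len(p), j)
    beta <- b[idx, j]
    t22 <- 1 / (w[j, j] - sum(w[idx, j] * beta))
    theta[j, j] <- t22
    theta[idx, j] <- -beta * t22
  }
  theta <- (theta + t(theta)) / 2
  # exact zeros for pairs never selected by the lasso subproblems
  zero <- b == 0 & t(b) == 0
  diag(zero) <- FALSE
  theta[zero] <- 0
  theta
}

#' Regression-based scores (PLS, ridge, lasso, elastic net)
#'
#' Regresses every standardized column on all other columns and symmetrizes
#' the two coefficients of each pair into a single score: the
#' sign-consistent geometric mean `sign(b_ij) * sqrt(b_ij * b_ji)` when the
#' signs agree (and are non-zero), and 0 otherwise. Hyperparameters (number
#' of PLS components; glmnet penalty for ridge/lasso/elastic net, mixing
#' fixed at 0.5 for the elastic net) are chosen by k-fold cross-validated
#' prediction error with seeded fold assignment, unless pinned via `lambda`
#' / `ncomp`.
#'
#' @param expr Expression tibble.
#' @param variant `"pls"`, `"ridge"`, `"lasso"` or `"elasticnet"`.
#' @param folds Number of cross-validation folds (default 10; must be
#'   between 2 and the sample count).
#' @param seed Integer seed for the fold assignment.
#' @param lambda Optional fixed glmnet penalty (skips cross-validation).
#' @param ncomp Optional fixed number of PLS components.
#' @return A `ppi_scores` object.
#' @export
infer_regression <- function(expr, variant = c("pls", "ridge", "lasso", "elasticnet"),
                             folds = 10L, seed = 1L, lambda = NULL, ncomp = NULL) {
  variant <- match.arg(variant)
  x <- standardize_cols(expr_matrix(expr))
  n <- nrow(x); p <- ncol(x)
  if (folds < 2L || folds > n) {
    config_error(sprintf("`folds` must be between 2 and the sample count (%d).", n))
  }
  foldid <- withr::with_seed(seed, sample(rep_len(seq_len(folds), n)))
  bmat <- matrix(0, p, p, dimnames = list(colnames(x), colnames(x)))
  params <- list(folds = folds, seed = seed)
  if (variant == "pls") {
    max_comp <- if (!is.null(ncomp)) ncomp else min(p - 1L, n - 2L, 10L)
    chosen <- integer(p)
    for (j in seq_len(p)) {
      z <- x[, -j, drop = FALSE]; y <- x[, j]
      nc <- if (!is.null(ncomp)) ncomp else cv_pls_ncomp(z, y, max_comp, foldid)
      chosen[j] <- nc
      bmat[-j, j] <- pls1_coefficients(z, y, nc)
    }
    params$ncomp <- chosen
  } else {
    alpha <- switch(variant, ridge = 0, lasso = 1, elasticnet = 0.5)
    chosen <- numeric(p)
    for (j in seq_len(p)) {
      z <- x[, -j, drop = FALSE]; y <- x[, j]
      if (!is.null(lambda)) {
        lam <- lambda
      } else {
        cvfit <- glmnet::cv.glmnet(z, y, alpha = alpha, foldid = foldid,
                                   standardize = FALSE, intercept = FALSE,
                                   thresh = 1e-12)
        lam <- cvfit$lambda.min
      }
      fit <- glmnet::glmnet(z, y, alpha = alpha, lambda = lam,
                            standardize = FALSE, intercept = FALSE,
                            thresh = 1e-12)
      bmat[-j, j] <- as.numeric(fit$beta)
      chosen[j] <- lam
    }
    params$lambda <- chosen
    params$alpha <- alpha
  }
  scores <- symmetrize_coefficients(bmat)
  new_ppi_scores(scores, toupper(variant), n, params = params)
}

# sign-consistent geometric-mean symmetrization of a coefficient matrix
symmetrize_coefficients <- function(b) {
  bt <- t(b)
  agree <- sign(b) == sign(bt) & b != 0
  s <- matrix(0, nrow(b), ncol(b), dimnames = dimnames(b))
  s[agree] <- sign(b[agree]) * sqrt(b[agree] * bt[agree])
  s
}

# PLS1 regression coefficients via NIPALS on centered, standardized data.
pls1_coefficients <- function(z, y, ncomp) {
  p <- ncol(z)
  ncomp <- min(ncomp, p, nrow(z) - 1L)
  wmat <- pmat <- matrix(0, p, ncomp)
  q <- numeric(ncomp)
  e <- z; f <- y
  used <- 0L
  for (h in seq_len(ncomp)) {
    w <- drop(crossprod(e, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_h <- drop(e %*% w)
    tt <- sum(t_h^2)
    if (tt < 1e-12) break
    p_h <- drop(crossprod(e, t_h)) / tt
    q_h <- sum(f * t_h) / tt
    e <- e - tcrossprod(t_h, p_h)
    f <- f - q_h * t_h
    wmat[, h] <- w; pmat[, h] <- p_h; q[h] <- q_h
    used <- h
  }
  if (used == 0L) return(numeric(p))
  wmat <- wmat[, seq_len(used), drop = FALSE]
  pmat <- pmat[, seq_len(used), drop = FALSE]
  q <- q[seq_len(used)]
  drop(wmat %*% solve(crossprod(pmat, wmat), q))
}

cv_pls_ncomp <- function(z, y, max_comp, foldid) {
  folds <- sort(unique(foldid))
  press <- numeric(max_comp)
  for (f in folds) {
    tr <- foldid != f
    if (sum(tr) < 3L) next
    ztr <- scale(z[tr, , drop = FALSE], scale = FALSE)
    ytr <- y[tr] - mean(y[tr])
    zte <- scale(z[!tr, , drop = FALSE],
                 center = attr(ztr, "scaled:center"), scale = FALSE)
    for (nc in seq_len(max_comp)) {
      bc <- pls1_coefficients(ztr, ytr, nc)
      pred <- drop(zte %*% bc) + mean(y[tr])
      press[nc] <- press[nc] + sum((y[!tr] - pred)^2)
    }
  }
  which.min(press)
}
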