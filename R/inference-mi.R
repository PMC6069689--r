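# Mutual-information estimation and the MI-based inference methods
# (ARACNE additive/multiplicative, CLR, MRNET).

#' Estimate a pairwise mutual-information matrix
#'
#' Two estimators:
#' * `empirical_equalfreq` — each column is discretized into `bins`
#'   equal-frequency bins and MI is computed from the joint histogram
#'   (natural log).
#' * `gaussian` — `MI = -1/2 * log(1 - r^2)` with `r` the Pearson
#'   correlation; `r^2` is capped at `1 - 1e-12` so duplicated antibodies
#'   yield a large finite value instead of infinity.
#'
#' @param expr Expression tibble (at least 5 samples).
#' @param estimator `"empirical_equalfreq"` or `"gaussian"`.
#' @param bins Number of equal-frequency bins (default `ceiling(sqrt(n))`).
#' @return A `ppi_mi` object: non-negative symmetric MI matrix with zero
#'   diagonal plus estimator metadata.
#' @export
estimate_mi <- function(expr, estimator = c("empirical_equalfreq", "gaussian"),
                        bins = NULL) {
  estimator <- match.arg(estimator)
  x <- expr_matrix(expr, min_n = 5L)
  n <- nrow(x); p <- ncol(x)
  if (estimator == "gaussian") {
    x <- standardize_cols(x)
    r2 <- pmin(cor(x)^2, 1 - 1e-12)
    mi <- -0.5 * log(1 - r2)
    bins <- NA_integer_
  } else {
    bins <- bins %||% ceiling(sqrt(n))
    if (bins < 2L) config_error("`bins` must be at least 2.")
    disc <- apply(x, 2L, function(col) {
      b <- ceiling(rank(col, ties.method = "average") * bins / n)
      pmin(pmax(b, 1L), bins)
    })
    mi <- matrix(0, p, p, dimnames = list(colnames(x), colnames(x)))
    for (i in seq_len(p - 1L)) {
      for (j in (i + 1L):p) {
        mi[i, j] <- mi[j, i] <- histogram_mi(disc[, i], disc[, j], bins)
      }
    }
  }
  diag(mi) <- 0
  mi[mi < 0] <- 0
  structure(list(mi = mi, estimator = estimator, bins = bins, n = n,
                 variable_ids = colnames(x)),
            class = "ppi_mi")
}

# plug-in MI (nats) from two integer-coded vectors
histogram_mi <- function(a, b, bins) {
  joint <- table(factor(a, levels = seq_len(bins)),
                 factor(b, levels = seq_len(bins))) / length(a)
  pa <- rowSums(joint); pb <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / outer(pa, pb)[nz]))
}

#' @export
print.ppi_mi <- function(x, ...) {
  cat(sprintf("<ppi_mi> %s estimator, %d variables, n = %d%s\n",
              x$estimator, length(x$variable_ids), x$n,
              if (is.na(x$bins)) "" else sprintf(", %d bins", x$bins)))
  invisible(x)
}

as_mi_matrix <- function(mi) {
  if (inherits(mi, "ppi_mi")) return(mi$mi)
  if (is.matrix(mi) && nrow(mi) == ncol(mi)) {
    m <- (mi + t(mi)) / 2
    diag(m) <- 0
    if (any(m < 0)) config_error("MI values must be non-negative.")
    if (is.null(colnames(m))) {
      dimnames(m) <- list(paste0("V", seq_len(ncol(m))), paste0("V", seq_len(ncol(m))))
    }
    return(m)
  }
  config_error("`mi` must be a ppi_mi object or a symmetric non-negative matrix.")
}

mi_n <- function(mi) if (inherits(mi, "ppi_mi")) mi$n else NA_integer_

#' ARACNE: prune indirect edges by the data-processing inequality
#'
#' For every ordered triple the weakest of the three MI values is removed:
#' edge (i, j) is zeroed when some third variable k satisfies
#' `mi_ij < min(mi_ik, mi_jk) - eps` (additive mode) or
#' `mi_ij < min(mi_ik, mi_jk) * (1 - eps)` (multiplicative mode). All
#' triples are evaluated against the original MI matrix and removals are
#' applied simultaneously; surviving edges keep their MI as score.
#'
#' @param mi A `ppi_mi` object or non-negative symmetric matrix.
#' @param mode `"additive"` or `"multiplicative"`.
#' @param eps Non-negative DPI tolerance (default 0).
#' @return A `ppi_scores` object (method `ARACNEA` or `ARACNEM`).
#' @export
aracne <- function(mi, mode = c("additive", "multiplicative"), eps = 0) {
  mode <- match.arg(mode)
  if (eps < 0) config_error("`eps` must be non-negative.")
  m <- as_mi_matrix(mi)
  p <- ncol(m)
  removed <- matrix(FALSE, p, p)
  for (k in seq_len(p)) {
    colk <- matrix(m[, k], p, p)            # colk[i, j] = mi_ik
    floor_k <- pmin(colk, t(colk))          # min(mi_ik, mi_jk)
    cond <- if (mode == "additive") m < floor_k - eps else m < floor_k * (1 - eps)
    cond[k, ] <- FALSE; cond[, k] <- FALSE  # k must be a third variable
    removed <- removed | cond
  }
  out <- m
  out[removed] <- 0
  diag(out) <- 0
  new_ppi_scores(out, if (mode == "additive") "ARACNEA" else "ARACNEM",
                 mi_n(mi), params = list(eps = eps, mode = mode))
}

#' CLR: context likelihood of relatedness
#'
#' Z-scores each MI value against the background MI distribution of both
#' variables: with `mu_i`, `sigma_i` the mean and standard deviation of
#' `{mi_ik : k != i}` and `z_i(j) = max(0, (mi_ij - mu_i) / sigma_i)`, the
#' score is `sqrt(z_i(j)^2 + z_j(i)^2)`. A zero standard deviation
#' contributes 0.
#'
#' @param mi A `ppi_mi` object or non-negative symmetric matrix (at least 3
#'   variables).
#' @return A `ppi_scores` object (method `CLR`).
#' @export
clr <- function(mi) {
  m <- as_mi_matrix(mi)
  p <- ncol(m)
  if (p < 3L) config_error("CLR needs at least 3 variables.")
  off <- m; diag(off) <- NA
  mu <- rowMeans(off, na.rm = TRUE)
  sg <- apply(off, 1L, sd, na.rm = TRUE)
  z <- (m - mu) / ifelse(sg > 0, sg, Inf)
  z[sg == 0, ] <- 0
  z <- pmax(z, 0)
  s <- sqrt(z^2 + t(z)^2)
  diag(s) <- 0
  new_ppi_scores(s, "CLR", mi_n(mi))
}

#' MRNET: maximum relevance / minimum redundancy network
#'
#' For each target variable a greedy forward MRMR selection ranks the other
#' variables: the first pick maximizes relevance `mi_kj`; subsequent picks
#' maximize `u_k = mi_kj - mean(mi_ks over already-selected s)`; selection
#' stops when the best available `u` is not positive. Each selected
#' variable keeps the `u` it had at selection, and the symmetric edge score
#' is `max(u_i^(target j), u_j^(target i), 0)`. Ties are broken towards the
#' lowest variable index.
#'
#' @param mi A `ppi_mi` object or non-negative symmetric matrix (at least 3
#'   variables).
#' @return A `ppi_scores` object (method `MRNET`).
#' @export
mrnet <- function(mi) {
  m <- as_mi_matrix(mi)
  p <- ncol(m)
  if (p < 3L) config_error("MRNET needs at least 3 variables.")
  u <- matrix(0, p, p)  # u[i, j] = score of predictor i for target j
  for (j in seq_len(p)) {
    cand <- setdiff(seq_len(p), j)
    selected <- integer(0)
    rel <- m[cand, j]
    red <- numeric(length(cand))
    while (length(cand)) {
      crit <- rel - if (length(selected)) red / length(selected) else 0
      best <- which.max(crit)   # which.max returns the first (lowest index) max
      if (crit[best] <= 0 && length(selected)) break
      if (length(selected) == 0L && crit[best] <= 0) break
      u[cand[best], j] <- crit[best]
      red <- red + m[cand, cand[best]]
      selected <- c(selected, cand[best])
      rel <- rel[-best]; red <- red[-best]; cand <- cand[-best]
    }
  }
  s <- pmax(u, t(u), 0)
  dimnames(s) <- dimnames(m)
  new_ppi_scores(s, "MRNET", mi_n(mi))
}
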