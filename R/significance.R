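# Significance filtering of score matrices.
#
# Non-MI methods: each pair score is referred to the Gaussian graphical
# model null for a partial correlation of a null (absent) edge,
#   f(r; kappa) ∝ (1 - r^2)^((kappa - 3) / 2),  r in [-1, 1],
# with the effective degree-of-freedom parameter kappa estimated by maximum
# likelihood treating all p(p-1)/2 observed scores as draws from the
# null-dominated mixture. Equivalently r^2 ~ Beta(1/2, (kappa - 1)/2), so
# the two-sided tail beyond |r| is pbeta(r^2, 1/2, (kappa-1)/2, lower = FALSE).
# MI methods use their own criterion: keep scores strictly greater than 0.

#' Fit the GGM null distribution to a set of scores
#'
#' Maximum-likelihood estimate of the null degree-of-freedom parameter
#' `kappa` of the density `f(r) ∝ (1 - r^2)^((kappa - 3)/2)` from observed
#' pair scores. Scores with `|r| >= 1` carry no likelihood information and
#' are excluded from the fit. When the ML optimization fails the analytic
#' fallback `kappa = n - 1 - (p - 2)` is used (when `n` and `p` are known).
#'
#' @param r Numeric vector of scores in \[-1, 1\].
#' @param fallback_kappa Value used when the ML fit fails (may be `NA`).
#' @return A list with elements `kappa` and `converged`.
#' @export
fit_ggm_null <- function(r, fallback_kappa = NA_real_) {
  r <- r[is.finite(r)]
  if (length(r) < 3L) numeric_error("Too few scores to fit the GGM null.")
  if (max(r) - min(r) < .Machine$double.eps^0.5) {
    numeric_error("Degenerate null fit: all scores identical.")
  }
  rr <- r[abs(r) < 1]
  # negative log-likelihood of kappa; log normalizer of the r-density is
  # log Gamma(kappa/2) - log Gamma((kappa-1)/2) - log sqrt(pi)
  nll <- function(log_k) {
    k <- exp(log_k) + 1
    -(length(rr) * (lgamma(k / 2) - lgamma((k - 1) / 2) - 0.5 * log(pi)) +
        (k - 3) / 2 * sum(log1p(-rr^2)))
  }
  fit <- tryCatch(optimize(nll, interval = c(log(1e-4), log(1e8))),
                  error = function(e) NULL)
  kappa <- if (!is.null(fit) && is.finite(fit$objective)) exp(fit$minimum) + 1 else NA_real_
  if (!is.na(kappa) && (kappa > 0.99e8 || kappa < 1 + 1e-4)) kappa <- NA_real_
  if (is.na(kappa)) {
    if (is.na(fallback_kappa)) numeric_error("GGM null fit failed and no fallback kappa available.")
    return(list(kappa = fallback_kappa, converged = FALSE))
  }
  list(kappa = kappa, converged = TRUE)
}

#' Two-sided GGM null p-value of a partial-correlation-scale score
#'
#' @param r Scores in \[-1, 1\].
#' @param kappa Null degree-of-freedom parameter.
#' @return `P(|R| >= |r|)` under the null density.
#' @export
ggm_null_pvalue <- function(r, kappa) {
  pbeta(pmin(r^2, 1), 0.5, (kappa - 1) / 2, lower.tail = FALSE)
}

#' Draw scores from the GGM null density
#'
#' Utility for calibration checks: samples `r` with `r^2 ~ Beta(1/2,
#' (kappa-1)/2)` and a random sign.
#'
#' @param m Number of draws.
#' @param kappa Null parameter.
#' @return Numeric vector of length `m`.
#' @export
rggm_null <- function(m, kappa) {
  r2 <- stats::rbeta(m, 0.5, (kappa - 1) / 2)
  sqrt(r2) * sample(c(-1, 1), m, replace = TRUE)
}

# Bring a method's scores onto the correlation scale in [-1, 1]:
# scores already in [-1, 1] pass through; otherwise everything is divided
# by the maximum absolute score (a score of magnitude > 1 cannot be a
# correlation). Non-negative-score methods (e.g. TOM) are treated as |r|.
rescale_to_correlation <- function(s) {
  mx <- max(abs(s))
  if (mx > 1) s <- s / mx
  s
}

#' GGM edge p-values for a score matrix
#'
#' Rescales the method's scores onto the correlation scale (see Details of
#' [filter_predictions()]), fits the null by maximum likelihood and returns
#' a two-sided null-tail p-value per variable pair.
#'
#' @param scores A `ppi_scores` object from a correlation,
#'   partial-correlation or regression method.
#' @param n Sample count (defaults to the count recorded in `scores`).
#' @return Tibble with columns `from`, `to`, `score`, `p_value`, plus the
#'   fitted `kappa` as an attribute.
#' @export
ggm_edge_pvalues <- function(scores, n = NULL) {
  if (!inherits(scores, "ppi_scores")) config_error("`scores` must be a ppi_scores object.")
  if (scores$category == "mutual_information") {
    config_error("MI-based methods are filtered by their own score > 0 criterion, not GGM p-values.")
  }
  n <- n %||% scores$n
  p <- length(scores$variable_ids)
  edges <- upper_pairs(scores$scores)
  r <- rescale_to_correlation(edges$score)
  fallback <- if (is.finite(n)) n - 1 - (p - 2) else NA_real_
  fit <- fit_ggm_null(r, fallback_kappa = fallback)
  edges$p_value <- ggm_null_pvalue(r, fit$kappa)
  attr(edges, "kappa") <- fit$kappa
  attr(edges, "converged") <- fit$converged
  edges
}

#' Filter a score matrix into a significant predicted network
#'
#' Mutual-information methods keep every pair with score strictly greater
#' than 0 (their own pruning already embodies the significance criterion).
#' All other methods keep pairs whose two-sided GGM null p-value is below
#' `alpha`. Scores of filtered-in edges are preserved as edge weights.
#'
#' @details Method scores that are not partial correlations are mapped onto
#' the correlation scale before the null fit: if any score exceeds 1 in
#' magnitude, all scores are divided by the maximum absolute score;
#' non-negative scores (e.g. TOM similarity) are treated as absolute
#' correlations. The null fit is per method and per dataset.
#'
#' @param scores A `ppi_scores` object.
#' @param alpha Significance threshold for non-MI methods (default 0.05).
#' @param n Sample count override (defaults to the count in `scores`).
#' @return A network tibble (`from`, `to`, `weight`, and `p_value` for
#'   non-MI methods) with attributes `method` and `alpha`.
#' @export
#' @examples
#' study <- generate_study(p = 8, n = 40, n_conditions = 1, seed = 7)
#' sc <- infer_network(study$expressions[[1]], "GENENET")
#' filter_predictions(sc, alpha = 0.05)
filter_predictions <- function(scores, alpha = 0.05, n = NULL) {
  if (!inherits(scores, "ppi_scores")) config_error("`scores` must be a ppi_scores object.")
  if (alpha < 0 || alpha > 1) config_error("`alpha` must lie in [0, 1].")
  if (scores$category == "mutual_information") {
    edges <- upper_pairs(scores$scores)
    out <- edges[edges$score > 0, , drop = FALSE]
    names(out)[names(out) == "score"] <- "weight"
  } else if (all(scores$scores == 0)) {
    # fully shrunken / fully penalized fit: nothing to test, no predictions
    out <- tibble(from = character(), to = character(),
                  weight = numeric(), p_value = numeric())
  } else {
    edges <- ggm_edge_pvalues(scores, n = n)
    out <- edges[edges$p_value < alpha, , drop = FALSE]
    names(out)[names(out) == "score"] <- "weight"
    attr(out, "kappa") <- attr(edges, "kappa")
  }
  out <- out[order(out$from, out$to), , drop = FALSE]
  attr(out, "method") <- scores$method
  attr(out, "alpha") <- alpha
  out
}
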