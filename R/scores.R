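# The ppi_scores container: one method's symmetric edge-score matrix.

new_ppi_scores <- function(scores, method, n, params = list()) {
  stopifnot(is.matrix(scores), nrow(scores) == ncol(scores))
  scores <- (scores + t(scores)) / 2    # enforce exact symmetry
  diag(scores) <- 0
  structure(
    list(scores = scores, method = method,
         category = method_category(method),
         variable_ids = colnames(scores), n = n, params = params),
    class = "ppi_scores"
  )
}

#' @export
print.ppi_scores <- function(x, ...) {
  cat(sprintf("<ppi_scores> method %s (%s), %d variables, n = %d samples\n",
              x$method, x$category, length(x$variable_ids), x$n))
  nz <- sum(x$scores[upper.tri(x$scores)] != 0)
  cat(sprintf("  non-zero pair scores: %d of %d\n", nz,
              n_pairs(x$variable_ids)))
  invisible(x)
}

#' Tidy a score matrix into an edge tibble
#'
#' @param x A `ppi_scores` object.
#' @param ... Unused.
#' @return Tibble with one row per unordered variable pair: `from`, `to`,
#'   `score`.
#' @export
tidy.ppi_scores <- function(x, ...) {
  upper_pairs(x$scores)
}

#' One-row summary of a score matrix
#'
#' @param x A `ppi_scores` object.
#' @param ... Unused.
#' @return Tibble with method, category, dimensions and score summaries.
#' @export
glance.ppi_scores <- function(x, ...) {
  s <- x$scores[upper.tri(x$scores)]
  tibble(method = x$method, category = x$category,
         n_variables = length(x$variable_ids), n_samples = x$n,
         n_nonzero = sum(s != 0), max_abs_score = if (length(s)) max(abs(s)) else NA_real_)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
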