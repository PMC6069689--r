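# Consensus ensemble networks from the set of best methods.

#' Collect the global set of best methods across conditions
#'
#' @param best Either a named character vector (condition -> method id) or
#'   a data frame with columns `condition` and `method`.
#' @return Deduplicated method ids ordered by the canonical listing order.
#' @export
collect_best_methods <- function(best) {
  ids <- if (is.data.frame(best)) as.character(best$method) else as.character(best)
  if (!length(ids)) config_error("`best` must be non-empty.")
  method_category(ids)  # validates
  ids <- unique(ids)
  ids[order(method_rank(ids))]
}

#' Build a consensus ensemble network
#'
#' Starting from all `C(|universe|, 2)` pairs at score 0, each of the `m`
#' best methods that predicts a pair adds `1/m` to its score; pairs with
#' score 0 are removed. The resulting score is the fraction of best
#' methods supporting each edge, in `{1/m, ..., 1}`.
#'
#' @param predictions Named list of predicted network tibbles (one per
#'   method id; must cover every id in `bm`).
#' @param bm Character vector of best-method ids forming the ensemble.
#' @param universe Gene universe the predictions live on.
#' @return A `ppi_ensemble` tibble: `from`, `to`, `score`, `n_methods`,
#'   with attributes `m` (ensemble size) and `methods`.
#' @export
#' @examples
#' preds <- list(A = tibble::tibble(from = "G1", to = "G2"),
#'               B = tibble::tibble(from = c("G1", "G1"), to = c("G2", "G3")))
#' names(preds) <- c("CLR", "PLS")
#' build_ensemble(preds, bm = c("CLR", "PLS"), universe = c("G1", "G2", "G3"))
build_ensemble <- function(predictions, bm, universe) {
  bm <- collect_best_methods(bm)
  missing <- setdiff(bm, names(predictions))
  if (length(missing)) {
    config_error(paste0("No prediction supplied for best method(s): ",
                        paste(missing, collapse = ", ")))
  }
  universe <- sort(unique(toupper(universe)))
  m <- length(bm)
  keys <- character(0)
  for (id in bm) {
    net <- predictions[[id]]
    nodes <- network_nodes(net)
    if (length(setdiff(nodes, universe))) {
      data_error(sprintf("Prediction of %s has node(s) outside the universe.", id))
    }
    keys <- c(keys, unique(pair_key(net$from, net$to)))
  }
  if (!length(keys)) {
    out <- tibble(from = character(), to = character(),
                  score = numeric(), n_methods = integer())
  } else {
    tab <- table(keys)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    out <- tibble(from = vapply(parts, `[[`, "", 1L),
                  to = vapply(parts, `[[`, "", 2L),
                  score = as.numeric(tab) / m,
                  n_methods = as.integer(tab))
    out <- out[order(out$from, out$to), ]
  }
  structure(out, m = m, methods = bm,
            class = c("ppi_ensemble", class(out)))
}

#' @export
tidy.ppi_ensemble <- function(x, ...) as_tibble(x)

#' One-row summary of an ensemble network
#'
#' @param x A `ppi_ensemble` tibble.
#' @param ... Unused.
#' @return Tibble with ensemble size, edge count and score summaries.
#' @export
glance.ppi_ensemble <- function(x, ...) {
  tibble(n_methods = attr(x, "m"),
         methods = paste(attr(x, "methods"), collapse = ","),
         n_edges = nrow(x),
         mean_score = if (nrow(x)) mean(x$score) else NA_real_,
         n_unanimous = sum(x$score == 1))
}

#' Write an ensemble network as TSV
#'
#' Columns geneA, geneB, score (4 decimals), n_methods, in canonical edge
#' order.
#'
#' @param ens A `ppi_ensemble` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ens, path) {
  body <- if (nrow(ens)) {
    paste(ens$from, ens$to, sprintf("%.4f", ens$score), ens$n_methods, sep = "\t")
  } else character()
  writeLines(c("geneA\tgeneB\tscore\tn_methods", body), path)
  invisible(path)
}
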