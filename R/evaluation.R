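# Scoring predicted networks against a gold standard: gene-level collapse,
# direct and indirect (path-length <= k) matching, confusion counts,
# precision / recall / F-measure, and best-method selection.

#' Collapse an antibody-level prediction to gene-level edges
#'
#' Nodes carrying the antibody-disambiguation suffix (`SYMBOL·k`, see
#' [map_to_genes()]) are collapsed to their gene symbol; an optional
#' explicit mapping is applied first. Parallel edges arising from multiple
#' antibodies of the same gene pair are merged keeping the maximum-absolute
#' weight, and edges between two antibodies of one gene become self-loops
#' and are dropped.
#'
#' @param pred Network tibble (columns `from`, `to`, optional `weight`).
#' @param mapping Optional mapping tibble (`id`, `symbol`) or named vector
#'   applied to node names before suffix stripping.
#' @return A gene-level network tibble.
#' @export
collapse_to_gene_edges <- function(pred, mapping = NULL) {
  from <- pred$from; to <- pred$to
  if (!is.null(mapping)) {
    map <- if (is.data.frame(mapping)) {
      setNames(toupper(as.character(mapping[[2L]])), toupper(as.character(mapping[[1L]])))
    } else setNames(toupper(as.character(mapping)), toupper(names(mapping)))
    from <- ifelse(from %in% names(map), map[from], from)
    to <- ifelse(to %in% names(map), map[to], to)
  }
  out <- pred
  out$from <- strip_antibody_suffix(from)
  out$to <- strip_antibody_suffix(to)
  as_network(out, quiet = TRUE)
}

#' Expand a gold standard to indirect interactions within path length k
#'
#' Builds the level-k reference: a pair of gold-standard nodes is an edge
#' of the result iff their shortest-path distance in the gold standard is
#' at most `k` (`cumulative = TRUE`, the default) or exactly `k`
#' (`cumulative = FALSE`, for sensitivity analysis). `k = 1` returns the
#' gold standard itself.
#'
#' @param gold Gold-standard network tibble.
#' @param k Path-length level (positive integer).
#' @param cumulative Accept all pairs at distance `<= k` (default) rather
#'   than exactly `k`.
#' @return A network tibble over the gold standard's nodes.
#' @export
gold_within_k <- function(gold, k, cumulative = TRUE) {
  if (k < 1) config_error("`k` must be a positive integer.")
  gold <- as_network(gold, quiet = TRUE)
  if (k == 1 && cumulative) return(gold[, c("from", "to")])
  g <- as_igraph(gold)
  d <- igraph::distances(g)
  keep <- if (cumulative) d <= k & d >= 1 else d == k
  ids <- rownames(d)
  idx <- which(keep & upper.tri(keep), arr.ind = TRUE)
  a <- ids[idx[, 1L]]; b <- ids[idx[, 2L]]
  out <- tibble(from = pmin(a, b), to = pmax(a, b))
  out[order(out$from, out$to), ]
}

#' Confusion counts of a prediction against a gold standard
#'
#' Over all `C(|universe|, 2)` unordered pairs of the gene universe:
#' TP = predicted and within distance `k` in the gold standard;
#' FP = predicted only; FN = in the level-k gold standard only;
#' TN = neither. Counts always sum to the pair-universe size.
#'
#' @param pred Predicted network tibble (nodes must lie in `universe`).
#' @param gold Gold-standard network tibble (nodes must lie in `universe`).
#' @param universe Character vector of gene symbols defining the pair
#'   universe.
#' @param k Path-length level (default 1: direct interactions).
#' @param cumulative Passed to [gold_within_k()].
#' @return One-row tibble: `k`, `tp`, `fp`, `tn`, `fn`, `universe_size`.
#' @export
confusion_counts <- function(pred, gold, universe, k = 1L, cumulative = TRUE) {
  universe <- sort(unique(toupper(universe)))
  pred <- as_network(pred, quiet = TRUE)
  gold <- as_network(gold, quiet = TRUE)
  pn <- network_nodes(pred)
  if (length(setdiff(pn, universe))) {
    data_error(paste0("Predicted node(s) outside the universe: ",
                      paste(head(setdiff(pn, universe), 5L), collapse = ", ")))
  }
  gn <- network_nodes(gold)
  if (length(setdiff(gn, universe))) {
    data_error(paste0("Gold-standard node(s) outside the universe: ",
                      paste(head(setdiff(gn, universe), 5L), collapse = ", ")))
  }
  gk <- gold_within_k(gold, k, cumulative = cumulative)
  total <- n_pairs(universe)
  pred_keys <- unique(pair_key(pred$from, pred$to))
  gold_keys <- unique(pair_key(gk$from, gk$to))
  tp <- sum(pred_keys %in% gold_keys)
  fp <- length(pred_keys) - tp
  fn <- length(gold_keys) - tp
  tn <- total - tp - fp - fn
  tibble(k = as.integer(k), tp = tp, fp = fp, tn = tn, fn = fn,
         universe_size = total)
}

#' Precision, recall and F-measure from confusion counts
#'
#' `precision = tp / (tp + fp)`, `recall = tp / (tp + fn)` (both 0 when the
#' denominator is 0), and
#' `F = 2 * precision * recall / (precision + recall)` (0 when
#' `precision + recall` is 0, hence whenever `tp = 0`).
#'
#' @param counts Data frame with columns `tp`, `fp`, `fn` (e.g. from
#'   [confusion_counts()]); extra columns are carried through.
#' @return The input with `precision`, `recall`, `f_measure` columns added.
#' @export
f_measure <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f <- ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
  counts$precision <- precision
  counts$recall <- recall
  counts$f_measure <- f
  as_tibble(counts)
}

#' Evaluate a set of method predictions against a gold standard
#'
#' @param predictions Named list of predicted network tibbles, one per
#'   method id.
#' @param gold Gold-standard network tibble.
#' @param universe Gene universe (see [confusion_counts()]).
#' @param k_levels Path-length levels to evaluate (subset of 1:4 typically).
#' @return A `ppi_evaluation` tibble: one row per method and level with
#'   confusion counts and metrics, ordered by the canonical method order.
#' @export
evaluate_methods <- function(predictions, gold, universe, k_levels = 1L) {
  if (!length(predictions)) config_error("`predictions` must be a non-empty named list.")
  ids <- names(predictions)
  if (is.null(ids) || any(!nzchar(ids))) config_error("`predictions` must be named by method id.")
  method_category(ids)  # validates ids
  rows <- purrr::map_dfr(ids, function(m) {
    purrr::map_dfr(k_levels, function(k) {
      out <- f_measure(confusion_counts(predictions[[m]], gold, universe, k = k))
      dplyr::bind_cols(tibble(method = m), out)
    })
  })
  rows <- rows[order(method_rank(rows$method), rows$k), ]
  class(rows) <- c("ppi_evaluation", class(rows))
  rows
}

#' Select the best method by F-measure
#'
#' Picks the method with the maximal direct (`k = 1`) F-measure; exact ties
#' are broken towards the earlier method in the canonical listing order
#' (see [ppi_methods()]).
#'
#' @param results Evaluation tibble from [evaluate_methods()] (must contain
#'   `method`, `k`, `f_measure`).
#' @return The winning method id (character scalar).
#' @export
select_best_method <- function(results) {
  if (!is.data.frame(results) || !nrow(results)) config_error("`results` must be a non-empty data frame.")
  res <- results[results$k == 1L, , drop = FALSE]
  if (!nrow(res)) config_error("No k = 1 rows in `results`.")
  res <- res[order(-res$f_measure, method_rank(res$method)), ]
  res$method[1L]
}
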