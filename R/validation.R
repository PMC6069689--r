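# Validation of predicted / ensemble networks against external references:
# overlap percentages, precision-recall curves, class tallies, and
# hypergeometric gene-set overlap.

#' Percentage of predicted edges present in a reference network
#'
#' `100 * |pred ∩ reference| / |pred|`, i.e. relative to the number of
#' unique predictions.
#'
#' @param pred Predicted network tibble (must be non-empty).
#' @param reference Reference network tibble.
#' @return A percentage in \[0, 100\].
#' @export
overlap_percentage <- function(pred, reference) {
  pk <- unique(pair_key(toupper(pred$from), toupper(pred$to)))
  if (!length(pk)) data_error("`pred` has no edges; overlap percentage undefined.")
  rk <- unique(pair_key(toupper(reference$from), toupper(reference$to)))
  100 * sum(pk %in% rk) / length(pk)
}

#' Precision-recall curve of an ensemble against a reference network
#'
#' Sweeps the distinct ensemble scores in decreasing order; at each
#' threshold `t` the prediction is the set of ensemble edges with score
#' `>= t`, scored against the reference's edges over the pair universe. A
#' final point taking every universe pair as predicted (recall 1) is
#' appended when the last threshold has not already reached full recall.
#'
#' When the reference resource covers only part of the assay panel, pass
#' its gene coverage as `reference_coverage`: pairs involving genes outside
#' the coverage are then excluded from the universe (they can never be
#' reference positives, so keeping them would only deflate precision).
#'
#' @param ens A `ppi_ensemble` tibble (or any edge tibble with a `score`
#'   column).
#' @param reference Reference network tibble with at least one edge in the
#'   universe.
#' @param universe Gene universe of the ensemble (defaults to the union of
#'   ensemble and reference nodes).
#' @param reference_coverage Optional character vector of genes the
#'   reference resource covers; restricts the pair universe.
#' @return A `ppi_pr_curve` tibble: `threshold` (strictly decreasing;
#'   `NA` for the appended all-pairs point), `precision`, `recall`.
#' @export
pr_curve <- function(ens, reference, universe = NULL, reference_coverage = NULL) {
  universe <- sort(unique(toupper(universe %||% c(network_nodes(ens), network_nodes(reference)))))
  kept <- universe
  if (!is.null(reference_coverage)) {
    kept <- intersect(universe, toupper(reference_coverage))
    dropped <- length(universe) - length(kept)
    if (dropped > 0) {
      inform(sprintf("Excluding %d universe gene(s) not covered by the reference.", dropped))
    }
  }
  total <- n_pairs(kept)
  ref <- induce_subnetwork(as_network(reference, quiet = TRUE), kept)
  pos_keys <- unique(pair_key(ref$from, ref$to))
  npos <- length(pos_keys)
  if (npos == 0L) data_error("Reference has no edges within the universe.")
  edges <- ens[toupper(ens$from) %in% kept & toupper(ens$to) %in% kept, , drop = FALSE]
  keys <- pair_key(toupper(edges$from), toupper(edges$to))
  scores <- edges$score
  thresholds <- sort(unique(scores), decreasing = TRUE)
  pts <- purrr::map_dfr(thresholds, function(t) {
    sel <- keys[scores >= t]
    tp <- sum(sel %in% pos_keys)
    tibble(threshold = t, precision = if (length(sel)) tp / length(sel) else 0,
           recall = tp / npos)
  })
  if (!nrow(pts) || pts$recall[nrow(pts)] < 1) {
    pts <- dplyr::bind_rows(pts, tibble(threshold = NA_real_,
                                        precision = npos / total, recall = 1))
  }
  structure(pts, n_positive = npos, universe_pairs = total,
            class = c("ppi_pr_curve", class(pts)))
}

#' Area under a precision-recall curve
#'
#' Trapezoidal area over recall, prepending a `(recall = 0, precision =
#' first precision)` anchor when needed.
#'
#' @param prc A `ppi_pr_curve` tibble (or any data frame with `recall` and
#'   `precision`).
#' @return The PR-AUC (scalar in \[0, 1\]).
#' @export
pr_auc <- function(prc) {
  r <- prc$recall; p <- prc$precision
  if (!length(r)) return(NA_real_)
  if (r[1L] > 0) { r <- c(0, r); p <- c(p[1L], p) }
  sum(diff(r) * (head(p, -1L) + p[-1L]) / 2)
}

#' Average precision of a score ranking against a true edge set
#'
#' Ranks all variable pairs by decreasing absolute score and computes the
#' average of precision-at-rank over the positions of the true edges (the
#' usual area under the interpolated precision-recall curve of a full
#' ranking). Used for parameter-recovery checks against a planted truth.
#'
#' @param scores A `ppi_scores` object, or an edge tibble with a `score`
#'   column covering all pairs to rank.
#' @param truth Network tibble of true edges.
#' @return The average precision (scalar in \[0, 1\]).
#' @export
average_precision <- function(scores, truth) {
  edges <- if (inherits(scores, "ppi_scores")) tidy(scores) else as_tibble(scores)
  keys <- pair_key(toupper(edges$from), toupper(edges$to))
  truth_keys <- unique(pair_key(toupper(truth$from), toupper(truth$to)))
  ord <- order(-abs(edges$score), keys)  # deterministic tie-break by pair key
  hit <- keys[ord] %in% truth_keys
  npos <- sum(truth_keys %in% keys)
  if (npos == 0L) data_error("No true edge lies among the ranked pairs.")
  prec_at <- cumsum(hit) / seq_along(hit)
  sum(prec_at[hit]) / npos
}

#' Tally predicted edges by reference class
#'
#' Each predicted edge is assigned the class of the matching reference pair
#' (e.g. the four tissue co-expression classes C1-C4) or `"unmatched"`.
#' Counts over all classes plus unmatched sum to the number of predicted
#' edges.
#'
#' @param pred Predicted network tibble.
#' @param class_map Tibble with columns `from`, `to`, `class` (see
#'   [read_class_map()]).
#' @return Tibble with columns `class` and `n`.
#' @export
classify_edges <- function(pred, class_map) {
  pk <- unique(pair_key(toupper(pred$from), toupper(pred$to)))
  if (is.null(class_map) || !nrow(class_map)) {
    return(tibble(class = "unmatched", n = length(pk)))
  }
  ck <- pair_key(toupper(class_map$from), toupper(class_map$to))
  cls <- class_map$class[match(pk, ck)]
  cls[is.na(cls)] <- "unmatched"
  out <- as.data.frame(table(class = cls), stringsAsFactors = FALSE)
  names(out) <- c("class", "n")
  out$n <- as.integer(out$n)
  as_tibble(out[order(out$class), ])
}

#' Hypergeometric gene-set overlap with FDR control
#'
#' For each set in the collection computes the one-sided (enrichment)
#' hypergeometric p-value of its overlap with `gene_list` over a universe
#' of `universe_size` genes, adjusts across the collection by
#' Benjamini-Hochberg, and returns the sets with `fdr < fdr_max` sorted by
#' p-value, truncated to the `top` best. Set `top = Inf, fdr_max = 1` for
#' pure intersection reporting.
#'
#' @param gene_list Character vector of query genes.
#' @param collection Named list of gene sets (e.g. from [read_gmt()]).
#' @param universe_size Number of genes in the universe (must be at least
#'   `length(gene_list)` and at least every set size).
#' @param fdr_max FDR threshold (default 0.05).
#' @param top Maximum number of sets returned (default 10).
#' @return Tibble: `set_name`, `overlap`, `set_size`, `list_size`,
#'   `universe_size`, `p_value`, `fdr`.
#' @export
geneset_overlap <- function(gene_list, collection, universe_size,
                            fdr_max = 0.05, top = 10) {
  gene_list <- unique(toupper(gene_list))
  nlist <- length(gene_list)
  if (universe_size < nlist) config_error("`universe_size` must be at least the query list size.")
  sizes <- lengths(collection)
  if (any(sizes > universe_size)) {
    config_error("A gene set is larger than the universe.")
  }
  rows <- purrr::imap_dfr(collection, function(set, nm) {
    set <- unique(toupper(set))
    k <- sum(gene_list %in% set)
    p <- phyper(k - 1, length(set), universe_size - length(set), nlist,
                lower.tail = FALSE)
    tibble(set_name = nm, overlap = k, set_size = length(set),
           list_size = nlist, universe_size = universe_size, p_value = p)
  })
  rows$fdr <- p.adjust(rows$p_value, method = "BH")
  rows <- rows[rows$fdr < fdr_max, , drop = FALSE]
  rows <- rows[order(rows$p_value, rows$set_name), , drop = FALSE]
  head(rows, n = top)
}
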