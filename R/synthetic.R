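# Synthetic benchmark studies: a known "true" PPI network, Gaussian
# graphical expression data whose precision-matrix support is that truth,
# and corrupted reference sets (tissue-like, non-interacting, class-labeled)
# derived from it. The generator's data model matches the model class the
# significance filter assumes (a Gaussian graphical model), so planted
# edges are recoverable in principle by the partial-correlation methods.

synthetic_gene_names <- function(p) sprintf("G%03d", seq_len(p))

#' Generate a random true interaction network
#'
#' Erdos-Renyi (`density_or_m` = edge density) or Barabasi-Albert
#' preferential attachment (`density_or_m` = integer m, the edges added per
#' node; the first m nodes start empty, so the edge count is `m * (p - m)`).
#' Up to 50 draws are attempted to obtain a connected graph; otherwise the
#' last draw is returned. Deterministic given `seed`.
#'
#' @param p Number of genes (at least 5).
#' @param model `"erdos_renyi"` or `"barabasi_albert"`.
#' @param density_or_m Edge density in (0, 1\] (ER) or attachment count m
#'   (BA).
#' @param seed Integer seed.
#' @return A network tibble over genes `G001 ... Gp`.
#' @export
generate_truth <- function(p, model = c("erdos_renyi", "barabasi_albert"),
                           density_or_m = 0.1, seed = 1L) {
  model <- match.arg(model)
  if (p < 5L) config_error("`p` must be at least 5.")
  genes <- synthetic_gene_names(p)
  total <- p * (p - 1L) / 2L
  withr::with_seed(seed, {
    if (model == "erdos_renyi") {
      n_edges <- round(density_or_m * total)
      if (n_edges < 1 || n_edges > total) {
        config_error(sprintf("Infeasible density %g for p = %d.", density_or_m, p))
      }
      pairs <- all_pairs(genes)
      for (try in seq_len(50L)) {
        sel <- sort(sample.int(total, n_edges))
        net <- pairs[sel, ]
        if (n_edges >= p - 1L &&
            igraph::is_connected(as_igraph(net, genes))) break
      }
      net
    } else {
      m <- as.integer(density_or_m)
      if (m < 1L || m >= p) config_error("`m` must be in [1, p - 1].")
      deg <- integer(p)
      from <- to <- integer(m * (p - m))
      e <- 0L
      for (v in (m + 1L):p) {
        existing <- seq_len(v - 1L)
        targets <- if (v == m + 1L) existing else {
          sample(existing, m, prob = deg[existing] + 1)
        }
        for (t in targets) {
          e <- e + 1L
          from[e] <- t; to[e] <- v
          deg[t] <- deg[t] + 1L; deg[v] <- deg[v] + 1L
        }
      }
      as_network(tibble(from = genes[from], to = genes[to]), quiet = TRUE)
    }
  })
}

#' Sample expression data from a Gaussian graphical model with known support
#'
#' Builds a precision matrix whose off-diagonal support equals the truth's
#' edges: entries drawn uniformly from `partial_corr_range` in magnitude
#' with random signs, the diagonal inflated so the minimum eigenvalue is at
#' least 0.1, then rescaled to unit diagonal (so off-diagonal entries are
#' the negated partial correlations). `n` samples are drawn from the
#' implied zero-mean multivariate normal. Deterministic given `seed`.
#'
#' @param truth Network tibble of true edges.
#' @param n Number of samples (at least 10).
#' @param partial_corr_range Magnitude range of the precision-matrix
#'   off-diagonal entries before rescaling (default `c(0.2, 0.4)`).
#' @param seed Integer seed.
#' @param genes Optional full gene panel (defaults to the truth's nodes).
#' @return Expression tibble (`sample_id` + one numeric column per gene),
#'   with the achieved partial-correlation magnitude range as attribute
#'   `pcor_range`.
#' @export
generate_expression <- function(truth, n, partial_corr_range = c(0.2, 0.4),
                                seed = 1L, genes = NULL) {
  if (n < 10L) config_error("`n` must be at least 10.")
  genes <- sort(unique(toupper(genes %||% network_nodes(truth))))
  p <- length(genes)
  withr::with_seed(seed, {
    omega <- diag(p)
    if (nrow(truth)) {
      fi <- match(toupper(truth$from), genes); ti <- match(toupper(truth$to), genes)
      mag <- runif(nrow(truth), partial_corr_range[1L], partial_corr_range[2L])
      sgn <- sample(c(-1, 1), nrow(truth), replace = TRUE)
      for (e in seq_along(fi)) {
        omega[fi[e], ti[e]] <- omega[ti[e], fi[e]] <- sgn[e] * mag[e]
      }
    }
    ev <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < 0.1) omega <- omega + (0.1 - ev) * diag(p)
    d <- sqrt(diag(omega))
    omega <- omega / tcrossprod(d)   # unit diagonal
    sigma <- solve(omega)
    z <- matrix(rnorm(n * p), n, p)
    x <- z %*% chol(sigma)
    colnames(x) <- genes
    pc <- prec_to_pcor(omega)
    achieved <- if (nrow(truth)) range(abs(pc[cbind(fi, ti)])) else c(0, 0)
    out <- tibble(sample_id = sprintf("S%04d", seq_len(n)))
    out <- dplyr::bind_cols(out, as_tibble(as.data.frame(x)))
    attr(out, "pcor_range") <- achieved
    out
  })
}

#' Generate corrupted reference sets from a truth network
#'
#' * `tissue_like`: a random `keep_frac` of the true edges plus
#'   `round(decoy_frac * |truth|)` decoy non-edges.
#' * `non_interacting`: a random sample of non-edges of the truth, disjoint
#'   from the tissue-like decoys (mimics a negative reference).
#' * `class_map`: kept true edges labeled C1/C2 and decoys C3/C4,
#'   uniformly at random.
#'
#' @param truth Network tibble.
#' @param keep_frac Fraction of true edges kept in the tissue-like
#'   reference (default 0.7).
#' @param decoy_frac Decoy edges as a fraction of the truth size (default
#'   0.1).
#' @param n_negative Size of the non-interacting set (default
#'   `min(|truth|, remaining non-edges)`).
#' @param seed Integer seed.
#' @param genes Optional full gene panel.
#' @return List with `tissue_like`, `non_interacting` (network tibbles) and
#'   `class_map` (tibble `from`, `to`, `class`).
#' @export
generate_references <- function(truth, keep_frac = 0.7, decoy_frac = 0.1,
                                n_negative = NULL, seed = 1L, genes = NULL) {
  if (keep_frac < 0 || keep_frac > 1 || decoy_frac < 0 || decoy_frac > 1) {
    config_error("`keep_frac` and `decoy_frac` must lie in [0, 1].")
  }
  genes <- sort(unique(toupper(genes %||% network_nodes(truth))))
  truth <- as_network(truth, quiet = TRUE)
  pairs <- all_pairs(genes)
  tk <- pair_key(truth$from, truth$to)
  non_edges <- pairs[!pair_key(pairs$from, pairs$to) %in% tk, ]
  n_keep <- round(keep_frac * nrow(truth))
  n_decoy <- round(decoy_frac * nrow(truth))
  withr::with_seed(seed, {
    kept <- truth[sort(sample.int(nrow(truth), n_keep)), c("from", "to")]
    if (n_decoy > nrow(non_edges)) data_error("Not enough non-edges for the requested decoys.")
    decoy_idx <- if (n_decoy > 0) sort(sample.int(nrow(non_edges), n_decoy)) else integer(0)
    decoys <- non_edges[decoy_idx, , drop = FALSE]
    remaining <- if (length(decoy_idx)) non_edges[-decoy_idx, , drop = FALSE] else non_edges
    n_neg <- min(n_negative %||% nrow(truth), nrow(remaining))
    if (n_neg < 1L) data_error("Not enough non-edges for a non-interacting reference.")
    negative <- remaining[sort(sample.int(nrow(remaining), n_neg)), ]
    class_map <- dplyr::bind_rows(
      if (nrow(kept)) tibble(from = kept$from, to = kept$to,
                             class = sample(c("C1", "C2"), nrow(kept), replace = TRUE)),
      if (nrow(decoys)) tibble(from = decoys$from, to = decoys$to,
                               class = sample(c("C3", "C4"), nrow(decoys), replace = TRUE))
    )
    tissue <- as_network(dplyr::bind_rows(kept, decoys), quiet = TRUE)
    list(tissue_like = tissue,
         non_interacting = as_tibble(negative),
         class_map = class_map)
  })
}

#' Generate a complete synthetic benchmark study
#'
#' One shared truth network; per-condition expression matrices drawn from
#' the Gaussian graphical model with condition-specific seeds
#' (`seed + condition index`), which re-draws the edge-weight magnitudes
#' and signs per condition (mild condition-to-condition jitter around the
#' same support); plus a bundled reference set. Fully deterministic given
#' the master seed.
#'
#' @param p Number of genes.
#' @param n Samples per condition.
#' @param n_conditions Number of conditions (default 16).
#' @param density Truth edge density (default 0.1, Erdos-Renyi).
#' @param seed Master seed.
#' @param partial_corr_range Passed to [generate_expression()].
#' @return A `ppi_study` list: `truth`, `expressions` (named list of
#'   expression tibbles), `references`, `genes`, `seed`, `params`.
#' @export
#' @examples
#' study <- generate_study(p = 12, n = 30, n_conditions = 2, seed = 42)
#' names(study$expressions)
generate_study <- function(p, n, n_conditions = 16L, density = 0.1, seed = 1L,
                           partial_corr_range = c(0.2, 0.4)) {
  if (p < 5L || n < 10L || n_conditions < 1L) {
    config_error("Need p >= 5, n >= 10, n_conditions >= 1.")
  }
  truth <- generate_truth(p, "erdos_renyi", density, seed = seed)
  genes <- synthetic_gene_names(p)
  conds <- sprintf("COND%02d", seq_len(n_conditions))
  expressions <- lapply(seq_len(n_conditions), function(i) {
    generate_expression(truth, n, partial_corr_range, seed = seed + i, genes = genes)
  })
  names(expressions) <- conds
  refs <- generate_references(truth, seed = seed + n_conditions + 1L, genes = genes)
  structure(list(truth = truth, expressions = expressions, references = refs,
                 genes = genes, seed = seed,
                 params = list(p = p, n = n, n_conditions = n_conditions,
                               density = density,
                               partial_corr_range = partial_corr_range)),
            class = "ppi_study")
}

#' @export
print.ppi_study <- function(x, ...) {
  cat(sprintf("<ppi_study> %d genes, %d conditions x %d samples, truth: %d edges (seed %d)\n",
              length(x$genes), length(x$expressions), x$params$n,
              nrow(x$truth), x$seed))
  invisible(x)
}

#' Write a synthetic study to disk in the pipeline's file formats
#'
#' Writes per-condition expression TSVs, the truth/tissue-like/
#' non-interacting networks, and the class map into `dir`.
#'
#' @param study A `ppi_study` object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cond in names(study$expressions)) {
    write_expression(study$expressions[[cond]],
                     file.path(dir, paste0("expression_", cond, ".tsv")))
  }
  write_network(study$truth, file.path(dir, "truth.tsv"))
  write_network(study$references$tissue_like, file.path(dir, "tissue_like.tsv"))
  write_network(study$references$non_interacting, file.path(dir, "non_interacting.tsv"))
  cm <- study$references$class_map
  writeLines(c("from\tto\tclass",
               if (nrow(cm)) paste(cm$from, cm$to, cm$class, sep = "\t")),
             file.path(dir, "class_map.tsv"))
  invisible(dir)
}
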