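# End-to-end orchestration: inference across methods and conditions,
# significance filtering, evaluation against the gold standard, best-method
# selection, consensus ensembles, validation and topology reports.

#' Run the full inference-and-consensus pipeline
#'
#' For every condition, runs the requested inference methods on the
#' condition's expression matrix, filters each score matrix into a
#' significant predicted network, collapses predictions to gene level,
#' evaluates them against the gold standard at the requested path-length
#' levels, and selects the best (maximum direct F-measure) method. The
#' union of per-condition best methods forms the global best-method (BM)
#' set, from which a consensus ensemble network is built per condition.
#' When references are given, each condition's best-method network is
#' compared with the tissue-like and non-interacting references (overlap
#' percentages, class tallies) and its ensemble yields a precision-recall
#' curve. A topology report (network statistics, minimum dominating set,
#' collective influence, cross-condition core module) is always produced.
#'
#' The evaluation pair universe is the gold standard's gene set intersected
#' with the measured genes; predictions outside it are excluded from
#' evaluation. Ensembles are built over the full measured panel.
#'
#' @param expressions Named list of expression tibbles (one per condition),
#'   or a single expression tibble.
#' @param gold Gold-standard network tibble.
#' @param mapping Optional antibody-to-gene mapping applied to expression
#'   columns.
#' @param references Optional list with any of `tissue_like`,
#'   `non_interacting` (network tibbles) and `class_map`.
#' @param methods Method ids to run (default: all fourteen).
#' @param alpha Significance threshold for non-MI methods.
#' @param k_levels Path-length levels for evaluation (default `1:4`).
#' @param seed Integer seed for cross-validated methods and any
#'   randomized analytics.
#' @param out_dir Optional output directory; when given, all reports are
#'   written as TSV plus a JSON summary.
#' @param annotations Optional node labels (data frame `node`, `label`) to
#'   trigger colored motif counting on the per-condition best networks.
#' @param motif_randomizations Rewiring-null size for motif p-values.
#' @return A `ppi_pipeline` list: `evaluation` (tibble over conditions,
#'   methods, k levels), `best_methods` (tibble condition/method/F),
#'   `bm_set`, `predictions` (per condition, per method), `ensembles`,
#'   `validation`, `topology`, `params`.
#' @export
run_pipeline <- function(expressions, gold, mapping = NULL, references = NULL,
                         methods = ppi_methods()$method, alpha = 0.05,
                         k_levels = 1:4, seed = 1L, out_dir = NULL,
                         annotations = NULL, motif_randomizations = 50L) {
  if (is.data.frame(expressions)) expressions <- list(COND01 = expressions)
  if (is.null(names(expressions)) || any(!nzchar(names(expressions)))) {
    config_error("`expressions` must be a named list of expression tibbles.")
  }
  methods <- toupper(methods)
  method_category(methods)  # validate before any computation
  if (alpha <= 0 || alpha > 1) config_error("`alpha` must lie in (0, 1].")
  if (!all(k_levels %in% 1:4)) config_error("`k_levels` must be a subset of 1:4.")
  gold <- as_network(gold, quiet = TRUE)

  conditions <- names(expressions)
  predictions <- list()
  eval_rows <- list()
  best <- tibble(condition = character(), method = character(), f_measure = numeric())
  for (cond in conditions) {
    expr <- expressions[[cond]]
    if (!is.null(mapping)) expr <- map_to_genes(expr, mapping, strict = FALSE)
    measured <- strip_antibody_suffix(toupper(colnames(expr)[-1L]))
    universe <- intersect(network_nodes(gold), unique(measured))
    if (length(universe) < 3L) {
      data_error(sprintf("Condition %s: fewer than 3 measured genes overlap the gold standard.", cond))
    }
    preds <- list()
    for (m in methods) {
      sc <- infer_network(expr, m, seed = seed)
      pred <- filter_predictions(sc, alpha = alpha)
      preds[[m]] <- collapse_to_gene_edges(pred)
    }
    predictions[[cond]] <- preds
    eval_preds <- lapply(preds, induce_subnetwork, genes = universe)
    ev <- evaluate_methods(eval_preds, induce_subnetwork(gold, universe),
                           universe, k_levels = k_levels)
    ev <- dplyr::bind_cols(tibble(condition = cond), ev)
    eval_rows[[cond]] <- ev
    bm <- select_best_method(ev)
    best <- dplyr::bind_rows(best, tibble(
      condition = cond, method = bm,
      f_measure = ev$f_measure[ev$method == bm & ev$k == 1L]))
  }
  evaluation <- dplyr::bind_rows(eval_rows)
  bm_set <- collect_best_methods(best)

  ensembles <- lapply(conditions, function(cond) {
    expr <- expressions[[cond]]
    if (!is.null(mapping)) expr <- map_to_genes(expr, mapping, strict = FALSE)
    panel <- unique(strip_antibody_suffix(toupper(colnames(expr)[-1L])))
    build_ensemble(predictions[[cond]], bm_set, universe = panel)
  })
  names(ensembles) <- conditions

  validation <- NULL
  if (!is.null(references)) {
    rows <- purrr::map_dfr(conditions, function(cond) {
      bnet <- predictions[[cond]][[best$method[best$condition == cond]]]
      out <- tibble(condition = cond,
                    best_method = best$method[best$condition == cond])
      if (!is.null(references$tissue_like) && nrow(bnet)) {
        out$tissue_overlap_pct <- overlap_percentage(bnet, references$tissue_like)
      }
      if (!is.null(references$non_interacting) && nrow(bnet)) {
        out$negative_overlap_pct <- overlap_percentage(bnet, references$non_interacting)
      }
      out
    })
    curves <- NULL
    if (!is.null(references$tissue_like)) {
      curves <- lapply(conditions, function(cond) {
        tryCatch(pr_curve(ensembles[[cond]], references$tissue_like),
                 ppinet_data_error = function(e) NULL)
      })
      names(curves) <- conditions
    }
    classes <- NULL
    if (!is.null(references$class_map)) {
      classes <- purrr::map_dfr(conditions, function(cond) {
        bnet <- predictions[[cond]][[best$method[best$condition == cond]]]
        dplyr::bind_cols(tibble(condition = cond), classify_edges(bnet, references$class_map))
      })
    }
    validation <- list(overlaps = rows, pr_curves = curves, class_counts = classes)
  }

  best_nets <- lapply(conditions, function(cond) {
    predictions[[cond]][[best$method[best$condition == cond]]]
  })
  names(best_nets) <- conditions
  stats <- purrr::map_dfr(conditions, function(cond) {
    bn <- best_nets[[cond]]
    st <- if (nrow(bn)) network_stats(bn) else
      tibble(n_nodes = 0L, n_edges = 0L, density = 0, mean_degree = 0,
             clustering_coefficient = NA_real_, n_components = 0L,
             largest_component_size = 0L)
    dplyr::bind_cols(tibble(condition = cond), st)
  })
  core <- if (length(conditions) >= 2L) core_module(best_nets) else best_nets[[1L]][, c("from", "to")]
  mds <- lapply(best_nets, minimum_dominating_set)
  ci <- lapply(best_nets, collective_influence)
  motifs <- NULL
  if (!is.null(annotations)) {
    motifs <- purrr::map_dfr(conditions, function(cond) {
      rep <- replicate_multilabel_nodes(best_nets[[cond]], annotations)
      dplyr::bind_rows(
        count_colored_motifs(rep$network, rep$labels, size = 3L,
                             randomizations = motif_randomizations, seed = seed),
        count_colored_motifs(rep$network, rep$labels, size = 4L,
                             randomizations = motif_randomizations, seed = seed)
      ) |> dplyr::mutate(condition = cond, .before = 1L)
    })
  }
  topology <- list(stats = stats, core_module = core,
                   dominating_sets = mds, collective_influence = ci,
                   motifs = motifs)

  result <- structure(
    list(evaluation = evaluation, best_methods = best, bm_set = bm_set,
         predictions = predictions, ensembles = ensembles,
         validation = validation, topology = topology,
         params = list(methods = methods, alpha = alpha, k_levels = k_levels,
                       seed = seed)),
    class = "ppi_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' @export
print.ppi_pipeline <- function(x, ...) {
  cat(sprintf("<ppi_pipeline> %d condition(s), %d method(s), BM set: %s\n",
              length(x$predictions), length(x$params$methods),
              paste(x$bm_set, collapse = ", ")))
  print(x$best_methods)
  invisible(x)
}

format_num <- function(x) formatC(x, digits = 6, format = "g")

write_report_tsv <- function(df, path) {
  out <- df
  num <- vapply(out, is.numeric, logical(1L))
  dbl <- num & !vapply(out, is.integer, logical(1L))
  out[dbl] <- lapply(out[dbl], format_num)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_report_tsv(result$evaluation, file.path(out_dir, "evaluation.tsv"))
  write_report_tsv(result$best_methods, file.path(out_dir, "best_methods.tsv"))
  for (cond in names(result$predictions)) {
    for (m in names(result$predictions[[cond]])) {
      write_network(result$predictions[[cond]][[m]],
                    file.path(out_dir, sprintf("prediction_%s_%s.tsv", cond, m)))
    }
    write_ensemble(result$ensembles[[cond]],
                   file.path(out_dir, sprintf("ensemble_%s.tsv", cond)))
  }
  write_report_tsv(result$topology$stats, file.path(out_dir, "network_stats.tsv"))
  write_network(result$topology$core_module, file.path(out_dir, "core_module.tsv"))
  mds <- result$topology$dominating_sets
  writeLines(c("condition\tnode",
               unlist(lapply(names(mds), function(cond) {
                 if (length(mds[[cond]])) paste(cond, mds[[cond]], sep = "\t") else character()
               }))),
             file.path(out_dir, "dominating_sets.tsv"))
  ci <- purrr::imap_dfr(result$topology$collective_influence,
                        ~ dplyr::bind_cols(tibble(condition = .y), .x))
  write_report_tsv(ci, file.path(out_dir, "collective_influence.tsv"))
  if (!is.null(result$validation)) {
    write_report_tsv(result$validation$overlaps, file.path(out_dir, "reference_overlaps.tsv"))
    if (!is.null(result$validation$pr_curves)) {
      for (cond in names(result$validation$pr_curves)) {
        prc <- result$validation$pr_curves[[cond]]
        if (!is.null(prc)) {
          write_report_tsv(as_tibble(prc), file.path(out_dir, sprintf("pr_curve_%s.tsv", cond)))
        }
      }
    }
    if (!is.null(result$validation$class_counts)) {
      write_report_tsv(result$validation$class_counts, file.path(out_dir, "class_counts.tsv"))
    }
  }
  if (!is.null(result$topology$motifs)) {
    write_report_tsv(result$topology$motifs, file.path(out_dir, "motifs.tsv"))
  }
  summary <- list(
    bm_set = result$bm_set,
    best_methods = setNames(as.list(result$best_methods$method),
                            result$best_methods$condition),
    f_measures = setNames(as.list(round(result$best_methods$f_measure, 6)),
                          result$best_methods$condition),
    alpha = result$params$alpha, seed = result$params$seed
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
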