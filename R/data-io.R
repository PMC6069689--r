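# Reading, writing and canonicalizing expression matrices, identifier
# mappings and networks.
#
# Networks are plain tibbles of undirected edges with columns `from` and
# `to` (gene symbols, stored uppercase, canonicalized so from < to and each
# unordered pair appears once) plus an optional `weight` column. Expression
# data are tibbles whose first column holds sample identifiers and whose
# remaining columns are numeric protein/antibody measurements.

#' Canonicalize an edge table into an undirected network
#'
#' Coerces a two- (or three-) column data frame of edges into the canonical
#' network form used throughout the package: symbols uppercased, endpoints
#' of each edge sorted lexicographically, duplicate and reversed-duplicate
#' edges collapsed (keeping the maximum-absolute weight when weights are
#' present), self-loops dropped (their count is reported via a message).
#'
#' @param edges Data frame whose first two columns are edge endpoints; an
#'   optional third numeric column is treated as the edge weight.
#' @param quiet Suppress the dropped self-loop message.
#' @return A tibble with columns `from`, `to` (and `weight` if supplied),
#'   sorted in canonical lexicographic edge order.
#' @export
#' @examples
#' as_network(data.frame(a = c("b", "a", "a"), b = c("a", "b", "a")))
as_network <- function(edges, quiet = FALSE) {
  if (!is.data.frame(edges) || ncol(edges) < 2L) {
    data_error("An edge table needs at least two columns (from, to).")
  }
  from <- toupper(as.character(edges[[1L]]))
  to <- toupper(as.character(edges[[2L]]))
  weight <- if (ncol(edges) >= 3L && is.numeric(edges[[3L]])) edges[[3L]] else NULL
  loops <- from == to
  if (any(loops)) {
    if (!quiet) inform(sprintf("Dropped %d self-loop(s).", sum(loops)))
    from <- from[!loops]; to <- to[!loops]
    if (!is.null(weight)) weight <- weight[!loops]
  }
  a <- pmin(from, to); b <- pmax(from, to)
  out <- tibble(from = a, to = b)
  if (!is.null(weight)) out$weight <- weight
  if (nrow(out)) {
    key <- pair_key(out$from, out$to)
    if (!is.null(weight)) {
      # keep the max-|weight| representative of each duplicated pair
      ord <- order(key, -abs(out$weight))
      out <- out[ord, ][!duplicated(key[ord]), ]
    } else {
      out <- out[!duplicated(key), ]
    }
    out <- out[order(out$from, out$to), ]
  }
  out
}

#' Node set of a network
#'
#' @param net Network tibble.
#' @param nodes Optional extra nodes (e.g. isolated genes) to include.
#' @return Sorted character vector of node names.
#' @export
network_nodes <- function(net, nodes = NULL) {
  sort(unique(c(net$from, net$to, if (!is.null(nodes)) toupper(nodes))))
}

# igraph view of an edge tibble (used for distances/components/motifs).
as_igraph <- function(net, nodes = NULL) {
  vs <- network_nodes(net, nodes)
  igraph::graph_from_data_frame(net[, c("from", "to")], directed = FALSE,
                                vertices = data.frame(name = vs))
}

#' Read an expression matrix from a TSV file
#'
#' Expects a tab-separated file with one header row. By default rows are
#' samples: the first column holds sample identifiers and the remaining
#' header fields are protein/antibody identifiers. With `transpose = TRUE`
#' the file is read variables-in-rows and transposed.
#'
#' @param path Path to the TSV file.
#' @param transpose Set when the file stores variables in rows.
#' @return A tibble: first column `sample_id`, remaining columns numeric.
#' @export
read_expression <- function(path, transpose = FALSE) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, name_repair = "minimal")
  if (ncol(raw) < 2L) data_error(sprintf("'%s': expected at least two columns.", path))
  if (transpose) {
    vals <- t(as.matrix(raw[, -1L, drop = FALSE]))
    out <- as_tibble(vals, .name_repair = "minimal")
    colnames(out) <- as.character(raw[[1L]])
    out <- tibble(sample_id = colnames(raw)[-1L], out)
    raw <- out
  }
  ids <- as.character(raw[[1L]])
  vars <- colnames(raw)[-1L]
  if (anyDuplicated(vars)) {
    data_error(sprintf("'%s': duplicate variable identifier(s): %s", path,
                       paste(unique(vars[duplicated(vars)]), collapse = ", ")))
  }
  parsed <- lapply(seq_along(vars), function(j) {
    v <- raw[[j + 1L]]
    x <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(x))
    if (length(bad)) {
      data_error(sprintf("'%s': non-numeric value '%s' at row '%s', column '%s'.",
                         path, v[bad[1L]], ids[bad[1L]], vars[j]))
    }
    x
  })
  names(parsed) <- vars
  out <- tibble(sample_id = ids)
  dplyr::bind_cols(out, as_tibble(parsed))
}

#' Write an expression matrix as TSV
#'
#' @param expr Expression tibble (first column sample ids).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  df <- expr
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 15, format = "g"))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read an antibody-to-gene-symbol mapping
#'
#' Two-column TSV (identifier, gene symbol) with a header row. Symbols are
#' stored uppercase; duplicate identifiers are an error.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `id` and `symbol`.
#' @export
read_gene_mapping <- function(path) {
  raw <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  if (ncol(raw) < 2L) data_error(sprintf("'%s': mapping needs two columns.", path))
  out <- tibble(id = as.character(raw[[1L]]), symbol = toupper(as.character(raw[[2L]])))
  if (anyDuplicated(out$id)) {
    data_error(sprintf("'%s': duplicate mapping key(s): %s", path,
                       paste(unique(out$id[duplicated(out$id)]), collapse = ", ")))
  }
  if (any(!nzchar(out$symbol))) data_error(sprintf("'%s': empty gene symbol(s).", path))
  out
}

#' Rename expression columns from antibody ids to gene symbols
#'
#' Columns are kept at antibody resolution: when several antibodies map to
#' the same gene the repeated symbols are disambiguated with a
#' middle-dot suffix (`TP53`, `TP53·2`, ...). The gene-level collapse is
#' deferred to edge level (see [collapse_to_gene_edges()]), so inference
#' runs per antibody.
#'
#' @param expr Expression tibble.
#' @param mapping Mapping tibble from [read_gene_mapping()] (columns `id`,
#'   `symbol`), or a named character vector.
#' @param strict Error on unmapped identifiers (default); otherwise drop
#'   unmapped columns with a message.
#' @return The expression tibble with renamed (and possibly fewer) columns.
#' @export
map_to_genes <- function(expr, mapping, strict = TRUE) {
  if (is.data.frame(mapping)) {
    map <- setNames(toupper(as.character(mapping[[2L]])), as.character(mapping[[1L]]))
  } else {
    map <- setNames(toupper(as.character(mapping)), names(mapping))
  }
  vars <- colnames(expr)[-1L]
  hit <- vars %in% names(map)
  if (!all(hit)) {
    if (strict) {
      data_error(paste0("Unmapped variable identifier(s): ",
                        paste(vars[!hit], collapse = ", ")))
    }
    inform(sprintf("Dropping %d unmapped column(s).", sum(!hit)))
    expr <- expr[, c(TRUE, hit)]
    vars <- vars[hit]
  }
  sym <- unname(map[vars])
  # disambiguate repeated symbols with a middle-dot counter suffix
  dup <- stats::ave(seq_along(sym), sym, FUN = seq_along)
  sym <- ifelse(dup > 1L, paste0(sym, "·", dup), sym)
  colnames(expr) <- c(colnames(expr)[1L], sym)
  expr
}

#' Strip antibody-disambiguation suffixes from symbols
#'
#' @param x Character vector of node/column names.
#' @return The gene symbols with any `·k` suffix removed.
#' @export
strip_antibody_suffix <- function(x) {
  sub("·\\d+$", "", x)
}

#' Read an undirected network from an edge-list file
#'
#' Supports two-column TSV (with or without a third numeric weight column)
#' and SIF (source, relation, target). Duplicate and reversed-duplicate
#' edges are collapsed and self-loops dropped with a message.
#'
#' @param path Path to the file.
#' @param format `"tsv"` or `"sif"`.
#' @param header Whether the TSV file has a header row (SIF never does).
#' @return A canonical network tibble (see [as_network()]).
#' @export
read_network <- function(path, format = c("tsv", "sif"), header = TRUE) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (format == "tsv" && header && length(lines)) lines <- lines[-1L]
  if (!length(lines)) return(as_network(tibble(from = character(), to = character())))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  need <- if (format == "sif") 3L else 2L
  nf <- lengths(parts)
  if (any(nf < need)) {
    bad <- which(nf < need)[1L] + as.integer(format == "tsv" && header)
    data_error(sprintf("'%s': malformed line %d (expected %d fields).", path, bad, need))
  }
  from <- vapply(parts, `[[`, "", 1L)
  if (format == "sif") {
    to <- vapply(parts, `[[`, "", 3L)
    df <- tibble(from = from, to = to)
  } else {
    to <- vapply(parts, `[[`, "", 2L)
    df <- tibble(from = from, to = to)
    if (all(nf >= 3L)) {
      w <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
      if (!anyNA(w)) df$weight <- w
    }
  }
  as_network(df)
}

#' Write a network as TSV or SIF
#'
#' Edges are written in canonical lexicographic order so output is
#' deterministic. Weights (TSV only) are written with six significant
#' digits.
#'
#' @param net Network tibble.
#' @param path Output path.
#' @param format `"tsv"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  net <- as_network(net, quiet = TRUE)
  if (format == "sif") {
    writeLines(if (nrow(net)) paste(net$from, "pp", net$to, sep = "\t") else character(),
               path)
    return(invisible(path))
  }
  hdr <- if ("weight" %in% names(net)) "from\tto\tweight" else "from\tto"
  body <- if (!nrow(net)) character() else if ("weight" %in% names(net)) {
    paste(net$from, net$to, formatC(net$weight, digits = 6, format = "g"), sep = "\t")
  } else {
    paste(net$from, net$to, sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Induce a subnetwork on a gene set
#'
#' Keeps exactly the edges whose both endpoints belong to `genes`
#' (case-insensitive). Inducing on a network's own node set is the
#' identity; the operation is idempotent.
#'
#' @param net Network tibble.
#' @param genes Character vector of gene symbols.
#' @return The induced network tibble (possibly empty).
#' @export
induce_subnetwork <- function(net, genes) {
  genes <- toupper(genes)
  net[net$from %in% genes & net$to %in% genes, , drop = FALSE]
}

#' Read gene sets from a GMT file
#'
#' @param path Path to the GMT file (set name, description, member genes,
#'   tab-separated).
#' @return A named list of uppercase gene-symbol vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) data_error(sprintf("'%s': malformed GMT line %d.", path, bad[1L]))
  sets <- lapply(parts, function(x) unique(toupper(x[-(1:2)])))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  sets
}

#' Read a three-column edge class map
#'
#' @param path TSV with columns geneA, geneB, class and a header row.
#' @return Tibble with columns `from`, `to`, `class` (canonical edge order).
#' @export
read_class_map <- function(path) {
  raw <- readr::read_tsv(path, col_types = "ccc", progress = FALSE)
  if (ncol(raw) < 3L) data_error(sprintf("'%s': class map needs three columns.", path))
  a <- toupper(raw[[1L]]); b <- toupper(raw[[2L]])
  tibble(from = pmin(a, b), to = pmax(a, b), class = as.character(raw[[3L]]))
}
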