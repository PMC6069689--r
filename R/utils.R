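# Internal helpers shared across modules.

config_error <- function(msg) abort(msg, class = "ppinet_config_error")
data_error <- function(msg) abort(msg, class = "ppinet_data_error")
numeric_error <- function(msg) abort(msg, class = "ppinet_numeric_error")

# Extract the numeric sample x protein matrix from an expression tibble
# (first column = sample identifier, remaining columns numeric).
expr_matrix <- function(expr, min_n = 3L, min_p = 2L) {
  if (!is.data.frame(expr) || ncol(expr) < 2L) {
    data_error("Expression data must be a data frame with a sample-id column and at least one protein column.")
  }
  ids <- as.character(expr[[1L]])
  vars <- colnames(expr)[-1L]
  if (anyDuplicated(vars)) {
    data_error(paste0("Duplicate variable identifiers: ",
                      paste(unique(vars[duplicated(vars)]), collapse = ", ")))
  }
  x <- as.matrix(expr[, -1L, drop = FALSE])
  if (!is.numeric(x)) {
    bad <- vars[!vapply(expr[-1L], is.numeric, logical(1L))]
    data_error(paste0("Non-numeric expression column(s): ", paste(bad, collapse = ", ")))
  }
  if (any(!is.finite(x))) {
    idx <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    data_error(sprintf("Non-finite expression value at sample '%s', variable '%s'.",
                       ids[idx[1L]], vars[idx[2L]]))
  }
  if (nrow(x) < min_n || ncol(x) < min_p) {
    data_error(sprintf("Need at least %d samples and %d variables; got %d x %d.",
                       min_n, min_p, nrow(x), ncol(x)))
  }
  rownames(x) <- ids
  x
}

# Column standardization to zero mean / unit variance (sample sd).
standardize_cols <- function(x) {
  s <- apply(x, 2L, sd)
  if (any(s == 0)) {
    data_error(paste0("Zero-variance column(s): ",
                      paste(colnames(x)[s == 0], collapse = ", ")))
  }
  scale(x, center = TRUE, scale = s)
}

# Canonical unordered pair key (endpoints sorted lexicographically).
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

# All unordered pairs over a node universe, as a two-column tibble in
# canonical (lexicographic) order.
all_pairs <- function(universe) {
  universe <- sort(unique(universe))
  if (length(universe) < 2L) {
    return(tibble(from = character(), to = character()))
  }
  cmb <- combn(universe, 2L)
  tibble(from = cmb[1L, ], to = cmb[2L, ])
}

n_pairs <- function(universe) {
  m <- length(unique(universe))
  as.integer(m * (m - 1L) / 2L)
}

# Upper-triangle values of a symmetric matrix as a tibble of pairs.
upper_pairs <- function(mat, value_name = "score") {
  p <- ncol(mat)
  ids <- colnames(mat)
  ut <- upper.tri(mat)
  idx <- which(ut, arr.ind = TRUE)
  out <- tibble(from = ids[idx[, 1L]], to = ids[idx[, 2L]])
  out[[value_name]] <- mat[ut]
  # canonicalize endpoint order without reordering rows
  swap <- out$from > out$to
  if (any(swap)) {
    tmp <- out$from[swap]
    out$from[swap] <- out$to[swap]
    out$to[swap] <- tmp
  }
  out
}

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
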