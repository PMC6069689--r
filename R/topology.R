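# Network topology analytics: summary statistics, rank-sum comparison,
# minimum dominating sets, collective influence, cross-condition core
# module, node replication for multi-label annotations, and colored
# non-induced motif counting with a degree-preserving rewiring null.

#' Summary statistics of a network
#'
#' Density, mean degree, mean local clustering (nodes of degree < 2
#' contribute 0), number of connected components and largest component
#' size.
#'
#' @param net Network tibble.
#' @param nodes Optional node universe including isolated nodes.
#' @return One-row tibble of statistics.
#' @export
network_stats <- function(net, nodes = NULL) {
  g <- as_igraph(net, nodes)
  nn <- igraph::vcount(g); ne <- igraph::ecount(g)
  if (nn < 1L) data_error("Network has no nodes.")
  cl <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  comp <- igraph::components(g)
  tibble(
    n_nodes = nn, n_edges = ne,
    density = if (nn >= 2L) 2 * ne / (nn * (nn - 1)) else 0,
    mean_degree = 2 * ne / nn,
    clustering_coefficient = if (nn) mean(cl) else NA_real_,
    n_components = comp$no,
    largest_component_size = max(comp$csize)
  )
}

#' Compare one network property across two groups (Wilcoxon rank-sum)
#'
#' Two-sided Wilcoxon rank-sum test on a column of two stacks of network
#' statistics (exact p-value for small tie-free samples, normal
#' approximation with tie correction otherwise, as in
#' [stats::wilcox.test()]).
#'
#' @param a,b Data frames of network statistics (rows = networks), e.g.
#'   rows of [network_stats()] output; each needs at least 3 rows.
#' @param property Name of the column to compare.
#' @return The two-sided p-value.
#' @export
compare_stats <- function(a, b, property) {
  if (!property %in% names(a) || !property %in% names(b)) {
    config_error(sprintf("Unknown network property '%s'.", property))
  }
  x <- a[[property]]; y <- b[[property]]
  if (length(x) < 3L || length(y) < 3L) config_error("Each group needs at least 3 networks.")
  suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))$p.value
}

#' Minimum dominating set
#'
#' Smallest node set S such that every node is in S or adjacent to a member
#' of S. Solved exactly by branch and bound (greedy upper bound, branching
#' on an undominated node's closed neighbourhood) up to `exact_limit`
#' nodes; larger networks fall back to the greedy approximation with a
#' warning. Ties are broken towards lexicographically smaller node names,
#' so the result is deterministic.
#'
#' @param net Network tibble.
#' @param nodes Optional node universe (isolated nodes dominate themselves).
#' @param exact_limit Largest node count solved exactly (default 300).
#' @return Character vector of dominating nodes (sorted).
#' @export
minimum_dominating_set <- function(net, nodes = NULL, exact_limit = 300L) {
  vs <- network_nodes(net, nodes)
  n <- length(vs)
  if (n == 0L) return(character(0))
  idx <- seq_len(n)
  adj <- lapply(idx, function(i) i)       # closed neighbourhoods
  if (nrow(net)) {
    fi <- match(net$from, vs); ti <- match(net$to, vs)
    for (e in seq_along(fi)) {
      adj[[fi[e]]] <- c(adj[[fi[e]]], ti[e])
      adj[[ti[e]]] <- c(adj[[ti[e]]], fi[e])
    }
    adj <- lapply(adj, function(x) sort(unique(x)))
  }
  greedy <- function() {
    undom <- rep(TRUE, n)
    sol <- integer(0)
    while (any(undom)) {
      gain <- vapply(idx, function(i) sum(undom[adj[[i]]]), integer(1L))
      pick <- which.max(gain)  # first max = lexicographically smallest name
      sol <- c(sol, pick)
      undom[adj[[pick]]] <- FALSE
    }
    sol
  }
  if (n > exact_limit) {
    warn(sprintf("Network has %d nodes (> %d); using the greedy approximation.", n, exact_limit))
    return(sort(vs[greedy()]))
  }
  best <- greedy()
  max_cover <- max(lengths(adj))
  search <- function(chosen, undom) {
    if (!any(undom)) {
      if (length(chosen) < length(best)) best <<- chosen
      return(invisible())
    }
    lb <- length(chosen) + ceiling(sum(undom) / max_cover)
    if (lb >= length(best)) return(invisible())
    # branch on the undominated node with the fewest candidate dominators
    und_idx <- which(undom)
    ncand <- vapply(und_idx, function(u) length(adj[[u]]), integer(1L))
    u <- und_idx[which.min(ncand)]
    for (v in adj[[u]]) {
      nd <- undom
      nd[adj[[v]]] <- FALSE
      search(c(chosen, v), nd)
    }
  }
  search(integer(0), rep(TRUE, n))
  sort(vs[best])
}

#' Collective influence centrality
#'
#' `CI_l(i) = (k_i - 1) * sum over nodes j at distance exactly l from i of
#' (k_j - 1)`, where `k` is the degree. Degree-1 and isolated nodes have
#' CI 0.
#'
#' @param net Network tibble.
#' @param nodes Optional node universe.
#' @param ell Ball radius (default 2).
#' @return Tibble with columns `node`, `degree`, `ci`.
#' @export
collective_influence <- function(net, nodes = NULL, ell = 2L) {
  if (ell < 1L) config_error("`ell` must be at least 1.")
  g <- as_igraph(net, nodes)
  vs <- igraph::V(g)$name
  k <- igraph::degree(g)
  d <- igraph::distances(g)
  ci <- vapply(seq_along(vs), function(i) {
    frontier <- which(d[i, ] == ell)
    (k[i] - 1) * sum(k[frontier] - 1)
  }, numeric(1L))
  tibble(node = vs, degree = as.integer(k), ci = ci)
}

#' Core module: edges common to all networks
#'
#' @param nets List of at least two network tibbles.
#' @return The intersection network tibble (canonical order), with the
#'   component membership of each edge's endpoints available via
#'   [network_stats()].
#' @export
core_module <- function(nets) {
  if (length(nets) < 2L) config_error("`nets` must contain at least two networks.")
  keysets <- lapply(nets, function(n) unique(pair_key(toupper(n$from), toupper(n$to))))
  common <- Reduce(intersect, keysets)
  if (!length(common)) return(tibble(from = character(), to = character()))
  parts <- strsplit(common, "\r", fixed = TRUE)
  out <- tibble(from = vapply(parts, `[[`, "", 1L),
                to = vapply(parts, `[[`, "", 2L))
  out[order(out$from, out$to), ]
}

#' Replicate multi-label nodes into single-label copies
#'
#' Motif counting requires a unique label per node. A node annotated with
#' `n` labels becomes `n` copies (named `node·label`), each inheriting all
#' incident edges; an edge between two multi-label nodes therefore expands
#' into all label-pair combinations. Unannotated nodes receive
#' `default_label`.
#'
#' @param net Network tibble.
#' @param annotations Either a data frame with columns `node`, `label`
#'   (repeated rows for multi-label nodes) or a named list of label
#'   vectors.
#' @param default_label Label for unannotated nodes (default `"GENERIC"`).
#' @return A list with `network` (the replicated edge tibble) and `labels`
#'   (tibble `node`, `label`, one row per replicated node).
#' @export
replicate_multilabel_nodes <- function(net, annotations, default_label = "GENERIC") {
  if (is.data.frame(annotations)) {
    ann <- split(as.character(annotations[[2L]]), toupper(as.character(annotations[[1L]])))
  } else {
    ann <- annotations
    names(ann) <- toupper(names(ann))
  }
  ann <- lapply(ann, function(x) unique(as.character(x)))
  nodes <- network_nodes(net)
  labels_of <- function(v) {
    l <- ann[[v]]
    if (is.null(l) || !length(l)) default_label else l
  }
  copies <- lapply(nodes, function(v) {
    l <- labels_of(v)
    tibble(node = if (length(l) > 1L) paste0(v, "·", l) else v,
           original = v, label = l)
  })
  copies <- dplyr::bind_rows(copies)
  rep_edges <- purrr::map_dfr(seq_len(nrow(net)), function(e) {
    a <- copies[copies$original == net$from[e], ]
    b <- copies[copies$original == net$to[e], ]
    tidyr::expand_grid(from = a$node, to = b$node)
  })
  rep_edges <- if (nrow(rep_edges)) as_network(rep_edges, quiet = TRUE) else
    tibble(from = character(), to = character())
  list(network = rep_edges,
       labels = tibble(node = copies$node, label = copies$label))
}

# --- colored non-induced motif machinery -----------------------------------

# canonical code of a small labeled graph: lexicographically smallest
# label-string + adjacency-bit encoding over all node permutations
canonical_pattern <- function(labels, adj) {
  s <- length(labels)
  perms <- all_permutations(s)
  best <- NULL
  for (pi in perms) {
    code <- paste0(paste(labels[pi], collapse = ","), "|",
                   paste(as.integer(adj[pi, pi][upper.tri(adj)]), collapse = ""))
    if (is.null(best) || code < best) best <- code
  }
  best
}

all_permutations <- function(s) {
  if (s == 1L) return(list(1L))
  sub <- all_permutations(s - 1L)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(s)) {
      out[[length(out) + 1L]] <- append(p, s, after = pos - 1L)
    }
  }
  out
}

# enumerate all connected node subsets of a given size (ESU-style unique
# enumeration); adjacency as a list of integer neighbour vectors
connected_subsets <- function(nbr, size) {
  n <- length(nbr)
  out <- list()
  extend <- function(sub, extension, v) {
    if (length(sub) == size) {
      out[[length(out) + 1L]] <<- sub
      return(invisible())
    }
    while (length(extension)) {
      w <- extension[1L]
      extension <- extension[-1L]
      excl <- unlist(lapply(nbr[sub], identity))
      new_ext <- c(extension, setdiff(nbr[[w]][nbr[[w]] > v], c(sub, excl, extension, w)))
      extend(c(sub, w), new_ext, v)
    }
  }
  for (v in seq_len(n)) {
    ext <- nbr[[v]][nbr[[v]] > v]
    extend(v, ext, v)
  }
  out
}

# count non-induced colored patterns: for every connected subset of `size`
# nodes, every connected spanning edge-subset of its induced subgraph is
# one occurrence of the corresponding canonical labeled pattern
count_patterns <- function(edges_idx, labels, n, size) {
  nbr <- lapply(seq_len(n), function(i) integer(0))
  if (nrow(edges_idx)) {
    for (e in seq_len(nrow(edges_idx))) {
      i <- edges_idx[e, 1L]; j <- edges_idx[e, 2L]
      nbr[[i]] <- c(nbr[[i]], j); nbr[[j]] <- c(nbr[[j]], i)
    }
    nbr <- lapply(nbr, function(x) sort(unique(x)))
  }
  counts <- new.env(parent = emptyenv())
  bump <- function(code) {
    assign(code, (get0(code, envir = counts) %||% 0L) + 1L, envir = counts)
  }
  subsets <- connected_subsets(nbr, size)
  npairs <- size * (size - 1L) / 2L
  pair_i <- combn(size, 2L)
  for (sub in subsets) {
    adj <- matrix(FALSE, size, size)
    for (q in seq_len(npairs)) {
      a <- sub[pair_i[1L, q]]; b <- sub[pair_i[2L, q]]
      adj[pair_i[1L, q], pair_i[2L, q]] <- adj[pair_i[2L, q], pair_i[1L, q]] <- b %in% nbr[[a]]
    }
    present <- which(adj[upper.tri(adj)])
    labs <- labels[sub]
    # iterate over non-empty subsets of present edges; keep spanning + connected
    m <- length(present)
    if (!m) next
    for (mask in seq_len(2L^m - 1L)) {
      sel <- present[bitwAnd(bitwShiftR(mask, seq_len(m) - 1L), 1L) == 1L]
      sadj <- matrix(FALSE, size, size)
      ut <- which(upper.tri(sadj))
      sadj[ut[sel]] <- TRUE
      sadj <- sadj | t(sadj)
      if (any(colSums(sadj) == 0L)) next          # spanning
      if (!subgraph_connected(sadj)) next          # connected
      bump(canonical_pattern(labs, sadj))
    }
  }
  vals <- as.list(counts)
  if (!length(vals)) return(tibble(pattern = character(), occurrences = integer()))
  tibble(pattern = names(vals), occurrences = as.integer(unlist(vals)))
}

subgraph_connected <- function(adj) {
  s <- nrow(adj)
  seen <- logical(s)
  stack <- 1L
  seen[1L] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    nb <- which(adj[v, ] & !seen)
    seen[nb] <- TRUE
    stack <- c(stack, nb)
  }
  all(seen)
}

#' Count colored non-induced motifs of 3 or 4 nodes
#'
#' Enumerates every connected node subset of the given size and, within
#' each, every connected spanning sub-pattern of the induced edges; two
#' occurrences count as the same motif when their labeled graphs are
#' isomorphic (label-preserving). A pattern therefore occurs whenever its
#' edges embed as a subset of a subgraph's edges - the non-induced
#' convention, which is robust to missing edges in inferred networks.
#' Significance is assessed against `randomizations` degree-preserving
#' edge rewirings of the network (labels fixed): the p-value is the
#' fraction of randomized networks whose count reaches the observed count.
#'
#' @param net Network tibble (post-replication: one label per node).
#' @param labels Data frame with columns `node`, `label` covering every
#'   node, e.g. from [replicate_multilabel_nodes()].
#' @param size Motif size, 3 or 4.
#' @param randomizations Number of rewired networks for the null (default
#'   100); set to 0 to skip p-values.
#' @param seed Integer seed for the rewiring null.
#' @return Tibble: `pattern` (canonical label/adjacency code), `size`,
#'   `occurrences`, `p_value` (`NA` when `randomizations = 0`).
#' @export
count_colored_motifs <- function(net, labels, size = 3L, randomizations = 100L,
                                 seed = 1L) {
  if (!size %in% c(3L, 4L)) config_error("`size` must be 3 or 4.")
  if (randomizations < 0L) config_error("`randomizations` must be non-negative.")
  vs <- network_nodes(net)
  lab_map <- setNames(as.character(labels$label), toupper(as.character(labels$node)))
  if (length(setdiff(vs, names(lab_map)))) {
    data_error("Every network node needs exactly one label.")
  }
  labs <- unname(lab_map[vs])
  eidx <- cbind(match(net$from, vs), match(net$to, vs))
  obs <- count_patterns(eidx, labs, length(vs), size)
  obs$size <- as.integer(size)
  if (!randomizations || !nrow(obs)) {
    obs$p_value <- NA_real_
    return(obs[, c("pattern", "size", "occurrences", "p_value")])
  }
  g <- as_igraph(net, vs)
  hits <- setNames(integer(nrow(obs)), obs$pattern)
  withr::with_seed(seed, {
    for (r in seq_len(randomizations)) {
      gr <- igraph::rewire(g, igraph::keeping_degseq(niter = max(10L * igraph::ecount(g), 1L)))
      el <- igraph::as_edgelist(gr, names = FALSE)
      rc <- count_patterns(el, labs, length(vs), size)
      cnt <- setNames(rc$occurrences, rc$pattern)
      got <- cnt[obs$pattern]
      got[is.na(got)] <- 0L
      hits <- hits + as.integer(got >= obs$occurrences)
    }
  })
  obs$p_value <- as.numeric(hits[obs$pattern]) / randomizations
  out <- obs[order(-obs$occurrences, obs$pattern), c("pattern", "size", "occurrences", "p_value")]
  out
}
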