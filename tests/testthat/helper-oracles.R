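# Independent brute-force oracles and small fixture generators used across
# the test files. Every oracle is written as a direct transcription of the
# defining formula (loops, enumeration, closed forms) so it shares no code
# path with the package implementation.

expr_fixture <- function(n, p, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p)
    colnames(x) <- sprintf("P%02d", seq_len(p))
    tibble::tibble(sample_id = sprintf("S%03d", seq_len(n)),
                   tibble::as_tibble(as.data.frame(x)))
  })
}

expr_from_matrix <- function(x) {
  if (is.null(colnames(x))) colnames(x) <- sprintf("P%02d", seq_len(ncol(x)))
  tibble::tibble(sample_id = sprintf("S%03d", seq_len(nrow(x))),
                 tibble::as_tibble(as.data.frame(x)))
}

random_edge_tibble <- function(nodes, n_edges, seed = 1) {
  pairs <- t(combn(nodes, 2))
  withr::with_seed(seed, {
    sel <- sample.int(nrow(pairs), min(n_edges, nrow(pairs)))
  })
  tibble::tibble(from = pairs[sel, 1], to = pairs[sel, 2])
}

score_matrix <- function(x) x$scores

# --- correlation / TOM / partial correlation --------------------------------

oracle_pearson <- function(x) {
  n <- nrow(x); p <- ncol(x)
  out <- diag(p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    xi <- x[, i] - mean(x[, i]); xj <- x[, j] - mean(x[, j])
    out[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
  }
  out
}

oracle_tom <- function(x, beta = 6) {
  a <- abs(oracle_pearson(scale(x)))^beta
  diag(a) <- 0
  p <- ncol(a)
  tom <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(p)) l <- l + a[i, u] * a[u, j]
    ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
    tom[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  tom
}

# partial correlation of i and j given the rest, via residual regression
oracle_pcor_residuals <- function(x) {
  p <- ncol(x)
  out <- matrix(0, p, p)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    others <- x[, -c(i, j), drop = FALSE]
    ri <- stats::lm.fit(cbind(1, others), x[, i])$residuals
    rj <- stats::lm.fit(cbind(1, others), x[, j])$residuals
    out[i, j] <- out[j, i] <- stats::cor(ri, rj)
  }
  out
}

# Schaefer-Strimmer shrinkage partial correlation, directly from the
# analytic lambda formula
oracle_genenet <- function(x) {
  n <- nrow(x); p <- ncol(x)
  xs <- scale(x) # unit sample sd
  r <- crossprod(xs) / (n - 1)
  num <- 0; den <- 0
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    w <- xs[, i] * xs[, j]
    num <- num + n / (n - 1)^3 * sum((w - mean(w))^2)  # Var-hat(r_ij)
    den <- den + r[i, j]^2
  }
  lambda <- max(0, min(1, num / den))
  rs <- (1 - lambda) * r
  diag(rs) <- 1
  om <- solve(rs)
  pc <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i != j) pc[i, j] <- -om[i, j] / sqrt(om[i, i] * om[j, j])
  }
  list(pcor = pc, lambda = lambda)
}

# graphical lasso KKT conditions: with W = Theta^{-1},
#   |S - W| <= rho on zero off-diagonals, S - W + rho*sign(Theta) = 0 on
#   the support, S - W = 0 on the diagonal (W has rho-inflated diagonal).
glasso_kkt_gap <- function(S, theta, rho) {
  W <- solve(theta)
  p <- ncol(S)
  gap <- 0
  for (i in seq_len(p)) for (j in seq_len(p)) {
    g <- S[i, j] - W[i, j]
    if (i == j) {
      gap <- max(gap, abs(g + rho))
    } else if (theta[i, j] != 0) {
      gap <- max(gap, abs(g + rho * sign(theta[i, j])))
    } else {
      gap <- max(gap, max(abs(g) - rho, 0))
    }
  }
  gap
}

# --- regression -------------------------------------------------------------

# elastic-net coordinate descent on glmnet's actual objective. glmnet
# standardizes y internally by its 1/n-denominator sd, which leaves the L1
# penalty at lambda*alpha but divides the L2 penalty by sd_n(y):
#   1/(2n) ||y - Zb||^2 + lambda*alpha |b|_1
#                       + lambda*(1-alpha)/(2*sd_n(y)) ||b||^2
# (verified against closed-form ridge). Run to near machine precision.
oracle_enet <- function(z, y, lambda, alpha, tol = 1e-14, maxit = 1e5) {
  n <- nrow(z); p <- ncol(z)
  b <- numeric(p)
  zz <- colSums(z^2) / n
  sy <- sqrt(sum((y - mean(y))^2) / n)
  l1 <- lambda * alpha
  l2 <- lambda * (1 - alpha) / sy
  for (it in seq_len(maxit)) {
    delta <- 0
    for (k in seq_len(p)) {
      r <- y - z %*% b + z[, k] * b[k]
      rho_k <- sum(z[, k] * r) / n
      new <- sign(rho_k) * max(abs(rho_k) - l1, 0) / (zz[k] + l2)
      delta <- max(delta, abs(new - b[k]))
      b[k] <- new
    }
    if (delta < tol) break
  }
  b
}

# PLS1 coefficients via the Krylov-subspace characterization: the a-component
# PLS solution is the least-squares fit restricted to
# span{Z'y, (Z'Z) Z'y, ..., (Z'Z)^(a-1) Z'y}
oracle_pls_krylov <- function(z, y, ncomp) {
  zz <- crossprod(z)
  zy <- crossprod(z, y)
  k <- matrix(0, ncol(z), ncomp)
  v <- zy
  for (a in seq_len(ncomp)) {
    k[, a] <- v
    v <- zz %*% v
  }
  q <- qr.Q(qr(k))
  drop(q %*% solve(crossprod(q, zz %*% q), crossprod(q, zy)))
}

# --- mutual information family ----------------------------------------------

oracle_hand_mi <- function(a, b) {
  # plug-in MI of two integer-coded vectors, via explicit probability sums
  n <- length(a)
  mi <- 0
  for (u in unique(a)) for (v in unique(b)) {
    puv <- sum(a == u & b == v) / n
    if (puv > 0) mi <- mi + puv * log(puv / ((sum(a == u) / n) * (sum(b == v) / n)))
  }
  mi
}

oracle_aracne <- function(mi, mode, eps = 0) {
  p <- ncol(mi)
  out <- mi
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    for (k in seq_len(p)) {
      if (k == i || k == j) next
      floor_k <- min(mi[i, k], mi[j, k])
      drop <- if (mode == "additive") mi[i, j] < floor_k - eps
              else mi[i, j] < floor_k * (1 - eps)
      if (drop) out[i, j] <- 0
    }
  }
  diag(out) <- 0
  out
}

oracle_clr <- function(mi) {
  p <- ncol(mi)
  z <- matrix(0, p, p)
  for (i in seq_len(p)) {
    vals <- mi[i, -i]
    mu <- mean(vals); sg <- stats::sd(vals)
    for (j in seq_len(p)) {
      z[i, j] <- if (sg > 0) max(0, (mi[i, j] - mu) / sg) else 0
    }
  }
  out <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    out[i, j] <- sqrt(z[i, j]^2 + z[j, i]^2)
  }
  diag(out) <- 0
  out
}

oracle_mrnet <- function(mi) {
  p <- ncol(mi)
  u <- matrix(0, p, p)
  for (j in seq_len(p)) {
    cand <- setdiff(seq_len(p), j)
    sel <- integer(0)
    repeat {
      if (!length(cand)) break
      crit <- sapply(cand, function(k) {
        mi[k, j] - if (length(sel)) mean(mi[k, sel]) else 0
      })
      best <- cand[which.max(crit)]
      if (max(crit) <= 0) break
      u[best, j] <- max(crit)
      sel <- c(sel, best)
      cand <- setdiff(cand, best)
    }
  }
  out <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) out[i, j] <- max(u[i, j], u[j, i], 0)
  diag(out) <- 0
  out
}

# --- graph oracles ----------------------------------------------------------

# pairs within distance <= k via boolean adjacency-matrix powers
oracle_within_k <- function(adj, k) {
  reach <- adj
  power <- adj
  if (k >= 2) for (s in 2:k) {
    power <- (power %*% adj) > 0
    reach <- reach | power
  }
  diag(reach) <- FALSE
  reach
}

edge_tibble_to_adj <- function(net, nodes) {
  p <- length(nodes)
  adj <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  if (nrow(net)) {
    for (e in seq_len(nrow(net))) {
      i <- match(net$from[e], nodes); j <- match(net$to[e], nodes)
      adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  adj
}

oracle_mds_size <- function(adj) {
  p <- ncol(adj)
  closed <- adj | diag(p) > 0
  for (size in 0:p) {
    if (size == 0) { if (p == 0) return(0) else next }
    for (set in utils::combn(p, size, simplify = FALSE)) {
      dominated <- rep(FALSE, p)
      for (v in set) dominated <- dominated | closed[v, ]
      if (all(dominated)) return(size)
    }
  }
  p
}

oracle_ci <- function(adj, ell) {
  p <- ncol(adj)
  deg <- rowSums(adj)
  # BFS distances
  d <- matrix(Inf, p, p)
  for (s in seq_len(p)) {
    d[s, s] <- 0
    frontier <- s
    dist <- 0
    while (length(frontier)) {
      dist <- dist + 1
      nxt <- integer(0)
      for (v in frontier) nxt <- c(nxt, which(adj[v, ]))
      nxt <- setdiff(unique(nxt), which(is.finite(d[s, ])))
      d[s, nxt] <- dist
      frontier <- nxt
    }
  }
  sapply(seq_len(p), function(i) {
    (deg[i] - 1) * sum(deg[which(d[i, ] == ell)] - 1)
  })
}

# --- colored motif oracle: count label-preserving injective embeddings of
# every connected labeled pattern, divided by the pattern's labeled
# automorphism count ------------------------------------------------------

perms_of <- function(s) {
  if (s == 1) return(list(1L))
  out <- list()
  for (p in perms_of(s - 1)) for (pos in seq_len(s)) {
    out[[length(out) + 1]] <- append(p, s, after = pos - 1)
  }
  out
}

pattern_code <- function(labels, adj) {
  best <- NULL
  for (pi in perms_of(length(labels))) {
    code <- paste0(paste(labels[pi], collapse = ","), "|",
                   paste(as.integer(adj[pi, pi][upper.tri(adj)]), collapse = ""))
    if (is.null(best) || code < best) best <- code
  }
  best
}

connected_adj <- function(adj) {
  s <- nrow(adj)
  seen <- logical(s); seen[1] <- TRUE
  repeat {
    new <- unique(unlist(lapply(which(seen), function(v) which(adj[v, ]))))
    if (all(seen[new])) break
    seen[new] <- TRUE
  }
  all(seen)
}

# independent motif route: embeddings / labeled automorphisms
oracle_motif_counts_embeddings <- function(adj, labels, size) {
  p <- ncol(adj)
  # collect candidate patterns = all (labels, edge set) seen, then count
  # injective label-preserving edge-subset embeddings over the whole graph
  pats <- list()
  add_pat <- function(plabs, padj) {
    code <- pattern_code(plabs, padj)
    if (is.null(pats[[code]])) pats[[code]] <<- list(labels = plabs, adj = padj)
    code
  }
  for (subset in utils::combn(p, size, simplify = FALSE)) {
    sub_adj <- adj[subset, subset]
    present <- which(sub_adj[upper.tri(sub_adj)])
    if (!length(present)) next
    ut <- which(upper.tri(sub_adj))
    for (mask in seq_len(2^length(present) - 1)) {
      sel <- present[bitwAnd(bitwShiftR(mask, seq_along(present) - 1), 1) == 1]
      padj <- matrix(FALSE, size, size)
      padj[ut[sel]] <- TRUE
      padj <- padj | t(padj)
      if (any(colSums(padj) == 0) || !connected_adj(padj)) next
      add_pat(labels[subset], padj)
    }
  }
  out <- list()
  perms <- perms_of(size)
  for (code in names(pats)) {
    pat <- pats[[code]]
    # automorphisms of the labeled pattern
    aut <- 0L
    for (pi in perms) {
      if (all(pat$labels[pi] == pat$labels) &&
          all(pat$adj[pi, pi] == pat$adj)) aut <- aut + 1L
    }
    # embeddings: ordered injective node tuples preserving labels & edges
    emb <- 0L
    tuples <- utils::combn(p, size, simplify = FALSE)
    for (tup in tuples) {
      for (pi in perms) {
        hosts <- tup[pi]  # pattern node a -> hosts[a]
        if (!all(labels[hosts] == pat$labels)) next
        ok <- TRUE
        for (a in seq_len(size - 1)) for (b in (a + 1):size) {
          if (pat$adj[a, b] && !adj[hosts[a], hosts[b]]) { ok <- FALSE; break }
        }
        if (ok) emb <- emb + 1L
      }
    }
    out[[code]] <- as.integer(emb / aut)
  }
  out
}
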