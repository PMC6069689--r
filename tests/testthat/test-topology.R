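# Network statistics, rank-sum comparison, dominating sets, collective
# influence, core module, node replication and colored motif counting.

tri_net <- tibble::tibble(from = c("A", "A", "B"), to = c("B", "C", "C"))
path4 <- tibble::tibble(from = c("A", "B", "C"), to = c("B", "C", "D"))

test_that("network statistics match hand values on canonical small graphs", {
  s <- network_stats(tri_net)
  expect_equal(s$density, 1)
  expect_equal(s$clustering_coefficient, 1)
  expect_equal(s$n_components, 1)

  s2 <- network_stats(path4)
  expect_equal(s2$clustering_coefficient, 0)
  expect_equal(s2$mean_degree, 1.5)
  expect_equal(s2$largest_component_size, 4)

  # isolated nodes via the universe argument
  s3 <- network_stats(tri_net, nodes = c("A", "B", "C", "Z"))
  expect_equal(s3$n_nodes, 4)
  expect_equal(s3$n_components, 2)
})

test_that("clustering equals brute-force triangle counting on random graphs", {
  withr::with_seed(55, {
    for (rep in seq_len(20)) {
      nn <- sample(5:12, 1)
      nodes <- sprintf("N%02d", seq_len(nn))
      net <- as_network(random_edge_tibble(nodes, sample.int(nn * 2, 1),
                                           seed = sample.int(1e6, 1)))
      adj <- edge_tibble_to_adj(net, nodes)
      deg <- rowSums(adj)
      local <- sapply(seq_len(nn), function(v) {
        if (deg[v] < 2) return(0)
        nbrs <- which(adj[v, ])
        links <- sum(adj[nbrs, nbrs]) / 2
        links / choose(deg[v], 2)
      })
      expect_equal(network_stats(net, nodes)$clustering_coefficient, mean(local),
                   tolerance = 1e-12)
    }
  })
})

test_that("rank-sum comparison gives exact small-sample p-values", {
  a <- tibble::tibble(density = c(1, 2, 3, 4, 5))
  b <- tibble::tibble(density = c(6, 7, 8, 9, 10))
  expect_equal(compare_stats(a, b, "density"), 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(compare_stats(a, a, "density"), 1)
  expect_error(compare_stats(a, b, "bogus"), "Unknown")

  # agreement with exact enumeration of the rank-sum distribution
  withr::with_seed(66, {
    for (rep in seq_len(10)) {
      x <- round(rnorm(4), 3); y <- round(rnorm(5), 3)
      if (anyDuplicated(c(x, y))) next
      got <- compare_stats(tibble::tibble(v = x), tibble::tibble(v = y), "v")
      # enumerate all assignments of ranks to group 1
      ranks <- rank(c(x, y))
      w_obs <- sum(ranks[seq_along(x)]) - length(x) * (length(x) + 1) / 2
      all_w <- sapply(utils::combn(9, 4, simplify = FALSE),
                      function(ix) sum(seq_len(9)[ix]) - 4 * 5 / 2)
      p_exact <- mean(abs(all_w - 10) >= abs(w_obs - 10))  # mean W under H0 is nm/2 = 10
      expect_equal(got, p_exact, tolerance = 1e-9)
    }
  })
})

test_that("minimum dominating sets are exact on canonical and random graphs", {
  star <- tibble::tibble(from = rep("HUB", 5), to = sprintf("L%d", 1:5))
  expect_identical(minimum_dominating_set(star), "HUB")
  expect_identical(minimum_dominating_set(tibble::tibble(from = c("A", "B"),
                                                         to = c("B", "C"))), "B")
  expect_identical(minimum_dominating_set(tri_net[0, ]), character(0))
  # isolated nodes must dominate themselves
  expect_identical(minimum_dominating_set(star, nodes = c(network_nodes(star), "ZZ")),
                   c("HUB", "ZZ"))

  withr::with_seed(88, {
    for (rep in seq_len(30)) {
      nn <- sample(4:11, 1)
      nodes <- sprintf("N%02d", seq_len(nn))
      net <- as_network(random_edge_tibble(nodes, sample.int(nn * 2, 1),
                                           seed = sample.int(1e6, 1)))
      adj <- edge_tibble_to_adj(net, nodes)
      mds <- minimum_dominating_set(net, nodes)
      # must dominate
      closed <- adj | diag(nn) > 0
      dominated <- rep(FALSE, nn)
      for (v in match(mds, nodes)) dominated <- dominated | closed[v, ]
      expect_true(all(dominated))
      # must be minimum
      expect_equal(length(mds), oracle_mds_size(adj))
    }
  })
})

test_that("collective influence matches the BFS-frontier brute force", {
  # hand case: path a-b-c-d, ell = 1: CI(b) = (2-1)*((1-1)+(2-1)) = 1
  ci1 <- collective_influence(path4, ell = 1)
  expect_equal(ci1$ci[ci1$node == "B"], 1)
  expect_equal(ci1$ci[ci1$node == "A"], 0)   # degree-1 nodes are always 0

  # 1-regular graph: all zero
  matching <- tibble::tibble(from = c("A", "C"), to = c("B", "D"))
  expect_true(all(collective_influence(matching, ell = 2)$ci == 0))

  withr::with_seed(99, {
    for (rep in seq_len(20)) {
      nn <- sample(5:15, 1)
      nodes <- sprintf("N%02d", seq_len(nn))
      net <- as_network(random_edge_tibble(nodes, sample.int(nn * 2, 1),
                                           seed = sample.int(1e6, 1)))
      adj <- edge_tibble_to_adj(net, nodes)
      for (ell in 1:3) {
        got <- collective_influence(net, nodes, ell = ell)
        expect_equal(got$ci, unname(oracle_ci(adj, ell)),
                     label = sprintf("rep %d ell %d", rep, ell))
      }
    }
  })
})

test_that("core module is the fold of pairwise edge intersections", {
  n1 <- tri_net
  expect_identical(core_module(list(n1, n1, n1)), n1[, c("from", "to")])
  disjoint <- tibble::tibble(from = "X", to = "Y")
  expect_equal(nrow(core_module(list(n1, disjoint))), 0)

  withr::with_seed(111, {
    nodes <- sprintf("N%02d", 1:9)
    nets <- lapply(1:3, function(i)
      as_network(random_edge_tibble(nodes, 14, seed = sample.int(1e6, 1))))
    got <- core_module(nets)
    pairwise <- core_module(list(core_module(nets[1:2]), nets[[3]]))
    expect_identical(got, pairwise)
    for (net in nets) {
      expect_true(all(paste(got$from, got$to) %in% paste(net$from, net$to)))
    }
  })
})

test_that("multi-label nodes replicate with all incident edges", {
  net <- tibble::tibble(from = "A", to = "B")
  rep1 <- replicate_multilabel_nodes(net, list(A = c("P", "S"), B = "CD"))
  expect_setequal(rep1$labels$node, c("A·P", "A·S", "B"))
  expect_setequal(paste(rep1$network$from, rep1$network$to),
                  c("A·P B", "A·S B"))

  # single-label everywhere: identity up to naming
  rep2 <- replicate_multilabel_nodes(net, list(A = "P", B = "S"))
  expect_identical(rep2$network, as_network(net, quiet = TRUE))

  # 3 labels, degree 2: 3 copies, 6 incident edges
  net2 <- tibble::tibble(from = c("A", "A"), to = c("B", "C"))
  rep3 <- replicate_multilabel_nodes(net2, list(A = c("X", "Y", "Z"), B = "L", C = "L"))
  expect_equal(sum(grepl("^A", rep3$labels$node)), 3)
  expect_equal(nrow(rep3$network), 6)

  # unannotated nodes receive the generic label
  rep4 <- replicate_multilabel_nodes(net, list(A = "P"))
  expect_identical(rep4$labels$label[rep4$labels$node == "B"], "GENERIC")
})

test_that("a uniformly labeled triangle yields one triangle and three path motifs", {
  labels <- tibble::tibble(node = c("A", "B", "C"), label = "L")
  counts <- count_colored_motifs(tri_net, labels, size = 3, randomizations = 0)
  tri_code <- counts$pattern[grepl("111$", counts$pattern)]
  path_code <- counts$pattern[!grepl("111$", counts$pattern)]
  expect_equal(counts$occurrences[counts$pattern == tri_code], 1)
  expect_equal(counts$occurrences[counts$pattern == path_code], 3)
  # edgeless network: nothing to count
  empty <- count_colored_motifs(tri_net[0, ], labels, size = 3, randomizations = 0)
  expect_equal(nrow(empty), 0)
})

test_that("non-induced colored motif counts equal the embedding/automorphism oracle", {
  withr::with_seed(123, {
    for (rep in seq_len(6)) {
      nn <- sample(6:9, 1)
      nodes <- sprintf("N%02d", seq_len(nn))
      net <- as_network(random_edge_tibble(nodes, sample.int(nn + 4, 1) + 2,
                                           seed = sample.int(1e6, 1)))
      labs <- sample(c("P", "S", "CD"), nn, replace = TRUE)
      labels <- tibble::tibble(node = nodes, label = labs)
      adj <- edge_tibble_to_adj(net, nodes)
      for (size in 3:4) {
        got <- count_colored_motifs(net, labels, size = size, randomizations = 0)
        expected <- oracle_motif_counts_embeddings(adj, labs, size)
        expect_equal(length(got$pattern), length(expected))
        for (code in names(expected)) {
          expect_equal(got$occurrences[got$pattern == code], expected[[code]],
                       label = paste("pattern", code))
        }
      }
    }
  })
})

test_that("motif counts are permutation-invariant and p-values are reproducible", {
  nodes <- sprintf("N%02d", 1:7)
  net <- as_network(random_edge_tibble(nodes, 9, seed = 4))
  labels <- tibble::tibble(node = nodes,
                           label = rep(c("P", "S"), length.out = 7))
  base <- count_colored_motifs(net, labels, size = 3, randomizations = 0)
  # permute node identities: counts per pattern must be identical
  perm <- setNames(rev(nodes), nodes)
  net_p <- tibble::tibble(from = perm[net$from], to = perm[net$to])
  labels_p <- tibble::tibble(node = perm[labels$node], label = labels$label)
  permuted <- count_colored_motifs(net_p, labels_p, size = 3, randomizations = 0)
  expect_identical(dplyr::arrange(base[, c("pattern", "occurrences")], pattern),
                   dplyr::arrange(permuted[, c("pattern", "occurrences")], pattern))

  p1 <- count_colored_motifs(net, labels, size = 3, randomizations = 20, seed = 9)
  p2 <- count_colored_motifs(net, labels, size = 3, randomizations = 20, seed = 9)
  expect_identical(p1, p2)
  expect_true(all(p1$p_value >= 0 & p1$p_value <= 1))
})
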