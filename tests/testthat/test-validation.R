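# Overlap percentages, PR curves, class tallies and gene-set overlap.

test_that("overlap percentage counts shared unique predictions", {
  pred <- tibble::tibble(from = sprintf("A%d", 1:8), to = sprintf("B%d", 1:8))
  ref3 <- pred[c(1, 3, 5), ]
  expect_equal(overlap_percentage(pred, ref3), 37.5)
  expect_equal(overlap_percentage(pred, pred), 100)
  expect_equal(overlap_percentage(pred, tibble::tibble(from = "X", to = "Y")), 0)
  expect_error(overlap_percentage(pred[0, ], pred), "no edges")
})

test_that("PR curve reproduces the two-edge hand example and the final-point rule", {
  ens <- structure(tibble::tibble(from = c("A", "A"), to = c("B", "C"),
                                  score = c(1.0, 0.5), n_methods = c(2L, 1L)),
                   m = 2L, methods = c("CLR", "PLS"),
                   class = c("ppi_ensemble", class(tibble::tibble())))
  reference <- tibble::tibble(from = "A", to = "B")
  prc <- pr_curve(ens, reference, universe = c("A", "B", "C"))
  expect_equal(prc$threshold[1:2], c(1.0, 0.5))
  expect_equal(prc$precision[1:2], c(1, 0.5))
  expect_equal(prc$recall[1:2], c(1, 1))
  expect_equal(nrow(prc), 2)  # recall already 1: no appended all-pairs point

  # reference equal to the ensemble edge set: precision 1 throughout
  ref_all <- ens[, c("from", "to")]
  prc2 <- pr_curve(ens, ref_all, universe = c("A", "B", "C"))
  expect_true(all(prc2$precision[!is.na(prc2$threshold)] == 1))

  # recall < 1 at the last threshold appends the all-pairs point
  ref_mixed <- tibble::tibble(from = c("A", "B"), to = c("B", "C"))
  prc3 <- pr_curve(ens, ref_mixed, universe = c("A", "B", "C"))
  expect_true(is.na(prc3$threshold[nrow(prc3)]))
  expect_equal(prc3$recall[nrow(prc3)], 1)
  expect_equal(prc3$precision[nrow(prc3)], 2 / 3)
  expect_error(pr_curve(ens, tibble::tibble(from = "X", to = "Y")[0, ]), "no edges")
})

test_that("PR curves match a brute-force threshold sweep (and ROCR on shared points)", {
  withr::with_seed(44, {
    for (rep in seq_len(20)) {
      nodes <- sprintf("N%02d", 1:7)
      pairs <- t(combn(nodes, 2))
      m <- 4
      scored <- sample(nrow(pairs), 12)
      ens <- tibble::tibble(from = pairs[scored, 1], to = pairs[scored, 2],
                            score = sample(1:m, 12, replace = TRUE) / m)
      ref <- as_network(random_edge_tibble(nodes, 6, seed = sample.int(1e6, 1)),
                        quiet = TRUE)
      prc <- pr_curve(ens, ref, universe = nodes)
      ref_keys <- paste(ref$from, ref$to)
      for (i in which(!is.na(prc$threshold))) {
        t <- prc$threshold[i]
        sel <- ens[ens$score >= t, ]
        tp <- sum(paste(sel$from, sel$to) %in% ref_keys)
        expect_equal(prc$precision[i], tp / nrow(sel))
        expect_equal(prc$recall[i], tp / nrow(ref))
      }
      # recall is non-decreasing as the threshold falls; last recall is 1
      expect_true(all(diff(prc$recall) >= -1e-12))
      expect_equal(prc$recall[nrow(prc)], 1)
    }
  })
})

test_that("PR points agree with ROCR on the scored pairs", {
  skip_if_not_installed("ROCR")
  nodes <- sprintf("N%02d", 1:8)
  pairs <- t(combn(nodes, 2))
  withr::with_seed(45, {
    scores <- runif(nrow(pairs))
    labels <- rbinom(nrow(pairs), 1, 0.3)
  })
  labels[1] <- 1  # at least one positive
  ens <- tibble::tibble(from = pairs[, 1], to = pairs[, 2], score = scores)
  ref <- tibble::tibble(from = pairs[labels == 1, 1], to = pairs[labels == 1, 2])
  prc <- pr_curve(ens, ref, universe = nodes)
  perf <- ROCR::performance(ROCR::prediction(scores, labels), "prec", "rec")
  # match by threshold: ROCR cutoffs include Inf first
  cuts <- perf@alpha.values[[1]]
  prec <- perf@y.values[[1]]
  rec <- perf@x.values[[1]]
  for (i in which(!is.na(prc$threshold))) {
    j <- which(abs(cuts - prc$threshold[i]) < 1e-12)
    expect_equal(prc$precision[i], prec[j], tolerance = 1e-12)
    expect_equal(prc$recall[i], rec[j], tolerance = 1e-12)
  }
})

test_that("class tallies cover every predicted edge", {
  pred <- tibble::tibble(from = c("A", "A", "B"), to = c("B", "C", "C"))
  cm <- tibble::tibble(from = c("A", "A"), to = c("B", "C"),
                       class = c("C1", "C3"))
  counts <- classify_edges(pred, cm)
  expect_equal(sum(counts$n), nrow(pred))
  expect_equal(counts$n[counts$class == "C1"], 1)
  expect_equal(counts$n[counts$class == "unmatched"], 1)

  all_c1 <- classify_edges(pred, tibble::tibble(from = pred$from, to = pred$to,
                                                class = "C1"))
  expect_identical(all_c1, tibble::tibble(class = "C1", n = 3L))
  none <- classify_edges(pred, cm[0, ])
  expect_identical(none, tibble::tibble(class = "unmatched", n = 3L))
})

test_that("hypergeometric overlap matches the closed form and controls FDR", {
  # universe 20, set 5, list 5, full overlap: p = 1 / C(20,5)
  res <- geneset_overlap(sprintf("G%d", 1:5),
                         list(S = sprintf("G%d", 1:5)),
                         universe_size = 20, fdr_max = 1, top = Inf)
  expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$overlap, 5)

  # zero overlap has p = 1 (upper tail includes 0)
  res0 <- geneset_overlap(sprintf("G%d", 1:5),
                          list(S = sprintf("H%d", 1:5)),
                          universe_size = 20, fdr_max = 1.1, top = Inf)
  expect_equal(res0$p_value, 1)
  expect_error(geneset_overlap("G1", list(S = sprintf("G%d", 1:30)),
                               universe_size = 20), "larger than the universe")

  # null simulation: with random lists, the BH-selected false-positive rate
  # stays at or below the nominal level
  withr::with_seed(77, {
    universe <- sprintf("G%03d", 1:60)
    collection <- lapply(1:8, function(i) sample(universe, 10))
    names(collection) <- sprintf("S%d", 1:8)
    hits <- replicate(400, {
      gl <- sample(universe, 8)
      nrow(geneset_overlap(gl, collection, universe_size = 60, fdr_max = 0.05))
    })
    expect_lte(mean(hits > 0), 0.05 + 0.02)
  })
})

test_that("average precision ranks a planted signal sensibly", {
  nodes <- c("A", "B", "C", "D")
  truth <- tibble::tibble(from = c("A", "B"), to = c("B", "C"))
  scores <- tibble::tibble(from = c("A", "A", "A", "B", "B", "C"),
                           to = c("B", "C", "D", "C", "D", "D"),
                           score = c(0.9, 0.1, 0.05, 0.8, 0.02, 0.01))
  # positives at ranks 1 and 2: AP = (1/1 + 2/2) / 2 = 1
  expect_equal(average_precision(scores, truth), 1)
  scores$score[4] <- 0.03  # B-C drops to rank 4: AP = (1 + 2/4) / 2
  expect_equal(average_precision(scores, truth), (1 + 2 / 4) / 2)
})
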