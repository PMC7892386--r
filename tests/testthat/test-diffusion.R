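test_that("network construction cleans edges and keeps the largest component", {
  net <- build_network(data.frame(a = c("A", "B", "B", "C"),
                                  b = c("B", "A", "B", "D")))
  expect_setequal(net$nodes, c("A", "B"))   # size tie broken lexicographically
  expect_equal(net$n_self_removed, 1L)
  expect_equal(net$n_dup_removed, 1L)
  expect_equal(net$n_nodes_dropped, 2L)

  tri <- build_network(data.frame(a = c("X", "Y", "Z", "P"),
                                  b = c("Y", "Z", "X", "Q")))
  expect_setequal(tri$nodes, c("X", "Y", "Z"))

  expect_error(build_network(data.frame(a = character(), b = character())),
               "empty")
  expect_warning(build_network(data.frame(a = "A", b = "B", w = 0.9)),
                 "columns")
})

test_that("diffusion matches the dense closed-form solve and conserves mass", {
  # path graph closed form
  edges <- data.frame(from = c("A", "B"), to = c("B", "C"))
  net <- build_network(edges)
  d <- diffuse(net, "A", r = 0.5)
  oracle <- rwr_oracle(edges, "A", 0.5)
  expect_equal(d$scores[names(oracle)], oracle, tolerance = 1e-7)
  expect_equal(sum(d$scores), 1, tolerance = 1e-12)

  # restart-only limit returns the seed distribution
  d1 <- diffuse(net, c("A", "C"), r = 1)
  expect_equal(unname(d1$scores[c("A", "C")]), c(0.5, 0.5))
  expect_equal(unname(d1$scores["B"]), 0)

  # symmetric nodes receive equal scores
  star <- build_network(data.frame(from = "HUB", to = paste0("L", 1:4)))
  ds <- diffuse(star, c("L1", "L2"), r = 0.4)
  expect_equal(unname(ds$scores["L1"]), unname(ds$scores["L2"]))
  expect_equal(unname(ds$scores["L3"]), unname(ds$scores["L4"]))

  # iterative agrees with the sparse exact solve on random graphs
  set.seed(41)
  for (i in 1:20) {
    e <- random_connected_edges(sample(5:50, 1))
    n2 <- build_network(e)
    seeds <- sample(n2$nodes, sample(1:3, 1))
    r <- runif(1, 0.1, 0.9)
    it <- diffuse(n2, seeds, r = r, tol = 1e-10)
    ex <- diffuse(n2, seeds, r = r, method = "exact")
    expect_lt(max(abs(it$scores - ex$scores)), 1e-8)
    expect_equal(sum(it$scores), 1, tolerance = 1e-10)
    expect_true(all(it$scores >= 0))
    # and against the independently written dense oracle
    orc <- rwr_oracle(e, seeds, r)
    expect_equal(ex$scores[names(orc)], orc, tolerance = 1e-8)
  }

  expect_error(diffuse(net, "ZZZ"), "disjoint")
  expect_error(diffuse(net, "A", r = 0), "restart")
})

test_that("scores decay monotonically with hop distance from a single seed", {
  path6 <- build_network(data.frame(from = paste0("P", 1:5),
                                    to = paste0("P", 2:6)))
  sc <- diffuse(path6, "P1", r = 0.3)$scores
  expect_true(all(diff(sc[paste0("P", 1:6)]) < 0))
})

test_that("gene ranking averages ties and honours exclusions", {
  s <- c(a = 0.5, b = 0.3, c = 0.2)
  expect_equal(rank_genes(s), c(a = 1, b = 2, c = 3))
  s2 <- c(a = 0.5, b = 0.5, c = 0.2)
  expect_equal(rank_genes(s2)[c("a", "b")], c(a = 1.5, b = 1.5))
  r3 <- rank_genes(s, exclude = "a")
  expect_equal(r3, c(b = 1, c = 2))
})

test_that("cross-validation records the designed number of ranks, within bounds", {
  sn <- synth_network(n_nodes = 300, module_size = 30,
                      intra_module_edge_boost = 0.4, rng_seed = 5)
  net <- build_network(sn$edges)
  seeds <- sn$truth$planted_module[1:25]
  cv <- cross_validate(net, seeds, k = 5, repeats = 2, rng_seed = 8)
  expect_length(cv$heldout_ranks, 25 * 2)
  n_retained <- 20  # 4/5 of the seeds kept each fold
  expect_true(all(cv$heldout_ranks >= 1 &
                    cv$heldout_ranks <= 300 - n_retained))
  expect_true(all(cv$unlabelled_ranks <= 300 - n_retained))

  # bit-identical under the same seed, different under another
  cv2 <- cross_validate(net, seeds, k = 5, repeats = 2, rng_seed = 8)
  expect_identical(cv, cv2)
  cv3 <- cross_validate(net, seeds, k = 5, repeats = 2, rng_seed = 9)
  expect_false(identical(cv$heldout_ranks, cv3$heldout_ranks))

  # held-out module genes rank ahead of the background
  expect_lt(median(cv$heldout_ranks), median(cv$unlabelled_ranks))

  expect_error(cross_validate(net, seeds, k = 1), "at least 2")
  expect_error(cross_validate(net, seeds[1:3], k = 5), "at least k")

  # degenerate star graph: ranks stay within bounds
  star <- build_network(data.frame(from = "HUB", to = paste0("L", 1:10)))
  cvs <- cross_validate(star, paste0("L", 1:10), k = 5, repeats = 1,
                        rng_seed = 2)
  expect_true(all(cvs$heldout_ranks >= 1 & cvs$heldout_ranks <= 11 - 8))
})

test_that("alternative CV designs and ranking domains run and stay reproducible", {
  sn <- synth_network(n_nodes = 200, module_size = 20, rng_seed = 3)
  net <- build_network(sn$edges)
  seeds <- sn$truth$planted_module
  h1 <- cross_validate(net, seeds, k = 4, repeats = 2, rng_seed = 1,
                       design = "holdout")
  h2 <- cross_validate(net, seeds, k = 4, repeats = 2, rng_seed = 1,
                       design = "holdout")
  expect_identical(h1, h2)
  u <- cross_validate(net, seeds, k = 4, repeats = 1, rng_seed = 1,
                      rank_among = "unlabelled")
  expect_true(all(u$heldout_ranks <= length(setdiff(net$nodes, seeds)) + 1))
})

test_that("rank significance agrees with exhaustive sign enumeration", {
  # nine ranks all better than the null median, distinct magnitudes
  ranks <- c(10, 20, 30, 40, 50, 60, 70, 80, 90)
  rs <- rank_significance(ranks, 17557)
  expect_equal(rs$p, 1 / 512)
  d <- ranks - (17557 + 1) / 2
  expect_equal(rs$p, signed_rank_oracle(d))

  # mixed ranks vs the oracle
  set.seed(51)
  for (i in 1:10) {
    # distinct magnitudes either side of the null median 51
    mag <- sample(1:50, sample(3:10, 1))
    rk <- 51 + mag * sample(c(-1, 1), length(mag), replace = TRUE)
    rs2 <- rank_significance(rk, 101)
    expect_equal(rs2$p, signed_rank_oracle(rk - 51), tolerance = 1e-10)
  }

  # symmetric ranks give a large p
  expect_gte(rank_significance(c(26, 76), 101)$p, 0.5)

  # a rank exactly at the null median carries no information
  expect_error(rank_significance(51, 101), "undefined")
  expect_error(rank_significance(numeric(), 100), "no observed")
  expect_error(rank_significance(150, 100), "\\[1, n_candidates\\]")

  # rank-sum flavour runs and detects enrichment of small ranks
  expect_lt(rank_significance(1:10, 1000, flavour = "rank_sum")$p, 0.01)
})

test_that("OA-interaction counting uses direct neighbours only", {
  star <- build_network(data.frame(from = "HUB", to = paste0("L", 1:5)))
  expect_equal(unname(count_oa_interactions(star, "HUB", paste0("L", 1:4))), 4L)
  expect_equal(unname(count_oa_interactions(star, "L1", paste0("L", 2:4))), 0L)
  expect_equal(unname(count_oa_interactions(star, "L1", "HUB")), 1L)
  expect_error(count_oa_interactions(star, "NOPE", "HUB"), "absent")
})

test_that("prioritisation applies all three filter conditions and sorts by rank", {
  ranks <- c(ACKR2 = 241, LOWDE = 100, KNOWN1 = 50, FEWINT = 10, GOOD2 = 300)
  de <- c(ACKR2 = 4, LOWDE = 2, KNOWN1 = 5, FEWINT = 6, GOOD2 = 3)
  ic <- c(ACKR2 = 4, LOWDE = 10, KNOWN1 = 5, FEWINT = 3, GOOD2 = 7)
  out <- prioritise(ranks, de, ic, known = "KNOWN1")
  expect_equal(out$gene, c("ACKR2", "GOOD2"))   # sorted by ascending rank
  expect_false(any(out$known))
  expect_true(all(out$n_human_de_datasets >= 3 & out$n_oa_interactions >= 4))
  # genes missing from the evidence maps count zero and are filtered
  out2 <- prioritise(c(X = 1, ACKR2 = 2), de, ic, known = character())
  expect_equal(out2$gene, "ACKR2")
  # tractability labels pass through
  out3 <- prioritise(ranks, de, ic, known = "KNOWN1",
                     tractability = c(ACKR2 = "small molecule"))
  expect_equal(out3$tractability[out3$gene == "ACKR2"], "small molecule")
})
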