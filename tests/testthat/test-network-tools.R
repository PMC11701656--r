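# 6-node toy graph: hub h links to all of q1..q3, spoke s links only to
# q1, and x hangs off the hub.
toy_net <- function() {
  network_table(data.frame(
    proteinA = c("q1", "q2", "q3", "q1", "h"),
    proteinB = c("h", "h", "h", "s", "x"),
    ppv = c(0.9, 0.9, 0.9, 0.99, 0.9)))
}

test_that("group search ranks common neighbors first", {
  net <- toy_net()
  res <- group_search(net, c("q1", "q2", "q3"), n_add = 1,
                      prioritize_common = TRUE, cutoff = 0.85)
  expect_equal(res$added_nodes$gene[1], "h")
  expect_equal(res$added_nodes$n_query_links[1], 3)

  # without common-neighbor priority the summed PPV decides; the spoke's
  # single 0.99 link loses to the hub's 2.7
  res2 <- group_search(net, c("q1", "q2", "q3"), n_add = 2,
                       prioritize_common = FALSE)
  expect_equal(res2$added_nodes$gene, c("h", "s"))

  # n_add = 0 returns the induced query subgraph
  res0 <- group_search(net, c("q1", "h"), n_add = 0)
  expect_equal(nrow(res0$subnetwork), 1)

  # duplicate query genes are deduplicated
  res_dup <- group_search(net, c("q1", "q1", "q2", "q3"), n_add = 1,
                          prioritize_common = TRUE)
  expect_equal(res_dup$added_nodes$gene[1], "h")

  expect_warning(res_na <- group_search(net, "absent", n_add = 1),
                 "no query gene")
  expect_equal(nrow(res_na$subnetwork), 0)
})

test_that("independent search expands per gene and grows at least as fast", {
  net <- network_table(data.frame(
    proteinA = c("a", "b"), proteinB = c("n1", "n2"), ppv = 0.9))
  res <- independent_search(net, c("a", "b"), n_add_per_gene = 1)
  expect_setequal(res$added_nodes$gene, c("n1", "n2"))

  # overlapping neighborhoods are deduplicated in the union
  net2 <- toy_net()
  res2 <- independent_search(net2, c("q1", "q2"), n_add_per_gene = 1)
  expect_equal(res2$added_nodes$gene[!duplicated(res2$added_nodes$gene)],
               unique(res2$added_nodes$gene))

  # on the same toy input the independent union is never smaller than the
  # group result
  grp <- group_search(net2, c("q1", "q2", "q3"), n_add = 1,
                      prioritize_common = TRUE)
  ind <- independent_search(net2, c("q1", "q2", "q3"), n_add_per_gene = 1)
  n_nodes <- function(r) {
    length(unique(c(r$query, r$added_nodes$gene)))
  }
  expect_gte(n_nodes(ind), n_nodes(grp))
})

test_that("MaxLink p-values match exhaustive hypergeometric enumeration", {
  # printed example: N = 10, q = 3, d = 4, x = 3 -> 6/126
  expect_equal(oracle_hyper_tail(3, 9, 3, 4), 6 / 126, tolerance = 1e-12)

  set.seed(61)
  for (i in 1:100) {
    n_nodes <- sample(6:12, 1)
    net <- make_toy_network(n_nodes, sample(3:10, 1), seed = i)
    nodes <- sort(unique(c(net$proteinA, net$proteinB)))
    q <- sample(2:3, 1)
    query <- sample(nodes, q)
    rk <- maxlink_rank(net, query, cutoff = 0)
    if (!nrow(rk)) next
    N <- length(nodes)
    qm <- length(intersect(query, nodes))
    for (j in seq_len(nrow(rk))) {
      expect_equal(rk$p_value[j],
                   oracle_hyper_tail(rk$links_to_query[j], N - 1, qm,
                                     rk$degree[j]),
                   tolerance = 1e-10)
    }
    # candidates with zero links into the query have p = 1
    expect_true(all(rk$p_value[rk$links_to_query == 0] == 1))
    # ranking is by link count first
    expect_true(!is.unsorted(rev(rk$links_to_query)))
  }
})

test_that("EASE enrichment subtracts one from the overlap", {
  expect_equal(ease_enrichment(paste0("q", 1:5),
                               c("q1", "q2", "q3", "x1", "x2", "x3"), 20),
               oracle_ease(3, 20, 6, 5), tolerance = 1e-12)
  # overlap of 1 tests P(X >= 0) = 1
  expect_equal(ease_enrichment(c("q1", "z1"), c("q1", "x1"), 20), 1)
  expect_equal(ease_enrichment(c("a"), c("b"), 10), 1)  # overlap 0
  # pathway = universe -> overlap can't beat chance
  expect_equal(ease_enrichment(paste0("g", 1:4), paste0("g", 1:10), 10), 1)
  set.seed(71)
  for (i in 1:100) {
    uni <- sample(15:40, 1)
    genes <- sprintf("g%03d", seq_len(uni))
    qs <- sample(genes, sample(3:8, 1))
    ps <- sample(genes, sample(3:10, 1))
    expect_equal(ease_enrichment(qs, ps, uni),
                 oracle_ease(length(intersect(qs, ps)), uni, length(ps),
                             length(qs)),
                 tolerance = 1e-12)
  }
})

test_that("ortholog alignment finds rectangle constellations", {
  netA <- network_table(data.frame(proteinA = "PSEN1", proteinB = "CRK",
                                   ppv = 0.9))
  netB <- network_table(data.frame(proteinA = "sel-12", proteinB = "ced-2",
                                   ppv = 0.9))
  om <- ortholog_map(data.frame(source = c("PSEN1", "CRK"),
                                target = c("sel-12", "ced-2"),
                                group = c("g1", "g2")))
  rect <- align_orthologs(netA, netB, om)
  expect_equal(nrow(rect), 1)
  expect_setequal(c(rect$proteinA2, rect$proteinB2), c("sel-12", "ced-2"))

  # swapping species roles finds the mirrored rectangle
  om_rev <- ortholog_map(data.frame(source = c("sel-12", "ced-2"),
                                    target = c("PSEN1", "CRK"),
                                    group = c("g1", "g2")))
  rect_rev <- align_orthologs(netB, netA, om_rev)
  expect_equal(nrow(rect_rev), 1)

  # no ortholog links -> empty
  empty_om <- ortholog_map(data.frame(source = character(),
                                      target = character(),
                                      group = character()))
  expect_equal(nrow(align_orthologs(netA, netB, empty_om)), 0)
})

test_that("random walk with restart matches the direct linear solve", {
  # two-node path, restart 0.75, seed on one node -> (0.8, 0.2)
  net <- network_table(data.frame(proteinA = "a", proteinB = "b",
                                  ppv = 0.9))
  p <- rwr(net, "a")
  expect_equal(unname(p), c(0.8, 0.2), tolerance = 1e-9)

  # restart = 1 returns the seed vector
  p1 <- rwr(net, "a", restart = 1)
  expect_equal(unname(p1), c(1, 0))

  set.seed(81)
  for (i in 1:100) {
    net_i <- make_toy_network(sample(5:20, 1), sample(3:15, 1), seed = i)
    nodes <- sort(unique(c(net_i$proteinA, net_i$proteinB)))
    seeds <- sample(nodes, sample(1:3, 1))
    p_iter <- rwr(net_i, seeds, tol = 1e-12)
    p_solve <- oracle_rwr(net_i, seeds, 0.75)
    expect_equal(p_iter[nodes], p_solve[nodes], tolerance = 1e-8)
    expect_equal(sum(p_iter), 1, tolerance = 1e-9)
  }
  expect_error(rwr(net, "zz"), "seed")
})

test_that("rewiring preserves degrees exactly without self-loops", {
  net <- make_toy_network(20, 25, seed = 3)
  deg <- function(n) {
    sort(table(c(n$proteinA, n$proteinB)))
  }
  rew <- rewire_preserve_degree(net, seed = 7)
  expect_equal(deg(rew)[names(deg(net))], deg(net))
  expect_true(all(rew$proteinA != rew$proteinB))
  expect_equal(nrow(rew), nrow(net))
  expect_identical(rewire_preserve_degree(net, seed = 7), rew)

  # a triangle admits no valid swap and comes back unchanged
  tri <- network_table(data.frame(proteinA = c("a", "a", "b"),
                                  proteinB = c("b", "c", "c"), ppv = 0.9))
  rew_tri <- rewire_preserve_degree(tri, seed = 1)
  expect_setequal(paste(rew_tri$proteinA, rew_tri$proteinB),
                  paste(tri$proteinA, tri$proteinB))
})

test_that("AUROC behaves at the extremes and PG is zero for equal medians", {
  set.seed(91)
  # perfect ranking -> 1; random ranking -> ~0.5
  expect_equal(coupnet:::auroc(c(5, 6, 7), c(1, 2, 3)), 1)
  r <- coupnet:::auroc(rnorm(4000), rnorm(4000))
  expect_equal(r, 0.5, tolerance = 0.05)

  mod <- make_module_network(seed = 9)
  bench <- performance_gain(mod$module, mod$net, n_splits = 10,
                            n_randomizations = 10, seed = 2)
  expect_s3_class(bench, "benchmark_result")
  expect_equal(bench$pg,
               (bench$median_real - bench$median_null) / bench$median_null)
  expect_length(bench$auroc_null, 100)

  # a planted interconnected module is recovered better on the real
  # network than on degree-matched rewirings
  expect_gt(bench$median_real, 0.5)
  expect_gt(bench$pg, 0)

  expect_warning(expect_null(
    performance_gain("absent", mod$net, n_splits = 2,
                     n_randomizations = 2)))
})

test_that("neighbor gain counts non-query first neighbors per query gene", {
  net <- network_table(data.frame(
    proteinA = c("q1", "q1", "q2", "q2", "q1"),
    proteinB = c("n1", "n2", "n3", "n4", "q2"),
    ppv = 0.9))
  # 4 outside neighbors / 2 query genes; q1-q2 links don't count
  expect_equal(neighbor_gain(net, c("q1", "q2")), 2)

  iso <- network_table(data.frame(proteinA = c("q1", "a"),
                                  proteinB = c("q2", "b"), ppv = 0.9))
  expect_equal(neighbor_gain(iso, c("q1", "q2")), 0)
})
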