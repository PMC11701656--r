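test_that("species_distance averages ortholog fractions in both directions", {
  om <- ortholog_map(data.frame(
    source = sprintf("a%02d", 1:50),
    target = sprintf("b%02d", c(1:40, 1:10)),  # 40 distinct targets
    group = sprintf("g%02d", 1:50)))
  # 50 of 100 in A, 40 of 200 in B -> 1 - (0.5 + 0.2)/2
  expect_equal(species_distance(om, 100, 200), 1 - (0.5 + 0.2) / 2)

  full <- ortholog_map(data.frame(source = c("a1", "a2"),
                                  target = c("b1", "b2"),
                                  group = c("g1", "g2")))
  expect_equal(species_distance(full, 2, 2), 0)
  none <- ortholog_map(data.frame(source = character(), target = character(),
                                  group = character()))
  expect_equal(species_distance(none, 5, 5), 1)
  expect_true(species_distance(om, 100, 200) >= 0 &&
                species_distance(om, 100, 200) <= 1)
})

test_that("build_species_tree reproduces hand-computed trees", {
  # two species: single split of total length d
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("s1", "s2"),
                                                     c("s1", "s2")))
  t2 <- build_species_tree(d2, method = "upgma")
  expect_equal(sum(t2$edge.length), 0.4)
  expect_setequal(t2$tip.label, c("s1", "s2"))

  # ultrametric 3-species matrix: UPGMA recovers heights 1 and 2
  dm <- matrix(c(0, 2, 4,
                 2, 0, 4,
                 4, 4, 0), 3, byrow = TRUE,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tu <- build_species_tree(dm, method = "upgma")
  cop <- ape::cophenetic.phylo(tu)
  expect_equal(cop["x", "y"], 2)
  expect_equal(cop["x", "z"], 4)
  expect_equal(cop["y", "z"], 4)

  # permuting the input leaves the topology unchanged
  perm <- c("z", "x", "y")
  tu2 <- build_species_tree(dm[perm, perm], method = "upgma")
  expect_equal(ape::cophenetic.phylo(tu2)[c("x", "y", "z"), c("x", "y", "z")],
               cop[c("x", "y", "z"), c("x", "y", "z")])

  # NJ rooted at a species of interest keeps all leaves
  dm4 <- as.matrix(dist(c(a = 0, b = 1, c = 3, d = 7)))
  tn <- build_species_tree(dm4, method = "nj", root_species = "a")
  expect_setequal(tn$tip.label, c("a", "b", "c", "d"))
  expect_true(ape::is.rooted(tn))
  expect_true(all(tn$edge.length >= 0))

  bad <- dm
  bad[1, 2] <- 9
  expect_error(build_species_tree(bad), "symmetric")
})

test_that("evidence transfer averages many-to-one orthology", {
  src <- evidence_table(data.frame(
    proteinA = c("A1", "B1", "C1"), proteinB = "D1",
    score = c(0.2, 0.4, 0.6)), evidence_type = "PIN", species = "sp1",
    dataset_id = "ds1")
  om <- ortholog_map(data.frame(
    source = c("A1", "B1", "C1", "D1"),
    target = c("A2", "A2", "A2", "D2"),
    group = c("g1", "g1", "g1", "g2")))
  out <- transfer_evidence(src, om, target_species = "sp2")
  expect_equal(nrow(out), 1)
  expect_equal(out$score, 0.4)  # mean of the three mapped scores
  expect_equal(attr(out, "species"), "sp2")

  # bijective map copies scores unchanged (and back-transfer restores them)
  bij <- ortholog_map(data.frame(source = c("A1", "B1", "C1", "D1"),
                                 target = c("a2", "b2", "c2", "d2"),
                                 group = sprintf("g%d", 1:4)))
  fwd <- transfer_evidence(src, bij)
  expect_setequal(fwd$score, src$score)
  back_map <- ortholog_map(data.frame(source = c("a2", "b2", "c2", "d2"),
                                      target = c("A1", "B1", "C1", "D1"),
                                      group = sprintf("g%d", 1:4)))
  back <- transfer_evidence(fwd, back_map)
  key <- function(d) paste(d$proteinA, d$proteinB, sep = "|")
  expect_equal(back$score[order(key(back))], src$score[order(key(src))])

  # unmapped endpoints produce no entry
  lonely <- evidence_table(data.frame(proteinA = "Z1", proteinB = "D1",
                                      score = 1), evidence_type = "PIN")
  expect_equal(nrow(transfer_evidence(lonely, om)), 0)

  dom <- evidence_table(data.frame(proteinA = "A1", proteinB = "D1",
                                   score = 1), evidence_type = "DOM")
  expect_error(transfer_evidence(dom, om), "cross-species")
})

test_that("closest_species prefers taxonomy and falls back on distances", {
  tax <- list(t = c("root", "cladeA", "genusX", "t"),
              c1 = c("root", "cladeA", "genusX", "c1"),
              c2 = c("root", "cladeB", "c2"))
  dm <- matrix(0.5, 3, 3, dimnames = list(c("t", "c1", "c2"),
                                          c("t", "c1", "c2")))
  diag(dm) <- 0
  expect_equal(closest_species("t", c("c1", "c2"), tax, dm), "c1")

  # taxonomic tie resolved by the smaller orthophylogram distance
  tax2 <- list(t = c("root", "t"), c1 = c("root", "c1"),
               c2 = c("root", "c2"))
  dm2 <- dm
  dm2["t", "c1"] <- dm2["c1", "t"] <- 0.5
  dm2["t", "c2"] <- dm2["c2", "t"] <- 0.3
  expect_equal(closest_species("t", c("c1", "c2"), tax2, dm2), "c2")

  # no taxonomy at all: pure distance argmin
  expect_equal(closest_species("t", c("c1", "c2"), NULL, dm2), "c2")
})

test_that("network transfer expands ortholog cross-products keeping scores", {
  net <- network_table(data.frame(proteinA = "X1", proteinB = "Y1",
                                  ppv = 0.9))
  om <- ortholog_map(data.frame(source = c("X1", "X1", "Y1"),
                                target = c("X2a", "X2b", "Y2"),
                                group = c("g1", "g1", "g2")))
  out <- transfer_network(net, om)
  expect_equal(nrow(out), 2)
  expect_true(all(out$ppv == 0.9))

  # endpoint without orthologs: link not transferred
  net2 <- network_table(data.frame(proteinA = "X1", proteinB = "Z1",
                                   ppv = 0.9))
  expect_equal(nrow(transfer_network(net2, om)), 0)

  # duplicate target pairs keep the maximum confidence
  net3 <- network_table(data.frame(proteinA = c("X1", "W1"),
                                   proteinB = c("Y1", "Y1"),
                                   ppv = c(0.9, 0.95)))
  om3 <- ortholog_map(data.frame(source = c("X1", "W1", "Y1"),
                                 target = c("X2", "X2", "Y2"),
                                 group = c("g1", "g1", "g2")))
  out3 <- transfer_network(net3, om3)
  expect_equal(nrow(out3), 1)
  expect_equal(out3$ppv, 0.95)

  # output never exceeds the sum of ortholog cross-products
  expect_lte(nrow(out), 2 * 1)
})

test_that("network similarity: identical, nested, disjoint", {
  a <- network_table(data.frame(proteinA = c("a", "b"),
                                proteinB = c("b", "c"), ppv = 0.9))
  expect_equal(unlist(network_similarity(a, a)),
               c(node_ji = 1, node_oc = 1, link_ji = 1, link_oc = 1))

  b <- network_table(data.frame(proteinA = c("a", "b", "c"),
                                proteinB = c("b", "c", "d"), ppv = 0.9))
  s <- network_similarity(a, b)
  expect_equal(s$link_oc, 1)
  expect_lt(s$link_ji, 1)
  expect_gte(s$node_oc, s$node_ji)  # overlap coefficient dominates Jaccard

  d <- network_table(data.frame(proteinA = "x", proteinB = "y", ppv = 0.9))
  s2 <- network_similarity(a, d)
  expect_equal(unlist(s2), c(node_ji = 0, node_oc = 0, link_ji = 0,
                             link_oc = 0))
  empty <- network_table(data.frame(proteinA = character(),
                                    proteinB = character(),
                                    ppv = numeric()))
  expect_equal(network_similarity(empty, empty)$link_ji, 0)
})
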