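test_that("dom_score evaluates the weighted domain-pair formula", {
  ann <- list(domains = list(A = c("d1", "d2"), B = "d3"),
              pair_scores = data.frame(domainA = "d1", domainB = "d3",
                                       score = 0.8),
              degree = c(d1 = 3, d3 = 5))
  expect_equal(dom_score("A", "B", ann), (1 / 2) * (0.8 / log(8)),
               tolerance = 1e-12)

  # no scored domain pair -> 0; all-zero support -> 0
  ann0 <- ann
  ann0$pair_scores <- data.frame(domainA = character(),
                                 domainB = character(), score = numeric())
  expect_equal(dom_score("A", "B", ann0), 0)
  annz <- ann
  annz$pair_scores$score <- 0
  expect_equal(dom_score("A", "B", annz), 0)
  expect_true(is.na(dom_score("A", "Z", ann)))
})

test_that("pin_score evaluates the publication-support formula", {
  sup <- list(publications = stats::setNames(list(c("p1", "p2")), "A|B"),
              publication_size = c(p1 = 1, p2 = 9),
              protein_degree = c(A = 5, B = 5))
  expect_equal(pin_score("A", "B", sup),
               ((1 / log(2) + 1 / log(10)) / 2) * (1 / log(10)),
               tolerance = 1e-12)

  # monotonically decreasing in hub degree
  hub <- sup
  hub$protein_degree <- c(A = 1e4, B = 1e4)
  expect_lt(pin_score("A", "B", hub), pin_score("A", "B", sup))
  expect_gt(pin_score("A", "B", hub), 0)

  # huge publications drive the score toward 0
  big <- sup
  big$publication_size <- c(p1 = 1e9, p2 = 1e9)
  expect_lt(pin_score("A", "B", big), 0.05)
  expect_true(is.na(pin_score("A", "C", sup)))
})

test_that("dom and pin match independent brute-force oracles", {
  set.seed(42)
  for (i in 1:100) {
    nda <- sample(1:4, 1)
    ndb <- sample(1:4, 1)
    doms <- sprintf("dom%02d", 1:10)
    ann <- list(
      domains = list(A = sample(doms, nda), B = sample(doms, ndb)),
      pair_scores = data.frame(
        domainA = sample(doms, 12, replace = TRUE),
        domainB = sample(doms, 12, replace = TRUE),
        score = runif(12)),
      degree = stats::setNames(sample(1:20, 10, replace = TRUE) + 1, doms))
    ann$pair_scores <- ann$pair_scores[
      !duplicated(paste(pmin(ann$pair_scores$domainA, ann$pair_scores$domainB),
                        pmax(ann$pair_scores$domainA, ann$pair_scores$domainB))), ]
    ann$pair_scores <- ann$pair_scores[
      ann$pair_scores$domainA != ann$pair_scores$domainB, ]
    expect_equal(dom_score("A", "B", ann), oracle_dom("A", "B", ann),
                 tolerance = 1e-12)

    n_pub <- sample(1:5, 1)
    sizes <- sample(1:50, n_pub)
    dA <- sample(2:100, 1)
    dB <- sample(2:100, 1)
    sup <- list(
      publications = stats::setNames(list(sprintf("pm%d", seq_len(n_pub))),
                                     "X|Y"),
      publication_size = stats::setNames(sizes, sprintf("pm%d", seq_len(n_pub))),
      protein_degree = c(X = dA, Y = dB))
    expect_equal(pin_score("X", "Y", sup), oracle_pin(sizes, dA, dB),
                 tolerance = 1e-12)
  }
})

test_that("profile correlations honor validity cutoffs", {
  expect_equal(profile_correlation_score(1:5, c(2, 4, 6, 8, 10), 5), 1)
  expect_equal(profile_correlation_score(1:5, 5:1, 5), -1)
  a <- c(1, 2, 3, 4, NA)
  b <- c(2, 4, 6, NA, 10)
  expect_true(is.na(profile_correlation_score(a, b, 5)))  # 3 shared valid
  expect_true(is.na(profile_correlation_score(rep(1, 6), 1:6, 5)))
  expect_error(profile_correlation_score(1:4, 1:5, 3), "same axis")
})

test_that("mex_postprocess filters homologs and rescales", {
  cors <- data.frame(proteinA = c("a", "a", "b", "c"),
                     proteinB = c("b", "c", "c", "d"),
                     r = c(0.3, -0.6, 0.8, 1.0))
  tab <- mex_postprocess(cors)
  expect_equal(nrow(tab), 3)  # r = 0.3 dropped
  expect_equal(sort(tab$score), c(0, 0.5, 1))

  hom <- mex_postprocess(cors, homolog_pairs = "b|c")
  keys <- paste(hom$proteinA, hom$proteinB, sep = "|")
  expect_false("b|c" %in% keys)

  none <- mex_postprocess(data.frame(proteinA = "a", proteinB = "b",
                                     r = 0.2))
  expect_equal(nrow(none), 0)
})

test_that("regulator and top-tissue Jaccard scores keep only positive values", {
  expect_equal(jaccard_regulator_score(c("m1", "m2"), c("m2", "m3")), 1 / 3)
  expect_equal(jaccard_regulator_score(c("m1"), c("m1")), 1)
  expect_true(is.na(jaccard_regulator_score(c("m1"), c("m2"))))
  expect_true(is.na(jaccard_regulator_score(character(), character())))

  tiss <- sprintf("t%d", 1:8)
  a <- stats::setNames(c(9, 8, 1, 1, 1, 1, 1, 1), tiss)
  expect_equal(pex_top_tissue_score(a, a), 1)
  b <- stats::setNames(c(1, 1, 1, 1, 9, 8, 1, 1), tiss)
  expect_true(is.na(pex_top_tissue_score(a, b)))  # disjoint top-2 sets
  c_ <- stats::setNames(c(1, 9, 1, 1, 8, 1, 1, 1), tiss)
  expect_equal(pex_top_tissue_score(a, c_), 1 / 3)  # {t1,t2} vs {t2,t5}
  expect_true(is.na(pex_top_tissue_score(rep(NA_real_, 8), a)))
})

test_that("php_score is a branch-length log ratio, symmetric and capped", {
  # 4 leaves; positive subtree (s1,s2) length 3, negative (s3,s4) 1.5,
  # total 6 -> ln((3/6)/(1.5/6)) = ln 2
  tr <- ape::read.tree(text = "((s1:1.5,s2:1.5):0.5,(s3:0.75,s4:0.75):1);")
  expect_equal(sum(tr$edge.length), 6)
  pa <- c(s1 = 1, s2 = 1, s3 = 1, s4 = 0)
  pb <- c(s1 = 1, s2 = 1, s3 = 0, s4 = 1)
  expect_equal(php_score(pa, pb, tr), log(2), tolerance = 1e-12)
  expect_equal(php_score(pb, pa, tr), php_score(pa, pb, tr))

  # permuted profile names give the same score
  perm <- sample(names(pa))
  expect_equal(php_score(pa[perm], pb[perm], tr), log(2), tolerance = 1e-12)

  # both proteins everywhere: negative score hits the epsilon cap
  ones <- c(s1 = 1, s2 = 1, s3 = 1, s4 = 1)
  # positive subtree spans all species (length 6)
  expect_equal(php_score(ones, ones, tr), log(6 / (1e-6 * 6)),
               tolerance = 1e-9)
  expect_error(php_score(pa[1:3], pb, tr), "length")
})

test_that("grg_score normalizes per dataset, assigns peaks and keeps maxima", {
  genes <- data.frame(gene = c("G1", "G2"), chrom = "chr1",
                      start = c(1000L, 50000L), end = c(2000L, 51000L),
                      strand = c("+", "+"))
  pk <- function(start, end, sv) {
    data.frame(chrom = "chr1", start = start, end = end, name = "p",
               score = 0L, strand = ".", signalValue = sv, pValue = -1,
               qValue = -1, peak = -1L)
  }
  # dataset range [2.5, 7.5]: peak over G1 normalizes to 1
  d1 <- rbind(pk(1200L, 1300L, 7.5), pk(49000L, 49100L, 2.5))
  tab <- grg_score(list(list(tf = "T", peaks = d1)), genes,
                   assign_window = 10000)
  expect_true(attr(tab, "directed"))
  expect_equal(tab$score[tab$proteinA == "T" & tab$proteinB == "G1"], 1)
  # the 2.5 peak sits 10 kb upstream of G2 and normalizes to 0
  expect_equal(tab$score[tab$proteinB == "G2"], 0)

  # same pair in a second dataset with higher normalized score wins
  d2 <- rbind(pk(1200L, 1300L, 5), pk(1400L, 1500L, 10),
              pk(49000L, 49100L, 0))
  tab2 <- grg_score(list(list(tf = "T", peaks = d1),
                         list(tf = "T", peaks = d2)), genes)
  expect_equal(tab2$score[tab2$proteinB == "G1"], 1)

  # a peak far from every gene window produces no pair
  far <- grg_score(list(list(tf = "T", peaks = pk(200000L, 200100L, 3))),
                   genes)
  expect_equal(nrow(far), 0)

  # constant signal normalizes to 1 by convention
  const <- grg_score(list(list(tf = "T", peaks = pk(1200L, 1250L, 4))),
                     genes)
  expect_equal(const$score, 1)
})

test_that("Wang semantic similarity follows the DAG topology", {
  dag <- data.frame(child = c("c", "p"), parent = c("p", "root"),
                    weight = c(0.8, 0.8))
  expect_equal(wang_semantic_similarity("c", "c", dag), 1)
  dag1 <- data.frame(child = "c", parent = "p", weight = 0.8)
  expect_equal(wang_semantic_similarity("c", "p", dag1), 1.8 / 2.8,
               tolerance = 1e-12)
  # disjoint components share no ancestor
  dag2 <- data.frame(child = c("a", "b"), parent = c("pa", "pb"),
                     weight = 0.8)
  expect_equal(wang_semantic_similarity("a", "b", dag2), 0)
  expect_error(wang_semantic_similarity("nope", "c", dag), "unknown term")

  # best-match average over term sets stays in [0, 1]
  s <- wang_semantic_similarity(c("c", "p"), c("p", "root"), dag)
  expect_true(s > 0 && s <= 1)
})
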