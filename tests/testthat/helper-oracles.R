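# Independent brute-force oracles and small fixture builders shared by the
# tests. The oracles deliberately re-derive each quantity from first
# principles (explicit sums, enumeration, linear solves) and never call the
# implementation under test.

# Direct evaluation of the domain-pair support formula, written as an
# explicit double loop over annotated domain pairs.
oracle_dom <- function(A, B, ann) {
  da <- ann$domains[[A]]
  db <- ann$domains[[B]]
  N <- length(da) * length(db)
  acc <- 0
  m <- 0
  for (x in da) {
    for (y in db) {
      row <- which((ann$pair_scores$domainA == x & ann$pair_scores$domainB == y) |
                     (ann$pair_scores$domainA == y & ann$pair_scores$domainB == x))
      if (length(row)) {
        m <- m + 1
        acc <- acc + ann$pair_scores$score[row[1]] /
          log(ann$degree[[x]] + ann$degree[[y]])
      }
    }
  }
  if (m == 0) return(0)
  (m / N) * (acc / m)
}

# Direct evaluation of the publication-support formula.
oracle_pin <- function(pmid_sizes, dA, dB) {
  s <- 0
  for (sz in pmid_sizes) s <- s + 1 / log(1 + sz)
  (s / length(pmid_sizes)) * (1 / log(dA + dB))
}

# Hypergeometric upper tail P(X >= x) by explicit enumeration.
oracle_hyper_tail <- function(x, pop, succ, draws) {
  if (x <= 0) return(1)
  j <- x:min(draws, succ)
  sum(choose(succ, j) * choose(pop - succ, draws - j)) / choose(pop, draws)
}

# EASE p-value by enumeration: overlap k replaced by k - 1.
oracle_ease <- function(k, universe, path_size, query_size) {
  if (k == 0) return(1)
  oracle_hyper_tail(k - 1, universe, path_size, query_size)
}

# Random walk with restart by direct linear solve of
# (I - (1 - r) W) p = r e.
oracle_rwr <- function(net, seeds, restart) {
  nodes <- sort(unique(c(net$proteinA, net$proteinB)))
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(net))) {
    A[net$proteinA[i], net$proteinB[i]] <- 1
    A[net$proteinB[i], net$proteinA[i]] <- 1
  }
  W <- sweep(A, 2, pmax(colSums(A), 1), "/")
  e <- setNames(numeric(n), nodes)
  e[intersect(seeds, nodes)] <- 1 / length(intersect(seeds, nodes))
  p <- solve(diag(n) - (1 - restart) * W, restart * e)
  setNames(as.numeric(p), nodes)
}

# Connected random toy network with ppv values in [0.85, 1].
make_toy_network <- function(n_nodes, n_extra_links, seed = 1) {
  set.seed(seed)
  nodes <- sprintf("g%03d", seq_len(n_nodes))
  # spanning path keeps it connected, then extra random links
  links <- data.frame(proteinA = nodes[-n_nodes], proteinB = nodes[-1])
  if (n_extra_links > 0) {
    more <- t(replicate(n_extra_links, sample(nodes, 2)))
    links <- rbind(links, data.frame(proteinA = more[, 1],
                                     proteinB = more[, 2]))
  }
  links <- links[links$proteinA != links$proteinB, ]
  a <- pmin(links$proteinA, links$proteinB)
  b <- pmax(links$proteinA, links$proteinB)
  links <- data.frame(proteinA = a, proteinB = b)
  links <- links[!duplicated(paste(a, b)), ]
  links$ppv <- round(runif(nrow(links), 0.85, 1), 3)
  network_table(links)
}

# Network with a planted interconnected module embedded in a
# degree-heterogeneous (preferential-attachment) background. Module genes
# are mid-degree nodes, so degree alone does not identify them and
# degree-preserving nulls form a fair baseline.
make_module_network <- function(n_nodes = 150, module_size = 40,
                                p_module = 0.5, m_pa = 4, seed = 1) {
  set.seed(seed)
  g <- igraph::sample_pa(n_nodes, m = m_pa, directed = FALSE)
  el <- igraph::as_edgelist(g)
  nodes <- sprintf("g%03d", seq_len(n_nodes))
  links <- data.frame(proteinA = nodes[el[, 1]], proteinB = nodes[el[, 2]])
  deg <- igraph::degree(g)
  module <- nodes[order(abs(deg - stats::median(deg)))[seq_len(module_size)]]
  mp <- t(combn(module, 2))
  add <- runif(nrow(mp)) < p_module
  links <- rbind(links, data.frame(proteinA = mp[add, 1],
                                   proteinB = mp[add, 2]))
  a <- pmin(links$proteinA, links$proteinB)
  b <- pmax(links$proteinA, links$proteinB)
  links <- data.frame(proteinA = a, proteinB = b)
  links <- links[!duplicated(paste(a, b)) & a != b, ]
  links$ppv <- round(runif(nrow(links), 0.85, 1), 3)
  list(net = network_table(links), module = module)
}
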