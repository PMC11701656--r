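# Query-time network algorithms (group/independent expansion, MaxLink,
# ortholog rectangle alignment), EASE enrichment, and the random-walk-
# with-restart benchmark with degree-preserving nulls and performance gain.

query_result <- function(subnetwork, added_nodes, query) {
  structure(list(subnetwork = subnetwork, added_nodes = added_nodes,
                 query = query), class = "query_result")
}

#' @export
print.query_result <- function(x, ...) {
  cat(sprintf("query_result: %d query genes, %d added, %d links\n",
              length(x$query), nrow(x$added_nodes), nrow(x$subnetwork)))
  invisible(x)
}

induced_subnetwork <- function(net, nodes, cutoff) {
  keep <- net$ppv >= cutoff & net$proteinA %in% nodes &
    net$proteinB %in% nodes
  network_table(as.data.frame(net)[keep, , drop = FALSE])
}

#' Group network search
#'
#' Queries the network with a gene set as a group: candidate neighbors are
#' ranked by their summed link confidence to the query set (and, when
#' `prioritize_common` is on, first by the number of distinct query genes
#' they link to above the cutoff), and the top `n_add` genes are appended.
#' With `depth > 1` the search is re-run on the grown node set.
#'
#' @param net A [network_table()].
#' @param query Character vector of query genes (duplicates are ignored).
#' @param n_add Number of genes to add per expansion step.
#' @param prioritize_common Rank by number of distinct query genes linked
#'   first (default FALSE).
#' @param cutoff Minimum link PPV considered (default 0.85).
#' @param depth Expansion depth (default 1).
#' @return A `query_result` with the induced subnetwork and the ranked
#'   added genes (`gene`, `n_query_links`, `sum_ppv`).
#' @export
group_search <- function(net, query, n_add, prioritize_common = FALSE,
                         cutoff = 0.85, depth = 1L) {
  query <- unique(query)
  nodes <- net_nodes(net)
  mapped <- intersect(query, nodes)
  if (!length(mapped)) {
    warning("no query gene is present in the network")
    return(query_result(induced_subnetwork(net, character(), cutoff),
                        data.frame(gene = character(),
                                   n_query_links = integer(),
                                   sum_ppv = numeric()), query))
  }
  current <- mapped
  added_all <- NULL
  for (step in seq_len(depth)) {
    edges <- net_edges(net, cutoff)
    to_query <- edges[edges$from %in% current & !(edges$to %in% current), ,
                      drop = FALSE]
    if (nrow(to_query) == 0L || n_add == 0L) break
    stats_df <- data.frame(
      gene = names(tapply(to_query$ppv, to_query$to, sum)),
      n_query_links = as.integer(tapply(to_query$from, to_query$to,
                                        function(v) length(unique(v)))),
      sum_ppv = as.numeric(tapply(to_query$ppv, to_query$to, sum)),
      stringsAsFactors = FALSE)
    ord <- if (prioritize_common) {
      order(-stats_df$n_query_links, -stats_df$sum_ppv, stats_df$gene)
    } else {
      order(-stats_df$sum_ppv, stats_df$gene)
    }
    stats_df <- stats_df[ord, , drop = FALSE]
    picked <- utils::head(stats_df, n_add)
    added_all <- rbind(added_all, picked)
    current <- union(current, picked$gene)
  }
  if (is.null(added_all)) {
    added_all <- data.frame(gene = character(), n_query_links = integer(),
                            sum_ppv = numeric(), stringsAsFactors = FALSE)
  }
  rownames(added_all) <- NULL
  query_result(induced_subnetwork(net, current, cutoff), added_all, mapped)
}

#' Independent network search
#'
#' Queries the network separately for each query gene and adds its
#' `n_add_per_gene` most confident neighbors; the union of the per-gene
#' expansions is returned. Generally grows faster than [group_search()].
#'
#' @inheritParams group_search
#' @param n_add_per_gene Neighbors added per query gene and step.
#' @return A `query_result`; `added_nodes` carries the per-gene strongest
#'   link (`gene`, `seed`, `ppv`).
#' @export
independent_search <- function(net, query, n_add_per_gene, cutoff = 0.85,
                               depth = 1L) {
  query <- unique(query)
  nodes <- net_nodes(net)
  mapped <- intersect(query, nodes)
  if (!length(mapped)) {
    warning("no query gene is present in the network")
    return(query_result(induced_subnetwork(net, character(), cutoff),
                        data.frame(gene = character(), seed = character(),
                                   ppv = numeric()), query))
  }
  current <- mapped
  added_all <- NULL
  for (step in seq_len(depth)) {
    edges <- net_edges(net, cutoff)
    new_nodes <- character()
    for (g in sort(current)) {
      nb <- edges[edges$from == g & !(edges$to %in% current), ,
                  drop = FALSE]
      if (nrow(nb) == 0L) next
      nb <- nb[order(-nb$ppv, nb$to), , drop = FALSE]
      picked <- utils::head(nb, n_add_per_gene)
      added_all <- rbind(added_all,
                         data.frame(gene = picked$to, seed = g,
                                    ppv = picked$ppv,
                                    stringsAsFactors = FALSE))
      new_nodes <- union(new_nodes, picked$gene %||% picked$to)
    }
    if (!length(new_nodes)) break
    current <- union(current, new_nodes)
  }
  if (is.null(added_all)) {
    added_all <- data.frame(gene = character(), seed = character(),
                            ppv = numeric(), stringsAsFactors = FALSE)
  } else {
    added_all <- added_all[!duplicated(added_all$gene), , drop = FALSE]
    rownames(added_all) <- NULL
  }
  query_result(induced_subnetwork(net, current, cutoff), added_all, mapped)
}

#' MaxLink candidate ranking
#'
#' Ranks non-query genes by their number of links into the query set and a
#' hypergeometric tail p-value: for a candidate with network degree d and
#' x links into the mapped query (size q) in a network of N nodes,
#' `p = P(X >= x)` with `X ~ Hypergeometric(N - 1, q, d)`. Primary ranking
#' key is x (descending), secondary the p-value, ties broken
#' lexicographically.
#'
#' @param net A [network_table()].
#' @param query Character vector of query genes.
#' @param cutoff Minimum link PPV considered (default 0.85).
#' @return data.frame `gene`, `links_to_query`, `degree`, `p_value`,
#'   ranked.
#' @export
maxlink_rank <- function(net, query, cutoff = 0.85) {
  query <- unique(query)
  if (!length(query)) stop("query must be non-empty")
  edges <- net_edges(net, cutoff)
  nodes <- sort(unique(c(edges$from, edges$to)))
  mapped <- intersect(query, nodes)
  q <- length(mapped)
  N <- length(nodes)
  cand <- setdiff(nodes, mapped)
  if (!length(cand) || q == 0L) {
    return(data.frame(gene = character(), links_to_query = integer(),
                      degree = integer(), p_value = numeric(),
                      stringsAsFactors = FALSE))
  }
  deg <- table(edges$from)
  into_q <- table(edges$from[edges$to %in% mapped])
  d <- as.integer(deg[cand])
  x <- as.integer(into_q[cand])
  x[is.na(x)] <- 0L
  p <- stats::phyper(x - 1L, m = q, n = N - 1L - q, k = d,
                     lower.tail = FALSE)
  out <- data.frame(gene = cand, links_to_query = x, degree = d,
                    p_value = p, stringsAsFactors = FALSE)
  out <- out[order(-out$links_to_query, out$p_value, out$gene), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' EASE pathway enrichment p-value
#'
#' Conservative one-sided Fisher/hypergeometric overlap test in which the
#' observed query-pathway overlap k is replaced by k - 1 before computing
#' the upper tail: `p = P(X >= k - 1)` for
#' `X ~ Hypergeometric(universe, |pathway|, |query|)`. Overlaps of 0 or 1
#' give p = 1 by construction.
#'
#' @param query Character vector of query genes.
#' @param pathway Character vector of pathway genes.
#' @param universe Total number of genes in the universe (count).
#' @return One-sided p-value.
#' @export
ease_enrichment <- function(query, pathway, universe) {
  query <- unique(query)
  pathway <- unique(pathway)
  if (length(pathway) > universe || length(query) > universe) {
    stop("query and pathway must be subsets of the universe")
  }
  k <- length(intersect(query, pathway))
  if (k == 0L) return(1)
  stats::phyper(k - 2L, m = length(pathway),
                n = universe - length(pathway), k = length(query),
                lower.tail = FALSE)
}

#' Align two networks through orthologs ("rectangle" constellations)
#'
#' Finds all conserved link patterns made of one link (a1, b1) in network
#' A, one link (a2, b2) in network B, and the two cross-species ortholog
#' links a1-a2 and b1-b2.
#'
#' @param netA,netB [network_table()] objects of the two species.
#' @param ortho An [ortholog_map()] with `source` in A's species and
#'   `target` in B's.
#' @return data.frame `proteinA1`, `proteinB1`, `proteinA2`, `proteinB2`,
#'   one row per rectangle.
#' @export
align_orthologs <- function(netA, netB, ortho) {
  empty <- data.frame(proteinA1 = character(), proteinB1 = character(),
                      proteinA2 = character(), proteinB2 = character(),
                      stringsAsFactors = FALSE)
  if (nrow(netA) == 0L || nrow(netB) == 0L || nrow(ortho) == 0L) {
    return(empty)
  }
  bkeys <- net_keys(netB)
  orth_of <- split(ortho$target, ortho$source)
  out <- list()
  for (i in seq_len(nrow(netA))) {
    a1 <- netA$proteinA[i]
    b1 <- netA$proteinB[i]
    a2s <- orth_of[[a1]]
    b2s <- orth_of[[b1]]
    if (is.null(a2s) || is.null(b2s)) next
    grid <- expand.grid(a2 = a2s, b2 = b2s, stringsAsFactors = FALSE)
    grid <- grid[grid$a2 != grid$b2, , drop = FALSE]
    hit <- pair_key(grid$a2, grid$b2) %in% bkeys
    if (any(hit)) {
      out[[length(out) + 1L]] <- data.frame(
        proteinA1 = a1, proteinB1 = b1,
        proteinA2 = grid$a2[hit], proteinB2 = grid$b2[hit],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[!duplicated(res), , drop = FALSE]
}

#' Random walk with restart
#'
#' Iterates `p = r e + (1 - r) W p` to convergence, where `W` is the
#' column-normalized (optionally PPV-weighted) adjacency matrix of the
#' undirected network and `e` is uniform over the mapped seed genes. The
#' stationary probabilities sum to 1.
#'
#' @param net A [network_table()].
#' @param seeds Character vector of seed genes (must intersect the
#'   network).
#' @param restart Restart probability (default 0.75).
#' @param tol Convergence tolerance on the max absolute change
#'   (default 1e-10).
#' @param weighted Use link PPVs as edge weights (default FALSE).
#' @param max_iter Iteration cap (default 10000).
#' @return Named numeric vector of stationary probabilities over network
#'   nodes.
#' @export
rwr <- function(net, seeds, restart = 0.75, tol = 1e-10, weighted = FALSE,
                max_iter = 10000L) {
  nodes <- net_nodes(net)
  mapped <- intersect(unique(seeds), nodes)
  if (!length(mapped)) stop("no seed gene is present in the network")
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  wts <- if (weighted) net$ppv else rep(1, nrow(net))
  ia <- match(net$proteinA, nodes)
  ib <- match(net$proteinB, nodes)
  for (i in seq_len(nrow(net))) {
    W[ia[i], ib[i]] <- W[ia[i], ib[i]] + wts[i]
    W[ib[i], ia[i]] <- W[ib[i], ia[i]] + wts[i]
  }
  cs <- colSums(W)
  cs[cs == 0] <- 1
  W <- sweep(W, 2L, cs, "/")
  e <- stats::setNames(numeric(n), nodes)
  e[mapped] <- 1 / length(mapped)
  p <- e
  for (it in seq_len(max_iter)) {
    p_new <- restart * e + (1 - restart) * as.vector(W %*% p)
    if (max(abs(p_new - p)) < tol) {
      p <- p_new
      break
    }
    p <- p_new
  }
  stats::setNames(as.numeric(p), nodes)
}

#' Degree-preserving network rewiring
#'
#' Seeded double-edge-swap randomization preserving every node's degree,
#' with self-loops and multi-edges forbidden; the number of attempted
#' swaps defaults to the number of links. Link attributes (PPV and
#' friends) are carried over to the rewired topology as a multiset, so the
#' null preserves the degree sequence and the confidence distribution but
#' not their association.
#'
#' @param net A [network_table()].
#' @param n_swaps Number of swap attempts (default `nrow(net)`).
#' @param seed Integer seed.
#' @return A rewired [network_table()].
#' @export
rewire_preserve_degree <- function(net, n_swaps = NULL, seed = 1L) {
  if (nrow(net) < 2L) return(net)
  n_swaps <- n_swaps %||% nrow(net)
  g <- igraph::graph_from_data_frame(
    as.data.frame(net)[, c("proteinA", "proteinB")], directed = FALSE)
  g2 <- with_seed(seed,
                  igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                           niter = n_swaps)))
  el <- igraph::as_edgelist(g2)
  network_table(data.frame(
    proteinA = el[, 1L], proteinB = el[, 2L],
    ppv = net$ppv, gold_standard = net$gold_standard, fbs = net$fbs,
    stringsAsFactors = FALSE))
}

#' Disease-gene recovery benchmark with performance gain
#'
#' For each of `n_splits` random half-splits of the gene set, a random
#' walk with restart is run from one half and the recovery of the held-out
#' half is scored as an AUROC against all other network genes. The same
#' splits are evaluated on `n_randomizations` degree-preserving rewirings
#' of the network, and the performance gain is
#' `PG = (median real AUROC - median null AUROC) / median null AUROC`.
#'
#' @param geneset Character vector of disease/pathway genes (>= 2 mapped).
#' @param net A [network_table()].
#' @param n_splits Number of half-splits (default 30).
#' @param n_randomizations Number of rewired networks (default 30; the
#'   null median is over `n_splits * n_randomizations` runs).
#' @param restart RWR restart probability (default 0.75).
#' @param seed Integer seed governing splits and rewirings.
#' @param weighted Use PPV-weighted propagation (default FALSE).
#' @return Object of class `benchmark_result`: `auroc_real`, `auroc_null`,
#'   `median_real`, `median_null`, `pg`, `n_mapped`; or NULL (with a
#'   warning) when fewer than 2 genes map.
#' @export
performance_gain <- function(geneset, net, n_splits = 30,
                             n_randomizations = 30, restart = 0.75,
                             seed = 1L, weighted = FALSE) {
  nodes <- net_nodes(net)
  mapped <- sort(intersect(unique(geneset), nodes))
  if (length(mapped) < 2L) {
    warning("gene set maps fewer than 2 genes to the network; skipped")
    return(NULL)
  }
  splits <- with_seed(seed, lapply(seq_len(n_splits), function(i) {
    sample(mapped, floor(length(mapped) / 2))
  }))
  eval_net <- function(network) {
    vapply(splits, function(half) {
      p <- rwr(network, half, restart = restart, weighted = weighted)
      held <- setdiff(mapped, half)
      others <- setdiff(names(p), mapped)
      auroc(p[held], p[others])
    }, numeric(1))
  }
  real <- eval_net(net)
  null <- unlist(lapply(seq_len(n_randomizations), function(j) {
    eval_net(rewire_preserve_degree(net, seed = seed + j))
  }))
  med_r <- stats::median(real, na.rm = TRUE)
  med_n <- stats::median(null, na.rm = TRUE)
  structure(list(auroc_real = real, auroc_null = null,
                 median_real = med_r, median_null = med_n,
                 pg = (med_r - med_n) / med_n,
                 n_mapped = length(mapped)), class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf(
    "benchmark_result: median AUROC %.3f (real) vs %.3f (null), PG = %.3f\n",
    x$median_real, x$median_null, x$pg))
  invisible(x)
}

#' First-order neighbor gain of a query set
#'
#' Ratio of non-query first-order neighbors of the query genes to the
#' number of mapped query genes; low values indicate specific, compact
#' neighborhoods.
#'
#' @param net A [network_table()].
#' @param query Character vector of query genes.
#' @return Numeric ratio (0 for isolated queries).
#' @export
neighbor_gain <- function(net, query) {
  nodes <- net_nodes(net)
  mapped <- intersect(unique(query), nodes)
  if (!length(mapped)) stop("query does not map to the network")
  edges <- net_edges(net)
  nb <- unique(edges$to[edges$from %in% mapped])
  length(setdiff(nb, mapped)) / length(mapped)
}
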