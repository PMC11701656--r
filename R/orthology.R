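# Orthology-based transfer of evidence and whole networks between species,
# species distances and trees (orthophylogram), closest-species selection,
# and similarity measures for evaluating transferred networks.

#' Ortholog-based species distance
#'
#' One minus the average fraction of orthologous proteins in both
#' directions: `1 - [(#orthologous in A)/nA + (#orthologous in B)/nB] / 2`.
#'
#' @param orthoAB An [ortholog_map()] between species A and B.
#' @param nA,nB Proteome sizes of A and B.
#' @return Distance in \[0, 1\].
#' @export
species_distance <- function(orthoAB, nA, nB) {
  if (nA <= 0 || nB <= 0) stop("proteome sizes must be positive")
  fa <- length(unique(orthoAB$source)) / nA
  fb <- length(unique(orthoAB$target)) / nB
  1 - (fa + fb) / 2
}

#' Build a species tree from a distance matrix
#'
#' Neighbour-joining (optionally rooted at a species of interest, as used
#' by the phylogenetic-profile score) or UPGMA (unweighted pair group
#' method, as used for the orthophylogram). Negative NJ branch lengths are
#' clamped to zero.
#'
#' @param distances Symmetric numeric matrix with zero diagonal and species
#'   labels as dimnames.
#' @param method `"nj"` or `"upgma"`.
#' @param root_species For `"nj"`, the leaf to root the tree at (optional).
#' @return An `ape::phylo` tree whose leaves are the species.
#' @export
build_species_tree <- function(distances, method = c("upgma", "nj"),
                               root_species = NULL) {
  method <- match.arg(method)
  distances <- as.matrix(distances)
  if (!isSymmetric(unname(distances), tol = 1e-9) ||
      any(abs(diag(distances)) > 1e-12)) {
    stop("distance matrix must be symmetric with zero diagonal")
  }
  labels <- rownames(distances) %||% colnames(distances)
  if (is.null(labels)) stop("distance matrix must carry species labels")
  rownames(distances) <- colnames(distances) <- labels
  n <- nrow(distances)
  if (n < 2L) stop("need at least two species")
  if (n == 2L) {
    tree <- list(edge = matrix(c(3L, 3L, 1L, 2L), 2L, 2L),
                 edge.length = rep(distances[1L, 2L] / 2, 2L),
                 tip.label = labels, Nnode = 1L)
    class(tree) <- "phylo"
  } else if (method == "upgma") {
    hc <- stats::hclust(stats::as.dist(distances), method = "average")
    tree <- ape::as.phylo(hc)
  } else {
    tree <- ape::nj(stats::as.dist(distances))
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  if (method == "nj" && !is.null(root_species)) {
    if (!root_species %in% tree$tip.label) {
      stop("root species not among the leaves")
    }
    tree <- ape::root(tree, outgroup = root_species, resolve.root = TRUE)
  }
  tree
}

#' Transfer an evidence table to another species via orthologs
#'
#' Each scored source pair is mapped through the ortholog map to every
#' combination of target orthologs of its two endpoints. When several
#' source pairs map onto the same target pair (many-to-one orthology),
#' their scores are averaged into a single entry. Evidence types that
#' already contain cross-species information (DOM, PHP, SCL) are refused.
#'
#' @param source An [evidence_table()] in the source species.
#' @param ortho An [ortholog_map()] with `source` identifiers in the source
#'   species and `target` identifiers in the target species.
#' @param target_species Label for the transferred table.
#' @return An [evidence_table()] in the target species.
#' @export
transfer_evidence <- function(source, ortho, target_species = "target") {
  ev_type <- attr(source, "evidence_type")
  if (ev_type %in% c("DOM", "PHP", "SCL")) {
    stop(ev_type, " is not transferable: such scores already contain ",
         "cross-species information")
  }
  directed <- isTRUE(attr(source, "directed"))
  if (nrow(source) == 0L) {
    return(evidence_table(as.data.frame(source), evidence_type = ev_type,
                          species = target_species,
                          dataset_id = attr(source, "dataset_id"),
                          directed = directed))
  }
  mapA <- merge(data.frame(source = source$proteinA,
                           row = seq_len(nrow(source))),
                as.data.frame(ortho)[, c("source", "target")], by = "source")
  mapB <- merge(data.frame(source = source$proteinB,
                           row = seq_len(nrow(source))),
                as.data.frame(ortho)[, c("source", "target")], by = "source")
  joined <- merge(mapA, mapB, by = "row", suffixes = c("A", "B"))
  joined <- joined[joined$targetA != joined$targetB, , drop = FALSE]
  if (nrow(joined) == 0L) {
    return(evidence_table(
      data.frame(proteinA = character(), proteinB = character(),
                 score = numeric()),
      evidence_type = ev_type, species = target_species,
      dataset_id = attr(source, "dataset_id"), directed = directed))
  }
  joined$score <- source$score[joined$row]
  key <- if (directed) dpair_key(joined$targetA, joined$targetB) else
    pair_key(joined$targetA, joined$targetB)
  # one source pair contributes once per target pair even if several
  # ortholog routes connect them
  dup <- duplicated(paste(joined$row, key))
  joined <- joined[!dup, , drop = FALSE]
  key <- key[!dup]
  avg <- tapply(joined$score, key, mean)
  parts <- strsplit(names(avg), "|", fixed = TRUE)
  evidence_table(data.frame(
    proteinA = vapply(parts, `[`, character(1), 1L),
    proteinB = vapply(parts, `[`, character(1), 2L),
    score = as.numeric(avg), stringsAsFactors = FALSE),
    evidence_type = ev_type, species = target_species,
    dataset_id = attr(source, "dataset_id"), directed = directed)
}

#' Pick the closest source species for network transfer
#'
#' Prefers the taxonomically nearest candidate (path length in the lineage
#' tree); ties, or candidates without taxonomy, are resolved by the
#' smallest orthophylogram distance.
#'
#' @param target Target species label.
#' @param candidates Candidate source species labels.
#' @param taxonomy Optional named list species -> ordered lineage
#'   (character vector from root to species).
#' @param distances Symmetric distance matrix over species (orthophylogram
#'   distances) with dimnames.
#' @return The selected candidate species label.
#' @export
closest_species <- function(target, candidates, taxonomy = NULL,
                            distances = NULL) {
  if (!length(candidates)) stop("at least one candidate is required")
  dist_of <- function(sp) {
    if (is.null(distances)) return(NA_real_)
    distances[target, sp]
  }
  if (!is.null(taxonomy) && !is.null(taxonomy[[target]])) {
    lt <- taxonomy[[target]]
    tax_dist <- vapply(candidates, function(sp) {
      ls <- taxonomy[[sp]]
      if (is.null(ls)) return(NA_real_)
      common <- 0L
      for (i in seq_len(min(length(lt), length(ls)))) {
        if (lt[i] == ls[i]) common <- i else break
      }
      (length(lt) - common) + (length(ls) - common)
    }, numeric(1))
    if (any(!is.na(tax_dist))) {
      best <- which(tax_dist == min(tax_dist, na.rm = TRUE))
      if (length(best) == 1L) return(candidates[best])
      candidates <- candidates[best]  # ties -> orthophylogram distance
    }
  }
  if (is.null(distances)) return(sort(candidates)[1L])
  d <- vapply(candidates, dist_of, numeric(1))
  candidates[order(d, candidates)][1L]
}

#' Transfer a whole network to another species via orthologs
#'
#' Every source link is expanded to the full cross-product of its
#' endpoints' target orthologs, keeping the original link confidence.
#' Duplicate target pairs keep the maximum PPV. Links with an endpoint
#' lacking orthologs are not transferred.
#'
#' @param source A [network_table()].
#' @param ortho An [ortholog_map()] (source -> target identifiers).
#' @return A [network_table()] in the target species.
#' @export
transfer_network <- function(source, ortho) {
  if (nrow(source) == 0L) return(source)
  om <- as.data.frame(ortho)[, c("source", "target")]
  mapA <- merge(data.frame(source = source$proteinA,
                           row = seq_len(nrow(source))), om, by = "source")
  mapB <- merge(data.frame(source = source$proteinB,
                           row = seq_len(nrow(source))), om, by = "source")
  joined <- merge(mapA, mapB, by = "row", suffixes = c("A", "B"))
  joined <- joined[joined$targetA != joined$targetB, , drop = FALSE]
  if (nrow(joined) == 0L) {
    return(network_table(data.frame(proteinA = character(),
                                    proteinB = character(),
                                    ppv = numeric())))
  }
  joined$ppv <- source$ppv[joined$row]
  joined$gold_standard <- source$gold_standard[joined$row]
  joined$fbs <- source$fbs[joined$row]
  dir_src <- source$direction[joined$row]
  flip <- joined$targetA > joined$targetB
  a <- ifelse(flip, joined$targetB, joined$targetA)
  b <- ifelse(flip, joined$targetA, joined$targetB)
  dir <- ifelse(dir_src == "none", "none",
                ifelse(xor(dir_src == "BA", flip), "BA", "AB"))
  key <- pair_key(a, b)
  ord <- order(key, -joined$ppv)
  first <- !duplicated(key[ord])
  sel <- ord[first]
  network_table(data.frame(
    proteinA = a[sel], proteinB = b[sel], ppv = joined$ppv[sel],
    direction = dir[sel], gold_standard = joined$gold_standard[sel],
    fbs = joined$fbs[sel], stringsAsFactors = FALSE))
}

#' Node and link similarity of two networks
#'
#' Jaccard index (`|A n B| / |A u B|`) and Szymkiewicz-Simpson overlap
#' coefficient (`|A n B| / min(|A|, |B|)`) for the node sets and the
#' unordered link sets. Empty comparisons are defined as 0.
#'
#' @param netA,netB [network_table()] objects.
#' @return Named list `node_ji`, `node_oc`, `link_ji`, `link_oc`.
#' @export
network_similarity <- function(netA, netB) {
  set_sim <- function(a, b) {
    a <- unique(a)
    b <- unique(b)
    inter <- length(intersect(a, b))
    uni <- length(union(a, b))
    mn <- min(length(a), length(b))
    list(ji = if (uni == 0L) 0 else inter / uni,
         oc = if (mn == 0L) 0 else inter / mn)
  }
  nodes <- set_sim(net_nodes(netA), net_nodes(netB))
  links <- set_sim(net_keys(netA), net_keys(netB))
  list(node_ji = nodes$ji, node_oc = nodes$oc,
       link_ji = links$ji, link_oc = links$oc)
}
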