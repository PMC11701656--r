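# Raw association scores for the ten evidence types. All logarithms are
# natural, matching the log-likelihood-ratio convention of the training
# stage.

#' Domain-domain interaction (DOM) score
#'
#' For proteins A and B with Pfam-style domain annotations, the score is
#' the fraction of scored domain pairs m / N (N = |domains(A)| * |domains(B)|)
#' times the average domain-pair support score, each pair down-weighted by
#' the log of the sum of the two domains' interaction degrees:
#' `DOM(A,B) = (m/N) * (1/m) * sum_i UniDomInt(a,b) / ln(d_a + d_b)`.
#'
#' @param A,B Protein identifiers.
#' @param ann Domain annotation: a list with `domains` (named list protein
#'   -> character vector of domain ids), `pair_scores` (data.frame
#'   `domainA`, `domainB`, `score` with support scores in \[0, 1\]) and
#'   `degree` (named numeric, scored-partner count per domain).
#' @return Numeric score (0 when no domain pair is scored); `NA` when a
#'   protein has no domain annotation.
#' @export
dom_score <- function(A, B, ann) {
  da <- ann$domains[[A]]
  db <- ann$domains[[B]]
  if (is.null(da) || is.null(db) || !length(da) || !length(db)) {
    return(NA_real_)
  }
  N <- length(da) * length(db)
  ps <- ann$pair_scores
  key <- paste(ps$domainA, ps$domainB)
  lookup <- function(x, y) {
    hit <- match(paste(x, y), key)
    if (is.na(hit)) hit <- match(paste(y, x), key)
    hit
  }
  total <- 0
  m <- 0L
  for (x in da) {
    for (y in db) {
      hit <- lookup(x, y)
      if (!is.na(hit)) {
        m <- m + 1L
        dsum <- ann$degree[[x]] + ann$degree[[y]]
        total <- total + ps$score[hit] / log(dsum)
      }
    }
  }
  if (m == 0L) return(0)
  (m / N) * (total / m)
}

#' Physical interaction (PIN) publication-support score
#'
#' Weighted average over the n publications supporting the pair, weighting
#' each publication by `1/ln(1 + |PMID_i|)` (interactions it reports), and
#' down-weighting hubs by `1/ln(d_A + d_B)`:
#' `PIN(A,B) = [sum_i 1/ln(1+|PMID_i|)]/n * 1/ln(d_A + d_B)`.
#'
#' @param A,B Protein identifiers.
#' @param support Publication support: list with `publications` (named list
#'   pair key -> character vector of publication ids; keys are canonical
#'   unordered pair keys from the smaller protein id), `publication_size`
#'   (named numeric, interactions reported per publication) and
#'   `protein_degree` (named numeric, total interactions per protein).
#' @return Numeric score, or `NA` when the pair has no supporting
#'   publication or the degree term is undefined (`d_A + d_B <= 1`).
#' @export
pin_score <- function(A, B, support) {
  pmids <- support$publications[[pair_key(A, B)]]
  if (is.null(pmids) || !length(pmids)) return(NA_real_)
  dA <- support$protein_degree[[A]]
  dB <- support$protein_degree[[B]]
  if (is.null(dA) || is.null(dB) || (dA + dB) <= 1) return(NA_real_)
  sizes <- support$publication_size[pmids]
  mean(1 / log(1 + sizes)) * (1 / log(dA + dB))
}

#' Spearman profile correlation with a validity cutoff
#'
#' Rank correlation over positions where both profiles are valid
#' (non-missing); used for genetic-interaction, mRNA co-expression and
#' protein co-expression profiles, with evidence-specific minimum numbers
#' of valid pairs (5, 3 and 5 respectively).
#'
#' @param profileA,profileB Numeric vectors on the same sample/tissue axis;
#'   NA marks missing entries.
#' @param min_valid Minimum number of jointly valid positions.
#' @return Spearman correlation in \[-1, 1\], or `NA` when fewer than
#'   `min_valid` positions are jointly valid or either valid subvector has
#'   zero variance.
#' @export
profile_correlation_score <- function(profileA, profileB, min_valid) {
  if (length(profileA) != length(profileB)) {
    stop("profiles must be on the same axis")
  }
  ok <- is.finite(profileA) & is.finite(profileB)
  if (sum(ok) < min_valid) return(NA_real_)
  a <- profileA[ok]
  b <- profileB[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b, method = "spearman")
}

#' Post-process mRNA co-expression correlations into an evidence table
#'
#' Homolog pairs are removed (co-expression between homologs reflects
#' sequence similarity rather than functional coupling), pairs with
#' absolute correlation not exceeding `min_abs_r` are dropped, and the
#' retained absolute correlations are min-max scaled to \[0, 1\] within the
#' dataset. When all retained values are equal they scale to 1.
#'
#' @param correlations data.frame `proteinA`, `proteinB`, `r`.
#' @param homolog_pairs Character vector of canonical pair keys (or a
#'   data.frame `proteinA`, `proteinB`) marking homologous pairs.
#' @param dataset_id,species Labels for the resulting table.
#' @param min_abs_r Retention threshold on |r| (default 0.5, strict).
#' @return An [evidence_table()] of type `"MEX"` (possibly empty).
#' @export
mex_postprocess <- function(correlations, homolog_pairs = character(),
                            dataset_id = "mex1", species = "unknown",
                            min_abs_r = 0.5) {
  if (is.data.frame(homolog_pairs)) {
    homolog_pairs <- pair_key(homolog_pairs$proteinA, homolog_pairs$proteinB)
  }
  df <- as.data.frame(correlations)
  if (nrow(df)) {
    if (any(abs(df$r) > 1 + 1e-12, na.rm = TRUE)) {
      stop("correlations must lie in [-1, 1]")
    }
    keys <- pair_key(df$proteinA, df$proteinB)
    df <- df[!(keys %in% homolog_pairs) & abs(df$r) > min_abs_r, ,
             drop = FALSE]
  }
  if (nrow(df) == 0L) {
    return(evidence_table(data.frame(proteinA = character(),
                                     proteinB = character(),
                                     score = numeric()),
                          evidence_type = "MEX", species = species,
                          dataset_id = dataset_id))
  }
  v <- abs(df$r)
  rng <- range(v)
  score <- if (diff(rng) == 0) rep(1, length(v)) else
    (v - rng[1L]) / diff(rng)
  evidence_table(data.frame(proteinA = df$proteinA, proteinB = df$proteinB,
                            score = score, stringsAsFactors = FALSE),
                 evidence_type = "MEX", species = species,
                 dataset_id = dataset_id)
}

#' Jaccard index of shared regulators
#'
#' Used for microRNA co-regulation (MIR) and shared transcription factor
#' binding (TFB): the Jaccard index of the regulator sets of the two
#' proteins, retaining only positive values.
#'
#' @param setA,setB Character vectors of regulators.
#' @return `|A n B| / |A u B|`, or `NA` when the index is 0 or both sets
#'   are empty.
#' @export
jaccard_regulator_score <- function(setA, setB) {
  setA <- unique(setA)
  setB <- unique(setB)
  u <- length(union(setA, setB))
  if (u == 0L) return(NA_real_)
  ji <- length(intersect(setA, setB)) / u
  if (ji == 0) NA_real_ else ji
}

#' Top-tissue protein co-expression (PEX) score
#'
#' Takes each protein's top `ceiling(top_fraction * T)` tissues by
#' expression and returns the Jaccard index of the two top-tissue sets,
#' retaining only positive values.
#'
#' @param exprA,exprB Numeric expression vectors over the same tissue axis
#'   (names or positions identify tissues); NA marks missing values.
#' @param top_fraction Fraction of tissues considered "top" (default 0.25).
#' @return Jaccard index in (0, 1\], or `NA` when it is 0 or either vector
#'   is all-missing.
#' @export
pex_top_tissue_score <- function(exprA, exprB, top_fraction = 0.25) {
  if (length(exprA) != length(exprB)) {
    stop("expression vectors must be on the same tissue axis")
  }
  n_top <- ceiling(top_fraction * length(exprA))
  top_set <- function(v) {
    ok <- which(is.finite(v))
    if (!length(ok)) return(NULL)
    ok[order(-v[ok], ok)][seq_len(min(n_top, length(ok)))]
  }
  ta <- top_set(exprA)
  tb <- top_set(exprB)
  if (is.null(ta) || is.null(tb)) return(NA_real_)
  jaccard_regulator_score(as.character(ta), as.character(tb))
}

# Total branch length of the minimal subtree of `tree` spanning the given
# tips (ape phylo). An edge belongs to the spanning subtree iff the tips
# below it contain some, but not all, of the target tips.
spanning_subtree_length <- function(tree, tips) {
  k <- length(tips)
  if (k < 2L) return(0)
  tr <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tr$tip.label)
  n_node <- n_tip + tr$Nnode
  # count of target tips below each node
  cnt <- integer(n_node)
  cnt[tips] <- 1L
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1L]
    ch <- tr$edge[e, 2L]
    cnt[p] <- cnt[p] + cnt[ch]
  }
  below <- cnt[tr$edge[, 2L]]
  sum(tr$edge.length[below > 0L & below < k])
}

#' Phylogenetic profile (PHP) similarity score
#'
#' Quantifies co-occurrence of two proteins across species, weighted by
#' evolutionary depth. The positive score is the total branch length of the
#' minimal subtree spanning species where both proteins have orthologs,
#' divided by the total tree length; the negative score is the same for
#' species where exactly one protein has an ortholog. The PHP score is
#' `ln(positive / negative)`; zero numerator or denominator is regularized
#' to `eps_frac` of the total tree length, which caps the score.
#'
#' @param profileA,profileB 0/1 presence vectors over the tree's leaf
#'   species, named by species or aligned with `tree$tip.label`.
#' @param tree Rooted `ape::phylo` species tree with branch lengths.
#' @param eps_frac Regularization fraction of total tree length
#'   (default 1e-6).
#' @return Numeric PHP score (symmetric in the two profiles).
#' @export
php_score <- function(profileA, profileB, tree, eps_frac = 1e-6) {
  tips <- tree$tip.label
  align <- function(p) {
    if (length(p) != length(tips)) {
      stop("profile length must equal the number of tree leaves")
    }
    if (!is.null(names(p))) {
      if (!setequal(names(p), tips)) {
        stop("profile species do not match the tree leaves")
      }
      p <- p[tips]
    }
    as.integer(p != 0)
  }
  a <- align(profileA)
  b <- align(profileB)
  total <- sum(tree$edge.length)
  if (total <= 0) stop("tree must have positive total branch length")
  eps <- eps_frac * total
  both <- which(a == 1L & b == 1L)
  one <- which(a + b == 1L)
  pos <- max(spanning_subtree_length(tree, both), eps)
  neg <- max(spanning_subtree_length(tree, one), eps)
  log((pos / total) / (neg / total))
}

#' Gene regulation (GRG) scores from ChIP-seq peak files
#'
#' Per dataset, `signalValue` enrichment is min-max normalized to \[0, 1\]
#' (a dataset with constant signal normalizes to 1). Each peak is assigned
#' to the genes whose annotated interval, extended by `assign_window` bp
#' upstream of the annotated start (strand-aware; unstranded genes are
#' treated as plus strand), it overlaps. The result is a directed
#' TF -> gene evidence table; pairs supported by several datasets keep the
#' maximum normalized enrichment.
#'
#' @param datasets List of entries `list(tf = <TF label>, peaks =
#'   <narrowPeak data.frame>)` (see [read_narrowpeak()]).
#' @param genes data.frame with columns `gene`, `chrom`, `start`, `end` and
#'   optionally `strand` (0-based half-open intervals).
#' @param assign_window Upstream assignment window in bp (default 10000).
#' @param species Species label for the resulting table.
#' @return A directed [evidence_table()] of type `"GRG"`.
#' @export
grg_score <- function(datasets, genes, assign_window = 10000,
                      species = "unknown") {
  if (!length(datasets)) stop("at least one dataset is required")
  if (!nrow(genes)) stop("gene annotation must be non-empty")
  strand <- if (is.null(genes$strand)) rep("+", nrow(genes)) else
    ifelse(genes$strand == "-", "-", "+")
  g_start <- ifelse(strand == "-", genes$start,
                    pmax(0L, genes$start - assign_window))
  g_end <- ifelse(strand == "-", genes$end + assign_window, genes$end)
  out <- list()
  for (d in datasets) {
    peaks <- d$peaks
    if (!nrow(peaks)) next
    sv <- peaks$signalValue
    rng <- range(sv)
    norm <- if (diff(rng) == 0) rep(1, length(sv)) else
      (sv - rng[1L]) / diff(rng)
    for (chr in unique(peaks$chrom)) {
      pk <- which(peaks$chrom == chr)
      gn <- which(genes$chrom == chr)
      if (!length(gn)) next
      # half-open intervals [start, end): overlap as closed [start, end-1]
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(peaks$start[pk] + 1L, peaks$end[pk]),
        IRanges::IRanges(g_start[gn] + 1L, g_end[gn]))
      if (!length(hits)) next
      out[[length(out) + 1L]] <- data.frame(
        proteinA = d$tf,
        proteinB = genes$gene[gn[S4Vectors::subjectHits(hits)]],
        score = norm[pk[S4Vectors::queryHits(hits)]],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(evidence_table(data.frame(proteinA = character(),
                                     proteinB = character(),
                                     score = numeric()),
                          evidence_type = "GRG", species = species,
                          dataset_id = "grg", directed = TRUE))
  }
  df <- do.call(rbind, out)
  df <- df[df$proteinA != df$proteinB, , drop = FALSE]
  key <- dpair_key(df$proteinA, df$proteinB)
  best <- tapply(df$score, key, max)
  parts <- strsplit(names(best), "|", fixed = TRUE)
  evidence_table(data.frame(
    proteinA = vapply(parts, `[`, character(1), 1L),
    proteinB = vapply(parts, `[`, character(1), 2L),
    score = as.numeric(best), stringsAsFactors = FALSE),
    evidence_type = "GRG", species = species, dataset_id = "grg",
    directed = TRUE)
}

# Wang S-values for one term: contribution of every ancestor (and the term
# itself) obtained by propagating products of edge weights upward.
wang_s_values <- function(term, dag) {
  if (!term %in% c(dag$child, dag$parent)) {
    stop("unknown term: ", term)
  }
  s <- c(1)
  names(s) <- term
  frontier <- term
  while (length(frontier)) {
    nxt <- character()
    for (t in frontier) {
      up <- which(dag$child == t)
      for (e in up) {
        p <- dag$parent[e]
        val <- dag$weight[e] * s[[t]]
        if (is.na(s[p]) || s[[p]] < val) {
          s[p] <- val
          nxt <- c(nxt, p)
        }
      }
    }
    frontier <- unique(nxt)
  }
  s
}

wang_term_similarity <- function(t1, t2, dag) {
  s1 <- wang_s_values(t1, dag)
  s2 <- wang_s_values(t2, dag)
  common <- intersect(names(s1), names(s2))
  if (!length(common)) return(0)
  sum(s1[common] + s2[common]) / (sum(s1) + sum(s2))
}

#' Wang graph-based semantic similarity of two term sets
#'
#' Implements the Wang et al. topology-based similarity on a term DAG
#' (gene-ontology style). Per-term S-values are products of edge weights
#' propagated from the term to its ancestors (taking the maximum over
#' paths); the similarity of two terms is the summed S-values of their
#' shared ancestors divided by the sum of their total semantic values. Term
#' sets are aggregated by the best-match average.
#'
#' @param termsA,termsB Character vectors of annotation terms.
#' @param dag data.frame with columns `child`, `parent`, `weight` (edge
#'   contribution factors; 0.8 for is-a and 0.6 for part-of relations by
#'   the original method's convention).
#' @return Similarity in \[0, 1\].
#' @export
wang_semantic_similarity <- function(termsA, termsB, dag) {
  termsA <- unique(termsA)
  termsB <- unique(termsB)
  if (!length(termsA) || !length(termsB)) return(NA_real_)
  sim <- matrix(0, length(termsA), length(termsB))
  for (i in seq_along(termsA)) {
    for (j in seq_along(termsB)) {
      sim[i, j] <- wang_term_similarity(termsA[i], termsB[j], dag)
    }
  }
  (mean(apply(sim, 1L, max)) + mean(apply(sim, 2L, max))) / 2
}
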