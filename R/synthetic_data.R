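#' Generate a synthetic world with planted functional couplings
#'
#' Creates a set of synthetic proteins and plants a fixed fraction of all
#' unordered protein pairs as truly functionally coupled. The world is the
#' ground truth against which gold standards, evidence tables and the whole
#' inference pipeline can be evaluated.
#'
#' @param n_proteins Number of proteins (>= 2).
#' @param coupling_fraction Fraction in (0, 1) of all `n*(n-1)/2` pairs that
#'   are planted as coupled; the planted count is
#'   `round(coupling_fraction * n_pairs)`.
#' @param seed Integer RNG seed; identical seeds yield identical worlds.
#'
#' @return An object of class `planted_world`: a list with `proteins`
#'   (character vector), `pairs` (data.frame `proteinA`, `proteinB` with
#'   `proteinA < proteinB`), `coupled` (logical vector aligned with `pairs`),
#'   `true_couplings` (character vector of canonical pair keys),
#'   `coupling_fraction` and `seed`.
#' @examples
#' w <- generate_world(10, 0.1, seed = 1)
#' sum(w$coupled)  # 4 of 45 pairs
#' @export
generate_world <- function(n_proteins, coupling_fraction, seed) {
  if (!is.numeric(n_proteins) || n_proteins < 2) {
    stop("`n_proteins` must be >= 2")
  }
  stopifnot_scalar_fraction(coupling_fraction, "coupling_fraction")
  n_proteins <- as.integer(n_proteins)
  proteins <- sprintf("P%04d", seq_len(n_proteins))
  idx <- utils::combn(n_proteins, 2L)
  pairs <- data.frame(proteinA = proteins[idx[1L, ]],
                      proteinB = proteins[idx[2L, ]],
                      stringsAsFactors = FALSE)
  n_pairs <- nrow(pairs)
  n_coupled <- round(coupling_fraction * n_pairs)
  coupled <- logical(n_pairs)
  if (n_coupled > 0) {
    picked <- with_seed(seed, sample.int(n_pairs, n_coupled))
    coupled[picked] <- TRUE
  }
  structure(list(
    proteins = proteins,
    pairs = pairs,
    coupled = coupled,
    true_couplings = pair_key(pairs$proteinA, pairs$proteinB)[coupled],
    coupling_fraction = coupling_fraction,
    seed = as.integer(seed)
  ), class = "planted_world")
}

#' @export
print.planted_world <- function(x, ...) {
  cat(sprintf("planted_world: %d proteins, %d pairs, %d coupled (seed %d)\n",
              length(x$proteins), nrow(x$pairs), sum(x$coupled), x$seed))
  invisible(x)
}

#' Gaussian score model specification
#'
#' Distribution specification for [generate_evidence()]. Gaussian score
#' models keep the analytic log-likelihood ratio linear,
#' `LLR(x) = (mu1 - mu0) x / sd^2 + const`, which makes closed-form oracles
#' available for the training stage.
#'
#' @param mean,sd Gaussian parameters.
#' @return A list with class `score_model`.
#' @export
gaussian_spec <- function(mean = 0, sd = 1) {
  if (sd <= 0) stop("`sd` must be positive")
  structure(list(dist = "norm", mean = mean, sd = sd), class = "score_model")
}

draw_scores <- function(model, n) {
  if (!inherits(model, "score_model")) {
    stop("distribution spec must be created with gaussian_spec()")
  }
  stats::rnorm(n, mean = model$mean, sd = model$sd)
}

#' Generate an evidence score table for a planted world
#'
#' Coupled pairs draw raw scores from `pos_model`, uncoupled pairs from
#' `neg_model`. Incomplete assay coverage is emulated by seeded Bernoulli
#' thinning: each pair receives a score independently with probability
#' `coverage`.
#'
#' @param world A [generate_world()] result.
#' @param pos_model,neg_model Score distributions ([gaussian_spec()]).
#' @param coverage Fraction in (0, 1] of pairs that receive a score.
#' @param dataset_id Dataset label; also folded into the derived RNG seed so
#'   different datasets of the same world are independent.
#' @param evidence_type Evidence type label (default `"MEX"`).
#' @param seed Optional explicit seed; by default derived deterministically
#'   from `world$seed` and `dataset_id`.
#'
#' @return An `evidence_table` (see [evidence_table()]).
#' @export
generate_evidence <- function(world, pos_model = gaussian_spec(1, 1),
                              neg_model = gaussian_spec(0, 1),
                              coverage = 1, dataset_id = "synth1",
                              evidence_type = "MEX", seed = NULL) {
  stopifnot(inherits(world, "planted_world"))
  stopifnot_scalar_fraction(coverage, "coverage", open_upper = FALSE)
  seed <- seed %||% string_seed(dataset_id, base = world$seed)
  n <- nrow(world$pairs)
  scores <- with_seed(seed, {
    s <- numeric(n)
    s[world$coupled] <- draw_scores(pos_model, sum(world$coupled))
    s[!world$coupled] <- draw_scores(neg_model, sum(!world$coupled))
    keep <- stats::runif(n) <= coverage
    list(s = s, keep = keep)
  })
  df <- world$pairs[scores$keep, , drop = FALSE]
  df$score <- scores$s[scores$keep]
  evidence_table(df, evidence_type = evidence_type, species = "synthetic",
                 dataset_id = dataset_id)
}

#' Generate an imperfect gold standard from a planted world
#'
#' Each true coupling is included with probability `recall`; each
#' non-coupling with probability `fpr` (false positive rate), emulating an
#' incomplete and partly noisy curated link set.
#'
#' @param world A [generate_world()] result.
#' @param recall,fpr Probabilities in \[0, 1\].
#' @param name Gold standard name.
#' @param seed Integer seed.
#' @return A `gold_standard` object (see [gold_standard()]).
#' @export
generate_gold_standard <- function(world, recall, fpr, name = "Complex",
                                   seed = 1L) {
  stopifnot(inherits(world, "planted_world"))
  stopifnot_scalar_fraction(recall, "recall", open_lower = FALSE,
                            open_upper = FALSE)
  stopifnot_scalar_fraction(fpr, "fpr", open_lower = FALSE,
                            open_upper = FALSE)
  keep <- with_seed(seed, {
    u <- stats::runif(nrow(world$pairs))
    ifelse(world$coupled, u <= recall, u <= fpr)
  })
  gold_standard(world$pairs[keep, c("proteinA", "proteinB")], name = name)
}

#' Generate a synthetic ortholog map between two planted worlds
#'
#' Walks through the proteins of `worldB` and assigns each one either a
#' single ortholog from `worldA` (1:1) or, with probability
#' `one_to_many_rate`, a co-ortholog group of `many_size` `worldA` proteins
#' mapping to the same `worldB` protein, until either proteome is exhausted.
#'
#' @param worldA,worldB Source and target worlds.
#' @param one_to_many_rate Probability that a target protein receives a
#'   many-to-one co-ortholog group.
#' @param seed Integer seed.
#' @param many_size Number of source co-orthologs in a many-to-one group.
#' @return An `ortholog_map` (see [ortholog_map()]).
#' @export
generate_ortholog_map <- function(worldA, worldB, one_to_many_rate = 0,
                                  seed = 1L, many_size = 3L) {
  stopifnot(inherits(worldA, "planted_world"),
            inherits(worldB, "planted_world"))
  stopifnot_scalar_fraction(one_to_many_rate, "one_to_many_rate",
                            open_lower = FALSE, open_upper = FALSE)
  srcs <- worldA$proteins
  tgts <- worldB$proteins
  res <- with_seed(seed, {
    rows <- list()
    i <- 1L
    g <- 0L
    for (t in tgts) {
      if (i > length(srcs)) break
      g <- g + 1L
      k <- if (stats::runif(1) <= one_to_many_rate) many_size else 1L
      k <- min(k, length(srcs) - i + 1L)
      rows[[g]] <- data.frame(source = srcs[i:(i + k - 1L)], target = t,
                              group = sprintf("g%04d", g),
                              stringsAsFactors = FALSE)
      i <- i + k
    }
    do.call(rbind, rows)
  })
  ortholog_map(res, species_pair = c("speciesA", "speciesB"))
}
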