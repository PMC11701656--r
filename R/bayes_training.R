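# Bin-free naive Bayesian core: Gaussian-kernel likelihoods with Silverman
# bandwidth, polynomial log-likelihood-ratio curves with fit-acceptance
# criteria, sequential redundancy weighting across datasets, and the final
# Bayesian score (FBS).

#' Fit a Gaussian kernel density estimate
#'
#' Bandwidth follows Silverman's rule of thumb,
#' `h = 0.9 * min(sd, IQR/1.34) * n^(-1/5)`.
#'
#' @param scores Numeric sample with at least two distinct finite values.
#' @return Object of class `kde_density` (evaluate with [kde_eval()] or
#'   `predict()`).
#' @export
fit_kde_likelihood <- function(scores) {
  x <- as.numeric(scores)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2L || length(unique(x)) < 2L) {
    stop("kernel density needs >= 2 distinct values (zero bandwidth)")
  }
  spread <- min(stats::sd(x), stats::IQR(x) / 1.34)
  if (spread == 0) spread <- stats::sd(x)
  h <- 0.9 * spread * n^(-1 / 5)
  structure(list(x = x, bw = h, n = n), class = "kde_density")
}

#' Evaluate a fitted kernel density
#' @param kde A `kde_density` object.
#' @param at Numeric vector of evaluation points.
#' @return Density values (integrate to 1 over the real line).
#' @export
kde_eval <- function(kde, at) {
  stopifnot(inherits(kde, "kde_density"))
  vapply(at, function(x0) mean(stats::dnorm(x0, kde$x, kde$bw)), numeric(1))
}

#' @export
predict.kde_density <- function(object, newdata, ...) kde_eval(object, newdata)

#' @export
print.kde_density <- function(x, ...) {
  cat(sprintf("kde_density: n = %d, bandwidth = %.4g\n", x$n, x$bw))
  invisible(x)
}

llr_rejection <- function(reason, detail = NULL) {
  structure(list(reason = reason, detail = detail), class = "llr_rejection")
}

#' Was a training step rejected?
#' @param x Result of [estimate_llr_curve()] or [fit_ppv_logistic()].
#' @return TRUE for a rejection object.
#' @export
is_rejection <- function(x) {
  inherits(x, "llr_rejection") || inherits(x, "ppv_rejection")
}

#' @export
print.llr_rejection <- function(x, ...) {
  cat("training rejected:", x$reason,
      if (!is.null(x$detail)) paste0("(", x$detail, ")"), "\n")
  invisible(x)
}

#' Estimate a polynomial log-likelihood-ratio curve
#'
#' Computes the pointwise log-likelihood ratio
#' `LLR(x) = ln( f_pos(x) / f_neg(x) )` between Gaussian-kernel density
#' estimates of the positive (gold-standard) and negative (unknown) score
#' populations, on an even grid over the common score range truncated at
#' the `max_percentile`-th percentile of the pooled scores, and summarizes
#' it as the lowest-degree polynomial in degrees 2-4 reaching
#' `R^2 >= min_r2`. Training is rejected when the positive sample size is
#' outside `[min_n, max_n]` ("lack of data") or no admissible degree fits
#' ("poor fit").
#'
#' @param pos_scores Raw scores of gold-standard (known coupling) pairs.
#' @param neg_scores Raw scores of unknown pairs.
#' @param max_percentile Upper truncation percentile of pooled scores
#'   (default 98).
#' @param min_n,max_n Admissible positive sample size range (defaults 1e3,
#'   1e6).
#' @param min_r2 Minimum R^2 of the polynomial fit (default 0.9).
#' @param degrees Candidate polynomial degrees (default 2:4, lowest
#'   sufficient degree wins).
#' @param grid_n Number of grid points (default 512).
#' @param evidence_type,dataset_id,gold_standard Labels stored in the model.
#' @return An object of class `llr_model` (fields `coefficients` beta0..4,
#'   `degree`, `valid_range`, `r2`, `n_pos`, `n_neg`) or a rejection object
#'   (see [is_rejection()]).
#' @export
estimate_llr_curve <- function(pos_scores, neg_scores, max_percentile = 98,
                               min_n = 1e3, max_n = 1e6, min_r2 = 0.9,
                               degrees = 2:4, grid_n = 512,
                               evidence_type = "NA", dataset_id = "ds1",
                               gold_standard = "GS") {
  pos <- pos_scores[is.finite(pos_scores)]
  neg <- neg_scores[is.finite(neg_scores)]
  if (!length(pos) || !length(neg)) {
    return(llr_rejection("lack of data", "empty positive or negative set"))
  }
  if (length(pos) < min_n || length(pos) > max_n) {
    return(llr_rejection("lack of data",
                         sprintf("n_pos = %d outside [%g, %g]",
                                 length(pos), min_n, max_n)))
  }
  lo <- max(min(pos), min(neg))
  hi <- min(max(pos), max(neg),
            stats::quantile(c(pos, neg), max_percentile / 100, names = FALSE))
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi) {
    return(llr_rejection("lack of data", "no common score range"))
  }
  kpos <- fit_kde_likelihood(pos)
  kneg <- fit_kde_likelihood(neg)
  grid <- seq(lo, hi, length.out = grid_n)
  fp <- pmax(kde_eval(kpos, grid), .Machine$double.xmin)
  fn <- pmax(kde_eval(kneg, grid), .Machine$double.xmin)
  llr <- log(fp / fn)
  ss_tot <- sum((llr - mean(llr))^2)
  for (deg in sort(degrees)) {
    fit <- stats::lm(llr ~ stats::poly(grid, degree = deg, raw = TRUE))
    r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
    if (r2 >= min_r2) {
      beta <- rep(0, 5)
      beta[seq_len(deg + 1L)] <- unname(stats::coef(fit))
      beta[is.na(beta)] <- 0
      return(structure(list(
        evidence_type = evidence_type, dataset_id = dataset_id,
        gold_standard = gold_standard, coefficients = beta, degree = deg,
        valid_range = c(lo, hi), r2 = r2,
        n_pos = length(pos), n_neg = length(neg)
      ), class = "llr_model"))
    }
  }
  llr_rejection("poor fit",
                sprintf("no degree in {%s} reached R^2 >= %g",
                        paste(degrees, collapse = ","), min_r2))
}

#' @export
print.llr_model <- function(x, ...) {
  cat(sprintf(
    "llr_model %s/%s vs %s: degree %d, R^2 = %.3f, range [%.3g, %.3g], n = %d/%d\n",
    x$evidence_type, x$dataset_id, x$gold_standard, x$degree, x$r2,
    x$valid_range[1], x$valid_range[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' Evaluate a polynomial LLR model
#'
#' The polynomial is evaluated at the raw score clamped to the model's
#' valid range, so extrapolation beyond the trained score range returns
#' the boundary value.
#'
#' @param model An `llr_model`.
#' @param x Raw score(s).
#' @return LLR value(s).
#' @export
evaluate_llr <- function(model, x) {
  stopifnot(inherits(model, "llr_model"))
  xc <- pmin(pmax(x, model$valid_range[1L]), model$valid_range[2L])
  b <- model$coefficients
  b[1L] + xc * (b[2L] + xc * (b[3L] + xc * (b[4L] + xc * b[5L])))
}

#' Serialize / load trained LLR models
#' @param models List of `llr_model` objects.
#' @param path JSON sidecar path.
#' @export
write_llr_models <- function(models, path) {
  payload <- lapply(models, function(m) unclass(m))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_llr_models
#' @export
read_llr_models <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  lapply(payload, function(m) {
    m$coefficients <- as.numeric(m$coefficients)
    m$valid_range <- as.numeric(m$valid_range)
    structure(m, class = "llr_model")
  })
}

#' Redundancy-weighted combination of per-dataset LLRs
#'
#' For one gene pair scored by several datasets of the same evidence type,
#' the LLRs are ranked decreasingly; the first keeps weight 1, and each
#' subsequent dataset k is down-weighted sequentially by
#' `w_k = alpha * (1 - max(0, r)) * w_(k-1)`, where `r` is the Spearman
#' correlation between dataset k and its predecessor in the ranking
#' (`predecessor = "previous"`, default) or the most correlated
#' higher-ranked dataset (`predecessor = "max"`). The combined LLR is
#' `sum_k w_k * LLR_k`.
#'
#' @param dataset_llrs Named numeric vector (dataset id -> LLR for this
#'   pair).
#' @param dataset_correlations Square matrix of between-dataset Spearman
#'   correlations with dataset ids as dimnames; missing entries count as 0
#'   (no redundancy evidence).
#' @param alpha Noise attenuation factor (default 0.7).
#' @param predecessor `"previous"` or `"max"`.
#' @return Combined LLR (single number).
#' @export
redundancy_weighted_llr <- function(dataset_llrs, dataset_correlations = NULL,
                                    alpha = 0.7,
                                    predecessor = c("previous", "max")) {
  predecessor <- match.arg(predecessor)
  k <- length(dataset_llrs)
  if (k == 0L) return(0)
  ord <- order(dataset_llrs, decreasing = TRUE)
  llrs <- dataset_llrs[ord]
  ids <- names(llrs) %||% as.character(seq_len(k))
  get_r <- function(i, j) {
    if (is.null(dataset_correlations)) return(0)
    if (!all(c(ids[i], ids[j]) %in% rownames(dataset_correlations))) {
      return(0)
    }
    r <- dataset_correlations[ids[i], ids[j]]
    if (is.na(r)) 0 else r
  }
  w <- numeric(k)
  w[1L] <- 1
  if (k > 1L) {
    for (j in 2:k) {
      r <- if (predecessor == "previous") {
        get_r(j, j - 1L)
      } else {
        max(vapply(seq_len(j - 1L), function(i) get_r(j, i), numeric(1)))
      }
      w[j] <- alpha * (1 - max(0, r)) * w[j - 1L]
    }
  }
  sum(w * llrs)
}

#' Spearman correlations between datasets' per-pair LLRs
#'
#' Computed on pairs scored in both datasets; dataset pairs sharing fewer
#' than `min_shared` scored pairs get correlation 0 (no redundancy
#' evidence).
#'
#' @param llr_tables Named list of data.frames `proteinA`, `proteinB`,
#'   `llr`, one per dataset.
#' @param min_shared Minimum shared pairs (default 10).
#' @return Symmetric correlation matrix with dataset names as dimnames.
#' @export
dataset_llr_correlations <- function(llr_tables, min_shared = 10) {
  ids <- names(llr_tables)
  k <- length(ids)
  m <- diag(1, k)
  dimnames(m) <- list(ids, ids)
  if (k < 2L) return(m)
  keyed <- lapply(llr_tables, function(d) {
    stats::setNames(d$llr, pair_key(d$proteinA, d$proteinB))
  })
  for (i in 1:(k - 1L)) {
    for (j in (i + 1L):k) {
      shared <- intersect(names(keyed[[i]]), names(keyed[[j]]))
      r <- if (length(shared) < min_shared) 0 else
        stats::cor(keyed[[i]][shared], keyed[[j]][shared],
                   method = "spearman")
      m[i, j] <- m[j, i] <- r
    }
  }
  m
}

#' Final Bayesian score of one pair
#'
#' Under the naive (conditional independence) assumption the final
#' Bayesian score is the plain sum of the per-evidence-type (and
#' per-source-species) redundancy-weighted LLRs.
#'
#' @param per_type_llrs Numeric vector of LLR contributions.
#' @return Their sum; `NA_real_` for an empty vector (pair absent).
#' @export
compute_fbs <- function(per_type_llrs) {
  v <- unlist(per_type_llrs, use.names = FALSE)
  v <- v[!is.na(v)]
  if (!length(v)) return(NA_real_)
  sum(v)
}

#' Per-pair LLR table for one dataset
#'
#' Applies a fitted LLR model to every scored pair of an evidence table.
#'
#' @param table An [evidence_table()].
#' @param model The dataset's `llr_model`.
#' @return data.frame `proteinA`, `proteinB`, `llr`.
#' @export
evidence_llr_table <- function(table, model) {
  data.frame(proteinA = table$proteinA, proteinB = table$proteinB,
             llr = evaluate_llr(model, table$score),
             stringsAsFactors = FALSE)
}

#' Combine several datasets' LLR tables into one evidence-type LLR table
#'
#' Applies the sequential redundancy weighting per pair across all
#' datasets that scored it.
#'
#' @param llr_tables Named list of data.frames `proteinA`, `proteinB`,
#'   `llr` (one per dataset).
#' @param dataset_correlations Matrix from [dataset_llr_correlations()];
#'   computed on the fly when NULL.
#' @param alpha Redundancy attenuation factor (default 0.7).
#' @return data.frame `proteinA`, `proteinB`, `llr`.
#' @export
combine_dataset_llrs <- function(llr_tables, dataset_correlations = NULL,
                                 alpha = 0.7) {
  if (!length(llr_tables)) {
    return(data.frame(proteinA = character(), proteinB = character(),
                      llr = numeric(), stringsAsFactors = FALSE))
  }
  if (is.null(names(llr_tables))) {
    names(llr_tables) <- paste0("ds", seq_along(llr_tables))
  }
  if (is.null(dataset_correlations)) {
    dataset_correlations <- dataset_llr_correlations(llr_tables)
  }
  long <- do.call(rbind, lapply(names(llr_tables), function(id) {
    d <- llr_tables[[id]]
    data.frame(key = pair_key(d$proteinA, d$proteinB), dataset = id,
               llr = d$llr, stringsAsFactors = FALSE)
  }))
  combined <- tapply(seq_len(nrow(long)), long$key, function(rows) {
    redundancy_weighted_llr(
      stats::setNames(long$llr[rows], long$dataset[rows]),
      dataset_correlations, alpha = alpha)
  })
  parts <- strsplit(names(combined), "|", fixed = TRUE)
  data.frame(
    proteinA = vapply(parts, `[`, character(1), 1L),
    proteinB = vapply(parts, `[`, character(1), 2L),
    llr = as.numeric(combined), stringsAsFactors = FALSE)
}

#' Final Bayesian score table across evidence types
#'
#' Sums the per-evidence-type LLR contributions per pair (the naive Bayes
#' integration step) and retains the per-type breakdown, whose row sums
#' reproduce the FBS exactly.
#'
#' @param type_llr_tables Named list (evidence type, or evidence type x
#'   source species, -> data.frame `proteinA`, `proteinB`, `llr`).
#' @param gold_standard Gold standard label stored on the table.
#' @return data.frame `proteinA`, `proteinB`, `fbs`, plus one `llr_<type>`
#'   column per contribution (NA where the pair is not scored by that
#'   type), with attribute `gold_standard`.
#' @export
compute_fbs_table <- function(type_llr_tables, gold_standard = "GS") {
  stopifnot(length(type_llr_tables) > 0, !is.null(names(type_llr_tables)))
  keyed <- lapply(type_llr_tables, function(d) {
    stats::setNames(d$llr, pair_key(d$proteinA, d$proteinB))
  })
  all_keys <- unique(unlist(lapply(keyed, names)))
  contrib <- vapply(keyed, function(v) unname(v[all_keys]),
                    numeric(length(all_keys)))
  contrib <- matrix(contrib, nrow = length(all_keys),
                    dimnames = list(NULL, names(keyed)))
  fbs <- rowSums(contrib, na.rm = TRUE)
  parts <- strsplit(all_keys, "|", fixed = TRUE)
  out <- data.frame(
    proteinA = vapply(parts, `[`, character(1), 1L),
    proteinB = vapply(parts, `[`, character(1), 2L),
    fbs = fbs, stringsAsFactors = FALSE)
  for (nm in colnames(contrib)) out[[paste0("llr_", nm)]] <- contrib[, nm]
  attr(out, "gold_standard") <- gold_standard
  out
}
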