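# End-to-end synthetic pipeline: world -> evidence -> gold standard ->
# LLR training -> FBS -> PPV calibration -> assembled network, with the
# planted truth retained so calibration and recovery can be evaluated.

#' Run the full inference pipeline on a synthetic world
#'
#' Generates a planted world, draws Gaussian evidence for one or more
#' datasets, builds an (optionally imperfect) gold standard, trains the
#' bin-free LLR models using gold-standard pairs as positives and all
#' other scored pairs as negatives, integrates the datasets with
#' sequential redundancy weighting into a final Bayesian score per pair,
#' calibrates FBS to PPV with resampled negatives and a logistic fit, and
#' assembles the final network.
#'
#' @param n_proteins Number of proteins (142 gives 10011 pairs).
#' @param coupling_fraction Planted coupling fraction.
#' @param n_datasets Number of independent evidence datasets.
#' @param pos_model,neg_model Score distributions for coupled/uncoupled
#'   pairs (shared by all datasets).
#' @param coverage Per-dataset assay coverage.
#' @param gs_recall,gs_fpr Gold standard recall and false positive rate
#'   relative to the planted truth.
#' @param gs_name Gold standard label.
#' @param alpha Redundancy attenuation factor.
#' @param min_n Minimum positive training size passed to the LLR fit.
#' @param n_resamples,n_thresholds PPV curve settings.
#' @param cutoff Final network confidence cutoff.
#' @param seed Master seed; all stages derive their seeds from it.
#' @return List with `world`, `gs`, `models` (per dataset), `fbs_table`,
#'   `ppv_model`, `network`, and `pairs`: a data.frame of every scored
#'   pair with `fbs`, fitted `ppv` and the planted `true` flag.
#' @export
run_synthetic_pipeline <- function(n_proteins = 142,
                                   coupling_fraction = 0.5,
                                   n_datasets = 1,
                                   pos_model = gaussian_spec(1, 1),
                                   neg_model = gaussian_spec(0, 1),
                                   coverage = 1,
                                   gs_recall = 1, gs_fpr = 0,
                                   gs_name = "Complex",
                                   alpha = 0.7, min_n = 1e3,
                                   n_resamples = 30, n_thresholds = 1000,
                                   cutoff = 0.85, seed = 1L) {
  world <- generate_world(n_proteins, coupling_fraction, seed = seed)
  gs <- generate_gold_standard(world, recall = gs_recall, fpr = gs_fpr,
                               name = gs_name, seed = seed + 1L)
  gs_set <- gs_keys(gs)

  tables <- lapply(seq_len(n_datasets), function(i) {
    generate_evidence(world, pos_model = pos_model, neg_model = neg_model,
                      coverage = coverage,
                      dataset_id = sprintf("mex%02d", i),
                      evidence_type = "MEX")
  })
  names(tables) <- vapply(tables, attr, character(1), "dataset_id")

  models <- list()
  llr_tables <- list()
  for (id in names(tables)) {
    tab <- tables[[id]]
    in_gs <- pair_key(tab$proteinA, tab$proteinB) %in% gs_set
    model <- estimate_llr_curve(tab$score[in_gs], tab$score[!in_gs],
                                min_n = min_n, evidence_type = "MEX",
                                dataset_id = id, gold_standard = gs_name)
    if (is_rejection(model)) {
      stop("LLR training rejected for dataset ", id, ": ", model$reason)
    }
    models[[id]] <- model
    llr_tables[[id]] <- evidence_llr_table(tab, model)
  }

  combined <- combine_dataset_llrs(llr_tables, alpha = alpha)
  fbs_table <- compute_fbs_table(list(MEX = combined),
                                 gold_standard = gs_name)

  keys <- pair_key(fbs_table$proteinA, fbs_table$proteinB)
  in_gs <- keys %in% gs_set
  fbs_pos <- fbs_table$fbs[in_gs]
  fbs_neg_pool <- fbs_table$fbs[!in_gs]
  sampler_seed <- seed + 1000L
  draw <- local({
    counter <- 0L
    function(n) {
      counter <<- counter + 1L
      with_seed(sampler_seed + counter,
                sample(fbs_neg_pool, n, replace = n > length(fbs_neg_pool)))
    }
  })
  curve <- ppv_curve(fbs_pos, draw, n_resamples = n_resamples,
                     n_thresholds = n_thresholds)
  ppv_model <- fit_ppv_logistic(curve, gold_standard = gs_name)
  if (is_rejection(ppv_model)) {
    stop("PPV calibration rejected: ", ppv_model$reason)
  }

  membership <- cbind(gs$links, gold_standard = gs_name)
  network <- assemble_network(
    fbs_tables = stats::setNames(list(fbs_table), gs_name),
    ppv_models = stats::setNames(list(ppv_model), gs_name),
    gs_membership = membership, cutoff = cutoff)

  pairs <- data.frame(
    proteinA = fbs_table$proteinA, proteinB = fbs_table$proteinB,
    fbs = fbs_table$fbs,
    ppv = predict_ppv(ppv_model, fbs_table$fbs),
    in_gs = in_gs,
    true = keys %in% world$true_couplings,
    stringsAsFactors = FALSE)

  list(world = world, gs = gs, models = models, fbs_table = fbs_table,
       ppv_curve = curve, ppv_model = ppv_model, network = network,
       pairs = pairs)
}

#' Calibration of fitted confidences against the planted truth
#'
#' Bins pairs by their fitted PPV and compares the empirical fraction of
#' planted true couplings per bin with the bin midpoint.
#'
#' @param pairs The `pairs` data.frame of [run_synthetic_pipeline()].
#' @param breaks Bin boundaries on the fitted PPV (default 0.85 to 1 in
#'   steps of 0.05; the last bin is closed).
#' @param min_bin_n Bins with fewer pairs are reported but flagged
#'   unreliable (default 30).
#' @return data.frame `bin_lo`, `bin_hi`, `midpoint`, `n`, `precision`,
#'   `deviation`, `reliable`.
#' @export
calibration_bins <- function(pairs, breaks = seq(0.85, 1, by = 0.05),
                             min_bin_n = 30) {
  out <- data.frame()
  for (i in seq_len(length(breaks) - 1L)) {
    lo <- breaks[i]
    hi <- breaks[i + 1L]
    sel <- pairs$ppv >= lo &
      (if (i == length(breaks) - 1L) pairs$ppv <= hi else pairs$ppv < hi)
    n <- sum(sel)
    prec <- if (n) mean(pairs$true[sel]) else NA_real_
    mid <- (lo + hi) / 2
    out <- rbind(out, data.frame(
      bin_lo = lo, bin_hi = hi, midpoint = mid, n = n, precision = prec,
      deviation = prec - mid, reliable = n >= min_bin_n))
  }
  out
}
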