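# FBS -> PPV calibration: empirical PPV curves over resampled negatives,
# logistic fitting, the gold-standard-count PPV floor (gsPPV), and final
# network assembly with directed links from positive gene-regulation LLRs.

#' Empirical PPV versus FBS curve
#'
#' For equal numbers of gold-standard positives and sampled negatives, the
#' positive predictive value at a threshold is `TP / (TP + FP)` among
#' examples with `FBS >= threshold`; at a threshold below all examples
#' `TP = FP` and the PPV is 0.5. Negatives are resampled `n_resamples`
#' times and the PPV is averaged per threshold over a grid of
#' `n_thresholds` evenly spaced FBS values; thresholds with no examples
#' above them in any resample are omitted.
#'
#' @param fbs_pos FBS values of gold-standard links.
#' @param fbs_neg_sampler Function `(n) -> numeric(n)` drawing negative
#'   examples (non-gold-standard scored pairs); seed it outside.
#' @param n_resamples Number of negative resamples (default 30).
#' @param n_thresholds Number of threshold values (default 1000).
#' @return data.frame `threshold`, `ppv`.
#' @export
ppv_curve <- function(fbs_pos, fbs_neg_sampler, n_resamples = 30,
                      n_thresholds = 1000) {
  pos <- sort(fbs_pos[is.finite(fbs_pos)])
  if (!length(pos)) stop("no positive examples")
  if (!is.function(fbs_neg_sampler)) {
    stop("negative examples are required: `fbs_neg_sampler` must be a function")
  }
  negs <- lapply(seq_len(n_resamples), function(i) {
    v <- sort(fbs_neg_sampler(length(pos)))
    if (length(v) != length(pos)) {
      stop("sampler must return as many negatives as there are positives")
    }
    v
  })
  count_ge <- function(sorted, thr) {
    length(sorted) - findInterval(thr, sorted, left.open = TRUE)
  }
  thr <- seq(min(pos[1L], vapply(negs, `[`, numeric(1), 1L)),
             max(pos[length(pos)],
                 vapply(negs, function(v) v[length(v)], numeric(1))),
             length.out = n_thresholds)
  tp <- count_ge(pos, thr)
  ppv_mat <- vapply(negs, function(neg) {
    fp <- count_ge(neg, thr)
    ifelse(tp + fp == 0L, NA_real_, tp / (tp + fp))
  }, numeric(length(thr)))
  ppv_mat <- matrix(ppv_mat, nrow = length(thr))
  ppv <- rowMeans(ppv_mat, na.rm = TRUE)
  keep <- is.finite(ppv)
  data.frame(threshold = thr[keep], ppv = ppv[keep])
}

ppv_rejection <- function(reason, detail = NULL) {
  structure(list(reason = reason, detail = detail), class = "ppv_rejection")
}

#' @export
print.ppv_rejection <- function(x, ...) {
  cat("PPV calibration rejected:", x$reason,
      if (!is.null(x$detail)) paste0("(", x$detail, ")"), "\n")
  invisible(x)
}

#' Fit a logistic confidence curve to a PPV-versus-FBS relation
#'
#' Least-squares fit of `PPV(x) = a / (1 + exp(-b (x - c)))`, where `a` is
#' the asymptotic maximum (typically 1), `b` the steepness and `c` the
#' horizontal shift. The fit is rejected ("poor fitting") when it fails to
#' converge, is non-increasing (`b <= 0`), or has `R^2 < min_r2`. The
#' non-standard variant with denominator `1 - exp(-b (x - c))` is
#' available as `form = "printed"` for auditing only; it is singular at
#' `x = c` and is not a logistic curve.
#'
#' @param curve data.frame `threshold` (or `fbs`) and `ppv`, e.g. from
#'   [ppv_curve()]; at least 10 points.
#' @param min_r2 Acceptance threshold on R^2 (default 0.9).
#' @param gold_standard Label stored in the model.
#' @param form `"logistic"` (default) or `"printed"`.
#' @return Object of class `ppv_model` (fields `a`, `b`, `c`, `r2`) or a
#'   rejection object.
#' @export
fit_ppv_logistic <- function(curve, min_r2 = 0.9, gold_standard = "GS",
                             form = c("logistic", "printed")) {
  form <- match.arg(form)
  x <- curve$threshold %||% curve$fbs
  y <- curve$ppv
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 10L) {
    return(ppv_rejection("lack of data", "fewer than 10 curve points"))
  }
  fun <- if (form == "logistic") {
    function(x, a, b, c) a / (1 + exp(-b * (x - c)))
  } else {
    function(x, a, b, c) a / (1 - exp(-b * (x - c)))
  }
  start <- list(a = min(max(y), 1), b = 2 / max(stats::sd(x), 1e-8),
                c = x[which.min(abs(y - (min(y) + max(y)) / 2))])
  # a is the asymptotic maximum the curve approaches (typically 1); left
  # unbounded it can drift into a degenerate quasi-exponential regime
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ fun(x, a, b, c), start = start,
                      lower = c(a = 0.1, b = -Inf, c = -Inf),
                      upper = c(a = 1.05, b = Inf, c = Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(ppv_rejection("poor fitting", "optimizer failed to converge"))
  }
  p <- as.list(stats::coef(fit))
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else
    1 - sum((y - fun(x, p$a, p$b, p$c))^2) / ss_tot
  if (form == "logistic" && p$b <= 0) {
    return(ppv_rejection("poor fitting", "non-increasing fitted curve"))
  }
  if (r2 < min_r2) {
    return(ppv_rejection("poor fitting", sprintf("R^2 = %.3f < %g", r2,
                                                 min_r2)))
  }
  structure(list(a = p$a, b = p$b, c = p$c, r2 = r2, form = form,
                 gold_standard = gold_standard), class = "ppv_model")
}

#' @export
print.ppv_model <- function(x, ...) {
  cat(sprintf("ppv_model (%s, %s): a = %.3f, b = %.3f, c = %.3f, R^2 = %.3f\n",
              x$gold_standard, x$form, x$a, x$b, x$c, x$r2))
  invisible(x)
}

#' Predict the calibrated confidence for FBS values
#' @param model A `ppv_model`.
#' @param fbs FBS value(s).
#' @return PPV value(s) clamped to \[0, 1\].
#' @export
predict_ppv <- function(model, fbs) {
  stopifnot(inherits(model, "ppv_model"))
  v <- if (model$form == "logistic") {
    model$a / (1 + exp(-model$b * (fbs - model$c)))
  } else {
    model$a / (1 - exp(-model$b * (fbs - model$c)))
  }
  pmin(pmax(v, 0), 1)
}

#' Gold-standard-count PPV floor (gsPPV)
#'
#' Links present in curated gold standards receive a confidence floor
#' depending on how many gold standards support them: 0.85 for one, 0.90
#' for two, 0.95 for three and 1.0 for more than three.
#'
#' @param n_supporting_gs Non-negative integer count(s).
#' @return gsPPV value(s); `NA` for a count of 0 (no gsPPV).
#' @export
assign_gsppv <- function(n_supporting_gs) {
  n <- as.integer(n_supporting_gs)
  if (any(is.na(n)) || any(n < 0)) {
    stop("number of supporting gold standards must be a non-negative count")
  }
  ifelse(n == 0L, NA_real_,
         ifelse(n == 1L, 0.85,
                ifelse(n == 2L, 0.90,
                       ifelse(n == 3L, 0.95, 1.0))))
}

#' Assemble the final calibrated network
#'
#' Per pair, the evidence PPV is the maximum over gold standards of the
#' calibrated confidence of its FBS (the union of the gold-standard
#' networks with maximum PPV); a gsPPV floor from the count of supporting
#' gold standards is applied unless the evidence PPV already exceeds it.
#' Only links with final PPV >= `cutoff` are kept. A link is flagged
#' directed (TF -> target) when its gene-regulation LLR is positive.
#'
#' @param fbs_tables Named list (gold standard -> data.frame `proteinA`,
#'   `proteinB`, `fbs`), e.g. from [compute_fbs_table()].
#' @param ppv_models Named list (gold standard -> accepted `ppv_model`).
#'   Gold standards whose calibration was rejected must be omitted.
#' @param gs_membership data.frame `proteinA`, `proteinB`, `gold_standard`:
#'   one row per (pair, supporting gold standard).
#' @param grg_llrs Optional data.frame `tf`, `target`, `llr` of directed
#'   gene-regulation LLRs.
#' @param cutoff Final confidence cutoff (default 0.85).
#' @return A [network_table()] with `ppv`, winning `gold_standard`, `fbs`,
#'   `direction` and `ppv_source` (`"evidence"` or `"gold_standard"`).
#' @export
assemble_network <- function(fbs_tables, ppv_models, gs_membership = NULL,
                             grg_llrs = NULL, cutoff = 0.85) {
  stopifnot(length(fbs_tables) > 0, !is.null(names(fbs_tables)))
  usable <- intersect(names(fbs_tables), names(ppv_models))
  rows <- list()
  for (gs in usable) {
    if (is_rejection(ppv_models[[gs]])) next
    d <- fbs_tables[[gs]]
    rows[[gs]] <- data.frame(
      key = pair_key(d$proteinA, d$proteinB),
      gs = gs, fbs = d$fbs,
      ppv = predict_ppv(ppv_models[[gs]], d$fbs),
      stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, rows)
  if (is.null(long) || nrow(long) == 0L) {
    return(network_table(data.frame(proteinA = character(),
                                    proteinB = character(),
                                    ppv = numeric())))
  }
  ord <- order(long$key, -long$ppv)
  long <- long[ord, ][!duplicated(long$key[ord]), , drop = FALSE]

  gs_count <- integer(0)
  if (!is.null(gs_membership) && nrow(gs_membership)) {
    mk <- pair_key(gs_membership$proteinA, gs_membership$proteinB)
    gs_count <- table(mk[!duplicated(paste(mk, gs_membership$gold_standard))])
  }
  n_sup <- as.integer(gs_count[long$key])
  n_sup[is.na(n_sup)] <- 0L
  gsppv <- suppressWarnings(assign_gsppv(n_sup))
  use_gs <- !is.na(gsppv) & gsppv > long$ppv
  final_ppv <- ifelse(use_gs, gsppv, long$ppv)

  dir_flag <- rep("none", nrow(long))
  if (!is.null(grg_llrs) && nrow(grg_llrs)) {
    pos <- grg_llrs[grg_llrs$llr > 0, , drop = FALSE]
    if (nrow(pos)) {
      # strongest positive regulation decides the orientation
      pos <- pos[order(pair_key(pos$tf, pos$target), -pos$llr), ,
                 drop = FALSE]
      pk <- pair_key(pos$tf, pos$target)
      pos <- pos[!duplicated(pk), , drop = FALSE]
      pk <- pk[!duplicated(pk)]
      hit <- match(long$key, pk)
      has <- !is.na(hit)
      dir_flag[has] <- ifelse(
        pos$tf[hit[has]] <= pos$target[hit[has]], "AB", "BA")
    }
  }

  keep <- final_ppv >= cutoff
  parts <- strsplit(long$key[keep], "|", fixed = TRUE)
  network_table(data.frame(
    proteinA = vapply(parts, `[`, character(1), 1L),
    proteinB = vapply(parts, `[`, character(1), 2L),
    ppv = final_ppv[keep],
    direction = dir_flag[keep],
    gold_standard = long$gs[keep],
    fbs = long$fbs[keep],
    ppv_source = ifelse(use_gs[keep], "gold_standard", "evidence"),
    stringsAsFactors = FALSE))
}
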