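#' @keywords internal
"_PACKAGE"

# Canonical unordered pair key: smaller identifier first.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

# Directed pair key (orientation preserved).
dpair_key <- function(a, b) paste(a, b, sep = "|")

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Small deterministic hash of a string, for deriving per-dataset seeds.
string_seed <- function(x, base = 0L) {
  codes <- utf8ToInt(as.character(x))
  h <- 0
  for (cc in codes) h <- (h * 31 + cc) %% 1000003
  as.integer((as.numeric(base) * 7919 + h) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_fraction <- function(x, name, open_lower = TRUE,
                                      open_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single number", name), call. = FALSE)
  }
  lo_ok <- if (open_lower) x > 0 else x >= 0
  hi_ok <- if (open_upper) x < 1 else x <= 1
  if (!lo_ok || !hi_ok) {
    stop(sprintf("`%s` = %g is outside the allowed range", name, x),
         call. = FALSE)
  }
  invisible(x)
}

# Area under the ROC curve by the rank (Mann-Whitney) statistic,
# with average ranks for ties.
auroc <- function(scores_pos, scores_neg) {
  n1 <- length(scores_pos)
  n2 <- length(scores_neg)
  if (n1 == 0L || n2 == 0L) return(NA_real_)
  r <- rank(c(scores_pos, scores_neg))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}
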