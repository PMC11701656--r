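#' Evidence score table
#'
#' Container for raw association scores of one dataset of one evidence type:
#' one row per gene pair with a finite numeric score. Undirected evidence is
#' stored with the lexicographically smaller protein first; directed
#' evidence (gene regulation, TF -> target) preserves orientation.
#'
#' @param df data.frame with columns `proteinA`, `proteinB`, `score`.
#' @param evidence_type One of DOM, GIN, GRG, MEX, MIR, PEX, PHP, PIN, SCL,
#'   TFB (GRG is directed).
#' @param species Species label.
#' @param dataset_id Dataset label.
#' @param directed Logical; defaults to TRUE for GRG.
#' @return data.frame of class `evidence_table` with attributes
#'   `evidence_type`, `species`, `dataset_id`, `directed`.
#' @export
evidence_table <- function(df, evidence_type, species = "unknown",
                           dataset_id = "ds1",
                           directed = identical(evidence_type, "GRG")) {
  types <- c("DOM", "GIN", "GRG", "MEX", "MIR", "PEX", "PHP", "PIN",
             "SCL", "TFB")
  if (!evidence_type %in% types) {
    stop("unknown evidence type: ", evidence_type)
  }
  df <- as.data.frame(df)[, c("proteinA", "proteinB", "score")]
  if (nrow(df)) {
    if (!all(is.finite(df$score))) stop("evidence scores must be finite")
    if (any(df$proteinA == df$proteinB)) stop("self-pairs are not allowed")
    if (!directed) {
      a <- pmin(df$proteinA, df$proteinB)
      b <- pmax(df$proteinA, df$proteinB)
      df$proteinA <- a
      df$proteinB <- b
      key <- pair_key(a, b)
      if (anyDuplicated(key)) df <- df[!duplicated(key), , drop = FALSE]
    }
  }
  rownames(df) <- NULL
  structure(df, evidence_type = evidence_type, species = species,
            dataset_id = dataset_id, directed = isTRUE(directed),
            class = c("evidence_table", "data.frame"))
}

#' Gold standard link set
#'
#' A named set of (optionally directed) protein pairs used as positive
#' examples during likelihood training. Regulatory gold standards carry
#' TF -> target orientation; all others are undirected and deduplicated on
#' the unordered pair.
#'
#' @param links data.frame with columns `proteinA`, `proteinB`.
#' @param name Gold standard name, e.g. one of Complex, Metabolic,
#'   Signaling, Operon, PPI, Regulatory.
#' @param directed Logical; TRUE only for Regulatory-style sets.
#' @return list of class `gold_standard` with `name`, `links`, `directed`.
#' @export
gold_standard <- function(links, name, directed = FALSE) {
  links <- as.data.frame(links)
  if (nrow(links)) {
    links <- links[, c("proteinA", "proteinB")]
    links <- links[links$proteinA != links$proteinB, , drop = FALSE]
    if (!directed) {
      a <- pmin(links$proteinA, links$proteinB)
      b <- pmax(links$proteinA, links$proteinB)
      links$proteinA <- a
      links$proteinB <- b
    }
    links <- links[!duplicated(dpair_key(links$proteinA, links$proteinB)), ,
                   drop = FALSE]
    rownames(links) <- NULL
  } else {
    links <- data.frame(proteinA = character(), proteinB = character(),
                        stringsAsFactors = FALSE)
  }
  structure(list(name = name, links = links, directed = isTRUE(directed)),
            class = "gold_standard")
}

#' @export
print.gold_standard <- function(x, ...) {
  cat(sprintf("gold_standard '%s': %d %s links\n", x$name, nrow(x$links),
              if (x$directed) "directed" else "undirected"))
  invisible(x)
}

# Canonical keys of a gold standard's links (unordered unless directed).
gs_keys <- function(gs, undirected = !gs$directed) {
  if (nrow(gs$links) == 0L) return(character())
  if (undirected) {
    unique(pair_key(gs$links$proteinA, gs$links$proteinB))
  } else {
    dpair_key(gs$links$proteinA, gs$links$proteinB)
  }
}

#' Ortholog map between two species
#'
#' Pairs of orthologous proteins plus their co-ortholog group labels
#' (InParanoid-style: several proteins of one species can share a group
#' with one protein of the other).
#'
#' @param df data.frame with columns `source`, `target`, `group`.
#' @param species_pair Character vector of length 2 (source, target labels).
#' @return data.frame of class `ortholog_map`.
#' @export
ortholog_map <- function(df, species_pair = c("speciesA", "speciesB")) {
  df <- as.data.frame(df)
  if (nrow(df)) {
    df <- df[, c("source", "target", "group")]
    df <- df[!duplicated(df), , drop = FALSE]
    rownames(df) <- NULL
  } else {
    df <- data.frame(source = character(), target = character(),
                     group = character(), stringsAsFactors = FALSE)
  }
  structure(df, species_pair = species_pair,
            class = c("ortholog_map", "data.frame"))
}

#' Calibrated network table
#'
#' Final network container: one row per link with its calibrated confidence
#' (`ppv`), the winning gold standard, the final Bayesian score (`fbs`), the
#' direction flag (`"none"`, `"AB"` = proteinA -> proteinB, `"BA"`), and
#' whether the confidence came from evidence calibration or the
#' gold-standard-count floor.
#'
#' @param df data.frame with at least `proteinA`, `proteinB`, `ppv`;
#'   optional `direction`, `gold_standard`, `fbs`, `ppv_source`.
#' @param validate_cutoff If non-NULL, error when any `ppv` is below it
#'   (assembled final networks use 0.85).
#' @return data.frame of class `network_table`.
#' @export
network_table <- function(df, validate_cutoff = NULL) {
  df <- as.data.frame(df)
  defaults <- list(direction = "none", gold_standard = NA_character_,
                   fbs = NA_real_, ppv_source = "evidence")
  for (nm in names(defaults)) {
    if (is.null(df[[nm]])) df[[nm]] <- rep(defaults[[nm]], nrow(df))
  }
  df <- df[, c("proteinA", "proteinB", "ppv", "direction", "gold_standard",
               "fbs", "ppv_source")]
  if (nrow(df)) {
    if (any(!is.finite(df$ppv)) || any(df$ppv < 0) || any(df$ppv > 1)) {
      stop("ppv values must lie in [0, 1]")
    }
    if (!is.null(validate_cutoff) && any(df$ppv < validate_cutoff)) {
      stop("network contains links below the ppv cutoff ", validate_cutoff)
    }
    if (!all(df$direction %in% c("none", "AB", "BA"))) {
      stop("direction must be one of 'none', 'AB', 'BA'")
    }
    # canonical order for undirected links; directed rows keep orientation
    # in the direction flag, so the pair itself can still be canonicalized
    flip <- df$proteinA > df$proteinB
    if (any(flip)) {
      tmp <- df$proteinA[flip]
      df$proteinA[flip] <- df$proteinB[flip]
      df$proteinB[flip] <- tmp
      df$direction[flip] <- c(none = "none", AB = "BA", BA = "AB")[
        df$direction[flip]]
    }
    key <- pair_key(df$proteinA, df$proteinB)
    if (anyDuplicated(key)) {
      stop("duplicate unordered pairs in network table")
    }
    rownames(df) <- NULL
  }
  structure(df, class = c("network_table", "data.frame"))
}

net_nodes <- function(net) sort(unique(c(net$proteinA, net$proteinB)))

net_keys <- function(net) pair_key(net$proteinA, net$proteinB)

# Long (both directions) edge list for neighborhood lookups.
net_edges <- function(net, cutoff = 0) {
  keep <- net$ppv >= cutoff
  data.frame(
    from = c(net$proteinA[keep], net$proteinB[keep]),
    to = c(net$proteinB[keep], net$proteinA[keep]),
    ppv = c(net$ppv[keep], net$ppv[keep]),
    stringsAsFactors = FALSE
  )
}
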