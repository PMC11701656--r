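# File formats: ENCODE narrowPeak, project TSV dialects for evidence
# tables, gold standards, ortholog maps and networks, plus a YAML pipeline
# config. All genomic coordinates are 0-based half-open internally.

#' Read an ENCODE narrowPeak (BED6+4) file
#'
#' @param path Path to a 10-column tab-separated narrowPeak file.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, `signalValue`, `pValue`, `qValue`, `peak`. Coordinates are
#'   kept 0-based half-open; `pValue`/`qValue` are -log10 values or -1;
#'   `peak` is the summit offset or -1. Strand `"."` means unstranded.
#' @export
read_narrowpeak <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  cols <- c("chrom", "start", "end", "name", "score", "strand",
            "signalValue", "pValue", "qValue", "peak")
  if (length(lines) == 0L) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(), score = integer(),
                      strand = character(), signalValue = numeric(),
                      pValue = numeric(), qValue = numeric(),
                      peak = integer(), stringsAsFactors = FALSE)
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != 10L)
  if (length(bad)) {
    stop(sprintf("narrowPeak format error at line %d: expected 10 columns, found %d",
                 bad[1L], nf[bad[1L]]))
  }
  m <- do.call(rbind, parts)
  out <- data.frame(
    chrom = m[, 1L],
    start = as.integer(m[, 2L]),
    end = as.integer(m[, 3L]),
    name = m[, 4L],
    score = as.integer(m[, 5L]),
    strand = m[, 6L],
    signalValue = as.numeric(m[, 7L]),
    pValue = as.numeric(m[, 8L]),
    qValue = as.numeric(m[, 9L]),
    peak = as.integer(m[, 10L]),
    stringsAsFactors = FALSE
  )
  bad <- which(!is.finite(out$start) | !is.finite(out$end) |
                 out$start >= out$end)
  if (length(bad)) {
    stop(sprintf("narrowPeak format error at line %d: start must be < end",
                 bad[1L]))
  }
  if (any(out$signalValue < 0)) {
    stop("narrowPeak signalValue must be >= 0")
  }
  out
}

#' Write records in narrowPeak format
#' @param x data.frame as returned by [read_narrowpeak()].
#' @param path Output path.
#' @export
write_narrowpeak <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

# key=value comment header helpers for the project TSV dialect -------------

read_tsv_with_meta <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) {
      meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
    }
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (length(body) <= 1L) {
    header <- if (length(body)) strsplit(body[1L], "\t")[[1L]] else character()
    df <- as.data.frame(matrix(character(), 0, length(header),
                               dimnames = list(NULL, header)),
                        stringsAsFactors = FALSE)
    return(list(meta = meta, df = df))
  }
  df <- utils::read.table(text = body, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  list(meta = meta, df = df)
}

write_tsv_with_meta <- function(df, meta, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta)) {
    writeLines(sprintf("#%s=%s", nm, meta[[nm]]), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read an InParanoid-style ortholog table
#'
#' Expects a tab-separated file with a header and columns `source`,
#' `target`, `group` (source-species protein, target-species protein,
#' co-ortholog group id). Duplicate rows are silently deduplicated.
#'
#' @param path Input path.
#' @return An [ortholog_map()].
#' @export
read_ortholog_table <- function(path) {
  parsed <- read_tsv_with_meta(path)
  df <- parsed$df
  need <- c("source", "target", "group")
  if (nrow(df) == 0L && ncol(df) == 0L) {
    return(ortholog_map(data.frame(source = character(),
                                   target = character(),
                                   group = character())))
  }
  if (!all(need %in% names(df))) {
    stop("ortholog table format error: need columns source, target, group")
  }
  sp <- strsplit(parsed$meta[["species_pair"]] %||% "speciesA,speciesB",
                 ",")[[1L]]
  ortholog_map(df[, need], species_pair = sp)
}

#' @rdname read_ortholog_table
#' @param x An [ortholog_map()].
#' @export
write_ortholog_table <- function(x, path) {
  sp <- attr(x, "species_pair") %||% c("speciesA", "speciesB")
  write_tsv_with_meta(as.data.frame(x),
                      list(species_pair = paste(sp, collapse = ",")), path)
}

#' Read/write evidence score tables
#'
#' Project TSV dialect: `#key=value` comment header carrying
#' `evidence_type`, `species`, `dataset_id`, `directed`, then a tab-separated
#' body `proteinA`, `proteinB`, `score`.
#'
#' @param path File path.
#' @return [read_evidence_table()] returns an [evidence_table()].
#' @export
read_evidence_table <- function(path) {
  parsed <- read_tsv_with_meta(path)
  df <- parsed$df
  if (nrow(df) == 0L) {
    df <- data.frame(proteinA = character(), proteinB = character(),
                     score = numeric(), stringsAsFactors = FALSE)
  }
  evidence_table(df,
                 evidence_type = parsed$meta[["evidence_type"]] %||% "MEX",
                 species = parsed$meta[["species"]] %||% "unknown",
                 dataset_id = parsed$meta[["dataset_id"]] %||% "ds1",
                 directed = identical(parsed$meta[["directed"]], "TRUE"))
}

#' @rdname read_evidence_table
#' @param x An [evidence_table()].
#' @export
write_evidence_table <- function(x, path) {
  write_tsv_with_meta(
    as.data.frame(x),
    list(evidence_type = attr(x, "evidence_type"),
         species = attr(x, "species"),
         dataset_id = attr(x, "dataset_id"),
         directed = as.character(attr(x, "directed"))),
    path)
}

#' Read/write gold standard link sets
#' @param path File path.
#' @return [read_gold_standard()] returns a [gold_standard()].
#' @export
read_gold_standard <- function(path) {
  parsed <- read_tsv_with_meta(path)
  df <- parsed$df
  if (nrow(df) == 0L) {
    df <- data.frame(proteinA = character(), proteinB = character(),
                     stringsAsFactors = FALSE)
  }
  gold_standard(df, name = parsed$meta[["name"]] %||% "GS",
                directed = identical(parsed$meta[["directed"]], "TRUE"))
}

#' @rdname read_gold_standard
#' @param x A [gold_standard()].
#' @export
write_gold_standard <- function(x, path) {
  write_tsv_with_meta(x$links,
                      list(name = x$name,
                           directed = as.character(x$directed)),
                      path)
}

#' Read/write calibrated network tables
#'
#' Tab-separated with header; undirected pairs are stored with the
#' lexicographically smaller protein first, direction is a per-row flag
#' (`none`/`AB`/`BA`). Reading validates that all PPVs lie in \[0, 1\].
#'
#' @param path File path.
#' @return [read_network()] returns a [network_table()].
#' @export
read_network <- function(path) {
  parsed <- read_tsv_with_meta(path)
  df <- parsed$df
  if (nrow(df) == 0L) {
    df <- data.frame(proteinA = character(), proteinB = character(),
                     ppv = numeric(), stringsAsFactors = FALSE)
  }
  if (any(df$ppv < 0 | df$ppv > 1)) {
    stop("network validation error: ppv outside [0, 1]")
  }
  network_table(df)
}

#' @rdname read_network
#' @param x A [network_table()].
#' @export
write_network <- function(x, path) {
  write_tsv_with_meta(as.data.frame(x), list(format = "coupnet-network-v1"),
                      path)
}

#' Read a YAML pipeline configuration
#'
#' Fills in the documented training/calibration defaults for keys missing
#' from the file: `alpha` 0.7, `min_r2` 0.9, `percentile` 98, `min_n` 1e3,
#' `max_n` 1e6, `grid_size` 512, `n_resamples` 30, `n_thresholds` 1000,
#' `ppv_cutoff` 0.85, `seed` 1.
#'
#' @param path YAML file, or NULL for pure defaults.
#' @return Named list of configuration values.
#' @export
read_pipeline_config <- function(path = NULL) {
  defaults <- list(alpha = 0.7, min_r2 = 0.9, percentile = 98,
                   min_n = 1000, max_n = 1e6, grid_size = 512,
                   n_resamples = 30, n_thresholds = 1000,
                   ppv_cutoff = 0.85, seed = 1)
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  utils::modifyList(defaults, user)
}
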