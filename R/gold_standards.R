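# Construction of the six gold-standard link sets from raw membership and
# experiment records: Complex, Metabolic, Signaling (pathway cliques),
# Operon, PPI (publication-supported physical interactions) and Regulatory
# (directed TF -> target pairs).

clique_links <- function(members) {
  members <- unique(members)
  if (length(members) < 2L) {
    return(data.frame(proteinA = character(), proteinB = character(),
                      stringsAsFactors = FALSE))
  }
  idx <- utils::combn(sort(members), 2L)
  data.frame(proteinA = idx[1L, ], proteinB = idx[2L, ],
             stringsAsFactors = FALSE)
}

#' Build the Complex gold standard
#'
#' Every complex contributes all unordered pairs of its members (clique
#' expansion); complexes larger than `max_size` members are excluded
#' entirely, since very large reported complexes are dominated by false
#' associations.
#'
#' @param records List of complex records, each a list with `id` and
#'   `members` (character vector of proteins).
#' @param max_size Maximum complex size admitted (default 100).
#' @return A [gold_standard()] named `"Complex"`.
#' @export
build_complex_gs <- function(records, max_size = 100) {
  links <- lapply(records, function(rec) {
    members <- unique(rec$members)
    if (length(members) > max_size) return(NULL)
    clique_links(members)
  })
  gold_standard(do.call(rbind, c(links, list(clique_links(character())))),
                name = "Complex")
}

#' Build a pathway gold standard (Metabolic or Signaling)
#'
#' Proteins belonging to the same pathway are fully connected (clique
#' expansion per pathway, union over pathways).
#'
#' @param records List of pathway records (`id`, `members`).
#' @param name `"Metabolic"` or `"Signaling"`.
#' @return A [gold_standard()].
#' @export
build_pathway_gs <- function(records, name) {
  if (!name %in% c("Metabolic", "Signaling")) {
    stop("pathway gold standard name must be 'Metabolic' or 'Signaling'")
  }
  links <- lapply(records, function(rec) clique_links(rec$members))
  gold_standard(do.call(rbind, c(links, list(clique_links(character())))),
                name = name)
}

#' Build the Operon gold standard
#'
#' Proteins sharing an operon are fully connected.
#'
#' @param operons List of character vectors (operon memberships).
#' @return A [gold_standard()] named `"Operon"`.
#' @export
build_operon_gs <- function(operons) {
  links <- lapply(operons, clique_links)
  gold_standard(do.call(rbind, c(links, list(clique_links(character())))),
                name = "Operon")
}

#' Build the PPI gold standard
#'
#' Physical interactions must be supported by at least `min_support`
#' distinct experiments, or be present in another gold standard.
#' Experiments reporting more than `max_exp_size` interactions are
#' discarded before support is counted.
#'
#' @param experiments List of experiment records, each a list with `id` and
#'   `interactions` (data.frame `proteinA`, `proteinB`).
#' @param other_gs List of other [gold_standard()] objects of the same
#'   species used for the rescue rule (checked on the undirected pair).
#' @param max_exp_size Maximum interactions per experiment (default 100).
#' @param min_support Minimum number of supporting experiments (default 2).
#' @return A [gold_standard()] named `"PPI"`.
#' @export
build_ppi_gs <- function(experiments, other_gs = list(), max_exp_size = 100,
                         min_support = 2) {
  keep <- Filter(function(e) nrow(e$interactions) <= max_exp_size,
                 experiments)
  if (length(keep) == 0L) {
    return(gold_standard(data.frame(proteinA = character(),
                                    proteinB = character()), name = "PPI"))
  }
  per_exp <- lapply(keep, function(e) {
    ints <- e$interactions
    ints <- ints[ints$proteinA != ints$proteinB, , drop = FALSE]
    unique(pair_key(ints$proteinA, ints$proteinB))
  })
  tab <- table(unlist(per_exp))
  rescue <- unique(unlist(lapply(other_gs, gs_keys, undirected = TRUE)))
  kept <- names(tab)[tab >= min_support | names(tab) %in% rescue]
  parts <- strsplit(kept, "|", fixed = TRUE)
  gold_standard(data.frame(
    proteinA = vapply(parts, `[`, character(1), 1L),
    proteinB = vapply(parts, `[`, character(1), 2L),
    stringsAsFactors = FALSE), name = "PPI")
}

#' Build the Regulatory gold standard
#'
#' Directed union of TF -> target pair sources; a pair reported in both
#' orientations yields two distinct directed links.
#'
#' @param sources List of data.frames with columns `tf`, `target`.
#' @return A directed [gold_standard()] named `"Regulatory"` with
#'   `proteinA` = TF, `proteinB` = target.
#' @export
build_regulatory_gs <- function(sources) {
  links <- lapply(sources, function(s) {
    data.frame(proteinA = s$tf, proteinB = s$target,
               stringsAsFactors = FALSE)
  })
  links <- c(links, list(data.frame(proteinA = character(),
                                    proteinB = character(),
                                    stringsAsFactors = FALSE)))
  gold_standard(do.call(rbind, links), name = "Regulatory", directed = TRUE)
}
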