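.at_granularity <- function(labels, granularity) {
  if (granularity == "family") sub("_[0-9]+$", "", labels) else labels
}

.classify_pattern <- function(labels) {
  if (length(labels) == 1L) "alone"
  else if (length(unique(labels)) == 1L) "multi_copy"
  else "with_accessory"
}

#' Build the domain architecture of one protein
#'
#' Orders the retained hits along the protein (`ali_from` ascending, ties
#' by `ali_to` then canonical family string) and classifies the
#' combinatorial pattern: `alone` (a single domain), `multi_copy` (two or
#' more copies of one family and nothing else) or `with_accessory` (at
#' least two distinct families). Subfamily labels are preserved verbatim
#' in the architecture string; with `granularity = "family"` they collapse
#' to their parent family for the pattern classification only.
#'
#' @param hits A `domain_hits` data.frame from a single protein, already
#'   filtered and overlap-resolved.
#' @param granularity `"subfamily"` (default) or `"family"`; the label
#'   resolution at which the pattern is judged.
#' @return One-row data.frame with columns `protein_id`, `organism_tag`,
#'   `architecture` (e.g. `"GH23+CBM50+CBM50"`), `pattern`, `n_domains`.
#' @examples
#' # a GH23 lysozyme-like domain followed by two CBM50 (LysM) modules
#' # classifies as "with_accessory"
#' @export
build_architecture <- function(hits,
                               granularity = c("subfamily", "family")) {
  granularity <- match.arg(granularity)
  validate_hits(hits)
  if (!nrow(hits))
    stop("cannot build an architecture from an empty hit list")
  if (length(unique(hits$protein_id)) != 1L)
    stop("build_architecture() expects hits from a single protein")
  ord <- order(hits$ali_from, hits$ali_to, hits$family)
  labels <- hits$family[ord]
  data.frame(
    protein_id = hits$protein_id[1],
    organism_tag = hits$organism_tag[1],
    architecture = paste(labels, collapse = "+"),
    pattern = .classify_pattern(.at_granularity(labels, granularity)),
    n_domains = length(labels),
    stringsAsFactors = FALSE)
}

#' Build architectures for every protein in a hit table
#'
#' @param hits A filtered `domain_hits` data.frame (any number of
#'   proteins).
#' @inheritParams build_architecture
#' @return An `architectures` data.frame, one row per protein, ordered by
#'   organism tag and protein id.
#' @export
build_architectures <- function(hits,
                                granularity = c("subfamily", "family")) {
  granularity <- match.arg(granularity)
  validate_hits(hits)
  if (!nrow(hits)) {
    out <- data.frame(protein_id = character(0),
                      organism_tag = character(0),
                      architecture = character(0), pattern = character(0),
                      n_domains = integer(0), stringsAsFactors = FALSE)
    class(out) <- c("architectures", "data.frame")
    return(out)
  }
  key <- paste(hits$organism_tag, hits$protein_id, sep = "\r")
  groups <- split(seq_len(nrow(hits)), key)
  out <- do.call(rbind, lapply(groups, function(idx)
    build_architecture(hits[idx, , drop = FALSE], granularity)))
  out <- out[order(out$organism_tag, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("architectures", "data.frame")
  out
}

#' Split architecture strings into their domain labels
#' @param architecture Character vector of `"+"`-joined labels.
#' @return List of character vectors.
#' @keywords internal
arch_domains <- function(architecture) {
  strsplit(architecture, "+", fixed = TRUE)
}

#' Partner families co-occurring with a focal family
#'
#' Counts proteins (not domain instances) that contain the focal family
#' together with at least one domain of each partner family. Proteins
#' carrying the focal family and no distinct partner are reported in the
#' `"self"` bucket — the alone/multi-copy mode of action.
#'
#' @param architectures An `architectures` data.frame.
#' @param focal Focal family label (string).
#' @param granularity `"subfamily"` (default) or `"family"`: collapse
#'   subfamilies to parents before matching.
#' @return A data.frame with columns `partner` and `proteins`, sorted by
#'   decreasing protein count (`"self"` listed with the partners).
#' @export
cooccurrence_table <- function(architectures, focal,
                               granularity = c("subfamily", "family")) {
  granularity <- match.arg(granularity)
  focal <- .at_granularity(canonical_family(focal), granularity)
  fam_sets <- lapply(arch_domains(architectures$architecture),
                     function(d) unique(.at_granularity(d, granularity)))
  tally <- new.env(parent = emptyenv())
  for (fams in fam_sets) {
    if (!(focal %in% fams)) next
    partners <- setdiff(fams, focal)
    if (!length(partners)) partners <- "self"
    for (p in partners)
      assign(p, (if (exists(p, tally)) get(p, tally) else 0L) + 1L, tally)
  }
  partners <- ls(tally)
  counts <- vapply(partners, get, integer(1), envir = tally)
  out <- data.frame(partner = partners, proteins = unname(counts),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$proteins, out$partner), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Combinatorial pattern frequency per family
#'
#' For every family occurring anywhere in the architecture set, counts the
#' proteins of each combinatorial pattern class (`alone`, `multi_copy`,
#' `with_accessory`) that contain it. A protein contributes once per
#' distinct family it carries, so the three counts for a family sum to the
#' number of proteins containing it.
#'
#' @inheritParams cooccurrence_table
#' @return Data.frame with columns `family`, `alone`, `multi_copy`,
#'   `with_accessory`, sorted by decreasing total.
#' @export
pattern_frequency <- function(architectures,
                              granularity = c("subfamily", "family")) {
  granularity <- match.arg(granularity)
  empty <- data.frame(family = character(0), alone = integer(0),
                      multi_copy = integer(0),
                      with_accessory = integer(0),
                      stringsAsFactors = FALSE)
  if (!nrow(architectures)) return(empty)
  doms <- arch_domains(architectures$architecture)
  per_protein <- lapply(doms, function(d) {
    labels <- .at_granularity(d, granularity)
    list(fams = unique(labels), pattern = .classify_pattern(labels))
  })
  fams <- sort(unique(unlist(lapply(per_protein, `[[`, "fams"))))
  out <- data.frame(family = fams, alone = 0L, multi_copy = 0L,
                    with_accessory = 0L, stringsAsFactors = FALSE)
  rownames(out) <- fams
  for (p in per_protein)
    out[p$fams, p$pattern] <- out[p$fams, p$pattern] + 1L
  out <- out[order(-(out$alone + out$multi_copy + out$with_accessory),
                   out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Protein-sharing matrix between all family pairs
#'
#' Symmetric matrix whose off-diagonal entry (A, B) is the number of
#' proteins containing both families; the diagonal entry (A, A) is the
#' number of proteins containing family A and no other family (the
#' `"self"` bucket of [cooccurrence_table()]).
#'
#' @inheritParams cooccurrence_table
#' @return Integer matrix with family dimnames.
#' @export
cooccurrence_matrix <- function(architectures,
                                granularity = c("subfamily", "family")) {
  granularity <- match.arg(granularity)
  fam_sets <- lapply(arch_domains(architectures$architecture),
                     function(d) unique(.at_granularity(d, granularity)))
  fams <- sort(unique(unlist(fam_sets)))
  m <- matrix(0L, length(fams), length(fams), dimnames = list(fams, fams))
  for (fs in fam_sets) {
    if (length(fs) == 1L) m[fs, fs] <- m[fs, fs] + 1L
    else for (a in fs) for (b in setdiff(fs, a))
      m[a, b] <- m[a, b] + 1L
  }
  m
}
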