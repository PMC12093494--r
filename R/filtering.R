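#' Filtering thresholds for CAZyme domain hits
#'
#' The defaults follow the widely used dbCAN parser conventions: a hit is
#' high quality when it covers at least 35% of the HMM profile and its
#' independent e-value is at most `1e-15` (relaxed to `1e-3` for short
#' alignments under 80 residues). Hits overlapping by more than 50% of the
#' shorter alignment interval are redundant and resolved by e-value. All
#' thresholds are configurable so any parser variant can be matched.
#'
#' @param max_ievalue Strict independent e-value ceiling (default `1e-15`).
#' @param min_coverage Minimum HMM profile coverage in `[0, 1]`
#'   (default `0.35`).
#' @param overlap_fraction Maximum tolerated pairwise overlap, as a
#'   fraction of the shorter alignment interval, in `(0, 1]`
#'   (default `0.5`).
#' @param relaxed_ievalue E-value ceiling applied instead of
#'   `max_ievalue` when the alignment is shorter than `short_cutoff`
#'   residues (default `1e-3`).
#' @param short_cutoff Alignment length (residues) below which
#'   `relaxed_ievalue` applies (default `80`).
#' @param same_family_only If `TRUE`, overlap resolution only arbitrates
#'   between hits of the same family; hits of different families may
#'   overlap freely. Default `FALSE` (resolve across families).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(max_ievalue = 1e-15, min_coverage = 0.35,
                          overlap_fraction = 0.5, relaxed_ievalue = 1e-3,
                          short_cutoff = 80, same_family_only = FALSE) {
  stopifnot(max_ievalue > 0, relaxed_ievalue > 0, short_cutoff > 0,
            min_coverage >= 0, min_coverage <= 1,
            overlap_fraction > 0, overlap_fraction <= 1,
            is.logical(same_family_only))
  structure(list(max_ievalue = max_ievalue, min_coverage = min_coverage,
                 overlap_fraction = overlap_fraction,
                 relaxed_ievalue = relaxed_ievalue,
                 short_cutoff = short_cutoff,
                 same_family_only = same_family_only),
            class = "filter_config")
}

#' Drop low-quality domain hits
#'
#' Retains a hit iff its HMM coverage is at least `min_coverage` and its
#' independent e-value passes the strict ceiling, or the relaxed ceiling
#' when the alignment spans fewer than `short_cutoff` residues. Input
#' order is preserved.
#'
#' @param hits A `domain_hits` data.frame.
#' @param cfg A [filter_config()].
#' @return The retained subset of `hits`.
#' @export
quality_filter <- function(hits, cfg = filter_config()) {
  validate_hits(hits)
  stopifnot(inherits(cfg, "filter_config"))
  if (!nrow(hits)) return(hits)
  ali_len <- hits$ali_to - hits$ali_from + 1L
  keep <- hits$coverage >= cfg$min_coverage &
    (hits$dom_ievalue <= cfg$max_ievalue |
       (ali_len < cfg$short_cutoff &
          hits$dom_ievalue <= cfg$relaxed_ievalue))
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resolve overlapping/redundant hits on one protein
#'
#' Greedy resolution: hits are visited by increasing independent e-value
#' (ties broken by higher coverage, then canonical family string, then
#' `ali_from`); a hit is accepted iff its alignment interval overlaps
#' every previously accepted hit by no more than `overlap_fraction` of
#' the shorter of the two intervals. Accepted hits are returned sorted by
#' `ali_from`. Surviving same-family copies are kept as separate hits —
#' tandem duplications are biologically meaningful.
#'
#' @param hits A `domain_hits` data.frame, all sharing one `protein_id`,
#'   already quality-filtered.
#' @param cfg A [filter_config()].
#' @return The accepted subset of `hits`, sorted by position.
#' @export
resolve_overlaps <- function(hits, cfg = filter_config()) {
  validate_hits(hits)
  stopifnot(inherits(cfg, "filter_config"))
  if (nrow(hits) <= 1L) {
    rownames(hits) <- NULL
    return(hits)
  }
  if (length(unique(hits$protein_id)) != 1L)
    stop("resolve_overlaps() expects hits from a single protein; got: ",
         paste(unique(hits$protein_id), collapse = ", "))
  ord <- order(hits$dom_ievalue, -hits$coverage, hits$family,
               hits$ali_from, hits$ali_to)
  af <- hits$ali_from; at <- hits$ali_to
  len <- at - af + 1L
  accepted <- integer(0)
  for (i in ord) {
    if (length(accepted)) {
      ov <- pmax(0L, pmin(at[i], at[accepted]) -
                   pmax(af[i], af[accepted]) + 1L)
      shorter <- pmin(len[i], len[accepted])
      conflict <- ov > cfg$overlap_fraction * shorter
      if (cfg$same_family_only)
        conflict <- conflict & hits$family[accepted] == hits$family[i]
      if (any(conflict)) next
    }
    accepted <- c(accepted, i)
  }
  out <- hits[accepted, , drop = FALSE]
  out <- out[order(out$ali_from, out$ali_to, out$family,
                   out$dom_ievalue), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter a whole proteome's hits
#'
#' Applies [quality_filter()] and then [resolve_overlaps()] per protein
#' (grouped by organism tag and protein id). Proteins left without hits
#' simply disappear from the table.
#'
#' @param hits A `domain_hits` data.frame, any number of proteins.
#' @param cfg A [filter_config()].
#' @return The retained `domain_hits`, ordered by organism, protein and
#'   position.
#' @export
filter_organism <- function(hits, cfg = filter_config()) {
  validate_hits(hits)
  hits <- quality_filter(hits, cfg)
  if (!nrow(hits)) return(empty_hits())
  key <- paste(hits$organism_tag, hits$protein_id, sep = "\r")
  groups <- split(seq_len(nrow(hits)), key)
  resolved <- lapply(groups, function(idx)
    resolve_overlaps(hits[idx, , drop = FALSE], cfg))
  out <- do.call(rbind, resolved)
  out <- out[order(out$organism_tag, out$protein_id, out$ali_from,
                   out$ali_to, out$family), , drop = FALSE]
  rownames(out) <- NULL
  validate_hits(out)
  out
}
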