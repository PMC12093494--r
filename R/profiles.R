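#' Percentage of coding sequences carrying a CAZyme domain
#'
#' `100 * cazyme_cds / total_cds`, the per-genome %CAZyme CDS statistic.
#' Full precision is retained; round only at display time.
#'
#' @param cazyme_cds Number of CDSs with at least one retained CAZyme
#'   domain (vectorised).
#' @param total_cds Total annotated CDS count (vectorised, must be
#'   positive).
#' @return Numeric vector of percentages in `[0, 100]`.
#' @examples
#' percent_cazyme(493, 9943)
#' @export
percent_cazyme <- function(cazyme_cds, total_cds) {
  if (any(total_cds <= 0))
    stop("total_cds must be positive")
  if (any(cazyme_cds < 0))
    stop("cazyme_cds must be non-negative")
  if (any(cazyme_cds > total_cds))
    stop("cazyme_cds cannot exceed total_cds")
  100 * cazyme_cds / total_cds
}

#' Proteins per CAZyme category
#'
#' A protein increments a category once if at least one of its domains
#' belongs to it; a protein carrying both a GH and a CBM domain counts
#' toward both categories.
#'
#' @param architectures An `architectures` data.frame (one organism).
#' @return Named integer vector over the six categories
#'   (GH, GT, PL, CE, AA, CBM).
#' @export
category_counts <- function(architectures) {
  out <- stats::setNames(integer(length(CAZY_CATEGORIES)), CAZY_CATEGORIES)
  if (!nrow(architectures)) return(out)
  cats <- lapply(arch_domains(architectures$architecture),
                 function(d) unique(sub("[0-9_].*$", "", d)))
  tab <- table(factor(unlist(cats), levels = CAZY_CATEGORIES))
  out[] <- as.integer(tab)
  out
}

#' Proteins per degradable substrate
#'
#' A protein counts once toward every substrate reachable from any of its
#' families through the substrate map; bifunctional families propagate the
#' protein to all their substrates, so the counts over substrates can sum
#' to more than the number of mapped proteins.
#'
#' @param architectures An `architectures` data.frame (one organism).
#' @param map A `substrate_map` (default [default_substrate_map()]).
#' @return Named integer vector over the eight substrates.
#' @export
substrate_counts <- function(architectures, map = default_substrate_map()) {
  out <- stats::setNames(integer(length(SUBSTRATES)), SUBSTRATES)
  if (!nrow(architectures)) return(out)
  doms <- arch_domains(architectures$architecture)
  all_fams <- unique(unlist(doms))
  lut <- lapply(all_fams, substrates_for_family, map = map)
  names(lut) <- all_fams
  subs <- lapply(doms, function(d) unique(unlist(lut[unique(d)])))
  tab <- table(factor(unlist(subs), levels = SUBSTRATES))
  out[] <- as.integer(tab)
  out
}

.meta_required <- c("tag", "suborder", "family", "genus", "habitat",
                    "genome_size_bp", "total_cds")

#' Read an organism metadata table
#'
#' Tab-delimited with header; required columns `tag`, `suborder`,
#' `family`, `genus`, `habitat` (soil/marine/other), `genome_size_bp`,
#' `total_cds`; optional `name`, `gc_percent`, `fasta_path`, `gff_path`.
#' When `total_cds` is missing for a row but `gff_path` is present, the
#' CDS count is derived from the GFF3 file.
#'
#' @param path Path to the TSV file.
#' @return Data.frame of organism metadata.
#' @export
read_metadata <- function(path) {
  meta <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE)
  if (!"total_cds" %in% names(meta) && "gff_path" %in% names(meta))
    meta$total_cds <- NA_integer_
  missing_cols <- setdiff(.meta_required, names(meta))
  if (length(missing_cols))
    stop("metadata '", path, "' lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  fill <- which(is.na(meta$total_cds))
  if (length(fill)) {
    if (!"gff_path" %in% names(meta))
      stop("metadata rows without total_cds and no gff_path to derive it: ",
           paste(meta$tag[fill], collapse = ", "))
    for (i in fill) {
      if (is.na(meta$gff_path[i]) || !nzchar(meta$gff_path[i]))
        stop("organism '", meta$tag[i],
             "' has no total_cds and no gff_path")
      meta$total_cds[i] <- count_cds_gff(meta$gff_path[i])
    }
  }
  bad <- !meta$habitat %in% c("soil", "marine", "other")
  if (any(bad))
    stop("habitat must be soil/marine/other; offending tag(s): ",
         paste(meta$tag[bad], collapse = ", "))
  meta
}

#' Count distinct CDS features in a GFF3 file
#'
#' Features of type `CDS`, made distinct by their `ID` attribute (a CDS
#' split across several lines of one gene model counts once); CDS lines
#' without an ID each count individually.
#'
#' @param path Path to a GFF3 file.
#' @return Integer CDS count.
#' @export
count_cds_gff <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("count_cds_gff() needs the rtracklayer package")
  gr <- rtracklayer::import(path)
  cds <- gr[as.character(gr$type) == "CDS"]
  ids <- cds$ID
  if (is.null(ids)) ids <- rep(NA_character_, length(cds))
  length(unique(ids[!is.na(ids)])) + sum(is.na(ids))
}

#' GC content of a nucleotide sequence
#'
#' `100 * (G + C) / (A + C + G + T)`, case-insensitive; ambiguity codes
#' and other characters are excluded from both numerator and denominator.
#'
#' @param sequence A single nucleotide string.
#' @return GC percentage in `[0, 100]`.
#' @examples
#' gc_percent("ATGCNNN")  # 50
#' @export
gc_percent <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            nzchar(sequence))
  s <- toupper(sequence)
  n <- function(ch) nchar(s) - nchar(gsub(ch, "", s, fixed = TRUE))
  counts <- vapply(c("A", "C", "G", "T"), n, numeric(1))
  denom <- sum(counts)
  if (denom == 0)
    stop("sequence contains no unambiguous A/C/G/T bases")
  100 * (counts[["G"]] + counts[["C"]]) / denom
}

#' Derive genome metadata from FASTA + GFF3
#'
#' Genome size and GC content from the assembly FASTA (via Biostrings),
#' CDS count from the GFF3 annotation.
#'
#' @param fasta_path Path to the genome FASTA.
#' @param gff_path Path to the GFF3 annotation.
#' @return List with `genome_size_bp`, `gc_percent`, `total_cds`.
#' @export
derive_metadata <- function(fasta_path, gff_path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("derive_metadata() needs the Biostrings package")
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  gc <- gc_percent(paste(as.character(seqs), collapse = ""))
  list(genome_size_bp = sum(Biostrings::width(seqs)),
       gc_percent = gc,
       total_cds = count_cds_gff(gff_path))
}

#' Assemble the profile of one organism
#'
#' Combines a metadata row with the organism's filtered hits: CAZyme CDS
#' count (proteins with at least one retained domain), %CAZyme CDS,
#' category counts and substrate counts.
#'
#' @param meta One-row data.frame of organism metadata (see
#'   [read_metadata()] for the columns).
#' @param hits Filtered `domain_hits` for this organism (may be empty).
#' @param map A `substrate_map`.
#' @return One-row data.frame: the metadata columns plus `cazyme_cds`,
#'   `pct_cazyme`, `n_<category>` and `n_<substrate>` columns.
#' @export
build_profile <- function(meta, hits, map = default_substrate_map()) {
  stopifnot(is.data.frame(meta), nrow(meta) == 1L)
  if (is.na(meta$total_cds) || meta$total_cds <= 0)
    stop("organism '", meta$tag, "': total_cds missing or non-positive")
  arch <- build_architectures(hits)
  if (nrow(arch) && any(arch$organism_tag != meta$tag))
    stop("hits organism tag does not match metadata tag '", meta$tag, "'")
  cats <- category_counts(arch)
  subs <- substrate_counts(arch, map)
  prof <- meta
  prof$cazyme_cds <- nrow(arch)
  prof$pct_cazyme <- percent_cazyme(nrow(arch), meta$total_cds)
  for (k in names(cats)) prof[[paste0("n_", k)]] <- cats[[k]]
  for (k in names(subs)) prof[[paste0("n_", k)]] <- subs[[k]]
  rownames(prof) <- NULL
  prof
}

.family_count_matrix <- function(hits, level = c("protein", "domain")) {
  level <- match.arg(level)
  fams <- sub("_[0-9]+$", "", hits$family)
  if (level == "protein") {
    key <- unique(data.frame(org = hits$organism_tag,
                             prot = hits$protein_id, fam = fams,
                             stringsAsFactors = FALSE))
    tab <- table(key$org, key$fam)
  } else {
    tab <- table(hits$organism_tag, fams)
  }
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  m[, order(colnames(m)), drop = FALSE]
}

#' Build profiles for a whole dataset
#'
#' @param metadata Data.frame of organism metadata (one row per
#'   organism).
#' @param hits Filtered `domain_hits` for all organisms; tags must be a
#'   subset of `metadata$tag`. Organisms without hits get all-zero
#'   counts.
#' @param map A `substrate_map`.
#' @return List with components `profiles` (one row per organism),
#'   `family_counts` (organisms x families, proteins containing the
#'   family; subfamilies collapsed to their parent), `family_domain_counts`
#'   (same shape, domain instances) and `substrate_counts` (organisms x
#'   substrates). Class `organism_profiles`.
#' @export
build_profiles <- function(metadata, hits, map = default_substrate_map()) {
  validate_hits(hits)
  stray <- setdiff(unique(hits$organism_tag), metadata$tag)
  if (length(stray))
    stop("hits carry organism tag(s) absent from metadata: ",
         paste(stray, collapse = ", "))
  rows <- lapply(seq_len(nrow(metadata)), function(i) {
    tag <- metadata$tag[i]
    build_profile(metadata[i, , drop = FALSE],
                  hits[hits$organism_tag == tag, , drop = FALSE], map)
  })
  profiles <- do.call(rbind, rows)
  fc <- .family_count_matrix(hits, "protein")
  fdc <- .family_count_matrix(hits, "domain")
  pad <- function(m) {
    missing_tags <- setdiff(metadata$tag, rownames(m))
    if (length(missing_tags)) {
      m <- rbind(m, matrix(0L, length(missing_tags), ncol(m),
                           dimnames = list(missing_tags, colnames(m))))
    }
    m[metadata$tag, , drop = FALSE]
  }
  sc <- as.matrix(profiles[, paste0("n_", SUBSTRATES), drop = FALSE])
  dimnames(sc) <- list(metadata$tag, SUBSTRATES)
  structure(list(profiles = profiles,
                 family_counts = pad(fc),
                 family_domain_counts = pad(fdc),
                 substrate_counts = sc),
            class = "organism_profiles")
}

#' @export
print.organism_profiles <- function(x, ...) {
  cat("CAZyme profiles for ", nrow(x$profiles), " organisms; ",
      ncol(x$family_counts), " families; median %CAZyme CDS ",
      sprintf("%.2f", stats::median(x$profiles$pct_cazyme)), "\n", sep = "")
  invisible(x)
}
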