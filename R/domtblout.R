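.hit_columns <- c("protein_id", "organism_tag", "family", "hmm_length",
                  "hmm_from", "hmm_to", "ali_from", "ali_to",
                  "env_from", "env_to", "full_seq_evalue", "dom_ievalue",
                  "dom_score", "coverage")

#' Validate a domain-hit table
#'
#' Checks the column set and the coordinate/coverage invariants of a
#' `domain_hits` data.frame: `hmm_from <= hmm_to <= hmm_length`,
#' `ali_from <= ali_to`, `env_from <= env_to`, non-negative e-values and
#' `coverage = (hmm_to - hmm_from + 1) / hmm_length`.
#'
#' @param hits A data.frame of domain hits.
#' @return `hits`, invisibly, with class `domain_hits`.
#' @export
validate_hits <- function(hits) {
  if (!is.data.frame(hits))
    stop("'hits' must be a data.frame")
  missing_cols <- setdiff(.hit_columns, names(hits))
  if (length(missing_cols))
    stop("hit table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(hits)) {
    with(hits, {
      if (any(hmm_length < 1L)) stop("hmm_length must be positive")
      if (any(hmm_from > hmm_to)) stop("hmm_from > hmm_to")
      if (any(hmm_to > hmm_length)) stop("hmm_to > hmm_length")
      if (any(hmm_from < 1L) || any(ali_from < 1L) || any(env_from < 1L))
        stop("coordinates are 1-based; found value < 1")
      if (any(ali_from > ali_to)) stop("ali_from > ali_to")
      if (any(env_from > env_to)) stop("env_from > env_to")
      if (any(full_seq_evalue < 0) || any(dom_ievalue < 0))
        stop("e-values must be non-negative")
      expected <- (hmm_to - hmm_from + 1) / hmm_length
      if (any(abs(coverage - expected) > 1e-9))
        stop("coverage does not equal (hmm_to - hmm_from + 1)/hmm_length")
    })
  }
  if (!inherits(hits, "domain_hits"))
    class(hits) <- c("domain_hits", class(hits))
  invisible(hits)
}

#' An empty domain-hit table with the canonical column types
#' @return A zero-row `domain_hits` data.frame.
#' @keywords internal
empty_hits <- function() {
  df <- data.frame(
    protein_id = character(0), organism_tag = character(0),
    family = character(0), hmm_length = integer(0),
    hmm_from = integer(0), hmm_to = integer(0),
    ali_from = integer(0), ali_to = integer(0),
    env_from = integer(0), env_to = integer(0),
    full_seq_evalue = numeric(0), dom_ievalue = numeric(0),
    dom_score = numeric(0), coverage = numeric(0),
    stringsAsFactors = FALSE)
  class(df) <- c("domain_hits", "data.frame")
  df
}

.num_field <- function(x, what, line_no) {
  out <- suppressWarnings(as.numeric(x))
  bad <- is.na(out) & !is.na(x)
  if (any(bad))
    stop("non-numeric ", what, " on line ",
         paste(line_no[bad], collapse = ", "))
  out
}

#' Read an HMMER3 per-domain table (--domtblout)
#'
#' Parses the whitespace-delimited per-domain table written by the HMMER3
#' suite. Lines starting with `#` are skipped; every other line must carry
#' at least 23 fields (trailing free-text description tolerated). Per-hit
#' HMM profile coverage, `(hmm_to - hmm_from + 1) / hmm_length`, is
#' computed on read.
#'
#' By default the protein is taken from the target-name column (1) and the
#' CAZyme HMM from the query-name column (4), with the profile length in
#' the `qlen` column (6) — the layout written by [write_domtblout()]. Files
#' produced by `hmmscan` itself carry the HMM as the *target* (profile
#' length `tlen`, column 3) and the protein as the query; read those with
#' `protein_is = "query"`.
#'
#' @param path Path to the domtblout file.
#' @param organism_tag Organism identifier attached to every hit; defaults
#'   to the file name stem.
#' @param protein_is Either `"target"` (default) or `"query"`; which of
#'   the two named sequences in the table is the protein.
#' @return A `domain_hits` data.frame (one row per domain match).
#' @seealso [write_domtblout()], [quality_filter()]
#' @export
read_domtblout <- function(path, organism_tag = NULL,
                           protein_is = c("target", "query")) {
  protein_is <- match.arg(protein_is)
  if (is.null(organism_tag))
    organism_tag <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  is_data <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  line_no <- which(is_data)
  if (!length(line_no))
    return(validate_hits(empty_hits()))
  fields <- strsplit(trimws(lines[line_no]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 23L))
    stop("domtblout '", path, "': fewer than 23 fields on line ",
         paste(line_no[nf < 23L], collapse = ", "))
  col <- function(i) vapply(fields, `[[`, character(1), i)
  if (protein_is == "target") {
    protein <- col(1); family_raw <- col(4); len_raw <- col(6)
  } else {
    protein <- col(4); family_raw <- col(1); len_raw <- col(3)
  }
  fam <- tryCatch(parse_family_label(family_raw)$canonical,
                  error = function(e)
                    stop("domtblout '", path, "': ", conditionMessage(e),
                         call. = FALSE))
  to_int <- function(x, what) {
    v <- .num_field(x, what, line_no)
    as.integer(round(v))
  }
  hits <- data.frame(
    protein_id = protein,
    organism_tag = organism_tag,
    family = fam,
    hmm_length = to_int(len_raw, "profile length"),
    hmm_from = to_int(col(16), "hmm coordinate"),
    hmm_to = to_int(col(17), "hmm coordinate"),
    ali_from = to_int(col(18), "alignment coordinate"),
    ali_to = to_int(col(19), "alignment coordinate"),
    env_from = to_int(col(20), "envelope coordinate"),
    env_to = to_int(col(21), "envelope coordinate"),
    full_seq_evalue = .num_field(col(7), "full-sequence E-value", line_no),
    dom_ievalue = .num_field(col(13), "independent E-value", line_no),
    dom_score = .num_field(col(14), "domain score", line_no),
    stringsAsFactors = FALSE)
  hits$coverage <- (hits$hmm_to - hits$hmm_from + 1) / hits$hmm_length
  bad <- hits$coverage < 0 | hits$coverage > 1
  if (any(bad))
    stop("domtblout '", path, "': hmm coordinates outside profile on line ",
         paste(line_no[bad], collapse = ", "))
  tryCatch(validate_hits(hits),
           error = function(e)
             stop("domtblout '", path, "': ", conditionMessage(e),
                  call. = FALSE))
  hits
}

#' Write domain hits as an HMMER3-style per-domain table
#'
#' Emits a syntactically valid domtblout file (comment header, 23
#' whitespace-separated fields per hit) that [read_domtblout()] parses back
#' to the identical hit table. Numeric fields use full `%.17g` precision so
#' the write/read cycle is lossless.
#'
#' @param hits A `domain_hits` data.frame (invariants are checked before
#'   anything is written).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_domtblout <- function(hits, path) {
  validate_hits(hits)
  hdr <- c(
    paste0("# target name        accession   tlen query name",
           "           accession   qlen   E-value  score  bias   #  of",
           "  c-Evalue  i-Evalue  score  bias  from    to  from    to",
           "  from    to  acc description of target"),
    paste0("#------------------- ---------- ----- --------------------",
           " ---------- ----- --------- ------ ----- --- --- ---------",
           " --------- ------ ----- ----- ----- ----- ----- ----- -----",
           " ---- ---------------------"))
  g <- function(x) sprintf("%.17g", x)
  lines <- character(0)
  if (nrow(hits)) {
    lines <- sprintf(
      "%s - %d %s - %d %s %s 0.0 1 1 %s %s %s 0.0 %d %d %d %d %d %d 0.90 -",
      hits$protein_id, hits$env_to + 10L, hits$family, hits$hmm_length,
      g(hits$full_seq_evalue), g(hits$dom_score), g(hits$dom_ievalue),
      g(hits$dom_ievalue), g(hits$dom_score),
      hits$hmm_from, hits$hmm_to, hits$ali_from, hits$ali_to,
      hits$env_from, hits$env_to)
  }
  writeLines(c(hdr, lines, "#"), path)
  invisible(path)
}
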