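#' The six CAZyme categories
#'
#' Glycoside hydrolases (GH), glycosyltransferases (GT), polysaccharide
#' lyases (PL), carbohydrate esterases (CE), auxiliary activities (AA) and
#' carbohydrate-binding modules (CBM).
#'
#' @format Character vector of length 6.
#' @export
CAZY_CATEGORIES <- c("GH", "GT", "PL", "CE", "AA", "CBM")

#' The polysaccharide substrates tracked by the substrate map
#'
#' @format Character vector of length 8.
#' @export
SUBSTRATES <- c("cellulose", "xylan", "lignin", "starch", "chitin",
                "dextran", "fructan", "pectin")

.family_label_re <- "^(GH|GT|PL|CE|AA|CBM)([0-9]+)(_([0-9]+))?$"

#' Parse CAZyme family labels
#'
#' Parses dbCAN-style family labels such as `"GH13_11.hmm"` or `"CBM50"`
#' into category, family number and optional subfamily number. A trailing
#' `".hmm"` suffix (as found in HMM model names) is stripped; the subfamily
#' is split on the underscore.
#'
#' @param raw Character vector of labels.
#' @return A data.frame with one row per input and columns `raw`,
#'   `category`, `family_number`, `subfamily` (`NA` when absent) and
#'   `canonical` (the normalised label string, e.g. `"GH13_11"`).
#' @examples
#' parse_family_label(c("GH13_11.hmm", "CBM50"))
#' @export
parse_family_label <- function(raw) {
  if (!is.character(raw) || length(raw) == 0L)
    stop("'raw' must be a non-empty character vector of family labels")
  tok <- sub("\\.hmm$", "", raw, ignore.case = TRUE)
  ok <- !is.na(tok) & grepl(.family_label_re, tok)
  if (any(!ok))
    stop("cannot parse CAZyme family label(s): ",
         paste(unique(raw[!ok]), collapse = ", "))
  category <- sub(.family_label_re, "\\1", tok)
  family_number <- as.integer(sub(.family_label_re, "\\2", tok))
  sub_str <- sub(.family_label_re, "\\4", tok)
  subfamily <- ifelse(nzchar(sub_str), suppressWarnings(as.integer(sub_str)),
                      NA_integer_)
  if (any(family_number < 1L))
    stop("family number must be a positive integer in: ",
         paste(unique(raw[family_number < 1L]), collapse = ", "))
  canonical <- paste0(category, family_number,
                      ifelse(is.na(subfamily), "",
                             paste0("_", subfamily)))
  data.frame(raw = raw, category = category,
             family_number = family_number, subfamily = subfamily,
             canonical = canonical, stringsAsFactors = FALSE)
}

#' Canonical family string for a label
#'
#' @param raw Character vector of labels (`".hmm"` suffix allowed).
#' @return Character vector of canonical labels, e.g. `"GH13_11"`.
#' @export
canonical_family <- function(raw) parse_family_label(raw)$canonical

#' Parent family of a (sub)family label
#'
#' `"GH13_11"` has parent `"GH13"`; labels without a subfamily are their
#' own parent.
#'
#' @param raw Character vector of labels.
#' @return Character vector of parent family canonical strings.
#' @export
parent_family <- function(raw) {
  sub("_[0-9]+$", "", canonical_family(raw))
}

#' Category of a family label
#'
#' @param raw Character vector of labels.
#' @return Character vector with values from [CAZY_CATEGORIES].
#' @export
family_category <- function(raw) parse_family_label(raw)$category

.new_substrate_map <- function(df) {
  stopifnot(all(c("substrate", "activity", "ec_number", "family") %in%
                  names(df)))
  bad <- !df$substrate %in% SUBSTRATES
  if (any(bad))
    stop("unknown substrate(s): ", paste(unique(df$substrate[bad]),
                                         collapse = ", "))
  df$family <- canonical_family(df$family)
  df <- unique(df[, c("substrate", "activity", "ec_number", "family")])
  rownames(df) <- NULL
  class(df) <- c("substrate_map", "data.frame")
  df
}

#' Built-in substrate -> enzyme activity -> CAZyme family map
#'
#' The shipped map covers the eight tracked polysaccharide substrates and
#' the CAZyme families with literature-curated degradative activities on
#' them. Some families are bifunctional and appear under more than one
#' substrate (GH13 acts on both starch and dextran; GH48 on both cellulose
#' and chitin; most cellulose beta-glucosidase families also act on xylan).
#' EC numbers are carried as opaque lookup keys. The map can be replaced
#' or extended with [load_substrate_map()].
#'
#' @return A `substrate_map` data.frame with columns `substrate`,
#'   `activity`, `ec_number`, `family`.
#' @examples
#' m <- default_substrate_map()
#' substrates_for_family(m, "GH13")   # starch + dextran
#' @export
default_substrate_map <- function() {
  row <- function(substrate, activity, ec, families)
    data.frame(substrate = substrate, activity = activity, ec_number = ec,
               family = families, stringsAsFactors = FALSE)
  df <- rbind(
    row("cellulose", "endocellulase", "3.2.1.4",
        c("GH5", "GH6", "GH8", "GH9", "GH10", "GH12", "GH44", "GH45",
          "GH48", "GH74")),
    row("cellulose", "cellobiohydrolase", "3.2.1.91",
        c("GH6", "GH9", "GH48", "GH51")),
    row("cellulose", "beta-glucosidase", "3.2.1.21",
        c("GH1", "GH2", "GH3", "GH30", "GH39", "GH116")),
    row("xylan", "endoxylanase", "3.2.1.8",
        c("GH5", "GH8", "GH10", "GH30", "GH43")),
    row("xylan", "beta-xylosidase", "3.2.1.37",
        c("GH1", "GH2", "GH3", "GH39", "GH43", "GH52", "GH116")),
    row("xylan", "alpha-L-arabinofuranosidase", "3.2.1.55", "GH51"),
    row("xylan", "alpha-glucuronidase", "3.2.1.139", "GH67"),
    row("xylan", "acetyl xylan esterase", "3.1.1.72",
        c("CE1", "CE4", "CE7")),
    row("xylan", "feruloyl esterase", "3.1.1.73", "CE1"),
    row("lignin", "laccase", "1.10.3.2", "AA1"),
    row("lignin", "lignin peroxidase", "1.11.1.14", "AA2"),
    row("lignin", "manganese peroxidase", "1.11.1.13", "AA2"),
    row("starch", "alpha-amylase", "3.2.1.1",
        c("GH13", "GH57", "GH119")),
    row("starch", "beta-amylase", "3.2.1.2", "GH14"),
    row("starch", "glucoamylase", "3.2.1.3", c("GH15", "GH97")),
    row("chitin", "endochitinase", "3.2.1.14",
        c("GH18", "GH19", "GH23", "GH48")),
    row("dextran", "dextranase", "3.2.1.11", c("GH49", "GH66")),
    row("dextran", "glucan-1,6-alpha-glucosidase", "3.2.1.70",
        c("GH13", "GH15")),
    row("dextran", "glucan-1,6-alpha-isomaltosidase", "3.2.1.94", "GH27"),
    row("fructan", "fructan exohydrolase", "3.2.1.80", "GH32"),
    row("pectin", "pectin methylesterase", "3.1.1.11", "CE8"),
    row("pectin", "endo-polygalacturonase", "3.2.1.15", "GH28"),
    row("pectin", "pectin lyase", "4.2.2.10", "PL1")
  )
  .new_substrate_map(df)
}

#' Load a substrate map from a TSV file
#'
#' The file must be tab-delimited with header columns `substrate`,
#' `activity`, `ec_number`, `family`; lines starting with `#` are ignored.
#' Duplicate rows collapse; the same family listed under several substrates
#' stays bifunctional.
#'
#' @param path Path to the TSV file.
#' @param base Optional `substrate_map` to extend (e.g.
#'   `default_substrate_map()`). Default `NULL` replaces rather than
#'   extends.
#' @return A `substrate_map` data.frame.
#' @export
load_substrate_map <- function(path, base = NULL) {
  df <- tryCatch(
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop("cannot read substrate map '", path, "': ",
                             conditionMessage(e)))
  if (nrow(df) == 0L)
    stop("substrate map '", path, "' contains no data rows")
  need <- c("substrate", "activity", "ec_number", "family")
  if (!all(need %in% names(df)))
    stop("substrate map '", path, "' must have columns: ",
         paste(need, collapse = ", "))
  for (i in seq_len(nrow(df))) {
    tryCatch(parse_family_label(df$family[i]),
             error = function(e)
               stop("substrate map '", path, "', row ", i, ": ",
                    conditionMessage(e), call. = FALSE))
  }
  out <- df[, need]
  if (!is.null(base)) {
    stopifnot(inherits(base, "substrate_map"))
    out <- rbind(as.data.frame(base), out)
  }
  .new_substrate_map(out)
}

#' Substrates degradable through a CAZyme family
#'
#' Subfamily labels inherit the substrates of their parent family, so
#' `substrates_for_family(m, "GH13_11")` equals
#' `substrates_for_family(m, "GH13")` unless the map lists the subfamily
#' explicitly.
#'
#' @param map A `substrate_map`.
#' @param family A single family label (string).
#' @return Sorted character vector of substrates (possibly empty).
#' @export
substrates_for_family <- function(map, family) {
  stopifnot(inherits(map, "substrate_map"), length(family) == 1L)
  canon <- canonical_family(family)
  keys <- unique(c(canon, sub("_[0-9]+$", "", canon)))
  sort(unique(map$substrate[map$family %in% keys]))
}

#' @export
print.substrate_map <- function(x, ...) {
  cat("CAZyme substrate map: ", length(unique(x$family)), " families, ",
      length(unique(x$substrate)), " substrates, ",
      nrow(x), " (substrate, activity, family) rows\n", sep = "")
  invisible(x)
}
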