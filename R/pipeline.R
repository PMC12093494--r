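#' Write a table as TSV
#'
#' Tab-delimited, header row, `.` decimal separator, no quoting and no
#' row names — the layout every reader in the package (and any
#' spreadsheet) accepts.
#'
#' @param x Data.frame or matrix (matrix row names become a `row` column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  if (is.matrix(x))
    x <- data.frame(row = rownames(x), as.data.frame(x),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path File path.
#' @return Data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read pipeline settings from a YAML config file
#'
#' Recognised keys mirror the arguments of [run_pipeline()]
#' (`domtblout_dir`, `metadata`, `out_dir`, `substrate_map`,
#' `granularity`, `pca_scale`, `protein_is`) plus a `filter` block with
#' the [filter_config()] fields.
#'
#' @param path Path to the YAML file.
#' @return Named list of arguments for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$filter))
    cfg$filter <- do.call(filter_config, cfg$filter)
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the comparative CAZyme pipeline end to end
#'
#' Reads one domtblout per organism from `domtblout_dir`, filters hits,
#' builds architectures and combinatorial-pattern tables, assembles
#' per-organism profiles and count matrices, and computes the comparative
#' statistics (group summaries of %CAZyme CDS by suborder, family and
#' habitat; pairwise Welch tests across suborders; regressions of CAZyme
#' counts on genome size; PCA of the six category counts). All tables are
#' written as TSV under `out_dir`, together with a machine-readable
#' `manifest.json` (configuration, package version, input and output
#' checksums). Outputs are a pure function of inputs plus configuration:
#' re-running on the same inputs reproduces every file byte for byte.
#'
#' @param domtblout_dir Directory containing `<tag>.domtblout` files.
#' @param metadata Metadata data.frame or path to a metadata TSV
#'   (see [read_metadata()]). Must cover every organism tag found in
#'   `domtblout_dir`.
#' @param out_dir Output directory (created if needed).
#' @param substrate_map A `substrate_map`, a path to a substrate-map TSV,
#'   or `NULL` for [default_substrate_map()].
#' @param filter A [filter_config()].
#' @param granularity `"subfamily"` or `"family"` label resolution for
#'   pattern and co-occurrence tables.
#' @param pca_scale Scale category counts to unit variance before PCA.
#' @param protein_is Orientation passed to [read_domtblout()].
#' @return Invisibly, a list with the main in-memory results
#'   (`profiles`, `filtered_hits`, `architectures`, `patterns`,
#'   `group_summaries`, `welch`, `regressions`, `pca`) and `paths`.
#' @export
run_pipeline <- function(domtblout_dir, metadata, out_dir,
                         substrate_map = NULL, filter = filter_config(),
                         granularity = c("subfamily", "family"),
                         pca_scale = FALSE,
                         protein_is = c("target", "query")) {
  granularity <- match.arg(granularity)
  protein_is <- match.arg(protein_is)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  meta <- .stage("metadata", {
    if (is.character(metadata)) read_metadata(metadata) else metadata
  })
  map <- .stage("substrate_map", {
    if (is.null(substrate_map)) default_substrate_map()
    else if (is.character(substrate_map)) load_substrate_map(substrate_map)
    else substrate_map
  })

  files <- list.files(domtblout_dir, pattern = "\\.domtblout$",
                      full.names = TRUE)
  if (!length(files))
    stop("stage 'read_hits' failed: no .domtblout files in directory '",
         domtblout_dir, "'", call. = FALSE)
  hits <- .stage("read_hits", {
    tags <- sub("\\.domtblout$", "", basename(files))
    unknown <- setdiff(tags, meta$tag)
    if (length(unknown))
      stop("domtblout files without metadata rows: ",
           paste(unknown, collapse = ", "))
    do.call(rbind, lapply(seq_along(files), function(i)
      read_domtblout(files[i], tags[i], protein_is = protein_is)))
  })

  filtered <- .stage("filter", filter_organism(hits, filter))
  arch <- .stage("architecture",
                 build_architectures(filtered, granularity))
  patterns <- .stage("patterns", pattern_frequency(arch, granularity))
  coocc <- .stage("cooccurrence", cooccurrence_matrix(arch, granularity))
  prof <- .stage("profiles", build_profiles(meta, filtered, map))

  p <- prof$profiles
  stats_out <- .stage("statistics", {
    gs <- rbind(group_summarize(p$pct_cazyme, p$suborder, "suborder"),
                group_summarize(p$pct_cazyme, p$family, "family"),
                group_summarize(p$pct_cazyme, p$habitat, "habitat"))
    welch <- pairwise_welch(p$pct_cazyme, p$suborder)
    cat_mat <- as.matrix(p[, paste0("n_", CAZY_CATEGORIES)])
    colnames(cat_mat) <- CAZY_CATEGORIES
    rownames(cat_mat) <- p$tag
    total_counts <- rowSums(cat_mat)
    reg_rows <- list()
    if (nrow(p) >= 3 && stats::var(p$genome_size_bp) > 0) {
      regs <- c(list(total_cazyme = total_counts,
                     total_cds = p$total_cds),
                stats::setNames(lapply(CAZY_CATEGORIES,
                                       function(k) cat_mat[, k]),
                                CAZY_CATEGORIES))
      reg_rows <- lapply(names(regs), function(nm) {
        f <- ols_r2(p$genome_size_bp, regs[[nm]])
        data.frame(response = nm, slope = f$slope,
                   intercept = f$intercept, r_squared = f$r_squared,
                   n = f$n, stringsAsFactors = FALSE)
      })
    }
    regressions <- if (length(reg_rows)) do.call(rbind, reg_rows)
                   else data.frame()
    pca <- if (nrow(p) >= 3) pca_counts(cat_mat, scale = pca_scale)
           else NULL
    list(group_summaries = gs, welch = welch,
         regressions = regressions, pca = pca, cat_mat = cat_mat)
  })

  paths <- c(filtered_hits = "filtered_hits.tsv",
             architectures = "architectures.tsv",
             pattern_frequency = "pattern_frequency.tsv",
             cooccurrence = "cooccurrence.tsv",
             profiles = "profiles.tsv",
             family_counts = "family_counts.tsv",
             family_domain_counts = "family_domain_counts.tsv",
             substrate_counts = "substrate_counts.tsv",
             group_summaries = "group_summaries.tsv",
             welch_tests = "welch_tests.tsv",
             regression = "regression.tsv")
  if (!is.null(stats_out$pca))
    paths <- c(paths, pca_variance = "pca_variance.tsv",
               pca_scores = "pca_scores.tsv",
               pca_loadings = "pca_loadings.tsv")
  paths <- stats::setNames(file.path(out_dir, paths), names(paths))
  .stage("write_outputs", {
    write_tsv(filtered, paths[["filtered_hits"]])
    write_tsv(arch, paths[["architectures"]])
    write_tsv(patterns, paths[["pattern_frequency"]])
    write_tsv(coocc, paths[["cooccurrence"]])
    write_tsv(prof$profiles, paths[["profiles"]])
    write_tsv(prof$family_counts, paths[["family_counts"]])
    write_tsv(prof$family_domain_counts, paths[["family_domain_counts"]])
    write_tsv(prof$substrate_counts, paths[["substrate_counts"]])
    write_tsv(stats_out$group_summaries, paths[["group_summaries"]])
    write_tsv(stats_out$welch, paths[["welch_tests"]])
    write_tsv(stats_out$regressions, paths[["regression"]])
    if (!is.null(stats_out$pca)) {
      pv <- data.frame(component = paste0("PC",
                         seq_along(stats_out$pca$variance_fraction)),
                       variance_fraction =
                         stats_out$pca$variance_fraction)
      write_tsv(pv, paths[["pca_variance"]])
      write_tsv(stats_out$pca$scores, paths[["pca_scores"]])
      write_tsv(stats_out$pca$loadings, paths[["pca_loadings"]])
    }
  })

  manifest <- list(
    package = "cazymeR",
    version = as.character(utils::packageVersion("cazymeR")),
    config = list(domtblout_dir = domtblout_dir, out_dir = out_dir,
                  granularity = granularity, pca_scale = pca_scale,
                  protein_is = protein_is,
                  filter = unclass(filter)),
    inputs = {
      x <- tools::md5sum(sort(files))
      stats::setNames(as.list(x), basename(names(x)))
    },
    outputs = {
      x <- tools::md5sum(sort(unname(paths)))
      stats::setNames(as.list(x), basename(names(x)))
    })
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(profiles = prof, filtered_hits = filtered,
                 architectures = arch, patterns = patterns,
                 group_summaries = stats_out$group_summaries,
                 welch = stats_out$welch,
                 regressions = stats_out$regressions,
                 pca = stats_out$pca,
                 category_matrix = stats_out$cat_mat,
                 paths = c(paths, manifest = manifest_path)))
}
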