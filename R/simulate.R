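.default_taxonomy <- function() {
  data.frame(
    suborder = c(rep("Cystobacterineae", 4), rep("Nannocystineae", 2),
                 rep("Sorangiineae", 3)),
    family = c("Myxococcaceae", "Archangiaceae", "Anaeromyxobacteraceae",
               "Vulgatibacteraceae", "Nannocystaceae", "Kofleriaceae",
               "Polyangiaceae", "Sandaracinaceae", "Labilitrichaceae"),
    n_members = c(26L, 11L, 3L, 2L, 4L, 2L, 11L, 1L, 1L),
    pct_mean = c(3.7, 4.4, 3.0, 2.8, 2.2, 2.3, 3.1, 3.3, 3.4),
    pct_sd = c(0.45, 0.45, 0.35, 0.35, 0.25, 0.25, 0.45, 0.3, 0.3),
    genome_min_mb = c(9, 9, 2, 4, 9, 9, 10, 10, 9),
    genome_max_mb = c(11, 13, 5, 5, 12, 10, 14, 11, 10),
    stringsAsFactors = FALSE)
}

.default_genera <- list(
  Myxococcaceae = c("Myxococcus", "Corallococcus"),
  Archangiaceae = c("Archangium", "Cystobacter", "Stigmatella",
                    "Vitiosangium"),
  Anaeromyxobacteraceae = "Anaeromyxobacter",
  Vulgatibacteraceae = "Vulgatibacter",
  Nannocystaceae = c("Nannocystis", "Plesiocystis"),
  Kofleriaceae = "Haliangium",
  Polyangiaceae = c("Sorangium", "Polyangium", "Minicystis"),
  Sandaracinaceae = "Sandaracinus",
  Labilitrichaceae = "Labilithrix")

.default_architecture_pool <- function() {
  data.frame(
    template = c("GT2", "GT4", "GH13", "GH23", "CBM50", "CE1", "CE4",
                 "GH23+CBM50", "GH23+CBM50+CBM50", "GH13_11+CBM48",
                 "GH13_10+CBM48", "GH6+CBM4", "GH9+CBM30", "GH74",
                 "GH18+CBM12", "GH19+CBM13", "GH5", "GH3", "GH2", "GH1",
                 "GH10", "GH43_4+CBM6", "GT2+GT2", "AA2",
                 "GH32+CBM66+CBM66", "CE8+CE8+CE8", "GH28", "PL1",
                 "PL9_2", "GH15", "GH97", "GH57", "GH18+GH18"),
    weight = c(14, 12, 4, 6, 3, 8, 4,
               3, 1.5, 2,
               1.5, 1, 1, 1,
               1.5, 1, 1.5, 3, 2, 1.5,
               1, 1, 1, 0.8,
               0.3, 0.1, 0.4, 0.5,
               0.5, 1, 0.8, 0.8, 0.3),
    stringsAsFactors = FALSE)
}

#' Configuration for the synthetic-data generator
#'
#' The defaults emulate the comparative study conditions: 61 organisms
#' over 3 suborders and 9 families with a Cystobacterineae-heavy sampling
#' (roughly 70/10/20%), 2-16 Mb genomes with CDS counts proportional to
#' genome size, per-family %CAZyme CDS targets in the 2-5% band
#' (Archangiaceae highest, the marine Nannocystineae lowest), and an
#' architecture pool built from the common observed combinatorial
#' patterns (GH23 alone or with CBM50 copies, GH13 subfamilies with
#' CBM48, GH6 with CBM4, triplicated CE8, GH32 with duplicated CBM66,
#' standalone GT2/GT4/CE1, ...).
#'
#' Decoys exercise both filter branches: overlap decoys copy a true hit's
#' interval shifted by under half its length with a 100-10000x worse
#' e-value (they survive the quality filter and must die in overlap
#' resolution); noise hits draw their profile coverage below 0.35 (they
#' must die in the quality filter).
#'
#' @param n_organisms Number of organisms; default the sum of
#'   `taxonomy$n_members` (61). Other values are allocated to families
#'   proportionally.
#' @param taxonomy Data.frame with columns `suborder`, `family`,
#'   `n_members`, `pct_mean`, `pct_sd`, `genome_min_mb`, `genome_max_mb`.
#' @param cds_range Length-2 clamp on the total CDS per organism.
#' @param architecture_pool Data.frame with columns `template`
#'   (`"+"`-joined family labels) and `weight`.
#' @param decoy_overlap_rate Expected overlap decoys per true hit.
#' @param decoy_noise_rate Expected low-coverage noise hits per true hit.
#' @param seed Integer RNG seed; the same seed gives byte-identical
#'   output files.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_organisms = NULL,
                       taxonomy = .default_taxonomy(),
                       cds_range = c(500L, 20000L),
                       architecture_pool = .default_architecture_pool(),
                       decoy_overlap_rate = 0.5,
                       decoy_noise_rate = 0.3,
                       seed = 1L) {
  stopifnot(is.data.frame(taxonomy),
            all(c("suborder", "family", "n_members", "pct_mean",
                  "pct_sd", "genome_min_mb", "genome_max_mb") %in%
                  names(taxonomy)),
            length(cds_range) == 2, cds_range[1] > 0,
            cds_range[2] >= cds_range[1],
            decoy_overlap_rate >= 0, decoy_noise_rate >= 0,
            all(architecture_pool$weight > 0))
  # every family in every template must parse as a CAZyme label
  lapply(strsplit(architecture_pool$template, "+", fixed = TRUE),
         parse_family_label)
  if (is.null(n_organisms)) n_organisms <- sum(taxonomy$n_members)
  stopifnot(n_organisms >= 1)
  structure(list(n_organisms = as.integer(n_organisms),
                 taxonomy = taxonomy, cds_range = cds_range,
                 architecture_pool = architecture_pool,
                 decoy_overlap_rate = decoy_overlap_rate,
                 decoy_noise_rate = decoy_noise_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# deterministic pseudo-HMM profile length for a family label
.hmm_profile_length <- function(family) {
  vapply(family, function(f) {
    h <- sum(utf8ToInt(f) * seq_len(nchar(f)) * 37L)
    100L + (h %% 351L)
  }, integer(1), USE.NAMES = FALSE)
}

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv())) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# largest-remainder allocation of n organisms to taxonomy rows
.allocate_members <- function(taxonomy, n) {
  if (n == sum(taxonomy$n_members)) return(taxonomy$n_members)
  raw <- taxonomy$n_members / sum(taxonomy$n_members) * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

.simulate_true_hits <- function(tag, protein_ids, templates) {
  rows <- vector("list", length(protein_ids))
  for (p in seq_along(protein_ids)) {
    fams <- canonical_family(strsplit(templates[p], "+", fixed = TRUE)[[1]])
    cur <- sample(5:50, 1)
    hr <- vector("list", length(fams))
    for (d in seq_along(fams)) {
      hlen <- .hmm_profile_length(fams[d])
      span <- round(stats::runif(1, 0.75, 0.98) * hlen)
      span <- max(min(span, hlen), ceiling(0.4 * hlen))
      hmm_from <- sample.int(hlen - span + 1L, 1)
      ali_from <- cur
      ali_to <- ali_from + span - 1L
      cur <- ali_to + sample(10:60, 1)
      hr[[d]] <- data.frame(
        protein_id = protein_ids[p], organism_tag = tag,
        family = fams[d], hmm_length = hlen,
        hmm_from = hmm_from, hmm_to = hmm_from + span - 1L,
        ali_from = ali_from, ali_to = ali_to,
        env_from = max(1L, ali_from - sample(0:5, 1)),
        env_to = ali_to + sample(0:5, 1),
        full_seq_evalue = 0, dom_ievalue = 10^stats::runif(1, -60, -25),
        dom_score = round(stats::runif(1, 40, 400), 1),
        stringsAsFactors = FALSE)
    }
    rows[[p]] <- do.call(rbind, hr)
  }
  hits <- do.call(rbind, rows)
  hits$full_seq_evalue <- hits$dom_ievalue / 10
  hits$coverage <- (hits$hmm_to - hits$hmm_from + 1) / hits$hmm_length
  hits
}

.simulate_decoys <- function(true_hits, cfg, pool_families) {
  n <- nrow(true_hits)
  out <- list()
  n_overlap <- stats::rbinom(n, 1, min(1, cfg$decoy_overlap_rate))
  idx <- which(n_overlap == 1)
  if (length(idx)) {
    d <- true_hits[idx, , drop = FALSE]
    span <- d$ali_to - d$ali_from + 1L
    shift <- pmax(1L, as.integer(round(
      span * stats::runif(length(idx), 0.05, 0.45))))
    d$ali_from <- d$ali_from + shift
    d$ali_to <- d$ali_to + shift
    d$env_from <- d$env_from + shift
    d$env_to <- d$env_to + shift
    d$dom_ievalue <- d$dom_ievalue * 10^stats::runif(length(idx), 2, 4)
    d$full_seq_evalue <- d$dom_ievalue / 10
    d$dom_score <- pmax(10, d$dom_score - round(stats::runif(length(idx),
                                                             20, 60), 1))
    out$overlap <- d
  }
  n_noise <- stats::rbinom(n, 1, min(1, cfg$decoy_noise_rate))
  idx <- which(n_noise == 1)
  if (length(idx)) {
    fam <- sample(pool_families, length(idx), replace = TRUE)
    hlen <- .hmm_profile_length(fam)
    span <- pmax(8L, as.integer(round(
      stats::runif(length(idx), 0.05, 0.30) * hlen)))
    hmm_from <- vapply(hlen - span + 1L,
                       function(m) sample.int(m, 1), integer(1))
    ali_from <- sample(1:800, length(idx), replace = TRUE)
    ie <- 10^stats::runif(length(idx), -40, -5)
    out$noise <- data.frame(
      protein_id = true_hits$protein_id[idx],
      organism_tag = true_hits$organism_tag[idx],
      family = fam, hmm_length = hlen,
      hmm_from = hmm_from, hmm_to = hmm_from + span - 1L,
      ali_from = ali_from, ali_to = ali_from + span - 1L,
      env_from = ali_from, env_to = ali_from + span - 1L + 3L,
      full_seq_evalue = ie / 10, dom_ievalue = ie,
      dom_score = round(stats::runif(length(idx), 5, 30), 1),
      coverage = 0, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(NULL)
  d <- do.call(rbind, out)
  d$coverage <- (d$hmm_to - d$hmm_from + 1) / d$hmm_length
  rownames(d) <- NULL
  d
}

#' Generate a synthetic comparative-genomics dataset with ground truth
#'
#' Writes, under `dir`: `metadata.tsv` (taxonomy, habitat, genome size,
#' GC, CDS counts), one `domtblout/<tag>.domtblout` per organism whose
#' true hits realise the sampled domain architectures (plus decoys per the
#' configuration), and ground-truth tables `truth/hits.tsv`,
#' `truth/architectures.tsv`, `truth/profiles.tsv`. With decoy rates zero
#' the filtering pipeline must recover the truth exactly. Marine habitat
#' is assigned to the Nannocystineae; everyone else is soil.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `dir`, `metadata`, `truth_hits`,
#'   `truth_architectures`, `truth_profiles` and the written paths.
#' @export
generate_dataset <- function(cfg = sim_config(), dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(file.path(dir, "domtblout"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  pool <- cfg$architecture_pool
  pool_families <- unique(unlist(strsplit(pool$template, "+",
                                          fixed = TRUE)))
  .with_seed(cfg$seed, {
    members <- .allocate_members(cfg$taxonomy, cfg$n_organisms)
    fam_idx <- rep(seq_len(nrow(cfg$taxonomy)), members)
    n <- length(fam_idx)
    tax <- cfg$taxonomy[fam_idx, , drop = FALSE]
    tags <- sprintf("org%02d", seq_len(n))
    genus <- vapply(tax$family, function(f) {
      g <- .default_genera[[f]]
      if (is.null(g)) paste0(f, "_genus") else sample(g, 1)
    }, character(1), USE.NAMES = FALSE)
    genome_bp <- round(stats::runif(n, tax$genome_min_mb,
                                    tax$genome_max_mb) * 1e6)
    total_cds <- as.integer(pmin(pmax(
      round(genome_bp / 1100 * stats::rnorm(n, 1, 0.04)),
      cfg$cds_range[1]), cfg$cds_range[2]))
    pct_target <- pmin(pmax(stats::rnorm(n, tax$pct_mean, tax$pct_sd),
                            0.2), 10)
    cazyme_cds <- pmax(1L, as.integer(round(pct_target / 100 * total_cds)))
    metadata <- data.frame(
      tag = tags,
      name = paste(genus, "sp.", toupper(tags)),
      suborder = tax$suborder, family = tax$family, genus = genus,
      habitat = ifelse(tax$suborder == "Nannocystineae", "marine", "soil"),
      genome_size_bp = genome_bp,
      gc_percent = round(stats::runif(n, 66, 75), 2),
      total_cds = total_cds, stringsAsFactors = FALSE)
    truth_hits <- vector("list", n)
    for (i in seq_len(n)) {
      templates <- pool$template[sample.int(nrow(pool), cazyme_cds[i],
                                            replace = TRUE,
                                            prob = pool$weight)]
      pids <- sprintf("%s_p%05d", tags[i], seq_len(cazyme_cds[i]))
      true <- .simulate_true_hits(tags[i], pids, templates)
      decoys <- .simulate_decoys(true, cfg, pool_families)
      all_hits <- rbind(true, decoys)
      all_hits <- all_hits[order(all_hits$protein_id, all_hits$ali_from,
                                 all_hits$family), , drop = FALSE]
      write_domtblout(validate_hits(all_hits),
                      file.path(dir, "domtblout",
                                paste0(tags[i], ".domtblout")))
      truth_hits[[i]] <- true
    }
    truth_hits <- validate_hits(do.call(rbind, truth_hits))
    truth_arch <- build_architectures(truth_hits)
    truth_profiles <- build_profiles(metadata, truth_hits)$profiles
    paths <- list(metadata = file.path(dir, "metadata.tsv"),
                  truth_hits = file.path(dir, "truth", "hits.tsv"),
                  truth_architectures = file.path(dir, "truth",
                                                  "architectures.tsv"),
                  truth_profiles = file.path(dir, "truth", "profiles.tsv"))
    write_tsv(metadata, paths$metadata)
    write_tsv(truth_hits, paths$truth_hits)
    write_tsv(truth_arch, paths$truth_architectures)
    write_tsv(truth_profiles, paths$truth_profiles)
    invisible(list(dir = dir, metadata = metadata,
                   truth_hits = truth_hits,
                   truth_architectures = truth_arch,
                   truth_profiles = truth_profiles, paths = paths))
  })
}

# mean of a negative binomial (given size) whose median is m:
# solve P(X <= m-1) + P(X <= m) = 1 so the median straddles m centrally
.nb_mu_for_median <- function(m, size) {
  h <- function(mu) stats::pnbinom(m - 1, size = size, mu = mu) +
    stats::pnbinom(m, size = size, mu = mu) - 1
  stats::uniroot(h, c(max(0.1, 0.2 * m), 4 * m + 10))$root
}

#' Draw a synthetic organisms x categories count matrix
#'
#' Category counts are drawn from negative-binomial distributions
#' parameterised by their median, so the configured medians are the
#' population medians of the draws. Default medians (GH 84, GT 77, CE 63,
#' CBM 62, AA 19, PL 14) and dispersions mirror realistic comparative
#' magnitudes. Dispersion is `1/size` of the negative binomial; a
#' dispersion of 0 yields the configured value exactly for every
#' organism.
#'
#' @param n Number of organisms (rows).
#' @param medians Named numeric vector of target category medians.
#' @param dispersion Named numeric vector (same names) of dispersions.
#' @param seed Optional integer seed (local to this call).
#' @return Integer matrix `n x length(medians)`.
#' @export
generate_count_matrix <- function(n = 61,
                                  medians = c(GH = 84, GT = 77, CE = 63,
                                              CBM = 62, AA = 19, PL = 14),
                                  dispersion = c(GH = 0.27, GT = 0.045,
                                                 CE = 0.09, CBM = 0.29,
                                                 AA = 0.06, PL = 0.23),
                                  seed = NULL) {
  stopifnot(all(names(medians) %in% names(dispersion)))
  draw <- function() {
    cols <- lapply(names(medians), function(k) {
      m <- medians[[k]]; phi <- dispersion[[k]]
      if (phi == 0) return(rep(as.integer(round(m)), n))
      size <- 1 / phi
      mu <- .nb_mu_for_median(round(m), size)
      stats::rnbinom(n, size = size, mu = mu)
    })
    mat <- do.call(cbind, cols)
    colnames(mat) <- names(medians)
    rownames(mat) <- sprintf("org%02d", seq_len(n))
    mat
  }
  if (is.null(seed)) draw() else .with_seed(seed, draw())
}
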