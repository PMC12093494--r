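# Programmatic fixtures: no files on disk, everything built in code.

fixture_families <- c("GH13", "GH13_11", "GH13_10", "GH23", "CBM50",
                      "CBM48", "GH6", "CBM4", "GT2", "GT4", "CE1", "CE8",
                      "PL1", "AA2", "GH74", "GH32", "CBM66", "GH18")

# a valid random hit table (one organism, several proteins)
random_hits <- function(n, n_proteins = max(1L, n %/% 3L),
                        tag = "orgX") {
  fam <- sample(fixture_families, n, replace = TRUE)
  hmm_length <- sample(80:500, n, replace = TRUE)
  span <- pmax(1L, as.integer(round(runif(n, 0.05, 1) * hmm_length)))
  hmm_from <- vapply(hmm_length - span + 1L,
                     function(m) sample.int(m, 1L), integer(1))
  ali_from <- sample(1:900, n, replace = TRUE)
  env_pad_l <- sample(0:4, n, replace = TRUE)
  env_pad_r <- sample(0:4, n, replace = TRUE)
  h <- data.frame(
    protein_id = sprintf("p%03d", sample.int(n_proteins, n,
                                             replace = TRUE)),
    organism_tag = tag,
    family = fam,
    hmm_length = hmm_length,
    hmm_from = hmm_from,
    hmm_to = hmm_from + span - 1L,
    ali_from = ali_from,
    ali_to = ali_from + span - 1L,
    env_from = pmax(1L, ali_from - env_pad_l),
    env_to = ali_from + span - 1L + env_pad_r,
    full_seq_evalue = 10^runif(n, -80, -1),
    dom_ievalue = 10^runif(n, -80, -1),
    dom_score = round(runif(n, 5, 500), 1),
    stringsAsFactors = FALSE)
  h$coverage <- (h$hmm_to - h$hmm_from + 1) / h$hmm_length
  validate_hits(h)
  h
}

# build a hit with explicit coordinates; defaults satisfy all invariants
make_hit <- function(protein_id = "p1", family = "GH13",
                     ali_from = 1L, ali_to = 100L,
                     ievalue = 1e-30, hmm_length = 200L,
                     hmm_from = 1L,
                     hmm_to = hmm_from + (ali_to - ali_from),
                     coverage = NULL, tag = "orgX", score = 100) {
  if (!is.null(coverage)) {
    # place the hmm interval to realise the requested coverage exactly
    span <- as.integer(round(coverage * hmm_length))
    hmm_from <- 1L
    hmm_to <- span
  }
  h <- data.frame(
    protein_id = protein_id, organism_tag = tag, family = family,
    hmm_length = as.integer(hmm_length),
    hmm_from = as.integer(hmm_from), hmm_to = as.integer(hmm_to),
    ali_from = as.integer(ali_from), ali_to = as.integer(ali_to),
    env_from = as.integer(ali_from),
    env_to = as.integer(ali_to) + 2L,
    full_seq_evalue = ievalue / 10, dom_ievalue = ievalue,
    dom_score = score, stringsAsFactors = FALSE)
  h$coverage <- (h$hmm_to - h$hmm_from + 1) / h$hmm_length
  h
}

make_hits <- function(...) {
  h <- do.call(rbind, list(...))
  validate_hits(h)
  h
}

# architectures table straight from domain label vectors
make_architectures <- function(domain_lists, tag = "orgX") {
  do.call(rbind, lapply(seq_along(domain_lists), function(i) {
    d <- domain_lists[[i]]
    labs <- if (length(d) == 1L) "alone"
            else if (length(unique(d)) == 1L) "multi_copy"
            else "with_accessory"
    data.frame(protein_id = sprintf("p%03d", i), organism_tag = tag,
               architecture = paste(d, collapse = "+"), pattern = labs,
               n_domains = length(d), stringsAsFactors = FALSE)
  }))
}

minimal_metadata <- function(tag = "orgX", total_cds = 200L,
                             suborder = "Cystobacterineae",
                             family = "Myxococcaceae",
                             habitat = "soil") {
  data.frame(tag = tag, name = paste0(tag, " sp."), suborder = suborder,
             family = family, genus = "Myxococcus", habitat = habitat,
             genome_size_bp = 9000000L, gc_percent = 70,
             total_cds = total_cds, stringsAsFactors = FALSE)
}
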