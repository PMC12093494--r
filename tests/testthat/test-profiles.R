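test_that("percent CAZyme CDS is exact rational arithmetic", {
  expect_equal(percent_cazyme(493, 9943), 100 * 493 / 9943)
  expect_equal(percent_cazyme(0, 1000), 0)
  expect_equal(percent_cazyme(50, 1000), 5)
  expect_error(percent_cazyme(1, 0), "positive")
  expect_error(percent_cazyme(11, 10), "exceed")
  expect_equal(percent_cazyme(c(1, 2), c(10, 10)), c(10, 20))
})

test_that("category counts are protein-level set membership", {
  arch <- make_architectures(list("GH13", c("GH13", "CBM48")))
  cc <- category_counts(arch)
  expect_equal(cc[["GH"]], 2L)
  expect_equal(cc[["CBM"]], 1L)
  expect_equal(sum(cc), 3L)
  expect_equal(sum(category_counts(arch[0, ])), 0L)
})

test_that("category counts match a brute-force scan on fuzzed proteomes", {
  set.seed(17)
  pool <- c("GH1", "GH13_11", "GT2", "PL1", "CE8", "AA2", "CBM50")
  for (rep in 1:10) {
    doms <- replicate(40, sample(pool, sample(1:4, 1), replace = TRUE),
                      simplify = FALSE)
    expect_equal(category_counts(make_architectures(doms)),
                 naive_category_counts(doms))
  }
})

test_that("substrate counts respect bifunctionality", {
  m <- default_substrate_map()
  amylase <- make_architectures(list("GH13"))
  sc <- substrate_counts(amylase, m)
  expect_equal(sc[["starch"]], 1L)
  expect_equal(sc[["dextran"]], 1L)
  expect_equal(sum(sc), 2L)
  cellulase <- make_architectures(list(c("GH6", "CBM4")))
  sc2 <- substrate_counts(cellulase, m)
  expect_equal(sc2[["cellulose"]], 1L)
  expect_equal(sum(sc2), 1L)
})

test_that("substrate counts match a naive scan and never undercount", {
  set.seed(29)
  m <- default_substrate_map()
  pool <- c("GH13", "GH13_11", "GH6", "GH48", "GH32", "CE8", "GT2",
            "CBM50", "AA2", "GH43_4")
  for (rep in 1:10) {
    doms <- replicate(30, sample(pool, sample(1:3, 1), replace = TRUE),
                      simplify = FALSE)
    arch <- make_architectures(doms)
    got <- substrate_counts(arch, m)
    expect_equal(got, naive_substrate_counts(doms, m))
    mapped <- sum(vapply(doms, function(d)
      any(vapply(d, function(f)
        length(substrates_for_family(m, f)) > 0, logical(1))),
      logical(1)))
    expect_gte(sum(got), mapped)   # bifunctionality inflates, never deflates
  }
})

test_that("organism profiles assemble counts, percentages and metadata", {
  meta <- minimal_metadata("orgX", total_cds = 200L)
  hits <- do.call(rbind, lapply(1:10, function(i)
    make_hit(sprintf("p%02d", i), "GH23",
             ali_from = 10L, ali_to = 200L)))
  prof <- build_profile(meta, validate_hits(hits))
  expect_equal(prof$cazyme_cds, 10L)
  expect_equal(prof$pct_cazyme, 5.0)
  expect_equal(prof$n_GH, 10L)
  expect_equal(prof$n_chitin, 10L)
  # zero hits: all counts zero
  p0 <- build_profile(meta, hits[0, ])
  expect_equal(p0$cazyme_cds, 0L)
  expect_equal(p0$pct_cazyme, 0)
  expect_equal(p0$n_GH + p0$n_cellulose, 0L)
  expect_error(build_profile(transform(meta, total_cds = NA), hits[0, ]),
               "total_cds")
})

test_that("profiles recover the generator's planted truth without noise", {
  cfg <- sim_config(n_organisms = 5, cds_range = c(150L, 300L), seed = 13,
                    decoy_overlap_rate = 0, decoy_noise_rate = 0)
  dir <- withr::local_tempdir()
  truth <- generate_dataset(cfg, dir)
  files <- list.files(file.path(dir, "domtblout"), full.names = TRUE)
  hits <- validate_hits(do.call(rbind, lapply(files, read_domtblout)))
  filtered <- filter_organism(hits)
  prof <- build_profiles(truth$metadata, filtered)
  expect_equal(prof$profiles, truth$truth_profiles)
  # cazyme_cds equals the number of architectures per organism
  arch <- build_architectures(filtered)
  expect_equal(prof$profiles$cazyme_cds,
               as.integer(table(arch$organism_tag)[prof$profiles$tag]))
})

test_that("GC content ignores ambiguity codes and rejects empty bases", {
  expect_equal(gc_percent("GGCC"), 100)
  expect_equal(gc_percent("ATGC"), 50)
  expect_equal(gc_percent("ATGCNNN"), 50)
  expect_equal(gc_percent("atgc"), 50)
  expect_error(gc_percent("NNN"), "unambiguous")
})

test_that("metadata derives CDS counts from GFF3 and GC from FASTA", {
  skip_if_not_installed("rtracklayer")
  skip_if_not_installed("Biostrings")
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tgene\t1\t900\t.\t+\t.\tID=gene1",
    "chr1\tx\tCDS\t1\t300\t.\t+\t0\tID=cds1;Parent=gene1",
    "chr1\tx\tCDS\t400\t900\t.\t+\t0\tID=cds1;Parent=gene1",
    "chr1\tx\tCDS\t950\t1200\t.\t+\t0\tID=cds2;Parent=gene1"), gff)
  expect_equal(count_cds_gff(gff), 2L)  # split CDS counted once by ID
  fasta <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", "ATGCATGCGG", "CCNNNN"), fasta)
  d <- derive_metadata(fasta, gff)
  expect_equal(d$genome_size_bp, 16L)
  expect_equal(d$gc_percent, 100 * 8 / 12)  # ATGCATGCGGCC: 8 G/C of 12
  expect_equal(d$total_cds, 2L)
})

test_that("metadata files round-trip and fill CDS counts from GFF paths", {
  meta <- minimal_metadata()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(meta, path)
  back <- read_metadata(path)
  expect_equal(back$tag, "orgX")
  expect_equal(back$total_cds, 200L)
  bad <- meta; bad$habitat <- "lunar"
  write_tsv(bad, path)
  expect_error(read_metadata(path), "habitat")
})
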