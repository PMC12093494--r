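test_that("quality filter applies the coverage and e-value predicate", {
  cfg <- filter_config()
  low_cov <- make_hit("p1", "GH5", 1, 100, ievalue = 1e-50,
                      coverage = 0.34)
  good <- make_hit("p1", "GH6", 200, 380, ievalue = 1e-30,
                   coverage = 0.90)
  weak_long <- make_hit("p1", "GH9", 400, 520, ievalue = 1e-10,
                        coverage = 0.60)
  weak_short <- make_hit("p1", "CBM4", 600, 650, ievalue = 1e-10,
                         coverage = 0.60)
  hits <- make_hits(low_cov, good, weak_long, weak_short)
  kept <- quality_filter(hits, cfg)
  # low coverage dies; strong hit lives; 1e-10 needs the short-alignment
  # relaxation (<80 residues) to survive
  expect_equal(kept$family, c("GH6", "CBM4"))
})

test_that("quality filter equals an independent per-hit predicate scan", {
  set.seed(5)
  cfg <- filter_config()
  for (rep in 1:10) {
    hits <- random_hits(20)
    kept <- quality_filter(hits, cfg)
    manual <- logical(nrow(hits))
    for (i in seq_len(nrow(hits))) {
      len <- hits$ali_to[i] - hits$ali_from[i] + 1
      pass_e <- hits$dom_ievalue[i] <= 1e-15 ||
        (len < 80 && hits$dom_ievalue[i] <= 1e-3)
      manual[i] <- hits$coverage[i] >= 0.35 && pass_e
    }
    expect_equal(as.data.frame(kept),
                 as.data.frame(hits[manual, ]), ignore_attr = TRUE)
  }
})

test_that("the better e-value wins between two heavily overlapping hits", {
  a <- make_hit("p1", "GH13", 1, 100, ievalue = 1e-50)
  b <- make_hit("p1", "GH13", 41, 140, ievalue = 1e-20)  # 60% of shorter
  kept <- resolve_overlaps(make_hits(a, b))
  expect_equal(nrow(kept), 1)
  expect_equal(kept$dom_ievalue, 1e-50)
})

test_that("disjoint hits are all kept, ordered by position", {
  a <- make_hit("p1", "CBM50", 220, 260, ievalue = 1e-20)
  b <- make_hit("p1", "GH23", 10, 200, ievalue = 1e-60)
  kept <- resolve_overlaps(make_hits(a, b))
  expect_equal(kept$family, c("GH23", "CBM50"))
  expect_equal(kept$ali_from, c(10L, 220L))
})

test_that("greedy chain resolution matches brute-force enumeration", {
  # B overlaps A by 60% of the shorter interval (conflict) and C by 20%
  # (tolerated); B still dies because A, with the better e-value, is
  # accepted first
  a <- make_hit("p1", "GH5", 1, 100, ievalue = 1e-40)
  b <- make_hit("p1", "GH6", 41, 140, ievalue = 1e-10)
  c_ <- make_hit("p1", "GH9", 121, 220, ievalue = 1e-30)
  hits <- make_hits(a, b, c_)
  kept <- resolve_overlaps(hits)
  expect_equal(kept$family, c("GH5", "GH9"))  # A and C survive, B dies
  # the greedy answer must be one of the pairwise-compatible subsets and
  # must match the definitional naive greedy
  subsets <- compatible_subsets(hits)
  expect_true(any(vapply(subsets, setequal, logical(1), y = c(1, 3))))
  expect_equal(as.data.frame(kept), as.data.frame(naive_resolve(hits)),
               ignore_attr = TRUE)
})

test_that("resolution equals its definition on fuzzed proteins", {
  set.seed(99)
  cfg <- filter_config()
  for (rep in 1:40) {
    hits <- random_hits(sample(2:6, 1), n_proteins = 1)
    kept <- resolve_overlaps(hits, cfg)
    expect_equal(as.data.frame(kept),
                 as.data.frame(naive_resolve(hits, cfg)),
                 ignore_attr = TRUE)
    # accepted set is pairwise compatible (enumeration oracle)
    subsets <- compatible_subsets(hits, cfg)
    members <- which(paste(hits$family, hits$ali_from, hits$dom_ievalue)
                     %in% paste(kept$family, kept$ali_from,
                                kept$dom_ievalue))
    expect_true(any(vapply(subsets, setequal, logical(1), y = members)))
  }
})

test_that("resolution is idempotent, order-independent and subsetting", {
  set.seed(7)
  for (rep in 1:20) {
    hits <- random_hits(8, n_proteins = 1)
    kept <- resolve_overlaps(hits)
    expect_lte(nrow(kept), nrow(hits))
    expect_equal(resolve_overlaps(kept), kept)
    shuffled <- hits[sample(nrow(hits)), ]
    expect_equal(as.data.frame(resolve_overlaps(shuffled)),
                 as.data.frame(kept), ignore_attr = TRUE)
    # no retained pair exceeds the overlap cap
    if (nrow(kept) >= 2) {
      for (i in 1:(nrow(kept) - 1)) for (j in (i + 1):nrow(kept)) {
        ov <- max(0, min(kept$ali_to[i], kept$ali_to[j]) -
                    max(kept$ali_from[i], kept$ali_from[j]) + 1)
        shorter <- min(kept$ali_to[i] - kept$ali_from[i] + 1,
                       kept$ali_to[j] - kept$ali_from[j] + 1)
        expect_lte(ov, 0.5 * shorter)
      }
    }
  }
})

test_that("mixed proteins are rejected by resolve_overlaps", {
  hits <- make_hits(make_hit("p1"), make_hit("p2", ali_from = 300,
                                             ali_to = 400))
  expect_error(resolve_overlaps(hits), "single protein")
})

test_that("same-family-only mode lets cross-family overlaps stand", {
  a <- make_hit("p1", "GH13", 1, 100, ievalue = 1e-50)
  b <- make_hit("p1", "CBM48", 30, 129, ievalue = 1e-20)
  cfg <- filter_config(same_family_only = TRUE)
  expect_equal(nrow(resolve_overlaps(make_hits(a, b), cfg)), 2)
  expect_equal(nrow(resolve_overlaps(make_hits(a, b))), 1)
})

test_that("filter_organism prunes per protein and drops empty proteins", {
  expect_equal(nrow(filter_organism(random_hits(5)[0, ])), 0)
  one <- make_hits(make_hit("p1"))
  expect_equal(as.data.frame(filter_organism(one)), as.data.frame(one),
               ignore_attr = TRUE)
  # a protein whose only hit fails quality vanishes from the table
  bad <- make_hit("p2", "GH5", 1, 60, ievalue = 1e-4, coverage = 0.10)
  both <- make_hits(make_hit("p1"), bad)
  out <- filter_organism(both)
  expect_equal(unique(out$protein_id), "p1")
})

test_that("planted architectures are recovered exactly from decoy-laden data", {
  cfg <- sim_config(n_organisms = 4, cds_range = c(150L, 300L), seed = 31,
                    decoy_overlap_rate = 0.8, decoy_noise_rate = 0.8)
  dir <- withr::local_tempdir()
  truth <- generate_dataset(cfg, dir)
  files <- list.files(file.path(dir, "domtblout"), full.names = TRUE)
  hits <- do.call(rbind, lapply(files, read_domtblout))
  expect_gt(nrow(hits), nrow(truth$truth_hits))  # decoys really present
  kept <- filter_organism(validate_hits(hits), filter_config())
  # precision = recall = 1: retained hits identical to the planted ones
  key <- function(h) sort(paste(h$organism_tag, h$protein_id, h$family,
                                h$ali_from, h$ali_to))
  expect_identical(key(kept), key(truth$truth_hits))
})
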