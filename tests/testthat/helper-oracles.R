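# Independent oracles, deliberately written with different code paths
# than the implementation they check.

# quadratic-scan greedy overlap resolution straight from its definition
naive_resolve <- function(hits, cfg = filter_config()) {
  idx <- seq_len(nrow(hits))
  key <- order(hits$dom_ievalue, -hits$coverage, hits$family,
               hits$ali_from, hits$ali_to)
  overlap_len <- function(i, j) {
    lo <- max(hits$ali_from[i], hits$ali_from[j])
    hi <- min(hits$ali_to[i], hits$ali_to[j])
    max(0L, hi - lo + 1L)
  }
  ilen <- function(i) hits$ali_to[i] - hits$ali_from[i] + 1L
  acc <- integer(0)
  for (i in key) {
    ok <- TRUE
    for (j in acc) {
      frac_cap <- cfg$overlap_fraction * min(ilen(i), ilen(j))
      same <- hits$family[i] == hits$family[j]
      if (overlap_len(i, j) > frac_cap &&
          (!cfg$same_family_only || same)) { ok <- FALSE; break }
    }
    if (ok) acc <- c(acc, i)
  }
  out <- hits[sort(acc), , drop = FALSE]
  out[order(out$ali_from, out$ali_to, out$family, out$dom_ievalue), ,
      drop = FALSE]
}

# all pairwise-compatible subsets of <= n hits (for maximality checks)
compatible_subsets <- function(hits, cfg = filter_config()) {
  n <- nrow(hits)
  stopifnot(n <= 10)
  ok_pair <- function(i, j) {
    lo <- max(hits$ali_from[i], hits$ali_from[j])
    hi <- min(hits$ali_to[i], hits$ali_to[j])
    ov <- max(0L, hi - lo + 1L)
    li <- hits$ali_to[i] - hits$ali_from[i] + 1L
    lj <- hits$ali_to[j] - hits$ali_from[j] + 1L
    ov <= cfg$overlap_fraction * min(li, lj)
  }
  subsets <- list()
  for (mask in 0:(2^n - 1)) {
    members <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    good <- TRUE
    if (length(members) >= 2) {
      prs <- utils::combn(members, 2)
      for (k in seq_len(ncol(prs)))
        if (!ok_pair(prs[1, k], prs[2, k])) { good <- FALSE; break }
    }
    if (good) subsets[[length(subsets) + 1L]] <- members
  }
  subsets
}

# order-statistics summary computed by hand (sorting, no quantile())
naive_summary <- function(v) {
  s <- sort(v)
  n <- length(s)
  med <- if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  q7 <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }
  sdv <- if (n >= 2) sqrt(sum((v - mean(v))^2) / (n - 1)) else NA_real_
  list(median = med, sd = sdv, q1 = q7(0.25), q3 = q7(0.75))
}

# protein-level category counting by a plain double loop
naive_category_counts <- function(domain_lists) {
  out <- setNames(integer(length(CAZY_CATEGORIES)), CAZY_CATEGORIES)
  for (d in domain_lists) {
    seen <- character(0)
    for (lab in d) {
      cat_ <- regmatches(lab, regexpr("^[A-Z]+", lab))
      if (!cat_ %in% seen) {
        out[cat_] <- out[cat_] + 1L
        seen <- c(seen, cat_)
      }
    }
  }
  out
}

naive_substrate_counts <- function(domain_lists, map) {
  out <- setNames(integer(length(SUBSTRATES)), SUBSTRATES)
  for (d in domain_lists) {
    subs <- character(0)
    for (lab in d)
      subs <- union(subs, substrates_for_family(map, lab))
    for (s in subs) out[s] <- out[s] + 1L
  }
  out
}

# protein-level co-occurrence by nested scan
naive_cooccurrence <- function(domain_lists, focal) {
  counts <- list()
  for (d in domain_lists) {
    fams <- unique(d)
    if (!(focal %in% fams)) next
    partners <- setdiff(fams, focal)
    if (!length(partners)) partners <- "self"
    for (p in partners)
      counts[[p]] <- (if (is.null(counts[[p]])) 0L else counts[[p]]) + 1L
  }
  counts
}
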