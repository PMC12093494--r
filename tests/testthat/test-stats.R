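test_that("group summaries give medians, sample SDs and type-7 quartiles", {
  gs <- group_summarize(c(1, 2, 3), rep("g", 3))
  expect_equal(gs$median, 2)
  expect_equal(gs$sample_sd, 1)
  flat <- group_summarize(c(2, 2, 2, 2), rep("g", 4))
  expect_equal(flat$median, 2)
  expect_equal(flat$sample_sd, 0)
  expect_error(group_summarize(1:3, c("a", NA, "b")), "label")
  expect_warning(
    group_summarize(1:3, factor(rep("a", 3), levels = c("a", "b"))),
    "empty")
})

test_that("group summaries match hand-rolled order statistics", {
  set.seed(3)
  for (rep in 1:20) {
    v <- round(rnorm(sample(2:25, 1), 50, 20), 3)
    g <- sample(c("x", "y", "z"), length(v), replace = TRUE)
    keep <- names(which(table(g) > 0))
    gs <- group_summarize(v, g)
    for (lab in keep) {
      want <- naive_summary(v[g == lab])
      row <- gs[gs$group == lab, ]
      expect_equal(row$median, want$median)
      expect_equal(row$sample_sd, want$sd)
      expect_equal(row$q1, want$q1)
      expect_equal(row$q3, want$q3)
      expect_true(row$q1 <= row$median && row$median <= row$q3)
    }
  }
  # one group over everything equals the ungrouped summary
  v <- rnorm(15)
  all_in_one <- group_summarize(v, rep("all", 15))
  expect_equal(all_in_one$median, median(v))
  expect_equal(all_in_one$sample_sd, sd(v))
})

test_that("welch test matches the textbook formula and stats::t.test", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  w <- welch_test(a, b)
  # direct Welch-Satterthwaite evaluation
  se2 <- var(a) / 3 + var(b) / 3
  t_manual <- (mean(a) - mean(b)) / sqrt(se2)
  dof_manual <- se2^2 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(w$t_statistic, t_manual)
  expect_equal(w$dof, dof_manual)
  expect_equal(w$p_value, 2 * pt(-abs(t_manual), dof_manual))
  ref <- t.test(a, b)                     # independent implementation
  expect_equal(w$t_statistic, unname(ref$statistic))
  expect_equal(w$dof, unname(ref$parameter))
  expect_equal(w$p_value, ref$p.value)
  set.seed(8)
  for (rep in 1:10) {
    x <- rnorm(sample(3:12, 1)); y <- rnorm(sample(3:12, 1), 1)
    ref <- t.test(x, y)
    got <- welch_test(x, y)
    expect_equal(got$p_value, ref$p.value)
    expect_equal(got$t_statistic, unname(ref$statistic))
  }
})

test_that("welch test is symmetric, shift-invariant and degenerate-safe", {
  a <- c(3, 1, 4, 1, 5)
  expect_equal(welch_test(a, a)$t_statistic, 0)
  expect_equal(welch_test(a, a)$p_value, 1)
  b <- c(2, 7, 1, 8)
  fwd <- welch_test(a, b); rev <- welch_test(b, a)
  expect_equal(fwd$p_value, rev$p_value)
  expect_equal(fwd$t_statistic, -rev$t_statistic)
  shifted <- welch_test(a + 100, b + 100)
  expect_equal(shifted$p_value, fwd$p_value)
  # zero-variance samples must not divide by zero
  same <- welch_test(c(2, 2), c(2, 2))
  expect_equal(c(same$t_statistic, same$p_value), c(0, 1))
  diff <- welch_test(c(2, 2), c(5, 5))
  expect_equal(diff$p_value, 0)
  expect_true(is.infinite(diff$t_statistic))
})

test_that("regression recovers exact lines and orthogonal noise", {
  x <- 1:10
  exact <- ols_r2(x, 2 * x + 1)
  expect_equal(exact$r_squared, 1)
  expect_equal(exact$slope, 2)
  expect_equal(exact$intercept, 1)
  # a response orthogonal to the centered predictor: R^2 = 0
  y <- c(1, -1, -1, 1)
  xo <- c(-1, -0.5, 0.5, 1)
  expect_equal(ols_r2(xo, y)$r_squared, 0)
  expect_error(ols_r2(rep(1, 5), 1:5), "constant")
  expect_equal(ols_r2(1:5, rep(3, 5))$r_squared, 0)
})

test_that("R^2 equals the squared Pearson correlation on noisy lines", {
  set.seed(21)
  for (rep in 1:10) {
    x <- runif(30, 0, 10)
    y <- 3 * x + rnorm(30, 0, 2)
    f <- ols_r2(x, y)
    expect_equal(f$r_squared, cor(x, y)^2)
    # scale invariance of R^2
    expect_equal(ols_r2(x, (y - mean(y)) / sd(y))$r_squared, f$r_squared)
  }
})

test_that("PCA variance fractions match an independent SVD", {
  set.seed(14)
  m <- matrix(rnbinom(20 * 6, mu = 50, size = 5), 20, 6,
              dimnames = list(NULL, CAZY_CATEGORIES))
  p <- pca_counts(m)
  centered <- scale(m, center = TRUE, scale = FALSE)
  sv <- svd(centered)$d
  expect_equal(p$variance_fraction, sv^2 / sum(sv^2))
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-12)
  expect_true(all(diff(p$variance_fraction) <= 1e-12))
  # loadings orthonormal
  expect_equal(crossprod(p$loadings), diag(6), ignore_attr = TRUE)
  # sign convention: dominant loading of every component positive
  for (j in 1:6)
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
})

test_that("PCA handles degenerate structure as specified", {
  m <- cbind(GH = c(1, 5, 9, 13), GT = 2, PL = 2, CE = 2, AA = 2, CBM = 2)
  p <- pca_counts(m)
  expect_equal(p$variance_fraction[1], 1)
  expect_true(all(abs(p$variance_fraction[-1]) < 1e-12))
  # duplicated organisms score identically
  m2 <- matrix(rpois(5 * 6, 30), 5, 6)
  m2 <- rbind(m2, m2[2, ])
  p2 <- pca_counts(m2)
  expect_equal(p2$scores[6, ], p2$scores[2, ])
  expect_error(pca_counts(m, scale = TRUE), "GT")
  expect_error(pca_counts(m[1:2, ]))
})

test_that("pairwise welch covers all group pairs and supports adjustment", {
  set.seed(2)
  v <- c(rnorm(5), rnorm(5, 3), rnorm(5, 6), 1)   # + a singleton group
  g <- c(rep("a", 5), rep("b", 5), rep("c", 5), "d")
  pw <- pairwise_welch(v, g)
  expect_equal(nrow(pw), 3)            # singleton group skipped
  expect_setequal(paste(pw$group1, pw$group2),
                  c("a b", "a c", "b c"))
  direct <- welch_test(v[g == "a"], v[g == "b"])
  expect_equal(pw$p_value[pw$group1 == "a" & pw$group2 == "b"],
               direct$p_value)
  adj <- pairwise_welch(v, g, adjust = "bonferroni")
  expect_equal(adj$p_adjusted, pmin(1, adj$p_value * 3))
})
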