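#' Per-group order-statistic summaries
#'
#' Median (midpoint of the two central order statistics for even n),
#' sample standard deviation (n - 1 denominator, `NA` for singleton
#' groups) and type-7 linearly interpolated quartiles, per group label.
#'
#' @param values Numeric vector, one value per organism.
#' @param groups Character/factor vector of group labels, same length;
#'   `NA` labels are an error.
#' @param level Optional name of the grouping level (e.g. `"suborder"`),
#'   recorded in the output.
#' @return Data.frame with columns `group`, `level`, `n`, `median`,
#'   `sample_sd`, `q1`, `q3`. Declared factor levels without members are
#'   omitted with a warning.
#' @export
group_summarize <- function(values, groups, level = NA_character_) {
  stopifnot(length(values) == length(groups))
  if (anyNA(groups))
    stop("every organism must carry a group label")
  groups <- as.factor(groups)
  empty <- levels(groups)[tabulate(groups, nbins = nlevels(groups)) == 0L]
  if (length(empty))
    warning("omitting empty group(s): ", paste(empty, collapse = ", "))
  present <- setdiff(levels(groups), empty)
  rows <- lapply(present, function(g) {
    v <- values[groups == g]
    q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    data.frame(group = g, level = level, n = length(v),
               median = stats::median(v),
               sample_sd = if (length(v) >= 2) stats::sd(v) else NA_real_,
               q1 = q[1], q3 = q[2], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Welch's two-sample t-test
#'
#' Unequal-variance location test:
#' `t = (mean(a) - mean(b)) / sqrt(var(a)/na + var(b)/nb)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value from the
#' Student-t distribution. Degenerate inputs are handled without division
#' failure: two zero-variance samples with equal means give `t = 0, p = 1`;
#' zero pooled variance with unequal means gives an infinite statistic and
#' `p = 0`.
#'
#' @param a,b Numeric samples, each of length at least 2.
#' @param labels Character pair naming the two groups.
#' @return Object of class `welch_test` with elements `t_statistic`,
#'   `dof`, `p_value`, `groups`, `means`, `n`.
#' @export
welch_test <- function(a, b, labels = c("a", "b")) {
  stopifnot(length(a) >= 2, length(b) >= 2, length(labels) == 2)
  na <- length(a); nb <- length(b)
  ma <- mean(a); mb <- mean(b)
  va <- stats::var(a); vb <- stats::var(b)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    if (ma == mb) {
      t <- 0; p <- 1; dof <- Inf
    } else {
      t <- sign(ma - mb) * Inf; p <- 0; dof <- Inf
    }
  } else {
    t <- (ma - mb) / sqrt(se2)
    dof <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * stats::pt(-abs(t), dof)
  }
  structure(list(t_statistic = t, dof = dof, p_value = p,
                 groups = labels, means = c(ma, mb), n = c(na, nb)),
            class = "welch_test")
}

#' @export
print.welch_test <- function(x, ...) {
  cat("Welch two-sample t-test: ", x$groups[1], " (n=", x$n[1], ") vs ",
      x$groups[2], " (n=", x$n[2], ")\n",
      "  t = ", format(x$t_statistic, digits = 4),
      ", df = ", format(x$dof, digits = 4),
      ", p = ", format(x$p_value, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Ordinary least-squares fit and coefficient of determination
#'
#' Simple linear regression via [stats::lm()];
#' `r_squared = 1 - SSres/SStot`, which for a single predictor equals the
#' squared Pearson correlation. A constant response gives `r_squared = 0`
#' by convention; a constant predictor is an error.
#'
#' @param x Predictor (numeric, length >= 3, non-constant).
#' @param y Response (numeric, same length).
#' @return Object of class `ols_fit` with `slope`, `intercept`,
#'   `r_squared`, `n` and the underlying `lm` fit.
#' @export
ols_r2 <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::var(x) == 0)
    stop("predictor is constant; regression is undefined")
  fit <- stats::lm(y ~ x)
  # 1 - SSres/SStot, computed directly (summary.lm warns on exact fits)
  r2 <- if (stats::var(y) == 0) 0
        else 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, n = length(x), fit = fit),
            class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat("OLS fit (n=", x$n, "): y = ",
      format(x$slope, digits = 4), " * x + ",
      format(x$intercept, digits = 4),
      ",  R^2 = ", format(x$r_squared, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Principal component analysis of category count vectors
#'
#' Centered (and optionally unit-variance scaled) PCA via
#' [stats::prcomp()] of an organisms x categories count matrix. The sign
#' of each component is fixed so that its largest-magnitude loading is
#' positive, making results reproducible across linear-algebra backends.
#'
#' @param mat Numeric matrix or data.frame, organisms in rows (at least
#'   3), count variables in columns, no missing cells.
#' @param scale If `TRUE`, scale columns to unit variance (correlation
#'   PCA). Default `FALSE`: covariance PCA, the [stats::prcomp()]
#'   default.
#' @return Object of class `pca_counts` with `variance_fraction`
#'   (non-increasing, sums to 1), `loadings` (orthonormal columns),
#'   `scores` and `sdev`.
#' @export
pca_counts <- function(mat, scale = FALSE) {
  mat <- as.matrix(mat)
  stopifnot(is.numeric(mat), nrow(mat) >= 3)
  if (anyNA(mat)) stop("count matrix contains missing cells")
  if (scale) {
    v <- apply(mat, 2, stats::var)
    if (any(v == 0)) {
      cols <- colnames(mat)[v == 0]
      if (is.null(cols)) cols <- which(v == 0)
      stop("cannot scale zero-variance column(s): ",
           paste(cols, collapse = ", "))
    }
  }
  p <- stats::prcomp(mat, center = TRUE, scale. = scale)
  for (j in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  structure(list(variance_fraction = p$sdev^2 / sum(p$sdev^2),
                 loadings = p$rotation, scores = p$x, sdev = p$sdev),
            class = "pca_counts")
}

#' @export
print.pca_counts <- function(x, ...) {
  vf <- sprintf("%.2f%%", 100 * x$variance_fraction)
  cat("PCA of count matrix (", nrow(x$scores), " organisms):\n  ",
      paste(paste0("PC", seq_along(vf), " ", vf), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' All pairwise Welch tests across groups
#'
#' @param values Numeric vector.
#' @param groups Group labels (same length). Groups with fewer than two
#'   members are skipped.
#' @return Data.frame with columns `group1`, `group2`, `n1`, `n2`,
#'   `t_statistic`, `dof`, `p_value`, plus `p_adjusted` when `adjust` is
#'   not `"none"`.
#' @param adjust Multiple-testing correction passed to
#'   [stats::p.adjust()]; default `"none"` (raw pairwise p-values).
#' @export
pairwise_welch <- function(values, groups, adjust = "none") {
  stopifnot(length(values) == length(groups))
  groups <- as.character(groups)
  labs <- names(which(table(groups) >= 2))
  labs <- sort(labs)
  if (length(labs) < 2)
    return(data.frame(group1 = character(0), group2 = character(0),
                      n1 = integer(0), n2 = integer(0),
                      t_statistic = numeric(0), dof = numeric(0),
                      p_value = numeric(0), stringsAsFactors = FALSE))
  pairs <- utils::combn(labs, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    w <- welch_test(values[groups == g1], values[groups == g2],
                    labels = c(g1, g2))
    data.frame(group1 = g1, group2 = g2, n1 = w$n[1], n2 = w$n[2],
               t_statistic = w$t_statistic, dof = w$dof,
               p_value = w$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust != "none")
    out$p_adjusted <- stats::p.adjust(out$p_value, method = adjust)
  rownames(out) <- NULL
  out
}
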