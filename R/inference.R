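#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up FDR adjustment. Rejections at level `q` are exactly the p-values
#' whose adjusted value is at most `q`; adjusted values are monotone
#' non-decreasing in raw-p rank and never smaller than the raw p.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return list with `p_adj` and logical `reject`.
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  p_adj <- stats::p.adjust(pvals, method = "BH")
  list(p_adj = p_adj, reject = p_adj <= q)
}

#' Partial correlation controlling for covariates
#'
#' Residualizes `x` and `y` on an intercept plus the covariates by least
#' squares, then computes the Pearson correlation of the residuals. The
#' p-value uses `t = r * sqrt((n - 2 - k) / (1 - r^2))` on `n - 2 - k`
#' degrees of freedom for `k` covariates.
#'
#' @param x,y numeric vectors of equal length `n > k + 3`.
#' @param covariates numeric matrix or data.frame with `k` columns.
#' @return list of class `partial_correlation`: `r`, `p`, `df`, `n`.
#' @export
partial_correlation <- function(x, y, covariates) {
  covariates <- as.matrix(as.data.frame(covariates))
  n <- length(x)
  k <- ncol(covariates)
  if (length(y) != n || nrow(covariates) != n)
    stop("x, y and covariates must have matching lengths")
  if (n <= k + 3) stop("need n > k + 3 observations (n = ", n, ", k = ", k, ")")
  X <- cbind(1, covariates)
  qrX <- qr(X)
  rx <- qr.resid(qrX, x)
  ry <- qr.resid(qrX, y)
  tol <- 1e-10
  if (stats::sd(rx) <= tol * max(1, stats::sd(x)) ||
      stats::sd(ry) <= tol * max(1, stats::sd(y)))
    stop("x or y is constant after residualization")
  r <- stats::cor(rx, ry)
  df <- n - 2 - k
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt(df / (1 - r^2))
    2 * stats::pt(-abs(tval), df)
  }
  structure(list(r = r, p = p, df = df, n = n), class = "partial_correlation")
}

#' Partial correlations of several pairs with Bonferroni correction
#'
#' Runs [partial_correlation()] for every requested (x, y) column pair of a
#' per-subject table and applies a Bonferroni correction over the number of
#' tests actually performed.
#'
#' @param data data.frame with one row per subject.
#' @param pairs data.frame or 2-column matrix of column-name pairs (x, y).
#' @param covariates covariate column names (default age, sex, bmi, tiv).
#' @return data.frame with `x`, `y`, `r`, `p`, `p_bonf`.
#' @export
clinical_correlations <- function(data, pairs,
                                  covariates = c("age", "sex", "bmi", "tiv")) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (ncol(pairs) != 2) stop("pairs must have two columns (x, y)")
  covmat <- sapply(covariates, function(nm) {
    v <- data[[nm]]
    if (is.null(v)) stop("covariate '", nm, "' not in data")
    if (nm == "sex" || is.character(v) || is.factor(v)) sex_indicator(v)
    else as.numeric(v)
  })
  m <- nrow(pairs)
  out <- do.call(rbind, lapply(seq_len(m), function(i) {
    xn <- pairs[i, 1]; yn <- pairs[i, 2]
    if (is.null(data[[xn]])) stop("no column '", xn, "' in data")
    if (is.null(data[[yn]])) stop("no column '", yn, "' in data")
    pc <- partial_correlation(as.numeric(data[[xn]]), as.numeric(data[[yn]]),
                              covmat)
    data.frame(x = xn, y = yn, r = pc$r, p = pc$p,
               stringsAsFactors = FALSE)
  }))
  out$p_bonf <- pmin(1, out$p * m)
  out
}

#' Two-sample t-test from summary statistics
#'
#' Pooled-variance two-sided t statistic computed from group means,
#' standard deviations and sizes, as used to check printed cohort tables.
#'
#' @param m1,s1,n1 mean, SD and size of group 1.
#' @param m2,s2,n2 mean, SD and size of group 2.
#' @return list with `t`, `df`, `p`.
#' @export
t_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  tval <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}

#' Power of a two-sided two-sample t-test
#'
#' Uses the noncentral t distribution with `df = n1 + n2 - 2` and
#' noncentrality `d * sqrt(n1 n2 / (n1 + n2))` for Cohen's d.
#'
#' @param d standardized effect size (Cohen's d), non-negative.
#' @param n1,n2 group sizes.
#' @param alpha two-sided significance level in (0, 1).
#' @return scalar power.
#' @export
two_sample_power <- function(d, n1, n2, alpha = 0.05) {
  if (d < 0) stop("effect size d must be non-negative")
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  tcrit <- stats::qt(1 - alpha / 2, df)
  stats::pt(-tcrit, df, ncp) + 1 - stats::pt(tcrit, df, ncp)
}

#' Descriptive group comparison of cohort variables
#'
#' Per variable: group means and SDs, then a pooled-variance two-sample
#' t-test when Shapiro-Wilk (at 0.05, per group) does not reject normality
#' in either group, otherwise a Mann-Whitney U test. `sex` is compared with
#' a Pearson chi-square test without continuity correction.
#'
#' @param ds a [thickness_dataset].
#' @param variables covariate column names to compare (default: all numeric
#'   covariates plus sex).
#' @return data.frame with one row per variable: group summaries, the test
#'   used, its statistic and two-sided p-value.
#' @export
cohort_stats <- function(ds, variables = NULL) {
  stopifnot(inherits(ds, "thickness_dataset"))
  cov <- ds$covariates
  g <- cov$group
  if (any(table(g) < 2)) stop("each group needs >= 2 subjects")
  if (is.null(variables)) {
    num <- names(cov)[vapply(cov, is.numeric, logical(1))]
    variables <- c(setdiff(num, "subject_id"),
                   if ("sex" %in% names(cov)) "sex")
  }
  lev <- levels(g)
  rows <- lapply(variables, function(v) {
    if (!v %in% names(cov)) stop("no covariate '", v, "' in dataset")
    if (v == "sex") {
      tab <- table(g, cov$sex)
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      return(data.frame(variable = v,
                        group1 = paste(tab[lev[1], ], collapse = "/"),
                        group2 = paste(tab[lev[2], ], collapse = "/"),
                        test = "chisq", statistic = unname(ct$statistic),
                        p = ct$p.value, stringsAsFactors = FALSE))
    }
    x1 <- cov[[v]][g == lev[1]]
    x2 <- cov[[v]][g == lev[2]]
    normal <- function(x) length(unique(x)) < 3 ||
      stats::shapiro.test(x)$p.value >= 0.05
    if (normal(x1) && normal(x2)) {
      if (stats::sd(x1) == 0 && stats::sd(x2) == 0 && mean(x1) == mean(x2)) {
        stat <- 0; p <- 1; test <- "t"
      } else {
        tt <- stats::t.test(x1, x2, var.equal = TRUE)
        stat <- unname(tt$statistic); p <- tt$p.value; test <- "t"
      }
    } else {
      wt <- suppressWarnings(stats::wilcox.test(x1, x2))
      stat <- unname(wt$statistic); p <- wt$p.value; test <- "mannwhitney"
    }
    data.frame(variable = v,
               group1 = sprintf("%.2f ± %.2f", mean(x1), stats::sd(x1)),
               group2 = sprintf("%.2f ± %.2f", mean(x2), stats::sd(x2)),
               test = test, statistic = stat, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[2:3] <- lev
  out
}
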