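test_that("Benjamini-Hochberg control matches hand-executed step-up", {
  r <- fdr_bh(c(0.01, 0.02, 0.03, 0.5), q = 0.05)
  expect_equal(sum(r$reject), 3)
  expect_equal(r$p_adj[1:3], rep(0.04, 3))
  expect_equal(sum(fdr_bh(rep(1, 10))$reject), 0)
  single <- fdr_bh(0.04, q = 0.05)
  expect_true(single$reject)
  expect_equal(single$p_adj, 0.04)
  set.seed(3)
  p <- stats::runif(50)
  r2 <- fdr_bh(p)
  expect_true(all(r2$p_adj >= p))
  # BH rejections contain Bonferroni rejections at the same level
  expect_true(all(r2$reject[p <= 0.05 / 50]))
  expect_error(fdr_bh(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("partial correlation reduces to Pearson r and recovers planted effects", {
  set.seed(61)
  n <- 60
  x <- stats::rnorm(n); y <- 0.5 * x + stats::rnorm(n)
  z <- matrix(stats::rnorm(n), ncol = 1)  # independent covariate
  pc <- partial_correlation(x, y, z)
  expect_equal(pc$r, stats::cor(stats::resid(stats::lm(x ~ z)),
                                stats::resid(stats::lm(y ~ z))))
  expect_lt(abs(pc$r - stats::cor(x, y)), 0.05)
  expect_equal(pc$df, n - 3)
  # y = x exactly -> r = 1
  expect_equal(partial_correlation(x, x, z)$r, 1)
  # planted partial correlation 0.4 behind a shared confounder
  set.seed(62)
  n <- 2000
  conf <- stats::rnorm(n)
  u <- stats::rnorm(n); v <- stats::rnorm(n)
  rho <- 0.4
  x2 <- 0.8 * conf + u
  y2 <- -0.6 * conf + rho * u + sqrt(1 - rho^2) * v
  pc2 <- partial_correlation(x2, y2, cbind(conf))
  expect_lt(abs(pc2$r - rho), 2 / sqrt(n))
  # marginal correlation is visibly confounded away from rho
  expect_gt(abs(stats::cor(x2, y2) - rho), 0.05)
  expect_error(partial_correlation(1:4, 1:4, cbind(1:4)), "n > k \\+ 3")
  expect_error(partial_correlation(rep(1, 10), stats::rnorm(10),
                                   cbind(stats::rnorm(10))), "constant")
})

test_that("clinical correlation tables apply Bonferroni over the tested pairs", {
  set.seed(44)
  n <- 50
  df <- data.frame(age = stats::runif(n, 45, 70),
                   sex = sample(c("male", "female"), n, TRUE),
                   bmi = stats::rnorm(n, 26, 4),
                   tiv = stats::rnorm(n, 1.4e6, 1e5),
                   hba1c = stats::rnorm(n, 8, 2),
                   cdt = stats::rnorm(n, 28, 2.5))
  df$score <- -0.5 * scale(df$hba1c)[, 1] + stats::rnorm(n, sd = 0.8)
  cc <- clinical_correlations(df, rbind(c("hba1c", "score"),
                                        c("cdt", "score")))
  expect_equal(nrow(cc), 2)
  expect_equal(cc$p_bonf, pmin(1, cc$p * 2))
  expect_lt(cc$r[1], 0)
  expect_error(clinical_correlations(df, rbind(c("nope", "score"))), "nope")
})

test_that("cohort descriptives use the documented tests and formulas", {
  # identical groups -> t = 0, p = 1
  ds <- flat_dataset(n1 = 8, n2 = 8, n_regions = 5, seed = 70)
  ds$covariates$age <- rep(ds$covariates$age[1:8], 2)
  cs <- cohort_stats(ds, variables = "age")
  expect_equal(cs$statistic, 0, tolerance = 1e-12)
  expect_equal(cs$p, 1)
  expect_equal(cs$test, "t")

  # sex split 42/14 vs 37/22: Pearson chi-square without continuity
  # correction equals the 2x2 formula value 2.017
  n <- 115
  cov <- data.frame(subject_id = sprintf("S%03d", 1:n),
                    group = rep(c("patient", "control"), c(56, 59)),
                    age = stats::runif(n, 45, 70),
                    sex = c(rep("male", 42), rep("female", 14),
                            rep("male", 37), rep("female", 22)),
                    tiv = stats::rnorm(n, 1.45e6, 1e5),
                    stringsAsFactors = FALSE)
  thick <- matrix(stats::runif(n * 4, 2, 3), n, 4)
  ds2 <- thickness_dataset(thick, cov, small_atlas(4))
  cs2 <- cohort_stats(ds2, variables = "sex")
  expect_equal(cs2$test, "chisq")
  expect_equal(cs2$statistic, 2.017, tolerance = 1e-3)

  # summary-statistics t for fasting glucose means/SDs at n = 56/59
  ts <- t_from_summary(8.32, 3.13, 56, 4.10, 2.06, 59)
  expect_equal(ts$t, 8.58, tolerance = 0.005)
  expect_equal(ts$df, 113)
  expect_lt(ts$p, 0.001)

  # a heavily skewed variable falls back to Mann-Whitney
  ds3 <- flat_dataset(n1 = 30, n2 = 30, n_regions = 4, seed = 71)
  set.seed(72)
  ds3$covariates$skew <- exp(stats::rnorm(60, 0, 1.5))
  cs3 <- cohort_stats(ds3, variables = "skew")
  expect_equal(cs3$test, "mannwhitney")
})

test_that("t-test power matches the noncentral-t closed form", {
  expect_equal(round(two_sample_power(0.56, 56, 59, 0.05), 2), 0.85)
  expect_equal(two_sample_power(0, 56, 59, 0.05), 0.05, tolerance = 1e-6)
  expect_gt(two_sample_power(3, 56, 59, 0.05), 0.999)
  # cross-check against stats::power.t.test at equal n
  ref <- stats::power.t.test(n = 40, delta = 0.5, sd = 1,
                             sig.level = 0.05)$power
  # power.t.test drops the opposite-tail rejection mass (~1e-5 here)
  expect_equal(two_sample_power(0.5, 40, 40, 0.05), ref, tolerance = 1e-4)
  expect_error(two_sample_power(-1, 10, 10), "non-negative")
  expect_error(two_sample_power(0.5, 1, 10), ">= 2")
  expect_error(two_sample_power(0.5, 10, 10, alpha = 0), "alpha")
})
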