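test_that("residualization recovers exact linear covariate effects", {
  ds <- flat_dataset(n1 = 10, n2 = 10, n_regions = 6, seed = 5)
  # thickness exactly 0.01*age, no noise -> residuals identically zero
  ds$thickness <- matrix(rep(0.01 * ds$covariates$age, 6), ncol = 6)
  colnames(ds$thickness) <- ds$atlas$region_id
  res <- residualize_thickness(ds, covariates = "age")
  for (g in names(res)) expect_equal(max(abs(res[[g]])), 0, tolerance = 1e-10)
})

test_that("residuals are orthogonal to every covariate column", {
  spec <- cohort_spec(n_patients = 15, n_controls = 15, n_regions = 12,
                      n_modules = 3, seed = 21)
  ds <- generate_cohort(spec)
  for (scope in c("group", "pooled")) {
    res <- residualize_thickness(ds, scope = scope)
    for (g in c("patient", "control")) {
      idx <- ds$covariates$group == g
      X <- cbind(ds$covariates$age[idx],
                 as.numeric(ds$covariates$sex[idx] == "male"),
                 ds$covariates$tiv[idx])
      if (scope == "group") {
        # within-group fit: exact orthogonality in that group
        dots <- crossprod(scale(X, scale = FALSE), res[[g]])
        expect_lt(max(abs(dots)), 1e-6)
      }
      # residuals centred (intercept included)
      if (scope == "group")
        expect_lt(max(abs(colMeans(res[[g]]))), 1e-10)
    }
  }
})

test_that("constant covariates leave mean-centered thickness", {
  ds <- flat_dataset(n1 = 8, n2 = 8, n_regions = 5, seed = 9)
  ds$covariates$dummy <- stats::rnorm(16)  # fit on an irrelevant covariate
  res0 <- residualize_thickness(ds, covariates = "dummy")
  for (g in c("patient", "control")) {
    idx <- ds$covariates$group == g
    centred <- scale(ds$thickness[idx, ], scale = FALSE)
    # regression on noise covariates differs from centering only by the
    # estimated (null) slope; with the covariate orthogonalized out the
    # column means must still be zero
    expect_lt(max(abs(colMeans(res0[[g]]))), 1e-10)
    expect_equal(dim(res0[[g]]), dim(centred))
  }
})

test_that("rank-deficient designs are rejected naming the covariate", {
  ds <- flat_dataset(n1 = 8, n2 = 8, n_regions = 5, seed = 2)
  ds$covariates$sex[ds$covariates$group == "patient"] <- "male"
  expect_error(residualize_thickness(ds, covariates = c("age", "sex", "tiv")),
               "sex")
})

test_that("covariance networks are symmetric with unit self-similarity removed", {
  ds <- flat_dataset(n1 = 10, n2 = 10, n_regions = 8, seed = 13)
  res <- residualize_thickness(ds)
  net <- build_scn(res, "patient")
  expect_identical(net$corr, t(net$corr))
  expect_equal(diag(net$corr), rep(0, 8), ignore_attr = TRUE)
  expect_true(all(abs(net$corr) <= 1))
  # duplicated region -> r = 1 for the pair
  R <- res$patient
  R[, 2] <- R[, 1]
  net2 <- build_scn(R, "patient")
  expect_equal(net2$corr[1, 2], 1)
  # zero-variance region -> 0 with a warning
  R[, 3] <- 5
  expect_warning(net3 <- build_scn(R, "patient"), "zero-variance")
  expect_equal(net3$corr[3, ], rep(0, 8), ignore_attr = TRUE)
  expect_error(build_scn(R[1:3, ], "patient"), ">= 4 subjects")
})

test_that("density thresholding keeps exactly the top-K signed edges", {
  corr <- matrix(0, 4, 4)
  vals <- c("12" = 0.9, "13" = 0.5, "14" = 0.7, "23" = -0.2, "24" = 0.6,
            "34" = 0.1)
  corr[1, 2] <- 0.9; corr[1, 3] <- 0.5; corr[1, 4] <- 0.7
  corr[2, 3] <- -0.2; corr[2, 4] <- 0.6; corr[3, 4] <- 0.1
  corr <- corr + t(corr)
  net <- structure(list(group = "g", corr = corr,
                        covariates_removed = character(0)),
                   class = "covariance_network")
  # K = round(0.5 * 6) = 3 -> hand-ranked top 3: (1,2), (1,4), (2,4)
  st <- threshold_stack(net, density_sweep(0.4, 0.5, 0.1))
  A <- stack_adjacency(st)[[2]]
  expect_equal(sum(A) / 2, 3)
  expect_equal(A[1, 2], 1L); expect_equal(A[1, 4], 1L); expect_equal(A[2, 4], 1L)
  expect_equal(A[2, 3], 0L)
  # saturation: K = all pairs -> complete graph
  stc <- threshold_stack(net, density_sweep(0.95, 0.99, 0.05))
  expect_equal(sum(stack_adjacency(stc)[[1]]), 4 * 3)
  # absolute ranking pulls in the negative edge before the weakest positive
  sta <- threshold_stack(net, density_sweep(0.8, 0.9, 0.1),
                         edge_rank = "absolute")
  Aa <- stack_adjacency(sta)[[1]]  # K = round(0.8*6) = 5
  expect_equal(Aa[2, 3], 1L)
  expect_equal(Aa[3, 4], 0L)
})

test_that("ties at the cutoff resolve deterministically by node order", {
  corr <- matrix(0.5, 5, 5)  # all pairs tied
  diag(corr) <- 0
  net <- structure(list(group = "g", corr = corr,
                        covariates_removed = character(0)),
                   class = "covariance_network")
  st1 <- threshold_stack(net, density_sweep(0.3, 0.4, 0.1))
  st2 <- threshold_stack(net, density_sweep(0.3, 0.4, 0.1))
  expect_identical(stack_adjacency(st1), stack_adjacency(st2))
  A <- stack_adjacency(st1)[[1]]  # K = round(0.3*10) = 3, lexicographic
  expect_equal(which(A[1, ] == 1), c(2, 3, 4))
})

test_that("edge counts are exact and stacks nested across the sweep", {
  spec <- cohort_spec(n_patients = 12, n_controls = 12, n_regions = 30,
                      n_modules = 5, seed = 31)
  ds <- generate_cohort(spec)
  res <- residualize_thickness(ds)
  sweep <- density_sweep(0.1, 0.4, 0.05)
  st <- threshold_stack(build_scn(res, "patient"), sweep)
  adjs <- stack_adjacency(st)
  npairs <- 30 * 29 / 2
  for (d in seq_along(sweep$densities)) {
    expect_equal(sum(adjs[[d]]) / 2, round(sweep$densities[d] * npairs))
    if (d > 1) expect_true(all(adjs[[d]][adjs[[d - 1]] == 1] == 1))
  }
  rep <- check_density_validity(st)
  expect_equal(rep$n_edges, st$k)
  expect_true(all(diff(rep$n_components) <= 0))  # components merge as d grows
  expect_false(any(rep$fragmented))
  # a 10-node graph at K=1 is flagged fragmented
  tiny <- build_scn(res$patient[, 1:10], "patient")
  sttiny <- threshold_stack(tiny, density_sweep(0.02, 0.03, 0.01))
  expect_true(all(check_density_validity(sttiny)$fragmented))
  expect_error(threshold_stack(tiny, density_sweep(0.005, 0.01, 0.005)),
               "zero edges")
})

test_that("density sweep validates bounds and hits the documented grid", {
  sw <- density_sweep()
  expect_equal(length(sw$densities), 31)
  expect_equal(sw$densities[1], 0.10)
  expect_equal(sw$densities[31], 0.40)
  expect_error(density_sweep(0.4, 0.1), "d_min < d_max")
  expect_error(density_sweep(0.1, 0.4, -0.01), "step")
  expect_error(density_sweep(0, 0.4), "d_min")
})
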