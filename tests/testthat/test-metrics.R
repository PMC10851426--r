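# canonical small graphs
K3 <- matrix(1, 3, 3) - diag(3)
P3 <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
K4 <- matrix(1, 4, 4) - diag(4)
STAR <- rbind(c(0, 1, 1, 1), c(1, 0, 0, 0), c(1, 0, 0, 0), c(1, 0, 0, 0))
C4 <- rbind(c(0, 1, 0, 1), c(1, 0, 1, 0), c(0, 1, 0, 1), c(1, 0, 1, 0))
TWO_TRI <- matrix(0, 6, 6)
TWO_TRI[1:3, 1:3] <- K3
TWO_TRI[4:6, 4:6] <- K3

test_that("metrics reproduce hand-computed values on canonical graphs", {
  expect_equal(clustering_coefficient(K3)$global, 1)
  expect_equal(clustering_coefficient(P3)$global, 0)
  expect_equal(characteristic_path_length(P3), 4 / 3)
  expect_equal(characteristic_path_length(K4), 1)
  expect_equal(characteristic_path_length(TWO_TRI), 1)  # finite pairs only
  expect_equal(global_efficiency(K4), 1)
  expect_equal(global_efficiency(P3), (1 + 1 + 0.5) / 3)
  expect_equal(local_efficiency(K3)$global, 1)
  expect_equal(local_efficiency(STAR)$global, 0)
  expect_equal(betweenness_centrality(STAR), c(3, 0, 0, 0))
  expect_equal(betweenness_centrality(P3), c(0, 1, 0))
  expect_equal(betweenness_centrality(C4), rep(0.5, 4))
  expect_equal(degree_centrality(K4), rep(3L, 4))
  expect_equal(degree_centrality(matrix(0, 3, 3)), rep(0L, 3))
  expect_equal(nodal_efficiency(STAR), c(1, 2 / 3, 2 / 3, 2 / 3))
  iso <- matrix(0, 3, 3); iso[1, 2] <- iso[2, 1] <- 1
  expect_equal(nodal_efficiency(iso)[3], 0)  # isolated node
  expect_error(characteristic_path_length(matrix(0, 3, 3)), "no edges")
  expect_equal(global_efficiency(matrix(0, 3, 3)), 0)
})

test_that("adjacency validation rejects malformed input", {
  expect_error(clustering_coefficient(matrix(1, 2, 3)), "square")
  expect_error(global_efficiency(matrix(2, 2, 2) - 2 * diag(2)), "binary")
  M <- matrix(0, 3, 3); M[1, 2] <- 1
  expect_error(degree_centrality(M), "symmetric")
  expect_error(betweenness_centrality(diag(3)), "diagonal")
})

test_that("all metrics agree with brute-force oracles on random graphs", {
  set.seed(404)
  for (rep in 1:25) {
    n <- sample(6:20, 1)
    A <- random_adj(n, stats::runif(1, 0.15, 0.5))
    expect_equal(clustering_coefficient(A)$nodal, oracle_clustering(A))
    lp <- oracle_lp(A)
    if (is.na(lp)) expect_error(characteristic_path_length(A), "no edges")
    else expect_equal(characteristic_path_length(A), lp)
    expect_equal(global_efficiency(A), oracle_eglobal(A))
    expect_equal(local_efficiency(A)$nodal, oracle_elocal(A))
    expect_equal(betweenness_centrality(A), oracle_bc(A))
    expect_equal(nodal_efficiency(A), oracle_ne(A))
    expect_equal(degree_centrality(A), as.integer(rowSums(A)))
    expect_equal(sum(degree_centrality(A)), sum(A))  # handshake lemma
  }
})

test_that("AUC over the sweep matches closed forms and per-interval sums", {
  sw <- density_sweep(0.1, 0.4, 0.01)
  expect_equal(auc_over_sweep(rep(1, 31), sw), 0.3)
  ramp <- seq(0, 1, length.out = 31)
  expect_equal(auc_over_sweep(ramp, sw), 0.15)
  set.seed(8)
  v <- stats::rnorm(31)
  d <- sw$densities
  manual <- sum(vapply(1:30, function(i)
    (d[i + 1] - d[i]) * (v[i] + v[i + 1]) / 2, numeric(1)))
  expect_equal(auc_over_sweep(v, sw), manual)
  expect_error(auc_over_sweep(v[1:10], sw), "one metric value per density")
  expect_error(auc_over_sweep(c(v[-1], NA), sw), "finite")
})

test_that("metric monotonicity holds along a nested density stack", {
  spec <- cohort_spec(n_patients = 12, n_controls = 12, n_regions = 25,
                      n_modules = 5, seed = 17)
  ds <- generate_cohort(spec)
  st <- threshold_stack(build_scn(residualize_thickness(ds), "control"),
                        density_sweep(0.1, 0.4, 0.05))
  mc <- metric_curves(st, metrics = c("C", "Lp", "Eglobal", "Elocal"),
                      nodal_metrics = c("BC", "DC", "NE"))
  expect_true(all(diff(mc$global[, "Eglobal"]) >= 0))
  expect_true(all(mc$nodal$DC[, -1] - mc$nodal$DC[, -ncol(mc$nodal$DC)] >= 0))
  expect_true(all(mc$global[, "C"] >= 0 & mc$global[, "C"] <= 1))
  expect_true(all(mc$global[, "Lp"] >= 1))
  # engine curves equal single-graph metrics at each density
  adjs <- stack_adjacency(st)
  for (d in c(1, 4, 7)) {
    expect_equal(unname(mc$global[d, "C"]),
                 clustering_coefficient(adjs[[d]])$global)
    expect_equal(unname(mc$global[d, "Elocal"]),
                 local_efficiency(adjs[[d]])$global)
    expect_equal(mc$nodal$BC[, d], betweenness_centrality(adjs[[d]]))
    expect_equal(mc$nodal$NE[, d], nodal_efficiency(adjs[[d]]))
  }
})
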