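# Shared fixtures and independent brute-force oracles. Oracles use Floyd-
# Warshall distances and explicit shortest-path enumeration, deliberately
# different algorithms from the package's BFS/Brandes engine.

small_atlas <- function(n) {
  region_atlas(sprintf("R%03d", seq_len(n)),
               rep(c("left", "right"), length.out = n))
}

# undirected binary G(n, p) adjacency
random_adj <- function(n, p) {
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  A + t(A)
}

oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A == 1] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) {
    nd <- D[i, k] + D[k, ]
    upd <- nd < D[i, ]
    D[i, upd] <- nd[upd]
  }
  D
}

oracle_lp <- function(A) {
  D <- oracle_distances(A)
  fin <- is.finite(D) & D > 0
  if (!any(fin)) return(NA_real_)
  mean(D[fin])
}

oracle_eglobal <- function(A) {
  D <- oracle_distances(A)
  iv <- 1 / D
  iv[!is.finite(iv)] <- 0
  diag(iv) <- 0
  mean(iv[row(iv) != col(iv)])
}

oracle_ne <- function(A) {
  D <- oracle_distances(A)
  iv <- 1 / D
  iv[!is.finite(iv)] <- 0
  diag(iv) <- 0
  rowSums(iv) / (nrow(A) - 1)
}

# exhaustive triangle count per node
oracle_clustering <- function(A) {
  n <- nrow(A)
  sapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      if (A[nb[a], nb[b]] == 1) tri <- tri + 1
    2 * tri / (k * (k - 1))
  })
}

oracle_elocal <- function(A) {
  n <- nrow(A)
  sapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    if (length(nb) < 2) return(0)
    oracle_eglobal(A[nb, nb, drop = FALSE])
  })
}

# betweenness by explicit enumeration of all shortest paths
oracle_bc <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  all_paths <- function(i, j) {
    if (i == j) return(list(i))
    out <- list()
    for (k in which(A[i, ] == 1))
      if (is.finite(D[k, j]) && D[k, j] == D[i, j] - 1)
        for (p in all_paths(k, j)) out <- c(out, list(c(i, p)))
    out
  }
  bc <- numeric(n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (!is.finite(D[i, j]) || D[i, j] < 2) next
    ps <- all_paths(i, j)
    for (p in ps) {
      inner <- p[-c(1, length(p))]
      bc[inner] <- bc[inner] + 1 / length(ps)
    }
  }
  bc
}

# quick two-group dataset without the cohort generator's module structure
flat_dataset <- function(n1 = 8, n2 = 8, n_regions = 10, seed = 1) {
  set.seed(seed)
  n <- n1 + n2
  cov <- data.frame(subject_id = sprintf("S%02d", seq_len(n)),
                    group = rep(c("patient", "control"), c(n1, n2)),
                    age = stats::runif(n, 45, 70),
                    sex = sample(c("male", "female"), n, replace = TRUE),
                    tiv = stats::rnorm(n, 1.45e6, 1e5),
                    stringsAsFactors = FALSE)
  thick <- matrix(stats::rnorm(n * n_regions, 2.5, 0.2), n, n_regions)
  thickness_dataset(thick, cov, small_atlas(n_regions))
}
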