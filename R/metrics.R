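# Graph-metric wrappers around the compiled engine. All operate on binary,
# symmetric, zero-diagonal adjacency matrices of undirected graphs.

check_adjacency <- function(adj) {
  adj <- as.matrix(adj)
  if (nrow(adj) != ncol(adj)) stop("adjacency must be square")
  if (any(adj != 0 & adj != 1)) stop("adjacency must be binary")
  if (any(adj != t(adj))) stop("adjacency must be symmetric")
  if (any(diag(adj) != 0)) stop("adjacency must have an empty diagonal")
  storage.mode(adj) <- "integer"
  adj
}

#' Clustering coefficient
#'
#' Watts-Strogatz nodal clustering: for node `i` with degree `k >= 2`,
#' `2 * triangles(i) / (k (k-1))`; degree below 2 contributes 0. The global
#' value is the mean over all nodes.
#'
#' @param adj binary symmetric adjacency matrix, no self-loops.
#' @return list with `global` (mean) and `nodal` (per-node vector).
#' @export
clustering_coefficient <- function(adj) {
  m <- graph_metrics_cpp(check_adjacency(adj))
  list(global = m$C, nodal = m$C_nodal)
}

#' Characteristic path length
#'
#' Mean breadth-first shortest-path length over all ordered pairs that are
#' connected; disconnected pairs are excluded, keeping the value finite on
#' fragmented graphs (the convention is reported alongside the component
#' count by [check_density_validity()]).
#'
#' @inheritParams clustering_coefficient
#' @return scalar path length (hops).
#' @export
characteristic_path_length <- function(adj) {
  m <- graph_metrics_cpp(check_adjacency(adj))
  if (is.na(m$Lp)) stop("characteristic path length undefined: graph has no edges")
  m$Lp
}

#' Global efficiency
#'
#' Mean of `1 / d(i, j)` over all ordered pairs, with `1/Inf = 0` for
#' disconnected pairs; an edgeless graph scores 0.
#'
#' @inheritParams clustering_coefficient
#' @return scalar in `[0, 1]`.
#' @export
global_efficiency <- function(adj) graph_metrics_cpp(check_adjacency(adj))$Eglobal

#' Local efficiency
#'
#' Per node, the [global_efficiency()] of the subgraph induced by its
#' neighbours (0 for fewer than 2 neighbours); the global value is the mean
#' over nodes.
#'
#' @inheritParams clustering_coefficient
#' @return list with `global` and `nodal`.
#' @export
local_efficiency <- function(adj) {
  m <- graph_metrics_cpp(check_adjacency(adj))
  list(global = m$Elocal, nodal = m$Elocal_nodal)
}

#' Betweenness centrality
#'
#' Brandes shortest-path betweenness, unnormalized, undirected convention
#' (each unordered pair counted once, fractional credit shared across
#' equal-length shortest paths).
#'
#' @inheritParams clustering_coefficient
#' @return per-node numeric vector.
#' @export
betweenness_centrality <- function(adj) graph_metrics_cpp(check_adjacency(adj))$BC

#' Degree centrality
#'
#' @inheritParams clustering_coefficient
#' @return per-node integer vector of edge counts (row sums).
#' @export
degree_centrality <- function(adj) graph_metrics_cpp(check_adjacency(adj))$DC

#' Nodal efficiency
#'
#' `NE(i) = mean_j 1 / d(i, j)` over the other `N - 1` nodes, with
#' `1/Inf = 0`; an isolated node scores 0.
#'
#' @inheritParams clustering_coefficient
#' @return per-node numeric vector in `[0, 1]`.
#' @export
nodal_efficiency <- function(adj) graph_metrics_cpp(check_adjacency(adj))$NE

#' Area under a metric-versus-density curve
#'
#' Trapezoidal integral of one metric value per density over the sweep,
#' the scalar summary that removes dependence on any single threshold.
#'
#' @param values numeric vector, one finite value per density.
#' @param sweep a [density_sweep()] (or a numeric density vector).
#' @return scalar AUC.
#' @export
auc_over_sweep <- function(values, sweep) {
  d <- if (inherits(sweep, "density_sweep")) sweep$densities else as.numeric(sweep)
  if (length(values) != length(d))
    stop("need one metric value per density (", length(values), " vs ",
         length(d), ")")
  if (!all(is.finite(values))) stop("metric values must be finite")
  if (length(d) < 2) stop("AUC needs at least two densities")
  sum(diff(d) * (utils::head(values, -1) + utils::tail(values, -1)) / 2)
}

# metric curves for a ranked-edge stack; the hot path of the permutation
# loop. Small-world metrics (gamma/lambda/sigma) are added on request by
# normalizing against degree-preserving nulls at every density.
metric_curves_engine <- function(edge_i, edge_j, n, kvec, metrics,
                                 nodal_metrics, n_random = 0,
                                 swaps_per_edge = 10) {
  sw_metrics <- intersect(metrics, c("gamma", "lambda", "sigma"))
  do_clust <- any(c("C", "gamma", "sigma") %in% metrics)
  do_path <- any(c("Lp", "Eglobal", "lambda", "sigma") %in% metrics) ||
    "NE" %in% nodal_metrics
  do_elocal <- "Elocal" %in% metrics
  do_bc <- "BC" %in% nodal_metrics
  nodal <- length(nodal_metrics) > 0
  raw <- stack_metrics_cpp(edge_i, edge_j, n, kvec, do_clust, do_path,
                           do_elocal, do_bc, nodal)
  nd <- length(kvec)
  glob <- matrix(NA_real_, nd, length(metrics),
                 dimnames = list(NULL, metrics))
  for (mname in intersect(metrics, c("C", "Lp", "Eglobal", "Elocal")))
    glob[, mname] <- raw[[mname]]
  if (length(sw_metrics) > 0) {
    if (n_random < 1)
      stop("gamma/lambda/sigma require n_random >= 1 random networks")
    cr <- lr <- matrix(NA_real_, nd, n_random)
    for (d in seq_len(nd)) {
      A <- matrix(0L, n, n)
      idx <- cbind(edge_i[seq_len(kvec[d])], edge_j[seq_len(kvec[d])])
      A[idx] <- 1L; A[idx[, c(2, 1), drop = FALSE]] <- 1L
      for (b in seq_len(n_random)) {
        R <- rewire_preserving_degree(A, swaps_per_edge, quiet = TRUE)
        mm <- graph_metrics_cpp(R)
        cr[d, b] <- mm$C; lr[d, b] <- mm$Lp
      }
    }
    c_rand <- rowMeans(cr); lp_rand <- rowMeans(lr)
    if (any(!is.finite(c_rand)) || any(c_rand == 0) ||
        any(!is.finite(lp_rand)) || any(lp_rand == 0))
      stop("degenerate random-network ensemble (zero mean C or Lp)")
    gam <- raw$C / c_rand
    lam <- raw$Lp / lp_rand
    if ("gamma" %in% metrics) glob[, "gamma"] <- gam
    if ("lambda" %in% metrics) glob[, "lambda"] <- lam
    if ("sigma" %in% metrics) glob[, "sigma"] <- gam / lam
  }
  nodal_out <- list()
  for (mname in nodal_metrics)
    nodal_out[[mname]] <- raw[[mname]]
  list(global = glob, nodal = nodal_out)
}

#' Metric curves across a density stack
#'
#' Computes the selected global metrics (`C`, `Lp`, `Eglobal`, `Elocal`,
#' and, given `n_random > 0`, the normalized `gamma`, `lambda`, `sigma`)
#' and nodal metrics (`BC`, `DC`, `NE`) at every density of a stack.
#'
#' @param stack a [threshold_stack()] result.
#' @param metrics global metric names.
#' @param nodal_metrics nodal metric names (may be `character(0)`).
#' @param n_random random networks per density for small-world
#'   normalization (only used when gamma/lambda/sigma are requested).
#' @param swaps_per_edge rewiring intensity for the nulls.
#' @return list with `densities`, `global` (densities x metrics matrix) and
#'   `nodal` (list of node x density matrices).
#' @export
metric_curves <- function(stack, metrics = c("C", "Lp", "Eglobal", "Elocal"),
                          nodal_metrics = character(0), n_random = 100,
                          swaps_per_edge = 10) {
  stopifnot(inherits(stack, "density_graph_stack"))
  out <- metric_curves_engine(stack$edge_i, stack$edge_j, stack$n, stack$k,
                              metrics, nodal_metrics, n_random,
                              swaps_per_edge)
  out$densities <- stack$densities
  out
}
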