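#' Define a network density sweep
#'
#' Density (sparsity) is the fraction of possible node pairs connected.
#' Thresholding both groups at the same density equalizes node and edge
#' counts, which group comparisons of binary-graph metrics require. The
#' default sweep, 0.10 to 0.40 in steps of 0.01 (31 points), covers the
#' range where a 148-node covariance network is neither fragmented
#' (below ~0.1 the edge count drops under the node count) nor essentially
#' random (above ~0.5).
#'
#' @param d_min,d_max,step sweep bounds and increment, all in (0, 1).
#' @return A list of class `density_sweep` with a `densities` vector.
#' @export
density_sweep <- function(d_min = 0.10, d_max = 0.40, step = 0.01) {
  if (!(d_min > 0 && d_min < d_max && d_max < 1))
    stop("need 0 < d_min < d_max < 1")
  if (step <= 0) stop("step must be positive")
  npts <- floor((d_max - d_min) / step + 1e-9) + 1
  structure(list(d_min = d_min, d_max = d_max, step = step,
                 densities = d_min + step * (seq_len(npts) - 1)),
            class = "density_sweep")
}

# design matrix for residualization; errors on rank deficiency naming the
# covariate (e.g. a single-sex group makes 'sex' constant)
build_design <- function(cov, covariate_names) {
  cols <- lapply(covariate_names, function(nm) {
    if (!nm %in% names(cov)) stop("covariate '", nm, "' not in dataset")
    v <- cov[[nm]]
    if (nm == "sex" || is.character(v) || is.factor(v)) {
      if (nm == "sex") sex_indicator(v)
      else as.numeric(as.factor(v)) - 1
    } else as.numeric(v)
  })
  X <- cbind(`(intercept)` = 1, do.call(cbind, cols))
  colnames(X) <- c("(intercept)", covariate_names)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient covariate design; offending covariate: ",
         paste(dropped, collapse = ", "))
  }
  X
}

# least-squares residuals of every region on the design, via one QR
ols_residuals <- function(X, Y) {
  qr.resid(qr(X), Y)
}

#' Residualize thickness on nuisance covariates
#'
#' Regresses each region's thickness on an intercept plus the named
#' covariates by ordinary least squares and returns the residuals, the
#' standard adjustment before computing structural covariance. `scope =
#' "group"` (default) fits the regressions within each group separately,
#' consistent with group-specific covariance matrices; `"pooled"` fits one
#' regression across all subjects and then splits the residuals.
#'
#' @param ds a [thickness_dataset].
#' @param covariates covariate names (default `age`, `sex`, `tiv`).
#' @param scope `"group"` or `"pooled"`.
#' @return A named list (one element per group level) of residual matrices
#'   (subjects x regions), class `scn_residuals`.
#' @export
residualize_thickness <- function(ds, covariates = c("age", "sex", "tiv"),
                                  scope = c("group", "pooled")) {
  stopifnot(inherits(ds, "thickness_dataset"))
  scope <- match.arg(scope)
  g <- ds$covariates$group
  out <- if (scope == "pooled") {
    X <- build_design(ds$covariates, covariates)
    R <- ols_residuals(X, ds$thickness)
    lapply(stats::setNames(levels(g), levels(g)),
           function(lev) R[g == lev, , drop = FALSE])
  } else {
    lapply(stats::setNames(levels(g), levels(g)), function(lev) {
      idx <- g == lev
      X <- build_design(ds$covariates[idx, , drop = FALSE], covariates)
      ols_residuals(X, ds$thickness[idx, , drop = FALSE])
    })
  }
  structure(out, covariates = covariates, scope = scope,
            class = "scn_residuals")
}

#' Build a structural covariance network
#'
#' Pearson correlation between every pair of regions across a group's
#' residualized thickness values. The diagonal is fixed to 0. A region with
#' zero residual variance would give undefined correlations; its pairs are
#' set to 0 with a warning so all matrices stay finite.
#'
#' @param residuals numeric matrix (subjects x regions) of residualized
#'   thickness for one group, or an `scn_residuals` list (then `group`
#'   selects the element).
#' @param group group label carried on the result.
#' @return An object of class `covariance_network` with elements `group`,
#'   `corr` (symmetric, zero-diagonal) and `covariates_removed`.
#' @export
build_scn <- function(residuals, group = "group") {
  covs <- character(0)
  if (inherits(residuals, "scn_residuals")) {
    covs <- attr(residuals, "covariates")
    if (!group %in% names(residuals))
      stop("no residuals for group '", group, "'")
    residuals <- residuals[[group]]
  }
  residuals <- as.matrix(residuals)
  if (nrow(residuals) < 4)
    stop("need >= 4 subjects to correlate (have ", nrow(residuals), ")")
  sds <- apply(residuals, 2, stats::sd)
  zero_var <- sds == 0 | !is.finite(sds)
  corr <- suppressWarnings(stats::cor(residuals))
  if (any(zero_var)) {
    warning(sum(zero_var), " zero-variance region(s); their correlations set to 0")
    corr[zero_var, ] <- 0
    corr[, zero_var] <- 0
  }
  corr[!is.finite(corr)] <- 0
  diag(corr) <- 0
  structure(list(group = group, corr = corr, covariates_removed = covs),
            class = "covariance_network")
}

# rank upper-triangle pairs strongest-first with deterministic lexicographic
# (i, j) tie-breaking; returns 1-based endpoint vectors
rank_edges <- function(corr, edge_rank = c("signed", "absolute")) {
  edge_rank <- match.arg(edge_rank)
  n <- ncol(corr)
  ut <- upper.tri(corr)
  ii <- row(corr)[ut]
  jj <- col(corr)[ut]
  v <- corr[ut]
  if (edge_rank == "absolute") v <- abs(v)
  ord <- order(-v, ii, jj)
  list(i = ii[ord], j = jj[ord], value = v[ord], n = n)
}

#' Threshold a covariance network across a density sweep
#'
#' For each density `d` keeps the `K = round(d * N(N-1)/2)` strongest edges
#' and binarizes. Ranking is by signed correlation (most positive first) by
#' default, or by `|r|` with `edge_rank = "absolute"`. Ties at the cutoff
#' are resolved by lexicographic `(i, j)` node order, so edge counts are
#' exact and runs reproducible, and the edge sets are nested across the
#' sweep by construction.
#'
#' @param net a [build_scn()] result.
#' @param sweep a [density_sweep()].
#' @param edge_rank `"signed"` or `"absolute"`.
#' @return An object of class `density_graph_stack`: ranked edge list plus
#'   per-density edge counts. Use [stack_adjacency()] to materialize binary
#'   matrices.
#' @export
threshold_stack <- function(net, sweep = density_sweep(),
                            edge_rank = c("signed", "absolute")) {
  stopifnot(inherits(net, "covariance_network"),
            inherits(sweep, "density_sweep"))
  edge_rank <- match.arg(edge_rank)
  n <- ncol(net$corr)
  npairs <- n * (n - 1) / 2
  k <- round(sweep$densities * npairs)
  if (any(k < 1))
    stop("density ", sweep$densities[which(k < 1)[1]],
         " yields zero edges on ", n, " nodes")
  edges <- rank_edges(net$corr, edge_rank)
  structure(list(group = net$group, n = n, densities = sweep$densities,
                 k = as.integer(k), edge_i = edges$i, edge_j = edges$j,
                 edge_rank = edge_rank),
            class = "density_graph_stack")
}

#' Binary adjacency matrices of a density stack
#'
#' @param stack a [threshold_stack()] result.
#' @param which_densities indices into `stack$densities` (default: all).
#' @return A list of binary symmetric adjacency matrices.
#' @export
stack_adjacency <- function(stack, which_densities = seq_along(stack$densities)) {
  stopifnot(inherits(stack, "density_graph_stack"))
  lapply(which_densities, function(d) {
    K <- stack$k[d]
    A <- matrix(0L, stack$n, stack$n)
    idx <- cbind(stack$edge_i[seq_len(K)], stack$edge_j[seq_len(K)])
    A[idx] <- 1L
    A[idx[, c(2, 1), drop = FALSE]] <- 1L
    A
  })
}

#' Report edge counts, components and fragmentation across a sweep
#'
#' A network whose edge count falls below its node count cannot be connected
#' and is flagged as fragmented; below density ~0.1 on 148 nodes this is the
#' regime the sweep's lower bound avoids.
#'
#' @param stack a [threshold_stack()] result.
#' @return data.frame with `density`, `n_edges`, `n_components`, `fragmented`.
#' @export
check_density_validity <- function(stack) {
  stopifnot(inherits(stack, "density_graph_stack"))
  adjs <- stack_adjacency(stack)
  ncomp <- vapply(adjs, function(A) {
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    as.integer(igraph::components(g)$no)
  }, integer(1))
  data.frame(density = stack$densities, n_edges = stack$k,
             n_components = ncomp, fragmented = stack$k < stack$n)
}
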