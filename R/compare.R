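#' Compare two groups' structural covariance networks
#'
#' The central fitting function of the package. For each group it
#' residualizes thickness on the nuisance covariates, builds the Pearson
#' correlation network, thresholds it across the density sweep, and
#' computes the requested global and nodal metrics; each metric's curve is
#' summarized by its area under the curve (AUC) over the sweep. Group
#' differences in AUC are tested by relabeling permutation: the full
#' pipeline (residualization included) is re-run on every relabeled split,
#' preserving the original group sizes, and the two-tailed p-value is
#' `(#\{|null| >= |observed|\} + 1) / (n_perm + 1)`, which can never be
#' exactly zero. Nodal p-values are FDR-adjusted (Benjamini-Hochberg)
#' within each nodal metric family across regions.
#'
#' Group 1 is the first level of the dataset's group factor (for generated
#' cohorts, `patient`); observed differences are group 1 minus group 2.
#'
#' @param ds a [thickness_dataset].
#' @param metrics global metrics among `C`, `Lp`, `Eglobal`, `Elocal`,
#'   `gamma`, `lambda`, `sigma`. The normalized metrics re-generate
#'   `n_random` degree-preserving nulls per density inside every
#'   permutation and are expensive; the default omits them.
#' @param nodal_metrics nodal metrics among `BC`, `DC`, `NE` (may be
#'   `character(0)` to skip nodal testing).
#' @param sweep a [density_sweep()].
#' @param covariates nuisance covariates to residualize on.
#' @param residual_scope `"group"` (fit within each group) or `"pooled"`.
#' @param edge_rank `"signed"` or `"absolute"` correlation ranking.
#' @param n_perm number of label permutations (>= 1).
#' @param n_random random networks per density for gamma/lambda/sigma.
#' @param swaps_per_edge rewiring intensity of those nulls.
#' @param fdr_q FDR level for nodal rejection flags.
#' @param seed integer seed for the permutation (and any rewiring) stream;
#'   the caller's RNG state is preserved.
#' @return An object of class `scn_comparison`; see [print.scn_comparison()],
#'   [summary.scn_comparison()], [plot.scn_comparison()].
#' @export
scn_compare <- function(ds, metrics = c("C", "Lp", "Eglobal", "Elocal"),
                        nodal_metrics = c("BC", "DC", "NE"),
                        sweep = density_sweep(),
                        covariates = c("age", "sex", "tiv"),
                        residual_scope = c("group", "pooled"),
                        edge_rank = c("signed", "absolute"),
                        n_perm = 1000, n_random = 100, swaps_per_edge = 10,
                        fdr_q = 0.05, seed = NULL) {
  stopifnot(inherits(ds, "thickness_dataset"),
            inherits(sweep, "density_sweep"))
  residual_scope <- match.arg(residual_scope)
  edge_rank <- match.arg(edge_rank)
  known_g <- c("C", "Lp", "Eglobal", "Elocal", "gamma", "lambda", "sigma")
  known_n <- c("BC", "DC", "NE")
  if (length(metrics) < 1 || !all(metrics %in% known_g))
    stop("metrics must be among: ", paste(known_g, collapse = ", "))
  if (!all(nodal_metrics %in% known_n))
    stop("nodal_metrics must be among: ", paste(known_n, collapse = ", "))
  if (n_perm < 1) stop("n_perm must be >= 1")

  Y <- ds$thickness
  n_region <- ncol(Y)
  npairs <- n_region * (n_region - 1) / 2
  kvec <- as.integer(round(sweep$densities * npairs))
  if (any(kvec < 1)) stop("sweep produces an empty graph at the lowest density")
  dens <- sweep$densities
  g <- ds$covariates$group
  lev <- levels(g)
  Dmat <- build_design(ds$covariates, covariates)[, -1, drop = FALSE]
  ut <- upper.tri(matrix(0, n_region, n_region))
  pair_i <- row(matrix(0, n_region, n_region))[ut]
  pair_j <- col(matrix(0, n_region, n_region))[ut]
  trapz_w <- diff(dens)

  auc_curve <- function(vals) sum(trapz_w * (vals[-length(vals)] + vals[-1]) / 2)
  auc_rows <- function(M) {  # rows = nodes, cols = densities
    as.numeric((M[, -ncol(M), drop = FALSE] + M[, -1, drop = FALSE]) %*%
                 trapz_w) / 2
  }

  pipe_once <- function(labels, nodal) {
    res_list <- if (residual_scope == "pooled") {
      R <- qr.resid(qr(cbind(1, Dmat)), Y)
      lapply(lev, function(l) R[labels == l, , drop = FALSE])
    } else {
      lapply(lev, function(l) {
        idx <- labels == l
        qr.resid(qr(cbind(1, Dmat[idx, , drop = FALSE])),
                 Y[idx, , drop = FALSE])
      })
    }
    out <- lapply(res_list, function(R) {
      corr <- suppressWarnings(stats::cor(R))
      corr[!is.finite(corr)] <- 0
      diag(corr) <- 0
      v <- corr[ut]
      if (edge_rank == "absolute") v <- abs(v)
      ord <- order(-v, pair_i, pair_j)
      cur <- metric_curves_engine(pair_i[ord], pair_j[ord], n_region, kvec,
                                  metrics, if (nodal) nodal_metrics
                                  else character(0),
                                  n_random, swaps_per_edge)
      list(global_auc = apply(cur$global, 2, auc_curve),
           nodal_auc = lapply(cur$nodal, auc_rows),
           curves = cur$global, nodal_curves = cur$nodal)
    })
    names(out) <- lev
    out
  }

  with_seed(seed, {
    obs <- pipe_once(g, nodal = length(nodal_metrics) > 0)
    obs_gdiff <- obs[[1]]$global_auc - obs[[2]]$global_auc
    obs_ndiff <- if (length(nodal_metrics) > 0)
      lapply(nodal_metrics, function(m)
        obs[[1]]$nodal_auc[[m]] - obs[[2]]$nodal_auc[[m]])
    else list()
    names(obs_ndiff) <- nodal_metrics

    null_global <- matrix(NA_real_, n_perm, length(metrics),
                          dimnames = list(NULL, metrics))
    nodal_count <- lapply(obs_ndiff, function(d) integer(length(d)))
    for (b in seq_len(n_perm)) {
      pl <- sample(g)
      pb <- pipe_once(pl, nodal = length(nodal_metrics) > 0)
      null_global[b, ] <- pb[[1]]$global_auc - pb[[2]]$global_auc
      for (m in nodal_metrics) {
        nd <- pb[[1]]$nodal_auc[[m]] - pb[[2]]$nodal_auc[[m]]
        nodal_count[[m]] <- nodal_count[[m]] +
          (abs(nd) >= abs(obs_ndiff[[m]]))
      }
    }

    p_global <- (colSums(abs(null_global) >=
                           rep(abs(obs_gdiff), each = n_perm)) + 1) /
      (n_perm + 1)
    global_tab <- data.frame(metric = metrics,
                             auc_1 = obs[[1]]$global_auc,
                             auc_2 = obs[[2]]$global_auc,
                             diff = obs_gdiff, p = p_global,
                             row.names = NULL, stringsAsFactors = FALSE)
    names(global_tab)[2:3] <- paste0("auc_", lev)

    nodal_tab <- NULL
    if (length(nodal_metrics) > 0) {
      nodal_tab <- do.call(rbind, lapply(nodal_metrics, function(m) {
        p <- (nodal_count[[m]] + 1) / (n_perm + 1)
        data.frame(region_id = ds$atlas$region_id, metric = m,
                   auc_1 = obs[[1]]$nodal_auc[[m]],
                   auc_2 = obs[[2]]$nodal_auc[[m]],
                   diff = obs_ndiff[[m]], p = p,
                   p_fdr = fdr_bh(p, fdr_q)$p_adj,
                   row.names = NULL, stringsAsFactors = FALSE)
      }))
      names(nodal_tab)[3:4] <- paste0("auc_", lev)
    }

    structure(list(call = match.call(), groups = lev,
                   group_sizes = as.integer(table(g)), sweep = sweep,
                   metrics = metrics, nodal_metrics = nodal_metrics,
                   curves = lapply(obs, `[[`, "curves"),
                   nodal_curves = lapply(obs, `[[`, "nodal_curves"),
                   global = global_tab, nodal = nodal_tab,
                   null_global = null_global, n_perm = n_perm,
                   n_random = n_random, fdr_q = fdr_q, seed = seed,
                   covariates = covariates, residual_scope = residual_scope,
                   edge_rank = edge_rank),
              class = "scn_comparison")
  })
}

#' @export
print.scn_comparison <- function(x, ...) {
  cat("Structural covariance network comparison\n")
  cat(sprintf("  groups: %s (n = %d) vs %s (n = %d)\n", x$groups[1],
              x$group_sizes[1], x$groups[2], x$group_sizes[2]))
  cat(sprintf("  densities: %.2f-%.2f (%d points), %d permutations\n",
              min(x$sweep$densities), max(x$sweep$densities),
              length(x$sweep$densities), x$n_perm))
  cat("\nGlobal metric AUCs:\n")
  print(format(x$global, digits = 4), row.names = FALSE)
  if (!is.null(x$nodal)) {
    sig <- sum(x$nodal$p_fdr <= x$fdr_q)
    cat(sprintf("\nNodal tests: %d region x metric rows, %d significant at FDR %.2f\n",
                nrow(x$nodal), sig, x$fdr_q))
  }
  invisible(x)
}

#' Summarize a network comparison
#'
#' @param object an [scn_compare()] result.
#' @param ... unused.
#' @return list with the `global` AUC table and the FDR-significant rows of
#'   the nodal table, printed on request.
#' @export
summary.scn_comparison <- function(object, ...) {
  sig <- if (!is.null(object$nodal))
    object$nodal[object$nodal$p_fdr <= object$fdr_q, , drop = FALSE]
  out <- list(global = object$global, nodal_significant = sig,
              groups = object$groups, n_perm = object$n_perm,
              fdr_q = object$fdr_q)
  class(out) <- "summary.scn_comparison"
  out
}

#' @export
print.summary.scn_comparison <- function(x, ...) {
  cat("Global metric AUC comparison (", x$groups[1], " - ", x$groups[2],
      ", ", x$n_perm, " permutations):\n", sep = "")
  print(format(x$global, digits = 4), row.names = FALSE)
  if (!is.null(x$nodal_significant)) {
    cat("\nNodal rows significant at FDR ", x$fdr_q, ":\n", sep = "")
    if (nrow(x$nodal_significant) == 0) cat("  none\n")
    else print(format(x$nodal_significant, digits = 4), row.names = FALSE)
  }
  invisible(x)
}

#' Plot metric-versus-density curves for both groups
#'
#' One panel per global metric, solid line for group 1, dashed for group 2.
#'
#' @param x an [scn_compare()] result.
#' @param metrics subset of fitted global metrics to draw.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.scn_comparison <- function(x, metrics = x$metrics, ...) {
  metrics <- intersect(metrics, x$metrics)
  if (length(metrics) == 0) stop("no fitted metrics selected")
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(metrics)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  d <- x$sweep$densities
  for (m in metrics) {
    Ym <- cbind(x$curves[[1]][, m], x$curves[[2]][, m])
    graphics::matplot(d, Ym, type = "l", lty = c(1, 2), col = c(2, 4),
                      xlab = "density", ylab = m, main = m, ...)
    graphics::legend("bottomright", legend = x$groups, lty = c(1, 2),
                     col = c(2, 4), bty = "n", cex = 0.8)
  }
  invisible(x)
}
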