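#' Assemble a pipeline run configuration
#'
#' Collects every tunable of the end-to-end pipeline in one validated list.
#' Inputs are either file paths (`thickness_path`, `covariates_path`) or a
#' [cohort_spec] (`simulate`) for a synthetic run. Validation happens here,
#' before any computation.
#'
#' @param thickness_path,covariates_path input tables ([read_thickness_table()]
#'   formats); ignored when `simulate` is given.
#' @param simulate optional [cohort_spec] to generate the input cohort.
#' @param density list with `min`, `max`, `step` (defaults 0.10/0.40/0.01).
#' @param covariates nuisance covariates for residualization.
#' @param residual_scope,edge_rank see [scn_compare()].
#' @param metrics,nodal_metrics see [scn_compare()].
#' @param n_perm,n_random,swaps_per_edge,fdr_q see [scn_compare()].
#' @param correlate optional data.frame/matrix of (x, y) column-name pairs
#'   for [clinical_correlations()] within the first group, e.g.
#'   `cbind("hba1c", "lh_G_temporal_inf")`; per-subject columns are clinical
#'   covariates and regional thickness (plus `mean_thickness`).
#' @param seed integer master seed.
#' @return list of class `scn_config`.
#' @export
scn_config <- function(thickness_path = NULL, covariates_path = NULL,
                       simulate = NULL,
                       density = list(min = 0.10, max = 0.40, step = 0.01),
                       covariates = c("age", "sex", "tiv"),
                       residual_scope = "group", edge_rank = "signed",
                       metrics = c("C", "Lp", "Eglobal", "Elocal"),
                       nodal_metrics = c("BC", "DC", "NE"),
                       n_perm = 1000, n_random = 100, swaps_per_edge = 10,
                       fdr_q = 0.05, correlate = NULL, seed = 1L) {
  sweep <- density_sweep(density$min, density$max, density$step)  # validates
  if (is.null(simulate) && is.null(thickness_path))
    stop("config needs either input paths or a simulation spec")
  if (!is.null(simulate) && !inherits(simulate, "cohort_spec"))
    stop("'simulate' must be a cohort_spec")
  if (n_perm < 1) stop("n_perm must be >= 1")
  structure(list(thickness_path = thickness_path,
                 covariates_path = covariates_path, simulate = simulate,
                 sweep = sweep, covariates = covariates,
                 residual_scope = residual_scope, edge_rank = edge_rank,
                 metrics = metrics, nodal_metrics = nodal_metrics,
                 n_perm = n_perm, n_random = n_random,
                 swaps_per_edge = swaps_per_edge, fdr_q = fdr_q,
                 correlate = correlate, seed = as.integer(seed)),
            class = "scn_config")
}

config_as_list <- function(config) {
  out <- unclass(config)
  out$sweep <- list(min = config$sweep$d_min, max = config$sweep$d_max,
                    step = config$sweep$step)
  if (!is.null(out$simulate)) out$simulate <- unclass(out$simulate)
  if (!is.null(out$correlate))
    out$correlate <- as.data.frame(out$correlate, stringsAsFactors = FALSE)
  out
}

#' Run the full pipeline and write result tables
#'
#' Loads (or simulates) the cohort, runs [scn_compare()], and writes to
#' `outdir`: `global_curves.tsv` (metric per density per group),
#' `global_auc.tsv`, `nodal_auc.tsv`, `cohort_stats.tsv`, optionally
#' `correlations.tsv`, plus `config.json` (the effective configuration) and
#' `log.txt` (stages, seeds, versions). Identical config and seed give
#' byte-identical tables.
#'
#' @param config an [scn_config()].
#' @param outdir output directory, created if missing.
#' @return Invisibly, the [scn_compare()] result.
#' @export
run_scn_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "scn_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  log_path <- file.path(outdir, "log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("scnet %s pipeline run", as.character(utils::packageVersion("scnet")))
  logf("seed: %d", config$seed)
  jsonlite::write_json(config_as_list(config),
                       file.path(outdir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  stage <- "load input"
  result <- tryCatch({
    ds <- if (!is.null(config$simulate)) {
      stage <- "simulate cohort"
      logf("stage: simulate cohort (seed %d)", config$simulate$seed)
      generate_cohort(config$simulate)
    } else {
      logf("stage: read input %s", config$thickness_path)
      read_thickness_table(config$thickness_path,
                           covariates_path = config$covariates_path)
    }
    logf("subjects: %d x regions: %d", nrow(ds$thickness), ncol(ds$thickness))

    stage <- "cohort statistics"
    cs <- cohort_stats(ds)
    write_table_auto(cs, file.path(outdir, "cohort_stats.tsv"))

    stage <- "network comparison"
    logf("stage: comparison (%d permutations, densities %.2f-%.2f)",
         config$n_perm, config$sweep$d_min, config$sweep$d_max)
    comp <- scn_compare(ds, metrics = config$metrics,
                        nodal_metrics = config$nodal_metrics,
                        sweep = config$sweep, covariates = config$covariates,
                        residual_scope = config$residual_scope,
                        edge_rank = config$edge_rank, n_perm = config$n_perm,
                        n_random = config$n_random,
                        swaps_per_edge = config$swaps_per_edge,
                        fdr_q = config$fdr_q, seed = config$seed)

    stage <- "write results"
    dens <- comp$sweep$densities
    curves <- do.call(rbind, lapply(comp$groups, function(gr) {
      data.frame(group = gr, density = dens,
                 comp$curves[[gr]], check.names = FALSE,
                 stringsAsFactors = FALSE)
    }))
    write_table_auto(curves, file.path(outdir, "global_curves.tsv"))
    gtab <- data.frame(region_id = "GLOBAL", comp$global,
                       check.names = FALSE, stringsAsFactors = FALSE)
    write_results_table(gtab, file.path(outdir, "global_auc.tsv"))
    if (!is.null(comp$nodal))
      write_results_table(comp$nodal, file.path(outdir, "nodal_auc.tsv"))

    if (!is.null(config$correlate)) {
      stage <- "clinical correlations"
      g1 <- ds$covariates$group == levels(ds$covariates$group)[1]
      per_subject <- data.frame(ds$covariates[g1, , drop = FALSE],
                                ds$thickness[g1, , drop = FALSE],
                                mean_thickness = rowMeans(ds$thickness[g1, ,
                                                                       drop = FALSE]),
                                check.names = FALSE, stringsAsFactors = FALSE)
      cc <- clinical_correlations(per_subject, config$correlate)
      write_table_auto(cc, file.path(outdir, "correlations.tsv"))
    }
    logf("stage: done")
    comp
  }, error = function(e) {
    logf("FAILED at stage '%s': %s", stage, conditionMessage(e))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

#' Write synthetic test fixtures
#'
#' Writes thickness/covariate tables for two cohorts drawn from `spec`: a
#' null cohort (both groups share the control loading, so no topological
#' group difference) and an effect cohort (the spec's own loadings).
#'
#' @param spec a [cohort_spec()].
#' @param outdir output directory, created if missing.
#' @return Invisibly, the four file paths.
#' @export
make_fixtures <- function(spec = cohort_spec(), outdir) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  null_spec <- spec
  null_spec$loading_patients <- spec$loading_controls
  paths <- character(0)
  for (nm in c("null", "effect")) {
    s <- if (nm == "null") null_spec else spec
    ds <- generate_cohort(s)
    p <- file.path(outdir, paste0(nm, "_thickness.tsv"))
    cp <- file.path(outdir, paste0(nm, "_covariates.tsv"))
    write_thickness_table(ds, p, cp)
    paths <- c(paths, p, cp)
  }
  invisible(paths)
}
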