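# Tabular I/O. Dialect: comma- vs tab-separated chosen by file extension
# (.csv vs .tsv/anything else), UTF-8, first column = subject id.

read_table_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.csv$", path, ignore.case = TRUE))
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  else
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

write_table_auto <- function(df, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  ok <- tryCatch({
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write to: ", path)
  invisible(path)
}

#' Read a thickness table (and covariates) from delimited text
#'
#' Expects one row per subject; the first column is the subject id and there
#' is one column per atlas region. Covariates may live in a companion file
#' (`covariates_path`) or as extra non-region columns of the same file.
#'
#' @param path thickness table (.csv or .tsv; dialect chosen by extension).
#' @param atlas a [region_atlas]; region columns are checked against it and
#'   reordered to its node order.
#' @param covariates_path optional companion covariate table keyed by the
#'   subject-id column.
#' @return A validated [thickness_dataset].
#' @export
read_thickness_table <- function(path, atlas = load_destrieux_atlas(),
                                 covariates_path = NULL) {
  df <- read_table_auto(path)
  if (ncol(df) < 2) stop("thickness table needs a subject-id column plus regions")
  id_col <- names(df)[1]
  missing_regions <- setdiff(atlas$region_id, names(df))
  if (length(missing_regions) > 0)
    stop("thickness table is missing region column '", missing_regions[1], "'")
  thick <- df[, atlas$region_id, drop = FALSE]
  for (j in seq_along(thick)) {
    v <- thick[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop("non-numeric thickness in column '", names(thick)[j], "', row ",
           ifelse(is.na(bad), 1, bad))
    }
  }
  thick <- as.matrix(thick)
  rownames(thick) <- as.character(df[[id_col]])

  if (!is.null(covariates_path)) {
    cov <- read_table_auto(covariates_path)
    names(cov)[1] <- "subject_id"
    cov$subject_id <- as.character(cov$subject_id)
    m <- match(rownames(thick), cov$subject_id)
    if (anyNA(m)) stop("covariate table is missing subject '",
                       rownames(thick)[is.na(m)][1], "'")
    cov <- cov[m, , drop = FALSE]
  } else {
    extra <- setdiff(names(df), c(id_col, atlas$region_id))
    if (length(extra) == 0)
      stop("no covariate columns found; supply 'covariates_path'")
    cov <- df[, extra, drop = FALSE]
    cov$subject_id <- as.character(df[[id_col]])
  }
  row.names(cov) <- NULL
  thickness_dataset(thick, cov, atlas)
}

#' Write a thickness dataset to delimited text
#'
#' Inverse of [read_thickness_table()]: one file for the thickness matrix
#' (subject id + one column per region, atlas order) and one for the
#' covariates. Numeric values keep full `write.table` precision, so a
#' read-back reproduces the matrix to text-representation accuracy.
#'
#' @param ds a [thickness_dataset].
#' @param path output thickness table path (.csv or .tsv).
#' @param covariates_path output covariate table path.
#' @return Invisibly, the two paths.
#' @export
write_thickness_table <- function(ds, path, covariates_path) {
  stopifnot(inherits(ds, "thickness_dataset"))
  tdf <- data.frame(subject_id = rownames(ds$thickness),
                    ds$thickness, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write_table_auto(tdf, path)
  cov <- ds$covariates
  cov <- cov[, c("subject_id", setdiff(names(cov), "subject_id")), drop = FALSE]
  write_table_auto(cov, covariates_path)
  invisible(c(path, covariates_path))
}

#' Write a results table
#'
#' Writes one row per (region, metric) record. The column order is stable:
#' `region_id` (or `"GLOBAL"`), `metric`, the two group values, `diff`, `p`,
#' `p_fdr`, followed by any extra columns in their input order.
#'
#' @param records data.frame of result rows; must contain `region_id` and
#'   `metric` columns (zero rows allowed -- a header-only file is written).
#' @param path output path (.tsv or .csv).
#' @return Invisibly, `path`.
#' @export
write_results_table <- function(records, path) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("region_id", "metric")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0)
    stop("results records missing column(s): ", paste(miss, collapse = ", "))
  lead <- intersect(c("region_id", "metric", "patients", "controls",
                      "diff", "p", "p_fdr"), names(records))
  records <- records[, c(lead, setdiff(names(records), lead)), drop = FALSE]
  write_table_auto(records, path)
}
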