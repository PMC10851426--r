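#' Assemble a cortical-thickness dataset
#'
#' Bundles a subjects-by-regions thickness matrix (mm) with per-subject
#' covariates and a two-level group label. All downstream stages
#' (residualization, network construction, permutation testing) consume this
#' container.
#'
#' Required covariates are `group`, `age` (years), `sex` and `tiv` (total
#' intracranial volume, mm^3). `sex` may be coded `male`/`female` or `1`/`0`
#' (1 = male); the mapping is reported via a message. Subjects with a missing
#' required covariate are dropped with a message stating the count; nothing
#' is imputed.
#'
#' @param thickness numeric matrix, subjects in rows, regions in columns
#'   (ordered as `atlas`); strictly positive and finite.
#' @param covariates data.frame with one row per subject: `subject_id`,
#'   `group`, `age`, `sex`, `tiv`, plus any clinical columns (e.g. `bmi`,
#'   `hba1c`, `cdt`, `ctt1`).
#' @param atlas a [region_atlas]; defaults to the bundled Destrieux list.
#' @return An object of class `thickness_dataset`: a list with elements
#'   `thickness`, `covariates`, `atlas`.
#' @export
thickness_dataset <- function(thickness, covariates,
                              atlas = load_destrieux_atlas()) {
  thickness <- as.matrix(thickness)
  if (!is.numeric(thickness)) stop("thickness must be numeric")
  if (ncol(thickness) != nrow(atlas))
    stop("thickness has ", ncol(thickness), " regions but atlas has ",
         nrow(atlas))
  bad <- which(!is.finite(thickness) | thickness <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-positive or non-finite thickness at row ", bad[1, 1],
         ", region '", atlas$region_id[bad[1, 2]], "'")
  colnames(thickness) <- atlas$region_id
  covariates <- as.data.frame(covariates, stringsAsFactors = FALSE)
  if (nrow(covariates) != nrow(thickness))
    stop("covariates must have one row per subject")
  req <- c("subject_id", "group", "age", "sex", "tiv")
  miss <- setdiff(req, names(covariates))
  if (length(miss) > 0)
    stop("missing required covariate column(s): ", paste(miss, collapse = ", "))
  covariates$sex <- decode_sex(covariates$sex)
  if (is.null(rownames(thickness)))
    rownames(thickness) <- as.character(covariates$subject_id)

  keep <- stats::complete.cases(covariates[, c("group", "age", "sex", "tiv")])
  if (any(!keep)) {
    message(sum(!keep), " subject(s) dropped for missing required covariates")
    thickness <- thickness[keep, , drop = FALSE]
    covariates <- covariates[keep, , drop = FALSE]
  }

  covariates$group <- as.factor(covariates$group)
  sizes <- table(covariates$group)
  if (length(sizes) != 2)
    stop("group must have exactly 2 levels, found: ",
         paste(names(sizes), collapse = ", "))
  if (any(sizes < 4))
    stop("each group needs >= 4 subjects for correlation; sizes: ",
         paste(sizes, collapse = "/"))
  structure(list(thickness = thickness, covariates = covariates,
                 atlas = atlas),
            class = "thickness_dataset")
}

decode_sex <- function(sex) {
  if (is.numeric(sex)) {
    if (!all(sex %in% c(0, 1, NA)))
      stop("numeric sex must be coded 1 (male) / 0 (female)")
    message("sex decoded as 1 = male, 0 = female")
    return(ifelse(is.na(sex), NA_character_, ifelse(sex == 1, "male", "female")))
  }
  sex <- tolower(as.character(sex))
  ok <- sex %in% c("male", "female") | is.na(sex)
  if (!all(ok)) stop("unknown sex value: '", sex[!ok][1], "'")
  sex
}

#' @export
print.thickness_dataset <- function(x, ...) {
  sizes <- table(x$covariates$group)
  cat("Cortical thickness dataset:", nrow(x$thickness), "subjects x",
      ncol(x$thickness), "regions\n")
  cat("  groups:", paste(sprintf("%s (n = %d)", names(sizes), sizes),
                         collapse = ", "), "\n")
  cat("  covariates:", paste(setdiff(names(x$covariates), "subject_id"),
                             collapse = ", "), "\n")
  invisible(x)
}

# numeric sex indicator used in design matrices (male = 1, female = 0)
sex_indicator <- function(sex) as.numeric(sex == "male")
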