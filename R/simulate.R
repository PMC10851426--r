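#' Specify a synthetic two-group cohort
#'
#' The generator emulates a case/control cortical-thickness cohort with a
#' modular (block) covariance structure. Regions are split into contiguous
#' modules; each module has one latent factor per subject, and a group's
#' `loading` scales how strongly its regions follow their module factor.
#' Lowering the patient loading weakens within-module covariance, which
#' lowers clustering and local efficiency of the patient network -- a
#' monotone knob for the effect direction the pipeline is designed to detect.
#'
#' The per-region model (all in mm) is
#' `thickness = mean_thickness + signal_scale * loading_g * factor_module +
#'  beta_age*(age - mean(age)) + beta_sex*male + beta_tiv*(tiv - mean(tiv)) + noise`,
#' with `factor ~ N(0,1)` i.i.d. per subject and module, and
#' `noise ~ N(0, noise_sd)`. `signal_scale` puts the latent factor on a
#' realistic morphometric scale (regional thickness SDs are a fraction of a
#' millimetre) so that thickness stays strictly positive; the loading keeps
#' its dimensionless covariance-strength meaning, and only the ratio
#' `signal_scale * loading / noise_sd` drives the network topology. Ages are
#' Uniform(45, 70) (middle-aged to older adults), sex is Bernoulli(0.5),
#' TIV is Normal(1.45e6, 1.3e5) mm^3.
#'
#' @param n_patients,n_controls group sizes (defaults 56 / 59).
#' @param n_regions number of regions (default 148, the Destrieux count).
#' @param n_modules number of covariance modules (default 8).
#' @param loading_patients,loading_controls within-module factor loadings in
#'   `[0, 1]` (defaults 0.5 / 0.9: weakened local covariance in patients).
#' @param signal_scale mm per unit of latent factor (default 0.15).
#' @param noise_sd residual thickness standard deviation, mm (default 0.1).
#' @param mean_thickness scalar or per-region mean thickness, mm (default 2.5).
#' @param beta_age age slope, mm/year (default -0.01, mild age thinning).
#' @param beta_sex additive male offset, mm (default 0.05).
#' @param beta_tiv TIV slope, mm/mm^3 (default 2e-7).
#' @param seed integer seed; all generator randomness flows from it.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 56, n_controls = 59, n_regions = 148,
                        n_modules = 8, loading_patients = 0.5,
                        loading_controls = 0.9, signal_scale = 0.15,
                        noise_sd = 0.1, mean_thickness = 2.5,
                        beta_age = -0.01, beta_sex = 0.05, beta_tiv = 2e-7,
                        seed = 1L) {
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (signal_scale < 0) stop("signal_scale must be non-negative")
  for (l in c(loading_patients, loading_controls))
    if (l < 0 || l > 1) stop("factor loadings must lie in [0, 1]")
  if (n_patients < 4 || n_controls < 4) stop("each group needs >= 4 subjects")
  if (n_modules < 1 || n_modules > n_regions)
    stop("n_modules must lie in [1, n_regions]")
  structure(list(n_patients = n_patients, n_controls = n_controls,
                 n_regions = n_regions, n_modules = n_modules,
                 loading_patients = loading_patients,
                 loading_controls = loading_controls,
                 signal_scale = signal_scale, noise_sd = noise_sd,
                 mean_thickness = mean_thickness, beta_age = beta_age,
                 beta_sex = beta_sex, beta_tiv = beta_tiv,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# contiguous module assignment: every region in exactly one module
module_assignment <- function(n_regions, n_modules) {
  sort(rep_len(seq_len(n_modules), n_regions))
}

#' Generate a synthetic cohort
#'
#' Draws a [thickness_dataset] from a [cohort_spec]. The same seed yields a
#' bit-identical dataset; the caller's RNG state is untouched. Clinical
#' columns (`bmi`, `hba1c`, `cdt`, `ctt1`) are drawn at realistic scales for
#' a type 2 diabetes case/control cohort so that the correlation stage has
#' material to work with; they do not enter the thickness model.
#'
#' @param spec a [cohort_spec].
#' @param atlas optional [region_atlas] with `spec$n_regions` rows; by
#'   default the bundled Destrieux atlas (148 regions) or, for other sizes,
#'   synthetic region labels split evenly across hemispheres.
#' @return A [thickness_dataset] with group levels `patient`, `control`.
#' @export
generate_cohort <- function(spec, atlas = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(atlas)) {
    atlas <- if (spec$n_regions == 148) load_destrieux_atlas()
    else region_atlas(sprintf("R%03d", seq_len(spec$n_regions)),
                      rep(c("left", "right"), length.out = spec$n_regions))
  }
  if (nrow(atlas) != spec$n_regions)
    stop("atlas has ", nrow(atlas), " regions but spec wants ", spec$n_regions)
  with_seed(spec$seed, {
    n <- spec$n_patients + spec$n_controls
    group <- rep(c("patient", "control"), c(spec$n_patients, spec$n_controls))
    age <- stats::runif(n, 45, 70)
    sex <- ifelse(stats::rbinom(n, 1, 0.5) == 1, "male", "female")
    tiv <- stats::rnorm(n, 1.45e6, 1.3e5)
    bmi <- stats::rnorm(n, ifelse(group == "patient", 27.6, 25.9), 4)
    hba1c <- pmax(4, stats::rnorm(n, ifelse(group == "patient", 8.1, 5.3),
                                  ifelse(group == "patient", 2.0, 1.2)))
    cdt <- stats::rnorm(n, 28, 2.5)
    ctt1 <- pmax(20, stats::rnorm(n, ifelse(group == "patient", 75, 66), 20))

    mods <- module_assignment(spec$n_regions, spec$n_modules)
    fac <- matrix(stats::rnorm(spec$n_modules * n), spec$n_modules, n)
    loading <- ifelse(group == "patient", spec$loading_patients,
                      spec$loading_controls)
    mu <- rep_len(spec$mean_thickness, spec$n_regions)

    # subjects x regions: module factor scaled per subject + covariate effects
    signal <- t(fac[mods, , drop = FALSE]) * (spec$signal_scale * loading)
    covar_effect <- spec$beta_age * (age - mean(age)) +
      spec$beta_sex * sex_indicator(sex) +
      spec$beta_tiv * (tiv - mean(tiv))
    thick <- matrix(mu, n, spec$n_regions, byrow = TRUE) + signal +
      covar_effect +
      matrix(stats::rnorm(n * spec$n_regions, 0, spec$noise_sd),
             n, spec$n_regions)
    if (any(thick <= 0))
      stop("generated non-positive thickness; reduce noise_sd or effects")
    covariates <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                             group = group, age = age, sex = sex, tiv = tiv,
                             bmi = bmi, hba1c = hba1c, cdt = cdt, ctt1 = ctt1,
                             stringsAsFactors = FALSE)
    rownames(thick) <- covariates$subject_id
    ds <- thickness_dataset(thick, covariates, atlas)
    ds$covariates$group <- factor(ds$covariates$group,
                                  levels = c("patient", "control"))
    ds
  })
}

#' Reduce patient-group thickness in selected regions
#'
#' Simulates focal cortical atrophy: subtracts `delta` mm from the patient
#' group's thickness in the listed regions, leaving controls untouched.
#'
#' @param ds a [thickness_dataset].
#' @param regions character vector of region ids (must exist in the atlas).
#' @param delta non-negative thinning in mm.
#' @param group group level to modify (default `"patient"`).
#' @return The modified [thickness_dataset].
#' @export
inject_regional_atrophy <- function(ds, regions, delta, group = "patient") {
  stopifnot(inherits(ds, "thickness_dataset"))
  if (!is.numeric(delta) || length(delta) != 1 || delta < 0)
    stop("delta must be a single non-negative thickness reduction (mm)")
  unknown <- setdiff(regions, ds$atlas$region_id)
  if (length(unknown) > 0) stop("unknown region: '", unknown[1], "'")
  if (!group %in% levels(ds$covariates$group))
    stop("no group level '", group, "' in dataset")
  rows <- ds$covariates$group == group
  ds$thickness[rows, regions] <- ds$thickness[rows, regions] - delta
  if (any(ds$thickness[rows, regions] <= 0))
    stop("atrophy delta drives thickness non-positive")
  ds
}
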