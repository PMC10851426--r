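---
title: "Group comparison of cortical-thickness structural covariance networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group comparison of cortical-thickness structural covariance networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

A structural covariance network (SCN) is a group-level graph whose nodes are
cortical regions and whose edges are inter-subject Pearson correlations of a
morphometric measure — here, mean cortical thickness per region of the
148-parcel Destrieux atlas (74 per hemisphere). Regions whose thickness
co-varies across individuals are assumed to be anatomically or
developmentally coupled, so differences in SCN topology between a patient
and a control group indicate coordinated, network-level alterations of the
cortex that single-region analyses miss.

The pipeline implemented by `scn_compare()` is:

1. **Residualization.** Each region's thickness is regressed (OLS) on an
   intercept plus nuisance covariates — age (years), sex, and total
   intracranial volume (TIV, mm³) by default — and the residuals are kept.
   By default the regressions are fit *within each group* separately, the
   common SCN convention that keeps each group's matrix free of that
   group's own covariate structure; a pooled fit is available
   (`residual_scope = "pooled"`) since either choice is defensible.
2. **Correlation.** Pearson correlation of residuals over every region
   pair gives one symmetric 148 × 148 matrix per group; the diagonal is
   fixed at 0. A zero-variance region (possible in degenerate simulated
   data) would give undefined correlations; its pairs are set to 0 with a
   warning rather than propagating `NaN`.
3. **Density thresholding.** At each target density *d* in a sweep
   (default 0.10–0.40, step 0.01, 31 points), the `K = round(d·N(N−1)/2)`
   strongest edges are kept and binarized. Using a density sweep rather
   than a fixed correlation cutoff guarantees both groups' graphs have
   identical node and edge counts at every point, a prerequisite for
   comparing binary-graph metrics. Below density ≈ 0.1 a 148-node network
   has fewer edges than nodes (necessarily fragmented); above ≈ 0.5 it
   approaches a random configuration — hence the default range.
   Ranking is by *signed* correlation (most positive first); at these
   densities negative edges are effectively excluded, which matches the
   usual reading of "above threshold". `edge_rank = "absolute"` ranks by
   |r| instead. Ties at the cutoff are broken by lexicographic (i, j)
   node order so edge counts are exact and runs reproducible.
4. **Graph metrics.** On each binary graph: clustering coefficient *C*
   (mean of Watts–Strogatz nodal coefficients), characteristic path
   length *Lp*, global efficiency *Eglobal*, local efficiency *Elocal*,
   and the nodal metrics betweenness centrality (BC, raw Brandes), degree
   (DC), and nodal efficiency (NE). Small-world indices γ = C/C_rand,
   λ = Lp/Lp_rand, σ = γ/λ normalize against the mean of degree-preserving
   random networks (Maslov–Sneppen double-edge swaps, default 10 attempted
   swaps per edge); σ > 1 indicates small-world organization.
5. **AUC and permutation inference.** Each metric's curve over the sweep
   is reduced to its trapezoidal area under the curve (AUC), removing
   dependence on any single threshold. Group difference in AUC is tested
   by relabeling permutation: group labels are shuffled (sizes preserved),
   the *entire* pipeline — residualization included — is re-run on each
   relabeled split, and the two-tailed p-value is
   `(#{|null| ≥ |observed|} + 1) / (n_perm + 1)`, which is never exactly 0.
   Nodal p-values are Benjamini–Hochberg adjusted within each nodal
   metric family (148 regions per family), matching the granularity at
   which nodal results are usually reported.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| density sweep | 0.10–0.40 step 0.01 | thresholding range (dimensionless density) |
| covariates | age, sex, tiv | nuisance regressors before correlation |
| `residual_scope` | `"group"` | where covariate fits are estimated |
| `edge_rank` | `"signed"` | edge ranking for binarization |
| `n_perm` | 1000 | label permutations (reference analyses use 1000) |
| `n_random` | 100 (1000 for reference σ) | degree-preserving nulls per density |
| `swaps_per_edge` | 10 | Maslov–Sneppen mixing allowance |
| `fdr_q` | 0.05 | nodal FDR level |

Permutation testing of γ/λ/σ re-generates `n_random` nulls at every density
inside every permutation and is therefore expensive; the default metric set
(`C`, `Lp`, `Eglobal`, `Elocal`) omits them, and they can be requested
explicitly when the cost is acceptable.

## The synthetic cohort generator

`generate_cohort()` emulates a two-group case/control thickness study
(defaults: 56 patients vs 59 controls, 148 regions) with a latent-factor
block model. Regions are split into `n_modules = 8` contiguous modules
(~18 regions each); each module has one standard-normal factor per subject,
and a group's dimensionless loading in [0, 1] scales how strongly its
regions follow their module factor:

```
thickness = mean_thickness
          + signal_scale · loading_group · factor_module
          + beta_age (age − mean age) + beta_sex · male
          + beta_tiv (tiv − mean tiv) + N(0, noise_sd)
```

A lower patient loading (defaults 0.5 vs 0.9) weakens within-module
covariance, which lowers clustering and local efficiency of the patient
network — a single monotone knob for the effect direction the pipeline is
built to detect, cleanly separated from noise. Ages are Uniform(45, 70)
(the recruitment window of a middle-aged/older cohort), sex Bernoulli(0.5),
TIV Normal(1.45·10⁶, 1.3·10⁵) mm³; covariate slopes default to mild,
realistic values (−0.01 mm/year, +0.05 mm for males, 2·10⁻⁷ mm/mm³).

`signal_scale` (default 0.15 mm) puts the latent factor on a realistic
morphometric scale. A literal `loading · N(0,1)` term in millimetres would
exceed the 2.5 mm mean thickness several times per cohort and violate
strict positivity; only the ratio `signal_scale · loading / noise_sd`
(noise default 0.1 mm) drives the correlation structure, so the loading
keeps its meaning while thickness stays positive. The generator emulates
modular covariance, covariate effects and group topology differences; it
does *not* emulate spatial autocorrelation on the cortical sheet,
hemispheric asymmetry, site/scanner effects, or realistic lesion load — a
green simulation test therefore establishes correctness of the estimator
and its calibration, not robustness to those real-data features.

## Numerical and design choices

- **Disconnected graphs.** *Lp* is the mean over finite-distance ordered
  pairs only (not an efficiency substitution); because of this, *Lp* can
  briefly *rise* with density while components merge and long finite paths
  enter the average. `check_density_validity()` reports edge counts,
  component counts and a fragmentation flag (edges < nodes) per density so
  the convention's effect is auditable. Efficiencies use 1/∞ = 0 and need
  no convention.
- **BC is unnormalized** (raw Brandes, each unordered pair once): the
  permutation comparison is invariant to the normalization constant.
- **C is the mean nodal coefficient** (Watts–Strogatz), the convention
  underlying small-world γ; the transitivity ratio is deliberately not
  substituted.
- **Null networks** preserve the full degree sequence (Maslov–Sneppen),
  the field-standard null for γ/λ/σ; connectedness is not enforced, since
  enforcing it biases the null and all metrics tolerate disconnection.
  Each density's graph gets its own ensemble, so nulls are automatically
  density-matched.
- **Permutation design.** Residualization is re-estimated inside every
  permutation so the null keeps the groups exchangeable end to end.
  The (b+1)/(m+1) estimator avoids p = 0 and is unbiased.
- **Normality gate** for descriptive tables: Shapiro–Wilk at 0.05 per
  group chooses between the pooled-variance t-test and Mann–Whitney U;
  sex uses Pearson's χ² without continuity correction.
- **Power** for a two-sided two-sample t-test uses the noncentral t
  distribution with noncentrality `d·sqrt(n1 n2/(n1+n2))`, including the
  (tiny) opposite-tail rejection mass.
- **Partial correlation** residualizes both variables on the covariates
  and tests `t = r·sqrt((n−2−k)/(1−r²))` on `n−2−k` df; Bonferroni
  correction uses the number of pairs actually tested. Note that a
  group-level SCN yields no per-subject network metric, so the
  correlation stage operates on whatever per-subject quantities the user
  supplies (clinical scores, regional thickness, externally derived
  individual metrics).
- **Config echo** is JSON (`config.json`) rather than YAML: JSON is
  equally self-describing and the serializer is a hard dependency anyway.
- The compiled metric engine uses word-parallel (bitset) breadth-first
  search; local efficiency masks the search to each neighbourhood, so the
  full permutation loop runs in seconds. Every metric is verified in the
  test suite against brute-force oracles (Floyd–Warshall distances,
  exhaustive triangle and shortest-path enumeration) and against igraph.

## Test-suite scaling

The calibration test (type-I error of the AUC permutation test on
homogeneous cohorts) uses 60 regions and 32 + 32 subjects: an exact
permutation test is calibrated at any problem size, so the check is run at
a size that keeps 200 × 200 pipeline evaluations inside the suite's time
budget. Direction-recovery uses the full 148-region 56/59 default cohort
with `n_perm = 100`. Reference analyses should keep `n_perm = 1000`.

## Known limitations

- Group-level networks only: no subject-level SCN variants, weighted or
  partial-correlation (sparse inverse covariance) networks.
- Binary undirected metrics only; no rich-club, modularity or hub
  classification.
- The Mann–Whitney fallback reports the U statistic, not a t-like value,
  so mixed tables mix statistic types (the `test` column disambiguates).
- Thickness estimation from images is out of scope: the pipeline starts
  at the subjects × regions table.
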