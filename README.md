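# scnet — structural covariance network analysis of cortical thickness

`scnet` builds and compares group-level **structural covariance networks
(SCN)** from regional cortical thickness, for neuroimaging researchers who
have a subjects × regions thickness table (e.g. 148 Destrieux parcels
extracted from T1-weighted MRI) and want to know whether two groups — say
patients with type 2 diabetes and healthy controls — differ in the
topology of cortical covariance.

## The method

For each group *g*, thickness is residualized on nuisance covariates
(age, sex, total intracranial volume) and a Pearson correlation matrix
*R⁽ᵍ⁾ ∈ [−1,1]^{148×148}* is computed across subjects. At each density
*d* in a sweep (0.10–0.40, step 0.01), the *K = round(d·N(N−1)/2)*
strongest edges are binarized, so both groups' graphs always share node
and edge counts. On each binary graph the package computes the clustering
coefficient *C*, characteristic path length *Lp*, global and local
efficiency *E_global*, *E_local*, small-world indices

γ = C / C_rand,  λ = Lp / Lp_rand,  σ = γ/λ,

(normalized by degree-preserving Maslov–Sneppen random networks), and the
nodal metrics betweenness (BC), degree (DC) and nodal efficiency (NE).
Each metric curve is summarized by its area under the curve (AUC) over the
sweep, and group differences in AUC are tested by label permutation with
the full pipeline re-run on every relabeling:

p = (#{|Δ_null| ≥ |Δ_obs|} + 1) / (n_perm + 1),

with Benjamini–Hochberg FDR across regions for nodal metrics. A synthetic
cohort generator with modular latent-factor covariance provides a ground
truth for every stage. See the vignette
(`vignettes/structural-covariance-networks.Rmd`) for the model, defaults
and numerical conventions.

## Worked example

```r
library(scnet)
spec <- cohort_spec(seed = 42)     # 56 patients vs 59 controls, 148 regions
ds <- generate_cohort(spec)
comp <- scn_compare(ds, metrics = c("C", "Lp", "Eglobal", "Elocal"),
                    nodal_metrics = "NE", n_perm = 200, seed = 43)
print(comp)
```

```
Structural covariance network comparison
  groups: patient (n = 56) vs control (n = 59)
  densities: 0.10-0.40 (31 points), 200 permutations

Global metric AUCs:
  metric auc_patient auc_control      diff        p
       C      0.1614      0.1943 -0.032824 0.004975
      Lp      0.5689      0.5710 -0.002064 0.945274
 Eglobal      0.1805      0.1697  0.010802 0.004975
  Elocal      0.2277      0.2460 -0.018245 0.004975
```

The default generator plants weaker within-module covariance in patients
(loading 0.5 vs 0.9). The comparison recovers exactly that signature:
clustering and local efficiency AUCs are significantly *lower* in
patients (Δ < 0, p ≈ 0.005, the smallest value 200 permutations can
resolve), path length shows no difference, and global efficiency is
slightly *higher* in patients — a less modular network is easier to
traverse globally. `summary()` lists FDR-significant nodal rows,
`plot(comp)` draws the metric-versus-density curves.

Real data enter through `read_thickness_table()` (CSV/TSV, one subject-id
column plus one column per atlas region, covariates alongside or in a
companion file); `run_scn_pipeline(scn_config(...), outdir)` runs
everything end to end and writes TSV tables, a JSON config echo and a log.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from
scratch — it simulates the default two-group cohort, executes the full
residualize → correlate → threshold → metrics → AUC-permutation pipeline
(writing its tables under `<out-dir>/pipeline_outputs/`) — and writes the
JSON report to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
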