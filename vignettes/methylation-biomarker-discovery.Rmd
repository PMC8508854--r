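---
title: "Longitudinal methylation biomarker discovery: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal methylation biomarker discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Metabolically healthy obesity (MHO) — obesity with fewer than two NCEP
ATPIII metabolic syndrome criteria — is not always stable: over a decade,
part of the MHO population transitions to a metabolically unhealthy (MUO)
phenotype. `methmarker` implements a discovery pipeline for blood DNA
methylation markers of that transition in the hardest practical regime:
two small groups (stable vs unstable MHO, around nine subjects each),
EPIC-scale probe counts (hundreds of thousands of CpGs), and two time
points roughly a decade apart.

The pipeline is:

1. **Probe filtering** — drop sex-chromosome probes, SNP-adjacent probes
   and probes with detection p-value > 0.01 in at least 10% of samples.
2. **BMIQ normalization** — correct the compressed dynamic range of
   Infinium type II probes by a per-sample three-state beta-mixture
   quantile map onto the type I distribution.
3. **Transforms** — `M = log2(beta / (1 - beta))` for test statistics;
   beta for interpretation.
4. **Two-stage PCA selection** — stage 1 keeps the top ~1% of probes by
   variable contribution on the first two components of the follow-up PCA;
   stage 2 refits PCA at baseline on the stage-1 probes and keeps probes
   whose contribution exceeds half the best probe's contribution on
   component 1 or 2 (the half-max rule).
5. **Per-site validation** — Kruskal–Wallis tests on M-values at both time
   points (alpha = 0.05 at each), a hyper/hypo direction call from the
   beta-scale group difference, and by default a concordance requirement
   across time points.
6. **Gene summaries** — for every gene hit by a validated site, the
   fraction of all its array CpGs that are differential.
7. **Biomarker model** — backward stepwise logistic regression of
   transition status on standardized baseline M-values of the validated
   sites, reporting per-SD odds ratios with Wald 95% intervals.

A synthetic-cohort generator with planted, known effects makes each stage
testable by parameter recovery; the package's acceptance checks are
statements about recovering that ground truth, not about any particular
cohort.

# The synthetic cohort generator

`generator_config()` fixes the study design: 9 + 9 subjects, two time
points, 20,000 probes by default (the probes >> samples geometry of the
850k array at desk scale), 84% type II probes, 4% sex-chromosome probes,
5% SNP-flagged probes.

**Methylation landscape.** Each probe has a latent mean drawn from a
trimodal mixture — unmethylated `Beta(3, 17)`, hemimethylated
`Beta(10, 10)`, methylated `Beta(17, 3)` with weights 0.40/0.20/0.40 —
reproducing the bimodal-with-shoulder beta distribution of real arrays.

**Noise model.** Per cell, `beta ~ Beta(m * kappa, (1 - m) * kappa)` with
`kappa = beta_precision` (default 1000, i.e. a replicate-level beta SD of
about 0.016 at mid-methylation, mid-range for published EPIC technical
replicates). Between-subject biology enters separately as a subject random
intercept on the M scale, sized per probe so that the M-value correlation
across the two time points equals `within_subject_corr` (default 0.7).
Because the intercept is shared across time points, a subject's deviation
persists — which is exactly why realized group differences fluctuate
probe-to-probe in a way no amount of per-time-point averaging removes.

**Planted effects.** `n_differential` CpGs (default 60) carry a group
difference of `delta_beta` (default 0.15) in mean beta at both time
points, with random sign (hyper- or hypomethylated in stable MHO);
`n_predictive` CpGs carry a baseline-only M shift scaled to a per-SD log
odds ratio. The type II shrink toward 0.5 (default 0.3) is applied to the
complete mean signal — landscape and planted effect alike — because the
design bias is a property of the measurement chemistry, not of the
biology; BMIQ is the step that restores comparability. Consequently the
raw realized |group difference| averages about `0.75 * delta_beta` before
normalization and about `delta_beta` after.

**Phenotypes.** Covariates are drawn per subject-time so that the NCEP
ATPIII criterion count is below two for stable subjects at both time
points and for unstable subjects at baseline, and two or more for unstable
subjects at follow-up; `classify_metabolic_status()` therefore agrees with
the group labels by construction. Baseline triglycerides run higher in the
unstable group, mirroring the clinical covariate the biomarker model can
force in.

**What the generator does not emulate:** raw fluorescence intensities (so
no NOOB-style background correction is possible or needed), dye-bias
channels, cell-type composition, batch structure, and cross-reactive
probes. Passing recovery tests on this generator demonstrates the
pipeline's statistical machinery; it does not certify performance on real
arrays with those additional artefacts.

# BMIQ: the three-state quantile map

Per sample and design class, a three-state beta mixture is fitted by EM
with method-of-moments updates, initialized at fixed cut-points
(0.2 / 0.8) so the procedure is deterministic. Three numerical choices
matter and were made on measured grounds:

* **Capped iteration budget** (default 25, log-likelihood tolerance 1e-4,
  best-likelihood fallback). The three-beta model is deliberately simple
  and misspecified; run to full ML convergence it shrinks the
  hemimethylated state below its real share, which moves boundary probes
  out of the well-conditioned dilation map (below) and measurably degrades
  effect restoration. The mixture is a scoring device for state
  assignment, and a capped fit keeps the type I and type II fits
  comparable.
* **Outer states map empirically.** Unmethylated and methylated type II
  probes are quantile-mapped (midrank source quantiles, empirical target
  quantiles) onto the matching type I state. Parametric CDF-ratio maps
  were measurably worse: their position-dependent slope error multiplies
  per-probe effect sizes by a factor with ~10% spread.
* **The hemimethylated state is dilated linearly** between the images of
  its boundaries. The inter-mode valley is sparse, so any density-ratio or
  empirical-quantile map is ill-conditioned there; the linear dilation is
  the published method's own device for this state.

Rank order within each type II state is preserved (every state map is
monotone), type I probes are returned bit-identical, and outputs are
clipped to (1e-6, 1 - 1e-6). When a design class is absent the input is
returned unchanged; a non-empty class below 50 probes is an error.

# The two-stage PCA selection

PCA treats samples as observations and probes as variables and is computed
from the SVD of the centered samples-by-probes matrix, so no
probes-by-probes matrix is ever formed and memory stays linear in the
probe count. The contribution of probe *j* to component *k* is
`100 * loading_jk^2` (unit-norm loadings), summing to 100 per component
and invariant to eigenvector sign.

* **Selection scale.** The pipeline default runs the PCA selection on
  normalized beta values and the per-site tests on M-values. On the beta
  scale the measurement noise of a probe is bounded; on the M scale noise
  is inflated at extreme methylation, and in the probes >> samples regime
  that inflation is enough to bury the group axis: in planted-recovery
  simulations the selection on M-values recovered about 10% of planted
  sites versus about 70% on beta. The scale is exposed as
  `pca_scale = c("beta", "m")`.
* **Centering but no unit-variance scaling** (the classic PCA default).
  Correlation-scaled PCA was also measured and recovers less: scaling
  boosts pure-noise probes' contributions.
* **Stage 1** takes the per-component top-q union sized to exactly
  `round(stage1_fraction * n_probes)` probes (default 1%), trimming the
  union's overshoot at the last depth by (max contribution, probe id).
  Ties everywhere break by (contribution descending, probe id ascending).
* **Stage 2** applies the strict half-max rule per component (1 and 2) on
  the baseline PCA refitted to the stage-1 probes, combining per-component
  keeps by union. The rule is a ratio rule: its retention is governed by
  the sampling spread of realized per-probe effects, so with nine subjects
  per group even an oracle-normalized pipeline retains only ~80% of
  planted sites — a property of the rule at this sample size, not of the
  implementation.

# Per-site validation and gene summaries

`kruskal_wallis()` computes H on midranks with the tie correction
`H / (1 - sum(t^3 - t) / (N^3 - N))` and a chi-square p-value with
`groups - 1` degrees of freedom; the all-tied degenerate case returns
`(H = 0, p = 1)` (base R's `kruskal.test`, used as a cross-check oracle in
the test suite, returns NaN there). At 9 + 9 the chi-square approximation
is serviceable but coarse: against a 10,000-draw permutation oracle the
median |p difference| is about 0.03. No multiple-testing correction is
applied by default — validation requires raw p < alpha at *both* time
points, and the direction concordance filter (on by default) removes
sites whose group ordering flips.

Gene summaries test every manifest CpG of each gene hit by a validated
site, at the same alpha at both time points; the denominator of the
reported fraction is the gene's manifest probe count, so filtered-out
(untestable) probes count as non-differential.

Group descriptives use Kruskal–Wallis for continuous covariates and
chi-square (no continuity correction) for categorical ones, switching to
Fisher's exact test when any *expected* cell count is below 5 (the
conventional reading of the "frequency < 5" switch).

# The stepwise biomarker model

`fit_logistic()` is a hand-written IRLS maximum-likelihood fit with an
optional ridge penalty on the non-intercept terms and Wald standard errors
from the inverse (penalized) observed information; `stats::glm()` serves
as the independent oracle in the tests at penalty 0. Perfect separation
with penalty 0 is a loud error advising a penalty.

`backward_stepwise()` standardizes predictors to unit SD (so odds ratios
are per 1 SD of baseline M — the only defensible default when the original
scale is arbitrary), then repeatedly drops the free term with the largest
Wald p until all remaining terms satisfy `p < alpha_stay` (default 0.05);
an AIC criterion is available. Forced-in covariates (for example baseline
triglycerides) are never eliminated and are reported with their
non-significance visible, and the empty, intercept-only model is a valid
outcome. Ties break by term name.

In the pipeline the candidate set is the validated sites' baseline
M-values with 18 samples — typically more candidates than observations, so
`run_config()` defaults the pipeline's stepwise fits to a mild ridge
(`biomarker_penalty = 1`): without it the initial full model's likelihood
is unbounded. The standalone `backward_stepwise()` keeps penalty 0 with an
explicit error, because silently penalizing a well-posed problem would be
worse. With 9 + 9 subjects the odds ratios and intervals from such a fit
are descriptive, not confirmatory; the package's recovery guarantees for
the stepwise stage are demonstrated at n = 200 in the acceptance tests.

# Numerical conventions

* Beta values are clipped to `[1e-6, 1 - 1e-6]` before the M transform;
  the beta/M round trip is the identity within 1e-10 on that range.
* Eigenvector signs are fixed by making the largest-magnitude loading
  positive; contributions are invariant to this.
* Filter report precedence is sex > SNP > detection (a probe failing
  several rules is counted once); totals are unaffected. The detection
  rule is boundary-inclusive ("at least 10% of samples").
* All generator output is a pure function of the configuration and seed;
  each generator stage derives its own sub-seed so the manifest, cohort
  and matrices are individually reproducible. RNG state of the calling
  session is restored.

# Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run the full pipeline at the
default 20,000 probes with 20 cohort replicates for recovery and null
calibration, 5,000 null sites for type-I-error calibration, 50 random
matrices for PCA oracle equivalence, 200 small-sample cases against a
10,000-draw permutation oracle for the Kruskal–Wallis test, and 50
replicates at n = 200 for stepwise recovery. These sizes were chosen so a
complete run finishes in minutes on a laptop while leaving the binomial
error of every calibration check well below the tolerance being asserted.

# Known limitations

* The stage-1 "around 1%" rule and the stage-2 combine-by-union reading
  are one consistent interpretation of a procedure that admits others; both
  are parameters (`selection_params()`).
* The half-max rule's retention degrades quickly as per-probe effect
  spread grows; with very small groups this is the pipeline's sensitivity
  bottleneck.
* BMIQ here corrects a monotone design distortion of beta values; it
  cannot (and does not claim to) correct background fluorescence, dye
  bias, or batch effects.
* The biomarker stage at n = 18 is exploratory; its ridge-stabilized
  intervals should be read qualitatively.
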