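# methmarker

Discovery of CpG methylation biomarkers of the transition from
metabolically healthy obesity (MHO) to a metabolically unhealthy phenotype
(MUO), from small longitudinal EPIC-array cohorts.

A subject with abdominal obesity is MHO when fewer than two NCEP ATPIII
metabolic syndrome criteria are present (elevated blood pressure, fasting
glucose ≥ 100 mg/dL, low HDL, triglycerides ≥ 150 mg/dL, or treatment),
and MUO otherwise. Given blood methylation measured at baseline and at a
follow-up a decade later for a stable-MHO and an unstable-MHO group,
`methmarker` runs the complete discovery pipeline:

1. **Probe filtering** — sex-chromosome probes, SNP-adjacent probes, and
   probes with detection *p* > 0.01 in ≥ 10% of samples are removed.
2. **BMIQ normalization** — a per-sample three-state beta-mixture quantile
   map corrects the compressed dynamic range of Infinium type II probes.
3. **β/M transforms** — `M = log2(β / (1 − β))` for testing, β for
   interpretation.
4. **Two-stage PCA selection** — rank probes by their PCA *variable
   contribution* (`100 · loading²`, summing to 100 per component): stage 1
   keeps the top ≈ 1% of probes on components 1–2 of the follow-up PCA;
   stage 2 refits PCA at baseline on those probes and keeps probes whose
   contribution exceeds half the best probe's contribution on component
   1 or 2 (the half-max rule).
5. **Per-site validation** — Kruskal–Wallis tests on M-values, requiring
   *p* < 0.05 at **both** time points with a concordant
   hyper-/hypomethylation direction call (`Δβ = mean(stable) −
   mean(unstable)`).
6. **Gene-level summaries** — for each gene hit by a validated site, the
   fraction of all its array CpGs that are differential.
7. **Biomarker model** — backward stepwise logistic regression of
   transition status on standardized baseline M-values, reporting odds
   ratios per 1 SD with Wald 95% confidence intervals; clinical covariates
   (e.g. baseline triglycerides) can be forced in.

Because cohorts of this design are rare and small, the package ships a
synthetic-cohort generator (`simulate_cohort()`) that emulates the study:
two groups of nine subjects, two time points, EPIC-like probe metadata,
beta-distributed noise, subject-level longitudinal correlation, type II
design bias, detection failures, and **planted** differential and
predictive CpGs whose identities are recorded in a truth set. Every stage
of the pipeline is validated by recovering that ground truth.

## Worked example

A self-contained run on a simulated cohort (20,000 probes, 9 + 9 subjects,
60 planted differential CpGs at Δβ = 0.15):

```r
library(methmarker)

cfg    <- run_config(generator = generator_config(seed = 2024))
report <- run_pipeline(cfg)
report
#> Methylation biomarker discovery run
#>   probes retained: 18115 (baseline), 18139 (follow-up)
#>   stage 1 / stage 2 selected: 181 / 61
#>   validated sites: 51
#>   biomarker model: 2 of 52 candidates retained
#>   recovery: sensitivity 0.85, FDR 0.00
```

The filter kept ~18k of 20,000 probes (4% sex-chromosome, 5% SNP-flagged,
a handful of detection failures). Stage 1 kept 181 probes (1% of the
retained set), the half-max rule kept 61, and 51 survived Kruskal–Wallis
validation at both time points — 85% of the planted sites, with no false
discoveries.

```r
head(report$sites, 3)
#>   probe_id   p_baseline p_followup delta_beta_baseline direction
#> 1 cg00000469   0.000349   0.000349              -0.132 hypo_in_stable
#> 2 cg00000690   0.000349   0.000349               0.166 hyper_in_stable
#> 3 cg00000704   0.000349   0.000349               0.149 hyper_in_stable
```

`direction` calls a site hyper- or hypomethylated in the stable group,
with the group difference reported on the β scale at both time points
(0.000349 is the smallest p-value the rank test can produce at 9 + 9).

```r
tidy(report$model)[, c("term", "odds_ratio", "ci_low", "ci_high", "p.value")]
#>   term          odds_ratio ci_low ci_high p.value
#> 1 cg00015092         0.158 0.0442   0.567 0.00462
#> 2 triglycerides      2.12  0.497    9.02  0.311
```

The stepwise model retained one CpG — higher baseline methylation at
cg00015092 is protective (OR 0.16 per SD) — while the forced-in
triglyceride covariate stays in the table with its non-significance
visible. `report$recovery` scores everything against the planted truth:

```r
report$recovery
#>   n_planted n_validated sensitivity   fdr biomarker_recall
#> 1        60          51        0.85     0                0
```

`autoplot()` methods draw PCA score plots and odds-ratio forest plots;
`plot_site_deltas()` shows per-site β differences at both time points.
Real data enter through `run_config(paths = list(...))` with TSV matrices,
a TSV manifest and a CSV sample sheet (`read_manifest()`,
`read_matrix_tsv()`, `read_sample_sheet()`).

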