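# rankscreen

Rank-based cross-platform differential-expression screening, with the
downstream biomarker-evaluation toolkit used in leukemia relapse studies.

## The problem

Microarray cohorts measured on different platforms report intensities on
incomparable scales, so intensity differences between, say, B-cell acute
lymphoblastic leukemia (B-ALL) marrow and normal B cells cannot be compared
directly across platforms. `rankscreen` works entirely on within-sample
**percentile rank scores**: in each sample the *N* intensities are ranked
ascending and the value at rank *k* is mapped to the score
⌈100·*k*/*N*⌉ ∈ {1, …, 100} (ties receive the mean of their mapped
scores). Any strictly increasing per-sample distortion of the intensities —
which is what a platform change amounts to — leaves these scores, and every
statistic built on them, exactly unchanged.

For a gene *g* and condition *c* the **average rank score** is

> ARS(g, c) = mean over samples s in c of r(g, s),  ARS ∈ [1, 100]

and the screening statistic is the **delta**:

> Δ(g) = ARS(g, case) − ARS(g, control).

Genes pass the screen when Δ > 45 and ARS(case) > 80 (both configurable),
and are ranked by case ARS with delta as tie-break. Multi-probe genes are
collapsed beforehand to the probe with maximal all-sample ARS. Rank-based
expression (RBE) curves — the distribution of a gene's rank scores within a
condition — visualize each hit, and a configurable plasticity score
summarizes rank-score spread.

Downstream, the package evaluates a candidate transcript as a biomarker the
way such screens are validated clinically: ROC curve with Mann–Whitney AUC
and DeLong confidence interval, Youden-index cutoff, over-expression rate,
median dichotomization, Kaplan–Meier relapse-free survival, Aalen–Johansen
cumulative incidence of relapse with death-in-remission as a competing
risk, Gray's test, cause-specific Cox models with sequential backward
elimination (drop the worst covariate while its Wald *P* > 0.1), and qPCR
quantification (2^−ΔΔCt and standard-curve efficiency). Seeded generators
for expression cohorts with rank-shifted spike-in genes and for clinical
cohorts with proportional-hazards relapse, competing death and uniform
censoring make every stage testable without patient data.

## Worked example

```r
library(rankscreen)

# simulate a two-condition cohort with a +4 SD spiked gene, measured
# through a different monotone distortion per sample
co <- gen_expression(expression_sim_spec(
  n_case = 50, n_control = 50, n_genes = 500, probes_per_gene = 2,
  effect_genes = data.frame(gene = 42, shift = 4),
  distortion = "random", seed = 7))

scores <- co$expression |>
  rank_transform() |>
  collapse_probes(co$probe_map) |>
  gene_score_table(co$conditions)
screen_genes(scores)
#> # A tibble: 1 × 5
#>   gene_id ars_case ars_control delta pass
#>   <chr>      <dbl>       <dbl> <dbl> <lgl>
#> 1 g0042       98.2        39.7  58.5 TRUE
```

The spiked gene is recovered with a case ARS of 98.2 against a control ARS
of 39.7 (delta 58.5), despite every sample being measured on its own
distorted scale — rerunning without `distortion` gives the identical table.
The bundled published screen table behaves the same way:

```r
screen_genes(published_screen_table())   # all 20 genes, ranked by case ARS
```

Clinical evaluation chains the same way:

```r
ch <- gen_cohort(cohort_sim_spec(
  n_subjects = 168, beta = c(biomarker_high = log(5.32)), seed = 7))
tidy(cox_fit(ch, "biomarker_high"))
#> # A tibble: 1 × 7
#>   term           estimate    hr std_error conf_low conf_high  p_value
#> 1 biomarker_high     1.81  6.12     0.255     3.72      10.1  1.20e-12
point_estimate_at(cif_fit(ch), t = 60)   # 5-year cumulative incidence
```

Here the simulated true hazard ratio of 5.32 is estimated at 6.12 with a
95% CI of 3.72–10.1 in one 168-subject replicate; across many replicates
the estimator is unbiased (see the tests). `autoplot()` methods draw RBE
curves, ROC curves, KM and CIF step functions; `run_pipeline()` executes
the whole chain from files given a YAML config.

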