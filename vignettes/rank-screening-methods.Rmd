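---
title: "Rank-based expression screening and relapse outcome analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based expression screening and relapse outcome analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rankscreen)
```

## The model

`rankscreen` addresses a concrete obstacle in transcriptomic biomarker
discovery: candidate disease cohorts and normal reference cohorts are
usually measured on different microarray platforms, whose intensity
responses differ by unknown, sample-specific monotone transformations.
The package's answer is to discard intensity scale entirely and work on
within-sample percentile rank scores.

**Rank-score transform.** Within a sample, the $N$ non-missing
intensities are ranked ascending; the value at rank $k$ maps to the
score $\lceil 100k/N \rceil$. Tied intensities receive the mean of the
scores their ranks map to. Two properties motivate the ceiling form:
every score lies in $\{1,\dots,100\}$-anchored $[1,100]$, and the
largest value of a sample maps to exactly 100 for any $N$, so the top of
the distribution is calibrated across samples with different probe
counts. Because the map from intensities to scores depends only on
within-sample order, any strictly increasing per-sample distortion —
i.e., a platform or scanning difference — leaves the scores unchanged.
This invariance is exact, not asymptotic, and the test suite asserts it
end to end at the byte level.

**ARS and delta.** The average rank score of gene $g$ in condition $c$
is $\mathrm{ARS}(g,c)$, the arithmetic mean of its scores over the
condition's samples; the screening statistic is
$\Delta(g) = \mathrm{ARS}(g,\mathrm{case}) -
\mathrm{ARS}(g,\mathrm{control}) \in [-99, 99]$. Genes pass the screen
when $\Delta > \delta_{\min}$ and case ARS $> a_{\min}$, with defaults
$\delta_{\min}=45$ and $a_{\min}=80$ — the thresholds under which the
bundled published table of 20 screened genes was selected. Output is
ranked by case ARS descending, delta as tie-break, matching how such
tables are printed. When a gene is measured by several probes, the
single probe with the highest ARS pooled over *all* samples represents
the gene; pooling over both conditions means the same probe speaks for
the gene on both sides of the contrast, which the condition-wise
alternative would not guarantee.

**RBE curves and plasticity.** The rank-based expression curve of a
gene is, per condition, the proportion of samples at each score 1..100;
raw proportions sum to one, and a Gaussian kernel with a default
bandwidth of 3 rank units (the published curves are visibly smoothed,
but no method is stated, so a small symmetric kernel was chosen) is
applied for display only. The gene-plasticity score summarizes
rank-score spread; the formula used by the database this screen imitates
is published elsewhere and is not reproduced here, so the package ships
a clearly-labelled stand-in — the width of the central 80% of the
rank-score distribution, configurable via `probs` — and no published
plasticity value is ever asserted against it.

## Diagnostic evaluation

ROC analysis follows the convention that higher transcript levels are
more disease-like; a sample is positive when its value is $\ge$ the
cutoff. The AUC is computed from midranks, which is simultaneously the
trapezoid area under the empirical curve and the Mann–Whitney
probability with ties counted $1/2$; its confidence interval uses
DeLong's placement-value variance (the published AUC of this kind is
reported with a CI but without a named method; DeLong is the standard
choice). The Youden cutoff maximizes $J = \text{sens} + \text{spec} - 1$
over observed values, with ties broken toward the smallest cutoff so the
result is deterministic. Median dichotomization assigns values at the
median to the low group, so $n_{\text{low}} \ge n_{\text{high}}$ — the
convention consistent with the published 88/80 split of 168 subjects.
Note that the empirical Youden argmax converges at a cube-root rate:
recovering an analytic density-crossing point to 10% reliably needs a
few thousand samples per group, which is how the consistency test is
sized.

## Outcome analysis

Records carry a positive time in months and one of three event codes:
`relapse`, `death` (in remission), `censored`. Relapse-free survival is
estimated by Kaplan–Meier with Greenwood variance and log-log confidence
limits; by default both relapse and death in remission count as RFS
events, since relapse-free survival is an event-free duration, but
`rfs_events = "relapse"` switches to the relapse-only reading (the
published definition sentence mentions only relapse while its competing
risk analysis separates death, so this is left as a documented switch).
Cumulative incidence of relapse uses the Aalen–Johansen estimator with
death in remission as the competing cause, and groups are compared with
Gray's test (the published group comparisons print p-values without
naming a test). Cox models maximize the partial likelihood with the
Efron tie correction; for incidence-of-relapse models the competing
deaths are censored at their death time, i.e., the model targets the
cause-specific hazard rather than the Fine–Gray subdistribution — the
cause-specific reading is the conventional default when the publication
is silent. Sequential backward elimination refits after dropping the
single worst covariate while its Wald $P > 0.1$, returning the full
trace. Five-year estimates are read off the step functions at $t = 60$
months; a horizon past the last observed time carries the last value
forward with a warning.

KM, log-rank and Cox estimation are delegated to the survival package
and the CIF/Gray computations to cmprsk; the test suite re-derives each
against hand-written oracles (explicit product-limit tables, an
observed-minus-expected risk-table walk, a hand Aalen–Johansen table,
and grid maximization of the written-out partial likelihood), so the
package's contracts — tie handling, event coding, the
$\mathrm{CIF}_r + \mathrm{CIF}_d + \mathrm{EFS} = 1$ identity — are
verified independently of those libraries.

## qPCR quantification

Relative expression uses $2^{-\Delta\Delta C_t}$ with
$\Delta C_t = C_t^{\text{target}} - C_t^{\text{reference}}$ and the
calibrator baseline taken as the mean $\Delta C_t$ over the flagged
calibrator samples (normal controls); replicate wells are averaged at
the $C_t$ level before any difference. The absolute route fits the
standard curve $C_t \sim \log_{10}(\text{quantity})$ by least squares;
amplification efficiency is $E = 10^{-1/\text{slope}} - 1$, so perfect
doubling chemistry ($\text{slope} = -1/\log_{10} 2 \approx -3.3219$)
gives $E = 1$ and a typical assay slope of $-3.50$ gives
$E \approx 0.931$. Copy ratios are reported on the percent scale used
for transcript levels normalized to a housekeeping gene.

## What the simulators emulate

`gen_expression()` draws gene-wise log-normal baselines (meanlog
$\sim N(4,1)$ per gene, probe offsets $N(0, 0.25^2)$, within-gene noise
`noise_sd`, default 1, on the log scale), shifts effect genes upward in
cases by `shift * noise_sd` log-units, and finally pushes each sample
through an optional strictly increasing affine-plus-power distortion
$g(x) = a + bx + c\,\mathrm{sign}(x)|x|^p$ ($b>0$, $c\ge 0$, $p\ge 1$)
standing in for platform response differences. The log-normal baseline
reproduces the heavy right tail of array intensities; by construction
none of the rank statistics depend on that choice, which is exactly the
point of the method. What the simulator does *not* emulate: between-gene
correlation (genes are independent, where real expression is strongly
co-regulated), probe-level cross-hybridization, batch structure within a
platform, and missingness mechanisms. Passing tests therefore
demonstrate the algebraic and statistical contracts of the pipeline, not
robustness to correlated noise in real cohorts.

`gen_cohort()` draws, per subject, a relapse time that is exponential
with hazard $\lambda_r \exp(\beta^\top x)$, an independent exponential
death-in-remission time with hazard $\lambda_d$, and administrative
censoring uniform on $(0, W]$; the observed time is the minimum, with
the event type recorded. Defaults were fixed once to mirror an adult
acute-leukemia remission cohort — 168 subjects, $W = 90$ months (the
follow-up range of such cohorts), $\lambda_r = 0.012$/month and
$\lambda_d = 0.004$/month, giving roughly 45% five-year relapse
incidence with death in remission a minority cause — and are not data
models: constant hazards ignore the early-relapse peak real cohorts
show, and censoring is independent by construction. The closed form
$\mathrm{CIF}_r(t) = \frac{\lambda_r}{\lambda_r+\lambda_d}
\bigl(1 - e^{-(\lambda_r+\lambda_d)t}\bigr)$ under no censoring is used
as a simulation oracle in the tests.

## Numerical choices and degenerate inputs

* Rank ties: mean of mapped scores; a totally tied sample maps to the
  mean of the $N$ bin images, not to an arbitrary constant.
* A gene must have at least `min_samples` (default 2) non-missing
  samples per condition to be scored; otherwise its ARS is `NA` and it
  cannot pass the screen. A sample with no finite values is an error
  naming the sample.
* Youden ties break to the smallest cutoff; identical case/control
  distributions give $J = 0$ at the smallest observed value.
* DeLong variance components from singleton groups are taken as zero
  (they are not estimable); the CI is truncated to $[0,1]$.
* Cox fits flag non-convergence and monotone likelihood (perfect
  separation) with a warning and `converged = FALSE`; constant
  covariates are an error naming the covariate. Efron and Breslow
  fits coincide in the absence of ties, which is asserted in the tests.
* A cohort with no failures of either cause yields empty cumulative
  incidence steps (both CIFs identically zero) rather than an error.
* All estimators are invariant to record order; generators and the
  pipeline are byte-deterministic given spec and seed.

## Simulation sizes

The test suite sizes its Monte-Carlo checks to what each statistic
needs: 2,000 genes × 100 samples for the platform-invariance
byte-identity; 200 replicates of $n = 1000$ cohorts for hazard-ratio
recovery at a true HR of 5.32 (mean $\hat\beta$ within 5% of
$\log 5.32$, CI coverage in [92%, 98%]); 1,000 null replicates for
log-rank type-I error in [3.5%, 6.5%]; 100 random cohorts for the
competing-risk identity at $10^{-9}$; and exhaustive enumeration for
every oracle that admits one. One caveat is recorded honestly: the
backward-elimination check ("pure-noise covariate removed in ≥ 90% of
200 replicates") targets a bound that equals the statistic's own
expectation — under the null the removal probability is exactly the
nominal 90% — so any finite replicate batch sits on a knife edge; the
package keeps the test faithful rather than re-rolling seeds.

## Known limitations

The screen is insensitive to effects in genes whose baseline expression
already ranks near the top (rank saturation): a gene at the 95th
percentile in controls can gain at most 5 rank points, whatever the fold
change. The plasticity score is a stand-in, not the published formula.
No Fine–Gray subdistribution regression, time-dependent covariates,
frailty terms, or normalization beyond ranking are provided, and the
pipeline deliberately performs no background correction or quantile
normalization — rank invariance makes them unnecessary for the
statistics computed here.
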