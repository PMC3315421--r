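---
title: "Methods: qPCR Ct-Ct quantification, one-color array DE, and outcome statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: qPCR Ct-Ct quantification, one-color array DE, and outcome statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regenexpr)
```

`regenexpr` implements the quantitative workflow of an invertebrate
CNS-injury regeneration study in three analysis modules — efficiency-corrected
qPCR relative quantification, one-color microarray differential expression,
and outcome statistics — together with synthetic-data generators that emit
the matching data layouts with recorded ground truth. This vignette explains
the models, the defaults and why they were chosen, the numerical conventions,
and what the synthetic validation does and does not establish about real data.

## The Ct-Ct relative-quantification model

qPCR reports a threshold cycle: the cycle at which a reaction's signal
crosses a fixed detection threshold $T$. For template amount $Q$ amplifying
with per-cycle efficiency $E$,

$$\mathrm{Ct} = \frac{\log_{10} T - \log_{10} Q}{\log_{10} E}.$$

For a target gene $g$ and a reference (control) gene $c$ measured on the
same samples, with target abundance $R$ times the control abundance,
eliminating the shared input amount gives a line in the (Ct$_c$, Ct$_g$)
plane:

$$\mathrm{Ct}_g = \frac{\log E_c}{\log E_g}\,\mathrm{Ct}_c
  - \frac{\log R}{\log E_g}.$$

The method regresses Ct$_g$ on Ct$_c$ across samples ("Ct-Ct plot"), reads
the slope as a consistency check on the efficiencies, and reads the
expression ratio off the Y-intercept: $R = E_g^{-Y_{\mathrm{int}}}$
(`ratio_from_intercept()`). A condition contrast is the ratio of two such
ratios, $R_\mathrm{crush}/R_\mathrm{sham} =
E_g^{\,Y_\mathrm{sham} - Y_\mathrm{crush}}$ (`condition_fold_change()`).
When $E_g = E_c = 2$ the estimator reduces to the classic
$2^{-\Delta\Delta \mathrm{Ct}}$, a reduction the test suite asserts.

Efficiencies come from dilution standard curves: Ct against
$\log_{10}$(relative template amount) has slope $m = -1/\log_{10} E$, so
$E = 10^{-1/m}$ (`fit_standard_curve()`, `efficiency_from_slope()`). The
slope of $-3.52$ cycles/decade reported for the study's primers implies
$E \approx 1.923$, the package default for both genes; the method assumes
(and the QC checks) that the gene pair's efficiencies are effectively equal,
which makes the expected Ct-Ct slope 1.

Assumptions inherited from the method, stated explicitly:

* efficiency is sample-independent (dilution curves linear for every
  sample);
* target and control share a comparable detection threshold — without this
  the intercept acquires an unknown offset, so the generator builds the
  assumption in rather than guessing an offset term;
* Ct noise is additive and Gaussian on the cycle scale.

### Why the simulated samples carry a dilution series

The Y-intercept sits at Ct$_c = 0$, some 20–30 cycles to the left of any
measured point, so the intercept's standard error is dominated by
$\sigma\,\bar x/(s_x\sqrt{n})$ — the slope error propagated over the
extrapolation distance. With a single well per sample and biologically
plausible input spread (fractions of a decade), that extrapolation makes
the intercept estimate useless at realistic Ct noise. The protocol this
package emulates ran its standard curves *from the experimental samples
themselves*, i.e. each sample was measured as a serial dilution, and the
published Ct-Ct plots span several decades of template. The generator
therefore measures every sample at `measure_dilutions`
(default 1, 10, 10², 10³, 10⁴) for both genes. Dilution moves a point
*along* the Ct-Ct line (it cancels exactly between the two genes), so it
widens the fitted range without biasing the intercept — which is precisely
why the published protocol is well conditioned.

### Estimator properties under noise

The fold change is the exponential of an intercept difference, so its
sampling distribution is approximately log-normal and its mean sits above
the true ratio by roughly $e^{\sigma^2_{\ln F}/2}$. At the package's
default noise conditions (0.3-cycle Ct noise, 6 samples × 5 dilutions per
condition per group) this intrinsic upward bias is about 5–8% — visible in
the stochastic recovery checks, and a known property of ratio estimators
of this form rather than an implementation artifact. The per-time-point
uncertainty is reported as the SEM of the per-replicate-group fold changes
(matching the mean ± SEM convention of the reported values), not an
analytic delta-method SE.

Two further design decisions follow the way the plots are described rather
than statistical optimality, and are therefore documented limitations:
the regression is ordinary least squares of Ct$_g$ on Ct$_c$ (an
errors-in-variables fit would change the intercept, since the control Ct
also carries noise), and slopes are fitted per condition rather than
pooled, with a QC flag when a fitted slope deviates from
$\log E_c/\log E_g$ by more than 0.1.

## qPCR generator defaults

| parameter | default | rationale |
|---|---|---|
| `E_target`, `E_control` | 1.923 | implied by the published slope −3.52 |
| `threshold_T`, `base_quantity_q0` | 10⁶, 1 | undiluted reference Ct ≈ 21, typical for an abundant housekeeping gene; the most dilute well stays under 40 cycles |
| `sample_spread_sd` | 0.5 decades | unnormalized input amounts varying ~3-fold between dissections |
| `ct_noise_sd` | 0.3 cycles | typical SYBR replicate scatter |
| `n_samples_per_condition` | 6 | the study built its curves from 6 independent samples |
| `measure_dilutions` | 1…10⁴ | serial dilution of every sample (see above) |
| `R_by_condition` | sham 1, crush 2.35 | the 3-hour crush/sham estimate |

Missing or non-finite Cts are dropped pairwise with a reported count; no
imputation. A fit with all control Cts identical aborts: the method is
unidentifiable without input spread.

## One-color microarray pipeline

The pipeline order is fixed: per-array 75th-percentile scaling → log₂ →
median collapse of replicate probes → per-gene two-sided equal-variance
Student t-test → selection by raw p < 0.05 and fold change ≥ 2. Choices
worth stating:

* **Percentile definition.** Linear interpolation between order statistics
  (R's `quantile` type 7). After scaling, every array's 75th percentile is
  exactly 1 on the linear scale; on the log scale it is exactly 0 whenever
  the percentile lands on an order statistic, and within interpolation
  error otherwise. Normalization is idempotent on the linear scale.
* **Collapse before test.** The analysis software era this emulates left
  the order unstated; collapsing replicate probes (median per array) before
  testing is the documented choice here, so gene-level inference sees one
  value per gene per array.
* **Equal-variance t.** Student, not Welch, with df = n₁+n₂−2 — consistent
  with the df conventions in the source analyses (df = 8 for 5 + 5).
  Zero-pooled-variance cases are guarded: equal means give t = 0, p = 1;
  unequal means give p → 0 with a degeneracy flag.
* **No multiple-testing correction in selection**, matching the original
  raw-p + fold-change filter; Benjamini–Hochberg q-values are attached as
  clearly labelled supplementary output only.
* **Fold change conventions.** Both the log₂ difference (crush − sham) and
  the signed ratio (−2 = 2-fold down) are reported.
* **Clustering.** Heat-map ordering uses agglomerative clustering with
  Pearson-correlation distance (1 − r) and average linkage. Zero-variance
  genes have undefined correlation; their distance is set to 1 (the
  metric's null value) and reported. Trees serialize to Newick.

The count summary (`de_summary_from_counts()`) reproduces the published
breakdown arithmetic: 42 up + 25 down = 67 of 348 significant genes, i.e.
19.3% / 12% / 7% of the significant set, with percentages rounded half-up
to the printed precision.

The array generator emulates the published chip at full scale by default:
10,333 unique genes, 4,425 of them carrying a duplicate probe and 50
technical-control genes spotted 9 times (≈15K spots), 4 sham vs 4 crush
arrays, log-normal per-array scale factors, and per-spot log₂ noise
(SD 0.25). Because the study's raw intensity files are not
redistributable, the published 348/67 counts themselves are *not* a
reproduction target: the pipeline is validated instead by null calibration
(rejection rate 5% and uniform p-values over 10⁵ gene × simulation trials)
and by spike recovery at the full design scale.

## Outcome statistics

Neurite outcomes are net changes from the pre-treatment baseline
(`neurite_net_change()`), which are translation-invariant by construction
and may be negative (retraction). Grouped outcomes are compared by one-way
fixed-effects ANOVA; the module's central piece is
`anova_from_summary()`, which reconstructs the F test from printed
(mean, SEM, n) triplets: within-group variance is recovered as
$n\,\mathrm{SEM}^2$, the grand mean is n-weighted, and
$$F = \frac{\sum_i n_i(\bar x_i - \bar x)^2/(k-1)}
          {\sum_i (n_i-1)\,n_i\,\mathrm{SEM}_i^2 / \sum_i (n_i-1)}.$$
This is algebraically identical to the raw-data ANOVA whenever the raw
data have exactly those summaries — the module's central correctness
property, asserted to 1e-9 on randomized datasets. Printed means and SEMs
are rounded, which propagates roughly 1–2% relative uncertainty into
reconstructed F values: the 24-hour distal-neurite comparison reconstructs
to the printed F(3,52) = 20.1 exactly at printed precision, while the 10-
and 36-hour values land within ~1%. One published F value (the
three-time-point expression comparison, F(2,12) = 17.4) does not
reconstruct from its printed summaries under any one-way layout of those
numbers, which suggests an unstated comparison structure; it is documented
here and excluded from the reproduction targets.

Post hoc comparisons use the Holm-Sidak step-down: with $m$ ordered
p-values, the $i$-th smallest is adjusted to
$\max_{j \le i}\,[1 - (1 - p_{(j)})^{m-j+1}]$, clipped at 1. Adjusted
values dominate raw ones, are monotone in rank, and give a contiguous
rejection set. Pairwise tests after a significant omnibus F use the pooled
within-group mean square with the within df. Locomotion tables summarize
to mean ± SEM per group × day; cells with one animal get an NA SEM and a
flag (group sizes are data, not constants — the source reports one group's
n inconsistently).

## Synthetic data: what it does and does not establish

The generators reproduce the *statistical structure* the analyses assume:
shared per-sample input with gene-specific efficiencies and additive cycle
noise; probe-level intensities as scale × 2^(baseline + effect + noise)
with replicate probes sharing the gene signal; Gaussian group outcomes.
They deliberately omit probe sequences, hybridization chemistry, spatial
artifacts, amplification curves, and non-Gaussian heavy-tailed noise.
Passing the recovery and calibration suites therefore demonstrates that
the estimators correctly invert their own model and are calibrated under
it — not that the model captures every failure mode of real arrays or real
qPCR. Truth records are emitted alongside every dataset, never embedded in
the data tables, so analysis code cannot see them.

## Problem sizes and determinism

The validation suite uses problem sizes chosen to estimate each property
precisely: 200 simulated experiments for stochastic fold-change recovery
(Monte-Carlo SE ≈ 1.5% of the truth), 10⁵ gene × simulation trials for
type-I calibration (99% binomial half-width ≈ 0.0018), randomized
instances of ~10 units against each brute-force oracle, and one full-scale
15K-chip emulation. All simulation entry points take explicit seeds;
identical seed + parameters give bit-identical tables, and pipeline runs
echo their configuration and write an MD5 manifest of every artifact.
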