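---
title: "Methods: biopsy-stratified trial simulation and analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biopsy-stratified trial simulation and analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathotrial)
```

# The problem this package addresses

In rheumatoid arthritis, over half of patients have low or absent CD20+
B cells in the inflamed synovium, yet rituximab — a B-cell-depleting
antibody — is a standard choice after anti-TNF failure. A biopsy-driven
randomised trial design stratifies patients by synovial B-cell status
(the *pathotype*) before 1:1 allocation to rituximab or tocilizumab
(an IL-6 receptor inhibitor), and asks whether tocilizumab is superior
in the B-cell *poor* stratum. Pathotype can be assigned two ways:
semi-quantitatively from immunohistochemistry, or from bulk RNA-seq of
the biopsy via a B-cell lineage gene-module score. This package
implements both classifiers, the trial's endpoint and analysis
machinery, its randomization and design calculations, and a synthetic
trial generator with known ground truth so that every stage can be
validated end to end without patient data.

# Composite indices and endpoints

`cdai()` is the plain sum TJC28 + SJC28 + patient global (0–10) +
evaluator global (0–10), range 0–76. `das28()` implements both standard
variants (ESR: `0.56·√TJC + 0.28·√SJC + 0.70·ln ESR + 0.014·GH`; CRP:
`0.56·√TJC + 0.28·√SJC + 0.36·ln(CRP+1) + 0.014·GH + 0.96`) with GH the
patient global on a 0–100 mm scale. Both globals are carried separately
in the data model (0–10 for CDAI, 0–100 for DAS28) to avoid unit
ambiguity; the patient VAS is the GH fed to DAS28, per the cited index
standard, since trials rarely state which global they used.

Binary endpoints (`endpoint_flags()`): CDAI50% is week-16 CDAI at or
below half of baseline — ties count as response, matching the "≥50%
improvement" reading. CDAI low disease activity is ≤ 10.1; the *major
treatment response* (CDAI-MTR) requires both. Some sources state the
MTR threshold as "< 10.1" and others as "≤ 10.1"; the two agree for
one-decimal inputs and the `≤` form with a 1e-9 tolerance is
implemented. DAS28 LDA/remission thresholds are 3.2 / 2.6 for both
variants. A baseline CDAI of 0 makes CDAI50% trivially true; this is
flagged with a warning because eligibility criteria exclude it in
practice.

# Histology classification

The randomization stratum comes from an ordinal 0–4 CD20 score:
ungradable tissue → *unknown*; CD20 < 2 → *B-cell poor*; CD20 2–4 →
*B-cell rich*; rich tissue with CD21+ follicular dendritic cell
networks → *germinal-centre positive*. The published rule couples the
rich class to CD20 aggregates and leaves "CD20 ≥ 2 without aggregates"
undefined; because the poor rule is purely "< 2", the score alone is
operative here and the aggregates flag is retained for audit. This is a
documented convention of the package, not an assertion about any
particular trial's behaviour. Only poor and rich patients enter the
primary analysis. Dual-observer adjudication is modelled as a
disagreement *report* (`observer_disagreement()`), never an automated
resolution.

# Molecular classification

Counts are normalised by median-of-ratios size factors (rescaled so
their geometric mean is 1) and transformed as `log2(count/sf + 1)` —
a monotone, ratio-invariant, variance-stabilising transform. The
module score is the per-sample mean of transformed module-gene values;
the aggregation statistic is not fixed by published descriptions, so
the mean was chosen as the simplest unbiased summary and the median is
offered as an option. Classification uses the *cohort median* of the
scores: at or below the median → poor, above → rich. Ties at the
median go to poor; the rule depends only on score ranks, hence is
invariant under any strictly increasing transform. Mirroring the
trial's sample flow, GC-positive (by histology), never-dosed, and
RNA-QC-failed samples are removed before the median is computed; QC
status is an input mask, since alignment QC is out of scope.

`cutoff_scan()` re-runs the classification at percentile cutoffs 40–60
(median ± 10 percentile points, the package's reading of a "20% range")
and recomputes the poor-stratum primary-endpoint risk difference at
each cutoff. Cutoffs that empty a treatment cell are flagged rather
than fatal.

# Randomization

`block_randomize()` implements stratified permuted blocks with sizes
drawn uniformly from {6, 4} per stratum per block (the size schedule is
not published; uniform random choice is the package's convention) and a
uniformly permuted balanced arm sequence within each block. The
imbalance within any stratum therefore never exceeds 3 at any prefix.
The site factor is binary (lead centre vs others) by default but any
number of site groups is accepted. The audit log carries the stratum;
the exported redacted view does not, honouring the masking of site
staff to pathotype.

# The statistical battery

* **Risk differences** are reported in percentage points, alternative
  (tocilizumab) minus reference (rituximab), with the unpooled Wald
  interval. This choice was validated by recomputation: of 41 published
  table rows with all four counts printed, the Wald interval with
  half-away-from-zero integer rounding reproduces 29 exactly and all 41
  to within one display point; the residual one-point discrepancies are
  printing inconsistencies in the source tables (no single rounding
  rule reproduces them all). A Newcombe hybrid interval is available
  but matches the printed bounds less well. Unrounded values are always
  retained; the all-zero-cell Wald degeneracy is flagged.
* **Binary tests**: Pearson χ² without continuity correction (this
  reproduces the published primary-endpoint p = 0.035 for 12/33 vs
  20/32), switching to Fisher's exact (two-sided, point-probability
  method) when any expected cell is below 5. The expected-cell trigger
  is a convention; Yates correction is available as an option.
* **ANCOVA**: change-from-baseline regressed on arm plus baseline;
  least-squares mean changes are evaluated at the grand-mean baseline,
  and the effect is reference minus alternative, matching the published
  sign convention for continuous endpoints. The residual-normality
  check (Shapiro–Wilk at α = 0.01, configurable) routes failures to the
  **rank (Quade) ANCOVA**: ranks of change on ranks of baseline, arm
  compared on the residuals by one-way ANOVA — monotone-invariant in
  the change.
* **Within-group change**: two-sided Wilcoxon signed-rank with zero
  differences dropped. For up to 50 retained pairs the p-value is exact
  even under ties, via the convolution of the signed midrank null
  (doubled midranks are integers, so the full distribution is built by
  dynamic programming); `stats::wilcox.test` cannot produce exact
  p-values with ties, which the constant-shift case always has. Larger
  samples use the tie-corrected normal approximation with continuity
  correction.
* **Interaction**: likelihood-ratio test between nested logistic models
  (pathotype + treatment vs their interaction), χ²(1) reference.
  Separation is detected (non-convergence or coefficients beyond ±12 on
  the logit scale) and reported as an error advising exact or penalized
  alternatives.
* **Multiple imputation**: chained equations written in-package —
  type-1 predictive mean matching (Bayesian coefficient draws, 5
  donors) for continuous columns, Bayesian logistic draws for binary
  ones, 10 sweeps, m = 20 by default — pooled by Rubin's rules with
  Barnard–Rubin degrees of freedom. Chained equations is implemented
  even though one published description also names an EM-bootstrap
  package; the two are different algorithms and the text's own wording
  ("chained equations") is followed.

## Numerical conventions worth knowing

Threshold comparisons use a 1e-9 tolerance. Display rounding is half
away from zero (22.66 → 23, −3.5 → −4). Degenerate 2×2 margins give
p = 1 rather than `NaN`. The χ²-vs-permutation oracle equivalence is a
*large-sample* statement: the permutation null of a 2×2 table is
discrete, and the gap between the asymptotic p and the exhaustive
permutation p (mid-point convention at the observed atom) only falls
below 0.01 uniformly once expected cells are in the thousands; the test
suite draws tables of 3000–5000 per arm for that check and verifies the
exact discrete oracles (Fisher, signed-rank) at small n instead.

# Design calculations

`n_per_group()` reports the pooled-variance normal-approximation size
(39 per group at 0.20 vs 0.55, 90% power, α = 0.05 two-sided), the
Fleiss continuity-corrected size (44), and optionally a simulation
search, side by side — published protocol totals often sit between the
variants, and no agreement is forced. `power_sim()` verifies the power
claim directly: at 41 per group the simulated power of the uncorrected
χ² is ≈ 92%. `recruitment_chain()` divides the required poor-stratum
count by the poor fraction and the attrition survivals sequentially and
rounds once, up, at the end: 82/(0.60·0.90·0.95) = 159.8 → 160.

# The synthetic generator

`simulate_trial()` draws, per patient: a latent poor/rich class
(default P(rich) = 0.45, between the histology and RNA-seq splits
observed in the motivating cohort); an ordinal CD20 score agreeing with
the latent class with probability `histology_concordance` (default
0.9); GC positivity among rich biopsies (0.12) and ungradable tissue
(0.06); a site (lead centre share 0.38); treatment via the package's
own stratified permuted-block randomizer; baseline visits whose
components are parameterised to the motivating cohort's summary
statistics (CDAI median ≈ 30 via NB joint counts and Beta globals, ESR
log-normal median 31, CRP median 11); a week-16 responder indicator
drawn from the treatment × class rate table (defaults: poor 0.20/0.55,
rich 0.50/0.48 — the near-null rich-stratum rates used in the
interaction power analysis); and a week-16 visit constructed so the
recomputed indices are *consistent with the drawn responder status* —
responders' improvement fraction is uniform on (0.5, 0.9) with joint
counts rounded down, non-responders' on (0.05, 0.45) with joint counts
rounded up, which makes CDAI50% hold exactly for responders and fail
strictly for non-responders. Item-level gaps are missing at random
conditional on baseline CDAI (logit-linear, marginal rate
`missing_rate`); dropout removes the whole week-16 visit; never-dosed
patients (rate 0.02) are excluded from ITT; protocol violations (0.05)
from per-protocol; RNA QC failures (0.17) from molecular
classification.

Expression is a genes × patients negative-binomial matrix: gene means
log-normal, shared dispersion 0.3, per-sample library-size factors
log-normal (sd 0.25), and the first `module_size` (default 73) genes
multiplied by `2^(LFC·rich + noise)` with LFC = 2 and per-sample module
noise sd 0.3. Gene identity is irrelevant to the algorithms, so ids are
synthetic (`GENE00001`…) and the module is simply the first block.

What the generator does *not* emulate: read-level sequencing artefacts,
batch effects, gene–gene correlation beyond the module, informative
(MNAR) missingness, visit schedules beyond baseline and week 16, and
non-responder trajectory shapes grounded in any published distribution
(none exists; the uniform-improvement choice is the package's own and
is documented here, not inferred). Passing tests therefore demonstrate
the *machinery* — classification, allocation, inference, calibration —
not distributional realism of synovial transcriptomes.

# Problem sizes used by the checks

The test suite and the analysis scripts run the generator at 120–400
patients with 300–1000 genes (module 20–73), 100 replicate trials for
the coverage check, 2000-replicate calibrations for the rank-ANCOVA and
Wilcoxon sizes, 200 replicates at n = 4000 for LRT null uniformity, and
10,000 simulated trials for the power verification. These sizes were
chosen as the smallest at which the binomial/Monte-Carlo error bands
are decisive for each property.

# Known limitations

Patient-level published results (least-squares mean changes, the
interaction p-value, the exact cohort composition) depend on unreleased
trial data and are deliberately out of reach; only statistics
recomputable from printed counts are checked against the source. The
published rich-class rule's aggregate requirement is simplified (see
above). The median cutoff is computed per cohort; a fixed external
cutoff is not implemented. The VST surrogate is a shifted log, not a
dispersion-fitted transform; for median-cutoff classification only the
induced ranking matters, and the ranking is monotone-identical for any
shared monotone transform.
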