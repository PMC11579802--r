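---
title: "Methods: scoring, cut-point estimation, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, cut-point estimation, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(briefhine)
```

## The instrument

The Brief-HINE is an 11-item short form of the Hammersmith Infant
Neurological Examination, intended as a screening tool at the routine
assessment ages of 3, 6, 9, and 12 months (corrected age for infants born
preterm; the package stores a single age value and leaves the correction to
the caller). Each item is recorded in one of four optimality columns
scoring 3, 2, 1, or 0: column 1 holds the responses seen in more than 75%
of typically developing infants, columns 3 and 4 responses seen in fewer
than 10%. The global score is the sum of the 11 item scores and ranges from
0 to 33.

Six limb and postural-reaction items (scarf sign, hip adductors, popliteal
angle, tendon reflexes, lateral tilting, forward parachute) are recorded
separately for the left and right side. When the two sides fall in
different columns the item scores the arithmetic mean of the two column
scores -- hence half-point item and global scores -- and the item counts as
one asymmetry. Which items admit lateral recording is not fixed by the
instrument's published description; the package's choice (the six items
above, i.e. the lateralizable limb-tone and reaction items) is a documented
convention, and every scoring function accepts a modified item table for
sites that record laterality differently.

Three items -- trunk posture, lateral tilting, forward parachute -- have
responses that mature over the first year: low scores on these are normal
at 3 and 6 months and only become informative from 9 months. This is
encoded once, in the item table's `age_related` flag, and drives both the
warning-sign rules and the synthetic generator.

## Warning signs and referral

A *warning sign* is an item score outside the 90th centile of the
typical-outcome cohort at that age: column scores 0 and 1 for the eight
non-age-related items at every age, and for the three age-related items at
9 and 12 months only. `derive_warning_scores()` recovers this table from
data: a score `s` is flagged when the empirical cumulative frequency
`P(score <= s)` in the typical cohort is strictly below 0.10. Ties at
exactly 10% are not flagged -- "outside the 90th centile" is read as a
strict left tail. On a degenerate item where nearly every infant scores 3,
the rule correctly flags 0, 1, *and* 2; the published table contains no
such item because column-2 responses occur in more than 10% of typical
infants for all 11 items.

Averaged half scores need a policy the instrument does not state: is an
asymmetric item scoring 1.5 a warning sign? The package's default is
conservative -- a warning requires the *effective* score to be at or below
the highest flagged column (0, 0.5, or 1 under the default rules), so 1.5
is not flagged. `floor_half_scores = TRUE` switches to flagging by the
rounded-down column.

Referral for the full 26-item examination is triggered by strictly more
than one warning sign. The screening instrument's summary phrasing ("more
than one warning sign, or items that are not optimal for the age of
assessment") can also be read as a second, stricter trigger; the package
treats the clause as a restatement of the warning-sign rule by default and
offers the literal reading as `screen_exams(strict = TRUE)`, under which
any item below its age-optimal score (3, or 2 for age-related items at 3-6
months) also refers.

## Risk classification and cut-point estimation

The published age-specific cut-offs (22, 25, 27, 27 at 3, 6, 9, 12 months)
classify an infant as at risk of cerebral palsy when the global score is
*strictly below* the threshold; half-point scores are compared numerically
(21.5 at 3 months is at risk, 22 is not). `classify_risk()` carries its
cut-off table explicitly so re-estimated thresholds can be swapped in.

Cut-points are re-estimated by the Liu criterion: the threshold maximizing
the product of sensitivity and specificity on the empirical ROC, with the
positive call being `score < threshold` throughout (low score = at risk;
the ROC is computed in this orientation and never auto-flipped). Numerical
choices, all of which the published analysis leaves open:

* **Candidate set.** Distinct observed scores plus one value above the
  maximum, so both ROC corners are reachable. A reporting mode
  (`integer_grid = TRUE`) restricts candidates to the integers 0-34,
  matching the fact that published cut-offs are integers.
* **Ties.** Equal products are broken toward the smallest threshold (the
  most specific rule).
* **Degeneracy.** If every candidate has a zero product (single observed
  value, or complete overlap at the extremes) the smallest candidate is
  returned with `degenerate = TRUE` rather than an arbitrary interior
  value.

AUC uses the Mann-Whitney estimator -- the probability that a typical
infant outscores a CP infant, ties counted half -- computed rank-based; it
equals the trapezoidal area under the empirical ROC exactly, which the test
suite verifies to 1e-9 on tied data.

Confidence intervals are percentile bootstrap, stratified within class so
every resample retains both CP and typical subjects, with a fixed seed
required in the analysis config (default B = 2000). `run_study()` reports
intervals for the metrics *at the chosen threshold* (and for AUC); the
threshold itself is not re-estimated per resample, so these are
conditional-on-cutoff intervals, the same flavour as the published table.
Metrics with a zero denominator are reported `NA`, never 0. For display the
package rounds half up to 2 decimals, matching the published table's
formatting; `metrics_from_rates()` uses the same half-up convention when
rebuilding integer confusion counts from published sensitivity/specificity
and the cohort sizes (82 CP, 228 typical).

## The synthetic cohort generator

No patient-level data accompany the instrument, so the package ships a
generator whose defaults *are* the published study conditions: 228
typical-outcome infants and 82 with CP (40 unilateral, 17 bilateral
diplegia, 25 bilateral quadriplegia), each examined at all four ages.
Group-wise global-score distributions reproduce the published per-group,
per-age mean/SD/range table; asymmetry counts reproduce the published
per-subtype medians and ranges. Everything below these marginals is an
explicit modelling choice:

* **Distribution family.** Global scores are drawn from a normal
  distribution with the published mean and SD, truncated to the published
  range and rounded to the 0.5-point score grid. The family is an
  assumption (only mean/SD/range are published); truncation keeps every
  draw inside the observed range, and the grid rounding perturbs moments
  only in the second decimal. `tnorm_moments()` (closed form) and
  `score_dist_moments()` (exact grid summation) expose the analytic
  moments of the parent and of the actual sampling distribution, and the
  tests require n = 10 000 samples to match them within three standard
  errors.
* **Subtype SDs.** The published table gives SDs for the typical and
  pooled CP cohorts but only ranges for the subtypes; subtype SDs default
  to range/4, the usual normal-range heuristic.
* **Longitudinal dependence.** Repeated measures are tied by a Gaussian
  copula: each subject carries a latent standard-normal variable, and the
  age-specific latent is `sqrt(rho) * subject + sqrt(1 - rho) * noise`, so
  `rho` is the pairwise between-age correlation of the latent quantile
  (default 0.8; `rho = 1` makes trajectories comonotone). No within-subject
  correlation is published; 0.8 encodes strong tracking of neurological
  status across the first year while leaving room for measurement noise.
* **Asymmetry counts.** Per-exam counts are drawn from a truncated
  geometric distribution on the published range, with the weight ratio `q`
  fitted so the distribution's median equals the published median: for a
  median at the lower bound, `q = 0.45` (a clear majority of mass at the
  bound, whole range still reachable); otherwise `q` solves
  `(F(m-1) + F(m))/2 = 0.5`, centring the median bin on the half quantile
  so the empirical median is stable at any sample size (ratios above 1 are
  allowed when the target median sits high in the range). The typical
  cohort instead gets a single-asymmetry exam with probability 10/228 --
  the published count of typical infants with one asymmetry, used directly
  because the percentage printed beside it is internally inconsistent --
  and never more than one.
* **Item-level allocation.** Item responses realizing a target global
  score are constructed, not sampled from published item distributions
  (those appear only as figures). Asymmetric items take sides one column
  apart, so k asymmetric items fix the reachable scores' fractional part;
  the target is rounded to the nearest reachable half point. Scores are
  spread by decrementing a random item among those currently highest,
  which keeps profiles flat except at very low targets. For typical
  infants the three age-related items start depressed at the younger ages
  -- scores 0-1 at 3 months, and 0/1/2 with probabilities 0.15/0.25/0.60
  at 6 months -- reflecting that optimal responses on these items emerge
  only after 6 months, and chosen so that scores of 0 and 1 each remain
  above the 10th centile of the simulated typical cohort at 3 and 6 months
  (as in the published cohort) while the group mean is preserved. High
  targets raise these items back up from the top score down, consuming the
  low scores last. Item-level profiles are therefore illustrative; only
  the global-score and asymmetry-count marginals are calibrated.

## What the tests show, and what they cannot

The test suite checks the scoring arithmetic against brute-force oracles,
the Liu estimator against an exhaustive sweep on a thousand random
datasets, AUC against both an O(n^2) pairwise count and an independent ROC
implementation, the predictive-value arithmetic against the published
table (the 9-month PPV is excluded: no integer confusion matrix at the
published cohort sizes rounds to it, so it is recorded as internally
inconsistent), the warning-rule derivation against the published rule
table on a large simulated typical cohort, and the generator's marginals
against their analytic moments.

The end-to-end pipeline check is deliberately a *band* property, not a
reproduction: on the default simulated study the per-age Liu thresholds
must fall strictly between the CP and typical group means, sensitivity and
specificity must each reach 0.75, and AUC 0.85. The published accuracy
figures cannot be reproduced exactly because they depend on the joint
item-level distribution of the real cohort, which is not published; a
generator calibrated only to group marginals typically *overstates*
separation slightly (simulated AUCs run around 0.97-0.99 against published
0.88-0.94), because true score distributions are heavier-tailed than a
truncated normal. Passing these tests shows the machinery is correct under
the published marginal structure, not that the instrument's field accuracy
is re-demonstrated.

Problem sizes in the shipped tests are chosen to make sampling error
negligible relative to each tolerance at interactive runtimes: 10 000
draws per distribution check, a 1500-subject typical cohort for the
centile-rule recovery, and the full 310-subject design for the pipeline
band.

## Known limitations

* Item-level score distributions are schematic (flat profiles plus the
  age-related depression); analyses that depend on which *items* fail,
  beyond the warning-sign machinery, should not lean on the generator.
* The analysis treats ages independently, as the published cut-offs do;
  the longitudinal structure in the generator is not exploited for
  inference.
* Bootstrap intervals are conditional on the estimated threshold;
  cut-point selection uncertainty is not propagated.
* The instrument's clinical administration is out of scope: the package
  models recorded column scores only.
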