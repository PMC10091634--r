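---
title: "Methods: RSVP visual-dynamics screening analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RSVP visual-dynamics screening analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsvpscreen)
```

## The task and its measures

The rapid serial visual presentation (RSVP) task presents a stream of
characters at 150 ms per character (9 frames at 60 Hz, stored as metadata
only — this package performs no stimulus presentation). Two targets, the
letters T1 and T2, are embedded among digit distractors; the separation of
a trial is the number of digits strictly between the targets, one of
{0, 1, 2, 4, 5, 6, 8}. A session has 70 trials, 10 per separation, in
random order. Target letters are drawn from the Latin alphabet minus
I, O, Q, S, U, V, W, X, Z and distractors from the digits
{3, 4, 6, 7, 8, 9}; both exclusions remove characters easily confused with
one another at this presentation rate.

Performance at separation $s$ is summarized by two conditional
probabilities:

$$\mathrm{AB}(s) = P(\text{T2 correct} \mid \text{T1 correct}), \qquad
  \mathrm{AM}(s) = P(\text{T1 correct} \mid \text{T2 correct}).$$

The attentional blink (AB) is the failure to report T2 after a correct T1;
attentional masking (AM) is the failure to report T1 after a correct T2, a
deficit associated with cognitive impairment and reported absent in
healthy aging. The global metrics are the mean of AB (resp. AM) over
separations 0–2 — the short-separation region where group differences are
concentrated — expressed on a 0–100 scale.

## Task-design choices

The literature fixes the separations, the trial count and the character
pools but not the full stream geometry, so the remaining choices are
configurable with these defaults:

- **Padding.** `pre_t1` distractors precede T1, drawn uniformly from 5–10
  per trial so the T1 position is not predictable; `post_t2 = 3`
  distractors follow T2 so the second target is itself subject to
  backward masking (a trailing target would be trivially reportable).
- **No two consecutive identical distractors**, preventing perceptual
  fusion of repeated characters at 150 ms; digits may repeat
  non-adjacently.
- **T1 ≠ T2**, otherwise a single reported letter would be ambiguous.
- **Case-insensitive scoring** (`score_trial()`): reports are verbal and
  transcribed, so case carries no information. A missing report is scored
  incorrect.

Schedules serialize to JSON and outcomes to CSV
(`participant_id,trial_id,separation,t1_correct,t2_correct`); positions in
the serialized stream are 1-based, matching R indexing.

## Estimation and degenerate cells

`compute_curve()` estimates AB and AM as the count ratios
$n_{both}/n_{T1}$ and $n_{both}/n_{T2}$. A zero denominator leaves the
conditional **undefined (`NA`), never 0** — a participant who never
reports T1 correctly has no measurable blink. Where a defined number is
required downstream the undefined cell is imputed as 0, the conservative
worst-performance score, with a warning:

- in the 14-column feature matrix (`build_feature_matrix()`; columns
  `ab_0 … ab_8, am_0 … am_8`, ordering fixed in the CSV header);
- in the per-participant global metrics when computed through
  `participant_globals()`/`build_report()`. The strict path,
  `compute_global()`, instead raises a named error identifying the
  offending separation. With 10 trials per separation and the default
  model the imputation triggers in roughly 2% of simulated cohorts, so the
  end-to-end report must be total; the strict error remains the behaviour
  of the low-level function.

## The synthetic cohort generator

The clinical dataset behind the published summaries is not deposited, so
the package ships a generative stand-in that the whole pipeline (and its
tests) runs against. What it emulates, and what it does not:

- **Joint outcome model.** The published statistics are conditionals and
  their group means, which do not identify a sampling model; the generator
  is therefore parameterized by the joint probabilities
  $(p_{11}, p_{10}, p_{01}, p_{00})$ of the four (T1, T2) correctness
  outcomes per group and separation. `joint_from_conditionals()` inverts
  the target conditionals given a chosen $p_{11}$ — the free parameter. At
  separations 0–2 the default conditionals are flat with means matching
  the published global metrics (CI: AB 55.88, AM 47.32; HC: AB 88.61,
  AM 69.89) and $p_{11} = 0.30$ (CI) / $0.60$ (HC), values in the interior
  of the admissible region ($p_{11}(1/\mathrm{AB} + 1/\mathrm{AM} - 1)
  \le 1$). At separations 4–8 the conditionals follow a qualitative
  recovery shape — rising toward recovery for CI, staying high for HC.
  Published per-separation curve values are intentionally not digitized
  from figures; only their shape is emulated, and all values are
  configurable.
- **Scores.** CDT (integer support 0–7) and Phototest (integer, ≥ 0)
  scores are rounded truncated normals with the published means and
  sd = SEM·√n (CDT: 5.69/1.77 CI, 6.56/0.96 HC; Phototest: 33.08/5.88,
  41.56/3.21). Truncation and rounding shift the realized means slightly
  (visibly for the HC CDT, whose mean sits near the ceiling of 7) — the
  published values are the *latent* normal parameters.
- **Not emulated:** age, sex and education covariates (reported but never
  used computationally), within-participant learning or fatigue across
  trials, and any dependence between test scores and RSVP performance
  beyond shared group membership. Passing tests on synthetic cohorts
  therefore demonstrate the correctness of the estimators and classifiers
  under the stated model, not clinical performance: the synthetic groups
  are cleanly separated by construction, so classifier accuracies on
  simulated cohorts run higher than on clinical data.

Trial outcomes are simulated directly from the joint model; character
streams are only materialized when the task-design layer is exercised.

## Group comparison

`mann_whitney()` uses midranks, so tied cross-group pairs contribute ½ to
U, and reports `min(u_ci, u_hc)` — the conventional tabled statistic,
consistent with the identity effect size = 1 − U/(n₁n₂) when the HC group
is superior. For pooled samples up to 25 (the study's n = 22 included) the
two-sided p-value is **exact**: the null distribution of the rank sum over
all $\binom{n}{n_1}$ assignments is computed by a shift-algorithm dynamic
programme over doubled midranks, which is mathematically identical to full
enumeration; the test suite verifies this against a brute-force `combn`
oracle on small instances. Beyond 25 a normal approximation with tie
correction and continuity correction is used and flagged in the output.
The two-sided criterion counts splits with $|U - n_1n_2/2|$ at least the
observed deviation (with a 1e-9 slack against floating-point ties). The
significance level is fixed at 5% and no multiple-testing correction is
applied, matching the study design.

The common-language effect size is P(HC > CI) + ½P(tie) over random
cross-group pairs, identical to $u_{hc}/(n_1 n_2)$; `cles_from_u()`
recovers it from a reported minimum-U.

## Classification

All four procedures treat CI as the positive class and use the
strict-below rule — "score below the cutoff ⇒ CI" — so boundary scores
(exactly 6 or 29) classify HC.

- **Fixed cutoffs**: CDT < 6, Phototest < 29 (literature screening
  thresholds).
- **Sequential**: CDT first; only CDT-passers are assessed with the
  Phototest. Its CI set therefore contains the CDT rule's CI set (a tested
  invariant).
- **LOOCV threshold on global AM** (`loocv_threshold()`): per fold, the
  cutoff maximizing training accuracy is chosen among midpoints between
  consecutive distinct scores plus ±∞ sentinels; ties break toward the
  smallest cutoff (a determinate, conservative choice — the paper is
  silent on ties). Each participant is predicted by a threshold fitted
  without their data.
- **Grid-searched logistic regression** (`grid_search_loocv()`): l1/l2
  penalty crossed with C = 10⁻⁷…10⁷ (30 combinations), each evaluated by
  LOOCV accuracy over the whole grid; the best combination and its LOOCV
  predictions are reported. Selection by whole-grid LOOCV accuracy (rather
  than nested CV) mirrors reporting a single best hyperparameter pair and
  its cross-validated accuracy; the resulting accuracy is optimistically
  biased relative to nested CV, which we accept to keep the reported
  quantities aligned with the study's. Grid ties break toward the smaller
  C (stronger penalty), then l2 before l1.

`fit_logistic()` is a penalized maximum-likelihood fit (glmnet coordinate
descent, convergence threshold 1e-8, max 1e5 passes; the penalty excludes
the intercept) with λ = 1/(C·n), matching the inverse-regularization-
strength convention. Features are z-scored with **training-fold**
statistics by default (`standardize = TRUE`): penalized fits are
scale-sensitive and per-fold standardization avoids leaking the holdout
into the fit (verified by a mutation test: perturbing a held-out row never
changes its fold's fit). Zero-variance columns are left unscaled.

## Evaluation

Precision and recall are macro-averaged — the unweighted mean of the
per-class values — and a per-class precision with an empty denominator
contributes 0 with a warning. Accuracy intervals treat the n predictions
as Bernoulli trials and use the **Wilson score interval** (the inversion
of the normal score test); this choice reproduces the published intervals
at two-decimal rounding where Wald and Clopper–Pearson do not, and the
regression test keeping that identification is part of the suite. Reports
print two decimals; serialized JSON retains full precision, and a rerun
from the same seed is byte-identical.

## Problem sizes used in the tests

The suite runs the exact-test-vs-enumeration comparison on 200 random
instances with group sizes ≤ 4, the type-I-error simulation on 2,000 null
draws at n = 13 + 9, parameter recovery at 10,000 trials per separation
(tolerance ±0.02), the generator calibration over 200 simulated cohorts
(within 2 published SEMs), Wilson coverage over 5,000 binomial draws at
p = 0.7, n = 22 (≥ 93%), and the classifier-ordering property (grid-
searched logistic regression ≥ fixed CDT cutoff accuracy) over 50 seeded
cohorts (≥ 90% of replicates). These sizes give stable pass/fail behaviour
at the stated tolerances.

## Known limitations

- The generator's flat conditionals at separations 0–2 and qualitative
  recovery tail are the minimal structure reproducing the published group
  summaries; real per-separation curves have shape within 0–2 as well.
- Published p-values and U statistics are realized statistics of the
  unavailable clinical sample and are not reproduced numerically — only
  their methods and the derived identities (effect sizes from U, table
  metrics from confusion matrices, Wilson intervals from counts) are.
- LOOCV accuracy on 22 participants has high variance; the Wilson
  intervals in the report quantify exactly that.
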