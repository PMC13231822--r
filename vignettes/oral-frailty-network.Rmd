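---
title: "Methods: the oral-frailty reference network and analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the oral-frailty reference network and analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ofbn` re-implements, as reusable and tested code, a complete
epidemiological modelling workflow for oral frailty in
maintenance-hemodialysis (MHD) patients: univariate screening,
multivariable logistic regression, discrete Bayesian-network structure
learning with expert constraints, maximum-likelihood parameterization,
exact risk inference, sensitivity analysis and validation. This vignette
is the package's own account of the modelling choices: what is taken
from the published study verbatim, what had to be reconstructed, and
what a green test does and does not establish.

## 1. The model

A discrete Bayesian network over 12 categorical variables — the binary
outcome `oral_frailty` and 11 predictors spanning personal traits (age,
polypharmacy, malnutrition, poor oral health, general frailty),
behaviour and psychology (eating alone, dietary pattern, depression),
the interpersonal network (social support) and living conditions
(education, monthly income). The joint factorizes as

$$P(X_1,\dots,X_{12}) \;=\; \prod_i P\!\left(X_i \mid \mathrm{pa}(X_i)\right),$$

with one conditional probability table (CPT) per node. The reference
structure has 15 directed edges; the four direct parents of the outcome
are polypharmacy, malnutrition, eating alone and general frailty, and
all remaining predictors act through them.

**The contested 15th edge.** The published prose describes eating alone
influencing malnutrition both directly and through dietary pattern, but
never enumerates its 15 edges. The default edge set includes the direct
`eating_alone -> malnutrition` arc — the only reading that reaches the
stated 15 — and `reference_edges(include_eating_malnutrition = FALSE)`
drops it for users who prefer the purely mediated reading.

## 2. What is exact and what is reconstructed

Known exactly and compiled into the package (`load_fixtures()`):

* the outcome CPT: all 16 rows of the published conditional-probability
  table, stored to the 4 printed decimals (e.g. 0.9246 for the
  all-four-parents-present row);
* every variable's marginal distribution in the 680-patient cohort
  (both outcome groups pooled), which parameterizes the root priors;
* the univariate contingency counts, used by the screening tests and as
  a transcription guard (each variable's columns must sum to 388 / 292).

Not published, hence reconstructed: the CPTs of the internal nodes.
These use a **logistic-link calibration**. For a child with states
$s_1,\dots,s_K$ and published marginal $m$, row probabilities under a
parent configuration $c$ are

$$P(s_k \mid c) \propto \exp\!\Big(\log\frac{m_k}{m_1} + \big(\sigma(c) - \bar\sigma\big)\, w_k\Big),
\qquad w_k = \frac{k-1}{K-1},$$

where $\sigma(c)$ sums, over parents, a signed effect $\delta$ times a
linear score of the parent's state index scaled to $[-1, 1]$, and
$\bar\sigma$ is its expectation under the parents' marginals. Centring
by $\bar\sigma$ keeps each child's simulated marginal close to its
published value (the residual gap is the Jensen gap of the softmax, at
most a few points for the default $\delta$).

Parameters of the calibration, fixed once:

* $\delta = 0.8$ (the `effect` argument): a moderate log-odds shift per
  parent, comparable in size to the adjusted odds ratios of 2–5
  reported for the strongest predictors;
* sign $-\delta$ for the two relations that are protective in the study
  (more social support → less eating alone; higher income → less
  malnutrition), $+\delta$ elsewhere ("later parent state pushes toward
  later child states" — for education → income this encodes the
  positive gradient found in the study).

Under these defaults the exact model-implied outcome prevalence is
42.43%, against the published 42.94% — the reconstruction was **not**
tuned to this number; it falls out of the calibration.

Two continuous auxiliaries (handgrip strength, ultrafiltration volume)
are attached as per-outcome-stratum Gaussians solely to exercise the
*t*/Mann-Whitney code paths. Handgrip strength is published as
median (IQR); it is converted to mean/sd via sd ≈ IQR/1.349
(22.0/5.19 vs 18.0/2.97 kg), a normal-theory approximation adequate for
that purpose only.

## 3. Synthetic cohorts: what they emulate and what they do not

`sample_cohort()` performs ancestral sampling in the lexicographically
smallest topological order, driven by a single `set.seed(seed)` call, so
cohorts are byte-reproducible across platforms. An optional MCAR mask
adds missingness; the default is complete data, matching the study's
complete-case analysis.

The generator reproduces: the marginal composition of the cohort, the
published dependence of the outcome on its four direct parents, and
plausible (calibrated, not estimated) dependence along the remaining
edges. It does **not** reproduce: the true pairwise correlations among
predictors beyond what the 15 edges induce, item-level instrument
scores (OFI-8, OHAT, MQSGA, …; the pipeline consumes dichotomized
statuses), or dialysis laboratory dynamics. Consequently a green
end-to-end test establishes that the *machinery* is correct and
self-consistent — e.g. that a self-scored synthetic cohort yields an
apparent AUC bracketing the published 0.845 — not that the synthetic
cohort is distributionally identical to the original patients. In
particular, the synthetic univariate chi-squares for *indirect*
predictors (age, education, income, depression, poor oral health) are
much smaller than the published ones, because a single mediated path
with $\delta = 0.8$ carries less association than the real data did.

## 4. Statistical conventions

* **Chi-square**: no Yates continuity correction anywhere — the
  published 2×2 statistics match the uncorrected formula (verified in
  the suite to ±0.01 for all rows). Expected counts from the margins;
  `df = (r-1)(c-1)`.
* **Continuous screening**: Shapiro-Wilk at α = 0.05 per outcome group
  routes to the pooled *t* test (both normal) else Mann-Whitney; the
  source describes the choice only as "as appropriate", and the pooled
  variant matches the commonly reported SPSS output line. Groups larger
  than 5000 are Shapiro-tested on a deterministic evenly spaced
  subsample (the test itself is capped at 5000).
* **Mann-Whitney**: midrank *U*, tie-corrected variance, two-sided
  normal *p*.
* **Logistic regression**: forced single-step entry of all screened
  variables (no stepwise selection is described in the source);
  reference level = first listed state; Wald (not likelihood-ratio)
  *p*-values; CI multiplier fixed at 1.959964; IRLS convergence at
  `max |Δβ| < 1e-8`, 100-iteration cap; coefficients exceeding 15 in
  absolute value trigger a separation warning and stop the iteration.
* **Hosmer-Lemeshow**: risk-ranked near-equal deciles,
  `Σ (O−E)²/(E(1−E/n_g))`, df = bins − 2; degenerate bins (expected 0
  or n) are merged with a neighbour and the merge is messaged.

## 5. Structure learning (MMHC)

* **CI test**: G² with per-stratum df adjustment — strata sum
  `(r_eff − 1)(c_eff − 1)` over their non-empty rows/columns, and
  strata with under two observed levels on either axis contribute
  nothing. α defaults to 0.05; the maximum conditioning-set size is 3
  (tractability guard at 12 nodes).
* **MMPC**: forward phase admits the candidate with the smallest
  worst-case *p* (equivalently, the largest minimum association
  `1 − p`) over conditioning subsets of the current set; ties break by
  smaller df, then lexicographic variable order. Backward pruning, then
  symmetry by intersection.
* **Score**: decomposable BIC, log-likelihood minus `(k/2)·ln N` per
  node, *higher is better* — stated explicitly because sign conventions
  differ between communities.
* **Search**: first-improving greedy ascent over add/delete/reverse
  moves in a fixed enumeration order (adds before deletes before
  reversals, lexicographic edges), restricted to the MMPC skeleton plus
  the whitelist, never violating the blacklist, acyclicity or the
  5-parent cap. The fixed order makes results platform-deterministic.
* **Expert constraints**: the study refined its learned structure by
  expert edits; `edge_constraints()` expresses these as whitelist /
  blacklist, and the default pipeline whitelists the full reference
  edge set (the published post-edit structure). Exact replication of
  the published figure from data alone is *not* asserted anywhere: the
  original run's test level, score and tie rules are unknown, so the
  published structure ships as the reference spec instead.

## 6. Inference

Exact inference by variable elimination: evidence absorbed by factor
slicing, hidden variables summed out in min-fill order (lexicographic
tie-break), result renormalized. Evidence with zero probability under
the model raises an error rather than returning NaN. The suite holds
elimination to exhaustive joint enumeration at 1e-9 on random networks,
and `conditional_table()` reproduces all 16 published outcome rows to
5e-5 (absorbing the 2-decimal printed rounding). Per-record risk
scoring (`predict_proba`) deduplicates identical evidence patterns, so
scoring a 5000-record cohort costs a few seconds.

## 7. Sensitivity and validation

The original analysis reports a GUI-computed sensitivity index whose
definition is not published. The package therefore offers two
*documented* indices — max-swing (default; the largest change in
`P(outcome = yes)` achievable by switching the probed node's state,
a 0–1 scale like the published column) and mutual information — and the
published values are never asserted against them; rankings may be
compared qualitatively, values may not.

Validation is apparent (training-set) performance, matching what the
source reports: ROC swept over unique predictions, trapezoidal AUC
(equal to the midrank *U* statistic — a property test), Youden
threshold with ties resolved toward the lower threshold,
equal-count decile calibration, Hosmer-Lemeshow with df = 8 at 10 bins.
The published AUC 0.845 / sensitivity 0.843 / specificity 0.814 /
HL 11.588 depend on the unavailable patient-level data; the substituted
acceptance check requires a self-scored synthetic cohort's AUC to fall
in [0.78, 0.90], which brackets the published value.

## 8. Numerical and degenerate-input choices

* CPT rows must sum to 1 within 1e-9 (validation rejects otherwise);
  posteriors renormalize and must sum to 1 within 1e-9.
* MLE rows for parent configurations never observed are uniform with a
  warning (or smoothed via `pseudocount`).
* Degenerate contingency tables (zero row/column margins), single-state
  screening columns, empty cohorts, zero-variance *t* inputs, all-tied
  Mann-Whitney inputs, single-class ROC outcomes and cyclic edge sets
  are rejected with informative errors; the screening loop skips
  single-state columns with a warning rather than aborting a run.
* All randomness in a pipeline run descends from the single configured
  seed; manifests record seed, configuration and versions, and two runs
  with the same configuration produce byte-identical artifacts.

## 9. Known limitations

* Internal-node CPTs are calibrated, not estimated — synthetic indirect
  associations are weaker than the originals (section 3).
* The univariate screening of a *simulated* 680-patient cohort
  therefore typically selects fewer variables than the study did; the
  pipeline's default `use_reference_nodes = TRUE` keeps the published
  11-node set for the network stages, with the regression-driven
  selection available as an option.
* One published univariate statistic (the depression row, χ² = 13.294)
  is inconsistent with its own printed counts, which recompute to
  ≈ 24.50; the package follows the counts and documents the
  discrepancy.
* No approximate inference, no continuous/hybrid networks, no
  equivalence-class (CPDAG) output, no bootstrap edge confidence, no
  multiple-testing correction (the source applies none).
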