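---
title: "Methods: from coded trials to graded evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from coded trials to graded evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cotmeta)
```

`cotmeta` turns a directory of coded controlled trials of
cognition-oriented treatments into per-study standardized effects, pooled
random-effects estimates, certainty grades and a synthesis report. This
vignette explains the statistical model at each stage, the parameters that
matter and their defaults, the numerical choices, and what the synthetic
calibration harness does and does not demonstrate.

## The trial record

A trial is one YAML document: citation, a workflow status, coding items
with controlled vocabularies, arms (each `experimental` or `control`),
measures, and numeric cells (n, mean, SD per arm × measure × time point ×
optional subgroup). Two modelling commitments are baked into the schema:

* **Every measure declares a direction** (`higher_better` /
  `lower_better`). Effects are reported with the convention that a
  positive g favors the experimental condition; without a declared
  direction that convention is unimplementable for inverted scales (many
  clinical instruments score symptoms, where lower is better), so the
  field is mandatory even though it is an analyst's judgement rather than
  something printed in most papers.
* **Cells may carry a missing SD.** Trials reporting means without
  variability are real and must load; they are excluded from every
  analysis automatically, with a logged reason, rather than rejected at
  the door. An SD of zero or a cell n below 2, by contrast, is a schema
  violation.

Time points are ordinal labels, not dates; effects are computed per time
point and never combined across time points. Baseline cells may be stored
but the effect engine only contrasts the groups at the analyzed time point
(change-from-baseline effects, which need pre–post correlations, are out
of scope).

The coding item catalogue and all scoring/grading rules are data
(`inst/extdata/*.yaml`), not code, because repository administrators add
items and response alternatives over time; extending them must not require
a release.

## Quality scoring

PEDro, Jadad and Cochrane Risk of Bias ratings are evaluated from the
coded items by per-item predicate rules (one editable YAML table per
index). Some scale items genuinely combine several coded responses — for
instance the Jadad "appropriate randomization" point requires both a
randomized design and an adequate sequence-generation method. Three
policies hold everywhere:

* a predicate only fires on positively coded evidence — a missing item
  scores unsatisfied (PEDro/Jadad) or leaves a domain unclear (RoB);
* a high-risk code beats a low-risk code within an RoB domain;
* no imputation, ever.

This makes scoring monotone (coding more satisfied items never lowers a
total) and conservative (removing coded information never improves a
rating), both enforced by property tests. The retention threshold for the
PEDro follow-up item is the scale's published >85%. Jadad is implemented
as the five additive points (randomization mentioned/appropriate, blinding
mentioned/appropriate, withdrawals described) without the deduction
variant: deductions would make scores non-monotone in the coded evidence,
which conflicts with the conservative-missing-data policy above; the
additive form spans the same 0–5 range.

## Per-study effects

Hedges' g with the small-sample correction:
d = (m̄_E − m̄_C)/s_pooled, J = 1 − 3/(4(n_E+n_C−2) − 1), g = J·d, and

Var(g) = J²·[(n_E+n_C)/(n_E n_C) + d²/(2(n_E+n_C−2))].

The variance uses d² (not g²) inside the bracket with the J² prefactor —
one of several textbook-equivalent variants; the oracle tests pin this
choice. Single-study confidence intervals use the normal 1.96 multiplier
(the t-based HKSJ correction applies only at the pooled level).

**Subgroups.** When a study reports only disjoint subgroups, subgroup
effects are combined by inverse-variance fixed-effect meta-analysis into
one study-level effect (the subgroups are independent samples, so a
common-effect combination within the study is appropriate).

**Multi-arm trials.** All experimental-vs-control (and
experimental-vs-experimental) pairwise comparisons are computed.
Comparisons sharing an arm are correlated; their covariance is taken as
J_k·J_l·(1/n_s + d_k·d_l/(2(N−2))) with n_s the shared arm's size and N
the total over the three distinct arms — the leading 1/n_s term dominates,
the d-product term is the usual second-order SMD correction. Each
comparison's variance is then inflated to ṽ_k = 1/(Σ⁻¹1)_k, which is
exactly the inflation that makes naive fixed-effect pooling of the
adjusted comparisons reproduce the generalized-least-squares estimate and
variance under the full covariance matrix Σ. The GLS equivalence — not
the covariance formula — is the binding contract, and is verified against
an independent GLS solve on hundreds of random 3–4-arm fixtures to 1e−8.
Experimental-vs-experimental comparisons are stored (they answer a
head-to-head question) but never pooled against controls, preserving the
"positive favors experimental" semantics.

**Correlated outcomes.** When one study contributes several measures of
the same broad domain on the same participants, they are combined as the
composite: ḡ with variance (1/m²)[Σv_i + Σ_{i≠j} r√(v_i v_j)]. The
between-measure correlation is rarely reported, so it defaults to
r = 0.50 — a deliberate middle value: r = 0 would overstate the
composite's precision, r → 1 would concede no gain at all. The variance is
monotone in r, so sensitivity analyses simply re-run with another value.
Where a trial is both multi-arm and multi-measure, the multi-arm
adjustment is applied first (it operates within a measure), then the
composite across measures.

## Pooling

For each (broad outcome, population) group, each study contributes one
combined effect. Eligibility is mechanical: studies without usable means
and SDs at the analyzed time point are excluded (and logged), and a group
pools only when at least `min_k = 3` studies remain — below that a pooled
estimate is more misleading than none.

The random-effects model uses the REML estimate of τ², obtained by
bounded scalar maximization of the restricted log-likelihood

−½[Σ log(v_i+τ²) + log Σ w_i + Σ w_i (y_i−μ̂)²],  w_i = 1/(v_i+τ²)

on [0, 10·(max v + var y)], with an explicit comparison against the τ² = 0
boundary and a local refinement pass (final accuracy well below 1e−8; the
test suite checks agreement with a brute-force grid search to 1e−6 and
with metafor). The pooled estimate uses weights 1/(v_i+τ̂²); its standard
error is the Hartung–Knapp–Sidik–Jonkman weighted-dispersion form

se²_HKSJ = Σ w_i (y_i−μ̂)² / [(k−1) Σ w_i]

with t(k−1) intervals. Plain HKSJ is used, with no ad-hoc variance floor:
when all study effects coincide the interval honestly degenerates to a
point, which is documented behavior rather than patched away.
Heterogeneity is reported as Cochran's Q (χ²_{k−1} p-value, flagged at
p < 0.10 — a flag only, never a gate on pooling), I² = max(0,
100·(Q−(k−1))/Q), and a 95% prediction interval μ̂ ± t(k−2)·√(τ̂²+se²)
(the k−2 degrees-of-freedom convention; k−1 is available via the
`prediction_interval(df=)` argument). Total participants count each
study's contributing arms once, at the analyzed time point, whole-study
rather than per-comparison in multi-arm trials.

## Grading and summaries

Certainty per pooled outcome is a pure function of three banded
components: mean methodological quality of contributing studies (PEDro by
default; mean ≥ 7 favorable, 4–6 intermediate, < 4 unfavorable), I²
(< 30% / 30–60% / > 60%), and precision as total participants (≥ 400 /
100–399 / < 100). The level is *high* iff all three are favorable, *low*
iff the quality band is unfavorable or any two bands are, and *moderate*
otherwise. These thresholds are a declared, config-driven stand-in for a
repository's house rules — the engine is threshold-driven precisely so a
different calibration drops in without code changes — and the monotonicity
of the rule (improving one band never lowers certainty) is property-tested
over all 27 band combinations.

Recommendations follow a fixed mapping: low certainty → none, regardless
of effect; moderate/high certainty → modest/strong, in favor when μ̂ > 0
with an HKSJ CI excluding zero, against when μ̂ < 0 with CI excluding
zero; a CI containing zero → none. Significance means the HKSJ CI, not
p_Q and not the per-study normal CI. Narrative wording uses the
conventional Cohen magnitude bands (|g| < 0.2 trivial, < 0.5 small, < 0.8
moderate, else large).

The report itself has seven fixed sections (overview, disclaimer, search
results, overall summary, detailed report, references, statistical
information). Narrative percentages — U3 = 100·Φ(g), overlap =
200·Φ(−|g|/2) (the overlapping coefficient of two unit-variance normals),
probability of superiority = 100·Φ(g/√2) — are rounded half-up to integer
percent in text; tables keep full precision. Report content is
deterministic given its inputs; timestamps live only in the run manifest.

## The synthetic repository and what it shows

`generate_repository()` draws each study's true effect θ_i ~
N(μ, τ²) and reports arm-level summaries on a standardized control scale
(control mean 0, SD 1), so μ is directly a standardized effect and
recovery targets are exact. Summary statistics are drawn from their exact
sampling distributions — means from the (multivariate) normal with
between-measure correlation `latent_r`, SDs from the scaled-χ
distribution — which is distributionally identical to simulating
individual participants at a fraction of the cost. Structural features of
real repositories are emulated with configurable probabilities: a second
experimental arm (default 0.15), subgroup-only reporting (0.10), missing
SDs (0.10), two correlated measures at r = 0.50, arm sizes uniform on
20–60, and three coding-quality profiles (ideal/moderate/weak at
0.3/0.5/0.2). These defaults were chosen once as plausible for the COT
trial literature (small trials, occasional three-arm designs, a
non-trivial fraction of unusable reporting) and are not tuned thereafter.

The calibration harness (`recovery_report()`, and the acceptance test
built on it) runs 1000 replicate repositories per setting over μ ∈ {0,
0.2, 0.5} × τ² ∈ {0, 0.05, 0.2} at k = 20 plain two-arm single-measure
trials, checking |bias(μ̂)| < 0.03 and 95% HKSJ coverage within
[0.90, 0.99]. The plain two-arm configuration isolates the meta-analytic
estimator itself; the multi-arm, subgroup and composite paths are covered
by their own exact oracles. What passing shows: the estimator chain is
unbiased and its intervals are calibrated *under the generating model* —
normal random effects, correctly reported summaries, no publication bias,
missingness independent of effect size. What it does not show: robustness
to non-normal effect distributions, selective reporting, correlated
missingness, or coder error — none of which the generator emulates.

## Numerical and degenerate-input conventions

* REML: boundary τ² = 0 compared explicitly; all-equal effects return 0
  without optimization.
* Q ≤ 0 or Q ≤ k−1 → I² = 0; p_Q = 1 for all-equal effects.
* Zero-dispersion HKSJ interval degenerates to the point estimate.
* Prediction intervals require k ≥ 3; below that they are omitted with a
  reason rather than fabricated.
* The shared-arm covariance matrix is checked for positive
  semidefiniteness and the adjusted weights for positivity; violations
  raise errors naming the trial.
* Half-up rounding (never banker's) for narrative percentages.
* Ties in eligibility (a trial coded to several populations) contribute
  the study to each matching group — population labels are facts about
  the sample, not exclusive strata.

## Problem sizes

The shipped tests run the full pipeline at desk scale: repositories of
3–30 trials, the 9 × 1000-replicate calibration grid at k = 20, a 10⁵-point
(plus refinement) likelihood grid for 100 REML fixtures, and 200 random
multi-arm fixtures for the GLS oracle. These sizes were chosen to make
Monte-Carlo error comfortably smaller than the tested tolerances while
keeping a full run in the minutes range on one core.
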