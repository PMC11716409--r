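---
title: "Scoring biomedical dataset trustworthiness with venusscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring biomedical dataset trustworthiness with venusscore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(venusscore)
```

## The instrument and its model

The Venus score rates a biomedical dataset's quality and trustworthiness
with ten questions, each worth one point, so totals live on a 0–10 scale.
The questions track the data-governance themes of the EU AI Act — origin,
context and purpose; data protection and licensing; devices, centers and
collection periods; variable documentation; protected attributes;
inaccuracy; noise; data preparation — plus two desiderata the instrument
adds on top: a peer-reviewed, data-centric publication, and unrestricted
availability under a persistent official identifier.

Each question `Qk` decomposes into named sub-items (e.g. `consent`,
`deidentification`, `terms_of_use`, `license` under the data-protection
question). An evaluator either records a holistic score in [0, 1] per
question, or fills per-sub-item fulfillment fractions in [0, 1]; in the
latter case the question score is the weight-weighted sum, where the
sub-item weights are nonnegative and sum to one, so the score cannot
exceed one by construction. Direct entry takes precedence because
consolidated annotation sheets (including the bundled cohort) record
per-question values only.

Two modelling assumptions deserve emphasis:

* **Equal sub-item weights by default.** The instrument's published
  description names the sub-items but not their internal weights, which
  live in a separate fillable spreadsheet. The built-in instrument
  therefore assigns equal weights within each question — the choice that
  preserves the documented per-question [0, 1] scale while remaining
  agnostic about relative importance — and any other weighting can be
  supplied as a YAML/JSON schema via `load_questionnaire()`. The shipped
  JSON-Schema document (`inst/schema/questionnaire.schema.json`) states the
  serialized contract; `load_questionnaire()` enforces the same invariants
  natively (weights nonnegative and summing to 1 within 1e-9, at least one
  sub-item, distinct ids, ten questions for the Venus v1.0 instrument).
* **No cross-question weighting.** All ten questions are worth one point;
  the total is a plain sum. Scoring is manual by design — the package
  validates and aggregates human judgment, it does not read documentation.

Out-of-range inputs are validation errors, never silently clamped:
`validate_annotation()` returns violations as data (one row per problem)
so an annotation sheet can be audited as a whole, while the scoring
functions refuse invalid sheets. Sub-items omitted from a sub-item-level
answer count as unfulfilled (score 0); unknown sub-item ids are errors,
since they usually indicate a schema mismatch rather than an intentional
blank.

## Display rounding

Totals are reported at two decimals with half-up rounding
(`round_half_up()`), the convention used for printed score tables; internal
arithmetic is never rounded. For the bundled cohort all twelve totals are
exact two-decimal sums, so no rounding ambiguity arises. Question means are
compared at ±0.01 in the test suite because some printed cohort averages
(e.g. 0.46 for a recomputed 0.465) cannot be reproduced by any single
consistent rounding rule.

## Multi-annotator machinery

`merge_annotations()` consolidates several annotators' sheets for a dataset
by resolving each to per-question scores and averaging — the procedure used
after disagreement resolution in a two-annotator design. Inter-annotator
agreement (`pearson_agreement()`) is Pearson's product-moment correlation
over the *flattened* (dataset × question) score series, not per-dataset
totals: this uses every observation and matches the granularity at which
disagreements are actually resolved. Constant series make the correlation
undefined and are an error rather than an `NA`.

`cohort_summary()` reports per-question mean, standard deviation, min, and
max across datasets. The **sample** (n−1) standard deviation is used: on
the bundled cohort it reproduces the printed Q1 dispersion of 0.23, where
the population form gives 0.22. Two summary cells printed with the original
cohort (the Q10 and total-row dispersion of 0.32) are inconsistent with any
statistic computable from the score matrix (the recomputed total-row sd is
about 1.62) and are deliberately not asserted anywhere.

## The Kaggle usability replica and weight deduction

The replica models the platform's usability score as an additive sum over
eleven fields (completeness 4.10 points, credibility 1.77, compatibility
4.13; total 10.00). Weights are stored as the published two-decimal values.
Column Description applies only to tabular datasets; for non-tabular
records its weight is excluded and *not* redistributed by default, so a
fully documented non-tabular record caps at 9.41 — mirroring observed
platform behavior — with an explicit `renormalize = TRUE` mode rescaling to
a 10 maximum for users who prefer a comparable scale.

`deduce_weights()` inverts the additive model: given (presence vector,
published score) observations it solves `X w = y` for nonnegative `w` by
nonnegative least squares (`pracma::lsqnonneg`). Negative checklist weights
are meaningless, hence the constraint. Each field is flagged identifiable
only when its weight is uniquely determined by the observations — its unit
vector lies in the row space of `X`, checked by a QR rank comparison —
because in underdetermined systems the solver still returns *a* solution
whose unidentifiable coordinates are arbitrary. When the instrument
maximum is known, `full_score = 10` adds an implicit all-present
observation; this is exactly what turns a single one-missing-field
observation into the printed deduction weight = 10 − score, and it is kept
optional so that pure observational fits remain unbiased.

## Crosswalk coverage conventions

The built-in crosswalk maps each question to an EU AI Act data-governance
requirement, Datasheets for Datasets question indices (1–57, indices only),
Kaggle fields, and additional desiderata. Two counting conventions are
exposed because they genuinely differ: counting a Datasheets question once
per Venus question listing it yields 20 references (the convention behind
the headline 20-of-57 ≈ 35% figure — question 13 appears under both the
inaccuracy and noise questions, and question 46 under both data protection
and open availability), while deduplicating yields 18 distinct questions.
`coverage()` reports both and lets the caller choose which drives the
percentage, which is rounded to the nearest integer percent.

## Synthetic annotations

`generate_synthetic_annotations()` exists to exercise the merging,
agreement, and cohort machinery under controlled conditions; it does not
claim to model human annotator behavior. Question scores are drawn as a
per-question base mean plus zero-mean Gaussian annotator noise, clamped to
[0, 1], with a per-dataset uniform shift (±0.2) so the flattened series is
non-constant. Defaults — 12 datasets, 2 annotators, noise sd 0.1, base
profile equal to the bundled cohort's question means — mirror the study
design the statistics machinery serves. Everything is deterministic given
the seed, and the caller's RNG state is restored.

What passing tests on synthetic data do show: the estimators are correct
(merging equals brute-force column means; the agreement statistic equals
the textbook covariance formula to 1e-12; annotator disagreement scales as
noise_sd·√2). What they do not show: anything about real annotator
reliability. In particular, the original two-annotator agreement trajectory
(ρ = 0.66 before resolution, 0.96 after) cannot be recomputed because the
raw per-annotator sheets are not published; only the machinery is verified.
Clamping at the scale bounds also means the Gaussian noise model is only
approximate near 0 and 1 — the scale-check test uses a mid-scale profile
where the clamp is inactive.

## Problem sizes and numerical choices

All bundled computations are desk-scale: twelve datasets × ten questions,
an 11-field weight table, and synthetic cohorts of at most a few hundred
datasets in the property tests; the full suite runs in a few seconds. Weight
recovery is asserted to 1e-9 on full-rank synthetic systems, agreement to
1e-12 against the independent formula, and fixture totals exactly (their
sums are exact decimals). Rank decisions in the identifiability check use
R's default QR tolerance, ample for 0/1 presence matrices of this size.

## Limitations

Scoring new real-world datasets remains a human judgment task; the package
contributes validation, aggregation, statistics, and reporting, not
assessment. The equal sub-item weighting is an assumption, overridable but
unvalidated. The Kaggle replica is an interpretation of an undisclosed
scoring rule deduced from published aggregate scores; whether the true
weights are exactly the stored two-decimal values is unknown (the platform
itself has shown a fully complete dataset scoring 9.41). The crosswalk
models Datasheets questions by index only.
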