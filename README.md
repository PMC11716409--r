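# venusscore

Biomedical datasets are rarely published with any indication of how
trustworthy they are: licensing, consent and de-identification, device and
collection-period provenance, protected-attribute distributions, and known
sources of inaccuracy or noise are often missing from dataset documentation.
**venusscore** implements the Venus score, a ten-question instrument for
rating the quality and trustworthiness of a biomedical dataset, together
with the surrounding machinery a scoring study needs: schema-validated
questionnaires, multi-annotator merging and agreement, cohort statistics,
datasheet-style reports, a crosswalk to the EU AI Act / Datasheets for
Datasets / Kaggle usability frameworks, and an additive replica of the
Kaggle Dataset Usability Score with a weight-deduction solver.

It is intended for data curators auditing their documentation before
release, for researchers screening candidate datasets, and for repository
maintainers who want a standard checklist for submissions.

## The score

A dataset is evaluated on ten questions Q1–Q10 (origin/context/purpose,
data protection and license, devices/centers/collection periods, variable
documentation, protected attributes, inaccuracy, noise, data preparation,
peer-reviewed publication, open availability with a persistent ID). Each
question yields a score

  s_q ∈ [0, 1],  computed as s_q = Σ_i w_i f_i

over the question's sub-items with weights Σ_i w_i = 1 and fulfillment
fractions f_i ∈ [0, 1] (or entered directly as a holistic judgment), and
the total is V = Σ_q s_q ∈ [0, 10]. Scoring is manual by design: the
package validates, aggregates, and reports human judgments, it does not
read dataset documentation.

The Kaggle replica models the platform's usability score as an additive sum
of eleven field weights; `deduce_weights()` inverts the model, recovering
hidden weights from (field presence, published score) observations by
nonnegative least squares, with per-field identifiability diagnostics. The
one-missing-field shortcut `deduce_weight_single()` is the special case
weight = 10 − published score.

## Worked example

```r
library(venusscore)

fx <- table4_fixture()              # bundled 12-dataset evaluation cohort
res <- score_dataset(fx$annotations[["D3"]])
res
#> <venus_result: dataset D3, total 7.45 / 10>
#>    Q1    Q2    Q3    Q4    Q5    Q6    Q7    Q8    Q9   Q10
#>  1.00  1.00  1.00  1.00  0.50  0.30  0.05  0.60  1.00  1.00

cohort_summary(lapply(fx$annotations, score_dataset))
#> <cohort_summary over 12 datasets>
#>  question_id mean   sd  min  max
#>           Q1 0.85 0.23 0.30 1.00
#>           ...
#> totals: mean 5.86, sd 1.62, min 2.70, max 8.10

coverage(builtin_crosswalk(), "datasheets")
#> <coverage_report: datasheets — 20 reference(s) (18 distinct) of 57, 35%>
```

The total 7.45/10 is the sum of the ten question scores for the MIMIC-III
annotation; the cohort summary gives per-question means across the twelve
datasets (e.g. inaccuracy, Q6, averages only 0.18 — documentation of error
sources is the cohort's weakest point); the coverage report says the
instrument references 20 Datasheets-for-Datasets questions (18 distinct) of
the 57, about 35%.

A thin CLI wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli","venus.R",package="venusscore"))') \
    score --annotation sheets.csv --out results.json
```

Subcommands: `score`, `merge`, `agree`, `cohort`, `kaggle`,
`kaggle-weights`, `crosswalk`, `report`, `fixtures`.

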