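# Shared expectations: the per-dataset totals of the bundled twelve-dataset
# cohort, as printed in its source evaluation.
cohort_totals <- c(D1 = 2.70, D2 = 6.48, D3 = 7.45, D4 = 5.02, D5 = 5.72,
                   D6 = 5.42, D7 = 8.10, D8 = 3.70, D9 = 7.97, D10 = 6.60,
                   D11 = 5.73, D12 = 5.43)

# A random valid annotation with direct scores, for property tests.
random_annotation <- function(dataset_id = "X1", annotator_id = "A1",
                              q = builtin_venus()) {
  qids <- vapply(q$questions, function(x) x$id, character(1))
  venus_annotation(dataset_id, annotator_id,
                   stats::setNames(as.list(round(stats::runif(length(qids)), 3)),
                                   qids))
}

# Independent textbook Pearson correlation (sum formulas), kept free of cor().
pearson_oracle <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - sum(x) / n) * (y - sum(y) / n)) / (n - 1)
  sx <- sqrt(sum((x - sum(x) / n)^2) / (n - 1))
  sy <- sqrt(sum((y - sum(y) / n)^2) / (n - 1))
  sxy / (sx * sy)
}
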