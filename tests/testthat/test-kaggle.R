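test_that("field table reproduces the printed group totals", {
  w <- builtin_kaggle_weights()
  expect_equal(nrow(w), 11L)
  groups <- tapply(w$weight, w$group, sum)
  expect_equal(unname(groups["completeness"]), 4.10, tolerance = 1e-12)
  expect_equal(unname(groups["credibility"]), 1.77, tolerance = 1e-12)
  expect_equal(unname(groups["compatibility"]), 4.13, tolerance = 1e-12)
  expect_equal(sum(w$weight), 10.00, tolerance = 1e-12)
  expect_equal(w$field[w$tabular_only], "Column Description")
})

test_that("non-scientific fields account for 41.1% of the score", {
  w <- builtin_kaggle_weights()
  non_sci <- c("Subtitle", "Tag", "Cover Image", "Public Notebook",
               "Update Frequency")
  expect_equal(100 * sum(w$weight[w$field %in% non_sci]) / sum(w$weight),
               41.1, tolerance = 1e-9)
})

test_that("scores sum present-field weights, with the documented non-tabular cap", {
  w <- builtin_kaggle_weights()
  all_p <- kaggle_presence(w$field, table = w)
  expect_equal(kaggle_score(all_p, w), 10.00, tolerance = 1e-12)

  no_cd <- kaggle_presence(setdiff(w$field, "Column Description"), table = w)
  expect_equal(kaggle_score(no_cd, w), 9.41, tolerance = 1e-12)

  no_ff <- kaggle_presence(setdiff(w$field, "File Format"), table = w)
  expect_equal(kaggle_score(no_ff, w), 8.82, tolerance = 1e-12)

  # a complete non-tabular record caps at 9.41 unless renormalized
  nontab <- kaggle_presence(setdiff(w$field, "Column Description"),
                            is_tabular = FALSE, table = w)
  expect_equal(kaggle_score(nontab, w), 9.41, tolerance = 1e-12)
  expect_equal(kaggle_score(nontab, w, renormalize = TRUE), 10, tolerance = 1e-12)
  expect_error(kaggle_presence(w$field, is_tabular = FALSE, table = w),
               "not applicable")
  expect_error(kaggle_presence("Vibes", table = w), "unknown Kaggle field")
})

test_that("the score is additive: dropping a field costs exactly its weight", {
  w <- builtin_kaggle_weights()
  full <- kaggle_score(kaggle_presence(w$field, table = w), w)
  for (f in w$field) {
    drop <- kaggle_score(kaggle_presence(setdiff(w$field, f), table = w), w)
    expect_equal(full - drop, w$weight[w$field == f], tolerance = 1e-12,
                 label = f)
  }
})

test_that("single-missing-field deduction recovers the printed weights", {
  w <- builtin_kaggle_weights()
  no_cd <- kaggle_presence(setdiff(w$field, "Column Description"), table = w)
  expect_equal(deduce_weight_single(kaggle_observation(no_cd, 9.41), w),
               c("Column Description" = 0.59))
  no_ff <- kaggle_presence(setdiff(w$field, "File Format"), table = w)
  expect_equal(deduce_weight_single(kaggle_observation(no_ff, 8.82), w),
               c("File Format" = 1.18))

  complete <- kaggle_observation(kaggle_presence(w$field, table = w), 10)
  expect_error(deduce_weight_single(complete, w), "least-squares")
  two_missing <- kaggle_observation(
    kaggle_presence(setdiff(w$field, c("Tag", "License")), table = w), 7.65)
  expect_error(deduce_weight_single(two_missing, w), "least-squares")
})

test_that("least squares recovers weights exactly from full-rank observations", {
  w <- builtin_kaggle_weights()
  set.seed(17)
  for (rep in 1:5) {
    true_w <- round(stats::runif(11, 0.05, 0.85), 3)  # keeps all scores within [0, 10]
    # leave-one-out presence patterns plus the complete pattern: full column rank
    patterns <- c(lapply(seq_len(11), function(i) w$field[-i]), list(w$field))
    obs <- lapply(patterns, function(pr) {
      p <- kaggle_presence(pr, table = w)
      kaggle_observation(p, sum(true_w[w$field %in% pr]))
    })
    fit <- deduce_weights(obs, w)
    expect_true(all(fit$identifiable))
    expect_equal(unname(fit$weights), true_w, tolerance = 1e-9)
    expect_lt(fit$residual_norm, 1e-9)
  }
})

test_that("identical presence patterns leave fields unidentifiable", {
  w <- builtin_kaggle_weights()
  p <- kaggle_presence(setdiff(w$field, "Tag"), table = w)
  obs <- list(kaggle_observation(p, 8.83), kaggle_observation(p, 8.83))
  fit <- deduce_weights(obs, w)
  # one linear combination observed: no single field is pinned down
  expect_true(sum(fit$identifiable) <= 1L)
  expect_false(fit$identifiable[["Subtitle"]])
})

test_that("the two printed observations pin down exactly their missing fields", {
  w <- builtin_kaggle_weights()
  obs <- list(
    kaggle_observation(
      kaggle_presence(setdiff(w$field, "Column Description"), table = w), 9.41),
    kaggle_observation(
      kaggle_presence(setdiff(w$field, "File Format"), table = w), 8.82))
  fit <- deduce_weights(obs, w, full_score = 10)
  expect_equal(unname(fit$weights["Column Description"]), 0.59, tolerance = 1e-9)
  expect_equal(unname(fit$weights["File Format"]), 1.18, tolerance = 1e-9)
  expect_equal(fit$identifiable[c("Column Description", "File Format")],
               c("Column Description" = TRUE, "File Format" = TRUE))
  expect_true(all(!fit$identifiable[setdiff(w$field,
                                            c("Column Description", "File Format"))]))
  # consistent with the one-missing-field shortcut
  expect_equal(unname(fit$weights["Column Description"]),
               unname(deduce_weight_single(obs[[1]], w)), tolerance = 1e-9)
  expect_error(deduce_weights(list(), w), "at least one")
})

test_that("presence CSVs round into observations", {
  w <- builtin_kaggle_weights()
  csv <- withr::local_tempfile(fileext = ".csv")
  df <- as.data.frame(matrix(1L, nrow = 2, ncol = 11,
                             dimnames = list(NULL, w$field)), check.names = FALSE)
  df[1, "Column Description"] <- 0L
  df$is_tabular <- TRUE
  df$published_score <- c(9.41, 10)
  write.csv(df, csv, row.names = FALSE)
  recs <- read_kaggle_csv(csv, w)
  expect_length(recs, 2L)
  expect_s3_class(recs[[1]], "kaggle_observation")
  expect_equal(deduce_weight_single(recs[[1]], w), c("Column Description" = 0.59))
})
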