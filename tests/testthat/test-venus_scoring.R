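test_that("validation reports violations as data, not exceptions", {
  q <- builtin_venus()
  fx <- table4_fixture()
  expect_equal(nrow(validate_annotation(fx$annotations[["D3"]], q)), 0L)

  bad <- fx$annotations[["D3"]]
  bad$entries$Q5 <- 1.2
  rep <- validate_annotation(bad, q)
  expect_equal(rep$type, "range")
  expect_equal(rep$question_id, "Q5")

  missing <- fx$annotations[["D3"]]
  missing$entries$Q7 <- NULL
  rep <- validate_annotation(missing, q)
  expect_equal(rep$type, "coverage")
  expect_equal(rep$question_id, "Q7")

  extra <- fx$annotations[["D3"]]
  extra$entries$Q11 <- 0.5
  expect_equal(validate_annotation(extra, q)$type, "unknown_question")

  subitem <- fx$annotations[["D3"]]
  subitem$entries$Q6 <- c(listed_sources = 1, bogus = 0.5)
  expect_true("unknown_sub_item" %in% validate_annotation(subitem, q)$type)
})

test_that("question scores pass direct values through and weight sub-items", {
  q <- builtin_venus()
  q5 <- q$questions[[5]]
  q6 <- q$questions[[6]]

  expect_identical(score_question(0.63, q5), 0.63)
  expect_equal(score_question(c(listed_sources = 1, characterized = 0), q6), 0.5)
  expect_equal(score_question(c(listed_sources = 0, characterized = 0), q6), 0)
  expect_equal(score_question(
    c(marginal_distribution = 1, joint_distribution = 1,
      expected_distribution = 1, label_provenance = 1), q5), 1)
  # omitted sub-items count as unfulfilled
  expect_equal(score_question(c(curators = 1), q$questions[[1]]), 1 / 3,
               tolerance = 1e-12)
  expect_error(score_question(c(nonsense = 1), q6), "nonsense")
  expect_error(score_question(1.2, q6), "outside")
})

test_that("dataset totals match the brute-force sum of fixture scores", {
  q <- builtin_venus()
  fx <- table4_fixture()
  raw <- read.csv(system.file("extdata", "table4_scores.csv",
                              package = "venusscore"))
  for (d in names(fx$annotations)) {
    res <- score_dataset(fx$annotations[[d]], q)
    brute <- sum(raw$score[raw$dataset_id == d])  # independent of score_dataset
    expect_equal(res$total, brute, tolerance = 1e-12)
    expect_equal(round_half_up(res$total, 2), unname(cohort_totals[d]),
                 tolerance = 1e-12, label = d)
    expect_equal(res$total, sum(res$question_scores), tolerance = 1e-12)
  }
})

test_that("an all-ones annotation reaches the maximum of 10", {
  q <- builtin_venus()
  ann <- venus_annotation("MAX", "A1",
                          stats::setNames(as.list(rep(1, 10)), paste0("Q", 1:10)))
  expect_equal(score_dataset(ann, q)$total, 10)
})

test_that("totals stay in [0, 10] and scoring is monotone in sub-item fulfillment", {
  q <- builtin_venus()
  set.seed(42)
  for (i in 1:25) {
    ann <- random_annotation(sprintf("R%d", i))
    res <- score_dataset(ann, q)
    expect_gte(res$total, 0)
    expect_lte(res$total, 10)
    expect_true(all(res$question_scores >= 0 & res$question_scores <= 1))
  }

  # raising one sub-item fulfillment never lowers the question score or total
  set.seed(7)
  for (i in 1:10) {
    entries <- lapply(paste0("Q", 1:10), function(qid) {
      si <- venusscore:::get_question(q, qid)$sub_items$id
      stats::setNames(round(stats::runif(length(si)), 3), si)
    })
    names(entries) <- paste0("Q", 1:10)
    ann <- venus_annotation("M1", "A1", entries)
    base <- score_dataset(ann, q)
    qid <- sample(paste0("Q", 1:10), 1)
    j <- sample(seq_along(ann$entries[[qid]]), 1)
    bumped <- ann
    bumped$entries[[qid]][j] <- min(1, bumped$entries[[qid]][j] + stats::runif(1))
    res <- score_dataset(bumped, q)
    expect_gte(res$question_scores[[qid]], base$question_scores[[qid]])
    expect_gte(res$total, base$total)
  }
})

test_that("annotations survive CSV and JSON round trips, including sub-items", {
  q <- builtin_venus()
  fx <- table4_fixture()

  csv <- withr::local_tempfile(fileext = ".csv")
  raw <- read.csv(system.file("extdata", "table4_scores.csv",
                              package = "venusscore"))
  raw$annotator_id <- "consensus"
  write.csv(raw, csv, row.names = FALSE)
  anns <- read_annotations_csv(csv)
  expect_length(anns, 12L)
  tot <- vapply(anns, function(a) score_dataset(a, q)$total, numeric(1))
  names(tot) <- vapply(anns, function(a) a$dataset_id, character(1))
  expect_equal(round_half_up(tot[names(cohort_totals)], 2), cohort_totals)

  json <- withr::local_tempfile(fileext = ".json")
  mixed <- venus_annotation("J1", "A9", list(
    Q1 = c(curators = 1, purpose = 0.5, context = 0),
    Q2 = 0.4, Q3 = 0.1, Q4 = 1, Q5 = 0,
    Q6 = c(listed_sources = 1), Q7 = 0, Q8 = 0.2, Q9 = 1, Q10 = 1),
    evidence = list(Q1 = "repo page"), sources_consulted = "landing page")
  write_annotations_json(mixed, json)
  back <- read_annotations_json(json)[[1]]
  expect_equal(score_dataset(back, q)$total, score_dataset(mixed, q)$total,
               tolerance = 1e-12)
  expect_equal(back$evidence$Q1, "repo page")
})
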