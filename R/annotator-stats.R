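#' Merge several annotators' sheets for one dataset
#'
#' Resolves each annotation to per-question scores under the instrument and
#' takes the arithmetic mean per question, mirroring how independent
#' annotations are consolidated after disagreement resolution. Evidence
#' notes for a question are concatenated across annotators.
#'
#' @param anns List of `venus_annotation`, all for the same dataset.
#' @param q A `venus_questionnaire`.
#' @return A `venus_annotation` with direct (already aggregated) question
#'   scores and a composite `annotator_id` (ids joined with `"+"`).
#' @export
merge_annotations <- function(anns, q = builtin_venus()) {
  stopifnot(is.list(anns), length(anns) >= 1L)
  ids <- vapply(anns, function(a) a$dataset_id, character(1))
  if (length(unique(ids)) != 1L)
    stop("annotations to merge refer to different datasets: ",
         paste(unique(ids), collapse = ", "), call. = FALSE)
  qids <- question_ids(q)
  for (a in anns) {
    report <- validate_annotation(a, q)
    if (nrow(report))
      stop("annotation by '", a$annotator_id, "' is invalid: ",
           paste(report$message, collapse = "; "), call. = FALSE)
  }
  score_tab <- vapply(anns, function(a) {
    vapply(qids, function(qid) score_question(a$entries[[qid]],
                                              get_question(q, qid)), numeric(1))
  }, numeric(length(qids)))
  score_tab <- matrix(score_tab, nrow = length(qids),
                      dimnames = list(qids, NULL))
  merged <- rowMeans(score_tab)
  evidence <- list()
  for (qid in qids) {
    notes <- unlist(lapply(anns, function(a) a$evidence[[qid]]))
    notes <- notes[!is.na(notes) & nzchar(notes)]
    if (length(notes)) evidence[[qid]] <- paste(notes, collapse = " | ")
  }
  venus_annotation(
    dataset_id = ids[1L],
    annotator_id = paste(vapply(anns, function(a) a$annotator_id, character(1)),
                         collapse = "+"),
    entries = stats::setNames(as.list(unname(merged)), qids),
    evidence = evidence,
    sources_consulted = unique(unlist(lapply(anns, function(a) a$sources_consulted)))
  )
}

flatten_series <- function(anns, q) {
  if (inherits(anns, "venus_annotation")) anns <- list(anns)
  qids <- question_ids(q)
  out <- do.call(rbind, lapply(anns, function(a) {
    report <- validate_annotation(a, q)
    if (nrow(report))
      stop("invalid annotation for dataset '", a$dataset_id, "': ",
           paste(report$message, collapse = "; "), call. = FALSE)
    data.frame(dataset_id = a$dataset_id, question_id = qids,
               score = vapply(qids, function(qid) {
                 score_question(a$entries[[qid]], get_question(q, qid))
               }, numeric(1)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Inter-annotator agreement (Pearson)
#'
#' Pearson product-moment correlation between two annotators' score series,
#' flattened over all (dataset, question) pairs so that every observation
#' contributes. Both series must cover exactly the same pairs.
#'
#' @param a,b A `venus_annotation` or list thereof (one annotator's sheets
#'   across datasets).
#' @param q A `venus_questionnaire`.
#' @return An `agreement_report`: `rho`, `n_pairs`, and `per_item_delta`
#'   (data frame of absolute per-item differences, largest first).
#' @export
pearson_agreement <- function(a, b, q = builtin_venus()) {
  fa <- flatten_series(a, q)
  fb <- flatten_series(b, q)
  key <- function(d) paste(d$dataset_id, d$question_id, sep = ":")
  if (nrow(fa) != nrow(fb) || !setequal(key(fa), key(fb)))
    stop("the two annotation series do not cover the same (dataset, question) pairs",
         call. = FALSE)
  fb <- fb[match(key(fa), key(fb)), ]
  if (nrow(fa) < 2L)
    stop("at least two score pairs are required", call. = FALSE)
  if (stats::sd(fa$score) == 0 || stats::sd(fb$score) == 0)
    stop("correlation is undefined: one annotation series is constant",
         call. = FALSE)
  delta <- data.frame(dataset_id = fa$dataset_id, question_id = fa$question_id,
                      delta = abs(fa$score - fb$score), stringsAsFactors = FALSE)
  structure(
    list(rho = stats::cor(fa$score, fb$score),
         n_pairs = nrow(fa),
         per_item_delta = delta[order(-delta$delta), ]),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report: rho = %.3f over %d score pairs>\n",
              x$rho, x$n_pairs))
  invisible(x)
}

#' Cohort summary statistics
#'
#' Per-question mean, sample standard deviation (n - 1 denominator),
#' minimum, and maximum across a cohort of scored datasets, plus the same
#' four statistics over the dataset totals.
#'
#' @param results List of `venus_result` (at least two, so that the
#'   standard deviation is defined) sharing one instrument.
#' @return A `cohort_summary`: `per_question` data frame, `total_stats`
#'   named vector, `n_datasets`.
#' @examples
#' fx <- table4_fixture()
#' cs <- cohort_summary(lapply(fx$annotations, score_dataset))
#' cs$per_question[cs$per_question$question_id == "Q6", "mean"]  # ~0.18
#' @export
cohort_summary <- function(results) {
  stopifnot(is.list(results))
  if (length(results) < 2L)
    stop("cohort_summary needs at least 2 results (sd undefined otherwise)",
         call. = FALSE)
  qids <- names(results[[1L]]$question_scores)
  for (r in results) {
    if (!identical(names(r$question_scores), qids))
      stop("results do not share the same instrument question set", call. = FALSE)
  }
  mat <- t(vapply(results, function(r) r$question_scores, numeric(length(qids))))
  per_question <- data.frame(
    question_id = qids,
    mean = colMeans(mat),
    sd = apply(mat, 2, stats::sd),
    min = apply(mat, 2, min),
    max = apply(mat, 2, max),
    stringsAsFactors = FALSE, row.names = NULL
  )
  totals <- vapply(results, function(r) r$total, numeric(1))
  structure(
    list(per_question = per_question,
         total_stats = c(mean = mean(totals), sd = stats::sd(totals),
                         min = min(totals), max = max(totals)),
         n_datasets = length(results)),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary over %d datasets>\n", x$n_datasets))
  df <- x$per_question
  df[, c("mean", "sd", "min", "max")] <-
    round(df[, c("mean", "sd", "min", "max")], 2)
  print(df, row.names = FALSE)
  cat(sprintf("totals: mean %.2f, sd %.2f, min %.2f, max %.2f\n",
              x$total_stats["mean"], x$total_stats["sd"],
              x$total_stats["min"], x$total_stats["max"]))
  invisible(x)
}
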