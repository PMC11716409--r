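#' Construct a dataset annotation
#'
#' One evaluator's fulfillment scores for one dataset under one instrument.
#' Each entry is either a direct question score in \[0, 1\] (how the averaged
#' cohort sheets record them) or a named vector of sub-item fulfillment
#' fractions in \[0, 1\] (how a fillable weighting spreadsheet records them).
#'
#' @param dataset_id Dataset token, e.g. `"D3"`.
#' @param annotator_id Annotator token.
#' @param entries Named list, one element per question id; each element a
#'   single unnamed number (direct score) or a named numeric vector of
#'   sub-item fulfillments.
#' @param evidence Optional named list/character of free-text notes per
#'   question.
#' @param sources_consulted Character vector of consulted sources
#'   (repository pages, publications).
#' @return An object of class `venus_annotation`.
#' @export
venus_annotation <- function(dataset_id, annotator_id, entries,
                             evidence = list(), sources_consulted = character()) {
  stopifnot(is.list(entries), !is.null(names(entries)))
  structure(
    list(dataset_id = as.character(dataset_id),
         annotator_id = as.character(annotator_id),
         entries = entries,
         evidence = as.list(evidence),
         sources_consulted = as.character(sources_consulted)),
    class = "venus_annotation"
  )
}

#' @export
print.venus_annotation <- function(x, ...) {
  cat(sprintf("<venus_annotation: dataset %s, annotator %s, %d entries>\n",
              x$dataset_id, x$annotator_id, length(x$entries)))
  invisible(x)
}

#' Validate an annotation against an instrument
#'
#' Violations are data, not exceptions: the report lists one row per problem
#' (missing or unknown question, value out of \[0, 1\], unknown sub-item id).
#' An empty report means the annotation is scoreable.
#'
#' @param ann A `venus_annotation`.
#' @param q A `venus_questionnaire` (default: the built-in instrument).
#' @return A data frame with columns `question_id`, `type`, `message`;
#'   zero rows when the annotation is valid.
#' @export
validate_annotation <- function(ann, q = builtin_venus()) {
  stopifnot(inherits(ann, "venus_annotation"))
  qids <- question_ids(q)
  bad <- list()
  flag <- function(qid, type, msg) {
    bad[[length(bad) + 1L]] <<- data.frame(
      question_id = qid, type = type, message = msg, stringsAsFactors = FALSE)
  }
  for (qid in setdiff(qids, names(ann$entries)))
    flag(qid, "coverage", paste0("question ", qid, " is not answered"))
  for (qid in setdiff(names(ann$entries), qids))
    flag(qid, "unknown_question", paste0("question ", qid, " is not in the instrument"))
  dup <- names(ann$entries)[duplicated(names(ann$entries))]
  for (qid in unique(dup))
    flag(qid, "duplicate", paste0("question ", qid, " answered more than once"))
  for (qid in intersect(names(ann$entries), qids)) {
    v <- ann$entries[[qid]]
    if (!is.numeric(v) || length(v) < 1L) {
      flag(qid, "type", paste0("entry for ", qid, " is not numeric"))
      next
    }
    if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
      flag(qid, "range",
           paste0("value ", paste(v[!is.finite(v) | v < 0 | v > 1], collapse = ", "),
                  " for ", qid, " outside [0, 1]"))
    if (!is.null(names(v))) {
      unknown <- setdiff(names(v), get_question(q, qid)$sub_items$id)
      if (length(unknown))
        flag(qid, "unknown_sub_item",
             paste0("unknown sub-item id(s) ", paste(unknown, collapse = ", "),
                    " for ", qid))
    }
  }
  if (length(bad)) do.call(rbind, bad)
  else data.frame(question_id = character(), type = character(),
                  message = character(), stringsAsFactors = FALSE)
}

#' Score a single question
#'
#' A direct (unnamed scalar) answer is returned unchanged. A named vector of
#' sub-item fulfillments is combined as the weight-weighted sum over the
#' question's sub-items; because the weights sum to one and fulfillments lie
#' in \[0, 1\], the result never exceeds 1 by construction. Sub-items omitted
#' from the answer count as unfulfilled (0); unknown sub-item ids are errors.
#'
#' @param answer A single number in \[0, 1\], or a named numeric vector of
#'   sub-item fulfillments in \[0, 1\].
#' @param question A `venus_question`.
#' @return The question score, a number in \[0, 1\].
#' @examples
#' q6 <- builtin_venus()$questions[[6]]
#' score_question(c(listed_sources = 1, characterized = 0), q6)  # 0.5
#' @export
score_question <- function(answer, question) {
  stopifnot(inherits(question, "venus_question"), is.numeric(answer))
  if (any(!is.finite(answer)) || any(answer < 0) || any(answer > 1))
    stop("answer for '", question$id, "' outside [0, 1]", call. = FALSE)
  if (is.null(names(answer))) {
    if (length(answer) != 1L)
      stop("direct answer for '", question$id, "' must be a single number",
           call. = FALSE)
    return(unname(answer))
  }
  si <- question$sub_items
  unknown <- setdiff(names(answer), si$id)
  if (length(unknown))
    stop("unknown sub-item id(s) for '", question$id, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  fulfil <- stats::setNames(rep(0, nrow(si)), si$id)
  fulfil[names(answer)] <- answer
  sum(si$weight * fulfil)
}

#' Score a dataset annotation
#'
#' Computes the ten per-question scores and the total Venus score (their
#' sum, between 0 and 10). The total is stored unrounded; display methods
#' report it at two decimals (round half up), matching how cohort totals are
#' conventionally printed.
#'
#' @param ann A `venus_annotation` (validated first; violations are an error).
#' @param q A `venus_questionnaire`.
#' @return An object of class `venus_result`: `dataset_id`,
#'   `question_scores` (named numeric), `total`.
#' @examples
#' fx <- table4_fixture()
#' score_dataset(fx$annotations[["D3"]])$total  # 7.45
#' @export
score_dataset <- function(ann, q = builtin_venus()) {
  report <- validate_annotation(ann, q)
  if (nrow(report))
    stop("invalid annotation for dataset '", ann$dataset_id, "':\n  ",
         paste(report$message, collapse = "\n  "), call. = FALSE)
  qids <- question_ids(q)
  scores <- vapply(qids, function(qid) {
    score_question(ann$entries[[qid]], get_question(q, qid))
  }, numeric(1))
  structure(
    list(dataset_id = ann$dataset_id,
         question_scores = scores,
         total = sum(scores)),
    class = "venus_result"
  )
}

#' Round half up
#'
#' Decimal rounding with ties going away from zero, the convention used for
#' reported score totals (base `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-12) / p
}

#' @export
print.venus_result <- function(x, ...) {
  cat(sprintf("<venus_result: dataset %s, total %.2f / 10>\n",
              x$dataset_id, round_half_up(x$total, 2)))
  print(round(x$question_scores, 3))
  invisible(x)
}

# ---- annotation / result IO ---------------------------------------------

#' Read annotation sheets from CSV
#'
#' Expects the long per-question layout: columns `dataset_id`,
#' `annotator_id`, `question_id`, `score`, and optionally `evidence`.
#' Sub-item answers are not expressible in CSV; use the JSON format for
#' those.
#'
#' @param path CSV file.
#' @return A list of `venus_annotation`, one per (dataset, annotator) pair.
#' @export
read_annotations_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("dataset_id", "annotator_id", "question_id", "score")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("annotation CSV missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  keys <- unique(df[, c("dataset_id", "annotator_id")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$dataset_id == keys$dataset_id[i] &
                df$annotator_id == keys$annotator_id[i], ]
    entries <- as.list(as.numeric(sub$score))
    names(entries) <- sub$question_id
    ev <- if ("evidence" %in% names(sub)) {
      notes <- as.list(sub$evidence)
      names(notes) <- sub$question_id
      notes[!vapply(notes, function(x) is.na(x) || x == "", logical(1))]
    } else list()
    venus_annotation(keys$dataset_id[i], keys$annotator_id[i], entries, ev)
  })
}

#' Read annotation sheets from JSON
#'
#' The nested JSON layout supports sub-item answers: each record has
#' `dataset_id`, `annotator_id`, `entries` (question id mapped to a number
#' or to an object of sub-item fulfillments), optional `evidence` and
#' `sources_consulted`.
#'
#' @param path JSON file containing one record or an array of records.
#' @return A list of `venus_annotation`.
#' @export
read_annotations_json <- function(path) {
  x <- jsonlite::read_json(path)
  if (!is.null(x$dataset_id)) x <- list(x)
  lapply(x, function(rec) {
    entries <- lapply(rec$entries, function(e) {
      if (is.list(e)) unlist(e) else as.numeric(e)
    })
    venus_annotation(rec$dataset_id, rec$annotator_id, entries,
                     if (is.null(rec$evidence)) list() else rec$evidence,
                     unlist(rec$sources_consulted))
  })
}

#' Write annotations to JSON
#'
#' @param anns A `venus_annotation` or list thereof.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_annotations_json <- function(anns, path) {
  if (inherits(anns, "venus_annotation")) anns <- list(anns)
  recs <- lapply(anns, function(a) {
    list(dataset_id = a$dataset_id, annotator_id = a$annotator_id,
         entries = lapply(a$entries, function(e) {
           if (is.null(names(e))) e else as.list(e)
         }),
         evidence = a$evidence, sources_consulted = a$sources_consulted)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write scoring results to JSON
#'
#' @param results A `venus_result` or list thereof.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(results, path) {
  if (inherits(results, "venus_result")) results <- list(results)
  recs <- lapply(results, function(r) {
    list(dataset_id = r$dataset_id,
         question_scores = as.list(r$question_scores),
         total = r$total,
         total_display = round_half_up(r$total, 2))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
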