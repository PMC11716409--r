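#' Render a datasheet-style report for a scored dataset
#'
#' Produces a human-readable Markdown datasheet — a header with the dataset
#' metadata, instrument version, and two-decimal total, then one section per
#' question with its score, evidence note, and the mapped EU AI Act
#' requirement, Datasheets items, and Kaggle fields — or a JSON twin with
#' identical content. Output is deterministic: the timestamp is injected,
#' never read from the clock.
#'
#' @param result A `venus_result`.
#' @param meta Optional one-row data frame (or list) of dataset metadata as
#'   in [table3_meta()].
#' @param crosswalk A `venus_crosswalk`.
#' @param q A `venus_questionnaire`.
#' @param format `"markdown"` or `"json"`.
#' @param evidence Optional named list of per-question evidence notes.
#' @param timestamp Optional character timestamp recorded in the report.
#' @return A single character string (Markdown) or JSON string.
#' @export
render_report <- function(result, meta = NULL, crosswalk = builtin_crosswalk(),
                          q = builtin_venus(),
                          format = c("markdown", "json"),
                          evidence = NULL, timestamp = NULL) {
  stopifnot(inherits(result, "venus_result"))
  format <- match.arg(format)
  qids <- question_ids(q)
  if (!setequal(names(result$question_scores), qids))
    stop("result does not match the instrument's question set", call. = FALSE)
  total_disp <- sprintf("%.2f", round_half_up(result$total, 2))
  name <- if (!is.null(meta) && !is.null(meta$name)) meta$name else result$dataset_id

  sections <- lapply(qids, function(qid) {
    row <- map_question(qid, crosswalk)
    list(question_id = qid,
         title = get_question(q, qid)$title,
         score = unname(result$question_scores[[qid]]),
         evidence = if (!is.null(evidence[[qid]])) evidence[[qid]] else "",
         ai_act_requirement = row$ai_act_requirement,
         datasheets_questions = row$datasheets_questions,
         kaggle_fields = row$kaggle_fields,
         additional_desiderata = row$additional_desiderata)
  })

  if (format == "json") {
    doc <- list(dataset_id = result$dataset_id, name = name,
                instrument = q$name, instrument_version = q$version,
                total = result$total, total_display = total_disp,
                generated = if (is.null(timestamp)) "" else as.character(timestamp),
                meta = if (is.null(meta)) NULL else as.list(meta),
                questions = sections)
    return(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE))
  }

  lines <- c(
    sprintf("# Venus datasheet: %s (%s)", name, result$dataset_id),
    "",
    sprintf("**Total Venus score: %s / 10** (%s v%s)", total_disp, q$name, q$version)
  )
  if (!is.null(timestamp))
    lines <- c(lines, sprintf("Generated: %s", timestamp))
  if (!is.null(meta)) {
    for (fld in intersect(c("field", "data_type", "disease", "repository"),
                          names(meta)))
      lines <- c(lines, sprintf("- %s: %s", gsub("_", " ", fld), meta[[fld]]))
  }
  for (s in sections) {
    lines <- c(lines, "",
               sprintf("## %s: %s", s$question_id, s$title),
               sprintf("Score: %.2f / 1", s$score))
    if (nzchar(s$evidence))
      lines <- c(lines, sprintf("Evidence: %s", s$evidence))
    if (nzchar(s$ai_act_requirement))
      lines <- c(lines, sprintf("EU AI Act requirement: %s", s$ai_act_requirement))
    if (length(s$datasheets_questions))
      lines <- c(lines, sprintf("Datasheets for Datasets questions: %s",
                                paste(s$datasheets_questions, collapse = ", ")))
    if (length(s$kaggle_fields))
      lines <- c(lines, sprintf("Kaggle usability fields: %s",
                                paste(s$kaggle_fields, collapse = ", ")))
    if (nzchar(s$additional_desiderata))
      lines <- c(lines, sprintf("Additional desiderata: %s",
                                s$additional_desiderata))
  }
  paste(lines, collapse = "\n")
}
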