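#' The built-in crosswalk from Venus questions to external frameworks
#'
#' One row per Venus question, mapping it to the EU AI Act data-governance
#' requirement it supports, the Datasheets for Datasets question indices
#' (1-57) it condenses, the Kaggle usability-score fields it overlaps with,
#' and any additional desideratum the instrument introduces on top of those
#' frameworks (permanent documentation and external validation; open data).
#'
#' @param path Optional CSV file overriding the bundled crosswalk (same
#'   columns, with `;`-separated multi-value cells).
#' @return A data frame of class `venus_crosswalk` with list columns
#'   `datasheets_questions` (integer vectors) and `kaggle_fields`
#'   (character vectors).
#' @export
builtin_crosswalk <- function(path = NULL) {
  if (is.null(path)) path <- extdata_path("table2_crosswalk.csv")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  split_ints <- function(x) {
    lapply(strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE), function(v) {
      v <- trimws(v[nzchar(trimws(v))])
      as.integer(v)
    })
  }
  split_chr <- function(x) {
    lapply(strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE), function(v) {
      trimws(v[nzchar(trimws(v))])
    })
  }
  cw <- data.frame(venus_qid = df$venus_qid,
                   ai_act_requirement = ifelse(is.na(df$ai_act_requirement), "",
                                               df$ai_act_requirement),
                   additional_desiderata = ifelse(is.na(df$additional_desiderata),
                                                  "", df$additional_desiderata),
                   stringsAsFactors = FALSE)
  cw$datasheets_questions <- split_ints(df$datasheets_questions)
  cw$kaggle_fields <- split_chr(df$kaggle_fields)
  cw <- cw[, c("venus_qid", "ai_act_requirement", "datasheets_questions",
               "kaggle_fields", "additional_desiderata")]
  bad <- unlist(cw$datasheets_questions)
  if (length(bad) && (any(bad < 1L) || any(bad > 57L)))
    stop("Datasheets question numbers must lie in [1, 57]", call. = FALSE)
  if (anyDuplicated(cw$venus_qid))
    stop("duplicated Venus question id in crosswalk", call. = FALSE)
  class(cw) <- c("venus_crosswalk", "data.frame")
  cw
}

#' Look up the crosswalk row for one Venus question
#'
#' @param qid A question id, e.g. `"Q5"`.
#' @param crosswalk A `venus_crosswalk`.
#' @return A list with the row's fields (`venus_qid`, `ai_act_requirement`,
#'   `datasheets_questions`, `kaggle_fields`, `additional_desiderata`);
#'   empty mappings are returned as empty vectors/strings.
#' @export
map_question <- function(qid, crosswalk = builtin_crosswalk()) {
  i <- match(qid, crosswalk$venus_qid)
  if (is.na(i)) stop("unknown question id '", qid, "'", call. = FALSE)
  list(venus_qid = crosswalk$venus_qid[i],
       ai_act_requirement = crosswalk$ai_act_requirement[i],
       datasheets_questions = crosswalk$datasheets_questions[[i]],
       kaggle_fields = crosswalk$kaggle_fields[[i]],
       additional_desiderata = crosswalk$additional_desiderata[i])
}

#' Coverage of an external framework by the Venus crosswalk
#'
#' Counts how many items of a target framework the crosswalk references.
#' Two counting conventions are exposed: `"per_venus_question"` counts a
#' target item once per Venus question listing it (so a Datasheets question
#' appearing under two Venus questions counts twice — the convention behind
#' the headline 20-of-57 figure), while `"distinct"` deduplicates. The
#' percentage is relative to the framework universe (57 Datasheets
#' questions; 11 Kaggle fields; undefined for the AI Act requirement
#' strings) and rounded to the nearest integer percent.
#'
#' @param crosswalk A `venus_crosswalk`.
#' @param framework One of `"datasheets"`, `"ai_act"`, `"kaggle"`.
#' @param counting Which convention drives `reference_count` and the
#'   percentage.
#' @return A list of class `coverage_report`: `framework`,
#'   `reference_count`, `distinct_count`, `universe_size` (NA for the AI
#'   Act), `percent_covered`.
#' @examples
#' coverage(builtin_crosswalk(), "datasheets")$reference_count  # 20
#' @export
coverage <- function(crosswalk = builtin_crosswalk(),
                     framework = c("datasheets", "ai_act", "kaggle"),
                     counting = c("per_venus_question", "distinct")) {
  framework <- match.arg(framework)
  counting <- match.arg(counting)
  refs <- switch(framework,
    datasheets = unlist(crosswalk$datasheets_questions),
    kaggle = unlist(crosswalk$kaggle_fields),
    ai_act = {
      r <- crosswalk$ai_act_requirement
      r[nzchar(r)]
    }
  )
  universe <- switch(framework, datasheets = 57L, kaggle = 11L, ai_act = NA_integer_)
  per_q <- length(refs)
  distinct <- length(unique(refs))
  count <- if (counting == "per_venus_question") per_q else distinct
  structure(
    list(framework = framework,
         reference_count = count,
         per_venus_question_count = per_q,
         distinct_count = distinct,
         universe_size = universe,
         percent_covered = if (is.na(universe)) NA_real_
                           else round(100 * count / universe)),
    class = "coverage_report"
  )
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("<coverage_report: %s — %d reference(s) (%d distinct)%s>\n",
              x$framework, x$reference_count, x$distinct_count,
              if (is.na(x$universe_size)) ""
              else sprintf(" of %d, %d%%", x$universe_size, x$percent_covered)))
  invisible(x)
}
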