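#' Construct a Venus question
#'
#' A question contributes at most one point to the total Venus score. Its
#' sub-items name the facets an evaluator considers (e.g. `consent`,
#' `deidentification` within the data-protection question); their weights are
#' fractions of the question's single point and must sum to 1.
#'
#' @param id Question identifier, conventionally `"Q1"`..`"Q10"`.
#' @param title Question text.
#' @param sub_items Data frame with columns `id`, `label`, `weight`. If
#'   `weight` is omitted, equal weights are assigned.
#' @param guidance Optional free-text guidance for evaluators.
#' @return An object of class `venus_question`.
#' @export
venus_question <- function(id, title, sub_items, guidance = "") {
  if (is.character(sub_items)) {
    sub_items <- data.frame(id = sub_items, label = sub_items,
                            weight = NA_real_, stringsAsFactors = FALSE)
  }
  sub_items <- as.data.frame(sub_items, stringsAsFactors = FALSE)
  if (is.null(sub_items$label)) sub_items$label <- sub_items$id
  if (is.null(sub_items$weight) || all(is.na(sub_items$weight))) {
    sub_items$weight <- rep(1 / nrow(sub_items), nrow(sub_items))
  }
  q <- structure(
    list(id = as.character(id), title = as.character(title),
         guidance = as.character(guidance),
         sub_items = sub_items[, c("id", "label", "weight")]),
    class = "venus_question"
  )
  validate_question(q)
  q
}

validate_question <- function(q) {
  si <- q$sub_items
  if (nrow(si) < 1L)
    stop("question '", q$id, "': at least one sub-item is required", call. = FALSE)
  if (anyDuplicated(si$id))
    stop("question '", q$id, "': duplicated sub-item id '",
         si$id[duplicated(si$id)][1L], "'", call. = FALSE)
  if (any(si$weight < 0))
    stop("question '", q$id, "': sub-item weight must be nonnegative (got ",
         min(si$weight), ")", call. = FALSE)
  if (abs(sum(si$weight) - 1) > 1e-9)
    stop("question '", q$id, "': sub-item weights must sum to 1 (got ",
         format(sum(si$weight), digits = 12), ")", call. = FALSE)
  invisible(q)
}

#' Construct a Venus questionnaire
#'
#' @param name Instrument name.
#' @param version Instrument version string.
#' @param questions List of [venus_question()] objects.
#' @return An object of class `venus_questionnaire`.
#' @seealso [builtin_venus()] for the built-in ten-question instrument.
#' @export
venus_questionnaire <- function(name, version, questions) {
  q <- structure(
    list(name = as.character(name), version = as.character(version),
         questions = questions),
    class = "venus_questionnaire"
  )
  validate_questionnaire(q)
  q
}

#' Validate a questionnaire against its structural invariants
#'
#' Checks per-question invariants (sub-item weights sum to one, nonnegative,
#' unique ids) and questionnaire-level invariants (distinct question ids;
#' for the built-in Venus v1.0 instrument, exactly ten questions so the
#' maximum attainable total is 10).
#'
#' @param q A `venus_questionnaire`.
#' @return `q`, invisibly; signals an error naming the violated invariant.
#' @export
validate_questionnaire <- function(q) {
  stopifnot(inherits(q, "venus_questionnaire"))
  ids <- vapply(q$questions, function(x) x$id, character(1))
  if (anyDuplicated(ids))
    stop("duplicated question id '", ids[duplicated(ids)][1L], "'", call. = FALSE)
  for (question in q$questions) validate_question(question)
  if (identical(q$name, "Venus") && length(q$questions) != 10L)
    stop("the Venus instrument must have exactly 10 questions (got ",
         length(q$questions), ")", call. = FALSE)
  invisible(q)
}

question_ids <- function(q) vapply(q$questions, function(x) x$id, character(1))

get_question <- function(q, qid) {
  ids <- question_ids(q)
  i <- match(qid, ids)
  if (is.na(i)) stop("unknown question id '", qid, "'", call. = FALSE)
  q$questions[[i]]
}

#' The built-in Venus v1.0 instrument
#'
#' Returns the ten-question Venus score questionnaire for biomedical dataset
#' quality and trustworthiness. Each question is worth one point, so a dataset
#' scores between 0 and 10 in total. Sub-items within a question carry equal
#' weights by default; a custom weighting can be supplied through a schema
#' file and [load_questionnaire()].
#'
#' @return A `venus_questionnaire` with questions Q1..Q10.
#' @examples
#' q <- builtin_venus()
#' length(q$questions)
#' @export
builtin_venus <- function() {
  venus_questionnaire(
    name = "Venus", version = "1.0",
    questions = list(
      venus_question("Q1", "Are the origin, context, and purpose of the dataset defined?",
        c("curators", "purpose", "context"),
        "Who curated the data, why it was collected, and in which setting."),
      venus_question("Q2", "Are data protection measures described? Is there a license for the data?",
        c("consent", "deidentification", "terms_of_use", "license"),
        "Patient consent, de-identification steps, terms of use, and licensing."),
      venus_question("Q3", "Are the devices, medical centers, and collection periods clearly identified?",
        c("devices", "medical_centers", "collection_period"),
        "How, where, and when the data entries were collected."),
      venus_question("Q4", "Are all variables and their values properly explained?",
        c("features", "values"),
        "Meaning of each variable and of the values it may take."),
      venus_question("Q5", "Does the documentation cover subpopulations identified by protected attributes?",
        c("marginal_distribution", "joint_distribution",
          "expected_distribution", "label_provenance"),
        "Age, sex, ethnicity, genetic ancestry: marginal and joint distributions, expected patterns, and how demographic labels were obtained."),
      venus_question("Q6", "Are sources of potential inaccuracy listed and characterized?",
        c("listed_sources", "characterized"),
        "Plausible sources of data inaccuracy and a quantification of their severity."),
      venus_question("Q7", "Is the information about noise included?",
        c("listed_sources", "characterized"),
        "Sources of signal noise (batch effects, baseline wander, artifacts) and their magnitude."),
      venus_question("Q8", "Does the documentation describe data preparation, including cleaning and annotation?",
        c("cleaning", "annotation"),
        "Signal filtering, imputation, outlier removal; labeling procedures and who performed them."),
      venus_question("Q9", "Is there a peer-reviewed scientific publication describing the data?",
        c("data_centric_publication", "reputable"),
        "A data-centric article in a reputable, ideally open-access indexed journal."),
      venus_question("Q10", "Is the dataset available online without restrictions with a global ID?",
        c("unrestricted", "persistent", "official"),
        "Unrestricted access, a persistent identifier (e.g. DOI), and an official release by the curators.")
    )
  )
}

# ---- serialization -------------------------------------------------------

questionnaire_to_list <- function(q) {
  list(
    name = q$name, version = q$version,
    questions = lapply(q$questions, function(x) {
      list(id = x$id, title = x$title, guidance = x$guidance,
           sub_items = lapply(seq_len(nrow(x$sub_items)), function(i) {
             list(id = x$sub_items$id[i], label = x$sub_items$label[i],
                  weight = x$sub_items$weight[i])
           }))
    })
  )
}

questionnaire_from_list <- function(x) {
  if (is.null(x$name) || is.null(x$version) || is.null(x$questions))
    stop("questionnaire schema: missing required field ",
         paste(setdiff(c("name", "version", "questions"), names(x)),
               collapse = ", "), call. = FALSE)
  questions <- lapply(x$questions, function(qq) {
    if (is.null(qq$id)) stop("questionnaire schema: question without 'id'", call. = FALSE)
    if (is.null(qq$sub_items) || length(qq$sub_items) == 0L)
      stop("questionnaire schema: question '", qq$id, "' has no sub_items", call. = FALSE)
    si <- do.call(rbind, lapply(qq$sub_items, function(s) {
      if (is.null(s$id) || is.null(s$weight))
        stop("questionnaire schema: sub-item of '", qq$id,
             "' missing 'id' or 'weight'", call. = FALSE)
      data.frame(id = s$id, label = if (is.null(s$label)) s$id else s$label,
                 weight = as.numeric(s$weight), stringsAsFactors = FALSE)
    }))
    venus_question(qq$id, if (is.null(qq$title)) "" else qq$title, si,
                   if (is.null(qq$guidance)) "" else qq$guidance)
  })
  venus_questionnaire(x$name, x$version, questions)
}

#' Save a questionnaire to YAML or JSON
#'
#' @param q A `venus_questionnaire`.
#' @param path Output file; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `path`, invisibly.
#' @export
save_questionnaire <- function(q, path) {
  validate_questionnaire(q)
  x <- questionnaire_to_list(q)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    writeLines(yaml::as.yaml(x, precision = 15L), path)
  } else if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    stop("unsupported questionnaire format '", ext, "' (use yaml or json)",
         call. = FALSE)
  }
  invisible(path)
}

#' Load a questionnaire from YAML or JSON
#'
#' The parsed instrument is validated: weight sums, nonnegativity, unique
#' ids, and (for an instrument named "Venus") the ten-question cardinality.
#'
#' @param path A YAML or JSON schema file, e.g. one written by
#'   [save_questionnaire()].
#' @return A `venus_questionnaire`.
#' @export
load_questionnaire <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  x <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path)
  } else {
    stop("unsupported questionnaire format '", ext, "' (use yaml or json)",
         call. = FALSE)
  }
  questionnaire_from_list(x)
}

#' @export
print.venus_questionnaire <- function(x, ...) {
  cat(sprintf("<%s questionnaire v%s: %d questions>\n",
              x$name, x$version, length(x$questions)))
  for (q in x$questions) {
    cat(sprintf("  %-4s %s [%s]\n", q$id, q$title,
                paste(q$sub_items$id, collapse = ", ")))
  }
  invisible(x)
}

extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "venusscore")
  if (p == "") stop("bundled fixture not found: ", file, call. = FALSE)
  p
}

#' Dataset metadata for the twelve-dataset biomedical cohort
#'
#' Metadata (field, data type, disease, repository, references) for the
#' twelve datasets D1..D12 of the bundled evaluation cohort, spanning
#' electronic health records, gene expression, physiologic signals, medical
#' imaging, cheminformatics, and medical text.
#'
#' @return A data frame with one row per dataset.
#' @export
table3_meta <- function() {
  meta <- utils::read.csv(extdata_path("table3_dataset_meta.csv"),
                          stringsAsFactors = FALSE)
  if (anyDuplicated(meta$dataset_id))
    stop("duplicated dataset_id in cohort metadata", call. = FALSE)
  meta
}
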