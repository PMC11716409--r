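#' Generate synthetic multi-annotator annotation sheets
#'
#' Simulates independent annotators scoring a cohort of datasets, for
#' exercising the merging, agreement, and cohort-statistics machinery. Each
#' question score is drawn as a per-question base mean plus zero-mean
#' Gaussian annotator noise, then clamped to \[0, 1\]. The default base
#' profile is the per-question mean of the bundled twelve-dataset cohort,
#' so synthetic sheets resemble the score levels seen in real biomedical
#' dataset evaluations; the default setup (12 datasets, 2 annotators)
#' mirrors a two-annotator study design.
#'
#' Determinism: the same `seed` and configuration produce identical output.
#'
#' @param seed Integer RNG seed.
#' @param n_datasets Number of datasets (ids `SD1`, `SD2`, ...).
#' @param n_annotators Number of annotators per dataset (ids `A1`, ...).
#' @param noise_sd Standard deviation of the annotator noise, in score
#'   units on the \[0, 1\] question scale.
#' @param base_profile Optional named numeric (question id to mean score in
#'   \[0, 1\]); defaults to the bundled cohort's question means.
#' @param q A `venus_questionnaire`.
#' @return A list of `venus_annotation`, ordered by dataset then annotator.
#' @export
generate_synthetic_annotations <- function(seed, n_datasets = 12L,
                                           n_annotators = 2L, noise_sd = 0.1,
                                           base_profile = NULL,
                                           q = builtin_venus()) {
  n_datasets <- as.integer(n_datasets)
  n_annotators <- as.integer(n_annotators)
  if (is.na(n_datasets) || n_datasets < 1L)
    stop("n_datasets must be a positive integer", call. = FALSE)
  if (is.na(n_annotators) || n_annotators < 1L)
    stop("n_annotators must be a positive integer", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("noise_sd must be nonnegative", call. = FALSE)
  qids <- question_ids(q)
  if (is.null(base_profile)) {
    fx <- table4_fixture()
    mat <- vapply(fx$annotations,
                  function(a) unlist(a$entries[qids]), numeric(length(qids)))
    base_profile <- rowMeans(mat)
    names(base_profile) <- qids
  }
  if (!all(qids %in% names(base_profile)))
    stop("base_profile must name every question of the instrument", call. = FALSE)
  if (any(base_profile < 0) || any(base_profile > 1))
    stop("base_profile means must lie in [0, 1]", call. = FALSE)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))

  # per-dataset shift keeps datasets distinguishable (non-constant series)
  dataset_shift <- stats::runif(n_datasets, -0.2, 0.2)
  out <- list()
  for (d in seq_len(n_datasets)) {
    for (a in seq_len(n_annotators)) {
      mu <- pmin(1, pmax(0, base_profile[qids] + dataset_shift[d]))
      scores <- pmin(1, pmax(0, mu + stats::rnorm(length(qids), 0, noise_sd)))
      out[[length(out) + 1L]] <- venus_annotation(
        dataset_id = sprintf("SD%d", d),
        annotator_id = sprintf("A%d", a),
        entries = stats::setNames(as.list(unname(scores)), qids)
      )
    }
  }
  out
}
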