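#' The twelve-dataset cohort fixture
#'
#' The consensus (annotator-averaged) per-question Venus scores for the
#' twelve biomedical datasets of the bundled evaluation cohort, together
#' with their metadata. Each annotation carries direct question scores;
#' totals follow by [score_dataset()].
#'
#' @return A list with `meta` (the [table3_meta()] data frame) and
#'   `annotations` (named list of twelve `venus_annotation`, D1..D12).
#' @examples
#' fx <- table4_fixture()
#' fx$annotations[["D2"]]$entries$Q5  # 0.63
#' @export
table4_fixture <- function() {
  scores <- utils::read.csv(extdata_path("table4_scores.csv"),
                            stringsAsFactors = FALSE)
  meta <- table3_meta()
  ids <- unique(scores$dataset_id)
  anns <- lapply(ids, function(d) {
    sub <- scores[scores$dataset_id == d, ]
    venus_annotation(
      dataset_id = d,
      annotator_id = "consensus",
      entries = stats::setNames(as.list(sub$score), sub$question_id),
      sources_consulted = strsplit(meta$references[meta$dataset_id == d],
                                   "; ", fixed = TRUE)[[1L]]
    )
  })
  names(anns) <- ids
  list(meta = meta, annotations = anns)
}
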