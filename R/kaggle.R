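#' Field-weight table of the Kaggle Dataset Usability Score replica
#'
#' The eleven score fields with the additive point weights deduced from
#' published scores of datasets missing exactly one field, grouped into
#' completeness, credibility, and compatibility. The weights sum to 10.00;
#' the Column Description field applies to tabular datasets only.
#'
#' @return A data frame of class `kaggle_field_table` with columns
#'   `position`, `field`, `group`, `weight`, `tabular_only`.
#' @examples
#' w <- builtin_kaggle_weights()
#' sum(w$weight)  # 10
#' @export
builtin_kaggle_weights <- function() {
  tab <- utils::read.csv(extdata_path("table1_kaggle_weights.csv"),
                         stringsAsFactors = FALSE)
  validate_kaggle_table(tab)
  class(tab) <- c("kaggle_field_table", "data.frame")
  tab
}

validate_kaggle_table <- function(tab) {
  if (anyDuplicated(tab$field))
    stop("duplicated Kaggle field name", call. = FALSE)
  if (any(tab$weight < 0))
    stop("Kaggle field weights must be nonnegative", call. = FALSE)
  if (abs(sum(tab$weight) - 10) > 0.005)
    stop("Kaggle field weights must total 10.00 (got ",
         format(sum(tab$weight)), ")", call. = FALSE)
  if (sum(tab$tabular_only) != 1L)
    stop("exactly one field must be tabular-only", call. = FALSE)
  invisible(tab)
}

#' Construct a Kaggle field-presence record
#'
#' @param present Character vector of the field names present on the
#'   dataset page, or a named logical vector over all fields.
#' @param is_tabular Is the dataset tabular? For non-tabular datasets the
#'   Column Description field is not applicable and must not be marked
#'   present.
#' @param table A `kaggle_field_table` used to validate field names.
#' @return An object of class `kaggle_presence`.
#' @export
kaggle_presence <- function(present, is_tabular = TRUE,
                            table = builtin_kaggle_weights()) {
  if (is.logical(present)) {
    if (is.null(names(present)))
      stop("a logical presence vector must be named by field", call. = FALSE)
    present <- names(present)[present]
  }
  unknown <- setdiff(present, table$field)
  if (length(unknown))
    stop("unknown Kaggle field name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  tab_field <- table$field[table$tabular_only]
  if (!is_tabular && tab_field %in% present)
    stop("'", tab_field, "' is not applicable to non-tabular datasets",
         call. = FALSE)
  structure(list(present = unique(present), is_tabular = isTRUE(is_tabular)),
            class = "kaggle_presence")
}

#' Compute the replica Kaggle usability score
#'
#' Sums the weights of the present fields. For non-tabular datasets the
#' Column Description weight is excluded and, by default, not redistributed,
#' so the maximum attainable score is 9.41 — mirroring the platform behavior
#' observed for fully documented non-tabular datasets. With
#' `renormalize = TRUE` non-tabular scores are rescaled so a complete record
#' reaches 10.
#'
#' @param p A `kaggle_presence` (or character vector of present fields).
#' @param table A `kaggle_field_table`.
#' @param renormalize Rescale non-tabular scores to a maximum of 10?
#' @return The score, a number in \[0, 10\].
#' @examples
#' w <- builtin_kaggle_weights()
#' kaggle_score(kaggle_presence(w$field), w)  # 10
#' @export
kaggle_score <- function(p, table = builtin_kaggle_weights(),
                         renormalize = FALSE) {
  if (is.character(p)) p <- kaggle_presence(p, is_tabular = TRUE, table = table)
  stopifnot(inherits(p, "kaggle_presence"))
  score <- sum(table$weight[table$field %in% p$present])
  if (!p$is_tabular && renormalize) {
    max_nontab <- sum(table$weight[!table$tabular_only])
    score <- score * 10 / max_nontab
  }
  score
}

#' Construct a (presence, published score) observation
#'
#' @param presence A `kaggle_presence`.
#' @param published_score The aggregate score published for the dataset,
#'   in \[0, 10\].
#' @return An object of class `kaggle_observation`.
#' @export
kaggle_observation <- function(presence, published_score) {
  stopifnot(inherits(presence, "kaggle_presence"))
  published_score <- as.numeric(published_score)
  if (!is.finite(published_score) || published_score < 0 || published_score > 10)
    stop("published_score must lie in [0, 10]", call. = FALSE)
  structure(list(presence = presence, published_score = published_score),
            class = "kaggle_observation")
}

applicable_fields <- function(p, table) {
  if (p$is_tabular) table$field else table$field[!table$tabular_only]
}

#' Deduce a single hidden field weight from one observation
#'
#' The one-missing-field shortcut: when a dataset's page lacks exactly one
#' applicable field, that field's weight is the full score (10) minus the
#' published score, reported at two decimals.
#'
#' @param obs A `kaggle_observation` with exactly one applicable field
#'   absent.
#' @param table A `kaggle_field_table` (field names and applicability only;
#'   its weights are not consulted).
#' @param full_score The instrument maximum (10).
#' @return Named numeric of length one: the deduced weight, named by field.
#' @examples
#' w <- builtin_kaggle_weights()
#' p <- kaggle_presence(setdiff(w$field, "Column Description"), table = w)
#' deduce_weight_single(kaggle_observation(p, 9.41), w)  # Column Description 0.59
#' @export
deduce_weight_single <- function(obs, table = builtin_kaggle_weights(),
                                 full_score = 10) {
  stopifnot(inherits(obs, "kaggle_observation"))
  absent <- setdiff(applicable_fields(obs$presence, table), obs$presence$present)
  if (length(absent) != 1L)
    stop(length(absent), " applicable field(s) absent; the single-field ",
         "deduction needs exactly one — use deduce_weights() for the ",
         "least-squares solver", call. = FALSE)
  stats::setNames(round(full_score - obs$published_score, 2), absent)
}

#' Deduce hidden field weights from aggregate-score observations
#'
#' Solves `presence-matrix %*% w = published_scores` for the nonnegative
#' weight vector `w` in the least-squares sense (nonnegative least squares
#' via [pracma::lsqnonneg()]). A field's weight is flagged identifiable only
#' when it is uniquely determined by the observations, i.e. its unit vector
#' lies in the row space of the presence matrix; unidentifiable entries of
#' the solution are arbitrary within the solution set and should not be
#' interpreted.
#'
#' When the instrument maximum is known, supplying `full_score` adds an
#' implicit all-fields-present observation with that score, which is what
#' makes the printed one-missing-field deduction (weight = 10 - score)
#' recoverable from single observations.
#'
#' @param obs List of `kaggle_observation`.
#' @param table A `kaggle_field_table` (field names / applicability).
#' @param full_score Optional known score of a complete record (e.g. 10);
#'   `NULL` to use only the observations.
#' @return A list of class `kaggle_weight_fit`: `weights` (named numeric),
#'   `identifiable` (named logical), `residual_norm`, `n_obs`.
#' @export
deduce_weights <- function(obs, table = builtin_kaggle_weights(),
                           full_score = NULL) {
  if (inherits(obs, "kaggle_observation")) obs <- list(obs)
  if (!length(obs)) stop("at least one observation is required", call. = FALSE)
  fields <- table$field
  rows <- lapply(obs, function(o) {
    stopifnot(inherits(o, "kaggle_observation"))
    as.numeric(fields %in% intersect(o$presence$present,
                                     applicable_fields(o$presence, table)))
  })
  X <- do.call(rbind, rows)
  y <- vapply(obs, function(o) o$published_score, numeric(1))
  if (!is.null(full_score)) {
    X <- rbind(X, rep(1, length(fields)))
    y <- c(y, as.numeric(full_score))
  }
  colnames(X) <- fields
  fit <- pracma::lsqnonneg(X, y)
  w <- stats::setNames(fit$x, fields)
  rk <- qr(X)$rank
  identifiable <- vapply(seq_along(fields), function(j) {
    e <- rep(0, length(fields)); e[j] <- 1
    qr(rbind(X, e))$rank == rk
  }, logical(1))
  structure(
    list(weights = w,
         identifiable = stats::setNames(identifiable, fields),
         residual_norm = sqrt(fit$resid.norm),
         n_obs = length(obs)),
    class = "kaggle_weight_fit"
  )
}

#' @export
print.kaggle_weight_fit <- function(x, ...) {
  cat(sprintf("<kaggle_weight_fit: %d observation(s), residual norm %.3g>\n",
              x$n_obs, x$residual_norm))
  df <- data.frame(field = names(x$weights),
                   weight = round(x$weights, 4),
                   identifiable = x$identifiable, row.names = NULL)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Read Kaggle presence/observation records from CSV
#'
#' One row per dataset: eleven 0/1 or TRUE/FALSE field columns (named as in
#' [builtin_kaggle_weights()], with spaces or slashes replaced by dots or
#' underscores if needed), an `is_tabular` column, and optionally a
#' `published_score` column.
#'
#' @param path CSV file.
#' @param table A `kaggle_field_table`.
#' @return A list of `kaggle_observation` (if `published_score` present) or
#'   `kaggle_presence`.
#' @export
read_kaggle_csv <- function(path, table = builtin_kaggle_weights()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  norm <- function(x) tolower(gsub("[^a-z0-9]+", "_", tolower(x)))
  field_cols <- match(norm(table$field), norm(names(df)))
  if (anyNA(field_cols))
    stop("presence CSV missing field column(s): ",
         paste(table$field[is.na(field_cols)], collapse = ", "), call. = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    pres <- as.logical(unlist(df[i, field_cols]))
    is_tab <- if ("is_tabular" %in% names(df)) as.logical(df$is_tabular[i]) else TRUE
    p <- kaggle_presence(table$field[pres], is_tabular = is_tab, table = table)
    if ("published_score" %in% names(df) && !is.na(df$published_score[i]))
      kaggle_observation(p, df$published_score[i])
    else p
  })
}
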