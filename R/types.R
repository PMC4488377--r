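CONDITIONS <- c("WARNING", "CUE", "MIDDLE", "BOTH_END",
                "EITHER_END_INITIAL", "EITHER_END_LAST", "ERROR")

CHOICE_CONDITIONS <- c("MIDDLE", "BOTH_END",
                       "EITHER_END_INITIAL", "EITHER_END_LAST")

#' Construct and validate a trial event table
#'
#' @param onset event onsets (s), non-negative and non-decreasing.
#' @param duration event durations (s), non-negative.
#' @param condition one of WARNING, CUE, MIDDLE, BOTH_END,
#'   EITHER_END_INITIAL, EITHER_END_LAST, ERROR.
#' @param correct logical; NA where correctness is not applicable.
#' @return a data.frame of class `event_table`.
#' @export
event_table <- function(onset = numeric(), duration = numeric(),
                        condition = character(), correct = logical()) {
  df <- data.frame(onset = as.numeric(onset),
                   duration = as.numeric(duration),
                   condition = as.character(condition),
                   correct = as.logical(correct),
                   stringsAsFactors = FALSE)
  validate_event_table(df)
  class(df) <- c("event_table", "data.frame")
  df
}

validate_event_table <- function(df) {
  stopifnot(all(c("onset", "duration", "condition", "correct") %in% names(df)))
  if (any(df$onset < 0)) stop("event onsets must be non-negative", call. = FALSE)
  if (is.unsorted(df$onset)) stop("event onsets must be non-decreasing", call. = FALSE)
  if (any(df$duration < 0)) stop("event durations must be non-negative", call. = FALSE)
  bad <- setdiff(unique(df$condition), CONDITIONS)
  if (length(bad))
    stop("unknown condition(s): ", paste(bad, collapse = ", "), call. = FALSE)
  invisible(df)
}

#' Construct a session time-series container
#'
#' Holds a timepoints-by-regions BOLD table, its sampling interval, and the
#' nuisance covariates (e.g. six motion parameters) recorded alongside it.
#'
#' @param values numeric matrix, timepoints x regions.
#' @param tr sampling interval (s).
#' @param region_labels character region names (defaults to column names).
#' @param nuisance numeric matrix, timepoints x covariates (or NULL).
#' @return an object of class `session_timeseries`.
#' @export
session_timeseries <- function(values, tr, region_labels = colnames(values),
                               nuisance = NULL) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("time series contains missing values", call. = FALSE)
  if (tr <= 0) stop("`tr` must be positive", call. = FALSE)
  if (is.null(region_labels))
    region_labels <- sprintf("R%02d", seq_len(ncol(values)))
  if (length(region_labels) != ncol(values))
    stop("`region_labels` length must match the number of regions", call. = FALSE)
  colnames(values) <- region_labels
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != nrow(values))
      stop("nuisance row count must equal the number of timepoints", call. = FALSE)
    if (anyNA(nuisance)) stop("nuisance table contains missing values", call. = FALSE)
    if (is.null(colnames(nuisance)))
      colnames(nuisance) <- sprintf("nuisance%d", seq_len(ncol(nuisance)))
  }
  structure(list(values = values, tr = tr, region_labels = region_labels,
                 nuisance = nuisance),
            class = "session_timeseries")
}

#' Construct and validate a connectivity matrix
#'
#' Square directed matrix of region-to-region weights; entry `[A, B]` is the
#' weight of the connection from A to B. The diagonal is never consumed by
#' any operation. Binary kinds must contain only 0 and 1.
#'
#' @param weights square numeric matrix.
#' @param labels region names (defaults to row names).
#' @param kind one of `ppi_beta_session`, `ppi_z_group`, `binarized_ppi`,
#'   `binary_anatomy`, `nondirectional`.
#' @return an object of class `connectivity_matrix` (a matrix with
#'   attributes `kind` and dimnames set to the labels).
#' @export
connectivity_matrix <- function(weights,
                                labels = rownames(weights),
                                kind = c("ppi_beta_session", "ppi_z_group",
                                         "binarized_ppi", "binary_anatomy",
                                         "nondirectional")) {
  kind <- match.arg(kind)
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights))
    stop("connectivity matrix must be square", call. = FALSE)
  n <- nrow(weights)
  if (is.null(labels)) labels <- sprintf("R%02d", seq_len(n))
  if (length(labels) != n || anyDuplicated(labels))
    stop("`labels` must be unique and match the matrix dimension", call. = FALSE)
  dimnames(weights) <- list(labels, labels)
  if (kind %in% c("binarized_ppi", "binary_anatomy")) {
    off <- weights[row(weights) != col(weights)]
    if (!all(off %in% c(0, 1)))
      stop("binary connectivity matrices may contain only 0 and 1", call. = FALSE)
    if (kind == "binary_anatomy" && any(diag(weights) != 0))
      stop("anatomical connectivity matrix must contain no self-connections",
           call. = FALSE)
  }
  structure(weights, kind = kind, class = c("connectivity_matrix", "matrix"))
}

cm_kind <- function(x) attr(x, "kind")

is_binary_kind <- function(x) {
  cm_kind(x) %in% c("binarized_ppi", "binary_anatomy")
}
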