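# Tab-separated readers and writers. One directory per session holding
# timeseries.tsv (timepoints x regions), events.tsv and nuisance.tsv; a
# cohort manifest lists session ids and performance.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write a session to a directory
#'
#' @param session a `session_record`.
#' @param dir parent directory; a subdirectory named after the session id
#'   is created.
#' @return the session directory, invisibly.
#' @export
write_session <- function(session, dir) {
  sdir <- file.path(dir, session$session_id)
  dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
  ts <- session$timeseries
  write_tsv(as.data.frame(ts$values), file.path(sdir, "timeseries.tsv"))
  write_tsv(as.data.frame(session$events), file.path(sdir, "events.tsv"))
  write_tsv(as.data.frame(ts$nuisance), file.path(sdir, "nuisance.tsv"))
  meta <- data.frame(session_id = session$session_id, tr = ts$tr,
                     performance = session$performance)
  write_tsv(meta, file.path(sdir, "session.tsv"))
  invisible(sdir)
}

#' Read a session from a directory
#'
#' Expects `timeseries.tsv`, `events.tsv`, `nuisance.tsv` and `session.tsv`
#' as written by [write_session()]; cross-checks row counts and that all
#' events fall within the scanned duration.
#'
#' @param dir session directory.
#' @return a `session_record`.
#' @export
read_session <- function(dir) {
  meta <- read_tsv(file.path(dir, "session.tsv"))
  values <- as.matrix(read_tsv(file.path(dir, "timeseries.tsv")))
  if (!is.numeric(values))
    stop("non-numeric cell in ", file.path(dir, "timeseries.tsv"), call. = FALSE)
  nuisance <- as.matrix(read_tsv(file.path(dir, "nuisance.tsv")))
  if (nrow(nuisance) != nrow(values))
    stop("nuisance and time-series row counts differ in ", dir, call. = FALSE)
  ev <- read_tsv(file.path(dir, "events.tsv"))
  validate_event_table(ev)
  scan_end <- nrow(values) * meta$tr
  if (nrow(ev) && any(ev$onset + ev$duration > scan_end))
    stop("events extend beyond the scanned duration (", scan_end, " s) in ",
         dir, call. = FALSE)
  class(ev) <- c("event_table", "data.frame")
  ts <- session_timeseries(values, meta$tr, nuisance = nuisance)
  structure(list(session_id = meta$session_id, timeseries = ts, events = ev,
                 performance = meta$performance),
            class = "session_record")
}

#' Write a cohort and its manifest
#'
#' @param cohort list of `session_record`s.
#' @param dir output directory.
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort) write_session(s, dir)
  manifest <- data.frame(session_id = vapply(cohort, `[[`, "", "session_id"),
                         performance = vapply(cohort, `[[`, 0, "performance"))
  path <- file.path(dir, "manifest.tsv")
  write_tsv(manifest, path)
  invisible(path)
}

#' Read a cohort via its manifest
#'
#' @param dir directory containing `manifest.tsv` and session subdirectories.
#' @return list of `session_record`s.
#' @export
read_cohort <- function(dir) {
  manifest <- read_tsv(file.path(dir, "manifest.tsv"))
  lapply(manifest$session_id, function(id) read_session(file.path(dir, id)))
}

#' Write a connectivity matrix as a labelled square table
#'
#' @param matrix a [connectivity_matrix()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_connectivity_matrix <- function(matrix, path) {
  df <- data.frame(region = rownames(matrix), unclass(as.matrix(matrix)),
                   check.names = FALSE)
  write_tsv(df, path)
  invisible(path)
}

#' Read a connectivity matrix written by [write_connectivity_matrix()]
#'
#' @param path input file.
#' @param kind declared matrix kind; binary kinds are validated for
#'   \{0, 1\} entries and (for anatomy) an empty diagonal.
#' @return a [connectivity_matrix()].
#' @export
read_connectivity_matrix <- function(path, kind = "ppi_z_group") {
  df <- read_tsv(path)
  labels <- df[[1]]
  w <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(w) != ncol(w))
    stop("matrix in ", path, " is not square", call. = FALSE)
  if (!identical(as.character(labels), colnames(w)))
    stop("row and column labels disagree in ", path, call. = FALSE)
  rownames(w) <- labels
  connectivity_matrix(w, labels, kind = kind)
}
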