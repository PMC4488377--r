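# Session-level feature tables feeding the classifier.

#' PPI connectivity feature table for a cohort
#'
#' Estimates the session PPI beta matrix for every session and flattens the
#' off-diagonal entries into a sessions x ordered-pairs table with
#' `"seed->target"` feature names.
#'
#' @param cohort list of `session_record`s (see [generate_cohort()]).
#' @inheritParams estimate_ppi
#' @return list with `features` (sessions x N(N-1) matrix, rownames session
#'   ids), `betas` (the per-session matrices), `performance` (per-session).
#' @export
ppi_feature_table <- function(cohort, hrf = hrf_model(), ridge = 1e-2,
                              highpass_cutoff = 128) {
  betas <- lapply(cohort, session_ppi_matrix, hrf = hrf, ridge = ridge,
                  highpass_cutoff = highpass_cutoff)
  labels <- rownames(betas[[1]])
  off <- which(row(betas[[1]]) != col(betas[[1]]))
  idx <- arrayInd(off, dim(betas[[1]]))
  feature_names <- paste0(labels[idx[, 1]], "->", labels[idx[, 2]])
  features <- t(vapply(betas, function(b) unclass(b)[off],
                       numeric(length(off))))
  dimnames(features) <- list(vapply(cohort, `[[`, "", "session_id"),
                             feature_names)
  list(features = features, betas = betas,
       performance = vapply(cohort, `[[`, 0, "performance"))
}

#' Activation feature table for a cohort
#'
#' Fits the session GLM (condition regressors with HRF derivatives, motion
#' covariates, high-pass set) and extracts the per-region MIDDLE minus
#' BOTH_END contrast estimate as one activation feature per region.
#'
#' @param cohort list of `session_record`s.
#' @param hrf an [hrf_model()].
#' @param highpass_cutoff high-pass cutoff (s).
#' @return sessions x regions matrix of contrast estimates.
#' @export
activation_feature_table <- function(cohort, hrf = hrf_model(),
                                     highpass_cutoff = 128) {
  rows <- lapply(cohort, function(sess) {
    ts <- sess$timeseries
    X <- build_design_matrix(sess$events, ts$tr, nrow(ts$values), hrf = hrf,
                             nuisance = ts$nuisance,
                             highpass_cutoff = highpass_cutoff)
    fit <- fit_glm(ts, X)
    cs <- contrast_stat(fit, make_contrast(fit, "MIDDLE", "BOTH_END"))
    cs$estimate
  })
  out <- do.call(rbind, rows)
  dimnames(out) <- list(vapply(cohort, `[[`, "", "session_id"),
                        cohort[[1]]$timeseries$region_labels)
  out
}
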