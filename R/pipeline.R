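# End-to-end driver: simulate -> PPI -> network metrics -> simulated lesion.

#' Pipeline configuration
#'
#' Collects the stage parameters and the single global seed from which every
#' stochastic stage derives its own seed (see [derive_seed()]).
#'
#' @param truth a [synthetic_truth()]; defaults to [planted_hub_truth()].
#' @param n_sessions cohort size.
#' @param rng_seed global integer seed.
#' @param n_rand randomizations for the betweenness null.
#' @param n_null draws for the lesion impact null.
#' @param spec a [classifier_spec()].
#' @param tr,n_timepoints acquisition parameters.
#' @param out_dir optional output directory for the summary files.
#' @param verbose print progress messages.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(truth = planted_hub_truth(), n_sessions = 30,
                            rng_seed = 1, n_rand = 10000, n_null = 200,
                            spec = classifier_spec(), tr = 2.5,
                            n_timepoints = 117, out_dir = NULL,
                            verbose = FALSE) {
  structure(list(truth = truth, n_sessions = n_sessions, rng_seed = rng_seed,
                 n_rand = n_rand, n_null = n_null, spec = spec, tr = tr,
                 n_timepoints = n_timepoints, out_dir = out_dir,
                 verbose = verbose),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Generates a cohort, estimates the session PPI matrices and the group
#' z-matrix, identifies hubs by weighted betweenness with a randomization
#' null, labels sessions by performance tertiles, classifies high versus low
#' performance with a grid-searched leave-one-out RBF-SVM from PPI and from
#' activation features, computes the per-node simulated-lesion impacts with
#' their random-edge-deletion null, and correlates impact with betweenness.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result` with elements `cohort_size`,
#'   `group_z`, `centrality`, `labels`, `svm` (chosen C/gamma and
#'   accuracies), `lesion` (the [simulated_lesion()] table),
#'   `impact_centrality` (r and p), `seeds`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (config$verbose) message(...)
  seeds <- list(cohort = derive_seed(config$rng_seed, "cohort"),
                netnull = derive_seed(config$rng_seed, "netnull"),
                lesion = derive_seed(config$rng_seed, "lesion"))

  say("generating cohort of ", config$n_sessions, " sessions")
  cohort <- generate_cohort(config$truth, n_sessions = config$n_sessions,
                            rng_seed = seeds$cohort, tr = config$tr,
                            n_timepoints = config$n_timepoints)

  say("estimating session PPI matrices")
  ppi <- ppi_feature_table(cohort)
  group_z <- group_ppi_matrix(ppi$betas)

  say("betweenness centrality with ", config$n_rand, " randomizations")
  centrality <- randomization_null_weighted(group_z, n_rand = config$n_rand,
                                            rng_seed = seeds$netnull)

  labels <- label_sessions(ppi$performance,
                           vapply(cohort, `[[`, "", "session_id"))
  keep <- labels$class %in% c("high", "low")
  classes <- droplevels(labels$class[keep])

  say("grid search and leave-one-out classification")
  feats <- ppi$features[keep, , drop = FALSE]
  gs <- grid_search(feats, classes, config$spec)
  spec_best <- config$spec; spec_best$C <- gs$C; spec_best$gamma <- gs$gamma

  act <- activation_feature_table(cohort)[keep, , drop = FALSE]
  gs_act <- grid_search(act, classes, config$spec)

  say("simulated lesion with ", config$n_null, " null draws")
  lesion <- simulated_lesion(feats, classes, spec_best,
                             n_null = config$n_null, rng_seed = seeds$lesion)

  bc <- centrality$nodes$betweenness[match(lesion$node, centrality$nodes$node)]
  impact_cor <- correlate_impact_centrality(lesion$impact, bc)

  n_hl <- sum(keep)
  svm <- list(C = gs$C, gamma = gs$gamma, accuracy_ppi = gs$accuracy,
              accuracy_activation = gs_act$accuracy,
              n_sessions = n_hl,
              p_binomial_ppi = binomial_accuracy_test(
                round(gs$accuracy * n_hl), n_hl),
              p_binomial_activation = binomial_accuracy_test(
                round(gs_act$accuracy * n_hl), n_hl))

  result <- structure(list(cohort_size = length(cohort), group_z = group_z,
                           centrality = centrality, labels = labels,
                           svm = svm, lesion = lesion,
                           impact_centrality = impact_cor, seeds = seeds),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_summary(result, config$out_dir)
  result
}

# Machine-readable summary (TSV tables plus a flat key-value file).
write_pipeline_summary <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_connectivity_matrix(result$group_z, file.path(out_dir, "group_z.tsv"))
  write_tsv(result$centrality$nodes, file.path(out_dir, "centrality.tsv"))
  write_tsv(as.data.frame(result$labels), file.path(out_dir, "labels.tsv"))
  write_tsv(as.data.frame(result$lesion), file.path(out_dir, "lesion.tsv"))
  flat <- c(result$svm,
            impact_centrality_r = result$impact_centrality$r,
            impact_centrality_p = result$impact_centrality$p,
            unlist(result$seeds))
  write_tsv(data.frame(key = names(flat), value = unlist(flat)),
            file.path(out_dir, "summary.tsv"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result over", x$cohort_size, "sessions\n")
  cat(sprintf("LOO accuracy: PPI %.3f, activation %.3f (C=%g, gamma=%g)\n",
              x$svm$accuracy_ppi, x$svm$accuracy_activation,
              x$svm$C, x$svm$gamma))
  cat(sprintf("impact vs betweenness: r = %.3f, p = %.4f\n",
              x$impact_centrality$r, x$impact_centrality$p))
  invisible(x)
}
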