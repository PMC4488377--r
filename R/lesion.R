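# Simulated-lesion analysis: tertile labelling of sessions by behavioural
# performance, leave-one-session-out soft-margin SVM classification of high
# versus low performance from connectivity patterns, per-node predicted
# impact via node-deleted feature sets, and a random-edge-deletion null
# fitted as a normal on the arcsine scale.

#' Label sessions by performance tertiles
#'
#' Sessions with performance below 0.5 are omitted as atypical. The
#' remaining sessions are ranked; the top `floor(n/3)` become the high set,
#' the bottom `floor(n/3)` the low set, and the rest intermediate. Ties are
#' broken by stable session order.
#'
#' @param performance per-session fractions correct in \[0, 1\].
#' @param session_id optional session identifiers.
#' @return data.frame of class `session_labels` with `session_id`,
#'   `performance`, `class` (high / intermediate / low / omitted).
#' @export
label_sessions <- function(performance, session_id = NULL) {
  if (any(performance < 0 | performance > 1, na.rm = TRUE))
    stop("performance values must lie in [0, 1]", call. = FALSE)
  n <- length(performance)
  if (is.null(session_id)) session_id <- sprintf("S%03d", seq_len(n))
  class <- rep("intermediate", n)
  class[performance < 0.5] <- "omitted"
  retained <- which(class != "omitted")
  if (length(retained) < 6)
    stop("too few sessions: ", length(retained),
         " retained after omission; need at least 6", call. = FALSE)
  k <- floor(length(retained) / 3)
  ord_hi <- retained[order(-performance[retained], seq_along(retained))]
  ord_lo <- retained[order(performance[retained], seq_along(retained))]
  class[ord_hi[seq_len(k)]] <- "high"
  class[ord_lo[seq_len(k)]] <- "low"
  out <- data.frame(session_id = session_id, performance = performance,
                    class = factor(class, levels = c("high", "intermediate",
                                                     "low", "omitted")),
                    stringsAsFactors = FALSE)
  class(out) <- c("session_labels", "data.frame")
  out
}

#' Radial basis function kernel
#'
#' `exp(-gamma * ||x - y||^2)`, the similarity used by the soft-margin SVM.
#'
#' @param x,y numeric feature vectors of equal length.
#' @param gamma positive kernel width parameter.
#' @return similarity in (0, 1\].
#' @export
rbf_kernel <- function(x, y, gamma) {
  if (length(x) != length(y)) stop("`x` and `y` lengths differ", call. = FALSE)
  if (gamma <= 0) stop("`gamma` must be positive", call. = FALSE)
  exp(-gamma * sum((x - y)^2))
}

#' Classifier specification
#'
#' @param kernel `"rbf"` or `"linear"`.
#' @param C soft-margin constant (> 0).
#' @param gamma RBF kernel width (> 0).
#' @param C_grid,gamma_grid grids for [grid_search()]; defaults span
#'   C in 2^-5 .. 2^15 and gamma in 2^-15 .. 2^3 in powers of 4.
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(kernel = c("rbf", "linear"), C = 1, gamma = 0.01,
                            C_grid = 2^seq(-5, 15, by = 2),
                            gamma_grid = 2^seq(-15, 3, by = 2)) {
  kernel <- match.arg(kernel)
  if (C <= 0 || gamma <= 0) stop("`C` and `gamma` must be positive", call. = FALSE)
  if (!length(C_grid) || !length(gamma_grid))
    stop("parameter grids must be non-empty", call. = FALSE)
  if (any(C_grid <= 0) || any(gamma_grid <= 0))
    stop("grid values must be positive", call. = FALSE)
  structure(list(kernel = kernel, C = C, gamma = gamma,
                 C_grid = sort(C_grid), gamma_grid = sort(gamma_grid)),
            class = "classifier_spec")
}

# Per-feature standardization fitted on the training rows only, then
# applied to both train and test (test sessions never influence scaling).
standardize_fold <- function(train, test) {
  mu <- colMeans(train)
  sdv <- apply(train, 2, sd)
  sdv[sdv == 0] <- 1
  list(train = sweep(sweep(train, 2, mu), 2, sdv, "/"),
       test = sweep(sweep(test, 2, mu), 2, sdv, "/"))
}

#' Leave-one-session-out classification accuracy
#'
#' k-fold cross validation with k equal to the number of sessions: each
#' session in turn is held out, a soft-margin SVM (libsvm, solver tolerance
#' 1e-6) is trained on the rest, and the held-out label is predicted.
#' Features are z-scored within each training fold. Deterministic given the
#' data and specification.
#'
#' @param features sessions x features numeric matrix.
#' @param classes two-level factor (or character) of session labels.
#' @param spec a [classifier_spec()].
#' @return fraction of sessions classified correctly.
#' @export
loo_accuracy <- function(features, classes, spec = classifier_spec()) {
  features <- as.matrix(features)
  classes <- factor(classes)
  if (nlevels(classes) != 2)
    stop("exactly two classes are required", call. = FALSE)
  n <- nrow(features)
  if (length(classes) != n)
    stop("one class label per session is required", call. = FALSE)
  correct <- logical(n)
  for (i in seq_len(n)) {
    tr_y <- classes[-i]
    if (nlevels(droplevels(tr_y)) < 2)
      stop("training fold for session ", i, " contains a single class",
           call. = FALSE)
    f <- standardize_fold(features[-i, , drop = FALSE],
                          features[i, , drop = FALSE])
    fit <- e1071::svm(f$train, tr_y,
                      kernel = if (spec$kernel == "rbf") "radial" else "linear",
                      cost = spec$C, gamma = spec$gamma, scale = FALSE,
                      tolerance = 1e-6)
    correct[i] <- predict(fit, f$test) == classes[i]
  }
  mean(correct)
}

#' Exhaustive grid search of C and gamma
#'
#' Evaluates [loo_accuracy()] on every point of `C_grid x gamma_grid` and
#' returns the maximizer; ties are broken toward smaller C, then smaller
#' gamma, so the result does not depend on grid ordering.
#'
#' @inheritParams loo_accuracy
#' @return list with `C`, `gamma`, `accuracy`.
#' @export
grid_search <- function(features, classes, spec = classifier_spec()) {
  gammas <- if (spec$kernel == "linear") spec$gamma_grid[1] else spec$gamma_grid
  best <- list(C = NA_real_, gamma = NA_real_, accuracy = -Inf)
  for (C in spec$C_grid) {
    for (g in gammas) {
      s <- spec; s$C <- C; s$gamma <- g
      acc <- loo_accuracy(features, classes, s)
      if (acc > best$accuracy + 1e-12)
        best <- list(C = C, gamma = g, accuracy = acc)
    }
  }
  best
}

# Parse "A->B" feature names into a seed/target table.
parse_edge_features <- function(feature_names) {
  parts <- strsplit(feature_names, "->", fixed = TRUE)
  if (any(lengths(parts) != 2))
    stop("feature names must be of the form 'seed->target'", call. = FALSE)
  data.frame(seed = vapply(parts, `[`, "", 1),
             target = vapply(parts, `[`, "", 2),
             stringsAsFactors = FALSE)
}

#' Delete all connectivity features incident to a node
#'
#' Removes every feature whose seed or target equals `node`; for a ten-node
#' network this takes the 90 ordered-pair features down to 72.
#'
#' @param features sessions x features matrix with `"seed->target"` column names.
#' @param node region label to delete.
#' @return the reduced feature matrix.
#' @export
node_deleted_features <- function(features, node) {
  edges <- parse_edge_features(colnames(features))
  if (!(node %in% edges$seed || node %in% edges$target))
    stop("unknown node: ", node, call. = FALSE)
  keep <- edges$seed != node & edges$target != node
  features[, keep, drop = FALSE]
}

#' Predicted impact on performance of deleting one node
#'
#' The reduction in leave-one-session-out prediction accuracy when all
#' connectivity features to/from `node` are removed, with the same
#' classifier specification for both fits.
#'
#' @inheritParams loo_accuracy
#' @param node region label to delete.
#' @param baseline optional precomputed full-pattern accuracy (saves refits
#'   when looping over nodes).
#' @return list with `node`, `baseline_accuracy`, `deleted_accuracy`, `impact`.
#' @export
predicted_impact <- function(features, classes, spec, node, baseline = NULL) {
  if (is.null(baseline)) baseline <- loo_accuracy(features, classes, spec)
  deleted <- loo_accuracy(node_deleted_features(features, node), classes, spec)
  list(node = node, baseline_accuracy = baseline, deleted_accuracy = deleted,
       impact = baseline - deleted)
}

#' Random-edge-deletion null for predicted impact
#'
#' Each null draw deletes `n_edges_deleted` features uniformly at random
#' (not constrained to a node), recomputes the leave-one-out accuracy, and
#' records the impact on the arcsine scale,
#' `asin(sqrt(a_full)) - asin(sqrt(a_deleted))`. A normal distribution is
#' fitted by mean and standard deviation; observed node impacts are tested
#' one-sided against its upper tail.
#'
#' @inheritParams loo_accuracy
#' @param n_edges_deleted features removed per draw (18 for a ten-node
#'   network's node deletion).
#' @param n_null number of null draws (>= 100; the reference analysis used
#'   100,000).
#' @param rng_seed integer seed.
#' @param baseline optional precomputed full-pattern accuracy.
#' @return list with `null_mean`, `null_sd` (arcsine scale), `null_impacts`,
#'   `n_null`, `rng_seed`, `baseline_accuracy`.
#' @export
impact_null <- function(features, classes, spec, n_edges_deleted = 18,
                        n_null = 1000, rng_seed = NULL, baseline = NULL) {
  if (n_null < 100) stop("`n_null` must be at least 100", call. = FALSE)
  features <- as.matrix(features)
  if (n_edges_deleted >= ncol(features))
    stop("`n_edges_deleted` must be smaller than the feature count",
         call. = FALSE)
  if (is.null(baseline)) baseline <- loo_accuracy(features, classes, spec)
  t_full <- arcsine_transform(baseline)
  null_impacts <- with_seed(rng_seed, vapply(seq_len(n_null), function(i) {
    drop_idx <- sample.int(ncol(features), n_edges_deleted)
    acc <- loo_accuracy(features[, -drop_idx, drop = FALSE], classes, spec)
    t_full - arcsine_transform(acc)
  }, numeric(1)))
  null_sd <- sd(null_impacts)
  if (null_sd == 0)
    stop("degenerate null: all random-deletion impacts identical; ",
         "increase `n_null`", call. = FALSE)
  list(null_mean = mean(null_impacts), null_sd = null_sd,
       null_impacts = null_impacts, n_null = n_null, rng_seed = rng_seed,
       baseline_accuracy = baseline)
}

#' Upper-tail p-value of an observed impact under the fitted null
#'
#' @param baseline_accuracy,deleted_accuracy accuracies in \[0, 1\].
#' @param null an [impact_null()] result.
#' @return one-sided p-value from the fitted normal on the arcsine scale.
#' @export
impact_p_value <- function(baseline_accuracy, deleted_accuracy, null) {
  obs <- arcsine_transform(baseline_accuracy) -
    arcsine_transform(deleted_accuracy)
  pnorm(obs, mean = null$null_mean, sd = null$null_sd, lower.tail = FALSE)
}

#' Full simulated-lesion report over all nodes
#'
#' Computes the baseline leave-one-out accuracy, the node-deleted accuracy
#' and predicted impact for every region, and the p-value of each impact
#' under the random-edge-deletion null.
#'
#' @inheritParams loo_accuracy
#' @param n_null null draws for [impact_null()].
#' @param rng_seed integer seed.
#' @param nodes nodes to delete (default: all regions in the feature names).
#' @return data.frame of class `lesion_impact` with one row per node:
#'   `node`, `baseline_accuracy`, `deleted_accuracy`, `impact`, `p_value`;
#'   attributes `null_mean`, `null_sd`, `n_null`, `rng_seed`.
#' @export
simulated_lesion <- function(features, classes, spec = classifier_spec(),
                             n_null = 1000, rng_seed = NULL, nodes = NULL) {
  features <- as.matrix(features)
  edges <- parse_edge_features(colnames(features))
  if (is.null(nodes)) nodes <- sort(unique(c(edges$seed, edges$target)))
  baseline <- loo_accuracy(features, classes, spec)
  n_del <- sum(edges$seed == nodes[1] | edges$target == nodes[1])
  null <- impact_null(features, classes, spec, n_edges_deleted = n_del,
                      n_null = n_null, rng_seed = rng_seed,
                      baseline = baseline)
  rows <- lapply(nodes, function(nd) {
    imp <- predicted_impact(features, classes, spec, nd, baseline = baseline)
    data.frame(node = nd, baseline_accuracy = imp$baseline_accuracy,
               deleted_accuracy = imp$deleted_accuracy, impact = imp$impact,
               p_value = impact_p_value(imp$baseline_accuracy,
                                        imp$deleted_accuracy, null),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "null_mean") <- null$null_mean
  attr(out, "null_sd") <- null$null_sd
  attr(out, "n_null") <- n_null
  attr(out, "rng_seed") <- rng_seed
  class(out) <- c("lesion_impact", "data.frame")
  out
}

#' Leave-one-out accuracy from activation features
#'
#' Identical cross-validation machinery applied to per-region activation
#' features (10 region means, or 90 when each region is partitioned into
#' nine parts); reported beside the connectivity accuracy as a baseline.
#'
#' @inheritParams loo_accuracy
#' @return fraction correct.
#' @export
activation_baseline <- function(features, classes, spec = classifier_spec()) {
  loo_accuracy(features, classes, spec)
}

#' Per-feature classification index
#'
#' Welch two-sample t statistic per feature contrasting high versus low
#' performance sessions, converted to z by CDF composition.
#'
#' @param features sessions x features matrix (high and low sessions only).
#' @param classes factor with levels including `high` and `low`.
#' @return data.frame with `feature`, `t`, `df`, `z`.
#' @export
classification_index <- function(features, classes) {
  features <- as.matrix(features)
  hi <- features[classes == "high", , drop = FALSE]
  lo <- features[classes == "low", , drop = FALSE]
  if (nrow(hi) < 2 || nrow(lo) < 2)
    stop("need at least 2 sessions per class", call. = FALSE)
  m1 <- colMeans(hi); m2 <- colMeans(lo)
  v1 <- apply(hi, 2, var) / nrow(hi)
  v2 <- apply(lo, 2, var) / nrow(lo)
  t <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (nrow(hi) - 1) + v2^2 / (nrow(lo) - 1))
  data.frame(feature = colnames(features), t = t,
             df = df, z = mapply(t_to_z, t, df), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Exact binomial test of a classification accuracy
#'
#' @param n_correct,n_total counts with `0 <= n_correct <= n_total`.
#' @param chance chance level in (0, 1).
#' @param sided `"one"` (upper tail) or `"two"`.
#' @return exact binomial p-value.
#' @export
binomial_accuracy_test <- function(n_correct, n_total, chance = 0.5,
                                   sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (n_correct < 0 || n_correct > n_total)
    stop("`n_correct` must lie in [0, n_total]", call. = FALSE)
  if (chance <= 0 || chance >= 1)
    stop("`chance` must lie in (0, 1)", call. = FALSE)
  if (sided == "one")
    pbinom(n_correct - 1, n_total, chance, lower.tail = FALSE)
  else
    binom.test(n_correct, n_total, p = chance)$p.value
}

#' Correlation of predicted impact with betweenness centrality
#'
#' @param impacts per-node predicted impacts (possibly pooled over cohorts).
#' @param centralities matching per-node betweenness values.
#' @return list with Pearson `r` and two-sided t-based `p`.
#' @export
correlate_impact_centrality <- function(impacts, centralities) {
  if (length(impacts) != length(centralities) || length(impacts) < 3)
    stop("need equal-length vectors of at least 3 values", call. = FALSE)
  if (sd(impacts) == 0 || sd(centralities) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  ct <- cor.test(impacts, centralities, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
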