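# Tertile labelling, SVM cross-validation, node deletion, impact null and
# the auxiliary statistics of the simulated-lesion analysis.

make_clouds <- function(n_per_class, n_features, separation, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * n_features), n_per_class),
             matrix(rnorm(n_per_class * n_features, mean = separation),
                    n_per_class))
  labels <- paste0(rep(c("R0", "R1"), 5), rep(1:5, each = 2))
  # edge-style feature names so node deletion can parse them
  pairs <- expand.grid(seed = paste0("N", 1:5), target = paste0("N", 1:5))
  pairs <- pairs[pairs$seed != pairs$target, ][seq_len(n_features), ]
  colnames(X) <- paste0(pairs$seed, "->", pairs$target)
  list(X = X, classes = factor(rep(c("low", "high"), each = n_per_class)))
}

test_that("sessions split into tertiles after omitting atypical ones", {
  perf <- c(0.9, 0.8, 0.7, 0.65, 0.6, 0.55)
  lab <- label_sessions(perf)
  expect_equal(as.character(lab$class),
               c("high", "high", "intermediate", "intermediate", "low", "low"))

  lab2 <- label_sessions(c(perf, 0.45))
  expect_equal(as.character(lab2$class[7]), "omitted")

  # 34 retained sessions -> floor(34/3) = 11 per extreme class
  set.seed(31)
  lab3 <- label_sessions(runif(34, 0.55, 0.95))
  expect_equal(sum(lab3$class == "high"), 11)
  expect_equal(sum(lab3$class == "low"), 11)
  expect_equal(sum(lab3$class == "intermediate"), 12)

  expect_error(label_sessions(c(0.9, 0.8, 0.7, 0.4, 0.3, 0.2, 0.1)),
               "too few sessions")
  expect_error(label_sessions(c(1.2, rep(0.8, 6))), "lie in")
})

test_that("RBF kernel evaluates exp(-gamma ||x-y||^2)", {
  expect_equal(rbf_kernel(c(1, 2), c(1, 2), gamma = 3), 1)
  expect_equal(rbf_kernel(0, 1, gamma = 1), exp(-1))
  expect_equal(rbf_kernel(c(0, 0), c(1, 1), gamma = 1e-9), 1, tolerance = 1e-6)
  expect_error(rbf_kernel(1:3, 1:2, 1), "lengths differ")
  expect_error(rbf_kernel(1, 2, 0), "gamma")
})

test_that("leave-one-out separates well-separated clouds and is deterministic", {
  d <- make_clouds(10, 12, separation = 5)
  spec <- classifier_spec(C = 10, gamma = 0.05)
  acc <- loo_accuracy(d$X, d$classes, spec)
  expect_equal(acc, 1.0)
  expect_equal(loo_accuracy(d$X, d$classes, spec), acc)

  # a one-class training fold is an error
  expect_error(loo_accuracy(d$X[c(1, 11, 12), ],
                            d$classes[c(1, 11, 12)], spec),
               "single class")
})

test_that("permuted labels give at-most-chance accuracy", {
  set.seed(32)
  d <- make_clouds(10, 12, separation = 5)
  spec <- classifier_spec(C = 1, gamma = 0.05)
  accs <- replicate(25, loo_accuracy(d$X, sample(d$classes), spec))
  # leave-one-out is pessimistically biased under random labels: the held-out
  # sample's class is always the training minority, so accuracy sits at or
  # below 0.5
  expect_lt(mean(accs), 0.55)
  expect_gt(mean(accs), 0.2)
})

test_that("grid search is exhaustive with deterministic tie-breaking", {
  d <- make_clouds(8, 10, separation = 4)
  one_point <- classifier_spec(C_grid = 2, gamma_grid = 0.1)
  res <- grid_search(d$X, d$classes, one_point)
  expect_equal(res$C, 2)
  expect_equal(res$gamma, 0.1)

  spec <- classifier_spec(C_grid = c(1, 100), gamma_grid = c(0.01, 0.1))
  r1 <- grid_search(d$X, d$classes, spec)
  spec_rev <- classifier_spec(C_grid = c(100, 1), gamma_grid = c(0.1, 0.01))
  r2 <- grid_search(d$X, d$classes, spec_rev)
  expect_equal(r1, r2)
  expect_equal(r1$accuracy, 1.0)
})

test_that("node deletion removes exactly the incident features", {
  labels <- sprintf("R%02d", 1:10)
  pairs <- expand.grid(seed = labels, target = labels,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$seed != pairs$target, ]
  X <- matrix(rnorm(4 * 90), 4, 90,
              dimnames = list(NULL, paste0(pairs$seed, "->", pairs$target)))
  del <- node_deleted_features(X, "R03")
  expect_equal(ncol(del), 72)
  expect_false(any(grepl("R03", colnames(del))))
  # a node with no remaining features is unknown to the deleted set
  expect_error(node_deleted_features(del, "R03"), "unknown node")
  # N = 3: 6 -> 2 features
  X3 <- X[, c("R01->R02", "R02->R01", "R01->R03", "R03->R01",
              "R02->R03", "R03->R02")]
  expect_equal(ncol(node_deleted_features(X3, "R03")), 2)
  # every feature is incident to exactly two nodes
  counts <- rowSums(vapply(labels, function(nd) {
    !colnames(X) %in% colnames(node_deleted_features(X, nd))
  }, logical(90)))
  expect_true(all(counts == 2))
  expect_error(node_deleted_features(X, "R99"), "unknown node")
})

test_that("impact null fits a normal on the arcsine scale", {
  expect_equal(arcsine_transform(0.5), pi / 4)
  expect_error(arcsine_transform(1.2), "0, 1")

  null <- list(null_mean = 0.1, null_sd = 0.05)
  # an impact at the null mean has p = 0.5
  a_full <- 0.8
  a_del <- sin(arcsine_transform(a_full) - 0.1)^2
  expect_equal(impact_p_value(a_full, a_del, null), 0.5)
  # mean + 1.645 sd -> p ~ 0.05
  a_del2 <- sin(arcsine_transform(a_full) - (0.1 + 1.645 * 0.05))^2
  expect_equal(impact_p_value(a_full, a_del2, null), 0.05, tolerance = 1e-3)
})

test_that("random-edge-deletion null yields calibrated impacts on noise", {
  set.seed(33)
  d <- make_clouds(8, 20, separation = 0)  # pure noise features
  spec <- classifier_spec(C = 1, gamma = 0.05)
  null <- impact_null(d$X, d$classes, spec, n_edges_deleted = 4,
                      n_null = 120, rng_seed = 9)
  expect_length(null$null_impacts, 120)
  expect_gt(null$null_sd, 0)
  # deleting uninformative features barely moves the accuracy
  expect_lt(abs(null$null_mean), 0.15)
})

test_that("classification index is an antisymmetric Welch t -> z transform", {
  set.seed(34)
  X <- matrix(rnorm(20 * 5), 20, 5,
              dimnames = list(NULL, paste0("F", 1:5)))
  X[11:20, 3] <- X[11:20, 3] + 5  # strong class difference on one feature
  cls <- factor(rep(c("low", "high"), each = 10))
  ci <- classification_index(X, cls)
  expect_gt(abs(ci$z[3]), 3)
  expect_lt(max(abs(ci$z[-3])), 3)
  swapped <- classification_index(X, factor(cls, levels = c("high", "low"),
                                            labels = c("low", "high")))
  expect_equal(swapped$z, -ci$z)
  expect_error(classification_index(X[1:3, ], factor(c("high", "low", "low"))),
               "at least 2")
})

test_that("binomial accuracy test matches exact tail sums", {
  expect_equal(binomial_accuracy_test(22, 22), 2^-22)
  # 20 of 22 one-sided: C(22,20)+C(22,21)+C(22,22) = 254 outcomes
  expect_equal(binomial_accuracy_test(20, 22), 254 / 2^22)
  expect_equal(binomial_accuracy_test(11, 22, sided = "two"), 1, tolerance = 0.01)
  expect_error(binomial_accuracy_test(23, 22), "n_total")
})

test_that("impact-centrality correlation behaves like Pearson r", {
  bc <- c(1, 3, 2, 5, 4, 7, 6, 9, 8, 10)
  res <- correlate_impact_centrality(2 * bc, bc)
  expect_equal(res$r, 1)
  expect_error(correlate_impact_centrality(rep(1, 5), 1:5), "zero variance")
  expect_error(correlate_impact_centrality(1:2, 1:2), "at least 3")
  set.seed(35)
  rs <- replicate(50, correlate_impact_centrality(rnorm(10), rnorm(10))$r)
  expect_lt(abs(mean(rs)), 0.15)
})
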