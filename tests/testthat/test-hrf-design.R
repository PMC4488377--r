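# Canonical HRF sampling and GLM design construction.

test_that("canonical HRF peaks near 6 s and is grid-consistent", {
  k <- canonical_hrf(2.5)
  expect_equal(max(k$hrf), 1)
  peak_time <- k$time[which.max(k$hrf)]
  expect_gte(peak_time, 5)
  expect_lte(peak_time, 7.5)

  # values on a coarse grid must agree with the fine grid at shared times
  fine <- canonical_hrf(0.5)
  shared <- match(k$time, fine$time)
  expect_equal(k$hrf, fine$hrf[shared], tolerance = 1e-9)
})

test_that("temporal derivative integrates to zero once the kernel covers the response", {
  # the derivative of a pulse that returns to baseline sums to ~0; use a
  # fine grid and a kernel long enough that the undershoot has decayed
  k <- canonical_hrf(0.1, hrf_model(kernel_length = 48))
  expect_lt(abs(sum(k$temporal_derivative) * 0.1), 1e-6 * max(k$hrf))
})

test_that("HRF model validates its parameters", {
  expect_error(hrf_model(peak_delay = -1), "positive")
  expect_error(hrf_model(kernel_length = 2), "kernel_length")
  expect_error(canonical_hrf(0), "tr")
})

test_that("a single impulse at t = 0 reproduces the sampled kernel", {
  ev <- event_table(0, 0, "MIDDLE", TRUE)
  X <- build_design_matrix(ev, tr = 2.5, n_timepoints = 40)
  k <- canonical_hrf(2.5 / 16)
  expected <- k$hrf[(seq_len(40) - 1) * 16 + 1]
  expected[is.na(expected)] <- 0  # volumes beyond the kernel support
  expect_equal(unname(X$columns[, "MIDDLE"]), expected, tolerance = 1e-10)
})

test_that("cosine high-pass column count follows floor(2L/cutoff) + 1", {
  X <- build_design_matrix(event_table(), tr = 2.5, n_timepoints = 120,
                           highpass_cutoff = 128)
  hp <- grep("^hpf_cos", X$names)
  expect_length(hp, floor(2 * 300 / 128) + 1)  # 5 for a 300 s run
  # with no events and no nuisance, the design is high-pass set + constant
  expect_equal(ncol(X$columns), length(hp) + 1)
  # high-pass columns are orthogonal to the constant
  expect_lt(max(abs(colSums(X$columns[, hp]))), 1e-8)
})

test_that("design construction rejects events beyond the scan", {
  ev <- event_table(400, 1, "MIDDLE", TRUE)
  expect_error(build_design_matrix(ev, 2.5, 120), "beyond scan end")
})

test_that("reaction-time modulation replaces the condition predictors", {
  ev <- event_table(c(0, 30, 60), c(1, 1, 1),
                    c("MIDDLE", "BOTH_END", "MIDDLE"), c(TRUE, TRUE, TRUE))
  X <- build_design_matrix(ev, 2.5, 60, rt_modulation = c(0.8, 1.4, 1.0))
  expect_true(all(c("task_main", "task_rt", "task_type") %in% X$names))
  expect_false("MIDDLE" %in% X$names)
  expect_error(build_design_matrix(ev, 2.5, 60, rt_modulation = c(1, 2)),
               "one value per")
})

test_that("OLS recovers exact coefficients and flags collinearity", {
  ev <- event_table(c(10, 50, 90), rep(2, 3), rep("MIDDLE", 3), rep(TRUE, 3))
  X <- build_design_matrix(ev, 2.5, 80)
  y <- 3 * X$columns[, "MIDDLE"]
  fit <- fit_glm(cbind(r1 = y), X)
  expect_equal(unname(fit$betas["MIDDLE", 1]), 3, tolerance = 1e-10)
  expect_equal(unname(fit$residual_variance), 0, tolerance = 1e-12)
  expect_equal(fit$dof, 80 - ncol(X$columns))

  # residuals orthogonal to every design column
  noise <- matrix(rnorm(80 * 2), 80)
  fit2 <- fit_glm(noise, X)
  ortho <- crossprod(X$columns, fit2$residuals)
  expect_lt(max(abs(ortho)) / max(abs(noise)), 1e-8)

  Xbad <- cbind(X$columns, dup = X$columns[, "MIDDLE"])
  expect_error(fit_glm(noise, Xbad), "collinear")
})

test_that("region permutation permutes betas identically", {
  set.seed(1)
  ev <- event_table(c(10, 60), c(2, 2), c("MIDDLE", "BOTH_END"), c(TRUE, TRUE))
  X <- build_design_matrix(ev, 2.5, 60)
  Y <- matrix(rnorm(60 * 4), 60, 4, dimnames = list(NULL, paste0("r", 1:4)))
  f1 <- fit_glm(Y, X)
  f2 <- fit_glm(Y[, c(3, 1, 4, 2)], X)
  expect_equal(unname(f2$betas), unname(f1$betas[, c(3, 1, 4, 2)]))
})

test_that("contrast statistics compose t and z correctly", {
  set.seed(2)
  ev <- event_table(c(10, 60), c(2, 2), c("MIDDLE", "BOTH_END"), c(TRUE, TRUE))
  X <- build_design_matrix(ev, 2.5, 60)
  Y <- matrix(rnorm(60 * 3), 60, 3)
  fit <- fit_glm(Y, X)
  expect_error(contrast_stat(fit, rep(0, length(fit$predictor_names))),
               "all zeros")
  cs <- contrast_stat(fit, make_contrast(fit, "MIDDLE", "BOTH_END"))
  # t = 0 maps to z = 0; the composition is monotone and clamped
  expect_equal(t_to_z(0, fit$dof), 0)
  expect_equal(t_to_z(1.984, 100), qnorm(pt(1.984, 100)), tolerance = 1e-9)
  expect_lt(abs(t_to_z(1.984, 100) - 1.96), 0.02)
  expect_equal(t_to_z(1e6, 10), 8.2)
  expect_true(all(is.finite(cs$z)))
})

test_that("contrast t follows the Student t distribution under pure noise", {
  set.seed(3)
  ev <- event_table(seq(10, 250, by = 30), rep(2, 9),
                    rep(c("MIDDLE", "BOTH_END"), length.out = 9),
                    rep(TRUE, 9))
  X <- build_design_matrix(ev, 2.5, 117)
  tvals <- replicate(20, {
    Y <- matrix(rnorm(117 * 10), 117)
    fit <- fit_glm(Y, X)
    contrast_stat(fit, make_contrast(fit, "MIDDLE", "BOTH_END"))$t
  })
  ks <- suppressWarnings(ks.test(as.numeric(tvals), pt,
                                 df = 117 - ncol(X$columns)))
  expect_gt(ks$p.value, 0.01)
})

test_that("homotopic peaks pair by mirrored nearest neighbour under 5 mm", {
  left <- data.frame(label = c("A", "B", "C"),
                     x = c(-12, -3, -20), y = c(14, 23, 0), z = c(15, 10, 0))
  right <- data.frame(label = c("A", "B", "D"),
                      x = c(12, 3, 20), y = c(16, 25, 10), z = c(15, 9, 0))
  pairs <- pair_homotopic_peaks(left, right)
  expect_equal(nrow(pairs), 2)
  expect_equal(pairs$distance[pairs$left_label == "A"], 2)
  expect_equal(pairs$distance[pairs$left_label == "B"], sqrt(5))
  # C-D at 10 mm is excluded by the threshold
  expect_false("C" %in% pairs$left_label)

  # pairing is symmetric in the hemisphere roles
  swapped <- pair_homotopic_peaks(right, left)
  expect_setequal(paste(pairs$left_label, pairs$right_label),
                  paste(swapped$right_label, swapped$left_label))

  expect_equal(nrow(pair_homotopic_peaks(left[0, ], right)), 0)
})
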