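# PPI construction: nuisance regression, deconvolution, interaction
# regressor, session estimation, group aggregation, FDR and symmetrization.

test_that("nuisance regression projects out covariates exactly", {
  set.seed(21)
  x <- rnorm(100)
  # constant only: mean centering
  expect_equal(regress_out_nuisance(x), x - mean(x))
  # a series equal to a covariate is annihilated
  nuis <- cbind(a = rnorm(100), b = rnorm(100))
  expect_lt(max(abs(regress_out_nuisance(nuis[, "a"], nuis))) /
              sd(nuis[, "a"]), 1e-10)
  # orthogonal series passes through (up to centering)
  q <- qr.Q(qr(cbind(1, nuis, rnorm(100))))
  ortho <- q[, 4]
  expect_equal(regress_out_nuisance(ortho, nuis), ortho - mean(ortho),
               tolerance = 1e-10)
  expect_error(regress_out_nuisance(x, cbind(nuis, nuis[, 1])), "collinear")
})

test_that("deconvolution inverts the HRF on smooth signals", {
  set.seed(22)
  tr <- 2.5
  n <- 200
  tt <- (seq_len(n) - 1) * tr
  neural <- sin(2 * pi * tt / 60) + 0.5 * cos(2 * pi * tt / 35)
  H <- hublesion:::hrf_convolution_operator(n, tr)
  bold <- drop(H %*% neural)
  rec <- deconvolve_neural(bold, tr, ridge = 1e-3)
  expect_gt(cor(rec, neural), 0.95)

  expect_equal(deconvolve_neural(numeric(50), tr), numeric(50))

  # heavy ridge flattens curvature (second differences shrink)
  r_small <- deconvolve_neural(bold, tr, ridge = 1e-3)
  r_big <- deconvolve_neural(bold, tr, ridge = 1e4)
  curv <- function(x) sum(diff(x, differences = 2)^2)
  expect_lt(curv(r_big), curv(r_small) / 100)
  expect_error(deconvolve_neural(bold, tr, ridge = -1), "non-negative")
})

test_that("the PPI regressor is bilinear in neural and psych", {
  set.seed(23)
  n <- 60
  neural <- rnorm(n)
  psych <- sample(c(-1, 0, 1), n, replace = TRUE)
  r <- build_ppi_regressor(neural, psych, 2.5)
  expect_length(r, n)
  expect_equal(build_ppi_regressor(neural, -psych, 2.5), -r)
  expect_equal(build_ppi_regressor(neural, numeric(n), 2.5), numeric(n))
  # constant neural with psych = +1 equals the HRF-convolved constant
  r1 <- build_ppi_regressor(rep(1, n), rep(1, n), 2.5)
  expect_equal(r1, convolve_kernel(rep(1, n), canonical_hrf(2.5)$hrf, dt = 2.5))
  expect_error(build_ppi_regressor(neural, psych[-1], 2.5), "lengths differ")
})

test_that("psych vector marks Choice periods of hits with +1/-1", {
  ev <- event_table(onset = c(10, 40, 70), duration = c(2, 2, 2),
                    condition = c("MIDDLE", "BOTH_END", "MIDDLE"),
                    correct = c(TRUE, TRUE, FALSE))
  p <- psych_vector(ev, tr = 2.5, n_timepoints = 40)
  expect_true(all(p %in% c(-1, 0, 1)))
  expect_gte(sum(p == 1), 1)   # the correct MIDDLE trial
  expect_gte(sum(p == -1), 1)  # the BOTH_END trial
  # the incorrect MIDDLE trial is excluded from the contrast
  p_all <- psych_vector(ev, 2.5, 40, correct_only = FALSE)
  expect_gt(sum(p_all == 1), sum(p == 1))
})

test_that("estimate_ppi rejects a seed equal to the target", {
  truth <- single_edge_truth()
  ev <- generate_task_events(rng_seed = 5)
  ts <- generate_session_timeseries(truth, ev, rng_seed = 6)
  sess <- list(session_id = "s", timeseries = ts, events = ev)
  expect_error(estimate_ppi(sess, "R01", "R01"), "must differ")
  est <- estimate_ppi(sess, "R01", "R02")
  expect_true(is.finite(est$beta))
})

test_that("group z aggregates session betas by one-sample t", {
  mk <- function(vals) {
    m <- matrix(0, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
    m[1, 2] <- vals[1]; m[2, 1] <- vals[2]
    out <- connectivity_matrix(m, kind = "ppi_beta_session")
    diag(out) <- NA
    out
  }
  betas <- list(mk(c(0.5, 0)), mk(c(1.0, 0)), mk(c(1.5, 0)))
  z <- group_ppi_matrix(betas)
  t_expected <- mean(c(0.5, 1, 1.5)) / (sd(c(0.5, 1, 1.5)) / sqrt(3))
  expect_equal(t_expected, 3.464, tolerance = 1e-3)
  expect_equal(z["A", "B"], t_to_z(t_expected, df = 2), tolerance = 1e-10)
  expect_equal(z["A", "B"], 1.786, tolerance = 2e-3)
  expect_equal(z["B", "A"], 0)

  # negating every beta negates every z
  nbetas <- lapply(betas, function(b) {
    out <- connectivity_matrix(-unclass(b), rownames(b),
                               kind = "ppi_beta_session")
    diag(out) <- NA
    out
  })
  zneg <- group_ppi_matrix(nbetas)
  off <- row(z) != col(z)
  expect_equal(unclass(zneg)[off], -unclass(z)[off])

  expect_error(group_ppi_matrix(betas[1:2]), "fewer than 3 sessions")
})

test_that("FDR thresholding matches brute-force Benjamini-Hochberg", {
  set.seed(24)
  for (i in 1:25) {
    m <- sample(3:10, 1)
    p <- runif(m)^sample(1:3, 1)
    q <- sample(c(0.01, 0.05, 0.1), 1)
    expect_equal(p.adjust(p, "BH") <= q, brute_force_bh(p, q))
  }
  # spec'd list: all three pass at q = .05
  expect_true(all(brute_force_bh(c(0.01, 0.02, 0.04), 0.05)))
  expect_true(brute_force_bh(0.04, 0.05))
  expect_false(any(brute_force_bh(rep(1, 10), 0.05)))
})

test_that("fdr_threshold returns the surviving edges as a binary matrix", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- 6; w[2, 3] <- 5.5; w[3, 4] <- 0.3
  m <- connectivity_matrix(w, kind = "ppi_z_group")
  res <- fdr_threshold(m, q = 0.05)
  expect_s3_class(res$binary, "connectivity_matrix")
  expect_equal(sum(unclass(res$binary)), 2)
  expect_setequal(paste(res$edges$seed, res$edges$target),
                  c("R01 R02", "R02 R03"))
  # all-null input yields an empty set
  res0 <- fdr_threshold(connectivity_matrix(matrix(0, 4, 4),
                                            kind = "ppi_z_group"))
  expect_equal(nrow(res0$edges), 0)
})

test_that("symmetrize produces the mean and max nondirectional variants", {
  w <- matrix(0, 3, 3); w[1, 2] <- 2; w[2, 1] <- 4
  m <- connectivity_matrix(w, kind = "ppi_z_group")
  s_mean <- symmetrize(m, "mean")
  s_max <- symmetrize(m, "max")
  expect_equal(s_mean[1, 2], 3); expect_equal(s_mean[2, 1], 3)
  expect_equal(s_max[1, 2], 4); expect_equal(s_max[2, 1], 4)
  # a symmetric matrix is a fixed point under both modes
  expect_equal(unclass(symmetrize(s_mean, "mean")), unclass(s_mean))
  expect_equal(unclass(symmetrize(s_mean, "max")), unclass(s_mean))
})
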