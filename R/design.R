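# GLM design construction and region-wise model fitting.
#
# Events are modelled at a microtime resolution (tr/16) as delta functions
# (zero-duration events) or boxcars, convolved with the canonical HRF and
# its temporal and dispersion derivatives, then sampled at the volume
# acquisition times. High-pass filtering is implemented as discrete-cosine
# regressors inside the design so degrees-of-freedom bookkeeping stays exact.

MICROTIME_BINS <- 16L

# Discrete-cosine high-pass basis: the first `n_cos` DCT-II vectors after
# the constant. Number of columns follows floor(2 * L / cutoff) + 1 where
# L is the run length in seconds.
dct_highpass_basis <- function(n_timepoints, tr, cutoff) {
  if (cutoff <= 2 * tr)
    stop("`highpass_cutoff` must exceed 2 * tr", call. = FALSE)
  L <- n_timepoints * tr
  n_cos <- floor(2 * L / cutoff) + 1
  n <- seq_len(n_timepoints) - 1
  basis <- vapply(seq_len(n_cos), function(k) {
    sqrt(2 / n_timepoints) * cos(pi * (2 * n + 1) * k / (2 * n_timepoints))
  }, numeric(n_timepoints))
  colnames(basis) <- sprintf("hpf_cos%02d", seq_len(n_cos))
  basis
}

# Stimulus function on the microtime grid: unit-area impulse for
# zero-duration events, unit-height boxcar otherwise.
stimulus_function <- function(onset, duration, amplitude, dt, n_micro) {
  u <- numeric(n_micro)
  for (i in seq_along(onset)) {
    if (duration[i] == 0) {
      j <- floor(onset[i] / dt) + 1L
      if (j <= n_micro) u[j] <- u[j] + amplitude[i] / dt
    } else {
      j0 <- floor(onset[i] / dt) + 1L
      j1 <- min(ceiling((onset[i] + duration[i]) / dt), n_micro)
      if (j0 <= n_micro) u[j0:j1] <- u[j0:j1] + amplitude[i]
    }
  }
  u
}

# Convolve a microtime stimulus function with a kernel sampled at dt and
# read off the values at the volume acquisition times.
convolve_and_sample <- function(u, kernel, dt, n_timepoints) {
  conv <- convolve_kernel(u, kernel, dt = dt)
  conv[(seq_len(n_timepoints) - 1L) * MICROTIME_BINS + 1L]
}

#' Build a GLM design matrix from trial events
#'
#' One predictor set per condition present in `events`: the stimulus
#' function (delta for zero-duration events, boxcar otherwise) convolved
#' with the canonical HRF and its temporal and dispersion derivatives.
#' Nuisance covariates, a discrete-cosine high-pass set for frequencies
#' below `1/highpass_cutoff`, and a constant complete the design.
#'
#' When `rt_modulation` is supplied, the MIDDLE and BOTH_END predictors are
#' replaced by the three-predictor parametric scheme: a main effect over
#' both trial types, a mean-centered reaction-time modulator, and a
#' trial-type code (+1 MIDDLE, -1 BOTH_END), each convolved with the
#' canonical HRF.
#'
#' @param events an [event_table()].
#' @param tr sampling interval (s).
#' @param n_timepoints number of volumes.
#' @param hrf an [hrf_model()].
#' @param nuisance optional timepoints x covariates matrix.
#' @param highpass_cutoff high-pass cutoff period (s); must exceed `2 * tr`.
#' @param rt_modulation optional reaction times (s), one per MIDDLE or
#'   BOTH_END event in chronological order.
#' @return an object of class `design_matrix`: list with `columns` (matrix),
#'   `names`, `confound_flags`, `tr`.
#' @export
build_design_matrix <- function(events, tr, n_timepoints, hrf = hrf_model(),
                                nuisance = NULL, highpass_cutoff = 128,
                                rt_modulation = NULL) {
  validate_event_table(events)
  L <- n_timepoints * tr
  if (nrow(events) && any(events$onset >= L))
    stop("events beyond scan end (", L, " s)", call. = FALSE)

  dt <- tr / MICROTIME_BINS
  n_micro <- n_timepoints * MICROTIME_BINS
  kern <- canonical_hrf(dt, hrf)

  cols <- list()
  flags <- logical()

  rt_conditions <- character()
  if (!is.null(rt_modulation)) {
    rt_conditions <- c("MIDDLE", "BOTH_END")
    ev <- events[events$condition %in% rt_conditions, , drop = FALSE]
    if (length(rt_modulation) != nrow(ev))
      stop("`rt_modulation` must have one value per MIDDLE/BOTH_END event",
           call. = FALSE)
    code <- ifelse(ev$condition == "MIDDLE", 1, -1)
    amp <- list(task_main = rep(1, nrow(ev)),
                task_rt = rt_modulation - mean(rt_modulation),
                task_type = code)
    for (nm in names(amp)) {
      u <- stimulus_function(ev$onset, ev$duration, amp[[nm]], dt, n_micro)
      cols[[nm]] <- convolve_and_sample(u, kern$hrf, dt, n_timepoints)
      flags <- c(flags, FALSE)
    }
  }

  for (cond in intersect(CONDITIONS, unique(events$condition))) {
    if (cond %in% rt_conditions) next
    ev <- events[events$condition == cond, , drop = FALSE]
    u <- stimulus_function(ev$onset, ev$duration, rep(1, nrow(ev)), dt, n_micro)
    cols[[cond]] <- convolve_and_sample(u, kern$hrf, dt, n_timepoints)
    cols[[paste0(cond, "_td")]] <-
      convolve_and_sample(u, kern$temporal_derivative, dt, n_timepoints)
    cols[[paste0(cond, "_dd")]] <-
      convolve_and_sample(u, kern$dispersion_derivative, dt, n_timepoints)
    flags <- c(flags, FALSE, FALSE, FALSE)
  }

  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != n_timepoints)
      stop("nuisance row count must equal `n_timepoints`", call. = FALSE)
    if (is.null(colnames(nuisance)))
      colnames(nuisance) <- sprintf("nuisance%d", seq_len(ncol(nuisance)))
    for (j in seq_len(ncol(nuisance))) {
      cols[[colnames(nuisance)[j]]] <- nuisance[, j]
      flags <- c(flags, TRUE)
    }
  }

  hp <- dct_highpass_basis(n_timepoints, tr, highpass_cutoff)
  for (j in seq_len(ncol(hp))) {
    cols[[colnames(hp)[j]]] <- hp[, j]
    flags <- c(flags, TRUE)
  }
  cols[["constant"]] <- rep(1, n_timepoints)
  flags <- c(flags, TRUE)

  X <- do.call(cbind, cols)
  nms <- names(cols)
  if (anyDuplicated(nms))
    stop("duplicate predictor names in design", call. = FALSE)
  colnames(X) <- nms
  structure(list(columns = X, names = nms, confound_flags = flags, tr = tr),
            class = "design_matrix")
}

#' Fit region-wise ordinary least squares
#'
#' @param ts a [session_timeseries()] (or a plain timepoints x regions matrix).
#' @param X a `design_matrix` (or a plain matrix).
#' @return an object of class `glm_fit` with per-region `betas`,
#'   `residual_variance`, `dof` (timepoints minus design rank), plus the
#'   cross-product inverse needed by [contrast_stat()].
#' @export
fit_glm <- function(ts, X) {
  Y <- if (inherits(ts, "session_timeseries")) ts$values else as.matrix(ts)
  Xm <- if (inherits(X, "design_matrix")) X$columns else as.matrix(X)
  if (nrow(Y) != nrow(Xm))
    stop("time series and design have different numbers of timepoints",
         call. = FALSE)
  qrx <- qr(Xm)
  if (qrx$rank < ncol(Xm)) {
    dropped <- colnames(Xm)[qrx$pivot[(qrx$rank + 1):ncol(Xm)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  betas <- qr.coef(qrx, Y)
  res <- Y - Xm %*% betas
  dof <- nrow(Y) - qrx$rank
  if (dof <= 0) stop("no residual degrees of freedom", call. = FALSE)
  rss <- colSums(res^2)
  xtx_inv <- chol2inv(qr.R(qrx))[order(qrx$pivot), order(qrx$pivot), drop = FALSE]
  structure(list(betas = betas, residual_variance = rss / dof, dof = dof,
                 xtx_inv = xtx_inv, predictor_names = colnames(Xm),
                 residuals = res),
            class = "glm_fit")
}

#' Contrast t and z statistics from a GLM fit
#'
#' `t = c'beta / se(c'beta)`; z is obtained by CDF composition through the
#' Student t distribution, clamped at |z| = 8.2.
#'
#' @param fit a `glm_fit`.
#' @param contrast numeric contrast vector over predictors.
#' @return data.frame with per-region `estimate`, `t`, `z`.
#' @export
contrast_stat <- function(fit, contrast) {
  stopifnot(inherits(fit, "glm_fit"))
  if (length(contrast) != nrow(fit$betas))
    stop("contrast length must equal the number of predictors", call. = FALSE)
  if (all(contrast == 0))
    stop("contrast vector is all zeros", call. = FALSE)
  cvar <- drop(t(contrast) %*% fit$xtx_inv %*% contrast)
  if (cvar <= 0) stop("contrast has zero design variance", call. = FALSE)
  est <- drop(crossprod(contrast, fit$betas))
  se <- sqrt(fit$residual_variance * cvar)
  if (any(se == 0 & est != 0)) {
    t <- ifelse(se == 0, sign(est) * Inf, est / se)
  } else {
    t <- ifelse(se == 0, 0, est / se)
  }
  regions <- colnames(fit$betas) %||%
    sprintf("Y%02d", seq_len(ncol(fit$betas)))
  data.frame(region = regions, estimate = est, t = t,
             z = t_to_z(t, fit$dof), row.names = NULL,
             stringsAsFactors = FALSE)
}

# Contrast vector with +1 / -1 on named predictors, 0 elsewhere.
make_contrast <- function(fit, plus, minus = character()) {
  v <- numeric(length(fit$predictor_names))
  names(v) <- fit$predictor_names
  v[plus] <- 1
  v[minus] <- -1
  v
}

#' Pair homotopic activation peaks across hemispheres
#'
#' Left-hemisphere peaks (negative x) are mirrored by flipping the sign of
#' their x coordinate; each left peak is then greedily matched to its
#' nearest right-hemisphere peak (globally closest pair first, each right
#' peak used at most once). Pairs at or beyond `max_dist` are discarded.
#'
#' @param left,right data.frames with columns `label`, `x`, `y`, `z`.
#' @param max_dist maximum pairing distance (mm).
#' @return data.frame with `left_label`, `right_label`, `distance`.
#' @export
pair_homotopic_peaks <- function(left, right, max_dist = 5) {
  empty <- data.frame(left_label = character(), right_label = character(),
                      distance = numeric(), stringsAsFactors = FALSE)
  if (!nrow(left) || !nrow(right)) return(empty)
  lx <- abs(left$x)
  rx <- abs(right$x)
  d <- outer(seq_len(nrow(left)), seq_len(nrow(right)),
             function(i, j) sqrt((lx[i] - rx[j])^2 +
                                 (left$y[i] - right$y[j])^2 +
                                 (left$z[i] - right$z[j])^2))
  out <- empty
  while (length(d) && any(is.finite(d)) && min(d, na.rm = TRUE) < max_dist) {
    ij <- which(d == min(d, na.rm = TRUE), arr.ind = TRUE)[1, ]
    out <- rbind(out, data.frame(left_label = left$label[ij[1]],
                                 right_label = right$label[ij[2]],
                                 distance = d[ij[1], ij[2]],
                                 stringsAsFactors = FALSE))
    d[ij[1], ] <- Inf
    d[, ij[2]] <- Inf
  }
  out[order(out$left_label), , drop = FALSE]
}
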