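# Psychophysiological interaction (PPI) estimation.
#
# For a seed region the BOLD "physiological" series is corrected for
# nuisance variance, deconvolved to the neural scale with a ridge-penalized
# least-squares inversion of the HRF convolution, multiplied by the
# psychological contrast (+1 MIDDLE, -1 BOTH_END, hits only), and
# reconvolved with the HRF to form the PPI predictor. The PPI beta of a
# target region is its regression weight alongside the physiological and
# psychological predictors, nuisance covariates, high-pass set and constant.

#' Psychological contrast vector
#'
#' +1 during the Choice period of condition-A trials, -1 during condition-B
#' Choice periods, 0 elsewhere, sampled on the volume grid. A volume is
#' marked if its acquisition bin `[t, t + tr)` overlaps the Choice period,
#' so short Choice periods are never lost between volumes. By default only
#' correct (hit) trials contribute.
#'
#' @param events an [event_table()].
#' @param tr sampling interval (s).
#' @param n_timepoints number of volumes.
#' @param positive,negative condition names coded +1 / -1.
#' @param correct_only restrict to hits.
#' @return integer vector in \{-1, 0, +1\}.
#' @export
psych_vector <- function(events, tr, n_timepoints,
                         positive = "MIDDLE", negative = "BOTH_END",
                         correct_only = TRUE) {
  validate_event_table(events)
  mark <- function(cond) {
    ev <- events[events$condition == cond, , drop = FALSE]
    if (correct_only) ev <- ev[ev$correct %in% TRUE, , drop = FALSE]
    v <- numeric(n_timepoints)
    t0 <- (seq_len(n_timepoints) - 1) * tr
    for (i in seq_len(nrow(ev)))
      v[t0 < ev$onset[i] + ev$duration[i] & (t0 + tr) > ev$onset[i]] <- 1
    v
  }
  p <- mark(positive) - mark(negative)
  sign(p)
}

#' Remove nuisance variance from a time series
#'
#' Residual of the OLS regression of `x` on the nuisance covariates plus a
#' constant. With no covariates this reduces to mean centering.
#'
#' @param x numeric vector.
#' @param nuisance timepoints x covariates matrix, or NULL.
#' @return corrected vector.
#' @export
regress_out_nuisance <- function(x, nuisance = NULL) {
  X <- cbind(constant = rep(1, length(x)),
             if (!is.null(nuisance)) as.matrix(nuisance))
  if (nrow(X) != length(x))
    stop("nuisance and series lengths differ", call. = FALSE)
  qrx <- qr(X)
  if (qrx$rank < ncol(X))
    stop("nuisance covariates are collinear", call. = FALSE)
  drop(qr.resid(qrx, x))
}

#' Deconvolve a BOLD series to the neural scale
#'
#' Ridge-penalized least squares: minimizes
#' `||H n - bold||^2 + lambda ||D n||^2` where `H` is the causal HRF
#' convolution operator on the acquisition grid and `D` the second-difference
#' roughness penalty; `lambda = ridge * mean(diag(H'H))` so the penalty is
#' trace-normalized against the operator's scale.
#'
#' @param bold numeric vector.
#' @param tr sampling interval (s).
#' @param hrf an [hrf_model()].
#' @param ridge non-negative roughness weight (default 1e-2).
#' @return neural-scale vector, same length as `bold`.
#' @export
deconvolve_neural <- function(bold, tr, hrf = hrf_model(), ridge = 1e-2) {
  if (ridge < 0) stop("`ridge` must be non-negative", call. = FALSE)
  n <- length(bold)
  if (all(bold == 0)) return(numeric(n))
  H <- hrf_convolution_operator(n, tr, hrf)
  D <- diff(diag(n), differences = 2)
  HtH <- crossprod(H)
  lambda <- ridge * mean(diag(HtH))
  solve(HtH + lambda * crossprod(D), crossprod(H, bold))[, 1]
}

# Lower-triangular Toeplitz convolution operator of the canonical HRF
# sampled at tr (dt-scaled so H n approximates the continuous convolution).
hrf_convolution_operator <- function(n, tr, hrf = hrf_model()) {
  k <- canonical_hrf(tr, hrf)$hrf * tr
  H <- matrix(0, n, n)
  for (j in seq_len(n)) {
    len <- min(length(k), n - j + 1)
    H[j:(j + len - 1), j] <- k[seq_len(len)]
  }
  H
}

#' Build the PPI regressor
#'
#' Elementwise product of the neural-scale seed signal and the psychological
#' contrast, reconvolved with the canonical HRF and truncated to the scan
#' length.
#'
#' @param neural neural-scale vector (from [deconvolve_neural()]).
#' @param psych psychological contrast (from [psych_vector()]).
#' @param tr sampling interval (s).
#' @param hrf an [hrf_model()].
#' @return regressor vector.
#' @export
build_ppi_regressor <- function(neural, psych, tr, hrf = hrf_model()) {
  if (length(neural) != length(psych))
    stop("`neural` and `psych` lengths differ", call. = FALSE)
  k <- canonical_hrf(tr, hrf)$hrf
  convolve_kernel(neural * psych, k, dt = tr)
}

# Shared per-session PPI context: psych contrast, its convolution, the
# high-pass set and nuisance covariates.
ppi_context <- function(session, hrf, highpass_cutoff,
                        positive = "MIDDLE", negative = "BOTH_END") {
  ts <- session$timeseries
  n <- nrow(ts$values)
  psych <- psych_vector(session$events, ts$tr, n, positive, negative)
  if (!any(psych == 1) || !any(psych == -1))
    stop("psychological contrast is degenerate: a condition has no hits",
         call. = FALSE)
  k <- canonical_hrf(ts$tr, hrf)$hrf
  list(ts = ts, psych = psych,
       psych_conv = convolve_kernel(psych, k, dt = ts$tr),
       hp = dct_highpass_basis(n, ts$tr, highpass_cutoff),
       nuisance = ts$nuisance)
}

ppi_design_for_seed <- function(ctx, seed_label, hrf, ridge) {
  phys <- ctx$ts$values[, seed_label]
  corrected <- regress_out_nuisance(phys, ctx$nuisance)
  neural <- deconvolve_neural(corrected, ctx$ts$tr, hrf, ridge)
  ppi <- build_ppi_regressor(neural, ctx$psych, ctx$ts$tr, hrf)
  X <- cbind(ppi = ppi, phys = phys, psych = ctx$psych_conv,
             ctx$nuisance, ctx$hp, constant = 1)
  qrx <- qr(X)
  if (qrx$rank < ncol(X))
    stop("collinear PPI design for seed ", seed_label, call. = FALSE)
  qrx
}

#' Estimate a single directed PPI
#'
#' @param session a `session_record` (list with `timeseries` and `events`).
#' @param seed,target region labels (or indices); must differ.
#' @param hrf an [hrf_model()].
#' @param ridge deconvolution roughness weight.
#' @param highpass_cutoff high-pass cutoff (s).
#' @return list with `session_id`, `seed`, `target`, `beta` (the PPI
#'   predictor's regression weight).
#' @export
estimate_ppi <- function(session, seed, target, hrf = hrf_model(),
                         ridge = 1e-2, highpass_cutoff = 128) {
  labels <- session$timeseries$region_labels
  if (is.numeric(seed)) seed <- labels[seed]
  if (is.numeric(target)) target <- labels[target]
  if (identical(seed, target))
    stop("`seed` and `target` must differ", call. = FALSE)
  ctx <- ppi_context(session, hrf, highpass_cutoff)
  qrx <- ppi_design_for_seed(ctx, seed, hrf, ridge)
  beta <- qr.coef(qrx, ctx$ts$values[, target])[["ppi"]]
  list(session_id = session$session_id, seed = seed, target = target,
       beta = beta)
}

#' Session-level PPI beta matrix over all ordered region pairs
#'
#' @param session a `session_record`.
#' @inheritParams estimate_ppi
#' @return a [connectivity_matrix()] of kind `ppi_beta_session`; entry
#'   `[A, B]` is the PPI beta from seed A to target B, diagonal NA.
#' @export
session_ppi_matrix <- function(session, hrf = hrf_model(), ridge = 1e-2,
                               highpass_cutoff = 128) {
  ctx <- ppi_context(session, hrf, highpass_cutoff)
  labels <- ctx$ts$region_labels
  R <- length(labels)
  w <- matrix(NA_real_, R, R, dimnames = list(labels, labels))
  for (a in seq_len(R)) {
    qrx <- ppi_design_for_seed(ctx, labels[a], hrf, ridge)
    betas <- qr.coef(qrx, ctx$ts$values[, -a, drop = FALSE])
    w[a, -a] <- betas["ppi", ]
  }
  diag(w) <- 0
  out <- connectivity_matrix(w, labels, kind = "ppi_beta_session")
  diag(out) <- NA_real_
  out
}

#' Group z-matrix from per-session PPI betas
#'
#' Per ordered pair, a one-sample t statistic of the session betas against
#' zero, converted to z by CDF composition (clamped at |z| = 8.2).
#'
#' @param betas list of `ppi_beta_session` matrices with identical labels.
#' @return a [connectivity_matrix()] of kind `ppi_z_group`.
#' @export
group_ppi_matrix <- function(betas) {
  if (!length(betas)) stop("no sessions supplied", call. = FALSE)
  labels <- rownames(betas[[1]])
  arr <- simplify2array(lapply(betas, unclass))
  n <- apply(!is.na(arr), c(1, 2), sum)
  off <- row(n) != col(n)
  if (any(n[off] < 3)) {
    bad <- which(n < 3 & off, arr.ind = TRUE)[1, ]
    stop("fewer than 3 sessions for pair ", labels[bad[1]], " -> ",
         labels[bad[2]], call. = FALSE)
  }
  m <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  s <- apply(arr, c(1, 2), sd, na.rm = TRUE)
  t <- matrix(NA_real_, nrow(m), ncol(m))
  pos <- off & s > 0
  t[pos] <- m[pos] / (s[pos] / sqrt(n[pos]))
  deg <- off & s == 0
  t[deg] <- ifelse(m[deg] == 0, 0, sign(m[deg]) * Inf)
  z <- matrix(t_to_z(t, df = n[1, 2] - 1), nrow(t), ncol(t))
  diag(z) <- NA_real_
  out <- connectivity_matrix(ifelse(is.na(z), 0, z), labels,
                             kind = "ppi_z_group")
  diag(out) <- NA_real_
  out
}

#' FDR-threshold a group z-matrix
#'
#' Benjamini-Hochberg over the N(N-1) off-diagonal p-values, one-sided on
#' positive z by default (the contrast tests connectivity increases).
#'
#' @param matrix a `ppi_z_group` [connectivity_matrix()].
#' @param q FDR level in (0, 1).
#' @param sided `"one"` (default) or `"two"`.
#' @return list with `binary` (a `binarized_ppi` matrix) and `edges`
#'   (data.frame of surviving seed/target pairs with z, p, p_adjusted).
#' @export
fdr_threshold <- function(matrix, q = 0.05, sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (q <= 0 || q >= 1) stop("`q` must lie in (0, 1)", call. = FALSE)
  labels <- rownames(matrix)
  off <- which(row(matrix) != col(matrix))
  z <- unclass(matrix)[off]
  p <- if (sided == "one") pnorm(z, lower.tail = FALSE)
       else 2 * pnorm(abs(z), lower.tail = FALSE)
  p_adj <- p.adjust(p, method = "BH")
  keep <- p_adj <= q
  bin <- matrix(0, nrow(matrix), ncol(matrix))
  bin[off[keep]] <- 1
  idx <- arrayInd(off[keep], dim(matrix))
  edges <- data.frame(seed = labels[idx[, 1]], target = labels[idx[, 2]],
                      z = z[keep], p = p[keep], p_adjusted = p_adj[keep],
                      stringsAsFactors = FALSE)
  list(binary = connectivity_matrix(bin, labels, kind = "binarized_ppi"),
       edges = edges[order(edges$p), , drop = FALSE])
}

#' Symmetrize a directed connectivity matrix
#'
#' Nondirectional variant: the weight between A and B becomes the mean (or
#' the larger) of the two directed entries.
#'
#' @param matrix a [connectivity_matrix()].
#' @param mode `"mean"` or `"max"`.
#' @return a [connectivity_matrix()] of kind `nondirectional`.
#' @export
symmetrize <- function(matrix, mode = c("mean", "max")) {
  mode <- match.arg(mode)
  w <- unclass(matrix)
  s <- if (mode == "mean") (w + t(w)) / 2 else pmax(w, t(w))
  connectivity_matrix(s, rownames(matrix), kind = "nondirectional")
}
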