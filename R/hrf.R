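#' Canonical hemodynamic response model
#'
#' Parameters of the canonical double-gamma hemodynamic response function
#' (HRF) in the convention popularized by SPM: a positive gamma density
#' peaking around 6 s minus a scaled gamma density modelling the
#' post-stimulus undershoot around 16 s.
#'
#' @param peak_delay delay of the response peak (s).
#' @param undershoot_delay delay of the undershoot (s).
#' @param peak_dispersion dispersion of the response gamma (s).
#' @param undershoot_dispersion dispersion of the undershoot gamma (s).
#' @param undershoot_ratio ratio of undershoot to peak amplitude.
#' @param kernel_length length of the sampled kernel (s).
#' @return an object of class `hrf_model`.
#' @export
hrf_model <- function(peak_delay = 6, undershoot_delay = 16,
                      peak_dispersion = 1, undershoot_dispersion = 1,
                      undershoot_ratio = 1 / 6, kernel_length = 32) {
  if (peak_delay <= 0 || undershoot_delay <= 0 ||
      peak_dispersion <= 0 || undershoot_dispersion <= 0)
    stop("HRF delays and dispersions must be positive", call. = FALSE)
  if (kernel_length < peak_delay)
    stop("`kernel_length` must be at least `peak_delay`", call. = FALSE)
  structure(list(peak_delay = peak_delay,
                 undershoot_delay = undershoot_delay,
                 peak_dispersion = peak_dispersion,
                 undershoot_dispersion = undershoot_dispersion,
                 undershoot_ratio = undershoot_ratio,
                 kernel_length = kernel_length),
            class = "hrf_model")
}

# Closed-form double gamma evaluated at times t (seconds), unscaled.
double_gamma <- function(t, model) {
  stats::dgamma(t, shape = model$peak_delay / model$peak_dispersion,
                scale = model$peak_dispersion) -
    model$undershoot_ratio *
      stats::dgamma(t, shape = model$undershoot_delay / model$undershoot_dispersion,
                    scale = model$undershoot_dispersion)
}

#' Sample the canonical HRF and its derivatives
#'
#' Returns the canonical double-gamma HRF sampled on the acquisition grid,
#' together with its temporal derivative (finite difference with respect to
#' an onset shift) and dispersion derivative (finite difference with respect
#' to the peak dispersion). The HRF is scaled to unit peak; both derivatives
#' are scaled by the same factor so the triple stays mutually comparable.
#'
#' @param tr sampling interval (s).
#' @param model an [hrf_model()].
#' @param dt_shift onset shift used for the temporal derivative (s).
#' @param dd_shift dispersion increment used for the dispersion derivative (s).
#' @return list with elements `time`, `hrf`, `temporal_derivative`,
#'   `dispersion_derivative`.
#' @export
canonical_hrf <- function(tr, model = hrf_model(), dt_shift = 0.1,
                          dd_shift = 0.01) {
  if (tr <= 0) stop("`tr` must be positive", call. = FALSE)
  tt <- seq(0, model$kernel_length, by = tr)
  h <- double_gamma(tt, model)
  scale <- max(h)
  if (scale <= 0) stop("degenerate HRF: non-positive peak", call. = FALSE)
  shifted <- double_gamma(pmax(tt - dt_shift, 0), model)
  td <- (h - shifted) / dt_shift
  m2 <- model
  m2$peak_dispersion <- model$peak_dispersion + dd_shift
  dd <- (h - double_gamma(tt, m2)) / dd_shift
  list(time = tt, hrf = h / scale,
       temporal_derivative = td / scale,
       dispersion_derivative = dd / scale)
}

# Causal discrete convolution of a signal with a sampled kernel, truncated
# to the signal length. `dt` scales the sum into an integral approximation.
convolve_kernel <- function(x, kernel, dt = 1) {
  n <- length(x)
  out <- convolve(x, rev(kernel), type = "open")[seq_len(n)]
  out * dt
}
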