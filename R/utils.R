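#' @useDynLib hublesion, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pt pnorm qnorm rnorm runif convolve lm.fit sd t.test
#'   p.adjust pbinom binom.test cor.test var plogis qlogis
NULL

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched. seed = NULL means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`rng_seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stage-specific seed from a global seed
#'
#' Every stochastic stage of the pipeline draws its seed deterministically
#' from the single configured seed and the stage name, so that a whole run
#' is reproducible from one integer while stages remain decoupled.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return a single integer below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 10007 + h * 97) %% 2147483629)
}

# Convert a t statistic to a standard-normal deviate by CDF composition,
# computed through log tail probabilities so large |t| stays finite, then
# clamped to +/- 8.2 (the usual neuroimaging convention; keeps 1/z finite).
t_to_z <- function(t, df, clamp = 8.2) {
  stopifnot(df > 0)
  z <- numeric(length(t))
  pos <- !is.na(t) & t >= 0
  # upper-tail composition for positive t, mirrored for negative
  z[pos] <- qnorm(pt(t[pos], df, lower.tail = FALSE, log.p = TRUE),
                  lower.tail = FALSE, log.p = TRUE)
  z[!pos] <- -qnorm(pt(-t[!pos], df, lower.tail = FALSE, log.p = TRUE),
                    lower.tail = FALSE, log.p = TRUE)
  z[is.na(t)] <- NA_real_
  pmin(pmax(z, -clamp), clamp)
}

#' Variance-stabilizing arcsine transform of an accuracy
#'
#' @param a accuracy in \[0, 1\].
#' @return arcsin(sqrt(a)), in radians.
#' @export
arcsine_transform <- function(a) {
  if (any(a < 0 | a > 1, na.rm = TRUE))
    stop("accuracy must lie in [0, 1]", call. = FALSE)
  asin(sqrt(a))
}
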