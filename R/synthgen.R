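# Synthetic task designs, BOLD time series with planted condition-dependent
# coupling, and session cohorts with performance-linked class structure.
#
# The forward model mirrors the analysis it feeds: neural activity per
# region is an activation boxcar plus instantaneous linear mixing from the
# other regions, where the mixing gains shift additively while the MIDDLE
# Choice period of a correct trial is active. The neural signals are
# convolved with the canonical HRF, sampled at the TR, and corrupted with
# AR(1) Gaussian noise. Recovering the additive gain shift is exactly what
# the PPI stage is asked to do.

#' Ground truth for a synthetic cohort
#'
#' @param n_regions number of regions (>= 2).
#' @param baseline_coupling N x N condition-independent directed neural
#'   coupling (zero diagonal).
#' @param coupling_modulation N x N additive coupling active only during the
#'   MIDDLE Choice period of correct trials; this is the PPI ground truth.
#' @param planted_hub region index whose incident modulation carries the
#'   class signal, or NULL.
#' @param activation_amplitudes conditions x regions matrix of boxcar
#'   amplitudes (rownames are condition names).
#' @param noise_ar1 AR(1) coefficient of the additive BOLD noise, in \[0, 1).
#' @param noise_sd marginal standard deviation of the AR(1) noise.
#' @param neural_noise_sd marginal standard deviation of region-specific
#'   ongoing neural fluctuations injected before the coupling mixes
#'   regions (scalar, or one value per region). These fluctuations are
#'   what makes directed coupling identifiable: the target inherits the
#'   seed's idiosyncratic activity only while the coupling is active.
#' @param neural_noise_tau time constant of those fluctuations (s); slow
#'   enough to survive hemodynamic smoothing.
#' @param hub_saturation saturation level of the hub's activity (signal
#'   units), or NULL for purely linear mixing. When set, the hub's state
#'   passes through `c * tanh(x / c)` -- a firing-rate ceiling. Purely
#'   linear chains make the downstream connectivity matrix close under
#'   transitivity (every source-to-target shortcut appears alongside the
#'   two hub-incident steps), which no real hub-centric network shows;
#'   saturation bounds the relayed signal and suppresses those
#'   second-order shortcuts.
#' @param hub_channel_mix fraction (gamma in \[0, 1\]) of the hub's common
#'   activity in each outgoing projection channel. Each target receives
#'   `gamma * g + sqrt(1 - gamma^2) * xi_t`, where `g` is the hub's common
#'   (saturated) activity and `xi_t` a channel-private fluctuation --
#'   distinct neuronal subpopulations projecting to different targets.
#'   Values below 1 decorrelate the hub's targets from one another while
#'   every target stays coupled to the hub's observed signal. Ignored when
#'   `hub_saturation` is NULL.
#' @param hub_gain_budget upper bound (in units of the hub's outgoing
#'   coupling) on the session-wise relay gain used for variance
#'   conservation at the targets: during modulated windows a target's
#'   intrinsic fluctuation is topped up so that relay share plus intrinsic
#'   share always meet the same budget. 0 disables conservation.
#' @param class_effect logistic scaling linking the session-wise hub-edge
#'   modulation factor to behavioural performance (>= 0).
#' @param session_scale_sd standard deviation of the session-wise common
#'   modulation scale factor around 1 (the component linked to performance).
#' @param edge_scale_sd standard deviation of the additional per-edge
#'   variation of hub-incident modulation around the session factor.
#' @param performance_noise_sd additive Gaussian noise on performance.
#' @param region_labels optional region names.
#' @return an object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(n_regions,
                            baseline_coupling,
                            coupling_modulation,
                            planted_hub = NULL,
                            activation_amplitudes,
                            noise_ar1 = 0.4,
                            noise_sd = 0.5,
                            neural_noise_sd = 1,
                            neural_noise_tau = 4,
                            hub_saturation = NULL,
                            hub_channel_mix = 1,
                            hub_gain_budget = 0,
                            class_effect = 2,
                            session_scale_sd = 0.3,
                            edge_scale_sd = 0.3,
                            performance_noise_sd = 0.05,
                            region_labels = NULL) {
  if (n_regions < 2) stop("`n_regions` must be at least 2", call. = FALSE)
  baseline_coupling <- as.matrix(baseline_coupling)
  coupling_modulation <- as.matrix(coupling_modulation)
  for (m in list(baseline_coupling, coupling_modulation)) {
    if (!all(dim(m) == n_regions))
      stop("coupling matrix shape mismatch with `n_regions`", call. = FALSE)
    if (any(diag(m) != 0))
      stop("coupling matrices must have zero diagonal", call. = FALSE)
  }
  lin <- if (is.null(hub_saturation)) baseline_coupling + coupling_modulation
         else baseline_coupling  # the saturated hub bounds modulated pathways
  rho <- max(Mod(eigen(lin, only.values = TRUE)$values),
             Mod(eigen(baseline_coupling, only.values = TRUE)$values))
  if (rho >= 0.95)
    stop("unstable coupling: spectral radius of the neural mixing matrix is ",
         signif(rho, 3), " (must stay well below 1 for the instantaneous ",
         "mixing to be solvable)", call. = FALSE)
  if (noise_ar1 < 0 || noise_ar1 >= 1)
    stop("`noise_ar1` must lie in [0, 1)", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  if (any(neural_noise_sd < 0))
    stop("`neural_noise_sd` must be non-negative", call. = FALSE)
  if (!length(neural_noise_sd) %in% c(1L, n_regions))
    stop("`neural_noise_sd` must be a scalar or one value per region",
         call. = FALSE)
  neural_noise_sd <- rep_len(neural_noise_sd, n_regions)
  if (neural_noise_tau <= 0)
    stop("`neural_noise_tau` must be positive", call. = FALSE)
  if (class_effect < 0) stop("`class_effect` must be non-negative", call. = FALSE)
  if (!is.null(planted_hub) &&
      (planted_hub < 1 || planted_hub > n_regions))
    stop("`planted_hub` index out of range", call. = FALSE)
  if (!is.null(hub_saturation)) {
    if (is.null(planted_hub))
      stop("`hub_saturation` requires a `planted_hub`", call. = FALSE)
    if (hub_saturation <= 0)
      stop("`hub_saturation` must be positive", call. = FALSE)
    if (hub_channel_mix < 0 || hub_channel_mix > 1)
      stop("`hub_channel_mix` must lie in [0, 1]", call. = FALSE)
  }
  activation_amplitudes <- as.matrix(activation_amplitudes)
  if (ncol(activation_amplitudes) != n_regions)
    stop("`activation_amplitudes` must have one column per region", call. = FALSE)
  if (is.null(region_labels))
    region_labels <- sprintf("R%02d", seq_len(n_regions))
  structure(list(n_regions = n_regions,
                 baseline_coupling = baseline_coupling,
                 coupling_modulation = coupling_modulation,
                 planted_hub = planted_hub,
                 activation_amplitudes = activation_amplitudes,
                 noise_ar1 = noise_ar1, noise_sd = noise_sd,
                 neural_noise_sd = neural_noise_sd,
                 neural_noise_tau = neural_noise_tau,
                 hub_saturation = hub_saturation,
                 hub_channel_mix = hub_channel_mix,
                 hub_gain_budget = hub_gain_budget,
                 class_effect = class_effect,
                 session_scale_sd = session_scale_sd,
                 edge_scale_sd = edge_scale_sd,
                 performance_noise_sd = performance_noise_sd,
                 region_labels = region_labels),
            class = "synthetic_truth")
}

#' Default study truth: a planted hub among ten regions
#'
#' Ten regions with weak condition-independent ring coupling. During the
#' MIDDLE Choice period of correct trials, the hub receives coupling of
#' strength `modulation_in` from each source region and relays to every
#' target region with gain `modulation_out`; its own activity passes
#' through a saturating ceiling (see `hub_saturation` in
#' [synthetic_truth()]). Sources and targets are disjoint, so the modulated
#' subgraph is acyclic and the neural fixed point is stable regardless of
#' the coupling strengths.
#'
#' With these defaults the hub sits on the shortest task-evoked paths from
#' every source to every target (and, because the relayed share of each
#' target is modest, between target pairs as well), while the saturation
#' keeps source-to-target shortcuts out of the connectivity matrix. The
#' hub-incident couplings scale with the session factor that drives
#' behavioural performance, so they also carry the class signal used by the
#' simulated-lesion classifier.
#'
#' Task-evoked activations are deliberately modest (0.1 signal units at
#' Choice, 0.3 at Cue) relative to the ongoing fluctuations (sd 1): the
#' planted effect of interest is interaction-driven connectivity, not the
#' shared evoked response.
#'
#' @param n_regions number of regions.
#' @param hub hub region index.
#' @param sources regions with modulated coupling into the hub.
#' @param targets regions receiving the hub's relayed signal.
#' @param modulation_in coupling strength source -> hub during MIDDLE Choice.
#' @param modulation_out relay gain hub -> target during MIDDLE Choice.
#' @param baseline ring coupling strength (condition independent).
#' @param hub_saturation hub activity ceiling (signal units).
#' @param session_scale_sd,edge_scale_sd session-wise modulation variation
#'   (see [synthetic_truth()]); the hub truth defaults are wider than the
#'   generic ones so the cohort spans a usable performance range.
#' @param ... passed on to [synthetic_truth()].
#' @return a `synthetic_truth`.
#' @export
planted_hub_truth <- function(n_regions = 10, hub = 5,
                              sources = c(1, 2, 3),
                              targets = c(4, 6, 7, 8, 9, 10),
                              modulation_in = 3, modulation_out = 1.2,
                              baseline = 0.1, hub_saturation = 1.2,
                              session_scale_sd = 0.6, edge_scale_sd = 0.4,
                              ...) {
  if (length(intersect(sources, targets)) || hub %in% c(sources, targets))
    stop("`sources`, `targets` and `hub` must be disjoint", call. = FALSE)
  B <- matrix(0, n_regions, n_regions)
  for (i in seq_len(n_regions)) B[i, i %% n_regions + 1] <- baseline
  diag(B) <- 0
  M <- matrix(0, n_regions, n_regions)
  M[sources, hub] <- modulation_in
  M[hub, targets] <- modulation_out
  synthetic_truth(n_regions, B, M, planted_hub = hub,
                  activation_amplitudes = default_amplitudes(n_regions),
                  hub_saturation = hub_saturation,
                  session_scale_sd = session_scale_sd,
                  edge_scale_sd = edge_scale_sd, ...)
}

#' Single-edge truth: modulation planted on one directed connection
#'
#' Fixture for directed recovery: the only condition-dependent coupling sits
#' on `from -> to`, so the group z-matrix should single out that ordered
#' pair.
#'
#' @param n_regions number of regions.
#' @param from,to seed and target indices of the modulated connection.
#' @param modulation additive coupling on `from -> to` during MIDDLE Choice.
#' @param baseline ring coupling strength.
#' @param ... passed on to [synthetic_truth()].
#' @return a `synthetic_truth`.
#' @export
single_edge_truth <- function(n_regions = 10, from = 1, to = 2,
                              modulation = 3, baseline = 0.1, ...) {
  B <- matrix(0, n_regions, n_regions)
  for (i in seq_len(n_regions)) B[i, i %% n_regions + 1] <- baseline
  diag(B) <- 0
  M <- matrix(0, n_regions, n_regions)
  M[from, to] <- modulation
  synthetic_truth(n_regions, B, M, planted_hub = NULL,
                  activation_amplitudes = default_amplitudes(n_regions), ...)
}

# Modest evoked responses at Cue and Choice, identical across the two
# Choice conditions of interest (the planted contrast lives in coupling,
# not activation).
default_amplitudes <- function(n_regions) {
  amp <- matrix(0, nrow = 3, ncol = n_regions,
                dimnames = list(c("CUE", "MIDDLE", "BOTH_END"), NULL))
  amp["CUE", ] <- 0.3
  amp["MIDDLE", ] <- 0.1
  amp["BOTH_END", ] <- 0.1
  amp
}

#' Trial timing parameters
#'
#' Defaults follow a short-trial design: a 3 s warning after the joystick
#' pull, four cue stimuli of 1.1 s separated by 0.6 s, a 5.5 s delay, a
#' 5 s choice/response/feedback epoch, and a 3 s intertrial interval with
#' up to 1 s of uniform jitter.
#'
#' @param warning,cue_dur,cue_isi,delay,choice,iti durations (s), positive.
#' @param cue_n number of cue stimuli per list.
#' @param iti_jitter upper bound of the uniform intertrial jitter (s).
#' @param align_choice grid (s) to which Choice onsets are synchronized by
#'   stretching the delay; 0 disables. Synchronizing the decision period to
#'   the volume acquisition grid keeps the sampled response of every Choice
#'   event comparable across trials and sessions.
#' @return a named list of timing parameters.
#' @export
task_timing <- function(warning = 3, cue_n = 4, cue_dur = 1.1, cue_isi = 0.6,
                        delay = 5.5, choice = 5, iti = 3, iti_jitter = 1,
                        align_choice = 0) {
  vals <- c(warning = warning, cue_dur = cue_dur, cue_isi = cue_isi,
            delay = delay, choice = choice, iti = iti)
  if (any(vals <= 0) || cue_n < 1)
    stop("timing parameters must be positive", call. = FALSE)
  if (iti_jitter < 0) stop("`iti_jitter` must be non-negative", call. = FALSE)
  if (align_choice < 0) stop("`align_choice` must be non-negative", call. = FALSE)
  list(warning = warning, cue_n = cue_n, cue_dur = cue_dur, cue_isi = cue_isi,
       delay = delay, choice = choice, iti = iti, iti_jitter = iti_jitter,
       align_choice = align_choice)
}

#' Generate a session's trial events
#'
#' Lays out trials sequentially (Warning, Cue, Delay, Choice, intertrial
#' interval) with the requested number of Choice events per condition, in a
#' randomly interleaved order. Correctness of each Choice event is drawn as
#' Bernoulli with the per-condition probability in `p_correct`.
#'
#' @param n_trials_per_condition named integer vector over Choice conditions
#'   (MIDDLE, BOTH_END, EITHER_END_INITIAL, EITHER_END_LAST).
#' @param timing a [task_timing()] list.
#' @param rng_seed integer seed (NULL: use the current RNG stream).
#' @param p_correct named per-condition probability of a correct response.
#' @return an [event_table()].
#' @export
generate_task_events <- function(n_trials_per_condition = c(MIDDLE = 5, BOTH_END = 5,
                                                            EITHER_END_INITIAL = 1,
                                                            EITHER_END_LAST = 1),
                                 timing = task_timing(), rng_seed = NULL,
                                 p_correct = c(MIDDLE = 0.75, BOTH_END = 0.9,
                                               EITHER_END_INITIAL = 0.85,
                                               EITHER_END_LAST = 0.85)) {
  if (any(n_trials_per_condition < 0))
    stop("trial counts must be non-negative", call. = FALSE)
  bad <- setdiff(names(n_trials_per_condition), CHOICE_CONDITIONS)
  if (length(bad))
    stop("unknown Choice condition(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  with_seed(rng_seed, {
    trial_conditions <- rep(names(n_trials_per_condition),
                            times = n_trials_per_condition)
    if (length(trial_conditions) > 1)
      trial_conditions <- sample(trial_conditions)
    onset <- numeric(); duration <- numeric()
    condition <- character(); correct <- logical()
    t <- 0
    cue_total <- timing$cue_n * timing$cue_dur +
      (timing$cue_n - 1) * timing$cue_isi
    for (cond in trial_conditions) {
      onset <- c(onset, t); duration <- c(duration, timing$warning)
      condition <- c(condition, "WARNING"); correct <- c(correct, NA)
      t <- t + timing$warning
      onset <- c(onset, t); duration <- c(duration, cue_total)
      condition <- c(condition, "CUE"); correct <- c(correct, NA)
      t <- t + cue_total + timing$delay
      if (timing$align_choice > 0)
        t <- ceiling(t / timing$align_choice) * timing$align_choice
      p <- if (cond %in% names(p_correct)) p_correct[[cond]] else 1
      hit <- runif(1) < p
      onset <- c(onset, t); duration <- c(duration, timing$choice)
      condition <- c(condition, cond); correct <- c(correct, hit)
      t <- t + timing$choice + timing$iti + runif(1, 0, timing$iti_jitter)
    }
    event_table(onset, duration, condition, correct)
  })
}

# Saturating-hub forward solve: the hub's activity passes through
# c * tanh(x / c) (a firing-rate ceiling); fixed-point iteration of
# z = sigma_hub(a + G' z), applied separately to timepoints with and
# without the condition-dependent coupling.
relay_network <- function(A, ind, B, M, truth, h) {
  cs <- truth$hub_saturation
  relay <- function(Arows, G) {
    if (!nrow(Arows)) return(Arows)
    Zs <- Arows
    for (iter in 1:50) {
      Znew <- Arows + Zs %*% G
      Znew[, h] <- cs * tanh(Znew[, h] / cs)
      if (max(abs(Znew - Zs)) < 1e-10) { Zs <- Znew; break }
      Zs <- Znew
    }
    Zs
  }
  Z <- matrix(0, nrow(A), ncol(A))
  Z[!ind, ] <- relay(A[!ind, , drop = FALSE], B)
  Z[ind, ] <- relay(A[ind, , drop = FALSE], B + M)
  Z
}

#' Generate a session's BOLD time series from a synthetic truth
#'
#' Neural activity per region is the sum of condition boxcars weighted by
#' the activation amplitudes and instantaneous linear input from the other
#' regions through `baseline_coupling`, augmented by `coupling_modulation`
#' while the MIDDLE Choice period of a correct trial is active. Neural
#' signals are convolved with the canonical HRF on a fine grid, sampled at
#' the TR, and AR(1) Gaussian noise plus a small motion-coupled component
#' are added. Six random-walk motion parameters are attached as nuisance
#' covariates.
#'
#' @param truth a [synthetic_truth()].
#' @param events an [event_table()].
#' @param tr sampling interval (s).
#' @param n_timepoints number of volumes.
#' @param rng_seed integer seed (NULL: current stream).
#' @param hrf an [hrf_model()].
#' @return a [session_timeseries()].
#' @export
generate_session_timeseries <- function(truth, events, tr = 2.5,
                                        n_timepoints = 117, rng_seed = NULL,
                                        hrf = hrf_model()) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (tr <= 0) stop("`tr` must be positive", call. = FALSE)
  if (n_timepoints < 10) stop("`n_timepoints` must be at least 10", call. = FALSE)
  R <- truth$n_regions
  with_seed(rng_seed, {
    bins <- 10L
    dt <- tr / bins
    n_micro <- n_timepoints * bins

    # condition boxcars -> activation input A (micro x regions)
    A <- matrix(0, n_micro, R)
    for (cond in rownames(truth$activation_amplitudes)) {
      ev <- events[events$condition == cond, , drop = FALSE]
      if (!nrow(ev)) next
      u <- stimulus_function(ev$onset, pmax(ev$duration, dt),
                             rep(1, nrow(ev)), dt, n_micro)
      A <- A + outer(u, truth$activation_amplitudes[cond, ])
    }

    # modulation indicator: Choice boxcar of correct MIDDLE trials
    evm <- events[events$condition == "MIDDLE" & events$correct %in% TRUE, ,
                  drop = FALSE]
    ind <- stimulus_function(evm$onset, pmax(evm$duration, dt),
                             rep(1, nrow(evm)), dt, n_micro) > 0

    # region-specific ongoing neural fluctuations
    if (any(truth$neural_noise_sd > 0)) {
      phi <- exp(-dt / truth$neural_noise_tau)
      nn_sd <- rep_len(truth$neural_noise_sd, R)
      A <- A + vapply(seq_len(R), function(r) {
        as.numeric(stats::filter(rnorm(n_micro, 0, nn_sd[r] * sqrt(1 - phi^2)),
                                 phi, method = "recursive"))
      }, numeric(n_micro))
    }

    Z <- matrix(0, n_micro, R)
    if (is.null(truth$hub_saturation)) {
      solve_base <- solve(diag(R) - truth$baseline_coupling)
      solve_mod <- solve(diag(R) - (truth$baseline_coupling +
                                      truth$coupling_modulation))
      if (any(!ind)) Z[!ind, ] <- A[!ind, , drop = FALSE] %*% solve_base
      if (any(ind)) Z[ind, ] <- A[ind, , drop = FALSE] %*% solve_mod
    } else if (truth$hub_channel_mix < 1 &&
               any(truth$coupling_modulation[truth$planted_hub, ] != 0)) {
      h <- truth$planted_hub
      gamma <- truth$hub_channel_mix
      out_gain <- truth$coupling_modulation[h, ]
      targets <- which(out_gain != 0)
      # stage 1: network without the hub's outgoing projections
      M_in <- truth$coupling_modulation
      M_in[h, ] <- 0
      Z <- relay_network(A, ind, truth$baseline_coupling, M_in, truth, h)
      g <- Z[, h]
      # stage 2: per-target projection channels: common saturated activity
      # mixed with channel-private fluctuations of matching scale
      phi_x <- exp(-dt / truth$neural_noise_tau)
      s_g <- max(sd(g), 1e-8)
      xi <- vapply(targets, function(t.) {
        s_g * as.numeric(stats::filter(rnorm(n_micro, 0, sqrt(1 - phi_x^2)),
                                       phi_x, method = "recursive"))
      }, numeric(n_micro))
      ch <- gamma * g + sqrt(1 - gamma^2) * xi
      Z[ind, targets] <- Z[ind, targets] +
        ch[ind, , drop = FALSE] %*% diag(out_gain[targets],
                                         length(targets))
      # the hub's observed activity carries all its channels
      Z[, h] <- gamma * g +
        sqrt((1 - gamma^2) / length(targets)) * rowSums(xi)
      # variance conservation at the targets: during the modulated windows
      # each target's intrinsic fluctuation yields to the relayed input so
      # that its total variance stays at the session-invariant budget
      # (cortical variability quenching under drive); without this, the
      # session-wise relay gain would be readable from every feature's
      # noise level rather than from the hub-incident couplings
      if (any(ind) && truth$hub_gain_budget > 0) {
        nn <- rep_len(truth$neural_noise_sd, R)
        v_budget <- (truth$hub_gain_budget * s_g)^2
        for (j in seq_along(targets)) {
          t. <- targets[j]
          extra <- sqrt(max(0, v_budget - (out_gain[t.] * s_g)^2))
          top_up <- extra * as.numeric(
            stats::filter(rnorm(n_micro, 0, sqrt(1 - phi_x^2)), phi_x,
                          method = "recursive"))
          Z[ind, t.] <- Z[ind, t.] + top_up[ind]
        }
      }
    } else {
      Z <- relay_network(A, ind, truth$baseline_coupling,
                         truth$coupling_modulation, truth,
                         truth$planted_hub)
    }

    kern <- canonical_hrf(dt, hrf)$hrf
    # each volume integrates the signal over its acquisition interval
    bin_of <- rep(seq_len(n_timepoints), each = bins)
    bold <- vapply(seq_len(R), function(r) {
      smooth <- convolve_kernel(Z[, r], kern, dt = dt)
      as.numeric(tapply(smooth, bin_of, mean))
    }, numeric(n_timepoints))

    # AR(1) noise with marginal sd noise_sd
    if (truth$noise_sd > 0) {
      innov_sd <- truth$noise_sd * sqrt(1 - truth$noise_ar1^2)
      noise <- vapply(seq_len(R), function(r) {
        e <- rnorm(n_timepoints, 0, innov_sd)
        as.numeric(stats::filter(e, truth$noise_ar1, method = "recursive"))
      }, numeric(n_timepoints))
      bold <- bold + noise
    }

    # six random-walk motion parameters, weakly coupled into the signal
    motion <- vapply(seq_len(6), function(j) cumsum(rnorm(n_timepoints, 0, 0.02)),
                     numeric(n_timepoints))
    colnames(motion) <- sprintf("motion%d", 1:6)
    bold <- bold + motion %*% matrix(rnorm(6 * R, 0, 0.05), 6, R)

    session_timeseries(bold, tr, region_labels = truth$region_labels,
                       nuisance = motion)
  })
}

#' Generate a cohort of sessions with performance-linked connectivity
#'
#' Each session draws a factor `s ~ N(1, session_scale_sd)` (truncated at
#' 0.1) that scales the planted hub's outgoing relay gain -- the efficacy
#' with which the hub's (capacity-limited) activity reaches its targets.
#' For a truth without a hub, the factor scales the whole
#' coupling-modulation matrix instead. Behavioural performance is a
#' logistic function of that factor, `plogis(qlogis(0.75) + class_effect *
#' (s - 1))`, plus Gaussian noise, clamped to \[0, 1\]. Top-tertile
#' sessions therefore carry systematically stronger hub-outgoing
#' task-evoked connectivity, and the session-to-session link between hub
#' throughput and performance is what the lesion classifier exploits. Correctness draws are conditioned on at least one correct
#' MIDDLE and one correct BOTH_END trial so the psychological contrast of
#' every session is defined.
#'
#' @param truth a [synthetic_truth()].
#' @param n_sessions number of sessions (>= 6).
#' @param timing a [task_timing()] list.
#' @param rng_seed integer seed.
#' @param tr,n_timepoints acquisition parameters.
#' @param n_trials_per_condition Choice trial counts per session.
#' @param hrf an [hrf_model()].
#' @return list of `session_record` objects (fields `session_id`,
#'   `timeseries`, `events`, `performance`, `modulation_scale`).
#' @export
generate_cohort <- function(truth, n_sessions = 30, timing = task_timing(),
                            rng_seed = NULL, tr = 2.5, n_timepoints = 117,
                            n_trials_per_condition = c(MIDDLE = 5, BOTH_END = 5,
                                                       EITHER_END_INITIAL = 1,
                                                       EITHER_END_LAST = 1),
                            hrf = hrf_model()) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (n_sessions < 6)
    stop("too few sessions: need at least 6 for a tertile split", call. = FALSE)
  with_seed(rng_seed, {
    lapply(seq_len(n_sessions), function(i) {
      session_truth <- truth
      if (is.null(truth$planted_hub)) {
        s <- max(0.1, rnorm(1, 1, truth$session_scale_sd))
        session_truth$coupling_modulation <- truth$coupling_modulation * s
      } else {
        # one factor per outgoing hub connection: the session's hub-relay
        # pattern; performance tracks the pattern's common component, so
        # the class signal is carried by the joint pattern of hub-edge
        # strengths rather than a single scalar. Incoming couplings are
        # left fixed: behind the saturating ceiling their session-to-
        # session variation would barely alter the relayed signal while
        # adding estimation noise to the source-to-hub connections.
        h <- truth$planted_hub
        tg <- which(truth$coupling_modulation[h, ] != 0)
        s_common <- max(0.1, rnorm(1, 1, truth$session_scale_sd))
        u_out <- pmax(0.1, s_common +
                        rnorm(length(tg), 0, truth$edge_scale_sd))
        session_truth$coupling_modulation[h, tg] <-
          truth$coupling_modulation[h, tg] * u_out
        s <- s_common
      }
      perf <- plogis(qlogis(0.75) + truth$class_effect * (s - 1)) +
        rnorm(1, 0, truth$performance_noise_sd)
      perf <- min(max(perf, 0), 1)

      p_correct <- c(MIDDLE = perf, BOTH_END = 0.9,
                     EITHER_END_INITIAL = 0.85, EITHER_END_LAST = 0.85)
      for (attempt in 1:100) {
        events <- generate_task_events(n_trials_per_condition, timing,
                                       rng_seed = NULL, p_correct = p_correct)
        hits <- function(cond) any(events$condition == cond &
                                     events$correct %in% TRUE)
        if (hits("MIDDLE") && hits("BOTH_END")) break
        if (attempt == 100)
          stop("could not generate a session with hits in both conditions",
               call. = FALSE)
      }
      ts <- generate_session_timeseries(session_truth, events, tr = tr,
                                        n_timepoints = n_timepoints,
                                        rng_seed = NULL, hrf = hrf)
      structure(list(session_id = sprintf("S%03d", i), timeseries = ts,
                     events = events, performance = perf,
                     modulation_scale = s),
                class = "session_record")
    })
  })
}

#' Planted-hub toy network
#'
#' Weighted directed matrix in which every connection to and from the hub
#' has weight `on_weight` and all other connections `off_weight`, so that
#' with `off_weight` small all shortest paths are forced through the hub.
#'
#' @param n_nodes number of nodes.
#' @param hub hub node index (1-based).
#' @param on_weight weight of hub-incident edges.
#' @param off_weight weight of the remaining edges (`on_weight > off_weight >= 0`).
#' @param jitter_sd optional sd of multiplicative weight jitter.
#' @param rng_seed integer seed (used only when `jitter_sd > 0`).
#' @return a [connectivity_matrix()] of kind `ppi_z_group`.
#' @export
make_planted_hub_network <- function(n_nodes, hub, on_weight, off_weight,
                                     jitter_sd = 0, rng_seed = NULL) {
  if (hub < 1 || hub > n_nodes) stop("`hub` index out of range", call. = FALSE)
  if (!(on_weight > off_weight) || off_weight < 0)
    stop("`on_weight` must exceed `off_weight` >= 0", call. = FALSE)
  w <- matrix(off_weight, n_nodes, n_nodes)
  w[hub, ] <- on_weight
  w[, hub] <- on_weight
  diag(w) <- 0
  if (jitter_sd > 0)
    w <- with_seed(rng_seed,
                   w * matrix(exp(rnorm(n_nodes^2, 0, jitter_sd)),
                              n_nodes, n_nodes))
  connectivity_matrix(w, kind = "ppi_z_group")
}

#' Random binary anatomy fixture
#'
#' Directed binary matrix with zero diagonal in which each ordered pair
#' carries a connection independently with probability `density`.
#'
#' @param n_nodes number of nodes.
#' @param density connection probability in \[0, 1\].
#' @param rng_seed integer seed.
#' @return a [connectivity_matrix()] of kind `binary_anatomy`.
#' @export
make_toy_anatomy <- function(n_nodes, density, rng_seed = NULL) {
  if (density < 0 || density > 1)
    stop("`density` must lie in [0, 1]", call. = FALSE)
  with_seed(rng_seed, {
    w <- matrix(as.numeric(runif(n_nodes^2) < density), n_nodes, n_nodes)
    diag(w) <- 0
    connectivity_matrix(w, kind = "binary_anatomy")
  })
}
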