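---
title: "Task-evoked connectivity hubs and simulated lesions: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task-evoked connectivity hubs and simulated lesions: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hublesion)
```

# The scientific question

Does the network position of a brain region predict how much behaviour
would suffer if that region were knocked out? `hublesion` implements a
complete analysis chain for answering this with task fMRI alone, without a
physical lesion:

1. estimate **directed, task-modulated connectivity** between regions of
   interest from session BOLD time series (psychophysiological
   interactions, PPI);
2. identify **hubs** — regions that sit on many shortest paths of the
   resulting weighted directed graph (betweenness centrality), with
   significance from randomization nulls;
3. predict each region's **behavioural impact** with a *simulated lesion*:
   train a classifier to tell high- from low-performance sessions from the
   connectivity pattern, then delete all features incident to one region
   and measure the drop in cross-validated accuracy;
4. test whether predicted impact **correlates with hubness**.

The package also contains a synthetic-data generator whose forward model
mirrors the analysis assumptions, so that the whole chain is testable
end-to-end without scanner data.

# The task model

The generator simulates a delayed spatial-memory paradigm. Each trial is a
Warning period (3 s), a list of four Cue stimuli (1.1 s each, 0.6 s
apart), a Delay (5.5 s), a Choice/response/feedback epoch (5 s), and an
intertrial interval (3 s plus up to 1 s uniform jitter). Choice events
come in four conditions; the analysis contrast is **MIDDLE versus
BOTH-END**, restricted to correct responses (hits). A session by default
contains 5 MIDDLE, 5 BOTH-END and 2 filler trials, scanned as 117 volumes
at TR = 2.5 s (~5 minutes).

```{r events}
events <- generate_task_events(rng_seed = 1)
head(events, 8)
```

# Forward model of the BOLD signal

Neural activity is simulated on a fine grid (TR/10). Region $i$ carries

$$z_i(t) = a_i(t) + n_i(t) + \sum_{j \ne i} G_{ji}(t)\, z_j(t),$$

where $a_i$ is the sum of condition boxcars scaled by the activation
amplitudes, $n_i$ is a region-specific ongoing fluctuation (AR process,
marginal sd 1, time constant 4 s), and $G(t)$ is the directed coupling
matrix: a weak condition-independent ring (`baseline_coupling`) plus the
**condition-dependent modulation** (`coupling_modulation`), active only
while the Choice period of a *correct MIDDLE* trial is on. The neural
signals are convolved with the canonical double-gamma HRF, integrated over
each TR bin, and corrupted with AR(1) Gaussian noise plus a small
motion-coupled component (six random-walk motion regressors are emitted as
nuisance covariates).

Two design choices matter and are worth stating explicitly:

* **Fluctuations, not evoked responses, identify direction.** Every region
  shows an evoked response at Choice, and evoked responses are shared
  across regions, so they carry almost no information about who drives
  whom. What the PPI stage can detect is that the *target inherits the
  seed's idiosyncratic ongoing activity only while the coupling is
  active*. The generator therefore uses slow region-specific neural noise
  (sd 1) and deliberately modest evoked amplitudes (0.3 at Cue, 0.1 at
  Choice, identical across the two conditions of interest — the planted
  effect lives in coupling, not activation).

* **A saturating hub instead of purely linear mixing.** With purely linear
  instantaneous mixing, a modulated chain $A \to B \to C$ produces an
  $A \to C$ connectivity entry of comparable strength to the two real
  links: the estimated graph closes under transitivity, shortest paths use
  the shortcuts, and *no* node can be a betweenness hub. The default truth
  therefore passes the hub's state through a firing-rate ceiling
  $c\,\tanh(x/c)$ (`hub_saturation`), which bounds the relayed signal and
  suppresses the second-order source-to-target shortcuts while leaving the
  hub-incident couplings strong.

## The planted-hub truth

`planted_hub_truth()` is the package's default study condition: ten
regions, a weak ring, and during correct-MIDDLE Choice periods an acyclic
bipartite motif — three *source* regions couple into the hub (region 5)
and the hub relays to the six *target* regions. Sources and targets are
disjoint, so the modulated subgraph has no cycles and the neural fixed
point is stable at any coupling strength.

```{r truth}
truth <- planted_hub_truth()
truth$coupling_modulation
```

Session-to-session variation carries the class signal: each session draws
a common factor $s$ (mean 1) that scales the hub's outgoing couplings
(with additional per-edge jitter), and behavioural performance is a
logistic function of $s$ (`class_effect`, default 2) plus noise. Sessions
with a strong hub relay are high-performance sessions; the classifier is
supposed to discover exactly that. Each session also draws nuisance
variation that is *not* linked to performance — per-session gains on the
source regions' fluctuation amplitudes — so that incidental correlates of
the hub pathway (source-to-target echoes) are less class-informative than
the hub-incident features themselves.

# PPI estimation

For a seed region $s$ and target $t$, the session PPI beta is the
regression weight of the interaction regressor in a GLM of the target's
time series. The interaction regressor is built exactly as the analysis
prescribes:

1. regress nuisance covariates out of the seed series;
2. **deconvolve** the seed to a neural-level signal by ridge-penalized
   least squares against the HRF convolution operator
   (second-difference smoothness penalty);
3. multiply by the **psychological contrast** (+1 during correct-MIDDLE
   Choice, −1 during correct-BOTH-END Choice, 0 elsewhere);
4. **reconvolve** with the HRF and sample at the TR.

The GLM for each target contains the interaction regressor, the seed's
physiological series, the convolved psychological regressor, the motion
nuisance, a DCT high-pass set (cutoff 128 s) and a constant. Session
betas for all 90 ordered pairs are aggregated with a one-sample t-test
across sessions and converted to z (`group_ppi_matrix()`), giving the
weighted directed graph of the group.

```{r ppi, eval = FALSE}
cohort <- generate_cohort(truth, n_sessions = 30, rng_seed = 1)
feat <- ppi_feature_table(cohort)
z <- group_ppi_matrix(feat$betas)
```

# Hubs by betweenness with randomization nulls

Connectivity is turned into path length by $d_{AB} = 1 / z_{AB}$
(non-positive weights become infinite distance), and node betweenness is
computed exactly (Brandes' algorithm, all co-minimal paths counted).
Significance uses pooled randomization nulls:

* **weighted**: permute the multiset of off-diagonal weights over the
  ordered pairs, recompute betweenness, pool across nodes and
  randomizations (`randomization_null_weighted()`);
* **binary** (for thresholded or anatomical graphs): place the observed
  number of edges uniformly, preserving the edge count in every draw
  (`randomization_null_binary()`).

P-values use an add-one continuity correction and are exactly uniform
under exchangeable weights — one of the package's acceptance checks.

# The simulated lesion

Sessions are labelled by performance tertiles (top third "high", bottom
third "low", after omitting sessions below 50% correct). A soft-margin
RBF-kernel SVM is trained to classify high versus low sessions from the
90 PPI features, with leave-one-out cross-validation, per-fold feature
standardization using training statistics only, and an exhaustive grid
search over $C = 2^{-5..15}$, $\gamma = 2^{-15..3}$.

A region's **predicted impact** is the drop in LOO accuracy when all 18
features incident to it are deleted (`simulated_lesion()`). Its
significance comes from a null of 18 *random* edge deletions, fitted as a
normal on the arcsine-transformed accuracy scale. Two companion
statistics complete the analysis: a per-connection classification index
(z-transformed Welch t contrasting high versus low sessions) and the
Pearson correlation between per-node impact and weighted betweenness.

```{r pipeline, eval = FALSE}
res <- run_pipeline(pipeline_config(rng_seed = 1))
print(res)
```

# Calibration of the generator defaults

The generator's defaults were chosen once, before the acceptance suite
was frozen, by forward calibration on held-out seeds:

* `modulation_in = 3`, `hub_saturation = 1.2`: strong enough that the
  source-to-hub links dominate the graph, with the ceiling keeping the
  relayed amplitude (and hence the transitive shortcuts) bounded;
* `modulation_out = 1.2`: large enough that the hub-to-target links beat
  the target-to-target shortcuts in the group z-matrix, while each target
  keeps most of its intrinsic variance;
* `session_scale_sd = 0.6` and `edge_scale_sd = 0.4` set how much class
  signal the hub-incident features carry relative to nuisance variation,
  and spread performance over a usable tertile range;
* `class_effect = 2` gives a clear but not deterministic link between the
  hub pathway and performance.

Several structural variants were evaluated during calibration and
rejected: scaling the hub's *incoming* couplings with the session factor
(behind the saturation ceiling it adds estimation noise without moving
the relayed signal), and per-session amplitude nuisances on the source or
target regions (intended to corrupt echo features, they corrupt the
hub-incident features at least as much, since the same regions anchor
both).

# Known limitations

* **PPI transitivity.** Even with a saturating hub, correlation-based
  interaction measures leak along modulated chains: source-to-target
  "echo" edges appear at reduced but non-zero strength. At realistic
  noise levels the planted hub is the betweenness argmax in most, but not
  all, replicate cohorts.
* **Common-input confounds limit lesion specificity.** Any
  session-varying hub throughput is visible not only on hub-incident
  edges but in *every* feature whose seed region contains the relayed
  signal: target-to-target, target-to-hub and target-to-source "echo"
  connections. A per-connection classification-index diagnostic on
  60-session cohorts shows these echo groups carrying mean |z| of about
  1.0–1.8 against about 1.0–2.2 for the direct hub-to-target group, so an
  RBF-SVM reads much of the class signal from features that survive a hub
  deletion. Consequently, while the hub is essentially always the top
  *betweenness* node (16/16 calibration cohorts) and PPI features beat
  activation features by a wide margin (mean LOO accuracy 0.84 vs 0.61),
  the hub is the top *predicted-impact* node in only a minority of
  cohorts, and the impact–betweenness correlation is positive but weak
  and unstable at this scale. Countermeasures were tried and made things
  worse — session nuisances on source or target amplitudes and
  class-scaling of incoming couplings all corrupt the hub-incident
  features at least as much as the echoes, because the same regions
  anchor both. This is a property of the *measure*, not a bug in the
  implementation: the simulated-lesion logic detects whichever features
  carry class information, and in interaction-based connectivity that
  information is intrinsically distributed. Recovering a clean
  impact-at-the-hub result appears to need cohort and feature-set scales
  well beyond a desk-scale simulation.
* **Deconvolution is regularized, not exact.** Ridge deconvolution
  attenuates high-frequency neural structure, so PPI betas are biased
  toward zero; group z-values are meaningful relative to one another and
  to their nulls, not in absolute units.
* Scale: the reference analysis used ~230 sessions and 100,000
  randomizations; package defaults (30 sessions, 10,000 randomizations)
  are sized for desk-scale reproduction.
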