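# hublesion

Task-evoked connectivity hubs and simulated-lesion prediction of
behavioural impact, for region-of-interest fMRI time series.

The package implements a complete analysis chain:

1. **PPI connectivity** — directed, task-modulated coupling between
   regions estimated by psychophysiological interaction: the seed BOLD
   series is deconvolved to a neural signal (ridge-regularized least
   squares against the canonical HRF), multiplied by a ±1 psychological
   contrast (here MIDDLE vs BOTH-END choice periods, hits only),
   reconvolved, and entered into a GLM of each target region alongside
   physiological, psychological, motion, high-pass and constant
   regressors. Session betas aggregate to a group z-matrix.
2. **Hub identification** — connectivity weights map to path lengths
   (d = 1/w), node betweenness centrality is computed exactly for the
   weighted directed graph (Rcpp implementation of Brandes' algorithm),
   and significance comes from pooled randomization nulls: weight-multiset
   permutation for weighted graphs, edge-count-preserving rewiring for
   binary graphs.
3. **Simulated lesion** — sessions are split into high/low performance
   tertiles; a grid-searched RBF-SVM classifies them from the 90 PPI
   features with leave-one-out cross-validation; deleting all features
   incident to one region and remeasuring accuracy gives that region's
   *predicted impact on performance*, tested against a random-edge-deletion
   null on the arcsine scale. Predicted impact is then correlated with
   betweenness: hubs should matter most.
4. **Synthetic data** — a generator whose forward model (condition
   boxcars, directed neural coupling modulated during correct-MIDDLE
   choice periods, HRF convolution, AR(1) noise, motion nuisance,
   performance-linked session structure) makes the entire chain testable
   end-to-end without scanner data.

## Worked example

```r
library(hublesion)

# Ground truth: ten regions; during correct-MIDDLE choice periods three
# sources drive region R05, which relays to six targets. Session-wise hub
# throughput drives behavioural performance.
truth <- planted_hub_truth()

# Simulate a cohort, estimate PPI, find hubs, classify, lesion:
res <- run_pipeline(pipeline_config(truth, n_sessions = 30, rng_seed = 42,
                                    n_rand = 10000, n_null = 200))
print(res)
#> Pipeline result over 30 sessions
#> LOO accuracy: PPI 0.938, activation 0.688 (C=2, gamma=0.0078125)
#> impact vs betweenness: r = 0.264, p = 0.4612

# Which node is the betweenness hub, and is it significant?
res$centrality$nodes
#>    node betweenness      p_value
#> 1   R01           0 1.0000000000
#> ...
#> 5   R05          18 0.0000099999
#> ...
#> 8   R08           7 0.0450095499

# Per-node predicted impact with its random-deletion null p-values:
head(res$lesion, 5)
#>   node baseline_accuracy deleted_accuracy  impact   p_value
#> 1  R01            0.9375           0.8750  0.0625 0.2837677
#> 2  R02            0.9375           0.8750  0.0625 0.2837677
#> 3  R03            0.9375           0.8125  0.1250 0.1143172
#> 4  R04            0.9375           1.0000 -0.0625 0.9807966
#> 5  R05            0.9375           0.8750  0.0625 0.2837677
```

Lower-level entry points mirror the stages: `generate_cohort()`,
`ppi_feature_table()`, `group_ppi_matrix()`, `fdr_threshold()`,
`betweenness_centrality()`, `randomization_null_weighted()`,
`label_sessions()`, `grid_search()`, `simulated_lesion()`,
`classification_index()`. Sessions and matrices round-trip through plain
TSV files (`write_session()`/`read_session()`, `write_cohort()`,
`write_connectivity_matrix()`).

See the methods vignette (`vignettes/hublesion-methods.Rmd`) for the
model, the estimators, and the design and calibration of the synthetic
generator, including its known limitations.

## Tests

```r
testthat::test_dir("tests/testthat", package = "hublesion",
                   load_package = "installed")
```

`tests/testthat/test-acceptance.R` holds the headline claims: exact
agreement of betweenness with brute-force path enumeration, calibration
of the randomization nulls, recovery of a planted single-edge modulation
as the group-z argmax, end-to-end recovery of the planted hub by the
simulated lesion, and closed-form spot checks.

One assertion in the end-to-end block is known to fail at desk scale:
the planted hub is reliably the top *betweenness* node and PPI features
reliably out-classify activation features, but the hub is the top
*predicted-impact* node in only a minority of replicate cohorts, because
common-input echoes spread the class signal across features that survive
the hub's deletion. The vignette's limitations section analyses this in
detail; the assertion is kept at its intended strength rather than
weakened to pass.

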