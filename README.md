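# waveconn

Wavelet-band functional connectivity, network efficiency, and mediation
analysis for resting-state fMRI cohorts.

## What it is for

A common question in clinical neuroimaging is whether a condition (here,
adolescent inhalant use disorder as the motivating design) alters the
*organization* of resting-state brain networks, and whether that
alteration explains group differences in cognition. `waveconn`
implements the full analysis chain for that question, starting from
extracted ROI time series:

1. **MODWT decomposition** (maximal-overlap discrete wavelet transform,
   Daubechies least-asymmetric LA(8) filter, periodic boundaries). At
   TR = 0.72 s the Nyquist frequency is 0.69 Hz and decomposition level 4
   isolates the 0.043–0.087 Hz band where resting-state correlations live.
2. **Connectivity graphs**: Pearson correlations between level-4
   coefficient series, binarized at a fixed 5% connection density by
   keeping exactly the top `round(0.05 · R(R−1)/2)` edges per subject
   (1736 edges for 264 regions) — the threshold varies per subject, the
   edge count never does.
3. **Efficiency**: global efficiency

   E = (1/n) Σᵢ (1/(n−1)) Σ_{j≠i} 1/dᵢⱼ

   with dᵢⱼ the shortest-path hop count (1/∞ ≡ 0), plus the subnetwork
   variant E_s evaluated on the node set of one functional network
   (default mode, salience, fronto-parietal).
4. **Group inference**: pooled-variance Student's t-tests on efficiencies,
   Kruskal–Wallis tests on cognitive scores, Benjamini–Hochberg FDR within
   each family.
5. **Mediation**: covariate residualization (sex, age, other substance
   use), maximum-likelihood recursive path models
   (group → network efficiency → cognition, plus direct paths), backward
   trimming of nonsignificant paths, and bootstrap percentile confidence
   intervals for indirect effects.

Because subject-level data of this kind are generally not shareable, the
package includes a synthetic cohort generator with planted
block-correlation structure and a planted structural model for cognition,
so every stage is validated against known ground truth. See the methods
vignette (`vignettes/wavelet-connectivity.Rmd`) for the model, the
defaults, and the design decisions.

## Worked example

```r
library(waveconn)

# a synthetic two-group cohort with a planted within-network deficit
# (consumer group 0.35 vs control 0.60), 30 + 27 subjects, T = 500
cfg <- cohort_config(n_regions = 88,
                     network_sizes = c(DMN = 19, SN = 6, FPN = 8),
                     seed = 1)
cohort <- generate_cohort(cfg)

adjs <- lapply(cohort$timeseries, function(x) {
  w <- modwt(x, levels = 6, tr_seconds = 0.72)
  threshold_to_density(correlation_matrix(wavelet_band_series(w, 4)), 0.05)
})
adjs[[1]]
#> Binary adjacency: 88 nodes, 191 edges (density 0.0499), threshold 0.3752 (signed)

eff <- cohort_efficiency(adjs, cohort$parcels)
cmp <- compare_cohort(eff, cohort$manifest)
cmp[, c("variable", "test", "statistic", "p_fdr", "mean_IC", "mean_HC")]
#>         variable           test statistic    p_fdr mean_IC mean_HC
#> 1       E_global      student_t    -23.18 1.86e-29  0.2667  0.0827
#> 2          E_DMN      student_t     14.93 1.08e-20  0.6394  0.9131
#> 3           E_SN      student_t      5.81 3.31e-07  0.4010  0.7959
#> 4          E_FPN      student_t      6.22 9.39e-08  0.4920  0.8596
#> 5 working_memory kruskal_wallis      3.62 1.14e-01 -0.7737 -0.1899
#> 6           wcst kruskal_wallis      8.93 1.12e-02 -0.6507  0.2322
#> 7         stroop kruskal_wallis      1.85 2.25e-01 -0.0543  0.2958
#> 8            toh kruskal_wallis      1.48 2.25e-01 -0.1315  0.1956
```

The planted deficit is recovered: every named network's E_s is
significantly lower in the consumer (IC) group after FDR correction
(rows 2–4), exactly where the generator weakened within-network
correlations. Global efficiency *rises* under the deficit (row 1): with a
fixed edge budget, weaker blocks release edges to the rest of the graph —
a nice illustration of why fixed-density comparisons must be interpreted
per metric.

Mediation on a single-mediator dataset with planted paths a = −0.5,
b = 0.4, c′ = −0.3 (indirect effect a·b = −0.2):

```r
d <- simulate_single_mediator(2000, a = -0.5, b = 0.4, c_prime = -0.3, seed = 1)
spec <- path_model_spec(c("group -> m", "m -> y", "group -> y"))
indirect_effect(spec, d, c("group", "m", "y"), n_boot = 1000, seed = 1)
#> Indirect effect group -> m -> y: -0.1891, 95% bootstrap CI [-0.2329, -0.1460] (1000 reps)
```

An end-to-end run (simulation → wavelets → graphs → efficiency →
inference → mediation, all artifacts on disk) is one call:

```r
run_pipeline(pipeline_config(output_dir = "run1",
                             simulate = cohort_config(seed = 1)))
```

or from a shell:

```sh
Rscript inst/scripts/waveconn-pipeline.R run --out run1 --seed 1
```

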