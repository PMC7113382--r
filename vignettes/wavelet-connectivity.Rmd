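---
title: "Wavelet-band connectivity, network efficiency, and mediation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet-band connectivity, network efficiency, and mediation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(waveconn)
```

## The analysis this package implements

`waveconn` is a complete, testable implementation of a classic resting-state
functional-connectivity workflow used to compare brain-network organization
between a clinical group and controls, and to ask whether network efficiency
*mediates* group differences in cognition:

1. **Band-limited connectivity.** Each subject's ROI time series
   (T timepoints x R regions, already motion-corrected and parcellated) is
   decomposed with the maximal-overlap discrete wavelet transform (MODWT)
   using the Daubechies least-asymmetric LA(8) filter. Level *j* of the
   transform isolates the dyadic frequency band
   (Nyquist/2^j, Nyquist/2^(j-1)]. At the HCP-style repetition time of
   0.72 s the Nyquist frequency is 0.694 Hz and level 4 covers
   0.043-0.087 Hz, the band in which resting-state BOLD correlations are
   most informative. Pearson correlations between the level-of-interest
   coefficient series give an R x R connectivity matrix per subject.
2. **Fixed-density binary graphs.** Each correlation matrix is binarized
   by retaining exactly `round(density * R(R-1)/2)` top-ranked edges
   (5% by default, 1736 edges for 264 regions). Fixing the *edge count*
   rather than the numeric cutoff means every subject's graph has the same
   number of connections, so efficiency differences reflect topology, not
   overall correlation level. The attained numeric threshold varies per
   subject and is reported.
3. **Efficiency.** On the binary graph, global efficiency is the mean
   inverse shortest-path length over ordered node pairs,
   E = (1/n) sum_i (1/(n-1)) sum_{j != i} 1/d_ij, with disconnected pairs
   contributing zero (the Latora-Marchiori convention). Subnetwork
   efficiency E_s evaluates the same formula on the node subset of one
   functional network (DMN, SN, FPN).
4. **Group inference.** Pooled-variance Student's t-tests compare
   efficiencies between groups; Kruskal-Wallis tests compare cognitive
   scores (which are typically non-normal); Benjamini-Hochberg FDR
   correction is applied within each family.
5. **Mediation.** Dependent and mediating variables are residualized
   against nuisance covariates (sex, age, other substance use), then a
   recursive path model — group membership acting on each network's
   efficiency, efficiencies acting on cognitive scores, plus direct
   group-to-score paths — is fitted by maximum likelihood, trimmed by
   backward elimination of nonsignificant paths, and the surviving
   indirect effects are tested with nonparametric bootstrap percentile
   confidence intervals.

Because cohort-level fMRI data of this kind are rarely public, the package
ships a first-class synthetic cohort generator with *planted* ground truth
at both ends of the pipeline: a known block-correlation structure in the
time series and a known structural model behind the cognitive scores.
Every stage can therefore be validated by recovery of known quantities,
which is what the test suite does.

## The wavelet stage

The MODWT is the undecimated variant of the discrete wavelet transform:
all coefficient series keep the length of the input, which is what makes
cross-regional correlation of coefficients straightforward. We implement
the standard pyramid algorithm with circular (periodic) boundary
treatment: at stage *j* the LA(8) filters, rescaled by 1/sqrt(2) per
stage, are applied with taps spaced 2^(j-1) samples apart. Perfect
reconstruction (`imodwt()`), the additive multiresolution decomposition
(`modwt_mra()`), and exact energy preservation are verified to
floating-point precision in the tests.

Two conventions are worth making explicit:

* **Boundary coefficients.** Circular filtering mixes the two ends of the
  series in the first (2^j - 1)(L - 1) coefficients of level *j*. They are
  *retained* by default — for T = 500 and level 4 they are a fifth of the
  series, and discarding them discards real signal; published analyses in
  this lineage typically keep them. `wavelet_band_series(...,
  drop_boundary = TRUE)` excludes them for sensitivity analyses.
* **Six levels by default.** With T = 500 the transform supports up to
  floor(log2 500) = 8 levels; six are computed by default so that the
  smooth series captures drifts below ~0.011 Hz, and the level of interest
  (4) sits well inside the decomposition.

Confound regression (OLS residualization of each region on an intercept
plus the confound columns) runs *before* decomposition when confound
tables are supplied, matching the usual preprocessing order.

## The synthetic cohort generator

The generator's defaults describe the study design the pipeline targets:
30 consumer (IC) and 27 control (HC) adolescents; a 264-region
parcellation with DMN/SN/FPN blocks of 58/18/25 regions; T = 500 volumes
at TR = 0.72 s; ages 12-17; a sex ratio of ~80% vs ~59% male; months of
other-substance use in the consumer group only.

**Connectivity structure.** Each subject's series is a T-sample draw from
a multivariate normal whose correlation is `rho_within` for pairs inside
the same named network (0.60 for HC, 0.35 for IC by default — the planted
consumer deficit), `rho_between = 0.1` elsewhere. This block matrix is
positive definite whenever `0 <= rho_between <= rho_within < 1`, and the
generator refuses to sample otherwise.

**Band limiting.** The draw is then shaped in the frequency domain by a
zero-phase filter with unit gain inside the level-4 band and a constant
floor gain elsewhere, chosen so that the band carries 50% of the expected
power (`band_power = 0.5`). Because the same filter acts on every region,
the cross-regional correlation structure is preserved exactly in
expectation. The floor matters: real BOLD signals have broadband content,
and a brick-wall filter of one-sixteenth bandwidth would reduce the
effective sample size of a correlation estimate to roughly T/16 —
at T = 500 the estimates would be so variable (SD about 0.18 under the
null) that correlation recovery would be meaningless. With the 50% floor
the effective sample size is about 0.23 T, the band still dominates any
other octave by an order of magnitude, and empirical correlations
converge to their targets (the tests verify |mean r - rho| < 0.05 at
T = 4096 and null correlations below 0.1 at T = 500).

**Cognition.** Cognitive scores follow a linear structural model
`score = c * group + b * efficiency + noise`, where `efficiency` is a
*planted construct* `a * group + noise` (default a = -0.55, i.e. the
group explains ~30% of its variance), not the downstream measured
efficiency. This makes the planted indirect effect exactly `a * b` and
keeps ground truth independent of the graph pipeline; the full-pipeline
tests use measured efficiency instead and accept the resulting
attenuation. Default score coefficients plant direct-only effects on two
scores (working memory, card sorting: c = -0.53 and -0.58, b = 0) and
mediated-only effects on two (Stroop, tower task: b = 0.4, c = 0),
mirroring the adjusted-model topology such studies report. Sex, age, and
other-substance months are nuisance-only and carry no planted effect.

**What the generator does not emulate:** spatial autocorrelation within
networks, head-motion artifacts, scanner drifts and physiological noise
spectra, hemodynamic response shapes, and inter-subject variability in
connectivity strength. Passing recovery tests therefore demonstrates the
*correctness of the estimators*, not robustness to every artifact of real
data.

## Graph construction choices

* **Edge count** is round-half-up of `density * R(R-1)/2` (so 5% of the
  34,716 pairs of a 264-node graph is 1735.8 -> 1736).
* **Ranking** is by signed correlation by default (the strongest positive
  couplings form the network); ranking by absolute value is available
  (`mode = "absolute"`) since treatments of negative correlations differ
  across the literature.
* **Ties** at the cutoff are broken by lexicographic (i, j) order, making
  binarization fully deterministic.
* No Fisher z-transform is applied before ranking: it is monotone, so the
  retained edge set would be identical.

## Efficiency conventions

Shortest paths are breadth-first-search hop counts (via igraph);
unreachable pairs have infinite distance and contribute zero efficiency —
no largest-component restriction is applied. Subnetwork efficiency is
computed on the **induced subgraph** by default: E_s then measures
information exchange *within* the subnetwork and not routes through the
rest of the brain. The alternative reading — whole-graph distances with
endpoints restricted to members (`mode = "restricted"`) — is provided for
sensitivity analysis; induced-mode E_s is never larger than
restricted-mode E_s, and both are validated against a literal evaluation
of the defining formula over Floyd-Warshall distances.

## The path-model machinery

For recursive (acyclic) models among observed variables with complete
data and no cross-equation constraints, the maximum of the multivariate-
normal likelihood is attained exactly at the equation-by-equation OLS
solution; `fit_path_model()` computes that solution in closed form and
then evaluates the ML discrepancy
F_ML = ln|Sigma(theta)| - ln|S| + tr(S Sigma^-1) - p at the optimum for
the chi-square test of exact fit ((n-1) F_ML), CFI (against the
independence baseline), and RMSEA. The test suite confirms on random
models that a direct numerical minimization of F_ML lands on the same
estimates. This design keeps a single fit cheap (one covariance matrix
and a few small linear solves), which is what makes large bootstrap and
replication studies practical.

Parameter accounting: free parameters are the path coefficients, one
residual variance per endogenous variable, and the full covariance block
of the exogenous variables; df = p(p+1)/2 minus that count, so a
saturated recursive model has df = 0, chi-square ~ 0, RMSEA = 0.

Other choices, and why:

* **Residualization** (rather than including covariates in the model)
  follows the two-step practice of regressing nuisance variables out of
  the dependent and mediating variables before path analysis.
* **Trimming** is backward elimination only: refit, drop the single
  least-significant path with p > alpha (ties broken lexicographically),
  repeat. Modification indexes for *adding* paths are out of scope. The
  initial endogenous/exogenous designation is preserved while trimming,
  so each removal frees exactly one parameter and df strictly increases.
* **Bootstrap CIs** are percentile intervals from case resampling,
  bit-reproducible under (seed, n_boot); replicates with singular
  resampled covariances are dropped and counted, with more than 5%
  failures treated as an error. Percentile rather than BCa is the
  default because the simpler interval's coverage is verified directly in
  the acceptance suite (empirical coverage of the planted indirect effect
  falls in [0.90, 0.98] at n = 200 with 1000 replicates).
* **Group coding** is a 0/1 indicator (consumer = 1).

## Numerical and degenerate-input conventions

* Correlations are clamped to [-1, 1]; constant regions are an error
  naming the offending region id.
* Two groups with zero variance and equal means give t = 0, p = 1 rather
  than an error; an all-identical Kruskal-Wallis input gives H = 0, p = 1.
* Chi-square 2x2 tests apply the Yates continuity correction by default
  (the package's demographic tables are small); `yates = FALSE` gives the
  raw Pearson statistic.
* The sample covariance in path fitting uses the ML divisor n; per-path
  standard errors use the per-equation OLS residual df (n - k - 1).
* All randomness flows from explicit seeds: a cohort seed deterministically
  derives per-subject seeds, and the same configuration reproduces every
  artifact byte for byte.

## Validation problem sizes

The test suite validates the cohort-level operating characteristics at a
deliberately desk-sized scale: an 88-region parcellation with
Power-atlas-proportional networks (DMN 19, SN 6, FPN 8), 30 + 27
subjects, T = 500, 50 simulation seeds per condition. At this scale the
type-I error of the FDR-corrected DMN comparison stays at or below the
nominal rate under a null cohort, and the planted within-network
correlation deficit (0.35 vs 0.60) is detected in at least 90% of seeds.
Mediation calibration uses 20 datasets of n = 2000 for estimation
accuracy and 300 replicates of n = 200 with 1000 bootstrap draws for CI
coverage. The package defaults remain at the full 264-region scale.

## Known limitations

* The pipeline consumes already-extracted ROI time series; no volumetric
  preprocessing (registration, motion correction, CompCor estimation) is
  included. `extract_roi_timeseries()` is a convenience for mean-signal
  extraction from preprocessed volumes only.
* Kruskal-Wallis with two groups is retained as such (it is equivalent to
  a Mann-Whitney test up to the chi-square reference distribution); no
  automatic normality-based test switching is performed.
* Binary, fixed-density graphs only: no weighted-graph metrics, no
  significance-based thresholding, no clustering/modularity measures.
* Observed-variable path models only: no latent variables, mean
  structure, missing-data FIML, or multi-group SEM.
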