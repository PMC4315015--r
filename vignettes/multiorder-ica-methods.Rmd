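---
title: "Multi-order group ICA subnetwork analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-order group ICA subnetwork analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Resting-state fMRI decomposes, via spatial independent component analysis
(ICA), into networks of regions with coherent spontaneous BOLD fluctuations.
The *model order* D — the number of components extracted — acts as a zoom
level: at low D (a few tens of components) one recovers the canonical
resting-state networks (default-mode, sensory-motor, ...); at high D those
networks split into subnetworks. Group differences in functional
connectivity can be confined to individual subnetworks, so a
high-dimensional decomposition can localize alterations that a
low-dimensional analysis blurs away — provided the subnetworks can be
related automatically and reproducibly to the networks they belong to.

`subnetica` implements that workflow end to end:

1. group spatial ICA of temporally concatenated multi-subject data at two
   model orders;
2. dual regression to obtain subject-specific time series and spatial maps;
3. an automatic spatio-temporal labeling rule assigning each high-D
   component to a low-D reference network (or to residual-noise/unknown
   classes);
4. temporal statistics — per-component time-series amplitude and
   full-correlation network matrices (netmats) on the Fisher-z scale — with
   permutation max-|t| family-wise error control;
5. spatial statistics — voxelwise group comparison of stage-2 maps with
   cluster-extent inference against the permutation null of the maximum
   cluster size.

Because no subject-level scan data accompany this package, a synthetic
multi-subject BOLD generator with planted hierarchical networks and group
effects provides the study conditions under which every stage is tested.

# The synthetic generator

## Model

A scene is a set of parent networks, each a list of subnetworks with compact
spatial footprints (Gaussian-tapered balls: weight 1 within `radius_mm` of
the center, Gaussian decay with scale `softness_mm` outside). Subnet time
courses follow a one-factor model per parent:

$$x_i(t) = c_i \, P(t) + \sqrt{1 - c_i^2}\; U_i(t),$$

where the parent signal $P$ and the unique signals $U_i$ are independent
unit-variance stationary AR(1) processes and $c_i \in [0, 1]$ is the
*parent coupling*. Every course has unit variance and two subnets of one
parent correlate as $c_i c_j$ exactly — this is why the factor form was
chosen over an additive "parent + noise" form, whose correlation would be a
nonlinear function of the coupling. Subject data are
$\sum_i \text{map}_i \otimes x_i + \varepsilon$, with
$\varepsilon \sim N(0, \sigma^2)$ i.i.d. white noise.

Group B (the "patient" group) modifies designated subnets in two ways:

* **amplitude**: the course is multiplied by `group_amplitude_ratio`
  (default 0.7), so the planted amplitude effect is exactly that ratio in
  population value;
* **coupling**: the effective coupling becomes
  $\max(c_i - \delta, 0)$ with `group_coupling_delta` $\delta$ (default
  0.2), lowering within-parent correlations on every edge touching an
  affected subnet.

## Parameters and defaults

| parameter | default | unit | rationale |
|---|---|---|---|
| grid | 24 x 24 x 16 | voxels (3 mm) | desk-scale analog of a whole brain |
| volumes / TR | 160 / 2.5 | – / s | typical 6-7 min resting acquisition |
| subjects | 20 per group | – | typical clinical rfMRI cohort |
| parents / subnets | 3 / (2, 3, 2) | – | posterior DMN, anterior DMN, sensory-motor analog |
| AR(1) coefficient | 0.3 | – | BOLD-like temporal autocorrelation; white noise would make permutation tests unrealistically well behaved |
| parent coupling | 0.8 | – | within-network correlation around 0.64, realistic for subnetworks of one network |
| noise SD | 1 | signal units | signal-to-noise of order 1 at blob cores |
| amplitude ratio | 0.7 | – | moderate, clearly detectable at n = 20 + 20 |
| coupling delta | 0.2 | – | drops a within-parent correlation from 0.64 to 0.48 (one end affected) or 0.36 (both ends) |

The affected subsets (amplitude: P1.1 and P2.2; coupling: P2.2, P3.1,
P3.2) deliberately leave unaffected subnets and null edges in place so both
power and specificity are measurable.

## What the generator does not emulate

Head motion, physiological noise, scanner drift beyond AR(1), registration
error, anatomical variability between subjects, non-Gaussian noise, and
spatially correlated noise (spatial correlation enters only through the
smoothing step). Passing tests therefore demonstrate correctness of the
algorithms under controlled, favorable conditions — not robustness to the
artifact structure of real scanner data, which upstream cleaning
(motion correction, ICA denoising, registration) is assumed to have handled.

# Preprocessing

Two steps remain meaningful on clean synthetic data: isotropic Gaussian
smoothing (default FWHM 5 mm, applied separably per axis with
$\sigma_\text{vox} = \text{FWHM} / (2\sqrt{2\ln 2}) / \text{voxel size}$,
reflecting at boundaries so interior mass is conserved) and temporal
high-pass filtering (default cutoff 0.01 Hz). The filter is a zero-phase
forward-backward order-4 Butterworth with steady-state initialization and
odd edge extension; the finite-length residual mean is removed afterwards,
so filtered series are exactly zero-mean. A Butterworth was chosen over a
Gaussian-weighted running-line detrend because its frequency response is
standard and closed-form — `highpass_gain()` exposes it, and the tests probe
the implemented response (gain above 0.95 at 0.05 Hz, below 0.5 at
0.002 Hz) rather than equivalence with any external tool. Variance
normalization is deliberately absent: amplitude analysis downstream is
defined on the raw scale.

# Group ICA

Subjects are demeaned voxelwise and temporally concatenated (variance
normalization optional, off by default). The stacked (time x voxel) matrix
is reduced to D dimensions by PCA on the time-by-time covariance and
whitened; spatial sources are then estimated by fixed-point ICA with the
logcosh contrast and symmetric decorrelation (tolerance 1e-6, up to 1000
iterations, best of 3 random restarts by the summed negentropy proxy;
deterministic given the seed). The PCA does not depend on D and is cached on
the concatenated-data object, so low- and high-order decompositions of one
dataset share the expensive step.

Numerical conventions:

* maps are z-scored over the mask (demeaned, unit variance) rather than
  given mixture-model z-scores — monotone-equivalent for thresholding and
  far simpler;
* each map is sign-fixed to positive voxel-value skewness (spatial sources
  are sparse-positive), with its mixing column negated in step; zero skew is
  left untouched;
* the mask defaults to voxels with nonzero variance, since synthetic grids
  have no anatomical mask;
* the model orders in tests are the scene's own dimensions (3 parents /
  7 subnets); larger orders for real data are plain arguments.

# Dual regression

Stage 1 regresses every volume simultaneously onto the demeaned group maps,
returning coefficient time series *on the raw scale* — their sample SD is
the amplitude measure, which any normalization would destroy. Stage 2
regresses each voxel's series onto all stage-1 courses; by default the
design columns are scaled to unit variance (`des_norm`), so per-component
amplitude is absorbed into the maps, matching common practice. Stage-2
outputs are raw regression coefficients, not t-maps; the spatial group
comparison operates on these coefficients.

# Labeling rule

For high-D component $i$ and low-D reference $j$, the spatial evidence
$DC_{ij}$ is the Dice coefficient between the positive-tail binarized maps
(default pseudo-z > 3; the threshold is configurable since no single
convention exists) and the temporal evidence $TC_{ij}$ is the Pearson
correlation between their stage-1 series, averaged arithmetically across
subjects (a Fisher-z average is available by flag; the arithmetic mean is
the default to follow the rule's plain formulation). With
$j_s = \arg\max_j DC_{ij}$ and $j_t = \arg\max_j TC_{ij}$:

* **noise** if $\max_j DC_{ij} < 0.1$ **or** $\max_j TC_{ij} < 0.4$
  (the OR reading is the stricter interpretation of "all $DC_{ij}$ or
  $TC_{ij}$ below threshold"; an AND variant is available by flag);
* **unknown** if $j_s \neq j_t$;
* otherwise the component is labeled $j_s$.

Ties break toward the lowest reference index and are logged. Negative
correlations are not clipped — the argmax runs over signed values. Noise
and unknown components are excluded from all downstream analyses.

# Group statistics

**Temporal.** Amplitude is the sample SD (n−1) of the raw stage-1 series.
Netmats are full Pearson correlations between component series, with |r|
capped at 1 − 1e−7 before the Fisher transform so noiseless synthetic cases
stay finite. Group comparison uses the pooled-variance two-sample t
statistic (Welch by flag) with p-values from the permutation distribution
(observed labeling always included, so p ≥ 1/n_perm): each test's own |t|
null for uncorrected p, and the maximum |t| within the declared family for
FWE-corrected p. Families mirror the analysis structure: one family across
components at low D, one family per parent network across its subnetworks
at high D, and within-network vs between-network edge families for netmats.
Permutation max-statistic correction was chosen because it is
assumption-light and exact under exchangeability; with fewer distinct group
labelings than requested permutations the test enumerates all of them.

**Spatial.** Per component, the one-sided pooled-t map of stage-2
coefficients is thresholded at the t-value whose one-sided p equals the
cluster-forming threshold (default 0.05, df = n_A + n_B − 2); connected
components at 26-connectivity (configurable) are measured by extent, and
each observed cluster's FWE p is the proportion of permutation maximum
cluster sizes at least as large. Cluster *size* (not mass, no TFCE, no
variance smoothing) is the statistic, and the image smoothness is whatever
preprocessing induced. An optional Bonferroni across components' minimum
corrected p-values is off by default.

# Problem sizes in tests and the acceptance script

The package's own test conditions: the full default scene (40 subjects,
160 volumes, 24 x 24 x 16) is analyzed once for the model-order and
labeling properties; amplitude and netmat power/specificity use 100–200
simulated cohorts at the time-course level (the statistics operate on
stage-1 series, so re-running ICA per replicate would test nothing new);
FWE calibration uses 500–1000 null replicates with 500 permutations each
(temporal: families of 5 tests at n = 20 + 20; spatial: 16 x 16 x 12
grids); determinism re-runs the full pipeline on a reduced configuration,
since reproducibility does not depend on scene size.

# Known limitations

* Cluster-extent inference has limited power for very small foci: the null
  maximum cluster size grows with the search volume, so an 8-voxel effect
  that is detectable on a small grid can be non-significant on a large one.
  This is a property of the method, not of the implementation.
* The pooled-variance t is exchangeable under the global null but only
  approximately valid when group variances differ; the Welch flag exists
  for that case.
* Arithmetic averaging of correlations across subjects slightly biases
  |TC| downward relative to the Fisher-z average; with the default 0.4
  threshold the two agree on all tested scenes.
* The ICA sign convention (positive skew) can in principle flip a genuinely
  symmetric map; on sparse-positive spatial sources this does not occur.
* Amplitude comparisons assume subjects within a group share the generative
  amplitude; real cohorts add between-subject variance that would lower
  power relative to the synthetic estimates reported here.
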