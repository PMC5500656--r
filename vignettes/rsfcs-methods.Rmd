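---
title: "Functional connectivity strength mapping: model, phantoms, and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional connectivity strength mapping: model, phantoms, and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsfcs)
```

## The measure

Resting-state functional connectivity strength (FCS) is a voxel-wise weighted
degree-centrality measure. For gray-matter voxel $i$ with preprocessed BOLD
series $x_i$, let $r_{ij}$ be the Pearson correlation with voxel $j$. Then

$$\mathrm{FCS}(i) \;=\; \sum_{j \neq i,\; r_{ij} > \theta} \operatorname{arctanh}(r_{ij}),$$

with correlation threshold $\theta = 0.2$ by default (0.1 and 0.3 as a
robustness sweep). Negative and sub-threshold correlations contribute
nothing; the threshold comparison is strict. The sum is partitioned by the
Euclidean mm-distance between voxel centers (affine-transformed indices):
pairs beyond 75 mm form the *long-range* FCS, pairs below it the
*short-range* FCS. Pairs at exactly the cutoff — reachable on a 3 mm grid,
e.g. the offset (45, 60, 0) — are assigned to short range so that
long + short = global holds exactly at every voxel. Correlations are clipped
to $\pm(1 - 10^{-7})$ before the Fisher transform so duplicated series
cannot produce infinities; clip and tie counts are reported in the map
metadata.

FCS sums are not normalized by the number of voxels: the measure is a sum,
so its scale depends on the mask. All comparisons in the package are within
one mask, where this is immaterial.

## Subject-level preprocessing

The fixed stage order is: discard the first 10 volumes (signal
equilibration), motion QC, nuisance regression, optional linear detrend,
ideal band-pass. Motion QC excludes a subject when any axis *strictly*
exceeds 2 mm translation or 2 degrees rotation; a maximum of exactly 2.0
passes. The nuisance model has 14 regressors — six motion parameters, their
backward-difference derivatives (first row zero), and the mean white-matter
and CSF signals — plus an intercept; the global mean signal is never
included. Residuals are exact least-squares residuals, orthogonal to every
regressor. The band-pass is an ideal discrete-Fourier filter: bins with
frequency in [0.01, 0.08] Hz (inclusive edges) are kept, everything else —
including the mean — is zeroed. As a projection it is idempotent, which the
tests verify. Whether regression should precede filtering is a genuinely
open choice in this literature; the package fixes regression-then-filter
and records it, since the filter is idempotent and the regressors are not
re-filtered.

Regression and filtering operate on the analysis-mask voxels only
(gray-matter probability > 0.3); voxels outside the mask are untouched.

## The phantom generator

Every downstream stage is validated on synthetic 4D cohorts with known
structure. Voxels are organized in disjoint *blocks*, each driven by one
latent Gaussian signal: a block voxel is
$\sqrt{w}\, s_b(t) + \sqrt{1-w}\,\varepsilon(t)$ with $w$ the target
within-block correlation, so two voxels of one block correlate at $w$ and
voxels of different blocks at $w \cdot C_{bc}$, where $C$ is the latent
correlation matrix (checked positive definite; the generator refuses a
spec that breaks this and names the offending eigenvalue). Latent series
come from a Cholesky factor applied to i.i.d. innovations and are exactly
standardized, so the expected sample correlation equals the target.

A planted group effect multiplies the hub block's between-block latent
correlations by $(1-\delta)$ in group 2 (patients). Which partners are
affected is classified by hub-to-partner centroid distance against the
75 mm cutoff, so an effect can be made purely long-range, purely
short-range, or both. A per-subject connectivity scale
$(1 + \sigma_s u_i)$, $u_i \sim N(0,1)$, creates individual differences
for correlation-recovery experiments.

Realism features and their limits:

* a shared slow scanner drift is added to every voxel. Its frequency is
  placed on a Fourier bin of the *retained* (post-discard) window,
  $2/(170 \cdot \mathrm{TR})\approx 0.006$ Hz, so the ideal filter removes
  it exactly. An off-bin drift leaks coherent power into the pass band and
  shifts every pairwise correlation above target — with a bin-locked drift
  the generator's correlation contract survives preprocessing.
* border voxels are marked non-gray (probability 0.1 vs 0.9 inside) and
  carry shared WM/CSF compartment signals, so masking and nuisance
  extraction do real work.
* motion traces are smooth random walks; QC-failing subjects get a 2.5 mm
  spike planted at a known sample.
* the clinical table mirrors a diabetes-cohort layout: matched age, gender
  and education, a large HbA1c/FBG group contrast, and cognition scores
  with no group difference.

The phantoms do **not** emulate spatial autocorrelation of measurement
noise, scanner artifacts, physiological cycles, hemodynamic autocorrelation
(an AR(1) option exists in principle but correlation-based metrics only see
wider nulls), or any claim about real brain topology — the block design is
a device for ground truth, not a model of the brain. Passing tests
demonstrate the *pipeline's* statistical behavior under known structure,
not performance on real data.

### Canonical study conditions

Three preset cohorts fix the conditions used by the test suite and the
acceptance script:

* `preset_null(seed)` — 12³ voxels at 3 mm, 8 + 8 subjects, 180 volumes at
  TR 2 s, three blocks, no effect. At this desk-scale geometry no voxel
  pair exceeds 75 mm, so the long-range map is identically zero and
  family-wise error is evaluated on the short-range contrast. (Full-scale
  brain grids are a config option, not a test requirement.)
* `preset_long_effect(seed)` — an elongated 36×10×10 grid (105 mm along x)
  hosting a hub block and three partner blocks of edge 4, every hub–partner
  pair separated by > 75 mm; voxel correlations 0.7 within / 0.5 between,
  and a 50% reduction of all hub–partner correlations in patients. Several
  partners matter statistically, not just anatomically: each partner has
  its own latent signal, so the hub's long-range FCS averages independent
  latent-correlation sampling noise across partners instead of riding on a
  single shared scalar — with one partner the whole block's T statistic
  rises and falls coherently and detection becomes all-or-nothing. The
  planted deficit is purely long-range; within-block and partner–partner
  correlations are identical across groups, so the short-range contrast
  should stay silent.
* `preset_coupled(seed)` — 10³ grid, 50 + 50 subjects, with the hub's
  connectivity scale varying across subjects and HbA1c drawn coupled to
  it. The coupling target (−0.4) refers to the correlation with the
  *measured* hub FCS; because a 170-volume FCS estimate is an attenuated
  readout of the latent (attenuation ≈ 0.775 for this design, from the
  sampling noise of the latent correlations plus within-block and
  background FCS variance), the latent mixing weight is scaled by that
  factor. The attenuation was quantified once when the design was fixed
  and is not a per-run tuning knob. Recovery means the ROI battery flags
  the hub-ROI × HbA1c pair negative and significant in at least one group
  — the coupling is planted in both.

## Group inference

Maps are smoothed (6 mm FWHM Gaussian, zero padding, no mask
renormalization — matching common practice when maps are computed
unsmoothed and smoothed afterwards) and entered into a voxel-wise OLS with
intercept, group (patient = 1), age, gender (male = 1) and education. The
group contrast with this coding makes "patients weaker" a *negative* T.
With only intercept and group the statistic reduces exactly to the
pooled-variance two-sample t, which the tests check to 1e−10. Voxels whose
maps are constant across subjects (e.g. an identically zero long-range map)
get T = 0 rather than 0/0.

### Smoothness estimation

Cluster correction needs the residual fields' smoothness. The package uses
the difference-variance estimator on standardized GLM residuals: per axis,
$\hat\rho = 1 - \overline{d^2} / (2\,\overline{v^2})$ over in-mask neighbor
pairs (the denominator uses the realized mean square, since columns
standardized with the $n-1$ convention have mean square $(n-1)/n$), and

$$\mathrm{FWHM} = \Delta x \sqrt{\frac{2\ln 2}{1-\hat\rho}}.$$

This is the *field* smoothness: spatially independent voxels give
$1.18\,\Delta x$ (the lattice's own resolution), and noise smoothed with a
known kernel recovers the composed kernel + lattice truth. A continuous-ACF
variant ($-\ln\hat\rho$ in the denominator) degenerates to 0 for white
noise and was rejected for that reason. When residuals are unavailable the
same estimator runs on the T map itself.

### Monte-Carlo cluster-extent correction

The null distribution of the maximum suprathreshold cluster size is
simulated: white noise on the grid is smoothed so that its lattice lag-1
autocorrelation *exactly* matches $\hat\rho$ (the kernel width is solved
numerically per axis — this inversion makes estimate→simulate
self-consistent and reduces to the classical continuous formula for smooth
fields), restandardized within the mask, thresholded two-sided at
voxel p = 0.001, and clustered. "Edge connected" is read as the
faces + edges neighborhood (18-connectivity); 6 and 26 are options. The
minimum extent is the smallest $k$ with
$P(\max \text{extent} \ge k) \le \alpha$ at $\alpha = 0.05$; the simulated
distribution also supplies per-cluster p-values. 1000 simulations is the
default; the operating-characteristic tests use 200 for speed. Extent is
non-decreasing in voxel p and non-increasing in $\alpha$.

Clusters are extracted separately per sign at the t-quantile matching the
simulation's z-threshold probability. Peaks are reported in mm through the
affine, mirroring a standard cluster table (region, peak, extent, peak T).

## Seed-based follow-up and ROI statistics

Seeds are 6 mm-diameter spheres at significant-cluster peaks; membership is
inclusive at the boundary, so on a 3 mm grid a seed centered on a voxel
holds 7 voxels (center + face neighbors at exactly 3.0 mm). The seed signal
is the unweighted mean of member voxels (the usual convention; the source
toolchains do not state an alternative); maps are
$\operatorname{arctanh}$-transformed correlations, computed on the same
preprocessed series as the FCS stream and smoothed identically before
inference.

ROI values are cluster means. The clinical battery computes, per group,
partial correlations (residual correlations after OLS on age, gender,
education; p from the t approximation on $n-2-k$ df), Bonferroni-adjusts
within the ROI × variable family (the family size is printed so users can
re-family), and compares groups with the Fisher r-to-z test
$z = (\operatorname{arctanh} r_1 - \operatorname{arctanh} r_2) /
\sqrt{1/(n_1-3) + 1/(n_2-3)}$. Published applications of this comparison
sometimes print z-values that the standard formula does not reproduce from
the printed r and n; this package implements the standard formula only.
Demographics tests follow the usual gate: Lilliefors normality per group,
pooled-variance t when both pass, Mann-Whitney (normal approximation, no
continuity correction) otherwise; gender uses Pearson's chi-squared without
continuity correction — the uncorrected statistic is what matches the
conventional reporting for 2×2 cohort tables (e.g. 25/28 vs 29/26 gives
$\chi^2 = 0.333$, p = 0.564).

## Numerical and scale choices

* Degenerate inputs error early with informative messages: non-positive
  definite correlation targets name the smallest eigenvalue, empty seed
  intersections name the nearest mask voxel, rank-deficient designs name
  the collinear column.
* Zero-variance voxels are dropped from the mask with a message before any
  correlation is formed.
* The operating-characteristic checks run at deliberately compact sizes —
  100 null cohorts (12³, 8+8), 10 planted cohorts (36×10×10, 8+8), 50
  coupled cohorts (10³, 50+50), 200 Monte-Carlo simulations — chosen so the
  whole suite completes on a laptop-class single core while the binomial
  noise of the measured rates stays well inside the asserted bands. The
  acceptance script uses 50/10/30 cohorts for the same quantities.
* Full determinism: every cohort is a function of its spec (including the
  seed), every Monte-Carlo stage draws from a seeded generator restored
  afterwards, and rerunning a pipeline config reproduces cluster tables
  bit for bit.

## Known limitations

* The Monte-Carlo correction assumes stationary Gaussian-kernel-like
  autocorrelation; block-structured phantom residuals are only
  approximately of this form. The null calibration test measures the
  realized family-wise error directly and keeps it inside [0.01, 0.10].
* The partial-correlation p uses the t approximation, not permutation.
* No slice-timing, realignment, or spatial normalization: inputs are
  assumed already in a common space, as the phantoms are by construction.
* Long-range FCS requires a grid that can host > 75 mm pairs; on smaller
  grids the long map is identically zero and is skipped by inference with
  a note rather than producing 0/0 statistics.
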