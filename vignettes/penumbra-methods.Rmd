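---
title: "Methods: wavelet Hurst mapping, peritumoral gradients, and network robustness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wavelet Hurst mapping, peritumoral gradients, and network robustness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`penumbra` quantifies how a focal brain tumor perturbs the temporal
complexity of resting-state BOLD signal as a function of distance from the
lesion, and how that complexity relates to functional-network structure.
The pipeline consumes co-registered volumes on a single voxel grid — a 4D
BOLD series, a tissue segmentation, a binary tumor mask, and optionally a
parcellation — and produces: a voxelwise Hurst exponent map, a peritumoral
annulus profile of homologous-region H ratios, parcel-level connectomes
with centrality and synthetic-lesioning metrics, and AIC-ranked
distance-gradient model fits. Upstream acquisition, denoising,
segmentation, and registration are explicitly out of scope: inputs are
assumed registered to a bilaterally symmetric reference space whose
mid-sagittal plane is world $x = 0$.

## Hurst estimation

Each voxel series is decomposed with a maximal-overlap discrete wavelet
transform (MODWT, Daubechies wavelet with 8 vanishing moments, periodic
boundary), which is shift-invariant and yields one detail series per scale
$j = 1,\dots,J$ (default $J = 5$). The per-scale wavelet variance
$\nu_j^2$ is estimated from boundary-free coefficients only (the standard
unbiased MODWT estimator) and rescaled by $2^j$, the normalisation in
which white noise has a flat variance-versus-scale profile. For
fractional Gaussian noise the log-variance is then linear in scale with
slope $\gamma = 2H - 1$, so an ordinary least-squares fit of
$\log_2 \nu_j^2$ on $j$ gives

$$H = \frac{\gamma + 1}{2}, \qquad D = 2 - H,$$

with $H = 0.5$ the white-noise reference and $D$ the fractal dimension.
Maps are thresholded at $H < 0.5$: voxels indistinguishable from white
noise are marked invalid and *excluded* from all downstream averages
(annulus, parcel, tissue), not clamped — the alternative reading of the
thresholding step; exclusion was chosen because values are extracted after
thresholding.

Two numerical consequences of the boundary-exclusion rule are worth
stating. At the emulated acquisition length (269 volumes) the level-5
equivalent filter (466 taps) exceeds the series, so scale 5 carries no
boundary-free coefficients and the regression automatically uses scales
1–4, with a warning. And the estimator's sampling SD at that length is
$\approx 0.14$; at $n = 1024$ (used for estimator-precision tests) all
five scales contribute and the SD drops to $\approx 0.05$, with mean bias
under 0.02 across $H \in [0.55, 0.85]$.

A known, deliberate limitation: subsampling an fGn series changes its
short-lag covariance even though the asymptotic power law is preserved, so
decimation shifts the estimate down systematically (about 0.1 at
$H = 0.8$); the tests assert a bounded shift rather than exact
scale-invariance.

## Peritumoral annuli and mirroring

The tumor mask is dilated in 2-mm metric increments to 30 mm and each
dilation minus its predecessor forms an annulus; equivalently, annulus $k$
contains the voxels whose Euclidean distance to the nearest tumor voxel
(computed with an exact separable squared-distance transform in world mm,
so anisotropic voxels are handled) lies in $((k-1)\cdot 2, k\cdot 2]$.
Annuli are intersected with grey matter, and each is reflected across the
interhemispheric fissure by nearest-voxel lookup (an exact involution on a
symmetric grid). The profile reports, per band, the mean valid H
ipsilaterally and in the mirrored annulus, and their ratio — the
homologous-region ratio. Band distance is reported at the band midpoint
(inner edge + 1 mm); the inner/outer-edge alternatives differ only by a
horizontal shift that the gradient models absorb into their coefficients.
Midline tumors (mask overlapping its own mirror) are rejected, matching
the lateralised lesions this analysis is designed for.

## Parcellation and connectomes

The randomized template partitions grey matter into `n_parcels` (default
256) connected, near-equal parcels: k-means seeds on world coordinates,
then balanced region growing (always extend the currently smallest
parcel), per hemisphere so every parcel is unilateral. Any user-supplied
integer-label NIfTI is accepted in its place; anatomical atlas templates
(e.g. 251-parcel equal-size atlases) are typically not redistributable,
so the bilateral generated template stands in for them in tests. Parcels overlapping the
tumor by at least one voxel are flagged removed (ids are never
renumbered); homologues are paired by mutual-nearest mirrored centroids;
node–tumor distance is centroid-to-centroid in mm.

Connectomes are built from mean parcel time series by Pearson correlation,
partial correlation, or Pearson correlation of MODWT detail coefficients
at a chosen scale (default 2, the band containing slow resting-state
fluctuations at TR = 2.42 s). Partial correlations invert a
shrinkage-regularised covariance (Ledoit–Wolf-style scaled-identity
target) because with ~250 parcels and ~270 timepoints the sample
covariance is near-singular. Negative correlations are set to zero edge
weight and no other threshold is applied, so matrices stay fully
connected in the retained-edge sense.

## Graph metrics and synthetic lesioning

Node strength, nodal efficiency (the node's mean inverse shortest-path
length), betweenness, within-module degree z-score, participation
coefficient, and eigenvector centrality are computed with edge length
$1/w$ for path-based measures. When no module partition is supplied, a
fixed-seed modularity-maximisation (Louvain) partition is computed and
recorded. Global efficiency is the mean inverse shortest-path length over
ordered pairs, unreachable pairs contributing zero. Delta efficiency
lesions one node and reports the percentage change of global efficiency;
by default the lesioned efficiency is computed on the reduced
$(n-1)$-node graph, with the keep-as-isolate alternative available as a
configuration switch since either reading of "removing a node" is
defensible. Metrics are z-scored across kept nodes and expressed as
contralateral homologue ratios where pairing exists.

## Gradient models and statistics

Five families are fitted to value-versus-distance data by least squares:
polynomials of degree 1–3, $b\,e^{cd}$, and $a + b\,e^{cd}$. The
exponential families use bounded multi-start Levenberg–Marquardt (8 fixed
starts over the sign patterns of $b$ and $c$; $|c|$ bounded so the
exponential cannot overflow on the observed range). Fits are compared by
the Gaussian least-squares AIC, $n\ln(\mathrm{RSS}/n) + 2(k+1)$, counting
the noise variance as a parameter; the best model is the minimum-AIC
family, exact ties broken toward fewer parameters. An interpolating fit
(RSS at rounding level) is snapped to exactly zero so ties resolve by the
parameter-count rule rather than floating-point dust. $R^2$ is
$1 - \mathrm{RSS}/\mathrm{TSS}$ for every family, so values are
comparable across families on the same data.

Minimum-AIC selection among nested families has a known ceiling: with a
true quadratic signal, the cubic term's likelihood-ratio statistic is
$\chi^2_1$ under the null, so AIC prefers cubic with probability
$\approx 0.16$ regardless of noise level. Model-recovery simulations in
the tests sit at this ceiling (~84% quadratic recovery); a
parsimony-within-2-AIC rule would push recovery above 95% but was
rejected so that the reported best model is always the literal AIC
minimum, the convention this pipeline's fit tables follow throughout.

One-way ANOVA (tissue contrasts) is computed from the between/within
sums-of-squares decomposition; the cohort ANCOVA fits
`log H ~ cohort * distance` from the explicit design matrix with a
nested-model F test for the interaction and Bonferroni-corrected pairwise
slope contrasts. Metric–H correlations are product-moment with Bonferroni
correction over the number of metrics tested,
$p_{\mathrm{bonf}} = \min(1, m\,p)$.

# The phantom cohort

No patient imaging ships with the package, so a phantom generator
provides the study conditions end to end. Anatomy: two mirrored
box-shaped hemispheres (grey matter with a white-matter slab) separated
by a 6-mm mid-sagittal CSF gap, on a 48×40×40 grid of 2-mm voxels; a
6-mm-radius spherical tumor sits in right-hemisphere grey matter at
(37, 0, 0) mm, placed so that even the outermost 30-mm annulus stays
ipsilateral. Signal: every voxel with a defined ground-truth H carries
*exact* fractional Gaussian noise — synthesised by circulant embedding of
the fGn autocovariance, so the finite-sample covariance is matched in
distribution, and the non-negativity of the embedding spectrum is
verified rather than truncated. Ipsilateral grey matter follows
$H(d) = 0.632 + 0.02 d - 0.0005 d^2$ (clipped to (0.05, 0.95)) in
distance $d$ from the tumor margin: suppression below the 0.8 baseline
out to 12 mm, overshoot peaking at 0.832 near 20 mm, returning to
baseline by 28 mm. Contralateral grey matter is constant at 0.8; white
matter, CSF, and tumor carry fixed H of 0.65, 0.5, and 0.3. Series length
269 and TR 2.42 s mirror the emulated acquisition. The trough, peak, and
crossing distances were chosen once for testability — deep enough to be
detected through estimator noise at the acquisition length, shallow
enough that the profile stays well inside (0, 1).

What the phantom does *not* emulate: hemodynamic response structure,
physiological noise, motion, scanner drift, spatial autocorrelation of
the BOLD signal, or anatomical realism. Passing the phantom tests
demonstrates that the estimator, geometry, and statistics recover an
implanted effect under fGn noise of realistic length; it does not
establish sensitivity on real patient data.

One interaction surfaced by the phantom deserves emphasis because it is a
property of the *procedure*, not a bug: thresholding at $H < 0.5$
truncates the estimator's sampling distribution wherever true H is within
roughly one sampling SD of 0.5. Near the implanted trough
($H \approx 0.63$, SD $\approx 0.14$) about a sixth of voxels are
excluded, biasing band means upward by up to ~0.045, decaying smoothly
with distance. The observed ratio profile is therefore slightly
third-order even though the implanted field is exactly quadratic, and
minimum-AIC model comparison — sensitive at pooled-cohort sample sizes —
can prefer cubic over quadratic for exactly this reason. The suppression
and overshoot bands themselves are recovered robustly.

# Problem sizes and determinism

Every generator is a pure function of its spec, including the seed, and
the pipeline stamps each output with an FNV-1a fingerprint of its
configuration. Test problem sizes were chosen to exercise each claim at
the smallest scale that makes the statistics meaningful: estimator
calibration at $n = 1024$ with 200 replicates; annulus set-equality
against brute force on 64³ voxels; graph-metric oracle equivalence on 100
random graphs with $n \le 5$ (where exhaustive path enumeration is
exact); model-recovery at 200 observations × 100 replicates; and the full
cohort run on the 11-subject phantom at the default grid.
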