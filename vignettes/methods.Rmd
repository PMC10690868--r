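---
title: "Graded connectivity parcellation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graded connectivity parcellation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradparc)
```

## The question the package addresses

Connectivity-based parcellation usually assumes a region decomposes into
discrete parcels with sharp borders. `gradparc` implements the alternative,
data-driven view: estimate *gradients* — continuous spatial axes of change
in a voxel's connectivity profile — and quantify whether the organization
is graded or blocked. Two independent connectivity modalities feed the same
machinery:

* **task-free**: Pearson correlation between the resting-state BOLD
  time-series of every pair of ROI voxels, aggregated run → subject →
  group through the Fisher z transform;
* **task-based**: for every ROI voxel, an activation-likelihood (ALE) map
  over the studies in a coordinate database that report a peak within 6 mm
  of the voxel (meta-analytic coactivation, MACM), and then the Pearson
  correlation between the unthresholded maps of every voxel pair.

Each similarity matrix is sparsified (top 10% of values row-wise), turned
into a cosine affinity, and embedded with the diffusion-map algorithm; the
leading nontrivial components are the gradient maps. Gradedness is
summarized by the **normalized algebraic connectivity**: the second-smallest
eigenvalue of the symmetric normalized Laplacian of the similarity graph,
scaled by $(n-1)/n$ so that 0 means "at least two disconnected subgraphs"
and 1 means "complete graph with uniform weights" (purely graded, no
substructure). Gradient extremes (the 20% lowest/highest voxels of a
gradient) are then characterized by seed-based FC contrasts, ALE contrasts,
network-overlap percentages and chi-square forward/reverse functional
decoding with Benjamini–Hochberg FDR.

## The model, step by step

### Similarity and aggregation

Run-level matrices are exact Pearson correlations. "z-score normalization"
before averaging is implemented as the Fisher r-to-z transform
$z = \operatorname{atanh}(r)$: it is the only standard reading under which
"transforming back from z-scores to correlations" is well defined, and it
variance-stabilizes the average. Runs are z-averaged within subject,
subjects are z-averaged with equal weight regardless of their run count,
and the group average is mapped back with $\tanh$. The diagonal is set to
$r = 1$ after aggregation rather than averaging $\operatorname{atanh}(1)$.

### Diffusion embedding

With affinity $W$, degree $D$, and anisotropy $\alpha = 0.5$
(Fokker–Planck normalization), the operator is
$P = D'^{-1} W'$ with $W' = D^{-\alpha} W D^{-\alpha}$. Eigenvectors are
computed through the symmetric conjugate of $P$ (numerically stable and
exact for symmetric $W$), the trivial stationary component is dropped, and
component $k$ is scaled by $\lambda_k/(1-\lambda_k)$ — the automatic
diffusion-time convention. Signs are fixed by making the largest-|loading|
entry positive, with ties broken at the lowest voxel index so the
convention is invariant to rescaling the affinity. Variance-explained
ratios are eigenvalue shares over the retained nontrivial set.

Negative cosines are clipped to zero: the Markov construction needs
nonnegative weights. A disconnected affinity graph makes the embedding
ill-defined, so `diffusion_embedding()` refuses it with instructions to
relax the sparsity; `embed_similarity()` automates that relaxation
(10-point steps) and records the percentage actually used.

### Gradation index

`gradation_index()` is applied by default to the nonnegatively rectified
similarity matrix itself, not to the sparsified affinity graph. The reason
is structural: a sparsified affinity of graded data is a band graph whose
algebraic connectivity vanishes with bandwidth (measured here at ~0.01
even for perfectly graded data), which would make the index useless as a
graded-vs-discrete summary; the similarity matrix, in contrast, yields
values near its theoretical behaviour. The exact noise-free limit for a
full-span two-network mixture is 0.697 (computable from the cosine
structure of the rank-2 similarity), and blocked data sits near 0.

### Coordinate-based meta-analysis

Per-study modelled-activation (MA) maps use Gaussian kernels whose FWHM
combines a fixed between-template uncertainty with a between-subject
uncertainty shrinking as $1/\sqrt{n}$ (Euclidean-distance constants 5.7 mm
and 11.6 mm, exposed as arguments, plus a fixed-FWHM override for
controlled tests). Within a study, foci combine by voxelwise **maximum**
— the revised, non-additive rule — so duplicated or clustered foci cannot
inflate convergence. Across studies, ALE is the probabilistic union
$1 - \prod_i (1 - \text{MA}_i)$. Voxel-level FWE control uses a
Monte-Carlo maximum-statistic null that redraws each study's foci
uniformly over the analysis-grid voxels (per-study focus counts and
kernels preserved); ALE contrasts use a study-label permutation null with
uncorrected voxelwise thresholds, as is conventional for ALE subtraction
analyses. Null iteration counts default to 1000 and are configurable.

The analysis grid for synthetic work is a coarse 4-mm bounding box around
the foci and the ROI (padded 8 mm): voxelwise MACM over 200 seeds then
costs seconds while preserving every algorithmic property; grid spacing is
a parameter, not a constant.

### Seed-based FC and inference

Cluster seed series are cluster means of run-concatenated series. Subject
maps are the Fisher-z of the voxel–seed correlation (the standardized
simple GLM with an intercept). Group inference is the closed-form
one-sample t (and its paired version on per-subject differences). FWE
voxel-height control offers Bonferroni (default) and a sign-flip max-t
permutation option. Probabilistic threshold-free cluster enhancement is
intentionally **not** re-implemented: the inferential contract — an
FWE-corrected voxel-height threshold at p < 0.05 — is preserved by the
standard methods above, and the package documents this substitution
rather than approximating an external algorithm.

### Functional decoding

A term is "present" in a study when its (continuous) frequency exceeds a
threshold (default 0: any positive frequency); a study "activates" a seed
when it reports at least one focus inside the seed mask — the same rule
the MACM selection uses. The 2×2 chi-square (optional Yates correction,
off by default) tests activation × term-presence independence; forward
inference reports the likelihood $P(\text{activation}\mid\text{term})$
against the activation base rate, reverse inference reports the posterior
$P(\text{term}\mid\text{activation})$ under the empirical term prior (a
uniform-prior variant is selectable). Both statistics are reported side by
side. BH-FDR is applied per analysis (per seed and direction), and the
cognitive-likelihood filter keeps terms annotated at ≥ 0.8 (boundary
inclusive).

## The synthetic generator: what it emulates and what it does not

`simulate_timeseries()` plants, per voxel $v$,

$$y_v = w(v)\, s_1 + (1 - w(v))\, s_2
      \;+\; a_2 \left( w_2(v)\, s_3 + (1 - w_2(v))\, s_4 \right)
      \;+\; c\, g \;+\; \varepsilon_v ,$$

with latent signals built directly in the frequency domain inside the
0.01–0.08 Hz analysis band (so band-pass preprocessing cannot destroy the
planted structure), mutually orthogonalized, and unit-variance;
$\varepsilon_v$ is white Gaussian noise (default sd 0.5, roughly 4:1
signal-to-noise variance for the principal axis — a clearly recoverable
but non-trivial regime).

Design choices that deserve an explanation:

* **Weight field.** Graded weights are uniformly rank-spaced along an axis
  oblique to the voxel lattice, spanning `[0.15, 0.85]`. The oblique axis
  makes all 200 weights distinct (an axis-aligned field collapses onto 10
  lattice planes, which degenerates order statistics of the gradient
  values); the narrowed span encodes that no voxel is a *pure*
  single-network voxel (partial-volume mixing at 2 mm), and places graded
  data in the strongly graded regime the index is designed to flag — the
  full-span limit of the index is 0.697, the `[0.15, 0.85]`-span limit is
  about 0.85. The blocked structure keeps $w \in \{0, 1\}$: it is the
  discrete counterfactual, not a realistic tissue model.
* **Global fluctuation** ($c = 0.15$ by default). All voxels share a weak
  band-limited co-fluctuation, as real parcels do. Numerically this keeps
  blocked data weakly positively connected: without it, refiltering the
  exactly-orthogonalized latents leaves each run a single shared random
  cross-block correlation, whose aggregate can be negative for every
  pair — all cross-block affinities then clip to zero and the blocked
  embedding is disconnected at any sparsity.
* **Unequal axes** ($a_2 = 0.7$). With two equal-strength planted axes the
  two leading embedding eigenvalues are degenerate and the embedding
  returns an arbitrary rotation within the planted plane; real gradient
  spectra are unequal, and the asymmetry pins component 1 to the stronger
  axis.
* **Global-signal regression is off in the synthetic configs.** On an
  ROI-only grid the in-mask mean *is* the mean of the planted network
  signals, and the OLS coefficient of every voxel on that mean is exactly
  1 — GSR then subtracts the network mean from every voxel and collapses a
  two-network mixture onto a single signed axis (a known GSR pathology:
  it manufactures anticorrelation). GSR is implemented, tested, and
  appropriate when the global mean is a genuine nuisance over a much
  larger mask; it is simply the wrong operation for these ROI-only
  simulations.
* **Coordinate database.** Each study belongs to one of two latent
  networks; it reports 5 foci from 4-mm Gaussian clouds around its
  network's two out-of-ROI loci (network clouds > 40 mm apart) and 3 foci
  at ROI voxel centres drawn with probability proportional to the
  network's weight field. Sample sizes are uniform on 10–50, exercising
  the sample-size-dependent kernel. Term frequencies are Poisson with base
  rate 0.2 — sparse, like real text-mined corpora; a dense base rate
  saturates the 2×2 decoding tables — elevated fivefold for a network's
  five associated terms in that network's studies. A per-term
  cognitive-likelihood annotation is emitted (planted terms ≥ 0.8).

What the generator does **not** emulate: hemodynamics, scanner noise
spectra, head motion, spatial autocorrelation of noise, anatomical
geometry, and the scale of real corpora (hundreds of studies and thousands
of terms rather than 100 × 40). Passing tests therefore demonstrate that
the *algorithms* recover planted structure under realistic band-limited
mixing — not that any particular real dataset is graded.

## Problem sizes and numerical choices

The reference configuration — 200 voxels, 10 subjects × 2 runs × 300
frames at TR 0.72 s, 100 studies on a ~4-mm grid of a few thousand
voxels — runs the full bimodal pipeline in well under a minute on one
CPU, and was chosen so the complete test-suite including the calibration
studies (100 seeded FWE repeats, 100 decoding nulls) stays at desk scale.
Eigendecompositions use dense symmetric solvers (exact at these sizes; an
independent dense eigendecomposition of the nonsymmetric random-walk
operator serves as the cross-check oracle in the tests). Sparsification
ties break by ascending voxel order; extreme-cluster tail sizes use
`floor`; `|r| = 1` is clipped to `1 - 1e-7` before `atanh` with a warning;
Butterworth band-pass (order 4, zero-phase) is the filter family — the
response curve is asserted in the tests rather than assumed.

## Known limitations

* The max/median gap diagnostic for gradient-value discontinuities is
  scale-sensitive: at 200 voxels even noise-free graded data shows a
  largest gap ~8–14× the median (embedding-density geometry plus order
  statistics at small n), while blocked data shows ~10⁵×. The *ratio
  between regimes* is diagnostic; the absolute bound of 5 used in
  large-ROI work does not transfer to small ROIs.
* The gradation index is computed on the rectified similarity graph;
  after global-signal regression (which induces negative correlations by
  construction) roughly half the entries clip to zero and the index is
  not interpretable — another reason GSR is off in the synthetic configs.
* Smoothing across a genuinely discrete boundary manufactures local
  gradation (blocked-data index rises from ~0.01 to ~0.2 with 4-mm
  smoothing); the discreteness analysis therefore runs unsmoothed.
* ALE nulls redraw foci uniformly over the analysis grid; anatomically
  informed null masks (e.g. gray-matter priors) are supported only insofar
  as the grid itself encodes them.
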