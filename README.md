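# gradparc

Graded connectivity-based parcellation: does the functional organization
of a brain region change gradually along continuous axes, or break into
discrete parcels with hard borders?

`gradparc` implements the full analysis chain for answering that question
from two independent connectivity modalities and validates it end-to-end
on synthetic data with planted ground truth. It is aimed at researchers
doing connectivity-based parcellation of volumetric ROIs who want
gradient (soft) parcellation with an explicit graded-versus-discrete
test, and at methodologists who want each stage of that pipeline as a
tested, reusable function.

## The method

For an ROI with voxels $v = 1, \dots, n$:

1. **Similarity matrices.**
   *Task-free:* the product-moment correlation $r_{uv}$ between voxel
   time-series, per run; run matrices are Fisher-z transformed
   ($z = \operatorname{atanh} r$), averaged within subject, then across
   subjects, and mapped back with $\tanh$.
   *Task-based:* for each voxel, an activation-likelihood (ALE) map over
   all studies in a coordinate database reporting a peak within 6 mm
   (meta-analytic coactivation modelling, MACM), with sample-size
   dependent Gaussian kernels, non-additive within-study combination, and
   $\text{ALE} = 1 - \prod_i (1 - \text{MA}_i)$ across studies; the
   similarity matrix is the correlation between the voxels' unthresholded
   maps.
2. **Gradients.** Each similarity matrix is sparsified to the top 10% of
   values row-wise, converted to a cosine affinity, and decomposed with
   the diffusion embedding algorithm (anisotropic normalization
   $\alpha = 0.5$, automatic diffusion time). The leading nontrivial
   components are the gradient maps; eigenvalue shares give variance
   explained.
3. **Gradation index.** The normalized algebraic connectivity
   $\lambda_2(L_{\text{sym}}) \cdot (n-1)/n$ of the rectified similarity
   graph, where $L_{\text{sym}} = I - D^{-1/2} W D^{-1/2}$: exactly 0 for
   a graph with two disconnected components (hard parcellation), exactly
   1 for a uniform complete graph (pure gradation).
4. **Characterization of gradient extremes** (20% lowest/highest voxels
   per gradient): seed-based resting-state FC with subject-level
   Fisher-z maps, group one-sample and paired t-tests and voxel-height
   FWE thresholds; ALE contrasts between the extremes' study selections;
   network-overlap percentages against a labelled atlas; and chi-square
   forward/reverse functional decoding of the associated text terms with
   Benjamini–Hochberg FDR and a cognitive-term filter.

A synthetic-data generator plants graded (1-D or 2-D) or blocked
network-mixing structure in band-limited multi-subject time-series and in
a coordinate database with coupled term frequencies, so every stage can
be checked against known ground truth. See `vignettes/methods.Rmd` for
the models, parameter choices and their rationale.

## Worked example

The analysis is organised as numbered drivers under `analysis/`, writing
tables under `results/`:

```sh
Rscript analysis/01_simulate.R            # synthetic study data
Rscript analysis/02_taskfree_gradients.R  # time-series branch
Rscript analysis/03_taskbased_gradients.R # MACM branch + cross-modal
Rscript analysis/04_characterize.R        # extremes: FC, MACM, decoding
Rscript analysis/05_discreteness.R        # graded vs blocked detection
```

On the reference graded configuration (200 voxels, 10 subjects × 2 runs
× 300 frames, 100 studies, seed 1) this prints, among other output:

```
group gradation index: 0.895; subject level: 0.895 +/- 0.006
|Spearman(gradient 1, planted weights)| = 0.997     # task-free branch
task-based gradation index: 0.972
|Spearman(gradient 1, planted weights)| = 0.964     # MACM branch
cross-modal gradient rank correlations: 0.97 (g1), 0.08 (g2)
top descriptive associations, low cluster: term01, term05, term03, term02, term04
```

Reading: both modalities recover the planted graded axis almost
perfectly in their leading gradient; the two branches agree with each
other (rank correlation 0.97 for gradient 1; gradient 2 is noise in a
1-D configuration); gradation indices sit high on the graded side of the
scale; and the decoding ranks exactly the five planted network terms at
the top for the matching gradient extreme. The discreteness stage prints
the contrast between regimes:

```
two_block : index 0.032, gradient-1 gap ratio 513717.3
graded_1d : index 0.850, gradient-1 gap ratio 13.6
```

A hard boundary drives the index to ~0 and produces one dominant gap in
the sorted gradient values; graded organization keeps the index high
with no comparably dominant gap.

The same computations are exposed as a single call
(`run_pipeline(default_config())`) for programmatic use, and every step
is an exported function (`timeseries_similarity()`,
`aggregate_similarity()`, `macm_voxelwise()`, `diffusion_embedding()`,
`gradation_index()`, `extreme_clusters()`, `decode_seed()`, ...).

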