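# dorsalfield

Quantitative analysis of somatotopic maps in the spinal dorsal horn and
of cutaneous mechanoreceptor physiology.

When the afferents of a small skin territory (a single digit, or one
nerve) are labelled with a transganglionic tracer such as CTB, their
central terminals form a diffuse 3D voxel cloud in the dorsal horn.
`dorsalfield` turns two-channel fluorescence stacks of such clouds into
per-specimen morphometry and group statistics, and classifies single
afferent fibres recorded in the ex vivo skin–nerve preparation. It is
aimed at labs studying somatotopic map formation, touch physiology and
nerve regeneration.

## What it computes

**Imaging.** A raw stack (tracer + autofluorescence channels) is
background-subtracted (voxelwise channel subtraction, clamped at 0),
binarized by stack-histogram thresholding at

&nbsp;&nbsp;&nbsp;&nbsp;*T* = mean + *k*·SD  (*k* = 3 over the whole stack),

and denoised by removing isolated voxels (3D 26-connectivity). From the
binary cloud the package measures:

* the **focus** — the unweighted centroid **c** = (1/N)·Σᵢ **vᵢ** of the
  N positive voxels, and its offsets to the annotated dorsal and medial
  grey–white matter borders;
* **spans** — extents of the axis-aligned bounding rectangles of the
  summed dorsoventral and rostrocaudal projections after a mean + 1·SD
  projection threshold (ML and RC spans from the DV projection, DV span
  from the RC projection);
* **areal densities** — N divided by the occupied projection area,
  in voxels/µm²;
* group comparisons: percent span expansion, percent density reduction,
  and the planar focus shift √(ΔML² + ΔDV²).

**Electrophysiology.** Conduction velocity = distance/latency
(> 10 m/s ⇒ Aβ, 1.5–10 m/s ⇒ Aδ), per-epoch spike counts and rates from
stimulus-locked trains, mechanical thresholds from rising force
envelopes, and afferent classes (RAM, SAM, D-hair, AM, tap-unit,
mechano-insensitive) from a fixed decision order.

**Statistics.** Pooled and Welch t tests and one-way ANOVA recomputed
either from raw samples or directly from printed summaries
(mean, SEM, n; SD reconstructed as SEM·√n), two-sided Fisher exact
tests by the point-probability rule, and Tukey/Bonferroni post hoc
comparisons.

**Synthetic data.** Seeded phantoms for both modalities — Gaussian-blob
stacks and paired control/mutant cohorts with configurable span,
density and focus effects, plus an inhomogeneous-Poisson fibre model —
give every pipeline stage a known ground truth. See the methods
vignette (`vignettes/terminal-field-morphometry.Rmd`) for the models
and design decisions.

## Worked example

Simulate a cohort (8 control vs 6 mutant specimens; mutant fields
configured to extend 14% further mediolaterally, 30% rostrocaudally, be
22% less dense, and sit 18.8 µm away in the ML–DV plane), push every
specimen through subtraction → binarization → denoising → morphometry,
and compare the groups:

```r
library(dorsalfield)
res <- run_pipeline(run_config(cohort = cohort_params(seed = 2026)))
print(res)
#> terminal_field_analysis: 8 control vs 6 mutant specimens
#>   ML span: +15.6%  (t(12) = 7.509, p = 7.15e-06)
#>   RC span: +30.6%  (t(12) = 15.397, p = 2.88e-09)
#>   DV span: +3.4%  (t(12) = 1.588, p = 0.138)
#>   DV density: -22.3%  (t(12) = -11.281, p = 9.59e-08)
#>   focus shift: 18.61 um lateral, 1.29 um ventral (planar 18.7 um)
```

At this realistic group size the pipeline recovers the configured
effects (+14% / +30% / −22% / 18.8 µm) to within sampling error, finds
the span and density differences highly significant, and correctly
leaves the dorsoventral span unchanged. `res$metrics` holds the
per-specimen rows; `res$manifest` records seeds and thresholds so the
run is exactly reproducible.

The statistics layer works straight from printed summaries. For
example, two groups published as 722.4 ± 133.9 (n = 3) and
649.2 ± 54.92 (n = 3):

```r
group_t_test(summary_stats(722.4, 133.9, 3), summary_stats(649.2, 54.92, 3))
#> t(4) = 0.5058, p = 0.6396
```

i.e. no detectable group difference (the pooled t on 4 degrees of
freedom is far from significance).

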