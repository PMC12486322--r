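---
title: "Terminal-field morphometry and afferent classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Terminal-field morphometry and afferent classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dorsalfield)
```

# What this package computes

`dorsalfield` quantifies how precisely a patch of skin is represented in
the spinal dorsal horn, and how well single cutaneous afferents respond
to mechanical stimulation. Both questions arise in studies of
somatotopic map formation and of nerve regeneration: after tracing the
afferents of one digit (or one nerve) with a transganglionic tracer such
as CTB, the labelled central terminals form a three-dimensional voxel
cloud whose *position* (focus), *extent* (spans) and *compactness*
(areal density) can be compared between genotypes or surgical groups; in
parallel, teased-fibre recordings from an ex vivo skin--nerve
preparation yield per-fibre conduction velocities and stimulus-locked
spike counts from which each afferent is assigned to a physiological
class.

Because raw imaging stacks for such experiments are rarely deposited,
the package ships a seeded synthetic-data layer that emulates both data
modalities with known ground truth. Every analysis stage is validated
against that truth (or against brute-force oracles), so the pipeline can
be trusted before it ever touches real data.

# Image processing model

A specimen enters as a two-channel stack in (z, y, x) = (dorsoventral,
rostrocaudal, mediolateral) order with per-axis voxel sizes in µm
(default 2 × 1 × 1 µm, matching two-photon stacks with 1 µm pixels and a
2 µm z-step).

1. **Background subtraction.** The autofluorescence channel is
   subtracted voxelwise from the tracer channel; negative differences
   are clamped to zero. Clamping (rather than keeping signed residuals)
   reflects that intensities are physical photon counts, and it is what
   makes the subsequent histogram statistics meaningful: the background
   collapses onto a half-normal hump near zero.
2. **Stack-histogram binarization.** A voxel is terminal-positive iff
   its intensity strictly exceeds the mean grey value of the *whole*
   subtracted stack plus `k_bin` (default 3) population standard
   deviations. Computing the statistics over all voxels — including the
   dominant zero background — is what turns mean + 3 SD into a
   high-percentile cut. The strict inequality makes the degenerate
   constant stack well-defined (empty mask).
3. **Isolated-voxel removal.** A positive voxel with no positive
   neighbour is deleted. The neighbourhood is 3D 26-connectivity by
   default: the objects are 3D voxel clouds, and per-slice 2D removal
   would delete genuine single-slice intersections of thin fibres. The
   connectivity (6/18/26) is configurable because the underlying
   convention in interactive tools is ambiguous. The operation is
   idempotent — an isolated voxel is nobody's neighbour, so removing it
   cannot isolate others — and the provenance of the mask records the
   threshold and removal count.

Whether the histogram statistics should be taken before or after
subtraction is not decidable from published descriptions; this
implementation computes them **after** subtraction, which is the variant
under which the background model above is coherent.

# Morphometry

All measurements operate on the binary mask:

* **Focus (centre of mass).** The unweighted centroid of the positive
  voxels — unweighted because binarization has already discarded
  intensity. Micrometre coordinates place the first voxel centre at
  0 µm. For alignment across specimens the focus is rounded to the
  nearest voxel with ties toward negative infinity (a deterministic,
  documented tie-break), and the mask is cropped/zero-padded to a fixed
  window around it.
* **Summed projections.** Collapsing one axis by summation gives a 2D
  count image; by construction the projection total equals the
  positive-voxel count (a conservation law the tests exploit).
* **Spans.** Each projection is thresholded at its mean plus `k_span`
  (default 1) SDs, and the span is the extent of the axis-aligned
  bounding rectangle of the surviving pixels: mediolateral and
  rostrocaudal spans from the dorsoventral projection, the dorsoventral
  span from the rostrocaudal projection. The rectangle is axis-aligned
  (no rotating calipers) because the anatomical axes themselves carry
  meaning.
* **Areal density.** Total voxel count divided by the occupied area of
  the projection, in voxels/µm². By default "occupied" means *any*
  positive pixel; the published wording applies the 1-SD threshold only
  to span measurement, so the density denominator uses the raw
  projection. Both choices are supported
  (`pipeline_config(density_on_thresholded = )`) since the wording is
  ambiguous.
* **Focus offsets and planar shift.** Distances from the focus to the
  annotated medial and dorsal grey--white matter borders (borders are
  supplied as annotations; segmenting them is out of scope). A group
  difference in the two offsets combines into a planar (Euclidean)
  shift.

`percent_change()` expresses group differences of any of these
quantities as `100·(comparison − reference)/reference`.

# The synthetic imaging cohort

`generate_terminal_stack()` renders anisotropic Gaussian blobs over
clipped-Gaussian background noise with sparse hot pixels, identically
distributed in both channels; the ground-truth support is the noise-free
field above half its maximum. This phantom drives the unit tests of the
processing chain (e.g. the mean + 3 SD cut recovers the half-maximum
support within 10% under the default geometry, where the two thresholds
coincide by construction).

`generate_cohort()` needs more care, because the quantities a cohort
must calibrate are *relative* (mutant/control ratios). Mean + k·SD
thresholds are not scale-invariant for smooth Gaussian mixtures: the
fraction of zero background pixels enters the projection statistics, so
simply inflating a Gaussian blob changes where the threshold falls
relative to the profile and the measured span ratio would
systematically undershoot the configured one. The cohort phantom is
therefore an **elliptical rostrocaudal band**: an elliptical ML--RC
footprint of uniform DV thickness, in which every image column carries
one contiguous run of bright voxels covering a configurable fill
fraction of the thickness at a random depth. This emulates the narrow
rostrocaudal band in which a single digit is represented, and makes the
effect controls exactly linear:

* span multipliers scale the footprint semi-axes, and since all
  projection pixels inside the footprint carry near-identical counts
  (a flat-top profile), the mean + 1 SD cut keeps *all* of them
  whenever the footprint covers less than half the projection — the
  measured span is the full footprint extent and its ratio is the
  configured multiplier;
* the density multiplier scales the column fill fraction, so the voxel
  count scales linearly while the occupied projection area is the
  footprint ellipse — the measured DV density ratio equals the
  configured multiplier;
* the focus displacement translates the band centre in the ML--DV
  plane and is recovered as the difference of group-mean border
  offsets.

Column runs are drawn as `floor + Bernoulli(frac)` so their expectation
equals the target exactly, and run depths are continuous-uniform before
voxel rounding so no aliasing bias accumulates in the dorsoventral
focus. Specimen-level biology is emulated by lognormal jitter on the
axis scales (3%) and fill fraction (4%) and Gaussian jitter on the band
centre (1.5 µm). Specimen seeds are drawn once and shared between the
groups ("seed-matched pairing"): with identity effect parameters the two
groups are bit-identical, so every group difference is attributable to
the configured effects.

Default effect sizes are the terminal-field phenotype the cohort
emulates: ML span ×1.14, RC span ×1.30, DV span ×1.00, DV density
×0.78, focus displaced (18.75, 1.42) µm latero-ventrally; default group
sizes are 8 control vs 6 mutant specimens. The default grid
(24 × 180 × 96 voxels at 2 × 1 × 1 µm) is a scaled-down dorsal-horn
segment chosen so a full 20-vs-20 cohort runs in well under a minute;
the band geometry (semi-axes 20/60/16 µm, 35% fill, peak 100 over
background 10 ± 2) keeps the labelled fraction of the stack near 5%,
which places the mean + 3 SD threshold safely between background and
signal for every jittered specimen.

**What the phantom does not model:** optics (PSF blur, depth-dependent
attenuation, clearing shrinkage), tiling artefacts, vascular shadows,
and spatially correlated autofluorescence. Passing the recovery tests
therefore demonstrates that the *measurement chain* is unbiased and
well-calibrated on clouds with known geometry — not that the pipeline
is robust to every optical artefact of real cleared-tissue stacks.

# Afferent recordings

Conduction velocity is distance/latency (mm/ms ≡ m/s); fibres above
10 m/s (strictly) are Aβ, fibres in [1.5, 10] m/s are Aδ — the boundary
value 10 m/s goes to Aδ, making the two bands a partition. The stimulus
battery (`standard_protocol()`) holds the conventions of the skin-nerve
preparation: ramp-and-hold stimuli at probe velocities 0.075, 0.15,
0.45 and 1.5 mm/s (96 µm displacement, ≈40 mN), a static series with a
fast force ramp and 2 s holds, a 50 Hz vibration of linearly increasing
amplitude for thresholds, and a manual tap — modelled as its own epoch
kind, because a real tap is literally manual and exceeds the 1.5 mm/s
ceiling of the stimulator.

Epoch membership is half-open `[start, end)` so boundary spikes are
counted once. The mechanical threshold is the envelope force at the
first spike inside a force-bearing dynamic epoch; with a linearly
rising envelope this is read directly off the spike time.

Classification follows a fixed decision order: (1) no spikes to
anything → mechano-insensitive; (2) spikes only to the tap → tap-unit;
(3) Aβ with ≥ 1 spike during a suprathreshold hold → SAM, else RAM;
(4) Aδ with threshold ≤ 1 mN and a response at the slowest ramp →
D-hair, else AM. The SAM criterion (one hold spike) and the D-hair
criterion (1 mN + slowest-ramp response) are configurable defaults, not
claims: the published decision rules say only "spike pattern", and
D-hairs are simply the most sensitive cutaneous mechanoreceptor class.

The generative fibre model is the simplest seeded process the
classifier must still recover: an inhomogeneous Poisson train (rate ∝
dynamic gain × ramp velocity during ramps; static gain ×
suprathreshold force during holds; a fixed entrainment rate above the
vibration threshold crossing) thinned by an absolute refractory period.
D-hair models use a high vibration entrainment rate (200 Hz), which is
also what keeps their recovered thresholds from overshooting the 1 mN
criterion: with a 10 mN/s envelope, a mean first-spike latency of 5 ms
adds only ≈0.05 mN of bias. Tap-units fire their single tap spike with
probability 0.95, so a few percent of them are (correctly, given the
data) recorded as mechano-insensitive — the recovery criterion for
tap-units is accordingly looser than for the other classes.

# Statistics layer

Published group data often survive only as mean ± SEM with n. The
summary path reconstructs the group SD as SEM·√n and computes the
pooled t (df = n₁+n₂−2), Welch t (Satterthwaite df) and one-way ANOVA F
from those moments; raw-sample and summary paths agree to machine
precision when the summaries come from the samples, which the tests
assert. The Welch "auto" trigger is an F test of variances at α = 0.05;
the default is pooled, because published degrees of freedom of the
recomputed comparisons are n₁+n₂−2 throughout. Recomputing printed
statistics from printed (rounded) summaries carries a documented ±3%
tolerance — inputs are given to 1–4 significant figures.

`fisher_exact()` implements the two-sided point-probability rule (sum
of hypergeometric probabilities of all tables no more probable than the
observed one, with 1e-7 relative slack against floating-point ties).
This is spelled out because two-sided conventions differ between
packages; the test suite verifies exact agreement with full
enumeration over *all* 2×2 tables with total ≤ 30 and with the
reference implementation in base R. Tukey post hoc tests use the
studentized range on the pooled within-group mean square; Bonferroni
multiplies pairwise pooled-t p-values by the number of comparisons.
Two-way repeated-measures ANOVA is deliberately not implemented: it
needs raw per-fibre repeated measures that summary tables cannot
provide, and standard implementations exist.

# Numerical conventions and edge cases

* Population (divisor-n) SD everywhere an image histogram is
  thresholded; sample SD in the inferential layer.
* Strict threshold comparisons by default; configurable.
* Empty masks are rejected with explicit messages wherever a
  measurement would be undefined (centroid, spans, density).
* Voxel i sits at (i−1)·voxel_size µm; all external lengths are µm.
* TIFF stacks are written as 32-bit samples scaled by a recorded
  maximum; round-trips are exact to ~1e-9 relative (the sample grid),
  masks round-trip bit-exactly. The JSON sidecar, not TIFF tags, is the
  authoritative voxel-size metadata — z-spacing conventions in TIFF
  are too inconsistent to rely on.
* All generators take explicit integer seeds and are bit-reproducible.

# Problem sizes used in validation

The shipped validation uses 200 random 4³–8³ masks against brute-force
oracles, a 20-vs-20 specimen cohort on the default grid, 200 synthetic
fibres per class, exhaustive Fisher enumeration to table total 30, and
10,000 null simulations for the t-test error rate — sizes chosen so the
whole suite completes in a few minutes on a laptop while keeping Monte
Carlo error far below the tolerances being asserted.

# Known limitations

* The cohort phantom's flat-top band makes span recovery exact by
  design; it does not probe how the 1-SD span threshold behaves on
  smoothly decaying real fields (where the measured span depends on the
  zero-pixel fraction of the projection — a property of the method
  itself, not of this implementation).
* The fibre model omits spontaneous activity, adaptation within epochs
  and waveform shape; the classifier is correspondingly tested on spike
  counts, not on sorting.
* D-hair vs AM separation depends on threshold recovery and is
  sensitive to the vibration entrainment rate; it is validated at ~90%
  rather than the ≥95% of the other classes.
* Atlas registration, lamina assignment and two-tracer overlap analysis
  are out of scope.
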