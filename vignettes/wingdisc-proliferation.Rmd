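---
title: "Quantifying driver-stripe proliferation in wing imaginal discs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying driver-stripe proliferation in wing imaginal discs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wingquant)
```

## The measurement

A wing imaginal disc is imaged in two registered channels: a junction
marker (typically DE-cadherin immunofluorescence) that outlines the
epithelium, and endogenous GFP expressed by a GAL4 driver (e.g. the
*patched* stripe) together with the genetic perturbation under study. The
quantity of interest is the proliferation index

$$\mathrm{PI} = \frac{A_\mathrm{GFP}}{A_\mathrm{disc}},$$

the GFP-positive area divided by the whole-disc area. Normalizing by the
disc's own area compensates for developmental asynchrony between animals:
a perturbation that merely delays the whole disc leaves PI unchanged,
whereas stripe-autonomous overgrowth raises it.

The pipeline assumes 2D single-plane input. Confocal stacks must be
projected before loading; the package deliberately refuses >2D data rather
than guessing a projection, since maximum-intensity versus mean projection
changes apparent areas.

## Disc segmentation: edges, then filling

The disc mask is obtained from the junction channel in three steps.

**Canny edge detection.** Intensities are normalized to $[0,1]$ at load
(dividing by $2^{\mathrm{bit\ depth}}-1$), so all thresholds are portable
across 8- and 16-bit acquisitions. The channel is smoothed with a Gaussian
of `smoothing_sigma` (default 2 px — wide enough to suppress pixel noise,
narrow enough not to merge the disc outline with nearby structures at the
10–20x magnifications typical for whole-disc imaging). Sobel gradients are
scaled so a unit intensity step has magnitude about 1; non-maximum
suppression with four quantized directions thins ridges to 1–2 px; and
hysteresis keeps weak edge pixels only when 8-connected to strong ones.

By default the hysteresis thresholds adapt to each image: the high
threshold is the 0.9 quantile of the non-zero gradient magnitude and the
low one is half of it. Junctional staining intensity varies between
batches and antibodies; fixed absolute thresholds would need retuning,
while the brightest decile of gradients reliably contains the tissue
outline. Absolute thresholds can be given instead
(`canny_params(low_threshold =, high_threshold =)`), in which case edge
detection is exactly linear: halving all intensities and both thresholds
reproduces the identical edge map.

**Closing and filling.** A pixel is interior to the outline iff it cannot
reach the image border through non-edge pixels (4-connectivity). Real
junctional outlines have small gaps, so with `closing_radius` $r>0$
(default 3 px, matching the gap sizes seen when a 1–2 px outline crosses a
dim membrane stretch) the edge map is dilated with a disk of radius $r$,
the dilated outline is filled, and the filled region is eroded with the
same disk before being united with the original edges. The order matters:
dilation bridges a gap of up to about $2r$ px and the fill then seals the
interior, after which erosion restores the boundary position. Applying
closing before filling instead would erode the thin bridge away again and
let the interior leak. The disc mask therefore includes the outline pixels
themselves. Filling alone ($r=0$) is exactly idempotent, and the
filled mask always contains the input edges.

**Component selection.** The largest 8-connected filled component is the
disc; components below `min_area_fraction` of the image (default 0.05) are
ignored, and the comparison is inclusive (a component exactly at the floor
is kept). 8-connectivity for foreground with 4-connectivity for the
background flood fill is the standard complementary pairing that avoids
topological paradoxes (a closed 8-connected curve would not enclose
anything under 8-connected background). When nothing passes the floor the
error reports the largest observed fraction so the caller can adjust
parameters deliberately rather than silently accepting debris.

## GFP segmentation

A pixel is GFP-positive iff its normalized intensity is **greater than or
equal to** the uniform threshold; the inclusive convention is arbitrary but
fixed and tested. One threshold per batch is the default (`scope =
"batch"`): a single cutoff applied uniformly across all conditions is what
makes between-genotype comparisons meaningful. Per-image thresholds are
available for exploration but flagged as non-uniform.

Whether the GFP mask should be clipped to the disc outline is a genuine
design choice: driver expression outside the detected outline (folds,
peripodial signal) could be real or artefactual. The default
`restrict_to_disc = TRUE` bounds PI by 1 and matches the intuition that
the index is a fraction of the disc; the unrestricted area is recorded
alongside in every batch record so the choice is auditable.

`suggest_threshold()` computes Otsu's threshold on the pooled 256-bin
histogram of a batch's reporter channels — a reproducible starting point
for what is ultimately a manually confirmed setting. It is never applied
silently. Ties in the between-class variance (common when the histogram
valley is empty) resolve to the first maximum.

## Statistics

Groups are compared with the unpaired, two-sided Student's *t* test with
pooled variance ($df = n_a + n_b - 2$); Welch's variant (Satterthwaite
*df*) is available and preferable when variances differ visibly. Stars
follow the conventional mapping with **strict** inequalities — `***` for
$p < .001$, `**` for $p < .01$, `*` for $p < .05$, nothing at $p = .05$
exactly ("ns" in plots). No multiple-testing correction is applied, which
mirrors how this assay is conventionally reported; if you compare many
genotypes against a control, interpret isolated single stars accordingly.

`compare_all()` tests every genotype against each named reference
condition (controls are themselves compared against the other references,
never against themselves). Zero pooled variance with equal means yields
$t=0, p=1$; with unequal means it is reported as a degenerate-input error
rather than an infinite statistic.

## The phantom generator

`generate_phantom()` builds the geometry the pipeline assumes: a
star-convex disc boundary $r(\theta) = R\,(1 + \sum_{k=2}^{4} a_k
\cos(k\theta + \varphi_k))$ with seeded harmonic amplitudes summing to
`boundary_irregularity` (capped at 0.2 so the outline stays closed — real
discs are lobed but not self-intersecting), a junctional band of width 3 px
just inside the boundary over a faint interior mesh texture (10% of the
band contrast, 8 px period, emulating sub-threshold cell outlines), and a
vertical reporter stripe whose width is found by bisection on the discrete
masks so the stripe-in-disc fraction hits `stripe_fraction` within 0.02
(the stripe centre is offset a quarter pixel so bisection resolves single
columns). Poisson noise at `photon_scale` (default 400 photons at unit
intensity, a realistic confocal budget) and Gaussian read noise at
`noise_sd` (default 0.02) are then applied and clipped to $[0,1]$. The
ground truth is the noise-free discrete masks, so validation comparisons
are exact set arithmetic, and the reporter background is exactly zero
before noise.

`simulate_experiment()` draws per-image stripe fractions from truncated
normals per genotype; each image's RNG stream derives from the experiment
seed and the image index, so batches are reproducible and any single image
can be regenerated alone.

What the phantoms do **not** emulate: folded or multi-layered epithelia,
apoptotic debris, bleed-through between channels, uneven illumination, or
out-of-focus light. Passing the phantom suite therefore demonstrates that
the algorithms are implemented correctly and behave stably under noise —
not that the default parameters are optimal for any particular microscope;
inspect the overlay renderings on your own data before trusting batch
numbers.

## Validation results regenerated by the tests

The test suite and `scripts/acceptance.R` recompute, from scratch:

- bit-exact equality of `close_and_fill` (radius 0) with an independent
  border flood-fill oracle on random 32×32 masks, and of `segment_gfp`
  counts with brute-force pixel counts;
- disc-area recovery within 5% mean relative error and per-image index
  recovery within 0.02, on seeded phantoms with radii 60–100 px, boundary
  irregularity up to 0.15, read noise up to 0.05 and stripe fractions
  0.1/0.2/0.3 (20 phantoms at 256×256);
- agreement of the pooled *t* test with the closed-form formula to
  1e-10 on 1000 random group pairs;
- calibration and power of the whole phantom→segmentation→*t*-test
  pipeline at the scale of a typical figure panel (n = 15 discs per
  group; 128×128 phantoms of radius 45 for speed): the type-I error rate
  at $p<.05$ over 200 replicates, and the detection rate for a true index
  difference of 0.10 vs 0.25 (s.d. 0.03) over 100 replicates.

The area-recovery error is dominated by a systematic ~1 px outward bias of
the detected outline (the fill includes the full 1–2 px edge thickness),
i.e. roughly $2/R$ relative — which is why accuracy is specified on discs
of radius 60–100 px and degrades for much smaller objects. Because the
bias is common to all conditions imaged with the same settings, it cancels
almost entirely from between-group comparisons of the index. Read noise up
to 0.2 barely moves the error: the adaptive gradient-quantile thresholds
track the noise floor (`analysis/04_noise_robustness.R` regenerates this
curve).

## Known limitations

- Single 2D planes only; no z-handling, registration, flat-fielding or
  deconvolution.
- One disc per field; multiple discs are resolved by size, not identity.
- The disc outline is taken to be the outermost closed contour of the
  junction channel; internal fold edges are absorbed by the fill but a
  broken outer outline (gap larger than about twice `closing_radius`)
  makes the disc unrecoverable and is reported as "no disc found".
- Area-based only: intensity-weighted or cell-count-based proliferation
  measures are out of scope.
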