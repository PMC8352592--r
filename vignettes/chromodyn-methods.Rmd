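---
title: "Models and methods behind chromodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chromodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromodyn)
```

chromodyn implements the quantitative readouts used in live-cell confocal
studies of chromatin-remodeler dynamics on *Drosophila* salivary-gland
polytene chromosomes: FRAP and FLIP-FRAP kinetics, histone-fluorescence
based chromatin condensation, fiber-model fold-compaction, and
clustering/colocalization statistics. This vignette explains the models,
their assumptions, the tunable parameters, and the design choices made
where the underlying experimental convention leaves room.

## FRAP normalization and kinetic model

A raw FRAP experiment yields three channels per frame: the mean intensity
of the bleached region (`roi`), of the whole nucleus (`whole`), and of a
cell-free background region. After background subtraction (floored at
zero, with floored frames flagged), curves are *double normalized*:

$$I_{dn}(t) = \frac{roi(t)/\overline{roi_{pre}}}{whole(t)/\overline{whole_{pre}}}$$

The whole-nucleus denominator cancels acquisition photobleaching, which is
why the protocol records it at all. Full-scale rescaling then maps the
pre-bleach mean to 1 and the first post-bleach frame to exactly 0:

$$F(t) = \frac{I_{dn}(t) - I_{dn}(t_0)}{1 - I_{dn}(t_0)}$$

Two conventions deserve making explicit, since "full-scale normalized" on
its own underdetermines them:

* **Normalization variant.** We use double normalization followed by
  full-scale rescaling, the scheme popularized by the widely used online
  FRAP analysis tools. The recorded whole-nucleus channel implies its use.
* **Bleach frame.** The bleach is taken as instantaneous at the
  protocol-defined frame `n_pre`, and the first post-bleach frame is the
  model's $t = 0$. A minimum-intensity fallback exists for unannotated CSV
  input (`read_curve_csv(..., bleach_detect = "min")`).

Recovery is fit with the empirical double-exponential model

$$F(t) = a\,(1 - e^{-k_1 t}) + b\,(1 - e^{-k_2 t}), \qquad k_1 \ge k_2,$$

whose plateau $a + b$ is the mobile fraction and whose half-time
$t_{1/2}$ solves $F(t_{1/2}) = (a+b)/2$ (unique by monotonicity; solved by
bracketed root-finding, `uniroot` at $10^{-12}$ s tolerance). This is a
deliberately empirical description: no reaction-diffusion PDE is fitted,
matching the practice the package reproduces.

Numerical choices in `fit_double_exponential()`:

* **Optimizer.** Box-constrained Levenberg-Marquardt (`minpack.lm::nls.lm`)
  on the raw residual function, with $a, b, k_1, k_2 \ge 0$. We do not use
  the `nls`-object wrapper because building its model matrix fails at
  degenerate optima (an amplitude collapsing to zero makes the paired rate
  column singular) even though the parameter estimates there are perfectly
  well defined.
* **Multi-start.** The heuristic start puts the plateau at the mean of the
  last quartile, splits it evenly between components, sets $k_1$ from the
  time to half-plateau and $k_2 = k_1/10$; five log-normally jittered
  restarts (fixed jitter seed) guard against local minima. Non-convergence
  after all restarts returns the best effort flagged `converged = FALSE`.
* **Degenerate-fit fallback.** If the two rates are indistinguishable
  ($|k_1-k_2|/k_1 < 10^{-3}$) or an amplitude falls below $10^{-3}$, the
  curve is refit as a single exponential; the amplitude split is
  unidentifiable in that regime.
* **Mobile fraction.** Reported from the fitted plateau, clipped to
  $[0, 1]$ with the raw value retained (`mobile_fraction_raw`), because
  noise can push plateaus slightly above 1. The late-frame mean
  (`mobile_fraction_late`, last 10% of frames) is reported alongside since
  published legends rarely state which of the two was read.
* **Fitting window.** All post-bleach frames; no truncation.

The biphasic variant `fit_biphasic()` ($A(1-e^{-Kt}) + st$, all
parameters non-negative) describes polymerase-style recovery: a fast
binding phase followed by a prolonged linear elongation phase.

## FLIP-FRAP and the two-compartment exchange model

Bleaching half a nucleus and following both halves tests whether a protein
exchanges freely across the nucleus. The forward model
(`simulate_flip_frap()`) is two well-mixed compartments of volumes $v_1,
v_2$ whose mobile pools exchange with rate constant $k_{ex}$; mean
concentrations relax exponentially toward equality with rate
$\lambda = k_{ex}(1/v_1 + 1/v_2)$, and an immobile fraction stays where
the bleach left it. In the noiseless model the volume-weighted total
signal is conserved exactly after the bleach — the rise of the bleached
half mirrors the loss of the unbleached half, which `analyze_flip_frap()`
checks as the gain/loss balance. Curves are expressed as percent of each
half's own pre-bleach mean, and the half-equilibration time is read from
the bleached-half rise by linear interpolation. Curves are normalized
per-curve and averaged afterwards when replicates are combined.

## Chromatin condensation from histone fluorescence

Histone-GFP intensity in a polytene nucleus tracks local chromatin
density. The pipeline is:

1. `rescale_to_full_range()` — per-nucleus linear auto-brightness mapping
   the [0.35%, 99.65%] percentile window onto the full 8-bit range (the
   common auto-adjust convention; percentiles configurable). The fixed
   class thresholds presuppose this rescaling. Applied per nucleus by
   default, with a per-slice option.
2. `classify_voxels()` — threshold binning into background (0-82), white
   interband chromatin (83-148), gray bands (149-224) and black chromatin
   (>224). Boundary behavior is exact: 82 is background, 83 white, 148
   white, 149 gray, 224 gray, 225 black.
3. `volume_fractions()` — voxel counting pooled across nuclei, fractions
   over chromatin voxels only (the readout is the composition of the
   *chromosome* volume, so background and nucleolus are excluded);
   per-nucleus fractions retained for the between-nucleus SD. The
   confocal slices are treated as an unbiased sample of nuclear volume.
4. `relative_condensation()` — per-class density = genomic fraction /
   volume fraction; pairwise condensation = density ratio. With genomic
   composition 5/25/70% and volume fractions 52/43/5%, gray chromatin is
   ~6-fold more condensed than white, black an additional ~24-fold
   (~146-fold over white). The ratio chain
   `black/white = black/gray x gray/white` holds to machine precision. A
   zero volume fraction yields a flagged infinite density rather than an
   error.

Fragment-level compaction compares an observed in vivo length with the
length of the same DNA packaged as an extended 11 nm nucleosomal array:
0.34 nm/bp contour length divided by the 6.8:1 packing ratio (both
configurable constants of `fiber_model()`, not hard-coded). 360 kb gives
an 18 µm extended fiber; observed at 0.72 µm that is 25-fold compaction.
Uncertainty is propagated from replicate SD by the delta method and
validated against a bootstrap in the tests. The volumetric variant models
fragments as cylinders and compares DNA densities (bp/µm³). The genomic
lengths of the puffed and distal fragments are not published, so only the
~360 kb band has a numeric worked example; the others are user inputs.

## Clustering and colocalization statistics

`local_variance_map()` is the variance filter: per-pixel *population*
variance over the circular neighborhood of radius 2 (Euclidean,
center-distance ≤ r), matching the definition in the reference image
-analysis tool. Border and mask policy is "no padding": each variance is
taken over the neighbors actually present inside the image and mask. The
per-nucleus readout is the mean of the map over the nuclear mask, in
intensity² units — punctate clustering raises it, as the monotonicity
property test verifies.

`two_sample_test()` accepts raw samples or published `(mean, sd, n)`
summaries. Welch's unequal-variance test is the default — with SDs as
unequal as 432 vs 171 the pooled Student test overstates significance —
but both p values are always reported, since figure legends often say
"Student's t test" without specifying the variant. From the printed
summaries 880 ± 432 (n = 29) vs 1351 ± 171 (n = 32), Welch gives
p ≈ 3.3 × 10⁻⁶ and the pooled variant ≈ 4 × 10⁻⁷; neither exactly
reproduces a published 2.7 × 10⁻⁶ computed from unrounded data, which is
expected from rounding of the summaries and is left as is.

`manders_coefficients()` reports both thresholded Manders coefficients;
M1 (fraction of channel-A intensity over above-threshold B) is the
headline number. The threshold default is Otsu per channel, with a fixed
-value override, because the experimental threshold convention is
typically unstated. Both coefficients are invariant under uniform
rescaling of the measured channel.

`heatmap_render()` is a bijective 256-entry false-color LUT, so gray
values round-trip exactly through a rendered image.

## The synthetic-data generators

No raw imaging data accompany the analyses the package reproduces, so
every stage is validated against seeded generators with known ground
truth:

* **Curves** (`simulate_frap_curve()` and relatives) wrap a noiseless
  model — pre-bleach baseline 1, instantaneous bleach of depth $d$ at
  frame `n_pre`, recovery $1 - d(1 - F(t))$ — with additive Gaussian
  noise on the normalized scale. Default protocols mirror the two
  acquisition regimes: 20 pre-/200 post-bleach frames at 70 ms (cultured
  cells) and 10 pre-/250 post-bleach frames at 648 ms (glands). The noise
  SD defaults to 0.02, chosen to match reported SD bands of averaged
  curves (a few percent of the pre-bleach level); the source protocols do
  not state a noise magnitude, so this is a configurable package default.
  Observational photobleaching is off by default; a linear whole-channel
  decay option exists to exercise the normalization's correction.
* **Phantoms** (`render_nucleus_phantom()`) build an ellipsoidal nucleus
  containing a cylinder-like chromosome of stacked bands (12 by default,
  interleaved so each class is spread along the axis, voxel quotas exact
  to one voxel), plus one spherical nucleolar void. Class intensities
  default to the centers of the threshold bins. Imaging is modeled as an
  in-plane Gaussian PSF (σ = 1 voxel) followed by Poisson shot noise and
  Gaussian read noise (SD 2). The default stack is 9 slices of 96 × 96
  voxels, mirroring the nine-slices-per-nucleus sampling of the imaging
  protocol at a size that keeps test suites fast.
* **Exchange pairs** (`simulate_flip_frap()`) use the closed-form
  two-compartment solution; the tests cross-check it against an explicit
  Runge-Kutta integration of the underlying ODE.

All generators are pure functions of their specification and one explicit
integer seed; no global RNG state is consumed or altered.

What the phantoms deliberately do *not* emulate: axial PSF anisotropy and
z-blur, chromatid-level substructure, intensity gradients with depth,
chromatic shift between channels, and segmentation error in the nuclear
mask. Passing the round-trip tests therefore shows the *analysis* is
correct and robust to in-plane blur and shot noise at realistic levels —
it does not certify performance on real stacks with strong axial blur or
mis-segmentation.

## Problem sizes and runtime choices

The validation suites use deliberately modest problem sizes chosen to
exercise the statistics without waste: 200 replicate curves per kinetic
regime (half-times 0.7, 1.7 and 3.1 s) for parameter-recovery medians, 20
seeded phantoms for the volume-fraction round trip, 1,000 random parameter
draws for the half-time root-finding oracle, and 10,000 permutations for
the t-test cross-check. Medians (not means) summarize recovered half-times
because the noise occasionally produces heavy-tailed fit errors in the
fast regime, where only a handful of frames sample the rising phase.

## Known limitations

* The double-exponential model is empirical; rate constants are not
  binding constants, and no diffusion coupling is modeled.
* Mobile fractions from full-scale normalized curves are relative to the
  bleached pool; deep bleaches of small mobile pools amplify noise in the
  plateau.
* The condensation readout assumes histone-GFP intensity is proportional
  to chromatin density and that auto-brightness makes nuclei comparable;
  strong inter-nucleus expression differences violate the second
  assumption and should be handled with the per-nucleus rescale.
* Volume fractions from few slices are unbiased but noisy for the rare
  black class; its density ratios inherit that noise disproportionately.
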