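---
title: "Region-wise combination of synthetic CT volumes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-wise combination of synthetic CT volumes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sctcombine)
```

## The problem

In adaptive radiotherapy of the head, megavoltage cone-beam CT (MVCBCT)
volumes acquired on the treatment machine show the patient's current
anatomy, but their voxel values are not accurate Hounsfield units: contrast
is compressed (values cap near 1400 HU), noise is high, and cup artifacts
depress values toward the image center. Image-translation models can map
MVCBCT to "synthetic CT" (sCT) volumes with CT-like HU values, and those
HU values feed directly into dose calculation, so their accuracy matters
tissue by tissue.

Before training such a model, voxel values must be normalized. The choice
of normalization decides how much of the trainable value range each tissue
receives, and therefore which tissues the model reproduces accurately. A
head CT is dominated by soft tissue — roughly three quarters of in-body
voxels lie in [-400, 150] HU — yet under linear min–max scaling of the CT
range [-1000, 3000] HU that interval occupies only 13.75% of the
normalized range. Nonlinear scaling with a hyperbolic tangent,

$$ N = \tanh\!\left(\frac{HU - a}{b}\right), $$

re-allocates the range: with center $a = 0$ HU and scale $b = 400$ HU the
soft-tissue interval expands to 56% of the range, at the price of
compressing high-HU (dental) tissue to under 0.1%. No single choice of
$(a, b)$ serves every tissue, which motivates the two components of this
package:

1. a **registry of seven normalization preprocesses** (`norm_methods()`):
   linear scaling onto [0, 1] (I) and [-1, 1] (II), and five tanh scalings
   (III–VII) whose centers/scales target the whole image, cavities, soft
   tissue, bony tissue and dental tissue respectively, each with exact
   inverses and interval-occupancy analysis;
2. a **region-wise combiner** (`fit_selection()`) that learns, per
   reference-HU bin, which of several candidate sCT volumes is most
   accurate, and stitches the winners into one combined volume.

## The combination algorithm

Candidate sCT volumes generated from the *same* MVCBCT share its anatomy,
so a voxel-wise selection among them is geometrically consistent. The
fitted object is a `selection_map`; fitting proceeds as:

1. **Smooth** the reference MVCBCT with a slice-wise 5×5 mean filter
   (`smooth_reference()`), so bin membership reflects local tissue rather
   than single-voxel noise.
2. **Partition** the in-body voxels into 48 bins of 50 HU over
   [-1000, 1400] HU by the smoothed value (`partition_regions()`). Bins
   are half-open with the last closed; out-of-range values clamp into the
   end bins.
3. **Score** every candidate in every bin by the structural similarity
   index against the planning CT, computed on the pooled masked voxel
   population (`region_ssim()`), pooling voxels across all training cases.
4. **Select** the best-scoring candidate per bin. Bins with fewer pooled
   voxels than `min_support` (default 100) inherit the winner of the
   nearest supported bin, ties resolved toward lower HU; exact score ties
   resolve to the lexicographically smaller candidate id. Both rules are
   arbitrary but deterministic, which we value over cleverness here.

Applying the map to a new case (`predict()`, `stitch()`) repeats steps 1–2
on the new reference, copies each in-body voxel from its bin's winner
(producing `sCT_Combine`), and median-filters the result with a slice-wise
5×5 window (`sCT_Blur`) to soften stitching seams. Smoothing is applied to
the whole image, not only inside the body, since evaluation masks exclude
outside-skin voxels anyway.

Two properties follow by construction and are enforced in the test suite:
the stitched volume contains no values that are not candidate values at
that voxel, and the pipeline is fully deterministic.

## Evaluation suite

`mae()`, `rmse()`, `psnr()` and `ssim()` implement the four standard
image-quality measures on arbitrary masked voxel populations. Two
conventions deserve mention:

* **SSIM** is computed in its global form on the masked population —
  means, population variances and covariance over the selected voxels —
  rather than as a sliding-window mean. The global form is well defined on
  arbitrary region masks (a windowed map is not), equals 1 exactly iff the
  masked values are identical, and uses the conventional stabilizers
  $c_1 = (0.01 L)^2$, $c_2 = (0.03 L)^2$ with $L = 4000$ HU (the CT span).
  Published window-based SSIM values are therefore not directly comparable
  to these scores.
* **PSNR**'s MAX defaults to the reference CT's maximum within the
  evaluated mask (configurable to a fixed ceiling), so identical volumes
  report `Inf` rather than an arbitrary large number.

`tissue_report()` evaluates per tissue range — cavity [-1000, -400), soft
[-400, 150), bone [150, 3000] — with membership decided by the *reference*
CT, so all candidate volumes are scored on identical voxel sets; shared
endpoints belong to the lower range, mirroring the combiner's bin
convention. `oar_report()` adds per-organ metrics, signed-error samples
and per-slice MAE series; `qq_and_hist2d()` produces matched quantile
pairs and a joint 2-D histogram for distributional comparison.

The body ("inside the skin") mask is derived by thresholding at -400 HU —
the cavity/soft-tissue boundary — keeping the largest 3-D connected
component and filling holes slice-wise (`body_mask()`). How the skin
contour was obtained in clinical datasets is generally not recorded; this
construction is reproducible and configurable, which we prefer to
guessing a proprietary contouring method.

## The phantom generator

Patient images cannot ship with a package, so `generate_ct()` builds a
head-like phantom from nested ellipsoids: a soft-tissue body containing an
air cavity, a mandible-like bone compartment with teeth-like high-HU
insets, and parotid-like soft-tissue OARs. Default volume fractions follow
head composition (cavity 0.95%, soft 75.55%, bone 21.44%, teeth 2.06% of
in-body voxels); sub-structure semi-axes are derived analytically from the
fractions, so realized fractions track the targets (within ±20% relative,
verified across seeds) for any jittered body size. Per-tissue HU values
are drawn from normal distributions (soft 30 ± 40 HU, bone 700 ± 200 HU,
teeth 2200 ± 250 HU, cavity -700 ± 80 HU) plus 10 HU global noise,
clipped to [-1000, 3000] HU.

`degrade_to_mvcbct()` emulates the MVCBCT appearance: a monotone
piecewise-linear contrast map with a 1400 HU ceiling (default: identity
below 400 HU, then linear compression of [400, 3000] onto [400, 1400]), a
radial cup bias `amplitude * (1 - (r/R)^p)` subtracted toward the center
axis (default 80 HU, $p = 2$; the phenomenon's functional form is not
standardized, so a smooth radial profile with configurable exponent was
chosen), and 25 HU Gaussian noise.

`simulate_candidates()` constructs candidate sets that make the combiner's
premise literal: each candidate is exact where the smoothed reference HU
falls inside its designated band and biased by 300 HU (plus 30 HU noise)
elsewhere, with the default three bands splitting [-1000, 1400] at -150
and 350 HU — multiples of the 50 HU bin width, so every bin lies wholly in
one band. Because band membership is decided on the *same* smoothed
reference the combiner partitions, the designed bin-to-candidate
assignment is recoverable exactly, giving an end-to-end oracle:
`fit_selection()` must return the designed winner on every supported bin,
and the stitched volume must match the ground truth inside the body.

What the phantom does **not** emulate: real anatomy (atlases would add
dependencies without sharpening any test), scatter or beam-hardening
physics, registration error between CT and MVCBCT, and — most importantly
— realistic sCT error structure, which in practice varies smoothly rather
than switching at band edges. Passing the oracle tests therefore
demonstrates algorithmic correctness of selection/stitching/evaluation,
not clinical performance; accuracy figures from phantom runs are not
comparable to patient-data results.

## Numerical choices

* Normalization bounds are fixed per modality (CT [-1000, 3000], MVCBCT
  [-1000, 1400] HU), never per-image min/max: published mapped-value
  tables are only consistent with fixed bounds, and per-image bounds would
  break cross-image comparability. Inputs are clipped to the bounds before
  mapping.
* Interval proportions divide by the full normalized-range width (1 for
  [0, 1] methods, 2 otherwise), not the achieved range width; only this
  denominator reproduces the published occupancy figures (e.g. 56.00% for
  soft tissue under method III).
* The tanh inverse clamps its argument to $[-1 + 10^{-7}, 1 - 10^{-7}]$ so
  saturated values map to finite HU; round trips are accurate to well
  under 0.5 HU wherever $|(HU - a)/b| \le 5$.
* Report tables round half away from zero at 2 decimals
  (`round_half_away()`), matching the convention of the published tables.
  One published cell (method III at -1000 HU) appears to have been
  truncated rather than rounded in print; this package follows the
  formula.
* Both window filters use replicated borders and operate slice-wise in
  2-D on axial slices, matching the 2-D filter semantics of common image
  libraries; they are implemented to be bit-identical to a brute-force
  double-loop evaluation (the mean filter accumulates shifted slices in a
  fixed scan order), which the tests exploit.
* Degenerate inputs fail loudly: empty masks, all-air volumes, manifests
  with mismatched grids and selection maps naming absent candidates all
  raise errors rather than guessing.

## Problem sizes

The test suite and the acceptance script run entirely on generated data:
unit tests use 48×48×10 phantoms (~8000 in-body voxels), and the
end-to-end combiner checks use the generator's default 96×96×24 grid with
three training cases and one test case per replicate, three replicates.
These sizes were chosen to exercise every code path — all 48 bins with
realistic support imbalance, sparse-bin fallback, multi-case pooling —
while keeping a full run in the order of seconds; the algorithms are
O(voxels) and transfer unchanged to clinical 256×256×N grids.

## Known limitations

* DICOM series input is not supported; convert series to NIfTI first.
  Registration and resampling are out of scope: all volumes of a case must
  share one grid, which is verified, not corrected.
* The per-bin SSIM is pooled in 3-D across slices and cases; per-slice
  scoring followed by averaging would weight slices equally instead of
  voxels and is not offered.
* Whether median smoothing helps or hurts a given metric depends on the
  error structure; the package reports both `sCT_Combine` and `sCT_Blur`
  and asserts no ordering between them.
* Automatic optimization of tanh centers/scales per tissue is not
  implemented; the registry is user-extensible via `norm_spec()` and
  JSON round trips.
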