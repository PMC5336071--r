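---
title: "Vein enhancement from NIR trans-illumination images: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vein enhancement from NIR trans-illumination images: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(veinviz)
```

## The problem

Venipuncture fails most often when the vein cannot be seen. In the
near-infrared window (700–1000 nm) skin chromophores absorb weakly while
hemoglobin still absorbs strongly, so a vein trans-illuminated with NIR light
appears as a dark curvilinear track on a brighter tissue background. A
practical device built around this idea has two halves, and so does this
package:

* an **image pipeline** that turns a raw NIR frame into a one-pixel vein
  skeleton overlaid on an enhanced image, and
* a **design calculator** for the illumination module itself: if light is
  shone from two sides at an angle, how steep must the angle be, and how far
  apart must the two diode lines sit, for the beams to meet at the vein?

Because the hardware (camera, diodes, filters, phantoms) is not reproducible
at a desk, the package carries a **synthetic phantom module** that renders
images with known ground-truth centerlines and simulates the two bench
experiments (intensity vs. phantom thickness, intensity vs. source distance)
that anchor the design numbers. Everything the tests assert runs against
these synthetic inputs.

## The pipeline

`run_pipeline()` composes eight deterministic stages. Each is exported on its
own, and composing them manually reproduces the pipeline result exactly.

1. **ROI crop** (`extract_roi`). With two-sided illumination and a band-pass
   filter, everything outside the lit band is black; processing is restricted
   to an explicit rectangle (default: the whole frame). Automatic band
   detection is deliberately out of scope — the lit band is a property of the
   rig, known to the operator.
2. **Gaussian blur** (`gaussian_blur`, `blur_sigma`, default 1 px). Light
   sensor-noise suppression before any contrast manipulation.
3. **Complex histogram equalization** (`che`). The pixelwise average of
   global histogram equalization (`ghe`) and contrast-limited adaptive
   equalization (`clahe`). GHE maximizes overall contrast but preserves the
   non-uniform two-sided illumination; CLAHE (default 8×8 tiles, clip
   limit 2.0 in multiples of the mean bin height) flattens the illumination
   but can promote local artifacts. Their mean keeps faint branches visible
   while damping both failure modes.
4. **Pre-filter smoothing** (`presmooth_sigma`, default 4 px). Histogram
   equalization steepens the intensity mapping exactly where the histogram
   peaks — the flat background — so it amplifies background noise by a large
   factor, and the Hessian-based filter of the next stage is highly
   noise-sensitive. The default equals the nominal vein half-width: structure
   narrower than the narrowest vessel of interest is treated as noise. This
   second blur is what makes the downstream threshold workable on noisy
   frames; with it disabled (`presmooth_sigma = 0`) the binarized map of a
   noisy image degenerates into speckle.
5. **Multiscale vesselness** (`frangi`). See below.
6. **Adaptive mean threshold** (`adaptive_threshold`, window 63 px, offset
   10). Each pixel of the 8-bit vesselness map is compared with the mean of
   its local window plus a small offset. The local window tracks whatever
   illumination bias survives equalization. The offset matters: against the
   bare mean, about half of the pixels of any noise-only flat region land on
   the foreground side, and the closing and thinning stages preserve such
   speckle. Demanding a response a fixed margin above the local mean (10 of
   255, ~4% of the range — well within the usual range of the offset constant
   in mean-type adaptive thresholding) suppresses this failure mode while
   leaving true vessel responses, which sit far above their local mean,
   untouched. `adaptive_threshold()` itself defaults to offset 0 (the bare
   textbook rule); the pipeline default is set in `segmentation_params()`.
7. **Morphological closing** (`morph_close`, filled-ellipse element, 13×3
   bounding box). Fills holes and reconnects broken segments; the wide, flat
   element matches roughly horizontal vein tracks. The defaults 63 and 13×3
   are tied to an 80×320 ROI; no scaling rule is defined, so other frame
   sizes keep the same defaults unless overridden.
8. **Zhang–Suen thinning and overlay** (`zhang_suen_skeleton`,
   `overlay_skeleton`). Classic two-subiteration thinning to a one-pixel
   skeleton, then saturating addition onto the CHE image so skeleton pixels
   render white.

A degenerate input with no line structure anywhere (vesselness identically
zero, e.g. a constant frame) short-circuits to an empty skeleton with a
warning rather than passing an all-zero map to the threshold, whose tie rule
(pixel equal to its window mean counts as foreground) would otherwise turn
the whole frame white.

## The vesselness filter

The local shape of the intensity surface is captured by the Hessian of the
image smoothed at scale $\sigma$, computed by separable convolution with
analytic Gaussian-derivative kernels (truncation radius $\lceil 3\sigma
\rceil$, edge-replicated borders) and normalized by $\sigma^{2\gamma}$ — one
factor $\sigma^{\gamma}$ per differentiation order — so that responses are
comparable across scales ($\gamma = 1$ by default: no preferred scale).

With eigenvalues ordered $|\lambda_1| \le |\lambda_2|$, a vessel cross-section
gives $\lambda_1 \approx 0$ (little change along the vessel) and a large
$\lambda_2$ of positive sign for a dark tube. Two dimensionless quantities
enter the score: the blobness ratio $R_B = \lambda_1/\lambda_2$ (near 0 on
lines, near 1 on blobs) and the structureness $S = \sqrt{\lambda_1^2 +
\lambda_2^2}$ (near 0 in flat background). The single-scale score is

$$V_0 = \begin{cases} 0 & \lambda_2 \le 0 \\
\exp\!\left(-\dfrac{R_B^2}{2\beta^2}\right)
\left(1 - \exp\!\left(-\dfrac{S^2}{2c^2}\right)\right) & \text{otherwise,}
\end{cases}$$

and the final map takes the per-pixel maximum over the scale list, recording
the argmax scale. A `polarity = "bright"` switch inverts the sign condition
for bright-on-dark structures.

Parameter choices:

* **Scales** default to $\{2, 3, 4, 5, 6\}$ px. The response of a line of
  Gaussian half-width $w$ peaks near $\sigma = \sqrt{2}\,w$, so the list must
  bracket the expected half-widths; the default brackets the nominal 4 px
  half-width used throughout the synthetic module.
* **$\beta = 0.5$**, the conventional 2D value for the blob discount.
* **$c$** defaults to `"auto"`: half the maximum Hessian norm observed in the
  image across all scales. One global value is used (rather than one per
  scale) so the cross-scale maximum is not distorted. If the global maximum
  is at floating-point residue level the image has no structure and the map
  is returned as exact zeros; likewise any pixel with $S \le 10^{-8}$ (far
  below the 8-bit quantization step) scores exactly zero.
* Eigenvectors use the sign convention "first nonzero component positive";
  an isotropic (scalar) Hessian gets the coordinate axes as its basis.

Two numerical details are deliberate. First, convolution taps are accumulated
as symmetric pairs $k_t (x_{+t} \pm x_{-t})$ from the center outward, and the
differentiated axis is always the inner separable stage (with the mixed
derivative symmetrized over both stage orders); because IEEE addition is
commutative this makes the filter *bitwise* equivariant under 90° rotations,
which the tests assert with `identical()`. Second, the even derivative
kernels have their truncation residual removed so constants map to exactly
zero. All internal arithmetic is double precision; the map is rescaled to
8 bits (max-normalization, all-zero maps stay zero) only at the segmentation
boundary and on disk — thresholding the 8-bit map rather than the raw floats
makes runs reproducible across platforms at the cost of 1/255 quantization.

Rounding everywhere in the package is *half away from zero*
(`round_half_away`), stated once and used for every real-to-8-bit
conversion, so results do not depend on the parity behavior of banker's
rounding.

## Histogram equalization details

`ghe` maps level $v$ to $\mathrm{round}(255\,\mathrm{cdf}(v))$ with the
empirical CDF over all pixels; the mapping is monotone, hence
rank-preserving, and near-idempotent. `clahe` partitions the frame into a
tile grid, clips each tile histogram at `clip_limit` multiples of the mean
bin height (the Zuiderveld convention; values ≥ 256 cannot clip anything),
redistributes the clipped mass uniformly over all 256 bins, and blends the
four neighboring tile mappings bilinearly at each pixel. With a single tile
and clipping disabled it reduces exactly to `ghe`, which the tests use as an
oracle. `che` averages the two outputs in real arithmetic and rounds once.

## Segmentation details

The adaptive threshold compares against the window mean with a $10^{-6}$
tolerance so pixels exactly at the mean land on the "at or above" branch
despite floating-point accumulation; ties go to foreground. The closing
embeds the mask in an infinite background (implemented by padding wide
enough that border effects cannot reach the frame), so the textbook
identities hold exactly: closing is extensive and idempotent, and the test
suite checks it against an independent brute-force set-operation oracle. The
structuring element is the filled discrete ellipse inscribed in its bounding
box; note that a 13×3 box yields the discrete plus-like shape (a 13-pixel row
plus single pixels above and below), the same shape conventional ellipse
constructions produce at that size. Zhang–Suen thinning works on {0,1}
internally, deletes flagged pixels simultaneously per subiteration, and stops
when a full pass changes nothing; it never adds pixels and preserves
8-connectivity, which the tests check on line, Y-junction and ring fixtures.

## The module design calculator

If the two diode lines sit a width $W$ apart on the skin and their beams
penetrate a depth $d$ through tissue before becoming too weak, the beams meet
at depth $D$ (the vein) when $\sin\theta = D/d$, giving $\theta =
\arcsin(D/d)$ and $W = 2\sqrt{d^2 - D^2} = 2d\cos\theta$. With the typical
cubital-fossa vein depth $D = 1.5$ cm and a measured penetration depth $d =
2$ cm this yields $\theta \approx 48.6°$ and $W \approx 2.65$ cm, the worked
example in the tests and acceptance script.

The penetration depth itself is defined *operationally* as the smallest
tissue thickness at which transmitted intensity falls to 80% of the
source-side reading — an unusual definition (much shallower than the 1/e
attenuation length), so `penetration_depth()` exposes the fraction as a
parameter rather than hard-coding it. The crossing is located by linear
interpolation between bracketing samples; a non-monotone profile uses the
first crossing; a profile that never reaches the threshold returns `NA` with
a warning rather than extrapolating.

## The synthetic phantom module

`render_phantom()` emulates what the rig photographs, not how the photons
travel:

* **illumination**: a sum of two mirrored exponential falloffs from the
  left/right frame edges (length scale `width/8`), bright at the edges and
  dim at the center, the signature of a two-sided module;
* **veins**: polyline centerlines subtracted with a Gaussian cross-profile
  (default half-width 4 px, contrast 40 gray levels — the half-width stands
  in for a 3 mm tube at the prototype's working distance; no px/mm
  calibration exists, so the value is a documented convention);
* **distractors**: radial Gaussian blobs, for testing the line-vs-blob
  discrimination;
* **noise**: additive Gaussian (default sd 5 gray levels) under a fixed
  seed, restoring the caller's RNG state afterwards.

The attenuation simulator is a phenomenological Beer–Lambert model
$I(t) = I_0 e^{-\mu t}$ with $\mu = \ln(1.25)/2 \approx 0.112\ \mathrm{cm^{-1}}$,
calibrated so intensity reaches 80% of $I_0$ at exactly 2 cm — the single
quantitative anchor available for the bench experiment; the distance series
multiplies in an inverse-square factor $(z_0/(z_0+z))^2$ with aperture scale
$z_0 = 1$ cm, for which only monotonicity and ratio properties are asserted.

What the simulator does *not* capture — and therefore what passing tests do
not demonstrate about real data: speckle and structured sensor noise, skin
texture and hair, scattering halos around veins, depth-dependent blur,
motion, and any spectral effect. The end-to-end recovery test (skeleton
within 2 px of the ground-truth centerline on average, ≥ 90% of centerline
pixels within 3 px of the skeleton, at noise sd 5 and contrast 40) validates
the pipeline's internal consistency on a clean-but-noisy phantom, not
clinical performance.

## Problem sizes and runtime

The canonical frame is 80×320 px (the ROI size the segmentation defaults are
tied to); a full pipeline run takes well under a second, the whole test suite
a few seconds, and the acceptance script (1000-matrix eigen oracle, fixture
rendering, one end-to-end run) a few seconds more.

## Known limitations

* No pruning of spurious skeleton branches; short spurs at junctions are
  expected and left in place.
* Threshold and closing defaults do not rescale with frame size.
* The CLAHE clip limit interacts with tile size; very small tiles with a low
  clip limit approach an identity mapping.
* The bright-band ROI is user input, not detected.
* `frangi` stores one Hessian eigenfield per scale while running; for very
  large frames with many scales, memory grows accordingly.
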