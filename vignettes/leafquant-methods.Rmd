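---
title: "Quantifying leaf disease symptoms: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying leaf disease symptoms: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafquant)
```

## The measurement problem

A leaf photographed flat against a uniform bright panel carries most of
the visual information a plant pathologist uses to grade disease
severity: yellowing (chlorosis), dark dead patches (necrosis), outline
distortion, bright spots, and — under back-light — abnormally prominent
venation (the mosaic / vein-clearing symptom).  `leafquant` turns each
of these into a number using only RGB channel arithmetic, thresholding,
mathematical morphology, connected components and edge detection, so
every step is fast, deterministic and auditable.

All five pipelines assume *panel imaging*: the leaf is darker than the
background in the blue channel, which is also the channel least
disturbed by yellowing (chlorosis raises red and green, not blue).
That single assumption gives a common leaf segmentation: threshold the
blue channel from below and keep the largest connected component.

## The five symptom statistics

**Chlorosis.** The yellow component is the equal-weight channel mix
$Y = 0.5R + 0.5G$.  The frame is split into four sections around the
intensity-weighted centroid of $Y$, and the section means
$R_1,\dots,R_4$ are summarized by two vector moduli:

$$R_n = \lVert (R_1, R_2, R_3, R_4)\rVert, \qquad
R_{diff} = \lVert (R_1{-}R_2,\; R_1{-}R_3,\; R_1{-}R_4,\;
R_2{-}R_3,\; R_2{-}R_4,\; R_3{-}R_4) \rVert.$$

$R_n$ measures how chlorotic the leaf is overall (a uniform image of
yellow value $v$ gives exactly $R_n = 2v$); $R_{diff}$ measures whether
the yellowing is localized ($R_{diff} = 0$ iff all section means are
equal).  By default section means are computed over leaf pixels only —
including a near-white panel background would swamp the means; a
whole-frame mode is kept for the literal per-frame definition.  Empty
sections (possible with an off-centre leaf and a mask) are excluded
with a warning.

**Necrosis.** Lesions are brown/black, so they are dark in the green
channel, where lesion/tissue contrast is best; chlorotic tissue remains
bright there, which is what makes the count chlorosis-proof.  The green
channel is first smoothed with a grayscale morphological *opening*
(removing bright speckle smaller than the structuring element, default
3×3 box), then thresholded from below inside the leaf mask:

$$A_n = 100\,\frac{A_{np}}{A_T}\ \%.$$

**Deformation.** The sphericity (deformation) index of the silhouette is

$$I = \frac{p^2}{4\pi A},$$

1 for a circle and increasing with outline irregularity.  Interior
holes are filled before measurement: only the outer contour defines
$p$.

**White spots.** The blue channel is thresholded from above.  Bright
components touching the frame border are panel background ($A_{BG}$);
this is the only parameter-free rule that keeps interior spots out of
the background class.  The largest dark component of the complement is
the leaf without its spots ($A_{TL}$).  Spots follow by exact
accounting over the frame size $A_{ZS}$:

$$A_{ws} = A_{ZS} - A_{BG} - A_{TL}, \qquad
A_{pws} = 100\,\frac{A_{ws}}{A_{TL} + A_{ws}}\ \%.$$

The identity is how $A_{ws}$ is *defined*, but the suite asserts it
anyway as a tripwire for component-bookkeeping bugs.  A consequence of
the arithmetic: stray dark noise outside the leaf is attributed to
$A_{ws}$; an optional pre-opening (`denoise = TRUE`) mitigates it.

**Mosaic.** Back-lit venation is brighter than the lamina in the blue
channel.  The channel is contrast-stretched onto the working scale
(0–1023 by default), enhanced with the two morphological hats,

$$A' = A + Thw_B(A) - Thb_B(A), \qquad
Thw_B = A - \gamma_B(A),\quad Thb_B = \varphi_B(A) - A,$$

and edges are extracted with the Canny detector (Gaussian smoothing,
Sobel gradients, non-maximum suppression, double-threshold hysteresis).
The reported density is $A_{mosaic} = 100\,A_{map}/A_{TL}$, the
percentage of leaf area covered by edge pixels.  The hat combination is
a design choice: "apply top-hat and bottom-hat sequentially" does not
fix an algebra, and the additive form above is the classical
morphological contrast enhancement that matches the stated purpose;
`hat_mode = "replace"` applies the two corrections in sequence instead.
Since hysteresis output is already binary, no further binarization is
applied to the edge map.  Leaf outline edges are counted in $A_{map}$;
on a vein-free full-frame leaf they contribute about 0.3 % (the
validation bound is 2 %).

## The morphological core

Binary erosion/dilation follow the literal set definitions: erosion
keeps a pixel when the structuring element translated there lies
entirely on foreground, dilation (with the point-reflected element)
when it overlaps foreground at all.  Grayscale versions are the min/max
filters.

*Border policy.*  Outside-of-frame pixels count as background for
binary erosion and dilation (the element must fit in the frame; masks
never grow past it), and are ignored by the grayscale filters (+∞ for
min, −∞ for max).  Closing is evaluated on a temporarily expanded frame
and cropped back, which makes it equal the infinite-plane closing of
the finite image.  These choices are not cosmetic: they are exactly
what keeps the classical lattice identities true on every fixture the
suite checks — duality
`dilate(A, B) = !erode(!A, reflect(B), pad = "foreground")`, opening
anti-extensive/increasing/idempotent, closing extensive/idempotent, and
both hats non-negative.  A naive background-padded erosion inside
closing would visibly violate extensivity at the frame border.

The "median filter based on morphological opening" used before
necrosis thresholding is implemented as a grayscale opening — the
defining formula, not the colloquial name, is authoritative.

## Perimeter estimation (a calibration trap)

The outer boundary is traced with Moore-neighbour tracing.  Three
length estimators are offered:

* `"polygon"` (default): length of the polygon through every 5th traced
  boundary point.  Chord subsampling averages out pixel jaggedness:
  a digitized disk of radius 200 yields $I = 1.000$ and a 300-pixel
  axis-aligned square $I = 1.257$ (analytic $4/\pi = 1.273$), and $I$
  varies by under 5 % under rotation.
* `"chain"`: the classical 8-chain length with diagonal steps weighted
  $\sqrt2$.  Intuitive, and exact for axis-aligned rectangles (a 5×5
  square gives $p = 16$), but it overestimates smooth curved boundaries
  by ≈5 % *systematically* (the well-known chain-length bias), which
  inflates the disk index to ≈1.11.  Corrected weight sets
  (e.g. Vossepoel–Smeulders) fix the disk but break the square.
* `"raw"`: plain step count, for literal pixel-counting comparisons.

Because no fixed per-step weighting can calibrate both the circle and
the square, the polygon estimator is the default; the chain mode is
retained for users who want the textbook chain length.  A single
isolated pixel reports $p = 4$ (unit-square convention).  The stride
adapts down for tiny objects (at least 8 polygon vertices).

## Tunable parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| `t_leaf` | 0.80 | blue threshold, fraction of `max_value`; leaf is below |
| `t_necro` | 0.35 | green threshold, fraction of `max_value`; necrosis below |
| `t_spot` | 0.80 | blue threshold, fraction of `max_value`; spots/panel above |
| `se_necrosis` | `se_box(3)` | opening prefilter; removes speckle < 3 px |
| `se_mosaic` | `se_disk(4)` | 9×9 disk; veins are thin relative to it |
| `canny_sigma` | 1.4 px | smoothing scale |
| `canny_lo`, `canny_hi` | 0.10, 0.25 | hysteresis thresholds, fractions of max gradient |
| `connectivity` | 8 | component adjacency (4 available) |
| `bit_depth` | 8 | working scale; 10 gives the 0–1023 range |
| `stretch_hi` | 1023 | mosaic working range upper end |

Thresholds are fractions so a configuration is valid at either bit
depth.  All of them are exposed through `analysis_config()` and the
command line; the threshold defaults assume panel imaging with the
intensity separation described next.

## What the synthetic generator emulates — and what it does not

`generate_leaf()` renders a leaf-like silhouette (polar curve
$r(\theta) = R(1 + a\cos k\theta)$ plus seeded band-limited radial
noise for boundary roughness) on a bright panel, and paints symptom
classes with pixel-exact ground truth: chlorotic yellowing (generalized
or one-quadrant), necrotic disks placed by rejection-adjusted dart
throwing until the requested fraction is covered to within ±1 %, white
spots kept ≥1 px inside the silhouette, and, under back-light, a
deterministic bifurcating venation tree whose pixel fraction grows
strictly with recursion depth.  Class intensity bands are separated by
far more than 10 % of the scale in each discriminating channel
(e.g. blue: tissue ≈45 vs panel ≈250 at 8 bit, ±3 units of uniform
noise), so thresholding at band midpoints recovers the class raster
*exactly*; residual pipeline errors in the validation suite are
therefore attributable to boundary pixels and morphology, not to
segmentation failure.

The generator deliberately does **not** emulate photographic reality:
no texture, no specular highlights, no illumination gradients, no
shadows, no demosaicing artifacts, no intermediate symptom intensities
along lesion rims.  Passing the suite shows the *algorithms* are
implemented correctly and respond monotonically to graded symptom
loads under clean separability; it does not certify the default
thresholds on real photographs, which is why every threshold is
user-tunable ("according to the light conditions").

Determinism contract: one seeded RNG stream per image, seed recorded in
the ground truth; the same `leaf_spec` reproduces the image bit for
bit, and the generator restores the caller's RNG state.

## Numerical choices and degenerate inputs

* Threshold comparisons are strict (`>` / `<`); pixels exactly at the
  threshold belong to neither mask.
* Centroid axis naming: `cx` is the *row* coordinate (the row index
  carries the `x` label in the defining sums).  Indexing is 1-based
  throughout, matching R; all reported statistics are index-origin
  invariant.
* Section boundary pixels go to the `>=` side; any consistent rule
  works since $R_n$ and $R_{diff}$ are permutation-invariant.
* Constant images: `contrast_stretch()` returns the midpoint with a
  warning; `enhance_venation()` passes the channel through unchanged.
* All-zero yellow image: the centroid errors out ("zero total
  intensity") rather than guessing.
* An all-bright frame raises "no leaf found"; in batch runs the error
  is recorded per image and the batch continues.
* The NMS tie-break (`>=` toward one gradient side, `>` toward the
  other) keeps exactly one pixel of a two-pixel plateau.

## Validation problem sizes

The shipped suite exercises the oracles exhaustively where that is
cheap (all 512 binary 3×3 images against brute-force set-definition
oracles; 100 random 16×16 grayscale images with random elements up to
5×5) and runs the generator sweeps at 384×320 to 640×512, sizes at
which boundary-pixel effects are already below the ±2-point acceptance
bands.  The end-to-end batch and the vein-free mosaic bound run at the
full 1280×1024 sensor frame.  These sizes are validation choices, not
limits: the pipelines are routinely run at 1280×1024 (a full panel
`all` analysis takes a few seconds per image).

## Known limitations

* The leaf mask is purely intensity-based; soil, shadows or a
  non-uniform panel will corrupt every area denominator.
* White-spot accounting attributes any off-leaf dark noise to the spot
  area (a direct consequence of the accounting identity).
* Spots touching the silhouette edge can bridge to the background
  brightness and then follow the border-touching rule; the generator
  keeps its spots interior, mirroring the idealized imaging setup.
* No cutoffs are provided to label a leaf "localized" vs "generalized"
  chlorosis or "deformed": the tool reports the continuous statistics
  and leaves classification to the user, who has the species context.
* $R_n$/$R_{diff}$ are reported in native intensity units of the
  working bit depth; they are comparable only between images taken at
  the same depth and exposure.
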