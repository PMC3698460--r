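---
title: "Measuring continuous perseveration from scribble images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring continuous perseveration from scribble images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spindex)
```

## The problem

Patients with hemispatial neglect often perseverate in cancellation tasks:
instead of crossing a target with a single mark they keep moving the pen
without lifting it, leaving a *scribble* — one continuous trace composed of
many elementary movements. The clinically interesting quantity is the number
N of those elementary movements, but N is only directly observable from a
video of the performance, which is rarely available. `spindex` computes a
retrospective proxy for N, the Scribble Perseveration Index (SPI), from the
scanned ink trace alone.

## The model

The elementary movements are assumed to be of two kinds: roughly linear
*strokes*, or roughly circular (≈360°) *loops*. If the pen travelled a total
path of length L made of elements of mean length l, then N = L / l. Neither
L nor l is observable once the trace overlaps itself, so both are replaced
by measurable quantities:

* L is estimated by A / t — the ink area divided by the pen-trace thickness
  (a trace of length L and width t covers about L·t of paper; overlap makes
  this an under-estimate);
* l is estimated by the scribble's linear size LS for stroke scribbles, and
  by π·LS for loop scribbles (a loop is about π times as long as its
  diameter).

Two adjustments make the degenerate pen-dot (L = 0, where LS = t and
A ≈ t²) score correctly null, and subtracting 1 counts only the movements
*beyond* the first, non-perseverative one:

* strokes: SPI = (A/t − t) / (LS − t) − 1
* loops:   SPI = (A/t − t) / (π (LS − t)) − 1

A count of perseverative movements cannot be negative, so negative values
(possible through measurement fluctuation) are clamped to zero; the raw
value is kept for diagnostics. Because the formula is a ratio of lengths,
the index is scale free: two scribbles identical in shape but different in
size obtain the same score, and pixel units cancel (no dpi metadata is
needed).

## The measurement chain

`score_scribble()` runs the full pipeline.

**Binarization.** Scans are dark ink on light paper; ink is every pixel at
or below a threshold. The automatic threshold maximizes the sum of Shannon
entropies of the two histogram classes (Kapur's maximum-entropy criterion),
evaluated exhaustively over all 255 cuts; when the objective plateaus (e.g.
a two-level histogram) the plateau midpoint is used, so the cut falls in
the middle of the intensity gap. A fixed integer threshold can be supplied
to reproduce a specific workflow bit-exactly. An empty mask is an error;
more than 90% ink raises a polarity warning.

**Area and thickness.** A is the foreground pixel count. The pen-trace
thickness t automates the manual act of measuring an isolated portion of
the trace: the mask is block-upsampled 2× (which removes the even/odd
quantization of medial distances), thinned to a one-pixel skeleton
(Zhang–Suen), and the Euclidean distance transform is read at skeleton
pixels that are local maxima of the distance map — each such value is the
radius of a pen disk inscribed in the trace. The thickness is the lower
quartile of those values (in upsampled pixels, numerically equal to the
trace width in original pixels). The lower quartile, not the median, is the
isolated-portion statistic: in densely perseverated scribbles the majority
of the skeleton can run through merged ink, whose medial width reflects the
pile-up rather than the pen; the stretches an experimenter would single out
populate the lower tail. On a mask with no trace structure at all (a filled
blob) the skeleton collapses to the centre and the estimate approaches the
blob radius; this is flagged (`BlobWarning`, raised when t exceeds 0.8 of
the minimum caliper width) rather than silently corrected.

**Linear size.** LS must reflect the distal component of the gesture (the
strokes/loops) and not the proximal transportation drift, so its
measurement direction follows three ordered rules:

1. *Stroke-aligned* — for stroke scribbles whose skeleton tangents are
   concentrated, LS is the caliper (Feret) diameter along the dominant
   orientation. Tangents come from the structure tensor of the smoothed
   mask evaluated along the skeleton; "concentrated" means at least 80% of
   the tensor-energy-weighted tangents lie within ±20° of the dominant
   axial mean. Both numbers are configurable; the defaults were chosen so
   that well-aligned zigzags pass and compact tangles fail.
2. *Elongated* — if LS_max is strictly more than twice LS_min (a tie is
   not elongated), the transportation likely acted along the major axis,
   and LS is measured orthogonally to the direction attaining LS_max — not
   as LS_min itself, which for concave shapes can occur off-orthogonal.
3. *Average* — otherwise LS = (LS_max + LS_min) / 2.

The caliper profile measures the extent of the projection of foreground
pixel centres on each probe direction plus one pixel of footprint, so a
single pixel has diameter 1 and a dot drawn with a 1-px pen satisfies
LS = t exactly. An experimenter can override both the composition label and
the measurement direction; overrides are recorded with `USER` provenance.

**Composition.** Loop scribbles enclose paper. The automatic classifier
fills the mask's holes, keeps holes larger than t² (crossing strokes
produce slivers of about that scale), and labels the scribble LOOPS when
qualifying holes cover at least 25% of the convex-hull area. The thresholds
are heuristics — the label carries a confidence and the experimenter
override exists precisely because composition is ordinarily judged by eye.

## Numerical choices

* Degenerate dot: when LS − t < 0.5 px the index is the dot case's 0/0;
  the raw value is undefined and the score is 0 with a `DegenerateDot`
  flag. The 0.5 px tolerance avoids division blow-up just short of the
  exact dot.
* π enters at full floating precision.
* Angles are degrees from the +x axis toward +y (image rows), axial in
  [0, 180); all lengths are pixels, with the origin at the top-left.
* All foreground components are measured as one scribble by default (pen
  scans can fragment under thresholding); `largest_component = TRUE`
  restricts to the largest.

## The simulator

`simulate_design()` generates scribbles with known ground truth by
simulating the two-component gesture and rasterizing the pen path.

* *Strokes*: a zigzag whose even vertices sit on a baseline that drifts
  orthogonally to the stroke axis and whose odd vertices are the jittered
  stroke tips. Anchoring the oscillation to the drifting baseline means
  length/angle jitter perturbs individual strokes without accumulating into
  a positional random walk that would swamp the transportation drift.
* *Loops*: full circles (90 samples each) whose centres drift across the
  sheet; the ground-truth path length is the sum of sampled circumferences.
* *Rendering*: a disk of the pen diameter is swept along the path; a pixel
  is ink when its centre lies within half the pen width of the path
  (exact point-to-segment distance — no grid rounding). A fixed 0.2071 px
  sub-pixel canvas offset keeps pixel centres off exact stadium boundaries,
  which for axis-aligned paths would otherwise inflate the trace width by
  one pixel.

The default design mirrors a 2 × 2 × 6 factorial with 4 repetitions
(96 items): pen thicknesses 2 and 6 px (an ordinary pen vs. a thick crayon
at a 100-dpi-like scale), strokes vs. loops, and true element counts
{1, 3, 6, 10, 15, 22}, spanning the movement-count range observed in
brain-damaged patients. Where the validation conditions are not pinned down
by that description — absolute sizes, jitters — the defaults are fixed
conventional values (stroke length 60 px, orthogonal drift 6 px, 10% length
jitter, 8° angle jitter; loop diameter 40 px, centre drift 8 px, 10%
diameter jitter) chosen once to resemble patient scribbles; since the index
is scale free, absolute scales are immaterial. Per-item seeds are derived
from the base seed and the cell indices by a small stable hash, so any cell
is reproducible in isolation and identical (design, seed) pairs give
byte-identical images.

What the simulator does *not* emulate: pen-pressure and velocity profiles
(no ink-density variation), curvilinear transportation, mixed stroke+loop
scribbles, paper texture and scanner noise, or the target letters under the
scribble. Passing the in-silico validation therefore shows that the index
recovers N from clean rasterized kinematics of the assumed gesture model —
not that it survives every artefact of real patient scans.

## Validation harness

`validate_design()` scores a simulated manifest (composition taken from the
manifest, as it is known to the experimenter who drew the scribble) and
reports the Pearson correlation of true N with SPI, the same correlation
for raw ink area (the naive competing proxy, which also absorbs pen
thickness, movement amplitude and movement type), the OLS fit of SPI on N,
and the percent under-estimation 100·(1 − slope). The test suite requires
r(N, SPI) ≥ 0.90, r(N, SPI) > r(N, area), strictly increasing cell-mean
SPI across the six levels, and a slope in (0, 1) — SPI is expected to
*under*-estimate N increasingly as overlap grows, which is why it is a
proxy and not an unbiased estimate. The full 96-item design is used for
these checks; the remaining tests run on single shapes or reduced designs,
keeping the whole suite around a minute.

## Known limitations

* Rule I's alignment thresholds and the hole-based composition classifier
  are heuristics; borderline scribbles should be scored with explicit
  `composition` / `direction_deg` overrides, which is the intended workflow
  for a human rater.
* Mixed stroke-and-loop scribbles and markedly curvilinear transportation
  are not automated; the rules cover the canonical cases and the overrides
  cover the rest.
* Thickness estimation assumes some stretch of the trace is (locally)
  isolated; on fully merged blobs the estimate degrades to the blob radius
  and is flagged.
* The two-stroke V-sign is expected to score positive but below 1; its
  exact value depends on the V angle and is not pinned by the method.
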