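---
title: "Quantifying animal movement with tracking and optical flow: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying animal movement with tracking and optical flow: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pigflow)
```

## The problem and the model

A fixed overhead camera watches a pen of 4–8 animals. A detector produces
scored boxes per frame; a tracker links them into per-identity tracks; the
question is how far each animal moved. The naive answer — the per-frame
displacement of each track's box centre,
\(M = \sqrt{(x_{c,t}-x_{c,t+1})^2 + (y_{c,t}-y_{c,t+1})^2}\) — inherits
every defect of the boxes. IoU-based association accepts any
sufficiently overlapping box, so a stationary animal's box wanders by a
few pixels per frame and changes size when the animal shifts posture or
is partially occluded. Those fluctuations are indistinguishable from
genuine movement under the centre-displacement estimator, and they
accumulate without bound.

The package therefore treats movement as a property of pixels, not boxes.
Dense optical flow assigns every pixel of frame \(t\) a displacement
\((\Delta x, \Delta y)\) toward frame \(t+1\) under brightness constancy,
\(I(x, y, t) = I(x+\Delta x, y+\Delta y, t+1)\). The tracker's only job
is to delimit which pixels belong to which animal. Per animal and frame
pair the default estimator is the mean in-box flow magnitude
\[
M = \frac{1}{|B|} \sum_{(u,v) \in B} \lVert F(u,v) \rVert_2 ,
\]
with \(B\) the pixel set of the animal's box. A representative-point
variant tracks a single point (the first box centre) through the flow
field; it is cheaper but blind to partial movement such as a head shake,
which is why the in-box average is the default. The centre-displacement
estimator is retained for comparison studies.

Two modelling consequences are worth stating plainly:

- **Fill factor.** The in-box average runs over *all* box pixels,
  background included. An object occupying fraction \(f\) of its box and
  moving rigidly at speed \(s\) over still background yields \(M = f s\)
  exactly (a property the tests verify against ground-truth flow). For a
  tight box around an animal \(f\) is close to 1 and stable over time, so
  cumulative comparisons between animals remain meaningful; absolute
  speeds are scaled by \(f\). No foreground mask is applied — the box is
  the deliberate unit of attribution.
- **Normalisation of partially visible boxes.** The normaliser is the
  discrete pixel count \(|B|\) of the box *clipped to the frame*, which
  equals the box area for interior boxes. Normalising by the nominal
  \(h \times w\) instead would bias animals at the frame edge toward
  zero movement.

## Tracking: two-stage association

Tracking follows the BYTE matching scheme. Per frame:

1. Greedy NMS (IoU 0.5) removes duplicate detections; scores below 0.1
   are discarded.
2. The remainder is split at \(\tau\) (default 0.5) into high- and
   low-confidence sets.
3. Every retained track (active *or* lost) is advanced by a
   constant-velocity Kalman filter over the state
   \((c_x, c_y, a, h, \dot c_x, \dot c_y, \dot a, \dot h)\), where
   \(a = w/h\).
4. High-confidence detections are associated to predicted boxes by
   minimum-cost assignment on \(1 - \mathrm{IoU}\); pairs under the gate
   (0.5) are unmatched.
5. Tracks still unmatched get a second association against the
   low-confidence detections. This is the occlusion path: an animal
   walking behind a pen-mate keeps its (amodal) box but loses detector
   confidence, and the second stage keeps its track alive instead of
   discarding the detection.
6. Matched tracks are Kalman-corrected and record the matched detection
   box; unmatched low-confidence detections are dropped as background;
   unmatched tracks become lost and are removed after 30 frames;
   unmatched high-confidence detections start new tracks immediately
   (no probation), and the retained set is capped at 100 tracks,
   evicting the longest-lost first.

Design points that were genuinely open, and the choices made:

- The split threshold \(\tau\) is configurable with default 0.5: the
  published pen experiments state a 0.5 matching threshold and a 0.1
  detection floor but never print \(\tau\) itself, and a single
  documented default beats a hidden constant.
- Lost tracks keep being predicted and may match in either stage;
  restricting the second stage to last-frame-active tracks is the other
  readable convention, but prediction of "each track" is the plainer
  reading and handles re-appearance after short occlusion.
- Kalman noise scales follow the SORT-family convention (standard
  deviations proportional to box height, 1/20 for positions, 1/160 for
  velocities); the filter specification is a reproducibility decision,
  not a tuned quantity.
- All assignment ties are broken lexicographically by (track index,
  detection index) via an infinitesimal cost bias, so runs are
  bit-reproducible.
- Degenerate (zero-area) boxes have IoU 0 against everything and are
  rejected as Kalman measurements, so they can never be matched or
  initiate state.

## Flow estimation

No learned flow model is bundled; downstream code accepts any provider
of per-pair flow fields (the built-in estimator, or per-pair Middlebury
`.flo` files, e.g. exported from an external network). The built-in
estimator is a classical coarse-to-fine scheme: Gaussian image pyramid
(`pyramid_levels` 3, `pyramid_scale` 0.5), and per level `iterations` 3
rounds of warp-and-refine weighted least squares on the
brightness-constancy normal equations. The `window` parameter (15 px,
odd) sets the Gaussian weighting scale (σ = window/4) of the local
structure sums. Numerical guards: pixels whose 2×2 normal matrix is
near-singular (determinant below 1e−9, trace below 1e−7 — flat texture,
aperture-degenerate) get zero increment rather than amplified noise;
increments are clamped to ±window; each level ends with a 3×3 median
filter, which is what keeps motion-boundary pixels close to the majority
motion of their side. Flow within about one window of the frame border
is inherently less reliable; the package's own property checks assert on
the interior margin.

Forward-flow convention throughout: \(F\) at pixel \((x,y)\) of frame
\(t\) points to frame \(t+1\), in pixels/frame; the box used for the
pair \((t, t+1)\) is the track's box at \(t\). Tracks with gaps (lost,
then re-found) simply contribute no movement records during the gap —
omission is auditable, interpolation would not be.

## Evaluation metrics

CLEAR counts use the standard correspondence rule: pairs carried over
from the previous frame survive while both parties are present and still
overlap at least the 0.5 gate; remaining entries are matched by optimal
gated assignment; `CTP`/`CFN`/`CFP` count matches, missed ground truth
and unmatched predictions, and an identity switch is counted when a
ground-truth identity's matched predicted identity differs from its most
recent previous match (gaps do not reset that memory). MOTA is reported
in percent and can be negative. Identity metrics choose one global
bijection between ground-truth and predicted identities minimising total
mismatches (solved as a padded assignment problem); IDF1 follows from
the resulting IDTP/IDFP/IDFN. Higher-order tracking scores (HOTA) and
localisation-quality metrics are out of scope.

## What the synthetic scenes emulate — and what they do not

The generator reproduces the structural features the pipeline is
sensitive to: 640×640 frames (the pen camera's working resolution),
15 fps as sequence metadata, 4–8 objects of pig-like apparent size
(roughly 10–20 % of the frame side), a mix of static and moving animals,
band-limited noise textures (smoothed white noise) on both background
and objects so that brightness-constancy estimation has gradients to
work with, sub-pixel trajectories rendered by bilinear texture sampling
(integer-snapped motion would quantise the flow and hide estimator
bugs), painter's-algorithm occlusion with amodal ground-truth boxes, and
a detection-noise model with centre/size jitter (default studies use
σ = 2 px), misses, spurious boxes, and occlusion-driven score drops
(detections of objects less than half visible score 0.3 against a 0.9
base). Ground-truth flow is exact by construction: object pixels carry
their object's displacement, occluded pixels the occluder's, background
is identically zero.

It does **not** emulate deformable bodies, lighting changes, shadows,
camera motion, or photometric noise. Passing tests therefore demonstrate
algorithmic correctness — association logic, metric bookkeeping, flow
recovery of rigid translation, estimator algebra — not detector quality
or flow robustness on real barn footage, where brightness constancy is
the binding assumption.

Problem sizes in the test-suite and acceptance studies are the package's
choices for tight feedback: flow-bearing scenes run at 160–320 px with
pig-proportioned objects (60×48 to 120×90), tracking-only studies at the
full 640×640 over 200 frames, Monte-Carlo jitter checks over 10⁴ boxes.

## Known limitations

- Movement is 2-D image-plane displacement in pixels; motion toward the
  camera is invisible and no pixel-to-metre calibration is attempted.
- The in-box average attributes any background motion inside the box
  (e.g. a pen-mate's leg) to the box owner; a segmentation mask would
  sharpen attribution at the cost of a far heavier labelling contract.
- The classical flow estimator underperforms learned models around
  occlusion boundaries; the backend contract exists precisely so a
  stronger flow source can be dropped in as `.flo` files.
- Identity is only as persistent as IoU association allows; animals that
  vanish longer than the lost-track horizon return under new identities.
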