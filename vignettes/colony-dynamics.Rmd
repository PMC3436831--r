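---
title: "Quantifying stem-cell colony dynamics: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stem-cell colony dynamics: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonytrack)
```

## The problem

Mouse embryonic stem cells grown under different media form colonies with
visibly different morphologies: compact, round, optically homogeneous
clusters under serum-free 2i medium, versus flat, spread, irregular sheets
under conventional LIF/serum. Phase-contrast time-lapse imaging captures how
these colonies grow, deform, merge and split over a day of culture, but the
colonies have no trackable landmarks: single cells cannot be resolved inside
a dense cluster, and colonies constantly exchange material. `colonytrack`
quantifies this kind of sequence at the level that *is* observable — the
whole colony and the dense motion field inside it — and turns a raw image
stack into per-colony time series of structural and dynamical statistics
plus a lineage graph.

The pipeline has five stages, each usable on its own:

1. **Fluid image registration** (`register_pair()`) estimates a dense
   displacement field between consecutive frames.
2. **Segmentation** (`segment_colonies()`) detects colony regions in a
   single frame.
3. **Tracking** (`track_sequence()`) propagates colony labels with the
   displacement field and reconciles them with fresh segmentations,
   recording merges and splits.
4. **Measurement** (`measure_sequence()`, `summarize_frames()`,
   `compare_conditions()`) computes per-colony features and condition-level
   statistics.
5. **Visualization** (`layout_streams()`, `render_streams()`,
   `autoplot()`) draws each colony as a downward stream whose width tracks
   area and whose color tracks circularity.

## The registration model

Given a source frame $S$ and template frame $T$ (gray values in $[0,1]$),
we seek a displacement field $u(x)$ such that $S(x - u(x)) \approx T(x)$
(an Eulerian warp). The matching energy is the sum of squared differences

$$E_{\text{match}}(u) = \tfrac12 \int \big(S(x - u(x)) - T(x)\big)^2\,dx ,$$

which alone is ill-posed. Instead of penalizing $u$ directly (an elastic
model, which resists the large rearrangements colonies actually undergo),
the regularity term acts on the *velocity* $v = \partial u/\partial \tau$
of a pseudo-time evolution — a fluid model — and penalizes its curvature:

$$E_{\text{reg}}(v) = \tfrac{\alpha}{2} \int \sum_{\ell} (\Delta v_\ell)^2\,dx .$$

Taking the over-damped limit of the Euler–Lagrange flow (inertia dropped,
position-independent damping $\gamma$, viscosity $\eta$) gives, at each
pseudo-time instant,

$$\gamma v + \eta \Delta^2 v = f(x, u), \qquad
  f(x, u) = \big(S(x-u) - T(x)\big)\, \nabla S\big|_{x-u},$$

with $f$ oriented as the descent direction of $E_{\text{match}}$ (for a
template shifted in $+x$, the force on a rising ramp is positive). The
displacement integrates $\dot u = v$ until the SSD residual stalls. Because
$v$, not $u$, is smoothed, the accumulated displacement can be large while
each increment stays regular — exactly the regime of colonies that translate
several pixels between frames while deforming internally.

Numerical choices:

* **Spectral solve.** With Neumann (reflective) boundaries, the 5-point
  Laplacian is diagonalized by the type-II discrete cosine transform, so
  $(\gamma + \eta \Delta^2)v = f$ is solved exactly per mode:
  $\hat v_k = \hat f_k / (\gamma + \eta \lambda_k^2)$ with
  $\lambda_k = 2\cos(\pi k / n) - 2$ per dimension. Reflective boundaries
  avoid the wrap-around artifacts a periodic FFT would introduce at frame
  edges. `solve_velocity()` exposes this solve; it is linear in $f$ and
  exact to floating point, which the test suite checks against single
  eigenmodes.
* **Pseudo-time integration.** An embedded Dormand–Prince 4(5) pair with
  step-size control (relative tolerance `rk_rel_tol`, default $10^{-3}$)
  integrates $\dot u = v$. The tolerance doubles as a stability control:
  the flow is stiff (sharp-texture modes equilibrate much faster than the
  bulk translation mode), and the embedded error estimate is what keeps the
  step inside the stability region. Tolerances looser than about
  $3\times10^{-3}$ destabilize the integration; tightening below $10^{-3}$
  costs steps without measurably improving the recovered field.
* **Stopping.** Integration stops when the relative SSD decrease per
  accepted step falls below `convergence_rel_change` (default $10^{-3}$).
  The residual decays roughly exponentially with a long tail; a tighter
  threshold roughly doubles runtime for endpoint-error gains of a few
  hundredths of a pixel.
* **Warping and gradients.** Bilinear interpolation with edge clamping for
  gray values; nearest-neighbour for label images (so propagation never
  invents labels); central differences (one-sided at borders) on the warped
  source for $\nabla S|_{x-u}$.
* **Defaults.** $\alpha = \eta = 1$, $\gamma = 0.01$. The ratio
  $\eta/\gamma$ sets the spatial cutoff below which modes are damped: with
  $\gamma$ as large as $0.1$ the near-uniform translation modes are
  overdamped and a 3 px shift is never fully recovered, while $\gamma =
  0.01$ recovers it to a fraction of a pixel. Optional Gaussian
  pre-smoothing ($\sigma = 1$, on by default) keeps SSD forces from being
  noise-dominated on raw phase-contrast texture. An `advection` switch
  implements the material-derivative transport $\dot u = v - (\nabla u)v$
  of the classical fluid formulation; the default is the plain Eulerian
  update, which is the form the over-damped variational flow regularizes.
* **Topology monitoring.** The Jacobian determinant of $x - u$ is
  monitored; values below 0.1 trigger a warning (folding risk) but no
  regridding — the method is used for inter-frame motions of a few pixels
  where regridding is unnecessary.

## Segmentation

Phase-contrast frames carry two artifacts that defeat naive thresholding:
bright halos around dense objects and slow illumination gradients. The
detection pipeline is:

1. **Single-scale retinex** (`retinex_correct()`):
   $\log(I + \epsilon) - \log(G_\sigma * I + \epsilon)$, rescaled to
   $[0,1]$ ($\sigma$ default 30 px, $\epsilon = 10^{-3}$; a constant frame
   maps to 0.5). This flattens illumination at scales above $\sigma$ and
   compresses halo excursions relative to the dynamic range.
2. **Total-variation denoising** (`tv_denoise()`): the Rudin–Osher–Fatemi
   model by Chambolle's dual projection (dual step $1/4$), weight default
   0.1, 30 iterations. Noise in flat regions drops by more than an order of
   magnitude while step edges stay within one pixel.
3. **Two-phase region-based active contour**
   (`active_contour_segment()`): a morphological implementation of the
   piecewise-constant (Chan–Vese-type) model — boundary pixels join the
   phase whose mean they are closer to in the squared sense, followed by
   alternating sup/inf curvature smoothing (default 200 iterations,
   smoothing 2, with an early stop when the contour stabilizes). Without an
   initialization a checkerboard is used and the brighter phase becomes
   foreground; a constant image deterministically returns an empty mask.
4. **Hole filling** (`fill_holes()`) and **8-connected labeling** with a
   minimum object size (`min_object_px`, default 30 px — single cells at
   10x magnification occupy tens of pixels). Labels are assigned in
   raster-scan order of each component's first pixel, making the whole
   pipeline deterministic.

The morphological contour only moves its boundary, so it cannot discover an
object disconnected from its initialization; wherever the tracker supplies
an initialization, it is therefore the union of the propagated mask and an
independent cold segmentation (see below).

## Tracking and the four reconciliation cases

Per frame pair: register, propagate the previous label mask along the
field, re-segment the new frame (initialized as just described), then
reconcile propagated against segmented objects by pixel overlap
(correspondences under `min_overlap_px = 10` px are ignored as warping
slivers):

* **one-to-one** — segmented shape, propagated label (`continue`);
* **merge** — one segmented blob covers several propagated labels: the
  propagated labels are kept and partition the blob (unclaimed blob pixels
  join the nearest propagated label, ties to the smaller id); one `merge`
  edge per parent. A "merge" whose parents already shared a connected
  object in the previous mask is an ongoing fused state and is downgraded
  to `continue`, so a fusion is reported exactly once;
* **split** — one propagated label covers several segmented objects: the
  segmented shapes are kept and every child receives a fresh label
  (`split` edges from the common parent);
* **new** — a segmented object with no significant propagated overlap gets
  a fresh label (`appear`). Propagated labels with no counterpart vanish.

Mixed configurations are resolved merge-first; a segmented object whose
only parents were consumed by a merge counts as new. Labels are never
reused.

**Backward tracking** (the default) processes the reversed sequence:
segmentations delineate objects that are separating much more reliably than
objects that are fusing, so running time backwards converts every fusion
into a separation. On output the masks are re-indexed to the original frame
order, edges point from the earlier to the later original frame, and a
processing-order split is reported as a forward-time merge (and vice
versa); processing-order appearances are forward-time track terminations
and yield no edge. The graph records the processing direction.

**Degraded modes.** If a registration fails outright, or recovers a field
whose maximum displacement exceeds `max_displacement_px` (default 12 px —
far outside the few-pixel inter-frame motion this imaging regime produces,
and the signature of the solver running away while chasing a topology
change), the pair falls back to the identity field with a warning and the
sequence continues; reconciliation then sees the undeformed mask, which is
exactly the right neutral prior for the overlap rules. The tracking default
registration also uses a stiffer curvature weight ($\alpha = 3$) than the
standalone default: label propagation needs smooth, topology-preserving
fields more than it needs the last fraction of a pixel of matching, and the
segmentation step refines mask shapes anyway.

## Colony measures

For colony $j$ with pixel set $\chi_j$, area $a$ (pixel count) and
perimeter $p$:

* **Covered-area fraction**: nonzero mask pixels over total pixels.
* **Elongation** $\xi = 1 - \text{minor}/\text{major}$, from the best-fit
  ellipse of the second-order central moments (axis length $4\sqrt{\text{eigenvalue}}$).
  A disc gives $\xi \approx 0$, a line $\xi \to 1$; degenerate collinear
  sets are capped at $1 - 10^{-6}$. The orientation is chosen so the
  stated behavior (round $\to 0$, elongated $\to 1$) holds; note that a
  literal major/minor ratio would leave the $[0,1)$ range.
* **Circularity** $\gamma_{\text{shape}} = 4\pi a / p^2$, equal to 1 for a
  circle. The perimeter uses a 4-direction Cauchy–Crofton estimator
  ($P = \tfrac{\pi}{8}(N_h + N_v + (N_{d1}+N_{d2})/\sqrt2)$ over boundary
  crossings of the four line families): raw boundary-pixel counting would
  bias a disc to $\approx 0.8$, while the Crofton estimate puts a
  rasterized $r=50$ disc within $[0.95, 1.05]$. Mild discretization
  overshoot is capped at 1.1.
* **Gray-level entropy** $H_j = -\sum_i p(g_i)\log p(g_i)$ (nats) over the
  gray values inside $\chi_j$, quantized to `n_levels` uniform bins on
  $[0,1]$ (default 256, coinciding with native 8-bit levels). Computed on
  the raw frame values, not the retinex/TV-preprocessed ones, so it
  measures the image texture rather than the preprocessing.
* **Displacement mean/SD**: mean and population standard deviation of
  $\lVert u(x)\rVert$ over $\chi_j$, attached to the earlier frame of each
  pair and `NA` on the terminal frame (missing, not zero).

Per-frame summaries use medians with 0.25/0.75 quantiles
(linear-interpolation definition), mirroring how such distributions are
usually plotted over time. Between-condition comparisons pool per-colony
values over frames and use the two-sided Wilcoxon rank-sum test
(`stats::wilcox.test`): exact for tie-free pools up to $n = 20$, a
tie-corrected normal approximation otherwise. The test suite carries an
independent exact-enumeration oracle for pool sizes up to 8.

## Stream visualization

`layout_streams()` assigns each colony, per frame, a horizontal interval
whose width is the colony's area divided by the frame pixel count — so the
widths of one frame sum to that frame's covered-area fraction, and a full-
width plot means confluency. Color encodes circularity, min–max normalized
over the sequence, with red = round and blue = irregular. Time runs
downward. Stream order is inherited frame to frame (initially by centroid
column); split children take their parent's slot, so diverging and
converging bands stay adjacent. Band boundaries are interpolated with a
monotone cubic between frames (pinned only for determinism — any smooth
interpolant would do). `render_streams()` writes a standalone SVG with one
class-tagged path per stream run, which the tests parse to count rendered
topology changes; `autoplot()` gives the equivalent ggplot2 view. A gap of
1% of plot width separates adjacent streams and is excluded from the width
budget.

## The synthetic sequence generator

`generate_sequence()` renders scripted scenarios with exact ground truth:
textured, roughly circular colonies (interior mean 0.6, band-limited
texture, background 0.2 — a contrast of 0.4, comfortably above the 0.3
contrast floor the segmentation suite assumes; noise default
$\sigma = 0.03$; optional halo rings) moving with per-frame translation and
isotropic growth. Texture is anchored to colony-local coordinates, so it
advects and dilates consistently with the recorded analytic fields — the
truth field for a colony moving $c_t \to c_{t+1}$ and growing
$r_t \to r_{t+1}$ is $u(x) = (c_{t+1} - c_t) + s(x - c_{t+1})$ with
$s = 1 - r_t/r_{t+1}$, tapered to zero a few pixels outside the disc.
Scripted **merges** pin one colony against another at 4 px overlap from the
event frame on; scripted **splits** replace a colony by two equal-area
children placed just-separated (5 px gap) along their offset directions, so
the scripted frame is exactly the frame the topology visibly changes.
Motion is restricted to rigid translation plus isotropic growth so truth
masks stay analytic; rotation and swirl fields exist for registration tests
but are not used in tracking fixtures. Everything is reproducible bit for
bit from the script seed.

What the generator does *not* emulate: the optics of phase contrast (no
point-spread or shade-off model), cell-scale texture dynamics inside
colonies, colony boundary roughness, or stage drift (sequences are assumed
pre-aligned). Passing the synthetic suite therefore demonstrates the
correctness of the algorithms under controlled deformations, not
performance on any particular microscope's data; on real sequences the
segmentation parameters (`retinex_sigma`, `tv_weight`, `min_object_px`)
are the knobs to revisit first.

## Validation scale and known limitations

The test suite and the acceptance script validate at desk scale:
registration recovery on ten 128x128 textured-blob pairs with smooth
ground-truth fields of 3–5 px magnitude (mean endpoint error well under a
pixel, SSD reductions above 90%); five 8-frame 160x160 tracking scenarios
(drift, growth, three-colony, merge, split) in both processing directions;
end-to-end determinism by artifact hashing; and exact closed forms for the
solver, shape, entropy and displacement measures. These sizes keep the full
suite within minutes on one CPU while exercising every code path at the
motion magnitudes the method targets.

Known limitations:

* The fluid model cannot represent a true topology change; at a split the
  field folds (negative Jacobian) and the plausibility guard falls back to
  the identity field. This is by design — the reconciliation rules, not
  the registration, own topology changes.
* Forward-time fusion relies on propagated masks and inherits their
  geometry; backward processing (the default) avoids this, which is why
  merged-state sub-labels partition a fused blob along propagated, not
  intensity, boundaries.
* The 4-direction Crofton perimeter is exact in expectation for isotropic
  boundaries but biases axis-aligned rectangles' circularity upward by
  about 0.01–0.015 (within the stated tolerance).
* `compare_conditions()` treats pooled per-colony values as exchangeable;
  repeated measures of the same colony across frames are not independent,
  so its p-values are descriptive unless pools are restricted to
  independent units.
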