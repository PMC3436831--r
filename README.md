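# colonytrack

Automated quantification and visualization of spatio-temporal patterning in
stem-cell colony time-lapse sequences.

Mouse embryonic stem cells form colonies whose morphology reflects their
culture condition: compact round clusters under 2i medium, flat irregular
sheets under LIF/serum. Phase-contrast time-lapse imaging records how these
colonies grow, deform, merge and split, but single cells inside a dense
colony cannot be resolved or tracked. `colonytrack` works at the scale that
is observable: it estimates the dense motion field between consecutive
frames, segments and tracks whole colonies through merges and splits, and
summarizes each colony's shape, texture and internal motion over time — for
anyone who needs objective, reproducible numbers (and a lineage picture)
out of a colony time-lapse experiment.

## The method in brief

**Fluid registration.** Between frames `S` (source) and `T` (template) a
dense displacement field `u` is found so that `S(x − u(x)) ≈ T(x)`,
minimizing the sum-of-squared-differences matching term

    E(u) = 1/2 ∫ (S(x − u(x)) − T(x))² dx

regularized not on `u` but on the velocity `v = du/dτ` of a pseudo-time
flow, through a curvature penalty `α/2 ∫ Σ(Δv_ℓ)² dx` — a fluid model,
which tolerates the large cumulative rearrangements colonies undergo. The
over-damped Euler–Lagrange flow gives, at each pseudo-time instant,

    γ v + η Δ² v = (S(x − u) − T) ∇S|_{x−u},

solved spectrally (DCT diagonalization of the biharmonic under Neumann
boundaries) and integrated with an adaptive Dormand–Prince 4(5) scheme
until the residual stalls.

**Segmentation.** Retinex illumination correction, total-variation
denoising (Chambolle projection), a two-phase region-based (Chan–Vese-type)
morphological active contour, hole filling, and 8-connected labeling.

**Tracking.** Labels are propagated along the displacement field and
reconciled with a fresh segmentation: one-to-one (continue), merge
(propagated labels partition the fused blob), split (children get new
labels), appear. Backward processing — the default — turns hard-to-segment
fusions into easy separations; events are re-expressed in forward time on
output.

**Measures.** Covered-area fraction; per-colony area, elongation
`ξ = 1 − minor/major` (moment ellipse), circularity `γ = 4πa/p²` (Crofton
perimeter), gray-level entropy `H = −Σ p(g) log p(g)` in nats, and the
mean/SD of `‖u‖` inside each colony; per-frame median and quartile
summaries; Wilcoxon rank-sum comparison between conditions.

**Visualization.** Each colony is a downward stream whose width is its area
normalized by the frame size (widths of a frame sum to the covered-area
fraction) and whose color encodes circularity (red round, blue irregular);
merges and splits appear as converging and diverging bands.

A scripted synthetic-sequence generator with exact ground truth (masks,
fields, event log) backs the whole test suite.

## Worked example

Generate a small synthetic sequence (two colonies, one drifting, one
growing), track it, and measure it:

```r
library(colonytrack)

script <- scenario_script(
  canvas = c(128, 128), n_frames = 5,
  colonies = list(
    list(id = 1, center = c(45, 40), radius = 16, velocity = c(1, 2)),
    list(id = 2, center = c(90, 88), radius = 18, growth = 0.03)),
  noise_sigma = 0.03, seed = 7)
gen <- generate_sequence(script)

trk <- track_sequence(gen$frames, tracking_params(direction = "forward"))
trk$graph
#> <track_graph> 10 nodes over 5 frames, 8 edges (continue: 8)

records <- measure_sequence(gen$frames, trk$masks, trk$fields)
dplyr::select(records, frame, colony_id, area_px, circularity, entropy,
              mean_displacement)
#> # A tibble: 10 × 6
#>    frame colony_id area_px circularity entropy mean_displacement
#>    <int>     <int>   <int>       <dbl>   <dbl>             <dbl>
#>  1     0         1     795       0.979    4.57             2.09
#>  2     0         2     999       0.953    4.77             0.451
#>  3     1         1     793       1.02     4.58             2.11
#>  4     1         2    1083       0.994    4.75             0.410
#>  ...
```

Both colonies keep their identity across all five frames (8 `continue`
edges, no spurious events). Colony 1 translates by `(1, 2)` px/frame and
its measured mean internal displacement is ≈ 2.1 px ≈ ‖(1,2)‖; colony 2
only grows, so its internal motion is small (≈ 0.45 px, the radial dilation
averaged over the disc). Circularities sit at ≈ 1.0 — both objects are
discs — and the entropy ≈ 4.6 nats reflects the band-limited interior
texture. Area of colony 2 rises from 999 to 1299 px (3%/frame radial
growth ⇒ ~6%/frame area growth), while colony 1's stays ≈ 793 px.

A single registration shows the convergence record:

```r
reg <- register_pair(gen$frames[[1]]$pixels, gen$frames[[2]]$pixels)
reg
#> <registration_result> 128x128 field, 179 accepted steps, converged
#>   SSD 8.99219 -> 0.834817
glance(reg)   # one-row summary: residuals, reduction, steps, max |u|
```

Summaries and the stream view:

```r
summarize_frames(records, "circularity")   # per-frame median, q25, q75
lay <- layout_streams(trk$graph, records)
render_streams(lay, stream_style(), "streams.svg")  # or autoplot(lay)
```

The full pipeline (frames on disk → masks, fields, track graph,
features.csv, summary.csv, streams.svg, content-hashed manifest) runs as:

```r
run_pipeline(pipeline_config(input = "frames/", output_dir = "results/"))
```

or from a shell via the thin CLI in `inst/cli/colonytrack.R`
(`run`, `segment`, `register`, `track`, `measure`, `summarize`,
`streamplot`, `synth` subcommands).

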