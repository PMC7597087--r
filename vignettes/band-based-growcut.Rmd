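---
title: "Band-Based GrowCut: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Band-Based GrowCut: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bbgrowcut)
```

## The automaton

GrowCut is a seeded cellular automaton for image segmentation. Every pixel
(or voxel) is a cell with state (λ, σ, C): label λ (0 = unlabeled, 1..L =
regions; for binary work 1 = background, 2 = foreground), strength
σ ∈ [0, 1], and feature C, the grey intensity normalized to [0, 1]. Seeds
start with σ = 1; all other cells with λ = 0, σ = 0. At each step, cell q
attacks its neighbour p with strength g(|C(p) − C(q)|) · σ(q), and p is
captured — inheriting λ(q) and the attack strength as its new σ — whenever
the attack *strictly* exceeds σ(p). The update is fully synchronous: all
attacks at step t read the state at t − 1. The run stops at the first
iteration with zero captures (convergence) or at `max_iter`.

Band-Based GrowCut (BBG) changes only the neighbourhood system. On top of
the standard radius-1 Moore neighbourhood, each cell also sees `k` *remote*
neighbours, re-drawn at every iteration uniformly without replacement from
the Chebyshev annulus `a ≤ d∞ ≤ b` around the cell (clipped to the grid).
A remote attacker captures only when strictly stronger than both the
defence and the best local attack: local neighbours win ties. Each capture
is classified by source — *local*, *remote* (no local attack succeeded), or
*override* (a remote attack beat an otherwise-successful local one) — and
the cumulative counts are reported per run.

## The attenuation g

The attenuation must be a monotone map of feature difference onto [0, 1]
that transfers full strength between identical features and nothing across
the maximal difference. The package uses

$$g(x) = 1 - x / \Delta_{\max}, \qquad \Delta_{\max} = 1$$

for features normalized to [0, 1]. This choice reproduces the four-pixel
worked example exactly: a seed of strength 1 attacking across an intensity
difference of 0.9 lands an attack of 0.1, and the captured cell's
counter-attack in the next iteration is 0.01. (Where g is loosely stated
only as monotone and bounded, the decaying direction is the one a capture
rule needs — attenuation must fall with dissimilarity, and the worked
example's numbers admit only that form.) 8-, 12- or 16-bit integer images
are divided by their type maximum on load (`read_image()`).

## Band membership: annulus, not corner blocks

Two readings of a "band spanning radii a through b" coexist in the
literature on this construction: the per-axis conjunction
`a ≤ |Δrow| ≤ b AND a ≤ |Δcol| ≤ b`, which keeps only four corner blocks,
and the Chebyshev annulus `a ≤ max(|Δrow|, |Δcol|) ≤ b`, which is what "a
band circumscribed to the classic neighbourhood" describes geometrically.
The package implements the annulus: it degenerates correctly to Moore
shells (`band (1, r)` ≡ Moore radius r) and surrounds the local
neighbourhood on all sides. The corner-block reading remains available via
`enumerate_band(..., corners_only = TRUE)` for comparison.

A related inconsistency concerns the band's cardinality. The closed form
commonly quoted for it, $(2b+1)^d - (2a+1)^d$ (exposed as
`band_count_formula()`), counts the *half-open* annulus `a < d∞ ≤ b`,
whereas the inclusive annulus the engine enumerates has
$(2b+1)^d - (2a-1)^d$ cells — 112 vs 96 for the (2, 5) band in 2D. The
test suite asserts both values against brute-force enumeration of their
respective membership predicates rather than hiding the discrepancy; the
engine's sampling pool is the inclusive annulus.

## Sampling the remote band

Nothing in the construction prescribes a sampling distribution, so the
minimal assumption is used: uniform without replacement over the in-grid
band cells, with a fresh draw per cell per iteration (matching the
1-dimensional hybrid-neighbourhood precedent, which was robust to dynamic
resampling). Internally the compiled engine draws by rejection from the
full offset table — which is uniform over the clipped subset — and falls
back to explicit enumeration for heavily clipped cells; both branches
produce `min(k, |band|)` distinct cells. A fully clipped band (possible on
small grids) simply yields no remote attackers for that cell.

Defaults follow the standard configurations: `k = 5` remote neighbours,
bands (2, 5), (5, 10), (10, 30), (30, 45), iteration cap 2000, with the
cap chosen so that non-converged runs are still returned in usable form.

## Numerical and tie-breaking choices

* **Ties among local attackers**: first in the deterministic row-major
  offset enumeration order. Any fixed rule suffices for reproducibility;
  this one makes the compiled engine and the pure-R reference bit-equal.
* **Local vs remote ties**: local wins, by construction of the rule.
* **Convergence under resampling**: the run is declared converged at the
  first iteration with zero captures, even though a different remote draw
  could in principle still succeed later. This keeps runs finite and
  matches the observed "converged" semantics; strengths are monotone
  non-decreasing per cell, so quiet iterations are typical of a settled
  state.
* **Recapture by a same-label attacker** (a pure strength refresh) counts
  as a capture: the rule is label-agnostic and the refresh changes state.
* **Seed cells are attackable** like any other cell; nothing exempts them.
* **Determinism**: given a neighbourhood spec, inputs, and `seed`, runs are
  bit-identical, including win statistics (the engine consumes R's RNG
  stream).

## Seeding

`generate_vertical_seeds()` removes subjectivity: for each of the two
regions of a ground-truth mask it takes, among all maximal contiguous
vertical runs of that region within single columns, the tallest one, and
trims it to `max(1, floor(0.75 · height))` pixels. Choices left open by
the procedure's description and fixed here: "height" is measured over
*contiguous* runs (a seed is a line of pixels, so a column's scattered
pixels do not pool); ties go to the leftmost column, then the topmost run;
the trimmed seed is centered in its run, slack split floor/ceil. For 3D,
seeds are generated per slice (one background and one foreground line per
slice) and serve both stitch and full modes.

## Metrics

Overlap scores use foreground as the positive class; Dice is the harmonic
mean of precision and recall and equals 2J/(1+J). Degenerate cases are
fixed by convention for reproducibility: both foregrounds empty → all
overlap scores 1; exactly one empty → 0. Over- and under-segmentation
entropy are the conditional entropies H(S|T) and H(T|S) of the joint label
distribution, in natural log (the base cancels in the OSE/USE ratios that
are compared); 0·log 0 terms are dropped, and `voi = ose + use`.
Region homogeneity measures are unnormalized sums of squared deviations
from the region mean ("sum of squared differences" taken literally);
discrepancy is the squared error between the image and its per-region-mean
reconstruction, which for a binary segmentation equals foreground error +
background error. Hausdorff distances compare foreground *boundary* pixels
(foreground with any 4-neighbour background, image border included) under
the Euclidean metric; the average-Hausdorff variant averages the two mean
directed nearest-neighbour distances.

## Synthetic scenes and what they show

The generators produce the structures the band construction is about:

* `worked_example()` — the four-pixel automaton with its full expected
  trajectory;
* `disconnected_scene()` — a seeded and a seedless foreground component of
  identical intensity separated by a background gap of width `w`. Classical
  GrowCut provably cannot label the seedless component foreground (no
  propagation path); a band with `b ≥ w + 1` bridges the gap. Default
  intensities 0.9/0.1 mirror the worked example's contrast.
* `synthetic_corpus()` — ten 64×64 two-region scenes, each a large main
  component plus one or two small seedless satellites at a distance that
  grows with the scene index, half with additive gaussian noise
  (sd 0.02–0.14), half with salt-and-pepper corruption (rate 0.02–0.16).
  Vertical seeding lands in the main component, so the satellites are
  reachable only through remote neighbours. These sizes keep the full
  five-configuration sweep comfortably fast while leaving room for the
  granularity trends to express themselves.

On this corpus the suite asserts the directional granularity property:
every band configuration over-segments more than classical GrowCut (mean
OSE strictly larger — remote attacks seed spurious foreground islands in
noisy backgrounds), while mean USE decreases in tendency as the band moves
outward (Spearman rank correlation ≤ 0 across the four bands — farther
bands rescue farther satellites, reducing under-segmentation). These are
properties of piecewise-constant scenes with well-separated intensity
modes; natural images with texture, gradients, and ambiguous boundaries
are not emulated, so passing tests demonstrate the mechanism, not
photographic-grade performance.

## 3D handling

`segment_volume()` offers the two standard interpretations of a volume:
*stitch* (each slice segmented independently as a 2D automaton, labels
stacked, win statistics summed, iteration count the per-slice maximum) and
*full* (one automaton whose cells are voxels, neighbourhoods extended by
3D Chebyshev distance). Stitch sidesteps anisotropic voxel spacing, which
the full 3D neighbourhood ignores; on a volume uniform along the third
axis the two agree exactly for classical neighbourhoods, which the suite
verifies on an 8×8×4 fixture. A seedless slice in stitch mode is returned
all-unlabeled with a warning rather than failing the volume.

## Known limitations

* The engine supports L labels in its data model, but all bundled
  experiments and metrics address foreground/background segmentation.
* BBG runs on noisy images frequently use the full iteration cap: remote
  resampling keeps finding marginally stronger attacks. The cap (2000) is
  then the effective stopping rule, as intended.
* Intensity is the only feature; multi-channel features would need a
  vector-valued C and a norm in g.
* The corner-block band variant is enumerable but not wired into the
  engine, which always samples the annulus.
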