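---
title: "Measuring intracortical remodelling from microradiographs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring intracortical remodelling from microradiographs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canalmorph)
```

## The measurement model

Cortical bone renews itself through basic multicellular units (BMUs):
osteoclasts cut a tunnel longitudinally through the matrix at roughly
40 µm/day, and osteoblasts refill it radially at 1.0–1.5 µm/day, leaving a
secondary osteon around a narrow Haversian canal. A transverse section
therefore shows canals whose cross-sectional area encodes the remodelling
stage. `canalmorph` adopts the standard size partition, derived from canal
diameters assuming circular cross-sections (A = πr²):

| stage | Ca.Ar (mm²) | Ca.Dm (µm) |
|---|---|---|
| mature Haversian canal | ≤ 0.002 | ≤ 50 |
| closing cone (infilling) | 0.002 – 0.04 | 50 – 225 |
| cutting cone (resorbing) | > 0.04 | > 225 |

The 50 µm lower bound is twice the coarsest pixel spacing used at the
imaging sites (25 µm), so the retained canals are at least two pixels across
in their narrowest dimension. It is deliberately distinct from the *minimum
resolvable* diameter — the equivalent circular diameter of a single pixel,
2s/√π, which `min_resolvable_diameter()` reports (11.28, 28.21 and 18.84 µm
at 10.0, 25.0 and 16.7 µm spacing). Class boundaries are strict at the upper
edge: exactly 0.002 mm² is mature (excluded from canal statistics, since
retention requires Ca.Ar *>* 0.002), and exactly 0.04 mm² is a closing cone.

Counting assumes each retained pore is one canal in cross-section. This is
the working assumption of 2-D histomorphometry; branching or obliquely cut
canals, and resorption on the surface of existing canals, are not
distinguishable from single canals in one section.

## Segmentation

The cortex is the region between a periosteal polygon and any number of
endosteal polygons, traced manually (the package reads them from a JSON
dialect, `{"periosteal": [[x, y], ...], "endosteal": [[[x, y], ...]]}`, in
pixel coordinates, origin top-left, y downward). A pixel belongs to the
cortex iff its centre lies inside the periosteal polygon and outside every
endosteal polygon, with a half-open boundary convention (boundary pixels
count as inside the periosteal polygon and outside endosteal ones) so that
abutting regions never double-count. Ct.Ar is the masked pixel count times
the pixel area.

Pore and bone phases are split by the triangle (Zack) threshold: both
histogram axes are normalised to [0, 1], a line is drawn from the peak to
the farthest nonzero bin on the longer-tail side, and the threshold is the
bin at maximum perpendicular distance from that line, ties broken toward the
peak. A single-bin histogram returns that bin (and, because pore assignment
is *strictly* beyond the level, a perfectly flat cortex then yields no pore
phase at all). The histogram is computed over the cortical mask by default
(`threshold_mode = "roi"`): a full frame is dominated by empty background,
which would drag the threshold away from the pore/bone transition. A
full-frame mode is provided for replicating analyses that thresholded whole
images; which of the two an existing analysis used cannot generally be
inferred after the fact, so neither is asserted as "the" historical mode.
Pore polarity defaults to `pores_below` (radiolucent pores are rendered
dark); it is configurable.

Important caveat: an automatic threshold always returns *some* level. On a
section with a pronounced background-intensity gradient (uneven sample
thickness) and few or no true pores, the triangle construction cuts inside
the unimodal cortex histogram and manufactures a pseudo-pore region. The
shape filters remove most such artefacts, but shading correction is
explicitly out of scope, and a flat-field (gradient-free, noise-free)
configuration is what realises the textbook "no pores in, no canals out"
behaviour.

## Particle analysis

Components are extracted under 8-connectivity (diagonal contact joins), the
behaviour of standard particle-analysis tools, implemented as connected
components of the pixel-adjacency graph and ordered deterministically by the
raster position of each component's topmost-leftmost pixel. Interior holes
are filled before measurement so a canal containing a central bone island
counts its full lumen.

Perimeter is the length of the Moore-traced 8-connected boundary chain, with
edge steps of one pixel spacing and diagonal steps of √2 spacings, closed
under Jacob's stopping criterion (terminate when the opening move repeats),
which traverses pixel-thin limbs once in each direction as it should. This
estimator overstates the perimeter of smooth shapes by a few percent (about
5% for a disc), biasing circularity 4πA/P² slightly low — a digitised disc
of radius 20 px measures ≈ 0.9. The circularity retention band [0.3, 1.0]
is wide enough that this bias never rejects a near-circular canal, while
elongated Volkmann-canal profiles (aspect ratio ≥ 8, circularity ≈ 0.1)
fall far below the lower bound. Circularity is clipped at 1.0 because
digitisation pushes 4πA/P² above 1 for very small particles; a single-pixel
component is assigned the perimeter of its pixel square (4s) by convention.

Endosteal-margin macro-porosities — the transition to cancellous bone —
are excluded automatically: a pore is flagged when its maximum Feret width
exceeds 600 µm *and* its boundary comes within 100 µm
(`endosteal_margin_um`, the one tunable the exclusion adds; the width
threshold comes from the morphological description of these porosities) of
an endosteal contour. Both conditions are needed: a wide canal in
mid-cortex is biology, not margin artefact, and a small canal hugging the
margin is a genuine canal. A manual exclusion-id list is also accepted for
exact replication of curated analyses. Exclusion flags are additive sets
(`excluded_by`) and never alter measured values, so the relative order of
shape filtering and endosteal exclusion is immaterial.

Pores clipped by the cortical mask are measured on their masked portion:
the cortex boundary is the biological boundary, and no edge-exclusion is
applied.

## Statistics

Group differences use the Mann–Whitney U test implemented from first
principles: joint mid-ranks, U₁ = R₁ − n₁(n₁+1)/2, and U = min(U₁, U₂) — the
convention under which U tends to 0 as the groups' rank distributions
separate. The default method is the normal approximation with continuity
correction and tie-corrected variance,

z = (U − n₁n₂/2 + 0.5)/σ, σ² = n₁n₂/12 · ((N³−N) − Σ(t³−t))/(N(N−1)),

with two-sided p = 2Φ(z) capped at 1; when every observation is tied σ = 0
and p = 1. With n = 6 vs 6 and complete separation this gives p = 0.005
(and 0.008 for 6 vs 5), whereas exact enumeration gives 0.002 and 0.004 —
the continuity-corrected approximation is therefore the replication default,
with exact enumeration (all C(N, n₁) labelings, no ties) available via
`method = "exact"`. The approximation tracks the exact tail to within about
0.035 at these sample sizes, worst at mid-range U. No multiple-testing
correction is applied across the site-by-index table; that matches the
analysis convention this package replicates and is stated rather than
silently "improved". Display precision of p-values is left to the caller;
full precision is retained internally.

One subtlety of the min(U₁, U₂) convention: "more separation" monotonically
decreases the *directed* statistic U₁ when a b-observation is raised above
all of a, but the reported min can increase when the move reduces
separation in the opposite direction. The property tests therefore assert
monotonicity of U₁.

## BMU kinetics

`infill_duration()` models radial infilling at a constant apposition rate:
(r_start − r_end)/rate, with defaults 100 µm (cement line) to 10 µm
(finished canal), spanning 60–90 days at 1.0–1.5 µm/day.
`cutting_advance()` is days × 40 µm/day. Real remodelling includes
substantial resting periods during which neither resorption nor deposition
occurs, so these constant-rate durations are lower-bound estimates, not a
spatiotemporal BMU simulation.

## The synthetic generator

`generate_section()` renders what the analysis chain consumes: an annular
(or, for the metacarpal metaphysis, half-annular) cortex at a matrix
intensity of 180, pores at 60, a multiplicative linear background gradient
of 20% peak-to-peak in a random direction (emulating uneven sample
thickness), and additive Gaussian noise of SD 6 intensity units — values
chosen to give the clear bimodal pore/bone histograms real microradiographs
show, while exercising the threshold under realistic shading. Canals are
non-overlapping discs (minimum 2 px separation, so labelling is
unambiguous); Volkmann-like distractors are thin rotated ellipses of aspect
ratio 8–12; endosteal macro-pores are irregular multi-disc blobs ≈ 800 µm
across straddling the endosteal contour. Every stamped pore is logged with
its analytic area, stamped pixel count, class and flags.

Canal areas are drawn from per-class truncated lognormals (a size law
chosen for its right skew; the real size law is not published, only class
counts and totals). The truncation intervals carry guard bands inside the
class intervals — mature up to 0.0015 mm², closing 0.0028–0.038 mm²,
cutting 0.044–0.12 mm² — so that rasterisation error (a few pixel-areas)
cannot push a stamped canal across a classification boundary. Exact-recovery
tests run on the rib geometry (10 µm spacing), where the 0.002 mm² boundary
is 20 pixel-areas; at 25 µm spacing that boundary is only 3.2 pixels and
stage assignment near it is quantisation-limited — which is precisely why
the 50 µm retention cut-off is set at twice the coarsest pixel spacing.

`generate_study()` emulates the full design: exercised and rested groups of
6 subjects across four sites (rib, tibia, metacarpal diaphysis, metacarpal
half-metaphysis), with per-cell closing/cutting densities calibrated so
group means land near the observed site-by-group means (e.g. rested
metaphyseal cutting-cone density ≈ 0.26 /mm² vs exercised ≈ 0.014 /mm²;
rib densities nearly equal between groups), Poisson canal counts with a
lognormal between-section multiplier (CV 0.35 — chosen to reproduce the
large reported between-animal SDs), 5% CV on cortical area, and an option
(on by default) that drops one rested subject's tibia and metacarpal
diaphysis, mirroring the two damaged specimens that left n = 5 in those
cells. With `render = FALSE` the study is returned at truth level (indices
without images), which is what makes 200-replicate calibration experiments
cheap; `render = TRUE` writes TIFFs, contour JSONs, `metadata.csv` and
`truth.csv` ready for `run_study()`.

What passing tests show — and don't. Ground-truth recovery on synthetic
sections demonstrates that the implementation measures what it stamps:
segmentation, labelling, measurement, filtering and classification are
internally consistent to pixel accuracy. It does not validate the biology
of real microradiographs: synthetic pores are ideal discs at uniform
intensity, with no partial-volume blur, no osteocyte lacunae texture, no
trabecularised margins beyond the stylised blobs, and a linear shading
model. Threshold behaviour on real images with stronger or non-linear
shading can differ.

## Numerical choices and problem sizes

* Triangle threshold: axes normalised to [0, 1]; candidate bins restricted
  to the peak-to-tail interval; distance ties broken toward the peak
  (making mirrored histograms give mirrored thresholds); degenerate
  single-bin histograms return that bin.
* Point-in-polygon: vectorised crossing-number parity with an explicit
  on-boundary pass implementing the half-open convention; contour polygons
  are validated simple (no self-intersection) and endosteal strictly inside
  periosteal.
* Feret width is the maximum centre-to-centre distance between boundary
  pixels (computed on the convex hull), so it understates the true
  silhouette Feret by up to one pixel — immaterial against the 600 µm rule.
* Degenerate inputs: constant 16-bit images rescale to 0; a single-section
  group cell reports SD 0 with `sd_defined = FALSE`; a zero exercised mean
  makes the fold ratio `Inf` with a warning.
* Seeds: generators run under a locally seeded RNG and restore the caller's
  stream; identical seeds give byte-identical sections and studies.
* Test problem sizes: unit and recovery tests use sections scaled to 0.4–0.5
  of the real geometry (≈ 600×600 px at 10 µm spacing, ≈ 20 mm² of cortex)
  and a rendered 6-section study at scale 0.25 for the end-to-end pipeline
  run; calibration properties (type-I error, threshold and labelling
  oracles) use 100–1000 replicates at truth level or on small rasters.
  These sizes were chosen to exercise every code path at full fidelity
  while keeping the default suite around a minute.

## Known limitations

* No shading correction; strong background gradients without true pores
  yield threshold artefacts (flagged above).
* 2-D sections cannot distinguish one large canal from coalesced smaller
  ones, nor capture canal connectivity; a 3-D extension is out of scope.
* The endosteal rule automates what was a manual curation step; the 600 µm
  width + 100 µm proximity defaults reproduce the described morphology but
  any specific historical analysis may have excluded a slightly different
  set (hence the manual-id escape hatch).
* Circularity inherits an estimator choice (chain-code perimeter); other
  tools' smoothed perimeters give slightly different values near the 0.3
  boundary.
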