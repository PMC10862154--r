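# canalmorph

Intracortical canal histomorphometry from 2-D bone microradiographs.

## The problem

Osteoclastic resorption tunnels through cortical bone ahead of a travelling
osteoclast–osteoblast ensemble (the basic multicellular unit, BMU), and the
tunnel is later refilled by osteoblasts to leave a secondary osteon with a
narrow Haversian canal. On a projection microradiograph of a transverse bone
section these stages are visible as radiolucent spots of characteristic size:
the resorptive **cutting cone** (Ca.Ar > 0.04 mm², i.e. diameter > 225 µm),
the partially infilled **closing cone** (0.002–0.04 mm²), and the finished
**Haversian canal** (≤ 0.002 mm², diameter ≤ 50 µm). Counting and sizing
these canals per section therefore measures remodelling activity — for
example, to compare limb bones of athletic animals that died in training
against animals rested after training.

`canalmorph` implements that measurement chain as a tested, reusable R
package:

1. **Segmentation** — the cortex is delimited by manually traced periosteal
   and endosteal contours (supplied as JSON polygon files); pore vs bone
   phases are separated by the triangle (Zack) automatic threshold on the
   cortical intensity histogram.
2. **Particle analysis** — 8-connected components are measured (area,
   boundary-chain perimeter, circularity 4πA/P², equivalent diameter,
   maximum Feret width), retained if circularity ∈ [0.3, 1.0] and
   Ca.Ar > 0.002 mm², and classified by remodelling stage. Elongated
   Volkmann-canal profiles fail the circularity band; large (> 600 µm)
   irregular porosities at the endosteal margin are excluded by a
   width-plus-proximity rule.
3. **Morphometry** — per-section indices Ct.Ar, N.Ca, Tt.Ca.Ar, N.Ca/Ct.Ar
   and Tt.Ca.Ar/Ct.Ar, for the combined (> 0.002 mm²) and cutting-only
   (> 0.04 mm²) selections.
4. **Statistics** — two-group Mann–Whitney U tests (U reported as
   min(U₁, U₂); continuity-corrected tie-aware normal approximation by
   default, exact enumeration on request) and rested/exercised fold ratios.
5. **BMU kinetics** — closed-form longitudinal advance (≈ 40 µm/day) and
   radial infilling durations (100 → 10 µm radius at 1.0–1.5 µm/day spans
   60–90 days).
6. **Synthetic data** — a seeded generator that renders annular or
   half-annular cortices with ground-truth pore tables, background-intensity
   gradients, noise, Volkmann-like distractors and endosteal macro-pores, so
   the whole pipeline is testable without any external images.

## Worked example

```r
library(canalmorph)

# one synthetic rib-like section, seeded and fully ground-truthed
spec <- synthetic_section_spec(site = "rib", scale = 0.5,
                               n_closing = 15, n_cutting = 3)
sec  <- generate_section(spec, seed = 42)
an   <- analyze_section(sec$image, sec$contours)
an$mask
#> <cortical_mask> 191924 px, Ct.Ar = 19.192 mm2, centroid (308.0, 308.0)
an$threshold$level
#> [1] 155

rbind(section_morphometry(an$pores, an$mask, "combined"),
      section_morphometry(an$pores, an$mask, "cutting_only"))[, 4:9]
#>      selection Ct_Ar_mm2 N_Ca Tt_Ca_Ar_mm2 N_Ca_per_Ct_Ar Tt_Ca_Ar_per_Ct_Ar
#> 1     combined      19.2   18        0.326          0.938            0.01698
#> 2 cutting_only      19.2    3        0.185          0.156            0.00965
```

The 15 closing cones and 3 cutting cones stamped by the generator are all
recovered (N.Ca = 18 combined, 3 cutting-only); the Volkmann distractors and
the endosteal macro-pore the generator also stamped were excluded by the
circularity and margin rules. Group comparison and kinetics:

```r
mann_whitney(c(0.016, 0.011, 0.021), c(0.035, 0.049, 0.042))
#> Mann-Whitney U test (asymptotic_cc): U = 0, p = 0.08086 (n1 = 3, n2 = 3)

infill_duration(appo_rate_um_per_d = c(1.5, 1.0))
#> [1] 60 90
```

A whole two-group study (12 subjects × 4 sites, or any subset) can be
simulated with `generate_study()` (truth-level indices, or rendered TIFF +
contour files with `render = TRUE`) and analysed end to end with
`run_study()`, which writes `pores.csv`, `sections.csv`, per-selection
comparison tables, polar canal maps, size-distribution plots and a run
manifest. A thin command-line wrapper with `run`, `synth`, `measure`,
`compare` and `kinetics` subcommands lives at `inst/cli/canalmorph.R`.

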