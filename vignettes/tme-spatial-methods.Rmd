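---
title: "Methods: simulation and spatial statistics in tmespatial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation and spatial statistics in tmespatial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmespatial)
```

This vignette documents the models and numerical procedures behind
`tmespatial`: what the synthetic-slide generator emulates, the exact
definitions of the spatial metrics, the statistical machinery, and the
design decisions and limitations a careful user should know about.

## 1. The data model

A `tme_dataset` couples two tables in one shared coordinate frame
(micrometers):

- **cells** — `cell_id`, `roi_id`, `x_um`, `y_um`, one intensity column per
  panel marker, and a `phenotypes` list-column (a cell may carry several
  labels, e.g. a CD8⁺PD-1⁺ TRM cell is also a CD8⁺ TRM cell and a CD8⁺ T
  cell);
- **rois** — `roi_id`, `region` (`TC`, `IM`, `N`), `group` (`NG`, `EG`),
  frame origin `x0_um`/`y0_um` and size `width_um`/`height_um`.

Frames default to 931 × 698 µm (0.649838 mm²), a common field-of-view size
for multiplexed imaging. Validation uses half-open bounds: a cell belongs to
its frame when `x0 ≤ x < x0 + width` and likewise in y, so abutting frames
never double-claim a boundary cell. ROI-local coordinates are simply the
special case `x0 = y0 = 0`.

## 2. The synthetic slide generator

`simulate_slide(sim_config(...))` builds a slide in four steps.

**Geometry.** `slide_geometry()` places a circular tumor (default radius
2300 µm) at the center of an 8000 × 8000 µm slide. The invasion margin is an
annulus of width `im_band_width_um` (default 1250 µm, within the ~1–1.5 mm
convention for margin definitions) straddling the tumor boundary
symmetrically: TC is everything deeper than `R − w/2`, IM the closed band
`[R − w/2, R + w/2]`, N the remainder. These defaults are chosen so each
compartment can hold at least six non-overlapping ROI frames;
`region_areas()` gives the exact analytic areas.

**ROI stamping.** Frames are stamped by a deterministic greedy row-major
scan (step 100 µm): a candidate frame is accepted when every point of the
rectangle lies in the wanted region (checked via the exact min/max distance
from the tumor center to the rectangle) and it overlaps no accepted frame.
If an active region cannot hold a single frame the simulator raises an
error rather than silently under-sampling.

**Point placement.** Each (phenotype, region) pair draws a homogeneous
Poisson process: a Poisson number of points with intensity λ (cells/µm²)
over the slide, rejected to the region mask. Intensities are configured in
cells/mm² (`default_sim_intensities()`); the treated-group defaults encode a
core-ward gradient for CD8⁺ TRM populations (e.g. CD8⁺PD-1⁺ TRM at
20/60/150 cells/mm² in N/IM/TC) while the untreated defaults are flat across
regions. **These defaults are the study conditions**; analyses and tests are
read against them, not tuned from them.

On top of the background, `attraction_spec(central, target, mean_children,
radius_um)` adds Thomas-style clustering: each central cell spawns a
Poisson(μ) number of target children uniformly in a disk of radius *a*
(treated default: CD8⁺PD-1⁺ TRM → CD68⁺ with μ = 2, a = 15 µm). Under
`boundary_mode = "toroidal"` children wrap around the window, which makes
the closed-form identity *pooled effective score ≈ μ* exact (no edge loss)
when centrals are sparse enough that background coincidences are negligible;
`"clip"` (the default for realistic slides) drops children that fall
outside.

**Marker emission.** Each cell draws marker intensities from a two-component
log-normal model: positive markers from LogNormal(meanlog = log 10,
sdlog = 0.35), negative from LogNormal(0, 0.35). The default gating
thresholds sit at the geometric midpoint `exp(log(10)/2) ≈ 3.16`, where the
two components overlap by well under 1%, so threshold gating recovers the
generating phenotype ≥ 99% of the time — a property the test suite asserts
rather than assumes.

All randomness flows from a single `seed` through deterministic substreams
(`substream_seed()`, a small string-hash mix per phenotype/region/stage), so
adding an attraction or phenotype does not perturb the draws of the others,
and identical configs reproduce byte-identical slides.

## 3. Phenotype gating

`gate_cells()` applies inclusive thresholding: marker M is positive when
`intensity ≥ threshold[M]`. A phenotype rule is a conjunction of required
positive and required negative markers (`default_phenotype_rules()` encodes
the eight standard populations, e.g. CD8⁺ TRM = CD8⁺ ∧ CD103⁺). Cells
positive for more than one lineage marker (CD8, CD4, CD68) are biologically
implausible segmentation artifacts; the `lineage_conflict_policy` either
labels them `"ambiguous"` (default, keeps them countable) or drops them.

## 4. Neighborhood metrics

For central phenotype C, target phenotype T and radius r (default 30 µm):

- pairs are ordered (central, target) with Euclidean distance **≤ r**
  (inclusive); a cell carrying both labels never pairs with itself;
- **effective score** = n_pairs / n_central, undefined when n_central = 0;
- **average distance** = Σ distances / n_pairs, undefined when n_pairs = 0;
- pooled metrics sum n_pairs, Σ distances and n_central over the scope
  (slide, region, or all) *before* dividing — a weighted, not unweighted,
  average over ROIs;
- pairing never crosses ROI boundaries, and **no edge correction** is
  applied: a central near a frame edge sees a truncated disk. This matches
  how the metric is used in practice (all ROIs share the same frame size, so
  the truncation bias is common-mode across compartments being compared).

Two search routes are implemented: a brute-force O(n²) oracle and a grid
accelerator (bucket width = r, 3 × 3 neighborhood scan) that returns the
identical pair set — the tests assert exact equality on random fixtures. The
toroidal option (used only for validation against closed forms) forces the
brute route with wrapped distances.

Closed-form oracles under complete spatial randomness: E[score] = λ_T π r²
and E[mean pair distance] = 2r/3 (the mean of a length distributed with
density 2d/r² on [0, r]). `permutation_null()` assesses observed scores by
permuting the phenotype labels over fixed positions, with the
add-one estimator p = (1 + #{null ≥ observed}) / (1 + n_perm), which is
never exactly zero and is exact under exchangeability.

## 5. Density and statistics

`density_table()` counts label occurrences per ROI (non-exclusive: a
multi-label cell counts toward each of its phenotypes) and converts to
cells/mm² using the frame area. The replication unit throughout is the
**ROI**, not the patient: p-values speak to within-slide heterogeneity and
would overstate evidence if read as patient-level inference.

- **Kruskal–Wallis** wraps `stats::kruskal.test` (tie-corrected, χ²
  approximation — adequate for the group sizes used here, conservative for
  n < 5 per group). All-identical input is short-circuited to H = 0, p = 1.
- **Dunn's post-hoc test** is implemented directly (no maintained
  implementation among the available dependencies): z_ij = (R̄_i − R̄_j) /
  √[ (N(N+1)/12 − Σ(t³−t)/(12(N−1))) (1/n_i + 1/n_j) ] with Bonferroni
  adjustment over all k(k−1)/2 pairs. Hand-worked fixtures (with and without
  ties) pin the implementation in the tests.
- **One-way ANOVA + Tukey HSD** wraps `stats::aov` and `stats::TukeyHSD`,
  with explicit handling of degenerate inputs (zero within-group variance).
- **Two-way interaction ANOVA** (`value ~ a * b`) is restricted to
  **balanced** designs with ≥ 2 replicates per cell; unbalanced layouts are
  rejected rather than silently analyzed with order-dependent Type-I sums of
  squares. The reported sums of squares satisfy
  SS_a + SS_b + SS_ab + SS_resid = SS_total to machine precision.
- **Pearson networks** (`pearson_network()`) run `stats::cor.test` per
  phenotype pair on per-ROI counts; constant columns or n < 3 produce
  flagged undefined edges instead of NaN propagation. Note that correlations
  of counts across ROIs mix true co-localization with shared density
  gradients across compartments; computing networks within a region (the
  `region` argument of `count_matrix()`) controls for the latter.

## 6. Pipeline and reproducibility

`run_pipeline()` executes input → gate → density → neighborhood → correlate
→ compare from a YAML or list config. Every CSV artifact carries a
`# config_hash=<hash>` header line — the hash covers the full configuration
except the output directory, so re-running the same analysis anywhere yields
byte-identical artifacts — and `report.json` records per-stage status and
timing. A failing comparison is recorded and reported without aborting the
remaining stages.

## 7. Tunable parameters at a glance

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| ROI frame | 931 × 698 | µm | standard mIHC field of view |
| pairing radius | 30 | µm | ~2–3 cell diameters; direct-interaction scale |
| IM band width | 1250 | µm | within the ~1–1.5 mm margin convention |
| tumor radius | 2300 | µm | fits ≥ 6 frames per compartment on an 8 mm slide |
| stamping step | 100 | µm | frame-placement granularity |
| marker model | log(10)/0.35 vs 0/0.35 | log-intensity | > 4 SD separation → clean gating |
| thresholds | exp(log(10)/2) ≈ 3.16 | intensity | geometric midpoint of the two components |
| attraction | μ = 2, a = 15 | children, µm | within-radius clustering, score ≈ μ identity |

## 8. What the simulator does and does not emulate

It reproduces the *statistical* structure the analysis consumes:
compartment-dependent densities, short-range attraction between phenotype
pairs, multi-label phenotype nesting, and marker-intensity overlap at the
gate. It does **not** model tissue architecture (vessels, stroma, necrosis),
cell-size exclusion (points may be arbitrarily close), segmentation error
beyond lineage conflicts, irregular tumor boundaries, or between-patient
heterogeneity. Conclusions about method behavior transfer; conclusions about
biology do not.
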