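# tmespatial

Spatial profiling of tumor-infiltrating immune cells from multiplexed
immunohistochemistry (mIHC) cell maps.

Multiplexed imaging of resected tumors yields, after segmentation, a table of
cells with positions and per-marker intensities inside fixed-size regions of
interest (ROIs, 931 × 698 µm) stamped in three tissue compartments: the tumor
core (TC), the invasion margin (IM, a ~1–1.5 mm band straddling the
tumor–normal interface) and normal tissue (N). `tmespatial` is for analysts
who start from those cell tables and want to answer the questions this kind
of study asks:

- which immune phenotypes (e.g. CD8⁺ tissue-resident memory T cells,
  CD8⁺PD-1⁺ TRM, CD68⁺ myeloid cells) are present, by threshold gating of
  marker intensities;
- how their densities and proportions differ across compartments and between
  untreated (NG) and checkpoint-blockade-treated (EG) groups;
- which phenotypes sit near each other, via radius-based neighborhood
  pairing;
- which phenotypes co-vary in abundance, via Pearson correlation networks of
  per-ROI counts.

Because studies of this design rarely release raw slides, the package ships a
synthetic slide simulator (Poisson backgrounds per compartment plus
Thomas-style attraction clustering and a log-normal marker-emission model)
that generates datasets with the statistical structure the analysis assumes,
for validation and power exploration.

## The statistics at the core

For a *central* phenotype C and a *target* phenotype T, every ordered pair of
distinct cells (c ∈ C, t ∈ T) with Euclidean nucleus-to-nucleus distance
d(c, t) ≤ r (default r = 30 µm, inclusive) is a neighbor pair. Writing P for
the pair set and n_C for the number of central cells:

- **effective score** = |P| / n_C — the average number of target neighbors
  per central cell (centrals with no neighbors stay in the denominator);
- **average distance** = Σ_{(c,t)∈P} d(c, t) / |P| — undefined when |P| = 0.

Both are computed per ROI (pairing never crosses ROI boundaries) and pooled
over a region or slide by summing pair and central counts before taking the
ratio. Under complete spatial randomness the effective score has the
closed-form expectation λ_T π r² and the mean pair distance is 2r/3; both are
exposed as oracles (`expected_effective_score_csr()`,
`expected_mean_pair_distance_csr()`) and verified by simulation in the test
suite. A label-permutation null (`permutation_null()`) provides significance
for observed scores.

Group comparisons follow the field's standard toolkit: Kruskal–Wallis with
Dunn's post-hoc test (Bonferroni-adjusted), one-way ANOVA with Tukey HSD, a
balanced two-way interaction ANOVA, and Pearson correlation with t-based
p-values.

## Worked example

```r
library(tmespatial)

cfg <- sim_config(group = "EG", n_rois_per_region = 4, seed = 7)
ds  <- gate_dataset(simulate_slide(cfg), gating_config(default_thresholds()))
ds
#> <tme_dataset>
#>   cells : 7854 across 12 ROIs
#>   panel : CD8, CD4, CD69, CD68, PD1, CD103
#>   ROIs  : IM/EG=4 N/EG=4 TC/EG=4

dens <- density_table(ds, c("CD8+TRM", "CD8+PD-1+TRM"))
dens |>
  dplyr::group_by(phenotype, region) |>
  dplyr::summarise(mean_density = mean(density), .groups = "drop")
#>   phenotype    region mean_density
#> 1 CD8+PD-1+TRM IM             58.1
#> 2 CD8+PD-1+TRM N              18.9
#> 3 CD8+PD-1+TRM TC            150.
#> 4 CD8+TRM      IM            182.
#> 5 CD8+TRM      N              81.6
#> 6 CD8+TRM      TC            385.

compare_density(dens, "CD8+PD-1+TRM", by = "region", test = "kw")
#> <tme_comparison> Kruskal-Wallis
#>   statistic = 9.8462 (df = 2), p = 0.007277
#>   post-hoc:
#>  level_a level_b        z     p_value  adjusted_p
#>       TC      IM 1.568929 0.116664465 0.349993394
#>       TC       N 3.137858 0.001701872 0.005105616
#>       IM       N 1.568929 0.116664465 0.349993394

pooled_neighborhood_metrics(ds, "CD8+PD-1+TRM", "CD68+", 30, scope = "region")
#>   region n_central n_pairs effective_score average_distance_um
#> 1     IM       151     374        2.476821            12.74725
#> 2      N        49     119        2.428571            12.02337
#> 3     TC       391    1247        3.189258            14.01136
```

Reading the output: the simulated checkpoint-treated slide carries the
configured core-ward gradient of CD8⁺PD-1⁺ TRM density (N 19 → IM 58 →
TC 150 cells/mm²), which the Kruskal–Wallis test across per-ROI densities
detects (p = 0.007; Dunn's test places the TC–N contrast at adjusted
p = 0.005). The pooled effective score says each CD8⁺PD-1⁺ TRM cell has
~2.4–3.2 CD68⁺ cells within 30 µm, and the average pair distance of
~12–14 µm — well below the 20 µm expected under spatial randomness —
reflects the configured attraction between the two phenotypes.

`autoplot()` methods on the density, neighborhood and correlation tables
produce the corresponding ggplot2 figures; `tidy()`/`glance()` turn
comparison objects into tibbles. `run_pipeline()` (or the
`inst/scripts/tme-spatial` command-line front end) chains
simulate/read → gate → density → neighborhood → correlate → compare into one
reproducible, seeded run with CSV artifacts and a JSON report.

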