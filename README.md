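# galeria

Quantitative analysis of paired grazed/restored gallery-forest monitoring
surveys, of the kind used to evaluate cattle-exclusion restoration in
forest-savanna mosaics such as the Beni Savannas of Bolivia. The package
takes tabular field-survey data — stem records from nested plots, shrub-layer
line-intercept intervals, ground-cover quadrats, and line-transect wildlife
observations — and computes:

- **Stand structure**: per-hectare densities and basal areas
  (BA = π·(dbh/200)² m² per stem) by site, life stage and functional group,
  with snags tallied as separate classes, plus height and dbh size-class
  distributions (acaulescent palm saplings form the smallest "dbh" band).
- **Natural Regeneration index**: for live saplings in height classes
  *j* ∈ {1–2 m, 2–3 m, >3 m}, NR_ij = (RD_ij + RF_ij)/2, where RD is the
  relative density and RF the relative frequency of group *i* normalized
  across groups within class *j*; reported per-class values carry the 1/3
  class weight so each class column sums to 100/3 and
  TNR_i = Σ_j NR_ij sums to 100 across groups.
- **Understory ordination**: correlation-matrix PCA of plot × variable
  percent-cover matrices (z-scored columns), with the latent-root criterion
  (eigenvalue > 1), |loading| > 0.5 salience sets, and per-site centroid/SD
  ellipses for the first two axes.
- **Wildlife**: encounter rates per km walked (mammals against total
  dusk + night distance, nocturnal birds against night-only distance),
  per-site richness and unique/shared species, and the exact (analytic)
  species-accumulation curve over 15-minute survey segments:
  E[S(k)] = Σ_i [1 − C(T−t_i, k)/C(T, k)], with the exact subset variance
  from pairwise joint-absence counts.
- **A seeded synthetic survey generator** whose defaults reproduce the
  reference site means (e.g. motacú saplings 1300/ha grazed vs 3200/ha
  restored), used for estimator recovery and directional testing.

Everything is tidyverse-shaped: data frames in, tibbles out, `autoplot()`
methods for the result types, `tidy()`/`glance()` for fitted ordinations.

## Worked example

```r
library(galeria)

ds <- simulate_survey(seed = 1)   # paired sites, 4 plots each
ds
#> <survey_data>
#>   sites:        grazed, restored
#>   stems:        990 records
#>   quadrats:     320 records
#>   seedlings:    80 records
#>   intercepts:   63 records
#>   efforts:      8 records
#>   observations: 148 records

nr_table(ds)
#> <nr_table> Natural Regeneration index (per-class NR % and TNR %)
#> # A tibble: 4 × 6
#>   site_id  group     nr_pct_12m nr_pct_23m nr_pct_3m_plus tnr_pct
#> 1 grazed   broadleaf       19.4       19.5           16.4    55.3
#> 2 grazed   motacu          13.9       13.8           17.0    44.7
#> 3 restored broadleaf       15.4       15.5           13.9    44.8
#> 4 restored motacu          17.9       17.9           19.4    55.2

cover_pca(shrub_cover_matrix(ds))
#> <cover_pca> shrub layer: 5 variables, 8 rows
#>   eigenvalues: 2.208, 1.558, 0.769, 0.439, 0.026
#>   retained (latent root > 1): PC1, PC2
#>   PC1 salient: palms, broadleafs, vines, ferns
#>   PC2 salient: palms, woody_shrubs
```

Reading the NR table: on this replicate, motacú TNR is 55.2% on the
restored site against 44.7% on the grazed site — the restored site holds the
larger share of advanced palm regeneration, the pattern the grazing-exclusion
contrast in the generator encodes. Per-class columns always sum to 100/3 and
TNR to 100 within a site; these conservation identities are tested on every
input. The shrub PCA retains two axes under the latent-root criterion; PC1 is
a shrub-density gradient (palm and broadleaf cover load above |0.5|).

The full pipeline (stage tables, both PCAs, encounter rates, accumulation
curves, `report.json`) runs from one config:

```r
run_pipeline(list(simulate = TRUE, seed = 1, out_dir = "out"))
```

Identical config and seed give byte-identical output bundles.

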