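---
title: "Methods: regeneration indices, cover ordination and wildlife metrics for paired-site forest monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regeneration indices, cover ordination and wildlife metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(galeria)
library(dplyr)
```

`galeria` implements the complete quantitative workflow of a
grazed-versus-restored gallery-forest monitoring study: stand structure and
regeneration indices from nested vegetation plots, ordination of understory
cover, and encounter/diversity metrics from line-transect wildlife surveys.
This vignette explains the models and conventions behind each stage, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the design choices made where the methodology was genuinely
open.

## Survey design and data model

Each site (one grazed, one restored) is sampled with four plots. A plot is a
100 m transect with a 20 × 20 m (400 m²) subplot for adult trees
(dbh > 10 cm at 1.3 m), the 200 m² western half-subplot for saplings
(height > 30 cm, dbh < 10 cm), and five 4 m² quadrats for ground cover and
seedling counts (< 30 cm). The shrub layer (≤ 2 m) is recorded by line
intercept over the full transect for five functional groups. Wildlife is
surveyed on two permanent line transects per site, each walked once at dusk
(mammals) and once at night (mammals and nocturnal birds).

Records are validated on entry: every invariant violation is an error naming
the table and row — nothing is silently dropped. Two conventions are worth
stating explicitly:

- **Seedlings are counts, not stems.** They are never individually measured,
  so a stem record with `stage = "seedling"` is invalid; seedling data live
  in the quadrat count table.
- **Snags are dead stems, not a taxon.** A standing dead stem is a live-group
  record with `alive = FALSE`; summaries derive `<group>_snag` classes from
  the flag. This keeps one taxonomy while making "exclude dead" filters
  explicit (the NR index, for instance, uses live saplings only).

Motacú (*Attalea princeps*) juveniles are acaulescent — stemless — so motacú
saplings carry heights but never a dbh, and contribute no basal area.

## Stand structure

Basal area per stem is the circular cross-section π·(dbh/200)² m². Densities
are counts scaled by the stage's sampled area (adults 400 m², saplings
200 m², seedlings 20 m² of quadrats per plot). Per-plot values are averaged
across the site's plots with the sample SD (n − 1); plots with no records of
a class contribute zeros rather than being skipped. Composition percentages
are shares of the stage total including snag classes, matching how field
tables report "% of total".

Size-class distributions use left-closed, right-open bands everywhere
(a 2.0 m sapling is in [2, 3); a stem of exactly 10 cm dbh is an adult):
1 m height bands for saplings, 10 cm dbh bands for saplings + adults
combined, and 3 m height bands for adults. In the dbh scheme all acaulescent
motacú saplings form the smallest "dbh" band. Stems missing the binning
measurement are reported in an explicit `unmeasured` band so band totals
always conserve the stem count.

## The Natural Regeneration index

For live saplings taller than 1 m, split into height classes 1–2 m, 2–3 m
and > 3 m (the lower cutoff restricts the index to individuals past the
early-mortality bottleneck), the index combines two within-class shares:

- relative density RD_ij: group *i*'s share of the plot-mean per-ha density
  in class *j*, as a percentage over groups;
- relative frequency RF_ij: group *i*'s share of plot occurrences (presence/
  absence per plot — plots, not quadrats, are the sampling unit for
  saplings) in class *j*, again normalized over groups.

The class score is (RD_ij + RF_ij)/2. Reported per-class NR percentages
carry the 1/3 class weight, so each class column sums to 100/3 across groups
and TNR_i = Σ_j NR_ij sums to 100. This grand-normalized convention is the
only one consistent with regeneration tables in which per-class columns sum
to a third of 100 and TNR row-sums partition 100; the raw (RD + RF)/2
intermediates are retained and exposed via `tidy()`. Broadleaf saplings with
a measured dbh ≥ 5 cm are excluded (they are past the regeneration stage of
interest); unmeasured broadleaf saplings are retained; all motacú saplings
enter since they have no dbh. A height class empty for every group
contributes zero with a warning; in that case TNR sums fall short of 100 by
construction, which is reported, not patched.

## Understory ordination

Shrub cover per plot and functional group is the union length of possibly
overlapping intercept intervals divided by transect length; ground cover per
plot and category is the mean of the five quadrat percentages. By default
the ground matrix carries the eight recorded categories plus a derived
`total_plant_cover` column (forbs + ferns + graminoids); the exact column
set is an argument, since the published variable lists for such analyses are
rarely enumerated — the choice is explicit and logged in the output
metadata rather than hard-wired.

The ordination is a correlation-matrix PCA: columns are z-scored (n − 1 SD)
so all variables enter with equal weight, which is what "standardized to
mean zero and unit variance" implies. Conventions:

- **Loadings** are variable–axis correlations, eigenvector × √eigenvalue.
  The conventional |0.5| salience threshold is defined for this scaling,
  not for raw eigenvectors, which is why this definition was chosen.
- **Retention** follows the latent-root criterion (eigenvalue > 1).
- **Sign** of each axis is flipped so its largest-magnitude loading is
  positive — eigenvectors are sign-indeterminate and this makes output
  deterministic and row-order invariant.
- **Zero-variance columns** cannot be z-scored and are dropped with a
  warning (this happens in small simulated replicates when a shrub group is
  absent everywhere).
- **Site ellipses** are axis-aligned 1-SD ellipses around each site's
  centroid in PC1–PC2 space — the simplest reading of "centroid and
  standard deviation per site"; no covariance rotation is applied.

With eight plots and nine ground variables the decomposition returns
min(rows − 1, p) axes; trailing axes carry zero eigenvalue, so eigenvalue
sums, communalities and score reconstruction are unaffected.

## Wildlife metrics

Encounter rates are per linear kilometre walked. Mammals were surveyed on
both walks, so their denominator is the site's total dusk + night distance;
nocturnal birds were surveyed only at night, so their denominator is the
night-only distance. The rate numerator defaults to individuals (the
convention under which reference encounter-rate tables reproduce from their
count columns: e.g. 17 coati individuals over 4.25 km = 4.00/km); an
events basis is available as an argument. Rates are computed and differenced
at full precision and rounded only for display.

For accumulation analysis, each site's observation period is cut into
15-minute segments (dusk walks first, then night walks, then transect id;
final partial bins kept; capped at 24 segments = 6 h). The segment order is
metadata only — the exact accumulation method is invariant to column order.
With t_i the number of segments holding taxon *i* and T segments in total,

E[S(k)] = Σ_i [1 − C(T−t_i, k)/C(T, k)]

is the expected richness over all equally likely size-k segment subsets, and
the variance adds the per-taxon Bernoulli terms and pairwise covariances
computed from joint-absence counts (segments holding neither taxon). This is
the analytic, resampling-free form; it is verified in the tests against
complete subset enumeration to 1e-10 for all T ≤ 10. The expectation agrees
with `vegan::specaccum(method = "exact")` to machine precision; vegan's SD
uses a moment approximation that can differ from the exact subset SD in the
second decimal, so the enumeration oracle — not vegan — is the reference for
the SD.

## The synthetic-survey generator

The generator exists so every estimator can be exercised against known
truth. Its default profiles encode the reference study conditions: adult,
sapling and seedling densities, dbh and height moments, and per-km wildlife
encounter rates equal the published site means of the Barba Azul
grazing-exclusion monitoring study, and the walked distances total 4.25 km
(grazed) and 3.86 km (restored). Distributional forms are this package's own
choices — the simplest standard forms reproducing those means and the
observed overdispersion:

- counts: Poisson in the sampled area (stems), negative binomial per quadrat
  (seedlings; the reported seedling SDs exceed their means, so
  `seedling_dispersion = 0.8` gives strong overdispersion);
- sizes: truncated normal dbh (> 10 cm for adults) and adult heights;
  sapling heights 0.3 m + exponential, with site-specific mean increments
  (1.8 m grazed, 1.2 m restored) so the grazed site carries relatively more
  tall saplings, as its published height-class pattern shows; broadleaf
  sapling dbh follows a simple linear allometry of height, capped below
  10 cm;
- cover: Dirichlet ground-cover shares per quadrat (concentrations chosen to
  put more bare ground, dung and litter on the grazed site and more grass,
  nuts and deadwood on the restored site — within-plot variance of cover is
  not published, so these are calibration choices, flagged in the config);
  shrub intercepts with exponential lengths (mean 5 m) placed uniformly, the
  interval count tuned so the expected intercepted length matches the cover
  target (overlap is allowed, so realized union cover sits slightly below
  the target — a known, documented bias that matters to none of the
  estimators);
- wildlife: Poisson encounter events per walk at the taxon's per-km rate,
  uniform event times, unit-shifted Poisson group sizes
  (`group_size_lambda = 0.25`, so the per-km rate is on the individuals
  scale).

Each site draws from one RNG substream derived deterministically from
`(seed, site_id)`; the same seed reproduces a dataset record for record, and
the generator restores the caller's RNG state.

What the generator does **not** emulate: spatial point patterns or
within-plot clustering of stems, seasonal (wet/dry) dynamics, imperfect
detection on transects, and observer effects. Passing recovery tests
therefore demonstrates estimator correctness under the stated sampling
model, not robustness to those field realities.

## Problem sizes and verification

The tests recover generator parameters with simulations of 400 plots per
site (Poisson 3-SE bands; basal area, being emergent from density × dbh
distribution rather than separately enforced, is checked to ±25%), verify
the directional grazed/restored contrasts (motacú sapling density and TNR
higher on the restored site) across 100 seeded replicates at the field
design of 4 plots, and check the accumulation-curve dominance property
across 50 replicates under uniformly higher restored rates. Determinism is
asserted byte-for-byte on full pipeline output bundles; for that reason run
metadata records the config and seed but neither timestamps nor the output
path.

## Known limitations

- The NR index is sensitive to the broadleaf dbh cutoff when many saplings
  lack dbh measurements; unmeasured stems are included, which is the
  permissive reading.
- Encounter rates are raw rates, not abundance estimates: no detection
  modelling, no distance sampling.
- Published three-axis variance figures for understory ordinations depend on
  the exact variable sets of the original analyses, which are not
  enumerated; the package makes the column sets configurable and does not
  claim to match any particular published loading table.
- With four plots per site, ordination group ellipses summarise four points;
  they are descriptive, not inferential.
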