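# Reference site means from the Barba Azul (Beni, Bolivia) grazing-exclusion
# monitoring study that this package's generator defaults emulate. These are
# benchmark inputs for consistency checks: the analysis functions must
# reproduce the study's derived quantities from them.

#' Reference stand-structure site means
#'
#' Site-mean densities (individuals/ha, with SD) and basal areas (m2/ha) by
#' life stage and functional group for the grazed and restored reference
#' sites. Snag classes are separate rows, as tallied in the field.
#'
#' @return A tibble: `treatment`, `stage`, `group_class`,
#'   `mean_density_per_ha`, `sd_density`, `mean_ba_m2_ha`, `sd_ba` (`NA`
#'   where not assessed; acaulescent motacu saplings have no basal area).
#' @export
ref_stand_structure <- function() {
  tibble::tribble(
    ~treatment, ~stage,     ~group_class,      ~mean_density_per_ha, ~sd_density, ~mean_ba_m2_ha, ~sd_ba,
    "grazed",   "seedling", "broadleaf",       27875,  11665,  NA,    NA,
    "grazed",   "seedling", "motacu",          10875,   3250,  NA,    NA,
    "grazed",   "sapling",  "broadleaf",        2938,   1551,  3.3,   2.3,
    "grazed",   "sapling",  "motacu",           1300,   1363,  NA,    NA,
    "grazed",   "sapling",  "broadleaf_snag",     50,    100,  0.06,  0.1,
    "grazed",   "adult",    "broadleaf",         388,    171,  17.5,  11.6,
    "grazed",   "adult",    "motacu",            225,   95.7,  28.4,  18.7,
    "grazed",   "adult",    "other_palm",          0,      0,  0,     0,
    "grazed",   "adult",    "broadleaf_snag",     25,   28.9,  0.24,  0.3,
    "grazed",   "adult",    "motacu_snag",         6,   12.5,  0.35,  0.7,
    "restored", "seedling", "broadleaf",       22125,  15418,  NA,    NA,
    "restored", "seedling", "motacu",          10750,  13763,  NA,    NA,
    "restored", "sapling",  "broadleaf",        2838,   1672,  0.8,   0.8,
    "restored", "sapling",  "motacu",           3200,   2618,  NA,    NA,
    "restored", "sapling",  "broadleaf_snag",      0,      0,  0,     0,
    "restored", "adult",    "broadleaf",          31,   31.5,  1.88,  1.3,
    "restored", "adult",    "motacu",            412,   32.3,  46.8,  5.7,
    "restored", "adult",    "other_palm",          6,   12.5,  0.74,  1.5,
    "restored", "adult",    "broadleaf_snag",      0,      0,  0,     0,
    "restored", "adult",    "motacu_snag",         6,   12.5,  0.13,  0.3
  )
}

#' Reference per-class Natural Regeneration percentages
#'
#' The reported per-height-class NR percentages (already on the grand-
#' normalized scale where each class column sums to 100/3 across groups) for
#' the two reference sites. TNR is recomputed from these, not stored.
#'
#' @return A tibble: `treatment`, `group`, `nr_pct_12m`, `nr_pct_23m`,
#'   `nr_pct_3m_plus`.
#' @export
ref_nr_classes <- function() {
  tibble::tribble(
    ~treatment, ~group,      ~nr_pct_12m, ~nr_pct_23m, ~nr_pct_3m_plus,
    "grazed",   "motacu",    15.00, 12.83, 10.57,
    "grazed",   "broadleaf", 18.33, 20.50, 22.76,
    "restored", "motacu",    17.98, 20.24,  9.39,
    "restored", "broadleaf", 15.35, 13.09, 23.94
  )
}

#' Reference wildlife counts and survey effort
#'
#' Individuals recorded per taxon and site on the reference line-transect
#' surveys, plus the published per-site effort (total walked km, with the
#' dusk/night split used by this package's effort model). Expanding the
#' counts into one observation row per (taxon, site) lets
#' [encounter_table()] recompute the published encounter rates from first
#' principles.
#'
#' @return A list with elements `counts` (tibble `taxon_id, taxon_class,
#'   n_grazed, n_restored`), `efforts` (a validated effort table totalling
#'   4.25 km grazed and 3.86 km restored), and `observations` (the expanded
#'   observation table).
#' @export
ref_wildlife <- function() {
  counts <- default_profiles()$grazed$wildlife |>
    select("taxon_id", "taxon_class") |>
    mutate(n_grazed = c(4, 8, NA, 17, 15, NA, 4, NA, NA, NA, 1, 1, NA, NA,
                        1, 2, 3, 9, NA, 7, 1),
           n_restored = c(11, 4, 3, 1, 18, 1, 2, 1, 1, 1, NA, 1, 1, 1,
                          3, NA, 7, 9, 1, 17, 4))
  efforts <- bind_rows(
    mutate(default_profiles()$grazed$efforts, site_id = "grazed"),
    mutate(default_profiles()$restored$efforts, site_id = "restored"))
  long <- counts |>
    tidyr::pivot_longer(c("n_grazed", "n_restored"),
                        names_to = "site_id", values_to = "n",
                        names_prefix = "n_") |>
    filter(!is.na(.data$n))
  observations <- long |>
    mutate(transect_id = ifelse(.data$site_id == "grazed", "g1", "r1"),
           survey = "night", elapsed_min = 0,
           n_individuals = .data$n,
           detection = ifelse(.data$taxon_class == "mammal",
                              "visual", "aural")) |>
    select("transect_id", "site_id", "survey", "elapsed_min", "taxon_id",
           "taxon_class", "n_individuals", "detection")
  list(counts = counts, efforts = efforts, observations = observations)
}
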