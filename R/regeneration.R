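# Stand structure and the Natural Regeneration (NR/TNR) index.

#' Basal area of a single stem
#'
#' Cross-sectional area at breast height from diameter:
#' \eqn{\pi (d/200)^2} square metres for a diameter `d` in centimetres.
#'
#' @param dbh_cm Stem diameter at 1.3 m, in cm. Vectorised; must be >= 0.
#' @return Basal area in m2.
#' @examples
#' stem_basal_area(20)  # 0.0314 m2
#' @export
stem_basal_area <- function(dbh_cm) {
  if (any(dbh_cm < 0, na.rm = TRUE)) {
    abort("stem_basal_area: dbh_cm must be >= 0",
          class = "galeria_domain_error")
  }
  pi * (dbh_cm / 200)^2
}

#' Scale a count to stems per hectare
#'
#' @param count Number of individuals observed.
#' @param sampled_area_m2 Area over which they were counted, m2 (> 0).
#' @return Density in individuals per hectare.
#' @examples
#' density_per_ha(1, 400)  # 25/ha
#' @export
density_per_ha <- function(count, sampled_area_m2) {
  if (any(sampled_area_m2 <= 0, na.rm = TRUE)) {
    abort("density_per_ha: sampled_area_m2 must be > 0",
          class = "galeria_domain_error")
  }
  count * 10000 / sampled_area_m2
}

# Group label with snags split out ("broadleaf_snag" etc.); type-stable on
# empty input.
group_with_snags <- function(group, alive) {
  out <- as.character(group)
  out[!alive] <- paste0(out[!alive], "_snag")
  out
}

design_for_site <- function(dataset, site) {
  d <- dataset$designs[[site]]
  if (is.null(d)) {
    abort(sprintf("no design registered for site '%s'", site),
          class = "galeria_parameter_error")
  }
  d
}

plot_grid <- function(dataset, site) {
  d <- design_for_site(dataset, site)
  obs <- unique(c(dataset$stems$plot_id[dataset$stems$site_id == site],
                  dataset$quadrats$plot_id[dataset$quadrats$site_id == site],
                  dataset$seedlings$plot_id[dataset$seedlings$site_id == site],
                  dataset$intercepts$plot_id[dataset$intercepts$site_id == site]))
  if (length(obs) > d$n_plots) {
    abort(sprintf("site '%s': %d plot ids observed but design says %d plots",
                  site, length(obs), d$n_plots),
          class = "galeria_validation_error")
  }
  # Pad with canonical ids so empty plots still enter means and SDs.
  if (length(obs) < d$n_plots) {
    pad <- setdiff(paste0(site, "_p", seq_len(d$n_plots)), obs)
    obs <- c(obs, pad[seq_len(d$n_plots - length(obs))])
  }
  sort(obs)
}

# Per-plot density and basal area per ha for every (stage, group-with-snag)
# cell, on the complete plot grid so absent plots count as zeros.
plot_stage_table <- function(dataset) {
  sites <- names(dataset$designs)
  per_site <- map(sites, function(site) {
    d <- design_for_site(dataset, site)
    plots <- plot_grid(dataset, site)
    stems <- filter(dataset$stems, .data$site_id == site)
    stem_cells <- stems |>
      mutate(group_class = group_with_snags(.data$group, .data$alive),
             ba_m2 = ifelse(is.na(.data$dbh_cm), 0,
                            stem_basal_area(.data$dbh_cm))) |>
      summarise(n = n(), ba_m2 = sum(.data$ba_m2),
                .by = c("plot_id", "stage", "group_class"))
    seed_cells <- dataset$seedlings |>
      filter(.data$site_id == site) |>
      mutate(stage = "seedling",
             group_class = dplyr::if_else(.data$group == "woody",
                                          "broadleaf", .data$group)) |>
      summarise(n = sum(.data$count), ba_m2 = 0,
                .by = c("plot_id", "stage", "group_class"))
    cells <- bind_rows(stem_cells, seed_cells)
    live <- .stem_groups
    grid <- bind_rows(
      expand_grid(plot_id = plots, stage = c("sapling", "adult"),
                  group_class = c(live, paste0(live, "_snag"))),
      expand_grid(plot_id = plots, stage = "seedling",
                  group_class = c("broadleaf", "motacu"))
    )
    grid |>
      left_join(cells, by = c("plot_id", "stage", "group_class")) |>
      mutate(n = coalesce(.data$n, 0), ba_m2 = coalesce(.data$ba_m2, 0),
             site_id = site,
             area_m2 = map_dbl(.data$stage, \(s) stage_area_m2(d, s)),
             density_per_ha = density_per_ha(.data$n, .data$area_m2),
             ba_m2_per_ha = .data$ba_m2 * 10000 / .data$area_m2)
  })
  list_rbind(per_site)
}

#' Stand-structure summary by site, life stage and functional group
#'
#' For each site, computes per-plot density (individuals/ha) and basal area
#' (m2/ha) for every life stage x functional group cell -- snags appear as
#' their own `<group>_snag` classes -- then averages across the site's plots
#' (sample SD, n-1 denominator). Composition percentages are shares of the
#' stage total (live plus snag classes) within each site. Motacu saplings are
#' acaulescent and contribute no basal area; seedling densities come from the
#' quadrat counts scaled by the summed quadrat area.
#'
#' @param dataset A validated `survey_data` object.
#' @return A tibble with one row per (site, stage, group class):
#'   `mean_density_per_ha`, `sd_density`, `pct_of_stage_total`,
#'   `mean_ba_m2_ha`, `sd_ba`, `pct_of_stage_ba`.
#' @export
site_stage_summary <- function(dataset) {
  stopifnot(inherits(dataset, "survey_data"))
  if (length(dataset$designs) == 0) {
    abort("site_stage_summary: dataset has no sites",
          class = "galeria_parameter_error")
  }
  plot_stage_table(dataset) |>
    summarise(mean_density_per_ha = mean(.data$density_per_ha),
              sd_density = if (n() > 1) sd(.data$density_per_ha) else 0,
              mean_ba_m2_ha = mean(.data$ba_m2_per_ha),
              sd_ba = if (n() > 1) sd(.data$ba_m2_per_ha) else 0,
              .by = c("site_id", "stage", "group_class")) |>
    mutate(sd_density = coalesce(.data$sd_density, 0),
           sd_ba = coalesce(.data$sd_ba, 0)) |>
    mutate(stage_total = sum(.data$mean_density_per_ha),
           stage_ba_total = sum(.data$mean_ba_m2_ha),
           .by = c("site_id", "stage")) |>
    mutate(pct_of_stage_total = ifelse(.data$stage_total > 0,
                                       100 * .data$mean_density_per_ha /
                                         .data$stage_total, NA_real_),
           pct_of_stage_ba = ifelse(.data$stage_ba_total > 0,
                                    100 * .data$mean_ba_m2_ha /
                                      .data$stage_ba_total, NA_real_)) |>
    select(-"stage_total", -"stage_ba_total") |>
    mutate(stage = factor(.data$stage, levels = .stages)) |>
    arrange(.data$site_id, .data$stage, .data$group_class)
}

#' Size-class distributions of stems
#'
#' Bins stems into the study's three class schemes and reports per-hectare
#' mean and SD across plots for every (site, group, band):
#' \describe{
#'   \item{`sapling_height_1m`}{live and snag saplings in 1 m height bands.}
#'   \item{`stem_dbh_10cm`}{saplings and adults combined in 10 cm dbh bands;
#'     acaulescent motacu saplings (no dbh by definition) form the smallest
#'     "dbh" band, flagged `acaulescent`.}
#'   \item{`adult_height_3m`}{adults with measured heights in 3 m bands (in
#'     practice motacu, the only group whose adult heights are measured).}
#' }
#' Bands are left-closed, right-open. Stems lacking the binning measurement
#' (other than acaulescent motacu under the dbh scheme) land in an explicit
#' `unmeasured` band rather than being dropped.
#'
#' @param dataset A validated `survey_data` object.
#' @param scheme One of `"sapling_height_1m"`, `"stem_dbh_10cm"`,
#'   `"adult_height_3m"`.
#' @return A tibble with columns `site_id`, `group_class`, `band`,
#'   `band_lower`, `band_upper`, `acaulescent`, `mean_count_per_ha`, `sd`.
#' @export
class_distribution <- function(dataset,
                               scheme = c("sapling_height_1m", "stem_dbh_10cm",
                                          "adult_height_3m")) {
  stopifnot(inherits(dataset, "survey_data"))
  scheme <- match.arg(scheme)
  stems <- mutate(dataset$stems,
                  group_class = group_with_snags(.data$group, .data$alive))
  width <- switch(scheme, sapling_height_1m = 1, stem_dbh_10cm = 10,
                  adult_height_3m = 3)
  stems <- switch(scheme,
    sapling_height_1m = filter(stems, .data$stage == "sapling") |>
      mutate(value = .data$height_m),
    stem_dbh_10cm = filter(stems, .data$stage %in% c("sapling", "adult")) |>
      mutate(value = .data$dbh_cm),
    adult_height_3m = filter(stems, .data$stage == "adult") |>
      mutate(value = .data$height_m))
  stems <- mutate(stems,
    acaulescent = scheme == "stem_dbh_10cm" & .data$group == "motacu" &
      .data$stage == "sapling",
    band_lower = ifelse(.data$acaulescent, 0, floor(.data$value / width) * width),
    band_upper = .data$band_lower + width,
    band = dplyr::case_when(
      acaulescent ~ "acaulescent",
      is.na(value) ~ "unmeasured",
      .default = sprintf("[%g,%g)", band_lower, band_upper)))
  # Area basis: saplings were searched on the half-subplot, adults on the
  # full subplot, so per-ha scaling happens per stem before pooling bands.
  dens <- map(names(dataset$designs), function(site) {
    d <- design_for_site(dataset, site)
    plots <- plot_grid(dataset, site)
    ss <- filter(stems, .data$site_id == site)
    if (nrow(ss) == 0) return(NULL)
    ss <- mutate(ss, area_m2 = map_dbl(.data$stage, \(s) stage_area_m2(d, s)),
                 dens = density_per_ha(1, .data$area_m2))
    bands <- distinct(ss, .data$group_class, .data$band,
                      .data$band_lower, .data$band_upper, .data$acaulescent)
    cell <- summarise(ss, dens = sum(.data$dens),
                      .by = c("plot_id", "group_class", "band"))
    expand_grid(plot_id = plots, bands) |>
      left_join(cell, by = c("plot_id", "group_class", "band")) |>
      mutate(dens = coalesce(.data$dens, 0), site_id = site)
  })
  dens <- list_rbind(dens)
  if (is.null(dens) || nrow(dens) == 0) {
    return(tibble(site_id = character(), group_class = character(),
                  band = character(), band_lower = numeric(),
                  band_upper = numeric(), acaulescent = logical(),
                  mean_count_per_ha = numeric(), sd = numeric()))
  }
  dens |>
    summarise(mean_count_per_ha = mean(.data$dens),
              sd = if (n() > 1) sd(.data$dens) else 0,
              .by = c("site_id", "group_class", "band",
                      "band_lower", "band_upper", "acaulescent")) |>
    arrange(.data$site_id, .data$group_class,
            !.data$acaulescent, .data$band_lower) |>
    structure(scheme = scheme)
}

#' Life-stage composition per functional group
#'
#' Sums the per-ha mean densities of live stems over seedling, sapling and
#' adult stages for each (site, group) and reports each stage's integer-
#' rounded percentage share. Groups with zero total get `NA` shares.
#'
#' @param dataset A validated `survey_data` object.
#' @return A tibble with `site_id`, `group`, `total_density_per_ha`, and
#'   `seedling_pct`, `sapling_pct`, `adult_pct` (rounded to integers).
#' @export
life_stage_composition <- function(dataset) {
  stage_summary_composition(site_stage_summary(dataset))
}

#' Life-stage composition from a stand-structure summary table
#'
#' The arithmetic core of [life_stage_composition()], exposed so that an
#' already-summarised table of site-mean densities (e.g. a published
#' reference table) can be reduced to totals and stage shares directly.
#' Snag classes are excluded; shares are rounded to integer percent.
#'
#' @param summary A tibble with columns `site_id` (or `treatment`), `stage`,
#'   `group_class` (or `group`) and `mean_density_per_ha`.
#' @return As [life_stage_composition()].
#' @export
stage_summary_composition <- function(summary) {
  summ <- as_tibble(summary)
  if (!"site_id" %in% names(summ) && "treatment" %in% names(summ)) {
    summ <- rename(summ, site_id = "treatment")
  }
  if (!"group" %in% names(summ) && "group_class" %in% names(summ)) {
    summ <- rename(summ, group = "group_class")
  }
  summ <- filter(summ, !grepl("_snag$", .data$group))
  wide <- summ |>
    select("site_id", "stage", "group", "mean_density_per_ha") |>
    tidyr::pivot_wider(names_from = "stage",
                       values_from = "mean_density_per_ha",
                       values_fill = 0)
  for (st in .stages) if (!st %in% names(wide)) wide[[st]] <- 0
  wide |>
    mutate(total_density_per_ha = .data$seedling + .data$sapling + .data$adult,
           seedling_pct = ifelse(.data$total_density_per_ha > 0,
                                 round(100 * .data$seedling /
                                         .data$total_density_per_ha), NA),
           sapling_pct = ifelse(.data$total_density_per_ha > 0,
                                round(100 * .data$sapling /
                                        .data$total_density_per_ha), NA),
           adult_pct = ifelse(.data$total_density_per_ha > 0,
                              round(100 * .data$adult /
                                      .data$total_density_per_ha), NA)) |>
    select("site_id", "group", "total_density_per_ha",
           "seedling_pct", "sapling_pct", "adult_pct") |>
    arrange(.data$site_id, .data$group)
}

#' Natural Regeneration index over sapling height classes
#'
#' For each site, live saplings taller than 1 m are split into height classes
#' (default 1-2 m, 2-3 m, >3 m). Within each class j and site, the relative
#' density of group i is
#' \eqn{RD_{ij} = 100\,\bar d_{ij} / \sum_i \bar d_{ij}} (plot-mean per-ha
#' densities) and the relative frequency is
#' \eqn{RF_{ij} = 100\,f_{ij} / \sum_i f_{ij}}, with \eqn{f_{ij}} the number
#' of plots where group i occurs in class j. The class score is
#' \eqn{(RD_{ij}+RF_{ij})/2}; the reported per-class NR percentage divides
#' this by the number of classes, so per-class NR sums to 100/3 across groups
#' and the total \eqn{TNR_i = \sum_j NR_{ij}} sums to 100 across groups.
#'
#' Broadleaf saplings with measured dbh at or above `broadleaf_dbh_max` are
#' excluded (they are past the regeneration stage of interest); all motacu
#' saplings are included since they carry no dbh. Dead saplings never enter.
#'
#' @param dataset A validated `survey_data` object.
#' @param class_breaks Lower edges of the height classes in metres; the last
#'   class is open above. Default `c(1, 2, 3)`.
#' @param broadleaf_dbh_max Exclusion threshold (cm) for measured broadleaf
#'   sapling dbh. Default 5.
#' @return A tibble of class `nr_table`: one row per (site, group) with a
#'   `nr_pct_*` column per height class and `tnr_pct`; the per-class RD/RF
#'   intermediates are attached as `attr(x, "components")` and retrievable
#'   with [tidy()].
#' @export
nr_table <- function(dataset, class_breaks = c(1, 2, 3),
                     broadleaf_dbh_max = 5) {
  stopifnot(inherits(dataset, "survey_data"))
  if (length(class_breaks) < 1 || is.unsorted(class_breaks, strictly = TRUE)) {
    abort("nr_table: class_breaks must be strictly increasing",
          class = "galeria_parameter_error")
  }
  n_class <- length(class_breaks)
  labels <- c(paste0(head(class_breaks, -1), "-",
                     class_breaks[-1], "m"),
              paste0(">", class_breaks[n_class], "m"))
  sap <- dataset$stems |>
    filter(.data$stage == "sapling", .data$alive,
           .data$height_m > class_breaks[1],
           !(.data$group == "broadleaf" & !is.na(.data$dbh_cm) &
               .data$dbh_cm >= broadleaf_dbh_max)) |>
    mutate(class_idx = findInterval(.data$height_m, class_breaks),
           class = labels[.data$class_idx])
  if (nrow(sap) == 0) {
    abort("nr_table: no live saplings above the first height class",
          class = "galeria_domain_error")
  }
  per_site <- map(names(dataset$designs), function(site) {
    d <- design_for_site(dataset, site)
    plots <- plot_grid(dataset, site)
    ss <- filter(sap, .data$site_id == site)
    groups <- sort(unique(ss$group))
    if (length(groups) == 0) return(NULL)
    cell <- summarise(ss, n = n(), .by = c("plot_id", "group", "class"))
    full <- expand_grid(plot_id = plots, group = groups, class = labels) |>
      left_join(cell, by = c("plot_id", "group", "class")) |>
      mutate(n = coalesce(.data$n, 0),
             dens = density_per_ha(.data$n, d$sapling_subplot_area_m2))
    by_class <- full |>
      summarise(mean_dens = mean(.data$dens),
                n_plots_present = sum(.data$n > 0),
                .by = c("group", "class"))
    empties <- by_class |>
      summarise(tot = sum(.data$mean_dens), .by = "class") |>
      filter(.data$tot == 0)
    if (nrow(empties) > 0) {
      warn(sprintf("site '%s': height class(es) %s empty for all groups; they contribute 0 to NR",
                   site, paste(empties$class, collapse = ", ")))
    }
    by_class |>
      mutate(rd_pct = {
               tot <- sum(.data$mean_dens)
               if (tot > 0) 100 * .data$mean_dens / tot else rep(0, n())
             },
             rf_pct = {
               tot <- sum(.data$n_plots_present)
               if (tot > 0) {
                 100 * .data$n_plots_present / tot
               } else {
                 rep(0, n())
               }
             },
             .by = "class") |>
      mutate(nr_class_pct = (.data$rd_pct + .data$rf_pct) / 2,
             nr_pct = .data$nr_class_pct / n_class,
             site_id = site)
  })
  components <- list_rbind(per_site) |>
    mutate(class = factor(.data$class, levels = labels)) |>
    select("site_id", "group", "class", "mean_dens", "n_plots_present",
           "rd_pct", "rf_pct", "nr_class_pct", "nr_pct") |>
    arrange(.data$site_id, .data$group, .data$class)
  wide <- components |>
    mutate(colname = paste0("nr_pct_", gsub("[->]", "", .data$class),
                            ifelse(grepl("^>", .data$class), "_plus", ""))) |>
    select("site_id", "group", "colname", "nr_pct") |>
    tidyr::pivot_wider(names_from = "colname", values_from = "nr_pct")
  tnr <- summarise(components, tnr_pct = sum(.data$nr_pct),
                   .by = c("site_id", "group"))
  out <- left_join(wide, tnr, by = c("site_id", "group")) |>
    arrange(.data$site_id, .data$group)
  structure(out, class = c("nr_table", class(out)),
            components = components, class_labels = labels)
}

#' @export
print.nr_table <- function(x, ...) {
  cat("<nr_table> Natural Regeneration index (per-class NR % and TNR %)\n")
  NextMethod()
}

#' Tidy the per-class components of an NR table
#'
#' @param x An `nr_table`.
#' @param ... Unused.
#' @return A long tibble with RD, RF, the raw class score (RD+RF)/2 and the
#'   reported per-class NR percentage for every (site, group, class).
#' @method tidy nr_table
#' @export
tidy.nr_table <- function(x, ...) {
  attr(x, "components")
}
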