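# Stand structure, size classes and the NR/TNR index.

test_that("stem basal area follows the circular cross-section formula", {
  expect_identical(stem_basal_area(0), 0)
  expect_equal(stem_basal_area(20), 0.031416, tolerance = 1e-4)
  expect_equal(stem_basal_area(200 / sqrt(pi)), 1.0, tolerance = 1e-12)
  expect_error(stem_basal_area(-1), class = "galeria_domain_error")
  # strictly increasing in dbh
  d <- seq(0.5, 120, by = 0.5)
  expect_true(all(diff(stem_basal_area(d)) > 0))
})

test_that("density scaling uses the stage's sampled area", {
  expect_equal(density_per_ha(1, 400), 25)
  expect_equal(density_per_ha(5, 20), 2500)
  expect_equal(density_per_ha(0, 123), 0)
  expect_error(density_per_ha(1, 0), class = "galeria_domain_error")
})

test_that("plot means and sample SD match the two-plot fixture", {
  stems <- tibble(site_id = "grazed", plot_id = "p1", stage = "adult",
                  group = "broadleaf", dbh_cm = c(20, 30),
                  height_m = NA_real_, alive = TRUE, grazing_damage = FALSE)
  ds <- survey_data(stems = stems,
                    designs = list(site_design("grazed", "grazed",
                                               n_plots = 2)))
  summ <- site_stage_summary(ds)
  row <- filter(summ, stage == "adult", group_class == "broadleaf")
  # plot p1: 2 stems on 400 m2 = 50/ha; the empty plot contributes 0
  expect_equal(row$mean_density_per_ha, 25)
  expect_equal(row$sd_density, sd(c(50, 0)), tolerance = 1e-12)
  # basal area: (pi*0.1^2 + pi*0.15^2) per 400 m2, averaged with 0
  ba_p1 <- (stem_basal_area(20) + stem_basal_area(30)) * 10000 / 400
  expect_equal(row$mean_ba_m2_ha, ba_p1 / 2, tolerance = 1e-12)
})

test_that("a single-plot site has zero SDs", {
  stems <- tibble(site_id = "grazed", plot_id = "p1", stage = "adult",
                  group = "motacu", dbh_cm = 35, height_m = 12,
                  alive = TRUE, grazing_damage = FALSE)
  ds <- survey_data(stems = stems,
                    designs = list(site_design("grazed", "grazed",
                                               n_plots = 1)))
  summ <- site_stage_summary(ds)
  expect_true(all(summ$sd_density == 0))
  expect_true(all(summ$sd_ba == 0))
})

test_that("snags are reported as their own classes, excluded from live composition", {
  stems <- tibble(site_id = "grazed", plot_id = "p1", stage = "adult",
                  group = "broadleaf", dbh_cm = c(20, 25),
                  height_m = NA_real_, alive = c(TRUE, FALSE),
                  grazing_damage = FALSE)
  ds <- survey_data(stems = stems,
                    designs = list(site_design("grazed", "grazed",
                                               n_plots = 1)))
  summ <- site_stage_summary(ds)
  expect_equal(
    filter(summ, group_class == "broadleaf_snag",
           stage == "adult")$mean_density_per_ha, 25)
  comp <- life_stage_composition(ds)
  # only the live stem counts toward the broadleaf life-stage total
  expect_equal(filter(comp, group == "broadleaf")$total_density_per_ha, 25)
})

test_that("height and dbh binning is left-closed and classifies edges", {
  stems <- tibble(site_id = "grazed", plot_id = "p1", stage = "sapling",
                  group = "broadleaf", dbh_cm = NA_real_,
                  height_m = c(1.2, 1.9, 2.5, 2.0), alive = TRUE,
                  grazing_damage = FALSE)
  ds <- survey_data(stems = stems,
                    designs = list(site_design("grazed", "grazed",
                                               n_plots = 1)))
  dist <- class_distribution(ds, "sapling_height_1m")
  bands <- filter(dist, mean_count_per_ha > 0)
  got <- setNames(bands$mean_count_per_ha / density_per_ha(1, 200),
                  bands$band)
  # 2.0 m joins [2,3): half-open left-closed bands
  expect_equal(got[["[1,2)"]], 2)
  expect_equal(got[["[2,3)"]], 2)
})

test_that("acaulescent motacu saplings form the smallest dbh band", {
  stems <- tibble(
    site_id = "grazed", plot_id = "p1",
    stage = c("sapling", "sapling", "sapling", "adult"),
    group = "motacu",
    dbh_cm = c(NA, NA, NA, 36),
    height_m = c(1.1, 1.5, 2.2, 14),
    alive = TRUE, grazing_damage = FALSE)
  ds <- survey_data(stems = stems,
                    designs = list(site_design("grazed", "grazed",
                                               n_plots = 1)))
  dist <- class_distribution(ds, "stem_dbh_10cm")
  acl <- filter(dist, band == "acaulescent")
  expect_equal(acl$mean_count_per_ha, density_per_ha(3, 200))
  expect_true(acl$acaulescent)
  adult_band <- filter(dist, band == "[30,40)")
  expect_equal(adult_band$mean_count_per_ha, density_per_ha(1, 400))
})

test_that("band totals conserve the stem count, including unmeasured stems", {
  ds <- simulate_survey(seed = 5)
  # adult height scheme: broadleaf/other-palm adults carry no heights and
  # must appear in the unmeasured bucket rather than vanish
  dist <- class_distribution(ds, "adult_height_3m")
  per_site_total <- dist |>
    summarise(dens = sum(mean_count_per_ha), .by = site_id)
  adults <- ds$stems |>
    filter(stage == "adult") |>
    summarise(n = dplyr::n(), .by = site_id) |>
    mutate(dens = density_per_ha(n, 400) / 4)  # 4 plots
  expect_equal(per_site_total$dens,
               adults$dens[match(per_site_total$site_id, adults$site_id)],
               tolerance = 1e-9)
  expect_true("unmeasured" %in% dist$band)
})

test_that("life-stage composition reduces a summary table to totals and shares", {
  comp <- stage_summary_composition(tibble(
    site_id = "grazed", group = "motacu",
    stage = c("seedling", "sapling", "adult"),
    mean_density_per_ha = c(10875, 1300, 225)))
  expect_equal(comp$total_density_per_ha, 12400)
  expect_equal(c(comp$seedling_pct, comp$sapling_pct, comp$adult_pct),
               c(88, 10, 2))
  single <- stage_summary_composition(tibble(
    site_id = "s", group = "motacu", stage = "adult",
    mean_density_per_ha = 100))
  expect_equal(single$adult_pct, 100)
  zero <- stage_summary_composition(tibble(
    site_id = "s", group = "motacu", stage = "adult",
    mean_density_per_ha = 0))
  expect_true(is.na(zero$adult_pct))
})

test_that("the NR toy dataset matches the hand-enumerated oracle", {
  ds <- nr_toy_dataset()
  # class >3m is empty everywhere: warned, contributes zero
  expect_warning(nr <- nr_table(ds), ">3m")
  comp <- tidy(nr)
  # Hand enumeration: class 1-2m has plot densities motacu {100, 0},
  # broadleaf {50, 0} => means 50 vs 25 => RD 66.67/33.33; one occupied plot
  # each => RF 50/50. Class 2-3m is broadleaf-only: RD = RF = 100.
  a_mot <- filter(comp, group == "motacu", class == "1-2m")
  expect_equal(a_mot$rd_pct, 200 / 3, tolerance = 1e-9)
  expect_equal(a_mot$rf_pct, 50)
  expect_equal(a_mot$nr_pct, (200 / 3 + 50) / 2 / 3, tolerance = 1e-9)
  wide <- as_tibble(nr)
  expect_equal(filter(wide, group == "motacu")$tnr_pct, 175 / 9,
               tolerance = 1e-9)
  # broadleaf: 125/9 (class 1-2m) + 100/3 (class 2-3m) = 425/9
  expect_equal(filter(wide, group == "broadleaf")$tnr_pct, 425 / 9,
               tolerance = 1e-9)
})

test_that("NR filters follow the sapling eligibility rules", {
  stems <- tibble(
    site_id = "grazed", plot_id = "p1", stage = "sapling",
    group = c("motacu", "broadleaf", "broadleaf", "broadleaf"),
    dbh_cm = c(NA, 6, 2, 3),
    height_m = c(1.5, 1.5, 0.8, 1.5),
    alive = c(TRUE, TRUE, TRUE, FALSE),
    grazing_damage = FALSE)
  ds <- survey_data(stems = stems,
                    designs = list(site_design("grazed", "grazed",
                                               n_plots = 1)))
  # dbh >= 5 broadleaf excluded, height <= 1 excluded, dead excluded:
  # only the motacu sapling remains => NR = 100/3 per occupied class
  nr <- suppressWarnings(as_tibble(nr_table(ds)))
  expect_identical(nr$group, "motacu")
  expect_equal(nr$nr_pct_12m, 100 / 3, tolerance = 1e-9)
  expect_equal(nr$tnr_pct, 100 / 3, tolerance = 1e-9)
})

test_that("NR normalization invariants hold on simulated datasets", {
  for (seed in c(2, 7)) {
    ds <- simulate_survey(seed = seed)
    comp <- tidy(nr_table(ds))
    sums <- comp |>
      summarise(class_sum = sum(nr_pct), .by = c(site_id, class))
    expect_equal(sums$class_sum, rep(100 / 3, nrow(sums)), tolerance = 1e-8)
    tnr <- comp |> summarise(tnr = sum(nr_pct), .by = site_id)
    expect_equal(tnr$tnr, rep(100, nrow(tnr)), tolerance = 1e-8)
  }
})

test_that("two groups with identical densities and frequencies split TNR evenly", {
  stems <- tidyr::expand_grid(
    plot_id = c("p1", "p2"),
    group = c("motacu", "broadleaf"),
    height_m = c(1.5, 2.5, 3.5)) |>
    mutate(site_id = "grazed", stage = "sapling", dbh_cm = NA_real_,
           alive = TRUE, grazing_damage = FALSE)
  ds <- survey_data(stems = stems,
                    designs = list(site_design("grazed", "grazed",
                                               n_plots = 2)))
  nr <- as_tibble(nr_table(ds))
  expect_equal(nr$tnr_pct, c(50, 50), tolerance = 1e-9)
})
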