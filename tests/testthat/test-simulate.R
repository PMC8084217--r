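# Synthetic-survey generator: determinism, validity, parameter recovery.

test_that("default profiles carry the reference site means", {
  ps <- default_profiles()
  sap <- function(p, g) {
    s <- p$saplings
    s$density_per_ha[s$group == g] * (1 - s$snag_fraction[s$group == g])
  }
  expect_equal(sap(ps$grazed, "motacu"), 1300)
  expect_equal(sap(ps$restored, "motacu"), 3200)
  adult <- function(p, g) {
    a <- p$adults
    a$density_per_ha[a$group == g] * (1 - a$snag_fraction[a$group == g])
  }
  expect_equal(adult(ps$restored, "other_palm"), 6)
  expect_equal(adult(ps$grazed, "broadleaf"), 388)
  # wildlife rates mirror the reference encounter rates
  wl <- ps$grazed$wildlife
  expect_equal(wl$rate_per_km[wl$taxon_id == "sa_coati"], 4.00)
  wl_r <- ps$restored$wildlife
  expect_equal(wl_r$rate_per_km[wl_r$taxon_id == "brown_agouti"], 2.85)
  # efforts reproduce the published walked distances
  expect_equal(sum(ps$grazed$efforts$distance_km), 4.25)
  expect_equal(sum(ps$restored$efforts$distance_km), 3.86)
})

test_that("identical seeds reproduce the dataset record for record", {
  a <- simulate_survey(seed = 4)
  b <- simulate_survey(seed = 4)
  for (nm in c("stems", "quadrats", "seedlings", "intercepts",
               "efforts", "observations")) {
    expect_identical(as.data.frame(a[[nm]]), as.data.frame(b[[nm]]),
                     label = nm)
  }
  c <- simulate_survey(seed = 5)
  expect_false(identical(as.data.frame(a$stems), as.data.frame(c$stems)))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(123)
  r1 <- runif(1)
  set.seed(123)
  invisible(simulate_survey(seed = 4))
  expect_identical(runif(1), r1)
})

test_that("all-zero rates yield an empty but structurally valid dataset", {
  ps <- default_profiles()
  p <- ps$grazed
  p$adults$density_per_ha <- 0
  p$saplings$density_per_ha <- 0
  p$seedlings$mean_per_quadrat <- 0
  p$shrub_cover$cover_pct <- 0
  p$wildlife$rate_per_km <- 0
  ds <- simulate_site(p, site_design("grazed", "grazed"), seed = 1)
  expect_identical(nrow(ds$stems), 0L)
  expect_identical(nrow(ds$observations), 0L)
  expect_identical(nrow(ds$intercepts), 0L)
  # quadrat cover is still drawn: 4 plots x 5 quadrats x 8 categories
  expect_identical(nrow(ds$quadrats), 160L)
  expect_true(all(ds$quadrats$cover_pct >= 0 & ds$quadrats$cover_pct <= 100))
})

test_that("generated data always pass validation", {
  for (seed in c(1, 17, 33)) {
    ds <- simulate_survey(seed = seed)
    expect_s3_class(ds, "survey_data")  # survey_data() validates on build
    expect_true(all(ds$stems$dbh_cm[ds$stems$stage == "adult"] > 10))
    sap <- filter(ds$stems, stage == "sapling")
    expect_true(all(sap$height_m > 0.3))
    expect_true(all(is.na(sap$dbh_cm[sap$group == "motacu"])))
  }
})

test_that("estimators recover the generating densities at 400 plots", {
  designs <- list(
    grazed = site_design("grazed", "grazed", n_plots = 400),
    restored = site_design("restored", "restored", n_plots = 400))
  ds <- simulate_survey(designs = designs, seed = 7)
  summ <- site_stage_summary(ds)
  # Poisson counting SE for a density target D sampled on area A over n plots
  se <- function(D, A, n = 400) sqrt(D * 10000 / (A * n))
  checks <- tibble::tribble(
    ~site, ~stage, ~group, ~target, ~area,
    "grazed", "sapling", "motacu", 1300, 200,
    "restored", "sapling", "motacu", 3200, 200,
    "grazed", "adult", "motacu", 225, 400,
    "restored", "adult", "motacu", 412, 400,
    "restored", "adult", "other_palm", 6, 400,
    "grazed", "adult", "broadleaf", 388, 400)
  for (i in seq_len(nrow(checks))) {
    ck <- checks[i, ]
    got <- filter(summ, site_id == ck$site, stage == ck$stage,
                  group_class == ck$group)$mean_density_per_ha
    expect_lt(abs(got - ck$target), 3 * se(ck$target, ck$area) + 1e-9,
              label = sprintf("%s %s %s density", ck$site, ck$stage,
                              ck$group))
  }
  # basal area emerges from density x dbh distribution: wide tolerance
  ba <- filter(summ, site_id == "restored", stage == "adult",
               group_class == "motacu")$mean_ba_m2_ha
  expect_lt(abs(ba - 46.8), 0.25 * 46.8)
})

test_that("encounter rates recover the generating rates at 100 km effort", {
  ps <- wildlife_only_profiles()
  # scale the walks up to >= 100 km per site, duration in proportion
  for (nm in names(ps)) {
    ps[[nm]]$efforts$distance_km <- ps[[nm]]$efforts$distance_km * 30
    ps[[nm]]$efforts$duration_min <- ps[[nm]]$efforts$duration_min * 30
  }
  ds <- simulate_survey(profiles = ps, seed = 3)
  et <- encounter_table(ds)
  for (taxon in c("sa_coati", "black_howler", "tropical_screech_owl")) {
    for (site in c("grazed", "restored")) {
      target <- ps[[site]]$wildlife$rate_per_km[
        ps[[site]]$wildlife$taxon_id == taxon]
      row <- filter(et, taxon_id == taxon, site_id == site)
      if (target == 0) {
        expect_equal(nrow(row) == 0 || row$er_per_km == 0, TRUE)
        next
      }
      # individuals ~ overdispersed Poisson per km; SE approx sqrt(r(1+2l)/L)
      lam <- ps[[site]]$group_size_lambda
      se <- sqrt(target * (1 + 2 * lam) / row$distance_km)
      expect_lt(abs(row$er_per_km - target), 3 * se + 1e-9,
                label = sprintf("%s at %s", taxon, site))
    }
  }
})

test_that("restored exceeds grazed in motacu sapling density and TNR in most replicates", {
  # a quick directional check; the full 100-replicate version runs with the
  # acceptance properties
  wins_density <- 0
  wins_tnr <- 0
  n_rep <- 30
  for (seed in seq_len(n_rep)) {
    ds <- simulate_survey(seed = seed)
    sap <- ds$stems |>
      filter(stage == "sapling", group == "motacu", alive) |>
      summarise(n = dplyr::n(), .by = site_id)
    n_g <- sum(sap$n[sap$site_id == "grazed"])
    n_r <- sum(sap$n[sap$site_id == "restored"])
    wins_density <- wins_density + (n_r > n_g)
    nr <- suppressWarnings(as_tibble(nr_table(ds)))
    t_g <- nr$tnr_pct[nr$site_id == "grazed" & nr$group == "motacu"]
    t_r <- nr$tnr_pct[nr$site_id == "restored" & nr$group == "motacu"]
    wins_tnr <- wins_tnr + (length(t_g) == 1 && length(t_r) == 1 && t_r > t_g)
  }
  expect_gte(wins_density, 27)
  expect_gte(wins_tnr, 27)
})
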