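# Encounter rates, richness, segmentation and the exact accumulation curve.

test_that("encounter rates reproduce the reference-table arithmetic", {
  rw <- ref_wildlife()
  et <- encounter_table(rw$observations, rw$efforts,
                        treatments = tibble(site_id = c("grazed", "restored"),
                                            treatment = c("grazed",
                                                          "restored")))
  rate <- function(taxon, site) {
    filter(et, taxon_id == taxon, site_id == site)$er_per_km
  }
  expect_equal(round(rate("sa_coati", "grazed"), 2), 4.00)
  expect_equal(round(rate("brown_agouti", "restored"), 2), 2.85)
  expect_equal(round(rate("capybara", "grazed"), 2), 1.88)
  # diff on full precision, then rounded: howler 18/3.86 - 15/4.25
  howler <- filter(et, taxon_id == "black_howler", site_id == "grazed")
  expect_equal(round(howler$diff_er_per_km, 2), 1.13)
  # zero events at a site: rate 0, diff = minus the other site's rate
  fox <- filter(et, taxon_id == "crab_eating_fox")
  expect_equal(fox$er_per_km[fox$site_id == "restored"], 0)
  expect_equal(fox$diff_er_per_km[1], -fox$er_per_km[fox$site_id == "grazed"])
})

test_that("mammals use total distance, birds night-only distance", {
  eff <- tibble(transect_id = c("t1", "t1"), site_id = "s",
                survey = c("dusk", "night"), distance_km = c(1, 3),
                duration_min = c(60, 120))
  obs <- tibble(transect_id = "t1", site_id = "s", survey = "night",
                elapsed_min = 5, taxon_id = c("mam", "owl"),
                taxon_class = c("mammal", "nocturnal_bird"),
                n_individuals = c(4, 4), detection = "visual")
  et <- encounter_table(obs, eff)
  expect_equal(filter(et, taxon_id == "mam")$distance_km, 4)
  expect_equal(filter(et, taxon_id == "mam")$er_per_km, 1)
  expect_equal(filter(et, taxon_id == "owl")$distance_km, 3)
  expect_equal(filter(et, taxon_id == "owl")$er_per_km, 4 / 3)
  # events basis counts encounter records instead of individuals
  et2 <- encounter_table(obs, eff, rate_basis = "events")
  expect_equal(filter(et2, taxon_id == "mam")$er_per_km, 1 / 4)
  # individual totals are conserved per site
  expect_equal(sum(et$n_individuals), sum(obs$n_individuals))
})

test_that("an observation on an unknown transect errors", {
  eff <- tibble(transect_id = "t1", site_id = "s", survey = "night",
                distance_km = 1, duration_min = 60)
  obs <- tibble(transect_id = "t9", site_id = "s", survey = "night",
                elapsed_min = 5, taxon_id = "mam", taxon_class = "mammal",
                n_individuals = 1, detection = "visual")
  expect_error(encounter_table(obs, eff),
               class = "galeria_validation_error")
})

test_that("richness and unique species match the reference species lists", {
  rw <- ref_wildlife()
  rich <- richness_and_uniques(rw$observations)
  sets <- attr(rich, "species_sets")
  expect_equal(sum(sets$taxon_class == "mammal"), 14)
  birds <- filter(rich, taxon_class == "nocturnal_bird")
  expect_equal(birds$n_species, c(6, 6))
  expect_equal(birds$n_unique, c(1, 1))
  bs <- filter(sets, taxon_class == "nocturnal_bird", n_sites == 1)
  expect_setequal(bs$unique_to, c("grazed", "restored"))
  # disjoint single-species sites
  toy <- tibble(transect_id = c("t1", "t2"), site_id = c("a", "b"),
                survey = "night", elapsed_min = 0,
                taxon_id = c("x", "y"), taxon_class = "mammal",
                n_individuals = 1, detection = "visual")
  r2 <- richness_and_uniques(toy)
  expect_equal(r2$n_species, c(1, 1))
  expect_equal(r2$n_unique, c(1, 1))
})

test_that("segments are laid out dusk-then-night with left-closed bins", {
  eff <- tibble(transect_id = c("t1", "t2"), site_id = "s",
                survey = c("dusk", "night"), distance_km = c(1, 2),
                duration_min = c(60, 120))
  obs <- tibble(transect_id = c("t1", "t1", "t2"), site_id = "s",
                survey = c("dusk", "dusk", "night"),
                elapsed_min = c(0, 15, 0),
                taxon_id = c("a", "a", "b"), taxon_class = "mammal",
                n_individuals = 1, detection = "visual")
  inc <- segmentize(obs, eff)
  segs <- attr(inc, "segments")
  expect_equal(nrow(segs), 4 + 8)  # 60 and 120 minutes in 15-min bins
  expect_equal(segs$survey[1:4], rep("dusk", 4))
  # elapsed 0 -> segment 1; elapsed 15 -> segment 2 (left-closed)
  a_rows <- filter(inc, taxon_id == "a")
  expect_equal(a_rows$segment, c(1, 2))
  # the night transect's first segment is global segment 5
  expect_equal(filter(inc, taxon_id == "b")$segment, 5)
  # a partial final bin is kept, and max_segments truncates
  eff2 <- tibble(transect_id = "t1", site_id = "s", survey = "night",
                 distance_km = 1, duration_min = 100)
  inc2 <- segmentize(tibble(transect_id = "t1", site_id = "s",
                            survey = "night", elapsed_min = 99,
                            taxon_id = "a", taxon_class = "mammal",
                            n_individuals = 1, detection = "visual"),
                     eff2)
  expect_equal(nrow(attr(inc2, "segments")), 7)  # ceiling(100/15)
  expect_equal(inc2$segment, 7)
  inc3 <- segmentize(obs, eff, max_segments = 6)
  expect_equal(max(attr(inc3, "segments")$segment), 6)
})

test_that("the exact curve hits the trivial endpoints", {
  # one taxon in every segment: E[S(k)] = 1 for all k, sd 0
  M <- matrix(TRUE, nrow = 1, ncol = 6)
  ac <- exact_accumulation(M)
  expect_equal(ac$expected_richness, rep(1, 6))
  expect_equal(ac$sd, rep(0, 6))
  # k = T reaches observed richness with sd 0
  M2 <- rbind(c(1, 0, 0, 0), c(1, 1, 0, 0), c(1, 1, 1, 1))
  ac2 <- exact_accumulation(M2)
  expect_equal(ac2$expected_richness[4], 3)
  expect_equal(ac2$sd[4], 0)
  # monotone non-decreasing in k
  expect_true(all(diff(ac2$expected_richness) >= -1e-12))
})

test_that("the exact curve equals complete enumeration on the T=4 toy", {
  M <- rbind(c(1, 0, 0, 0), c(1, 1, 0, 0), c(1, 1, 1, 1))
  ac <- exact_accumulation(M)
  orc <- enumerate_accumulation(M)
  expect_equal(ac$expected_richness, orc$expected_richness, tolerance = 1e-10)
  expect_equal(ac$sd, orc$sd, tolerance = 1e-10)
})

test_that("the exact curve equals enumeration for random matrices up to T = 10", {
  set.seed(99)
  for (rep in 1:25) {
    T_seg <- sample(1:10, 1)
    S <- sample(1:6, 1)
    M <- matrix(rbinom(S * T_seg, 1, runif(1, 0.2, 0.8)), nrow = S)
    ac <- exact_accumulation(M)
    orc <- enumerate_accumulation(M)
    expect_equal(ac$expected_richness, orc$expected_richness,
                 tolerance = 1e-10)
    expect_equal(ac$sd, orc$sd, tolerance = 1e-10)
    expect_true(all(diff(ac$expected_richness) >= -1e-12))
  }
})

test_that("the analytic sd agrees with vegan's exact method", {
  skip_if_not_installed("vegan")
  set.seed(7)
  M <- matrix(rbinom(5 * 8, 1, 0.4), nrow = 5)
  M[1, ] <- c(1, rep(0, 7))  # include a singleton taxon
  ac <- exact_accumulation(M)
  sp <- vegan::specaccum(t(M), method = "exact")
  expect_equal(ac$expected_richness, unname(sp$richness), tolerance = 1e-10)
  # vegan's sd uses a moment approximation that can differ from the exact
  # subset variance in the second decimal; the enumeration oracle above is
  # the authority for the sd, vegan is a sanity bound here
  expect_equal(ac$sd, unname(sp$sd), tolerance = 0.05)
})

test_that("richer restored rates produce a dominating accumulation curve", {
  # the property is conditional on uniformly higher restored rates: every
  # taxon is at least as encounterable on the restored site (element-wise
  # max of the two default rate tables, which also keeps the restored-only
  # species) on identical walks
  ps <- wildlife_only_profiles()
  ps$restored$wildlife$rate_per_km <- pmax(ps$grazed$wildlife$rate_per_km,
                                           ps$restored$wildlife$rate_per_km)
  ps$restored$efforts <- ps$grazed$efforts |>
    mutate(transect_id = sub("^g", "r", transect_id))
  dominates <- 0
  for (seed in 1:50) {
    ds <- simulate_survey(profiles = ps, seed = seed)
    inc <- segmentize(ds)
    ac <- exact_accumulation(inc, taxon_class = "mammal")
    wide <- tidyr::pivot_wider(ac, names_from = site_id,
                               values_from = c(expected_richness, sd))
    if (all(wide$expected_richness_restored >=
              wide$expected_richness_grazed - 1e-9)) {
      dominates <- dominates + 1
    }
  }
  expect_gte(dominates, 45)
})
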