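# Seeded synthetic survey generation.
#
# One RNG substream per site, derived deterministically from (seed, site_id),
# so the same seed always reproduces the same dataset record for record and
# sites can be generated independently.

# list_rbind() of an all-empty list yields a zero-column tibble; treat that
# as "no records" so survey_data() substitutes the canonical empty schema.
table_or_null <- function(x) {
  if (is.null(x) || ncol(x) == 0) NULL else x
}

site_substream_seed <- function(seed, site_id) {
  h <- sum(utf8ToInt(site_id) * seq_along(utf8ToInt(site_id)))
  (as.integer(seed) %% 1000003L) * 2011L + (h %% 104729L) * 7L
}

rtrunc_norm <- function(n, mean, sd, lower) {
  if (n == 0) return(numeric())
  if (is.na(sd) || sd <= 0) return(rep(pmax(mean, lower), n))
  p0 <- pnorm(lower, mean, sd)
  qnorm(p0 + runif(n) * (1 - p0), mean, sd)
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- rep(1, length(alpha))
  g / sum(g)
}

# Negative binomial by mean and size; vectorised over mean, mean 0 gives 0.
rnbinom_mean <- function(n, mean, size) {
  if (n == 0) return(integer())
  stats::rnbinom(n, size = size, mu = pmax(mean, 0))
}

simulate_plot_stems <- function(profile, design, site, plot) {
  rows <- list()
  a_area <- design$adult_subplot_area_m2
  s_area <- design$sapling_subplot_area_m2
  for (i in seq_len(nrow(profile$adults))) {
    p <- profile$adults[i, ]
    n <- rpois(1, p$density_per_ha * a_area / 10000)
    if (n == 0) next
    alive <- runif(n) >= p$snag_fraction
    dbh <- rtrunc_norm(n, p$dbh_mean_cm, p$dbh_sd_cm, 10)
    dbh <- pmax(dbh, 10 + 1e-6)
    height <- if (!is.na(p$height_mean_m)) {
      pmax(rtrunc_norm(n, p$height_mean_m, p$height_sd_m, 1.3), 1.3 + 1e-6)
    } else {
      rep(NA_real_, n)
    }
    rows[[length(rows) + 1]] <- tibble(
      site_id = site, plot_id = plot, stage = "adult", group = p$group,
      dbh_cm = dbh, height_m = height, alive = alive,
      grazing_damage = FALSE)
  }
  for (i in seq_len(nrow(profile$saplings))) {
    p <- profile$saplings[i, ]
    n <- rpois(1, p$density_per_ha * s_area / 10000)
    if (n == 0) next
    alive <- runif(n) >= p$snag_fraction
    height <- 0.3 + rexp(n, rate = 1 / profile$sapling_height_decay_m)
    dbh <- if (p$group == "broadleaf") {
      # simple allometry: slender stems, never reaching the adult threshold
      pmin(pmax(1.2 * height + rnorm(n, 0, 0.5), 0.1), 9.9)
    } else {
      rep(NA_real_, n)  # palms are acaulescent as juveniles
    }
    damage <- alive & runif(n) < profile$damage_fraction
    rows[[length(rows) + 1]] <- tibble(
      site_id = site, plot_id = plot, stage = "sapling", group = p$group,
      dbh_cm = dbh, height_m = height, alive = alive,
      grazing_damage = damage)
  }
  list_rbind(rows)
}

simulate_plot_quadrats <- function(profile, design, site, plot) {
  q <- design$quadrats_per_plot
  cover <- map(seq_len(q), \(i) {
    shares <- rdirichlet1(profile$ground_concentration)
    tibble(site_id = site, plot_id = plot, quadrat_index = i,
           category = .ground_categories, cover_pct = 100 * shares)
  }) |> list_rbind()
  seeds <- map(seq_len(q), \(i) {
    tibble(site_id = site, plot_id = plot, quadrat_index = i,
           group = profile$seedlings$group,
           count = as.numeric(rnbinom_mean(nrow(profile$seedlings),
                                           profile$seedlings$mean_per_quadrat,
                                           profile$seedling_dispersion)))
  }) |> list_rbind()
  list(quadrats = cover, seedlings = seeds)
}

simulate_plot_intercepts <- function(profile, design, site, plot,
                                     mean_interval_m = 5) {
  len <- design$transect_length_m
  rows <- list()
  for (i in seq_len(nrow(profile$shrub_cover))) {
    p <- profile$shrub_cover[i, ]
    target_len <- p$cover_pct / 100 * len
    if (target_len <= 0) next
    n <- rpois(1, target_len / mean_interval_m)
    if (n == 0) next
    lens <- pmin(rexp(n, rate = 1 / mean_interval_m), len - 1e-6)
    starts <- runif(n, 0, len - lens)
    rows[[length(rows) + 1]] <- tibble(
      site_id = site, plot_id = plot, group = p$group,
      start_m = starts, end_m = starts + lens)
  }
  list_rbind(rows)
}

simulate_wildlife <- function(profile, site) {
  efforts <- mutate(profile$efforts, site_id = site,
                    .after = "transect_id")
  rows <- list()
  for (w in seq_len(nrow(efforts))) {
    e <- efforts[w, ]
    for (i in seq_len(nrow(profile$wildlife))) {
      tx <- profile$wildlife[i, ]
      if (tx$taxon_class == "nocturnal_bird" && e$survey != "night") next
      if (tx$rate_per_km <= 0) next
      # rate is individuals/km; events carry 1 + Pois(lambda) individuals
      ev_rate <- tx$rate_per_km / (1 + profile$group_size_lambda)
      # birds are rated against night-only km, which is what e covers
      n_ev <- rpois(1, ev_rate * e$distance_km)
      if (n_ev == 0) next
      rows[[length(rows) + 1]] <- tibble(
        transect_id = e$transect_id, site_id = site, survey = e$survey,
        elapsed_min = sort(runif(n_ev, 0, e$duration_min)),
        taxon_id = tx$taxon_id, taxon_class = tx$taxon_class,
        n_individuals = 1 + rpois(n_ev, profile$group_size_lambda),
        detection = ifelse(tx$taxon_class == "nocturnal_bird" &
                             runif(n_ev) < 0.6, "aural", "visual"))
    }
  }
  list(efforts = efforts, observations = list_rbind(rows))
}

#' Simulate one site's survey dataset
#'
#' Draws a complete synthetic field survey for one site under a
#' [site_profile()] and [site_design()]: per plot, adult stem counts are
#' Poisson in the subplot area with truncated-normal dbh (> 10 cm) and, where
#' the profile provides height moments, truncated-normal heights; sapling
#' counts are Poisson in the half-subplot with heights 0.3 m plus an
#' exponential increment; seedling counts per quadrat are negative binomial;
#' ground cover per quadrat is Dirichlet scaled to percent; shrub intercepts
#' are placed uniformly with exponential lengths so the expected intercepted
#' length matches the profile's cover target (overlap allowed); snag and
#' damage flags are Bernoulli. Wildlife encounter events are Poisson per
#' transect walk with uniform event times and unit-shifted-Poisson group
#' sizes. All draws come from one seeded substream derived from
#' `(seed, site_id)`, so a given seed reproduces the dataset exactly.
#'
#' @param profile A `site_profile`.
#' @param design A `site_design`; its `site_id`/`treatment` label the output.
#' @param seed Integer seed.
#' @return A validated `survey_data` holding the one simulated site.
#' @export
simulate_site <- function(profile, design, seed) {
  stopifnot(inherits(profile, "site_profile"), inherits(design, "site_design"))
  site <- design$site_id
  sub_seed <- site_substream_seed(seed, site)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(sub_seed)
  plots <- paste0(site, "_p", seq_len(design$n_plots))
  stems <- list(); quadrats <- list(); seedlings <- list(); intercepts <- list()
  for (plot in plots) {
    stems[[plot]] <- simulate_plot_stems(profile, design, site, plot)
    qq <- simulate_plot_quadrats(profile, design, site, plot)
    quadrats[[plot]] <- qq$quadrats
    seedlings[[plot]] <- qq$seedlings
    intercepts[[plot]] <- simulate_plot_intercepts(profile, design, site, plot)
  }
  wl <- simulate_wildlife(profile, site)
  survey_data(stems = table_or_null(list_rbind(stems)),
              quadrats = table_or_null(list_rbind(quadrats)),
              seedlings = table_or_null(list_rbind(seedlings)),
              intercepts = table_or_null(list_rbind(intercepts)),
              efforts = wl$efforts,
              observations = table_or_null(wl$observations),
              designs = list(design))
}

#' Simulate the full paired-site survey
#'
#' Runs [simulate_site()] for each profile/design pair and binds the results
#' into one `survey_data`. Per-site RNG substreams make the combined dataset
#' reproducible under a single seed.
#'
#' @param profiles Named list of `site_profile`s (default
#'   [default_profiles()]).
#' @param designs Named list of `site_design`s matching `profiles` by name.
#' @param seed Integer seed.
#' @return A validated two-site `survey_data`.
#' @export
simulate_survey <- function(profiles = default_profiles(),
                            designs = default_designs(), seed = 1) {
  if (!setequal(names(profiles), names(designs))) {
    abort("simulate_survey: profiles and designs must share names",
          class = "galeria_parameter_error")
  }
  parts <- map(names(profiles),
               \(nm) simulate_site(profiles[[nm]], designs[[nm]], seed))
  survey_data(
    stems = table_or_null(list_rbind(map(parts, "stems"))),
    quadrats = table_or_null(list_rbind(map(parts, "quadrats"))),
    seedlings = table_or_null(list_rbind(map(parts, "seedlings"))),
    intercepts = table_or_null(list_rbind(map(parts, "intercepts"))),
    efforts = list_rbind(map(parts, "efforts")),
    observations = table_or_null(list_rbind(map(parts, "observations"))),
    designs = unname(map(names(profiles), \(nm) designs[[nm]]))
  )
}
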