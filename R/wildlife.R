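# Line-transect wildlife metrics: encounter rates, richness, and exact
# (analytic) species-accumulation curves over 15-minute survey segments.

#' Encounter rates per kilometre walked
#'
#' For each (taxon, site): the number of encounter events, the number of
#' individuals, and the encounter rate per km of transect walked. Mammal
#' rates use the site's summed dusk + night distance; nocturnal-bird rates
#' use the night-only distance (birds were surveyed only after dark). The
#' rate numerator defaults to individuals, which is the convention of the
#' field tables this reproduces; set `rate_basis = "events"` to rate
#' encounter events instead. When a treatment lookup is available the
#' restored-minus-grazed rate difference is added per taxon, computed at full
#' precision; `er_per_km` itself is reported at full precision (round for
#' display).
#'
#' @param observations A validated observation table, or a `survey_data`
#'   object (then `efforts`/`treatments` are taken from it).
#' @param efforts A validated effort table (required unless `observations`
#'   is a `survey_data`).
#' @param treatments Optional tibble `site_id`, `treatment` mapping sites to
#'   grazed/restored; enables the `diff_er_per_km` column.
#' @param rate_basis `"individuals"` (default) or `"events"`.
#' @return A tibble with one row per (taxon, site):
#'   `taxon_id`, `taxon_class`, `site_id`, `n_observations`,
#'   `n_individuals`, `distance_km`, `er_per_km`, and `diff_er_per_km`
#'   (restored - grazed, repeated on both site rows) when treatments are
#'   known.
#' @export
encounter_table <- function(observations, efforts = NULL, treatments = NULL,
                            rate_basis = c("individuals", "events")) {
  rate_basis <- match.arg(rate_basis)
  if (inherits(observations, "survey_data")) {
    treatments <- treatments %||% site_treatments(observations)
    efforts <- observations$efforts
    observations <- observations$observations
  }
  if (is.null(efforts)) {
    abort("encounter_table: `efforts` is required",
          class = "galeria_parameter_error")
  }
  efforts <- validate_efforts(efforts)
  observations <- validate_observations(observations, efforts)
  sites <- sort(unique(c(efforts$site_id, observations$site_id)))
  effort_ctx <- expand_grid(site_id = sites, taxon_class = .taxon_classes) |>
    mutate(distance_km = map2_dbl(.data$site_id, .data$taxon_class, \(s, cl) {
      e <- efforts[efforts$site_id == s, ]
      if (cl == "nocturnal_bird") e <- e[e$survey == "night", ]
      sum(e$distance_km)
    }))
  if (nrow(observations) == 0) {
    out <- tibble(taxon_id = character(), taxon_class = character(),
                  site_id = character(), n_observations = integer(),
                  n_individuals = numeric(), distance_km = numeric(),
                  er_per_km = numeric())
    return(out)
  }
  taxa <- distinct(observations, .data$taxon_id, .data$taxon_class)
  counts <- observations |>
    summarise(n_observations = n(),
              n_individuals = sum(.data$n_individuals),
              .by = c("taxon_id", "taxon_class", "site_id"))
  out <- expand_grid(distinct(taxa), site_id = sites) |>
    left_join(counts, by = c("taxon_id", "taxon_class", "site_id")) |>
    mutate(n_observations = coalesce(.data$n_observations, 0L),
           n_individuals = coalesce(.data$n_individuals, 0)) |>
    left_join(effort_ctx, by = c("site_id", "taxon_class")) |>
    mutate(er_per_km = ifelse(.data$distance_km > 0,
                              (if (rate_basis == "individuals") {
                                .data$n_individuals
                              } else {
                                .data$n_observations
                              }) / .data$distance_km, NA_real_))
  if (!is.null(treatments)) {
    out <- left_join(out, as_tibble(treatments), by = "site_id")
    if (all(c("grazed", "restored") %in% out$treatment)) {
      diffs <- out |>
        select("taxon_id", "treatment", "er_per_km") |>
        tidyr::pivot_wider(names_from = "treatment",
                           values_from = "er_per_km") |>
        mutate(diff_er_per_km = .data$restored - .data$grazed) |>
        select("taxon_id", "diff_er_per_km")
      out <- left_join(out, diffs, by = "taxon_id")
    }
  }
  arrange(out, .data$taxon_class, .data$taxon_id, .data$site_id)
}

#' Species richness, unique and shared species per site
#'
#' Counts distinct taxa per site within each taxon class, and identifies the
#' species found at exactly one site (unique) versus at more than one
#' (shared).
#'
#' @param observations A validated observation table or a `survey_data`.
#' @return A tibble with one row per (site, taxon class): `n_species`,
#'   `n_unique`; the underlying species sets are attached as
#'   `attr(x, "species_sets")` (a tibble `taxon_id`, `taxon_class`,
#'   `sites`, `n_sites`, `unique_to`).
#' @export
richness_and_uniques <- function(observations) {
  if (inherits(observations, "survey_data")) {
    observations <- observations$observations
  }
  observations <- validate_observations(observations)
  sets <- observations |>
    distinct(.data$taxon_id, .data$taxon_class, .data$site_id) |>
    summarise(sites = list(sort(unique(.data$site_id))),
              n_sites = dplyr::n_distinct(.data$site_id),
              .by = c("taxon_id", "taxon_class")) |>
    mutate(unique_to = ifelse(.data$n_sites == 1,
                              map_chr(.data$sites, 1), NA_character_))
  out <- observations |>
    distinct(.data$site_id, .data$taxon_class, .data$taxon_id) |>
    left_join(select(sets, "taxon_id", "taxon_class", "n_sites"),
              by = c("taxon_id", "taxon_class")) |>
    summarise(n_species = n(),
              n_unique = sum(.data$n_sites == 1),
              .by = c("site_id", "taxon_class")) |>
    arrange(.data$taxon_class, .data$site_id)
  structure(out, species_sets = sets)
}

#' Slice survey walks into fixed-length segments and build an incidence
#' matrix
#'
#' Within each site, walks are ordered dusk before night and by transect id,
#' and each walk's observation period is cut into `segment_min`-minute bins
#' (left-closed; a final partial bin is kept). Segments are then laid
#' end-to-end and truncated at `max_segments` per site. A taxon is present in
#' a segment if at least one of its observations falls in it.
#'
#' @param observations A validated observation table or a `survey_data`.
#' @param efforts Effort table (ignored when `observations` is a
#'   `survey_data`).
#' @param segment_min Segment length in minutes (default 15).
#' @param max_segments Per-site cap on segments (default 24, i.e. 6 hours).
#' @return An `incidence` tibble with one row per (site, segment, taxon)
#'   presence; segment metadata (transect, survey, within-walk start time)
#'   is attached as `attr(x, "segments")`.
#' @export
segmentize <- function(observations, efforts = NULL, segment_min = 15,
                       max_segments = 24) {
  if (inherits(observations, "survey_data")) {
    efforts <- observations$efforts
    observations <- observations$observations
  }
  if (segment_min <= 0) {
    abort("segmentize: segment_min must be > 0",
          class = "galeria_domain_error")
  }
  efforts <- validate_efforts(efforts)
  observations <- validate_observations(observations, efforts)
  walks <- efforts |>
    mutate(survey = factor(.data$survey, levels = .surveys)) |>
    arrange(.data$site_id, .data$survey, .data$transect_id) |>
    mutate(n_seg = ceiling(.data$duration_min / segment_min))
  segments <- walks |>
    mutate(seg_in_walk = map(.data$n_seg, seq_len)) |>
    tidyr::unnest("seg_in_walk") |>
    mutate(start_min = (.data$seg_in_walk - 1) * segment_min) |>
    mutate(segment = dplyr::row_number(), .by = "site_id") |>
    filter(.data$segment <= max_segments) |>
    select("site_id", "segment", "transect_id", "survey", "seg_in_walk",
           "start_min") |>
    mutate(survey = as.character(.data$survey))
  obs <- observations |>
    left_join(select(walks, "transect_id", "survey", "n_seg") |>
                mutate(survey = as.character(.data$survey)),
              by = c("transect_id", "survey")) |>
    mutate(seg_in_walk = pmin(floor(.data$elapsed_min / segment_min) + 1,
                              .data$n_seg)) |>
    inner_join(segments,
               by = c("site_id", "transect_id", "survey", "seg_in_walk")) |>
    distinct(.data$site_id, .data$segment, .data$taxon_id, .data$taxon_class)
  structure(arrange(obs, .data$site_id, .data$segment, .data$taxon_id),
            class = c("incidence", class(obs)),
            segments = segments, segment_min = segment_min)
}

#' Turn an incidence tibble into one site's presence matrix
#'
#' @param incidence An `incidence` tibble from [segmentize()].
#' @param site Site id to extract.
#' @param taxon_class Optional filter (`"mammal"` or `"nocturnal_bird"`).
#' @return A logical matrix, taxa in rows, segments in columns (all the
#'   site's segments, including empty ones).
#' @export
incidence_matrix <- function(incidence, site, taxon_class = NULL) {
  segs <- attr(incidence, "segments")
  if (is.null(segs)) {
    abort("incidence_matrix: input lacks segment metadata; use segmentize()",
          class = "galeria_parameter_error")
  }
  n_seg <- sum(segs$site_id == site)
  inc <- filter(incidence, .data$site_id == site)
  if (!is.null(taxon_class)) {
    cl <- taxon_class
    inc <- filter(inc, .data$taxon_class == cl)
  }
  taxa <- sort(unique(inc$taxon_id))
  M <- matrix(FALSE, nrow = length(taxa), ncol = n_seg,
              dimnames = list(taxa, NULL))
  if (nrow(inc) > 0) {
    M[cbind(match(inc$taxon_id, taxa), inc$segment)] <- TRUE
  }
  M
}

# Core analytic accumulation for one presence matrix (taxa x segments).
# p_i(k) = P(taxon i in a uniform size-k segment subset)
#        = 1 - C(T - t_i, k)/C(T, k), and the variance of richness uses the
# pairwise joint-absence probabilities q_ij = C(n00_ij, k)/C(T, k).
accumulate_exact_matrix <- function(M) {
  if (is.data.frame(M)) M <- as.matrix(M)
  M <- M > 0
  T_seg <- ncol(M)
  if (T_seg < 1) {
    abort("exact_accumulation: need at least one segment",
          class = "galeria_domain_error")
  }
  t_i <- rowSums(M)
  t_i <- t_i[t_i > 0]  # taxa never seen contribute nothing
  S_obs <- length(t_i)
  if (S_obs == 0) {
    return(tibble(k = seq_len(T_seg), expected_richness = 0, sd = 0))
  }
  Mp <- M[rowSums(M) > 0, , drop = FALSE]
  # joint absences: segments containing neither i nor j
  absent <- !Mp
  n00 <- absent %*% t(absent)
  lchoose_T <- lchoose(T_seg, seq_len(T_seg))
  out <- map(seq_len(T_seg), function(k) {
    # absence probability a_i = C(T - t_i, k)/C(T, k)
    a <- ifelse(T_seg - t_i >= k,
                exp(lchoose(T_seg - t_i, k) - lchoose_T[k]), 0)
    p <- 1 - a
    q <- matrix(ifelse(n00 >= k, exp(lchoose(n00, k) - lchoose_T[k]), 0),
                nrow = S_obs)
    cov_sum <- sum(q - outer(a, a)) - sum(diag(q) - a^2)
    v <- sum(p * (1 - p)) + cov_sum
    tibble(k = k, expected_richness = sum(p), sd = sqrt(max(v, 0)))
  })
  list_rbind(out)
}

#' Exact (analytic) species-accumulation curve
#'
#' For every subset size k of survey segments, the expected species richness
#' and its standard deviation over all equally likely size-k segment subsets,
#' computed combinatorially (no resampling): with \eqn{t_i} the number of
#' segments holding taxon i,
#' \eqn{E[S(k)] = \sum_i 1 - \binom{T-t_i}{k}/\binom{T}{k}}, and the variance
#' sums the per-taxon Bernoulli variances plus pairwise covariances obtained
#' from joint-absence counts. At k = T the curve reaches the observed
#' richness with SD 0.
#'
#' @param incidence An `incidence` tibble from [segmentize()] (curves are
#'   computed per site), or a single presence matrix (taxa x segments).
#' @param taxon_class Optional taxon-class filter when `incidence` is a
#'   tibble.
#' @return An `accumulation_curve` tibble: `site_id` (for tibble input),
#'   `k`, `expected_richness`, `sd`.
#' @export
exact_accumulation <- function(incidence, taxon_class = NULL) {
  if (is.matrix(incidence) || is.data.frame(incidence) &&
      !inherits(incidence, "incidence")) {
    out <- accumulate_exact_matrix(incidence)
    return(structure(out, class = c("accumulation_curve", class(out))))
  }
  segs <- attr(incidence, "segments")
  sites <- sort(unique(segs$site_id))
  out <- map(sites, \(s) {
    M <- incidence_matrix(incidence, s, taxon_class)
    mutate(accumulate_exact_matrix(M), site_id = s, .before = 1)
  }) |> list_rbind()
  structure(out, class = c("accumulation_curve", class(out)))
}
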