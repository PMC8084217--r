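# Validation of field-survey tables against the domain invariants.
#
# Every record either loads cleanly or produces an error that names the
# offending table and row; nothing is silently dropped. Controlled-vocabulary
# columns are matched case-insensitively and stored lower-case.

match_vocab <- function(x, allowed, table, column) {
  x <- tolower(trimws(as.character(x)))
  bad <- setdiff(unique(x[!is.na(x)]), allowed)
  if (length(bad) > 0) {
    abort(sprintf(
      "%s: unknown %s value(s) %s; allowed: %s",
      table, column, paste(sQuote(bad), collapse = ", "),
      paste(allowed, collapse = ", ")),
      class = "galeria_vocabulary_error")
  }
  x
}

require_columns <- function(df, cols, table) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s: missing required column(s): %s",
                  table, paste(missing, collapse = ", ")),
          class = "galeria_schema_error")
  }
  invisible(df)
}

fail_rows <- function(bad, table, what) {
  if (any(bad, na.rm = TRUE)) {
    rows <- which(bad)
    abort(sprintf("%s: %s (row%s %s)", table, what,
                  if (length(rows) > 1) "s" else "",
                  paste(head(rows, 10), collapse = ", ")),
          class = "galeria_validation_error")
  }
}

as_flag <- function(x, table, column) {
  if (is.logical(x)) return(x)
  v <- tolower(trimws(as.character(x)))
  out <- dplyr::case_when(
    v %in% c("true", "t", "1", "yes") ~ TRUE,
    v %in% c("false", "f", "0", "no") ~ FALSE,
    .default = NA
  )
  fail_rows(!is.na(x) & is.na(out), table,
            sprintf("column %s is not interpretable as TRUE/FALSE", column))
  out
}

#' Validate a stem table
#'
#' Checks one measured woody individual per row against the life-stage rules:
#' adults need dbh > 10 cm, saplings need height > 0.3 m (and, for measured
#' broadleafs, dbh < 10 cm), motacu saplings are acaulescent and carry no dbh,
#' and seedlings are never individually measured (they are counted per
#' quadrat), so `stage = "seedling"` is rejected.
#'
#' @param stems Data frame with columns `site_id, plot_id, stage, group,
#'   dbh_cm, height_m, alive, grazing_damage`.
#' @return A validated tibble (vocabulary columns lower-cased, flags logical).
#' @export
validate_stems <- function(stems) {
  stems <- as_tibble(stems)
  require_columns(stems, c("site_id", "plot_id", "stage", "group",
                           "dbh_cm", "height_m", "alive", "grazing_damage"),
                  "stems")
  if (nrow(stems) == 0) {
    return(mutate(stems,
                  across(c("site_id", "plot_id", "stage", "group"), as.character),
                  across(c("dbh_cm", "height_m"), as.numeric),
                  across(c("alive", "grazing_damage"), as.logical)))
  }
  stems <- mutate(stems,
                  site_id = as.character(.data$site_id),
                  plot_id = as.character(.data$plot_id),
                  stage = match_vocab(.data$stage, c("sapling", "adult", "seedling"),
                                      "stems", "stage"),
                  group = match_vocab(.data$group, .stem_groups, "stems", "group"),
                  dbh_cm = as.numeric(.data$dbh_cm),
                  height_m = as.numeric(.data$height_m),
                  alive = as_flag(.data$alive, "stems", "alive"),
                  grazing_damage = as_flag(.data$grazing_damage, "stems",
                                           "grazing_damage"))
  fail_rows(stems$stage == "seedling", "stems",
            "seedlings are counted per quadrat, not measured as stems")
  fail_rows(stems$stage == "adult" &
              (is.na(stems$dbh_cm) | stems$dbh_cm <= 10),
            "stems", "adults require dbh_cm > 10")
  fail_rows(stems$stage == "sapling" &
              (is.na(stems$height_m) | stems$height_m <= 0.3),
            "stems", "saplings require height_m > 0.3")
  fail_rows(stems$stage == "sapling" & stems$group == "broadleaf" &
              !is.na(stems$dbh_cm) & stems$dbh_cm >= 10,
            "stems", "broadleaf saplings require dbh_cm < 10 when measured")
  fail_rows(stems$stage == "sapling" & stems$group == "motacu" &
              !is.na(stems$dbh_cm),
            "stems", "motacu saplings are acaulescent and carry no dbh")
  fail_rows(!is.na(stems$dbh_cm) & stems$dbh_cm < 0, "stems", "negative dbh_cm")
  stems
}

#' Validate a quadrat ground-cover table (long form)
#'
#' @param quadrats Data frame with columns `site_id, plot_id, quadrat_index,
#'   category, cover_pct`; one row per quadrat x cover category.
#' @return A validated tibble.
#' @export
validate_quadrats <- function(quadrats) {
  quadrats <- as_tibble(quadrats)
  require_columns(quadrats, c("site_id", "plot_id", "quadrat_index",
                              "category", "cover_pct"), "quadrats")
  quadrats <- mutate(quadrats,
                     site_id = as.character(.data$site_id),
                     plot_id = as.character(.data$plot_id),
                     quadrat_index = as.integer(.data$quadrat_index),
                     category = match_vocab(.data$category, .ground_categories,
                                            "quadrats", "category"),
                     cover_pct = as.numeric(.data$cover_pct))
  fail_rows(is.na(quadrats$cover_pct) | quadrats$cover_pct < 0 |
              quadrats$cover_pct > 100,
            "quadrats", "cover_pct must lie in [0, 100]")
  fail_rows(is.na(quadrats$quadrat_index) | quadrats$quadrat_index < 1,
            "quadrats", "quadrat_index must be a positive integer")
  quadrats
}

#' Validate a seedling-count table
#'
#' @param seedlings Data frame with columns `site_id, plot_id, quadrat_index,
#'   group, count`; groups are `motacu` and `woody`.
#' @return A validated tibble.
#' @export
validate_seedlings <- function(seedlings) {
  seedlings <- as_tibble(seedlings)
  require_columns(seedlings, c("site_id", "plot_id", "quadrat_index",
                               "group", "count"), "seedlings")
  seedlings <- mutate(seedlings,
                      site_id = as.character(.data$site_id),
                      plot_id = as.character(.data$plot_id),
                      quadrat_index = as.integer(.data$quadrat_index),
                      group = match_vocab(.data$group, .seedling_groups,
                                          "seedlings", "group"),
                      count = as.numeric(.data$count))
  fail_rows(is.na(seedlings$count) | seedlings$count < 0 |
              seedlings$count != round(seedlings$count),
            "seedlings", "count must be a non-negative integer")
  seedlings
}

#' Validate a shrub-layer line-intercept table
#'
#' @param intercepts Data frame with columns `site_id, plot_id, group,
#'   start_m, end_m`.
#' @param design A [site_design()] supplying the transect length (used as the
#'   upper bound on positions). When `NULL`, a 100 m transect is assumed.
#' @return A validated tibble.
#' @export
validate_intercepts <- function(intercepts, design = NULL) {
  len <- if (is.null(design)) 100 else design$transect_length_m
  intercepts <- as_tibble(intercepts)
  require_columns(intercepts, c("site_id", "plot_id", "group",
                                "start_m", "end_m"), "intercepts")
  intercepts <- mutate(intercepts,
                       site_id = as.character(.data$site_id),
                       plot_id = as.character(.data$plot_id),
                       group = match_vocab(.data$group, .shrub_groups,
                                           "intercepts", "group"),
                       start_m = as.numeric(.data$start_m),
                       end_m = as.numeric(.data$end_m))
  fail_rows(is.na(intercepts$start_m) | is.na(intercepts$end_m) |
              intercepts$start_m < 0 | intercepts$end_m > len |
              intercepts$start_m >= intercepts$end_m,
            "intercepts",
            sprintf("intervals must satisfy 0 <= start_m < end_m <= %g", len))
  intercepts
}

#' Validate a transect-effort table
#'
#' @param efforts Data frame with columns `transect_id, site_id, survey,
#'   distance_km, duration_min`.
#' @return A validated tibble.
#' @export
validate_efforts <- function(efforts) {
  efforts <- as_tibble(efforts)
  require_columns(efforts, c("transect_id", "site_id", "survey",
                             "distance_km", "duration_min"), "efforts")
  efforts <- mutate(efforts,
                    transect_id = as.character(.data$transect_id),
                    site_id = as.character(.data$site_id),
                    survey = match_vocab(.data$survey, .surveys,
                                         "efforts", "survey"),
                    distance_km = as.numeric(.data$distance_km),
                    duration_min = as.numeric(.data$duration_min))
  fail_rows(is.na(efforts$distance_km) | efforts$distance_km <= 0,
            "efforts", "distance_km must be > 0")
  fail_rows(is.na(efforts$duration_min) | efforts$duration_min <= 0,
            "efforts", "duration_min must be > 0")
  dup <- duplicated(efforts[c("transect_id", "survey")])
  fail_rows(dup, "efforts", "duplicate (transect_id, survey) effort record")
  efforts
}

#' Validate a wildlife-observation table
#'
#' Each row is one encounter on a survey walk. Nocturnal birds can only be
#' recorded on night surveys, and every observation must fall within the
#' duration of its transect walk (hence `efforts` is required).
#'
#' @param observations Data frame with columns `transect_id, site_id, survey,
#'   elapsed_min, taxon_id, taxon_class, n_individuals, detection`.
#' @param efforts A validated effort table, used to bound `elapsed_min`.
#' @return A validated tibble.
#' @export
validate_observations <- function(observations, efforts = NULL) {
  observations <- as_tibble(observations)
  require_columns(observations,
                  c("transect_id", "site_id", "survey", "elapsed_min",
                    "taxon_id", "taxon_class", "n_individuals", "detection"),
                  "observations")
  observations <- mutate(observations,
                         transect_id = as.character(.data$transect_id),
                         site_id = as.character(.data$site_id),
                         survey = match_vocab(.data$survey, .surveys,
                                              "observations", "survey"),
                         elapsed_min = as.numeric(.data$elapsed_min),
                         taxon_id = as.character(.data$taxon_id),
                         taxon_class = match_vocab(.data$taxon_class,
                                                   .taxon_classes,
                                                   "observations", "taxon_class"),
                         n_individuals = as.numeric(.data$n_individuals),
                         detection = match_vocab(.data$detection, .detections,
                                                 "observations", "detection"))
  fail_rows(is.na(observations$n_individuals) |
              observations$n_individuals < 1 |
              observations$n_individuals != round(observations$n_individuals),
            "observations", "n_individuals must be an integer >= 1")
  fail_rows(observations$taxon_class == "nocturnal_bird" &
              observations$survey != "night",
            "observations", "nocturnal birds are only recorded on night surveys")
  fail_rows(is.na(observations$elapsed_min) | observations$elapsed_min < 0,
            "observations", "elapsed_min must be >= 0")
  if (!is.null(efforts) && nrow(observations) > 0) {
    key <- paste(observations$transect_id, observations$survey)
    ekey <- paste(efforts$transect_id, efforts$survey)
    fail_rows(!(key %in% ekey), "observations",
              "observation on a transect/survey with no effort record")
    dur <- efforts$duration_min[match(key, ekey)]
    fail_rows(observations$elapsed_min > dur, "observations",
              "elapsed_min exceeds the duration of its transect walk")
  }
  observations
}

empty_survey_tables <- function() {
  list(
    stems = tibble(site_id = character(), plot_id = character(),
                   stage = character(), group = character(),
                   dbh_cm = numeric(), height_m = numeric(),
                   alive = logical(), grazing_damage = logical()),
    quadrats = tibble(site_id = character(), plot_id = character(),
                      quadrat_index = integer(), category = character(),
                      cover_pct = numeric()),
    seedlings = tibble(site_id = character(), plot_id = character(),
                       quadrat_index = integer(), group = character(),
                       count = numeric()),
    intercepts = tibble(site_id = character(), plot_id = character(),
                        group = character(), start_m = numeric(),
                        end_m = numeric()),
    efforts = tibble(transect_id = character(), site_id = character(),
                     survey = character(), distance_km = numeric(),
                     duration_min = numeric()),
    observations = tibble(transect_id = character(), site_id = character(),
                          survey = character(), elapsed_min = numeric(),
                          taxon_id = character(), taxon_class = character(),
                          n_individuals = numeric(), detection = character())
  )
}

#' Assemble a validated survey dataset
#'
#' Bundles the six survey tables and the per-site designs into a single
#' `survey_data` object after validating every record. Any table may be
#' omitted, in which case an empty table with the canonical schema is used.
#'
#' @param stems,quadrats,seedlings,intercepts,efforts,observations The survey
#'   tables (see the `validate_*` functions for the schemas).
#' @param designs A named list of [site_design()] objects keyed by `site_id`,
#'   or a single design applied to every site.
#' @param taxa Optional static taxon annotation table
#'   (`taxon_id, common_name, scientific_name, taxon_class, iucn_trend`).
#' @return A `survey_data` object: a list of validated tibbles plus designs.
#' @export
survey_data <- function(stems = NULL, quadrats = NULL, seedlings = NULL,
                        intercepts = NULL, efforts = NULL,
                        observations = NULL, designs = default_designs(),
                        taxa = NULL) {
  if (inherits(designs, "site_design")) designs <- list(designs)
  if (!all(map_lgl(designs, inherits, "site_design"))) {
    abort("`designs` must be site_design objects",
          class = "galeria_parameter_error")
  }
  names(designs) <- map_chr(designs, "site_id")
  empty <- empty_survey_tables()
  d1 <- designs[[1]]
  x <- list(
    stems = validate_stems(stems %||% empty$stems),
    quadrats = validate_quadrats(quadrats %||% empty$quadrats),
    seedlings = validate_seedlings(seedlings %||% empty$seedlings),
    intercepts = validate_intercepts(intercepts %||% empty$intercepts, d1),
    efforts = validate_efforts(efforts %||% empty$efforts),
    observations = NULL,
    taxa = if (!is.null(taxa)) as_tibble(taxa) else NULL,
    designs = designs
  )
  x$observations <- validate_observations(observations %||% empty$observations,
                                          x$efforts)
  structure(x, class = "survey_data")
}

#' @export
print.survey_data <- function(x, ...) {
  cat("<survey_data>\n")
  cat(sprintf("  sites:        %s\n",
              paste(names(x$designs), collapse = ", ")))
  for (nm in c("stems", "quadrats", "seedlings", "intercepts",
               "efforts", "observations")) {
    cat(sprintf("  %-13s %d records\n", paste0(nm, ":"), nrow(x[[nm]])))
  }
  invisible(x)
}

#' Lookup of site treatments in a survey dataset
#'
#' @param dataset A `survey_data` object.
#' @return A tibble with columns `site_id`, `treatment`.
#' @export
site_treatments <- function(dataset) {
  tibble(site_id = map_chr(dataset$designs, "site_id"),
         treatment = map_chr(dataset$designs, "treatment"))
}

#' Read survey CSV files into a validated dataset
#'
#' Reads the canonical UTF-8 CSV layout (`stems.csv`, `quadrats.csv`,
#' `seedlings.csv`, `intercepts.csv`, `efforts.csv`, `observations.csv`, and
#' optionally `taxa.csv`) from a directory or from an explicitly named set of
#' paths, validating every record. Missing files yield empty tables.
#'
#' @param paths A directory containing the CSV files, or a named list/vector
#'   of file paths keyed by table name.
#' @param designs Passed to [survey_data()].
#' @return A validated `survey_data` object.
#' @export
read_survey_tables <- function(paths, designs = default_designs()) {
  tables <- c("stems", "quadrats", "seedlings", "intercepts",
              "efforts", "observations", "taxa")
  if (is.character(paths) && length(paths) == 1 && dir.exists(paths)) {
    paths <- stats::setNames(file.path(paths, paste0(tables, ".csv")), tables)
  }
  paths <- as.list(paths)
  read_one <- function(name) {
    p <- paths[[name]]
    if (is.null(p) || !file.exists(p)) return(NULL)
    readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
  }
  survey_data(stems = read_one("stems"),
              quadrats = read_one("quadrats"),
              seedlings = read_one("seedlings"),
              intercepts = read_one("intercepts"),
              efforts = read_one("efforts"),
              observations = read_one("observations"),
              taxa = read_one("taxa"),
              designs = designs)
}

#' Write a survey dataset back to its canonical CSV layout
#'
#' @param dataset A `survey_data` object.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_survey_tables <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "survey_data"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  for (nm in c("stems", "quadrats", "seedlings", "intercepts",
               "efforts", "observations", "taxa")) {
    tbl <- dataset[[nm]]
    if (is.null(tbl)) next
    path <- file.path(out_dir, paste0(nm, ".csv"))
    readr::write_csv(tbl, path, progress = FALSE)
    written <- c(written, path)
  }
  invisible(written)
}
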