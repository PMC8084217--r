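#' Sampling design for one monitored site
#'
#' Describes the nested plot geometry used at a site: a 100 m transect per
#' plot with a 400 m2 adult-tree subplot centred on it, a 200 m2 western
#' half-subplot for saplings, and five regularly spaced 4 m2 ground-cover
#' quadrats. The shrub layer is recorded by line intercept along the full
#' transect up to 2 m height. Defaults reproduce that layout.
#'
#' @param site_id Site label, e.g. `"grazed"`.
#' @param treatment Either `"grazed"` or `"restored"`.
#' @param n_plots Number of plots sampled at the site.
#' @param transect_length_m Plot transect length in metres.
#' @param adult_subplot_area_m2 Area searched for adult stems, m2.
#' @param sapling_subplot_area_m2 Area searched for saplings, m2 (at most the
#'   adult subplot area).
#' @param quadrat_area_m2 Area of one ground-cover quadrat, m2.
#' @param quadrats_per_plot Number of quadrats per plot.
#' @param shrub_layer_max_height_m Upper height bound of the shrub layer, m.
#'
#' @return A `site_design` object (a validated named list).
#' @examples
#' site_design("grazed", "grazed")
#' @export
site_design <- function(site_id,
                        treatment = c("grazed", "restored"),
                        n_plots = 4,
                        transect_length_m = 100,
                        adult_subplot_area_m2 = 400,
                        sapling_subplot_area_m2 = 200,
                        quadrat_area_m2 = 4,
                        quadrats_per_plot = 5,
                        shrub_layer_max_height_m = 2) {
  treatment <- match.arg(treatment)
  x <- list(
    site_id = as.character(site_id),
    treatment = treatment,
    n_plots = as.integer(n_plots),
    transect_length_m = transect_length_m,
    adult_subplot_area_m2 = adult_subplot_area_m2,
    sapling_subplot_area_m2 = sapling_subplot_area_m2,
    quadrat_area_m2 = quadrat_area_m2,
    quadrats_per_plot = as.integer(quadrats_per_plot),
    shrub_layer_max_height_m = shrub_layer_max_height_m
  )
  lens <- c("transect_length_m", "adult_subplot_area_m2",
            "sapling_subplot_area_m2", "quadrat_area_m2",
            "shrub_layer_max_height_m")
  for (f in lens) {
    if (!is.numeric(x[[f]]) || length(x[[f]]) != 1 || !is.finite(x[[f]]) ||
        x[[f]] <= 0) {
      abort(sprintf("site_design: `%s` must be a single positive number", f),
            class = "galeria_parameter_error")
    }
  }
  if (x$sapling_subplot_area_m2 > x$adult_subplot_area_m2) {
    abort("site_design: sapling subplot cannot exceed the adult subplot",
          class = "galeria_parameter_error")
  }
  if (is.na(x$n_plots) || x$n_plots < 1) {
    abort("site_design: `n_plots` must be >= 1",
          class = "galeria_parameter_error")
  }
  if (is.na(x$quadrats_per_plot) || x$quadrats_per_plot < 1) {
    abort("site_design: `quadrats_per_plot` must be >= 1",
          class = "galeria_parameter_error")
  }
  structure(x, class = "site_design")
}

#' @export
print.site_design <- function(x, ...) {
  cat(sprintf(
    "<site_design> %s (%s): %d plots, %g m transect, %g/%g m2 subplots, %dx%g m2 quadrats\n",
    x$site_id, x$treatment, x$n_plots, x$transect_length_m,
    x$adult_subplot_area_m2, x$sapling_subplot_area_m2,
    x$quadrats_per_plot, x$quadrat_area_m2))
  invisible(x)
}

#' Default paired-site study design
#'
#' The layout of the monitoring study: one grazed and one restored site, four
#' plots each, with the default nested geometry of [site_design()].
#'
#' @return A named list of two `site_design` objects (`grazed`, `restored`).
#' @export
default_designs <- function() {
  list(grazed = site_design("grazed", "grazed"),
       restored = site_design("restored", "restored"))
}

# Per-stage sampled area (m2) within one plot under a design.
stage_area_m2 <- function(design, stage) {
  switch(stage,
         adult = design$adult_subplot_area_m2,
         sapling = design$sapling_subplot_area_m2,
         seedling = design$quadrats_per_plot * design$quadrat_area_m2,
         abort(sprintf("unknown stage '%s'", stage)))
}
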