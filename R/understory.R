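# Shrub/ground cover matrices and standardized PCA ordination.

# Union length of possibly overlapping [start, end) intervals.
interval_union_length <- function(start, end) {
  if (length(start) == 0) return(0)
  o <- order(start)
  start <- start[o]; end <- end[o]
  total <- 0
  cur_s <- start[1]; cur_e <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] > cur_e) {
      total <- total + (cur_e - cur_s)
      cur_s <- start[i]; cur_e <- end[i]
    } else {
      cur_e <- max(cur_e, end[i])
    }
  }
  total + (cur_e - cur_s)
}

#' Shrub-layer percent cover from line-intercept intervals
#'
#' Per plot and functional group, overlapping intercept intervals of the same
#' group are merged and the union length is expressed as a percentage of the
#' transect length. Groups never intercepted score 0.
#'
#' @param dataset A validated `survey_data` object, or an intercept tibble
#'   (then supply `designs`).
#' @param designs Optional named list of [site_design()] when `dataset` is a
#'   raw table.
#' @return A wide tibble (class `cover_matrix`): one row per plot,
#'   `site_id`, `plot_id`, then one percent-cover column per shrub group.
#' @export
shrub_cover_matrix <- function(dataset, designs = NULL) {
  if (inherits(dataset, "survey_data")) {
    intercepts <- dataset$intercepts
    designs <- dataset$designs
  } else {
    designs <- designs %||% default_designs()
    if (inherits(designs, "site_design")) designs <- list(designs)
    names(designs) <- map_chr(designs, "site_id")
    intercepts <- validate_intercepts(dataset, designs[[1]])
  }
  rows <- map(names(designs), function(site) {
    d <- designs[[site]]
    plots <- if (inherits(dataset, "survey_data")) {
      plot_grid(dataset, site)
    } else {
      sort(unique(intercepts$plot_id[intercepts$site_id == site]))
    }
    if (length(plots) == 0) return(NULL)
    expand_grid(plot_id = plots, group = .shrub_groups) |>
      mutate(site_id = site,
             cover_pct = purrr::map2_dbl(.data$plot_id, .data$group, \(p, g) {
               iv <- intercepts[intercepts$site_id == site &
                                  intercepts$plot_id == p &
                                  intercepts$group == g, ]
               100 * interval_union_length(iv$start_m, iv$end_m) /
                 d$transect_length_m
             }))
  })
  out <- list_rbind(rows) |>
    tidyr::pivot_wider(names_from = "group", values_from = "cover_pct") |>
    select("site_id", "plot_id", dplyr::all_of(.shrub_groups)) |>
    arrange(.data$site_id, .data$plot_id)
  structure(out, class = c("cover_matrix", class(out)), layer = "shrub")
}

#' Ground-layer percent cover from quadrat records
#'
#' Per plot and cover category, the mean of the plot's quadrat percentages.
#' Every plot must carry its complete quadrat set. By default a derived
#' `total_plant_cover` column (forbs + ferns + graminoids) is appended;
#' seedling densities can optionally be joined as additional columns.
#'
#' @param dataset A validated `survey_data` object.
#' @param total_plant_cover Append the derived summed plant-cover column?
#' @param include_seedlings Append per-ha seedling density columns
#'   (`seedlings_motacu`, `seedlings_woody`) from the quadrat counts?
#' @return A wide `cover_matrix` tibble, one row per plot.
#' @export
ground_cover_matrix <- function(dataset, total_plant_cover = TRUE,
                                include_seedlings = FALSE) {
  stopifnot(inherits(dataset, "survey_data"))
  quadrats <- dataset$quadrats
  rows <- map(names(dataset$designs), function(site) {
    d <- design_for_site(dataset, site)
    plots <- plot_grid(dataset, site)
    qq <- filter(quadrats, .data$site_id == site)
    for (p in plots) {
      got <- sort(unique(qq$quadrat_index[qq$plot_id == p]))
      if (length(got) != d$quadrats_per_plot) {
        abort(sprintf(
          "ground_cover_matrix: plot '%s' at site '%s' has %d of %d quadrats",
          p, site, length(got), d$quadrats_per_plot),
          class = "galeria_validation_error")
      }
    }
    expand_grid(plot_id = plots, category = .ground_categories) |>
      mutate(site_id = site,
             cover_pct = purrr::map2_dbl(.data$plot_id, .data$category, \(p, cat) {
               v <- qq$cover_pct[qq$plot_id == p & qq$category == cat]
               if (length(v) == 0) 0 else
                 sum(v) / d$quadrats_per_plot  # absent rows count as 0 cover
             }))
  })
  out <- list_rbind(rows) |>
    tidyr::pivot_wider(names_from = "category", values_from = "cover_pct") |>
    select("site_id", "plot_id", dplyr::all_of(.ground_categories)) |>
    arrange(.data$site_id, .data$plot_id)
  if (total_plant_cover) {
    out <- mutate(out, total_plant_cover =
                    .data$forbs + .data$ferns + .data$graminoids)
  }
  if (include_seedlings) {
    seeds <- map(names(dataset$designs), function(site) {
      d <- design_for_site(dataset, site)
      area <- d$quadrats_per_plot * d$quadrat_area_m2
      dataset$seedlings |>
        filter(.data$site_id == site) |>
        summarise(count = sum(.data$count), .by = c("plot_id", "group")) |>
        mutate(site_id = site, dens = density_per_ha(.data$count, area))
    }) |> list_rbind()
    if (nrow(seeds) > 0) {
      seeds <- seeds |>
        mutate(colname = paste0("seedlings_", .data$group)) |>
        select("site_id", "plot_id", "colname", "dens") |>
        tidyr::pivot_wider(names_from = "colname", values_from = "dens",
                           values_fill = 0)
      out <- left_join(out, seeds, by = c("site_id", "plot_id")) |>
        mutate(across(dplyr::starts_with("seedlings_"), \(v) coalesce(v, 0)))
    }
  }
  structure(out, class = c("cover_matrix", class(out)), layer = "ground")
}

#' Standardized principal-component ordination of a cover matrix
#'
#' Columns are z-scored (mean 0, unit variance, n-1 SD) so the analysis is a
#' correlation-matrix PCA: every variable enters with equal weight. Axes are
#' ordered by descending eigenvalue and each axis is sign-flipped so its
#' largest-magnitude loading is positive, making results deterministic.
#' Interpretable axes follow the latent-root criterion (eigenvalue > 1);
#' variables with |loading| > `salient_threshold` on a retained axis are its
#' salient set. Loadings are variable-axis correlations (eigenvector times
#' the square root of its eigenvalue). Zero-variance columns cannot be
#' z-scored and are dropped with a warning.
#'
#' @param matrix A `cover_matrix` (or any data frame with `site_id`,
#'   `plot_id` and numeric variable columns).
#' @param columns Optional character vector restricting the variables used.
#' @param salient_threshold Absolute-loading cutoff for salience (default 0.5).
#' @return A `cover_pca` object with elements `eigenvalues`,
#'   `variance_fraction`, `retained_axes`, `scores`, `loadings`, `salient`,
#'   `group_summary` (per-site centroid and SD on the first two axes),
#'   `dropped` and `layer`.
#' @export
cover_pca <- function(matrix, columns = NULL, salient_threshold = 0.5) {
  df <- as_tibble(matrix)
  id_cols <- intersect(c("site_id", "plot_id"), names(df))
  vars <- setdiff(names(df), id_cols)
  if (!is.null(columns)) {
    missing <- setdiff(columns, vars)
    if (length(missing) > 0) {
      abort(sprintf("cover_pca: unknown column(s): %s",
                    paste(missing, collapse = ", ")),
            class = "galeria_parameter_error")
    }
    vars <- columns
  }
  X <- as.matrix(df[vars])
  if (nrow(X) < 2) {
    abort("cover_pca: need at least 2 rows", class = "galeria_domain_error")
  }
  sds <- apply(X, 2, sd)
  dropped <- vars[sds == 0 | is.na(sds)]
  if (length(dropped) == length(vars)) {
    abort("cover_pca: all columns are constant", class = "galeria_domain_error")
  }
  if (length(dropped) > 0) {
    warn(sprintf("cover_pca: dropping zero-variance column(s): %s",
                 paste(dropped, collapse = ", ")))
    vars <- setdiff(vars, dropped)
    X <- X[, vars, drop = FALSE]
  }
  fit <- prcomp(X, center = TRUE, scale. = TRUE)
  eig <- fit$sdev^2
  # Deterministic sign: largest-|loading| variable loads positively.
  for (a in seq_along(eig)) {
    v <- fit$rotation[, a]
    if (v[which.max(abs(v))] < 0) {
      fit$rotation[, a] <- -v
      fit$x[, a] <- -fit$x[, a]
    }
  }
  loadings <- sweep(fit$rotation, 2, sqrt(eig), `*`)
  retained <- which(eig > 1)
  salient <- map(retained, \(a) {
    l <- loadings[, a]
    names(l)[abs(l) > salient_threshold]
  })
  names(salient) <- paste0("PC", retained)
  scores <- bind_cols(df[id_cols], as_tibble(fit$x))
  group_summary <- NULL
  if ("site_id" %in% id_cols && ncol(fit$x) >= 2) {
    group_summary <- scores |>
      summarise(centroid_pc1 = mean(.data$PC1), centroid_pc2 = mean(.data$PC2),
                sd_pc1 = sd(.data$PC1), sd_pc2 = sd(.data$PC2),
                .by = "site_id")
  }
  structure(list(
    eigenvalues = eig,
    variance_fraction = eig / sum(eig),
    retained_axes = retained,
    scores = scores,
    loadings = loadings,
    rotation = fit$rotation,
    center = fit$center,
    scale = fit$scale,
    salient = salient,
    salient_threshold = salient_threshold,
    group_summary = group_summary,
    dropped = dropped,
    variables = vars,
    layer = attr(matrix, "layer") %||% "cover"
  ), class = "cover_pca")
}

#' @export
print.cover_pca <- function(x, ...) {
  cat(sprintf("<cover_pca> %s layer: %d variables, %d rows\n", x$layer,
              length(x$variables), nrow(x$scores)))
  cat(sprintf("  eigenvalues: %s\n",
              paste(sprintf("%.3f", x$eigenvalues), collapse = ", ")))
  cat(sprintf("  retained (latent root > 1): %s\n",
              if (length(x$retained_axes)) {
                paste0("PC", x$retained_axes, collapse = ", ")
              } else "none"))
  for (nm in names(x$salient)) {
    cat(sprintf("  %s salient: %s\n", nm,
                paste(x$salient[[nm]], collapse = ", ")))
  }
  invisible(x)
}

#' Tidy the loadings of a cover PCA
#'
#' @param x A `cover_pca`.
#' @param ... Unused.
#' @return A long tibble: `variable`, `axis`, `loading`, `salient`.
#' @method tidy cover_pca
#' @export
tidy.cover_pca <- function(x, ...) {
  L <- x$loadings
  tibble(variable = rep(rownames(L), ncol(L)),
         axis = rep(colnames(L), each = nrow(L)),
         loading = as.vector(L)) |>
    mutate(salient = abs(.data$loading) > x$salient_threshold)
}

#' One-row-per-axis summary of a cover PCA
#'
#' @param x A `cover_pca`.
#' @param ... Unused.
#' @return A tibble with eigenvalue, variance fraction, cumulative variance
#'   and the latent-root retention flag per axis.
#' @method glance cover_pca
#' @export
glance.cover_pca <- function(x, ...) {
  tibble(axis = paste0("PC", seq_along(x$eigenvalues)),
         eigenvalue = x$eigenvalues,
         variance_fraction = x$variance_fraction,
         cumulative_variance = cumsum(x$variance_fraction),
         retained = seq_along(x$eigenvalues) %in% x$retained_axes)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
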