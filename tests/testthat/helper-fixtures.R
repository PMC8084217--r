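# Shared fixtures and independent oracles.

suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

two_plot_designs <- function(n_plots = 2) {
  list(grazed = site_design("grazed", "grazed", n_plots = n_plots),
       restored = site_design("restored", "restored", n_plots = n_plots))
}

# Minimal quadrat set for one plot: every category at a fixed cover.
full_quadrats <- function(site, plot, q = 5, cover = 10) {
  tidyr::expand_grid(quadrat_index = seq_len(q),
                     category = c("bare_ground", "leaf_litter", "motacu_nuts",
                                  "deadwood", "cow_dung", "forbs", "ferns",
                                  "graminoids")) |>
    mutate(site_id = site, plot_id = plot, cover_pct = cover)
}

# Two-plot toy sapling dataset used for the hand-enumerated NR oracle:
# plot 1 holds two motacu and one broadleaf sapling in the 1-2 m class,
# plot 2 holds one broadleaf sapling in the 2-3 m class.
nr_toy_dataset <- function() {
  stems <- tribble(
    ~site_id, ~plot_id, ~stage, ~group, ~dbh_cm, ~height_m, ~alive, ~grazing_damage,
    "grazed", "p1", "sapling", "motacu", NA, 1.5, TRUE, FALSE,
    "grazed", "p1", "sapling", "motacu", NA, 1.6, TRUE, FALSE,
    "grazed", "p1", "sapling", "broadleaf", 2, 1.2, TRUE, FALSE,
    "grazed", "p2", "sapling", "broadleaf", 3, 2.5, TRUE, FALSE
  )
  survey_data(stems = stems,
              designs = list(site_design("grazed", "grazed", n_plots = 2)))
}

# Complete-enumeration oracle for the exact accumulation curve: averages
# richness over every size-k subset of segments.
enumerate_accumulation <- function(M) {
  M <- M > 0
  T_seg <- ncol(M)
  out <- lapply(seq_len(T_seg), function(k) {
    subs <- utils::combn(T_seg, k)
    S <- apply(subs, 2, function(idx) {
      sum(rowSums(M[, idx, drop = FALSE]) > 0)
    })
    data.frame(k = k, expected_richness = mean(S),
               sd = sqrt(mean(S^2) - mean(S)^2))
  })
  do.call(rbind, out)
}

# Eigendecomposition-based PCA oracle, independent of prcomp: correlation
# matrix eigenvectors, scores by projection of the z-scored data.
pca_oracle <- function(X) {
  Z <- scale(X, center = TRUE, scale = TRUE)
  e <- eigen(stats::cor(X), symmetric = TRUE)
  scores <- Z %*% e$vectors
  list(eigenvalues = e$values, vectors = e$vectors, scores = scores, z = Z)
}

# Align oracle axis signs to the package's convention (largest-|loading|
# variable positive) before comparing.
align_signs <- function(vectors, scores) {
  for (a in seq_len(ncol(vectors))) {
    v <- vectors[, a]
    if (v[which.max(abs(v))] < 0) {
      vectors[, a] <- -v
      scores[, a] <- -scores[, a]
    }
  }
  list(vectors = vectors, scores = scores)
}

# Default profiles stripped of vegetation, for fast wildlife-only simulation.
wildlife_only_profiles <- function() {
  ps <- default_profiles()
  for (nm in names(ps)) {
    ps[[nm]]$adults$density_per_ha <- 0
    ps[[nm]]$saplings$density_per_ha <- 0
    ps[[nm]]$seedlings$mean_per_quadrat <- 0
    ps[[nm]]$shrub_cover$cover_pct <- 0
  }
  ps
}
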