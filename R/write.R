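# Writing analysis outputs as stable CSV tables plus run metadata.

#' Write pipeline result tables to a directory
#'
#' Writes each recognised result table (`site_stage_summary`, `nr_table`,
#' `class_distributions`, `life_stage_composition`, `pca_scores`,
#' `pca_loadings`, `pca_eigenvalues`, `pca_groups`, `encounter_rates`,
#' `richness`, `accumulation_curve`) as a UTF-8 CSV with a fixed column
#' order, and always writes `run_metadata.json` capturing the configuration,
#' seed and package version. Re-running with the same results and metadata
#' produces byte-identical files.
#'
#' @param results A named list of tibbles (any subset of the recognised
#'   names; unrecognised names are written as-is).
#' @param out_dir Output directory, created if needed.
#' @param metadata Named list merged into the metadata JSON (e.g. config and
#'   seed).
#' @return Invisibly, the character vector of files written.
#' @export
write_outputs <- function(results = list(), out_dir, metadata = list()) {
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    abort(sprintf("write_outputs: cannot create directory '%s'", out_dir),
          class = "galeria_io_error")
  }
  written <- character()
  for (nm in names(results)) {
    tbl <- results[[nm]]
    if (is.null(tbl)) next
    path <- file.path(out_dir, paste0(nm, ".csv"))
    readr::write_csv(as_tibble(tbl), path, progress = FALSE)
    written <- c(written, path)
  }
  meta <- c(list(package = "galeria",
                 version = as.character(utils::packageVersion("galeria")),
                 r_version = paste(R.version$major, R.version$minor, sep = "."),
                 tables = as.list(names(results))),
            metadata)
  meta_path <- file.path(out_dir, "run_metadata.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(written, meta_path))
}
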