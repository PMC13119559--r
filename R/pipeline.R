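# Pipeline orchestration: config-driven three-stage workflow
# (cross-tabulate -> analyze -> decompose/report) over raster, matrix or
# simulated input, with a machine-readable run manifest.

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

#' Read a pipeline run configuration
#'
#' A RunConfig is a YAML or JSON file (or an equivalent R list) with fields:
#' `mode` (`"simulate"`, `"matrices"` or `"rasters"`), `out` (output
#' directory), `seed`, thresholds (`min_targeted_frac`, `min_area_km2`,
#' `area_drift_tol`), and per-mode inputs — `matrices`: a vector of matrix
#' CSV paths; `rasters`: `maps` (paths + years), `strata` path and labels,
#' `scheme` (`"glc_level1"` or a CSV of id/abbrev/name), `reclassify` flag.
#'
#' @param path config file path (`.yaml`/`.yml`/`.json`).
#' @return The config as a list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

resolve_scheme <- function(spec) {
  if (is.null(spec) || identical(spec, "glc_level1")) return(glc_level1_scheme())
  if (is.character(spec) && length(spec) == 1) {
    if (!file.exists(spec)) stop("scheme file not found: ", spec)
    df <- utils::read.csv(spec, stringsAsFactors = FALSE)
    return(lc_scheme(df$id, df$abbrev,
                     if ("name" %in% names(df)) df$name else df$abbrev))
  }
  stop("unrecognised scheme specification")
}

#' Run the full analysis pipeline
#'
#' Executes the staged workflow on a RunConfig: builds or loads the matrix
#' series (simulating, reading matrix tables, or cross-tabulating rasters per
#' stratum and interval), validates it, runs [intensity_analysis()], and
#' writes the complete result bundle — matrices (when derived here), all
#' result CSVs, network files, a trajectory grid (raster/simulate modes) and
#' a JSON run manifest. Identical inputs produce identical outputs.
#'
#' @param config a config list or path to a YAML/JSON file
#'   (see [read_run_config()]).
#' @return The [intensity_analysis()] bundle, invisibly, with a `validation`
#'   attribute carrying the [validate_series()] report.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- stage("config", read_run_config(config))
  mode <- match.arg(config$mode, c("simulate", "matrices", "rasters"))
  out <- config$out %||% "lcintensity_results"
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  scheme <- stage("scheme", resolve_scheme(config$scheme))
  maps_fl <- NULL            # first/last maps when we have rasters
  if (mode == "simulate") {
    cfg <- stage("simulate", {
      dims <- config$dims %||% c(120, 120)
      default_sim_config(seed = config$seed %||% 1L, dims = dims,
                         boosts = config$boosts)
    })
    sim <- stage("simulate", simulate_series(cfg))
    series <- sim$series
    scheme <- cfg$scheme
    tps <- cfg$time_points
    maps_fl <- list(first = sim$maps[[1]], last = sim$maps[[length(tps)]])
    mdir <- file.path(out, "matrices")
    dir.create(mdir, showWarnings = FALSE)
    stage("write_matrices", for (t in seq_len(n_intervals(series)))
      for (s in names(series$mats[[t]]))
        write_matrix_table(series$mats[[t]][[s]], file.path(
          mdir, sprintf("matrix_%d_%d_%s.csv", series$intervals$from[t],
                        series$intervals$to[t], s))))
  } else if (mode == "matrices") {
    paths <- config$matrices
    if (is.null(paths) || !length(paths)) stop("stage 'input': no matrix paths")
    mats <- stage("read_matrices", lapply(paths, read_matrix_table,
                                          scheme = scheme))
    series <- stage("series", matrix_series(mats, scheme))
  } else {
    mp <- config$maps
    if (is.null(mp)) stop("stage 'input': rasters mode needs a 'maps' table")
    mp <- as.data.frame(mp, stringsAsFactors = FALSE)
    maps <- stage("read_rasters", lapply(seq_len(nrow(mp)), function(i)
      read_ascii_grid(mp$path[i], year = mp$year[i],
                      cell_area = config$cell_area %||% 1)))
    if (isTRUE(config$reclassify))
      maps <- stage("reclassify", lapply(maps, reclassify_map, scheme = scheme))
    strata <- NULL
    if (!is.null(config$strata)) {
      sg <- stage("read_strata", read_ascii_grid(config$strata$path))
      strata <- lc_strata(sg$values, config$strata$labels)
    }
    ord <- order(vapply(maps, function(m) m$year, integer(1)))
    maps <- maps[ord]
    mats <- stage("crosstab", {
      res <- list()
      for (t in seq_len(length(maps) - 1)) {
        if (is.null(strata)) {
          res[[length(res) + 1]] <- crosstab(maps[[t]], maps[[t + 1]], scheme)
        } else for (s in strata$labels)
          res[[length(res) + 1]] <- crosstab(maps[[t]], maps[[t + 1]], scheme,
                                             strata = strata, stratum = s)
      }
      res
    })
    series <- stage("series", matrix_series(mats, scheme))
    maps_fl <- list(first = list(ALL = maps[[1]]),
                    last = list(ALL = maps[[length(maps)]]))
  }
  validation <- stage("validate",
                      validate_series(series,
                                      config$area_drift_tol %||% 1e-6))
  pw <- if (all(c("FST", "CRP", "SHR", "GRS", "BAL", "WET") %in%
               category_labels(scheme))) default_pathways() else NULL
  fit <- stage("analyze", intensity_analysis(
    series,
    min_targeted_frac = config$min_targeted_frac %||% 0.5,
    min_area_km2 = config$min_area_km2,
    pathways = pw))
  stage("write_results", write_results(fit, out))
  if (!is.null(maps_fl) && !is.null(pw)) stage("trajectories", {
    for (s in names(maps_fl$first)) {
      tm <- label_trajectories(maps_fl$first[[s]], maps_fl$last[[s]], pw,
                               scheme)
      write_trajectory_map(tm, file.path(out, paste0("trajectory_", s, ".asc")))
    }
  })
  if (nrow(validation))
    utils::write.csv(validation, file.path(out, "validation.csv"),
                     row.names = FALSE)
  stage("manifest", jsonlite::write_json(list(
    mode = mode, seed = config$seed,
    parameters = list(min_targeted_frac = config$min_targeted_frac %||% 0.5,
                      min_area_km2 = config$min_area_km2,
                      area_drift_tol = config$area_drift_tol %||% 1e-6),
    n_intervals = n_intervals(series), strata = series$strata,
    categories = category_labels(scheme),
    U_pct_yr = fit$U,
    package_version = as.character(utils::packageVersion("lcintensity")),
    validation_issues = nrow(validation)),
    file.path(out, "manifest.json"), auto_unbox = TRUE, digits = NA))
  attr(fit, "validation") <- validation
  invisible(fit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render summary report artifacts from an analysis bundle
#'
#' Writes deterministic summary tables (interval panel with regional shares,
#' category gain/loss panel) and a multi-page PDF with the interval,
#' category, stationarity and network plot families.
#'
#' @param fit an [intensity_analysis()] bundle.
#' @param dir output directory.
#' @param pdf write `report.pdf` with the plot families (default TRUE).
#' @return `dir`, invisibly.
#' @export
render_report <- function(fit, dir, pdf = TRUE) {
  if (!inherits(fit, "intensity_analysis"))
    stop("incomplete bundle: expected an intensity_analysis object")
  needed <- c("intervals", "categories", "stationarity", "network")
  missing <- needed[vapply(needed, function(f) is.null(fit[[f]]), logical(1))]
  if (length(missing))
    stop("incomplete bundle: missing ", paste(missing, collapse = ", "))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  iv <- fit$intervals
  panel <- iv[, c("from", "to", "duration", "gross_area_km2", "gross_pct",
                  "St_pct_yr", "U_pct_yr", "tempo")]
  if (!is.null(fit$contributions)) {
    ic <- fit$contributions[fit$contributions$level == "interval", ]
    shares <- do.call(rbind, lapply(split(ic, ic$interval), function(d)
      stats::setNames(as.data.frame(t(d$share_pct)), paste0("share_", d$stratum))))
    panel <- cbind(panel, shares[match(paste0(iv$from, "-", iv$to),
                                       rownames(shares)), , drop = FALSE])
  }
  utils::write.csv(panel, file.path(dir, "report_intervals.csv"),
                   row.names = FALSE)
  utils::write.csv(fit$categories, file.path(dir, "report_categories.csv"),
                   row.names = FALSE)
  if (pdf) {
    grDevices::pdf(file.path(dir, "report.pdf"), width = 9, height = 6)
    on.exit(grDevices::dev.off())
    plot(fit, "intervals")
    for (t in seq_len(nrow(iv))) plot(fit, "categories", interval = t)
    plot(fit, "stationarity")
    plot(fit, "network")
  }
  invisible(dir)
}
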