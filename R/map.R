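#' Categorical land-cover map
#'
#' A single-date categorical raster held as an integer matrix, with nodata
#' cells stored as `NA`, a cell-area specification (constant km^2 per cell or
#' a per-cell area matrix of the same dimensions), and the map date.
#'
#' @param values integer matrix of category ids (or source codes before
#'   reclassification); `NA` marks nodata.
#' @param year integer map date.
#' @param cell_area scalar km^2 per cell, or a matrix of per-cell areas
#'   matching `dim(values)`; all areas must be strictly positive.
#' @param scheme optional [lc_scheme()]; when supplied, every non-nodata value
#'   must be a valid id.
#' @return An object of class `lc_map`.
#' @export
lc_map <- function(values, year, cell_area = 1, scheme = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (is.matrix(cell_area)) {
    if (!identical(dim(cell_area), dim(values)))
      stop("per-cell area grid must match map dimensions")
    if (any(cell_area <= 0, na.rm = TRUE)) stop("cell areas must be positive")
  } else {
    if (length(cell_area) != 1 || cell_area <= 0)
      stop("cell_area must be a positive scalar or a matrix")
  }
  if (!is.null(scheme)) {
    bad <- setdiff(unique(values[!is.na(values)]), scheme$categories$id)
    if (length(bad))
      stop("map contains ids not in scheme: ", paste(sort(bad), collapse = ", "))
  }
  structure(list(values = values, year = as.integer(year),
                 cell_area = cell_area, scheme = scheme),
            class = "lc_map")
}

#' @export
print.lc_map <- function(x, ...) {
  d <- dim(x$values)
  cat("Categorical map, year ", x$year, ": ", d[1], " x ", d[2], " cells, ",
      sum(is.na(x$values)), " nodata\n", sep = "")
  invisible(x)
}

cell_areas <- function(map) {
  if (is.matrix(map$cell_area)) map$cell_area
  else array(map$cell_area, dim = dim(map$values))
}

#' Stratum set
#'
#' Assigns every cell of the analysis grid to at most one stratum (spatial
#' sub-region). Strata are mutually exclusive by construction: the membership
#' grid holds one stratum index per cell (`NA` = outside all strata).
#'
#' @param values integer matrix of stratum indices (1..K), `NA` outside.
#' @param labels character stratum labels in index order (e.g.
#'   `c("EAF","MED","SAF","SAH","WAF")`).
#' @return An object of class `lc_strata`.
#' @export
lc_strata <- function(values, labels) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "integer"
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("stratum labels must be unique")
  idx <- unique(values[!is.na(values)])
  if (length(idx) && max(idx) > length(labels))
    stop("stratum index exceeds number of labels")
  structure(list(values = values, labels = labels), class = "lc_strata")
}

#' @export
print.lc_strata <- function(x, ...) {
  cat("Stratum set:", length(x$labels), "strata:",
      paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

# ---- plain-text raster I/O (ESRI ASCII grid) --------------------------------

#' Read a categorical map from an ESRI ASCII grid
#'
#' Reads the standard plain-text raster interchange format (`ncols`/`nrows`/
#' `xllcorner`/`yllcorner`/`cellsize`/`NODATA_value` header followed by rows
#' of values). Map metadata (year, cell area in km^2) comes from an optional
#' JSON sidecar `<path>.json` or from the arguments.
#'
#' @param path path to the `.asc` file.
#' @param year map date; overridden by a sidecar `year` field if present.
#' @param cell_area km^2 per cell; overridden by a sidecar `cell_area_km2`.
#' @param scheme optional [lc_scheme()] to validate ids against.
#' @return An [lc_map()].
#' @export
read_ascii_grid <- function(path, year = NA_integer_, cell_area = 1,
                            scheme = NULL) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  for (f in c("ncols", "nrows"))
    if (is.null(hdr[[f]])) stop("ASCII grid missing header field ", f)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ASCII grid has ", length(vals), " values, expected ",
         hdr$ncols * hdr$nrows)
  m <- matrix(as.integer(vals), nrow = hdr$nrows, ncol = hdr$ncols,
              byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == as.integer(hdr$nodata_value)] <- NA
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(meta$year)) year <- meta$year
    if (!is.null(meta$cell_area_km2)) cell_area <- meta$cell_area_km2
  }
  lc_map(m, year = year, cell_area = cell_area, scheme = scheme)
}

#' Write a categorical map as an ESRI ASCII grid
#'
#' Writes the grid plus a JSON sidecar `<path>.json` holding the year and the
#' cell area, so [read_ascii_grid()] round-trips the map.
#'
#' @param map an [lc_map()] (constant cell area only).
#' @param path output `.asc` path.
#' @param nodata integer code used for `NA` cells in the file.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(map, path, nodata = -9999L) {
  v <- map$values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(v)), paste("nrows", nrow(v)),
               "xllcorner 0", "yllcorner 0", "cellsize 1",
               paste("NODATA_value", nodata)), con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  meta <- list(year = map$year,
               cell_area_km2 = if (is.matrix(map$cell_area)) NULL else map$cell_area)
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
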