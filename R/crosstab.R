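#' Area transition matrix for one interval
#'
#' A square matrix whose entry (i, j) is the area (km^2) that was in category
#' i at the start of the interval and in category j at its end. Row sums are
#' the category start sizes, column sums the end sizes; the diagonal is
#' persistence.
#'
#' @param mat square numeric matrix with identical row/column labels (category
#'   abbreviations) and non-negative entries.
#' @param from_year,to_year interval bounds (years); `to_year > from_year`.
#' @param stratum stratum label, or `"ALL"` for an aggregate.
#' @return A `transition_matrix` (a numeric matrix with interval attributes).
#' @export
transition_matrix <- function(mat, from_year, to_year, stratum = "ALL") {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop("transition matrix must be square")
  if (is.null(rownames(mat)) || !identical(rownames(mat), colnames(mat)))
    stop("row and column labels must be present and identical")
  if (any(mat < 0)) stop("transition areas must be non-negative")
  from_year <- as.integer(from_year); to_year <- as.integer(to_year)
  if (to_year <= from_year) stop("interval duration must be positive")
  structure(mat, class = c("transition_matrix", "matrix", "array"),
            from_year = from_year, to_year = to_year,
            stratum = as.character(stratum))
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("Transition matrix ", attr(x, "from_year"), "-", attr(x, "to_year"),
      " [", attr(x, "stratum"), "], total area ",
      format(sum(x), digits = 6), " km2\n", sep = "")
  print(unclass_tm(x), ...)
  invisible(x)
}

unclass_tm <- function(x) {
  attributes(x) <- list(dim = dim(x), dimnames = dimnames(x))
  x
}

#' Interval duration of a transition matrix, in years
#' @param m a [transition_matrix()].
#' @return `to_year - from_year`.
#' @export
duration_years <- function(m) attr(m, "to_year") - attr(m, "from_year")

#' Cross-tabulate two categorical maps into a transition matrix
#'
#' Computes the area cross-tabulation between two co-registered maps of the
#' same scheme. Cells that are nodata at either date are excluded entirely, so
#' the matrix total equals the area valid at both dates.
#'
#' @param map_t0,map_t1 [lc_map()] objects on identical grids, with
#'   `map_t0$year < map_t1$year`, values already in scheme ids.
#' @param scheme the [lc_scheme()] defining matrix dimensions and labels.
#' @param strata optional [lc_strata()] aligned to the maps.
#' @param stratum stratum label to restrict to (requires `strata`); `NULL`
#'   uses every valid cell and labels the matrix `"ALL"`.
#' @return A [transition_matrix()].
#' @export
crosstab <- function(map_t0, map_t1, scheme, strata = NULL, stratum = NULL) {
  stopifnot(inherits(map_t0, "lc_map"), inherits(map_t1, "lc_map"))
  if (!identical(dim(map_t0$values), dim(map_t1$values)))
    stop("maps are on different grids")
  if (map_t0$year >= map_t1$year) stop("map_t0 must predate map_t1")
  a <- as.vector(map_t0$values); b <- as.vector(map_t1$values)
  w <- as.vector(cell_areas(map_t0))
  keep <- !is.na(a) & !is.na(b)
  label <- "ALL"
  if (!is.null(stratum)) {
    if (is.null(strata)) stop("stratum selection requires a strata object")
    k <- match(stratum, strata$labels)
    if (is.na(k)) stop("unknown stratum: ", stratum)
    if (!identical(dim(strata$values), dim(map_t0$values)))
      stop("strata grid does not match maps")
    keep <- keep & !is.na(as.vector(strata$values)) &
      as.vector(strata$values) == k
    label <- stratum
  }
  if (!any(keep)) stop("no analyzable cells",
                       if (!is.null(stratum)) paste0(" in stratum ", stratum))
  labs <- category_labels(scheme)
  J <- length(labs)
  idx <- (a[keep] - 1L) * J + b[keep]          # row-major (from, to) cell index
  sums <- rowsum(w[keep], idx)
  g <- as.integer(rownames(sums))
  mat <- matrix(0, J, J, dimnames = list(labs, labs))
  mat[cbind((g - 1L) %/% J + 1L, (g - 1L) %% J + 1L)] <- sums[, 1]
  transition_matrix(mat, map_t0$year, map_t1$year, label)
}

#' Sum per-stratum transition matrices into an aggregate
#'
#' Element-wise sum of matrices for the same interval and scheme; the result
#' carries the stratum label `"ALL"`.
#'
#' @param matrices list of [transition_matrix()] objects with identical
#'   interval bounds and category labels, distinct stratum labels.
#' @return A [transition_matrix()] labelled `"ALL"`.
#' @export
sum_strata <- function(matrices) {
  if (!length(matrices)) stop("no matrices to sum")
  ref <- matrices[[1]]
  labs <- vapply(matrices, function(m) attr(m, "stratum"), character(1))
  if (anyDuplicated(labs)) stop("stratum labels must be distinct")
  out <- unclass_tm(ref) * 0
  for (m in matrices) {
    if (attr(m, "from_year") != attr(ref, "from_year") ||
        attr(m, "to_year") != attr(ref, "to_year"))
      stop("matrices cover different intervals")
    if (!identical(dimnames(m), dimnames(ref)))
      stop("matrices use different schemes")
    out <- out + unclass_tm(m)
  }
  transition_matrix(out, attr(ref, "from_year"), attr(ref, "to_year"), "ALL")
}

# ---- matrix table I/O -------------------------------------------------------

#' Write a transition matrix as a CSV table
#'
#' Wide dialect: first column `from` holds the row (losing-category) labels,
#' remaining header names are the column (gaining-category) labels. Interval
#' metadata goes to a JSON sidecar `<path>.json`.
#'
#' @param m a [transition_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_matrix_table <- function(m, path) {
  df <- data.frame(from = rownames(m), unclass_tm(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(from_year = attr(m, "from_year"), to_year = attr(m, "to_year"),
         stratum = attr(m, "stratum"), categories = rownames(m)),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a transition matrix from a CSV table
#'
#' Accepts the wide dialect written by [write_matrix_table()] and a long
#' dialect with columns `from`, `to`, `area` (unlisted pairs are zero).
#' Metadata is taken from a `<path>.json` sidecar when present, else from the
#' arguments.
#'
#' @param path CSV path.
#' @param scheme optional [lc_scheme()]; labels must be drawn from it.
#' @param from_year,to_year,stratum metadata fallbacks when no sidecar exists.
#' @return A [transition_matrix()].
#' @export
read_matrix_table <- function(path, scheme = NULL, from_year = NULL,
                              to_year = NULL, stratum = "ALL") {
  if (!file.exists(path)) stop("matrix table not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(meta$from_year)) from_year <- meta$from_year
    if (!is.null(meta$to_year)) to_year <- meta$to_year
    if (!is.null(meta$stratum)) stratum <- meta$stratum
  }
  if (is.null(from_year) || is.null(to_year))
    stop("interval bounds missing: supply from_year/to_year or a JSON sidecar")
  long <- all(c("from", "to", "area") %in% names(df))
  if (long) {
    labs <- if (!is.null(scheme)) category_labels(scheme)
            else sort(unique(c(df$from, df$to)))
    bad <- setdiff(unique(c(df$from, df$to)), labs)
    if (length(bad)) stop("unknown category label(s): ",
                          paste(bad, collapse = ", "))
    mat <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
    for (r in seq_len(nrow(df)))
      mat[df$from[r], df$to[r]] <- mat[df$from[r], df$to[r]] + df$area[r]
  } else {
    if (names(df)[1] != "from") stop("wide table must start with a 'from' column")
    rows <- as.character(df$from)
    cols <- names(df)[-1]
    if (nrow(df) != length(cols) || !setequal(rows, cols))
      stop("matrix table is not square with matching labels")
    mat <- as.matrix(df[, -1, drop = FALSE])
    rownames(mat) <- rows
    mat <- mat[, rows, drop = FALSE]            # align column order to rows
    colnames(mat) <- rows
    if (!is.null(scheme)) {
      labs <- category_labels(scheme)
      bad <- setdiff(rows, labs)
      if (length(bad)) stop("unknown category label(s): ",
                            paste(bad, collapse = ", "))
      full <- matrix(0, length(labs), length(labs),
                     dimnames = list(labs, labs))
      full[rows, rows] <- mat
      mat <- full
    }
  }
  if (any(mat < 0)) stop("negative area entries in ", path)
  transition_matrix(mat, from_year, to_year, stratum)
}

# ---- matrix series ----------------------------------------------------------

#' Series of per-stratum transition matrices over contiguous intervals
#'
#' Organises one [transition_matrix()] per (interval, stratum) under a common
#' scheme. Intervals must be contiguous (each `to_year` equals the next
#' `from_year`) and every matrix must share the scheme's labels.
#'
#' @param matrices flat list of [transition_matrix()] objects.
#' @param scheme the common [lc_scheme()].
#' @return An object of class `matrix_series` with elements `scheme`,
#'   `intervals` (data frame: `from`, `to`, `duration`), `strata` (labels) and
#'   `mats` (`mats[[t]][[stratum]]`).
#' @export
matrix_series <- function(matrices, scheme) {
  stopifnot(length(matrices) > 0)
  labs <- category_labels(scheme)
  for (m in matrices)
    if (!identical(rownames(m), labs))
      stop("matrix labels do not match scheme: ",
           paste(rownames(m), collapse = ","))
  from <- vapply(matrices, attr, integer(1), which = "from_year")
  to <- vapply(matrices, attr, integer(1), which = "to_year")
  strat <- vapply(matrices, attr, character(1), which = "stratum")
  iv <- unique(data.frame(from = from, to = to))
  iv <- iv[order(iv$from), , drop = FALSE]
  rownames(iv) <- NULL
  iv$duration <- iv$to - iv$from
  strata <- unique(strat)
  mats <- vector("list", nrow(iv))
  for (t in seq_len(nrow(iv))) {
    sel <- which(from == iv$from[t] & to == iv$to[t])
    if (anyDuplicated(strat[sel]))
      stop("duplicate stratum '", strat[sel][duplicated(strat[sel])][1],
           "' for interval ", iv$from[t], "-", iv$to[t])
    mats[[t]] <- stats::setNames(matrices[sel], strat[sel])
  }
  structure(list(scheme = scheme, intervals = iv, strata = strata,
                 mats = mats),
            class = "matrix_series")
}

#' @export
print.matrix_series <- function(x, ...) {
  cat("Matrix series: ", nrow(x$intervals), " interval(s) ",
      x$intervals$from[1], "-", x$intervals$to[nrow(x$intervals)], ", strata: ",
      paste(x$strata, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of intervals in a series
#' @param series a [matrix_series()].
#' @return Integer count of intervals.
#' @export
n_intervals <- function(series) nrow(series$intervals)

#' Extract the matrix for one interval and stratum
#'
#' @param series a [matrix_series()].
#' @param t interval index (1-based).
#' @param stratum stratum label, or `"ALL"` for the sum over strata (computed
#'   by [sum_strata()] when not stored explicitly).
#' @return A [transition_matrix()].
#' @export
series_matrix <- function(series, t, stratum = "ALL") {
  mt <- series$mats[[t]]
  if (stratum %in% names(mt)) return(mt[[stratum]])
  if (stratum == "ALL") return(sum_strata(unname(mt)))
  stop("no matrix for stratum '", stratum, "' in interval ", t)
}

#' Validate a matrix series
#'
#' Reports (without erroring) interval gaps or overlaps, negative entries, and
#' per-stratum area drift — the maximum relative deviation of a stratum's
#' total area across intervals, which should be ~0 for a closed landscape.
#'
#' @param series a [matrix_series()].
#' @param area_tol relative tolerance above which area drift is flagged.
#' @return A data frame of issues (`type`, `where`, `value`, `message`);
#'   zero rows when all invariants hold.
#' @export
validate_series <- function(series, area_tol = 1e-6) {
  issues <- list()
  add <- function(type, where, value, message)
    issues[[length(issues) + 1]] <<- data.frame(
      type = type, where = where, value = value, message = message,
      stringsAsFactors = FALSE)
  iv <- series$intervals
  if (nrow(iv) > 1)
    for (t in 2:nrow(iv))
      if (iv$from[t] != iv$to[t - 1])
        add(if (iv$from[t] > iv$to[t - 1]) "gap" else "overlap",
            paste0(iv$to[t - 1], "|", iv$from[t]),
            iv$from[t] - iv$to[t - 1],
            paste0("interval ", t - 1, " ends ", iv$to[t - 1],
                   " but interval ", t, " starts ", iv$from[t]))
  for (t in seq_len(nrow(iv)))
    for (s in names(series$mats[[t]]))
      if (any(series$mats[[t]][[s]] < 0))
        add("negative", paste0("t", t, ":", s), NA_real_,
            "negative transition area")
  for (s in series$strata) {
    tot <- vapply(seq_len(nrow(iv)), function(t) {
      if (s %in% names(series$mats[[t]])) sum(series$mats[[t]][[s]])
      else NA_real_
    }, numeric(1))
    tot <- tot[!is.na(tot)]
    if (length(tot) > 1 && max(tot) > 0) {
      drift <- (max(tot) - min(tot)) / max(tot)
      if (drift > area_tol)
        add("area_drift", s, drift,
            sprintf("stratum %s total area varies by %.3g%% across intervals",
                    s, 100 * drift))
    }
  }
  if (!length(issues))
    return(data.frame(type = character(), where = character(),
                      value = numeric(), message = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, issues)
}
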