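#' Category scheme for categorical land-cover maps
#'
#' A scheme is the ordered list of category codes used in an analysis, plus an
#' optional reclassification map translating fine-grained source codes (e.g.
#' the 35-class legend of a global land-cover product) into the scheme's ids.
#'
#' @param ids integer category ids, unique and contiguous (1..J) in listed order.
#' @param abbrevs short unique labels, one per id (used as matrix dimnames).
#' @param names optional long names, one per id; defaults to `abbrevs`.
#' @param reclass_map named integer vector mapping source codes (names) to
#'   category ids (values), or `NULL` when maps are already in scheme ids.
#' @return An object of class `lc_scheme`.
#' @seealso [glc_level1_scheme()] for the ten-class Level-1 scheme.
#' @export
lc_scheme <- function(ids, abbrevs, names = abbrevs, reclass_map = NULL) {
  ids <- as.integer(ids)
  if (anyDuplicated(ids)) stop("category ids must be unique")
  if (!identical(ids, seq_along(ids)))
    stop("category ids must be contiguous 1..J in listed order")
  if (length(abbrevs) != length(ids) || anyDuplicated(abbrevs))
    stop("abbrevs must be unique, one per id")
  if (length(names) != length(ids)) stop("names must have one entry per id")
  if (!is.null(reclass_map)) {
    reclass_map <- vapply(reclass_map, as.integer, integer(1))
    if (is.null(names(reclass_map)) || any(!nzchar(names(reclass_map))))
      stop("reclass_map must be a named vector (source code -> id)")
    if (anyDuplicated(names(reclass_map)))
      stop("each source code must map to exactly one id")
    bad <- setdiff(unique(reclass_map), ids)
    if (length(bad))
      stop("reclass_map targets unknown ids: ", paste(bad, collapse = ", "))
  }
  structure(
    list(categories = data.frame(id = ids, abbrev = as.character(abbrevs),
                                 name = as.character(names),
                                 stringsAsFactors = FALSE),
         reclass_map = reclass_map),
    class = "lc_scheme")
}

#' @export
print.lc_scheme <- function(x, ...) {
  cat("Category scheme:", nrow(x$categories), "categories\n")
  print(x$categories, row.names = FALSE)
  if (!is.null(x$reclass_map))
    cat("Reclassification map:", length(x$reclass_map), "source codes\n")
  invisible(x)
}

#' Number of categories in a scheme
#' @param scheme an [lc_scheme()].
#' @return Integer J.
#' @export
n_categories <- function(scheme) nrow(scheme$categories)

#' Category abbreviations of a scheme
#' @param scheme an [lc_scheme()].
#' @return Character vector of length J, in id order.
#' @export
category_labels <- function(scheme) scheme$categories$abbrev

#' Ten-class Level-1 land-cover scheme
#'
#' The Level-1 aggregation of the GLC_FCS30D fine classification system:
#' ten mutually exclusive classes (Cropland, Forest, Shrubland, Grassland,
#' Tundra, Wetland, Impervious Surface, Bare Area, Water Body, Permanent
#' Snow/Ice) together with the reclassification map from the fine legend
#' codes to these ids.
#'
#' @return An `lc_scheme` with J = 10 and a complete reclass map.
#' @export
glc_level1_scheme <- function() {
  abbrev <- c("CRP", "FST", "SHR", "GRS", "TUD", "WET", "IMP", "BAL", "WTR", "PSI")
  name <- c("Cropland", "Forest", "Shrubland", "Grassland", "Tundra",
            "Wetland", "Impervious Surface", "Bare Area", "Water Body",
            "Permanent Snow/Ice")
  codes <- list(
    `1` = c(10L, 11L, 12L, 20L),          # rainfed, irrigated, paddy, greenhouse
    `2` = 51:92,                          # all forest sub-types
    `3` = c(120L, 121L, 122L),
    `4` = 130L,
    `5` = 140L,                           # lichens and mosses
    `6` = 181:187,
    `7` = 190L,
    `8` = c(150L, 152L, 153L, 200:202),   # sparse vegetation, bare rock/soil/sand
    `9` = 210L,
    `10` = 220L)
  rmap <- unlist(lapply(seq_along(codes), function(i) {
    stats::setNames(rep(i, length(codes[[i]])), codes[[i]])
  }))
  lc_scheme(1:10, abbrev, name, reclass_map = rmap)
}

#' Reclassify a categorical map to a scheme's Level-1 ids
#'
#' Applies the scheme's reclassification map to every non-nodata cell. The
#' grid, nodata cells, year and cell areas are unchanged.
#'
#' @param map an [lc_map()] whose values are source codes.
#' @param scheme an [lc_scheme()] with a non-`NULL` `reclass_map` covering all
#'   codes present in `map`.
#' @return An `lc_map` with values in scheme ids.
#' @export
reclassify_map <- function(map, scheme) {
  stopifnot(inherits(map, "lc_map"), inherits(scheme, "lc_scheme"))
  if (is.null(scheme$reclass_map)) stop("scheme has no reclass_map")
  v <- map$values
  codes <- v[!is.na(v)]
  known <- as.integer(names(scheme$reclass_map))
  bad <- setdiff(unique(codes), known)
  if (length(bad)) {
    cnt <- sum(codes %in% bad)
    stop("unmapped source code(s) ", paste(sort(bad), collapse = ", "),
         " in ", cnt, " cell(s)")
  }
  idx <- match(v, known)
  out <- map
  out$values <- array(ifelse(is.na(v), NA_integer_,
                             unname(scheme$reclass_map)[idx]), dim = dim(v))
  out$scheme <- scheme
  out
}
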