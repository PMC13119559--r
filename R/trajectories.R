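# Dominant transition pathways, first-to-last trajectory maps, pathway
# budgets and the targeted-transition network.

#' Define a set of named transition pathways
#'
#' A pathway is a named set of ordered (from, to) category pairs (e.g.
#' deforestation = forest -> cropland). No pair may appear in more than one
#' pathway of a set, so every changed cell maps to at most one pathway.
#'
#' @param ... named arguments, each a two-column matrix or data frame of
#'   (from, to) category abbreviations.
#' @return An object of class `pathway_set`: a data frame with columns
#'   `pathway`, `code` (1-based display code), `from`, `to`.
#' @export
pathway_set <- function(...) {
  defs <- list(...)
  if (is.null(names(defs)) || any(!nzchar(names(defs))))
    stop("every pathway must be named")
  rows <- lapply(seq_along(defs), function(i) {
    p <- as.data.frame(defs[[i]], stringsAsFactors = FALSE)
    if (ncol(p) != 2 || !nrow(p)) stop("pathway '", names(defs)[i],
                                       "' must be a non-empty set of pairs")
    data.frame(pathway = names(defs)[i], code = i,
               from = as.character(p[[1]]), to = as.character(p[[2]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(out$from == out$to)) stop("pathway pairs must change category")
  key <- paste(out$from, out$to)
  if (anyDuplicated(key))
    stop("pair ", key[duplicated(key)][1],
         " appears in more than one pathway")
  structure(out, class = c("pathway_set", "data.frame"))
}

#' The six default dominant land-cover transition pathways
#'
#' Deforestation (FST->CRP), Forest Degradation (FST->SHR), Agricultural
#' Expansion (SHR/GRS/BAL->CRP), Wetland Expansion (FST->WET), Shrub
#' Degradation (SHR->GRS) and Desertification (GRS->BAL), on the ten-class
#' Level-1 scheme.
#'
#' @return A [pathway_set()].
#' @export
default_pathways <- function() {
  pathway_set(
    `Deforestation` = cbind("FST", "CRP"),
    `Forest Degradation` = cbind("FST", "SHR"),
    `Agricultural Expansion` = cbind(c("SHR", "GRS", "BAL"), "CRP"),
    `Wetland Expansion` = cbind("FST", "WET"),
    `Shrub Degradation` = cbind("SHR", "GRS"),
    `Desertification` = cbind("GRS", "BAL"))
}

#' Select dominant transitions by stationarity and cumulative area
#'
#' Ranks ordered category pairs that (i) were targeted in at least
#' `ceiling(min_targeted_frac * n_intervals)` intervals and (ii) moved at
#' least `min_area_km2` of area between the first and last dates, by area
#' descending.
#'
#' @param stationarity a [stationarity_table()].
#' @param first_last a [transition_matrix()] cross-tabulating the first
#'   against the last date.
#' @param min_targeted_frac minimum fraction of intervals with targeted
#'   status (default 0.5).
#' @param min_area_km2 minimum first-to-last transition area; default is the
#'   90th percentile of the positive off-diagonal pair areas (top decile).
#' @return Data frame: `from`, `to`, `n_targeted`, `n_intervals`,
#'   `area_km2`, ranked by area descending. May have zero rows.
#' @export
select_dominant_transitions <- function(stationarity, first_last,
                                        min_targeted_frac = 0.5,
                                        min_area_km2 = NULL) {
  cnt <- stationarity$counts
  mm <- unclass_tm(first_last)
  if (!all(unique(c(cnt$from, cnt$to)) %in% rownames(mm)))
    stop("stationarity table and matrix use different schemes")
  if (is.null(min_area_km2)) {
    off <- mm[row(mm) != col(mm)]
    pos <- off[off > 0]
    min_area_km2 <- if (length(pos)) stats::quantile(pos, 0.9, names = FALSE)
                    else Inf
  }
  cnt$area_km2 <- mm[cbind(cnt$from, cnt$to)]
  need <- ceiling(min_targeted_frac * cnt$n_intervals)
  sel <- cnt[cnt$n_targeted >= need & cnt$area_km2 >= min_area_km2, ,
             drop = FALSE]
  sel <- sel[order(-sel$area_km2), c("from", "to", "n_targeted",
                                     "n_intervals", "area_km2")]
  rownames(sel) <- NULL
  sel
}

#' Label a first-to-last trajectory map
#'
#' Compares the first-date and last-date maps cell by cell: unchanged cells
#' are labelled persistence (code 0), cells whose (first, last) pair belongs
#' to a pathway get that pathway's code, any other changed pair is
#' other-change (code -1), and cells nodata at either date stay nodata.
#'
#' @param map_first,map_last [lc_map()] objects on identical grids, in scheme
#'   ids.
#' @param pathways a [pathway_set()].
#' @param scheme the [lc_scheme()] of the maps.
#' @return An object of class `trajectory_map`: `values` (integer code
#'   matrix), `legend` (data frame `code`, `label`), plus `cell_area` and the
#'   two years.
#' @export
label_trajectories <- function(map_first, map_last, pathways, scheme) {
  if (!identical(dim(map_first$values), dim(map_last$values)))
    stop("maps are on different grids")
  labs <- category_labels(scheme)
  J <- length(labs)
  # lookup over all ordered pairs: 0 persistence, -1 other change
  lut <- matrix(-1L, J, J, dimnames = list(labs, labs))
  diag(lut) <- 0L
  lut[cbind(pathways$from, pathways$to)] <- as.integer(pathways$code)
  a <- map_first$values; b <- map_last$values
  out <- array(NA_integer_, dim = dim(a))
  ok <- !is.na(a) & !is.na(b)
  out[ok] <- lut[cbind(a[ok], b[ok])]
  legend <- rbind(
    data.frame(code = 0L, label = "persistence", stringsAsFactors = FALSE),
    data.frame(code = -1L, label = "other change", stringsAsFactors = FALSE),
    unique(data.frame(code = as.integer(pathways$code),
                      label = pathways$pathway, stringsAsFactors = FALSE)))
  structure(list(values = out, legend = legend,
                 cell_area = map_first$cell_area,
                 from_year = map_first$year, to_year = map_last$year),
            class = "trajectory_map")
}

#' @export
print.trajectory_map <- function(x, ...) {
  cat("Trajectory map ", x$from_year, "-", x$to_year, "\n", sep = "")
  tab <- table(factor(x$values, levels = x$legend$code,
                      labels = x$legend$label))
  print(tab)
  invisible(x)
}

#' Write a trajectory map as an ASCII grid with a JSON legend
#'
#' @param tmap a trajectory map from [label_trajectories()].
#' @param path output `.asc` path; the legend goes to `<path>.legend.json`.
#' @param nodata integer code for nodata cells.
#' @return `path`, invisibly.
#' @export
write_trajectory_map <- function(tmap, path, nodata = -9999L) {
  m <- lc_map(tmap$values + 0L, year = tmap$to_year,
              cell_area = tmap$cell_area)
  write_ascii_grid(m, path, nodata = nodata)
  jsonlite::write_json(tmap$legend, paste0(path, ".legend.json"))
  invisible(path)
}

#' Pathway area budget with regional shares
#'
#' Pools each pathway's member-pair areas from per-stratum first-to-last
#' matrices: the continental total per pathway plus each stratum's area and
#' percentage share.
#'
#' @param mats list of per-stratum first-to-last [transition_matrix()]
#'   objects.
#' @param pathways a [pathway_set()].
#' @return Data frame: `pathway`, `stratum`, `area_km2`, `total_km2`,
#'   `share_pct`, `dominant`. Pathways with zero continental area are
#'   omitted.
#' @export
pathway_budget <- function(mats, pathways) {
  strata <- check_interval_mats(mats)
  out <- list()
  for (p in unique(pathways$pathway)) {
    prs <- pathways[pathways$pathway == p, ]
    areas <- vapply(mats, function(m)
      sum(unclass_tm(m)[cbind(prs$from, prs$to)]), numeric(1))
    total <- sum(areas)
    if (total <= 0) next
    cf <- contribution_frame("pathway", interval_id(mats[[1]]), p,
                             strata, unname(areas))
    cf$total_km2 <- total
    out[[p]] <- cf[, c("target", "stratum", "area_km2", "total_km2",
                       "share_pct", "dominant")]
  }
  if (!length(out))
    return(data.frame(pathway = character(), stratum = character(),
                      area_km2 = numeric(), total_km2 = numeric(),
                      share_pct = numeric(), dominant = logical(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  names(res)[names(res) == "target"] <- "pathway"
  rownames(res) <- NULL
  res
}

#' Build the targeted-transition network
#'
#' Nodes are categories sized by their mean class area over the series' time
#' points; directed edges run from the losing to the gaining category for
#' every pair targeted in at least one interval, weighted by the cumulative
#' transition area and annotated with the dominant contributing stratum
#' (pooled over the contributing intervals).
#'
#' @param series a [matrix_series()].
#' @param targeted_only sum edge area over targeted intervals only (default)
#'   or over all intervals.
#' @param min_targeted minimum number of targeted intervals for an edge.
#' @return An object of class `transition_network`: `nodes` (`category`,
#'   `mean_area_km2`) and `edges` (`from`, `to`, `area_km2`, `n_targeted`,
#'   `dominant_stratum`, `dominant_share_pct`).
#' @export
build_network <- function(series, targeted_only = TRUE, min_targeted = 1) {
  st <- stationarity_table(series, "ALL")
  Tn <- n_intervals(series)
  # time-point class areas: start sizes of every interval + end of the last
  labs <- category_labels(series$scheme)
  areas <- sapply(seq_len(Tn), function(t)
    rowSums(unclass_tm(series_matrix(series, t, "ALL"))))
  areas <- cbind(areas, colSums(unclass_tm(series_matrix(series, Tn, "ALL"))))
  nodes <- data.frame(category = labs, mean_area_km2 = rowMeans(areas),
                      row.names = NULL, stringsAsFactors = FALSE)
  sts <- st$statuses
  multi_strata <- length(series$strata) > 1
  edges <- list()
  cnt <- st$counts[st$counts$n_targeted >= min_targeted, , drop = FALSE]
  for (r in seq_len(nrow(cnt))) {
    f <- cnt$from[r]; g <- cnt$to[r]
    rows <- sts[sts$from == f & sts$to == g, ]
    use <- if (targeted_only) rows$status == "targeted" else rep(TRUE, nrow(rows))
    ivs <- rows$interval[use]
    area <- sum(rows$area_km2[use])
    dom <- list(stratum = NA_character_, share_pct = NA_real_)
    if (multi_strata && length(ivs)) {
      pooled <- rowsum(
        unlist(lapply(ivs, function(t) vapply(series$mats[[t]], function(m)
          unclass_tm(m)[f, g], numeric(1)))),
        unlist(lapply(ivs, function(t) names(series$mats[[t]]))))
      tot <- sum(pooled)
      if (tot > 0) {
        ord <- match(rownames(pooled), series$strata)     # declaration order
        pooled <- pooled[order(ord), , drop = FALSE]
        i <- which(pooled[, 1] == max(pooled[, 1]))[1]
        dom <- list(stratum = rownames(pooled)[i],
                    share_pct = pooled[i, 1] / tot * 100)
      }
    }
    edges[[r]] <- data.frame(from = f, to = g, area_km2 = area,
                             n_targeted = cnt$n_targeted[r],
                             dominant_stratum = dom$stratum,
                             dominant_share_pct = dom$share_pct,
                             stringsAsFactors = FALSE)
  }
  edges <- if (length(edges)) do.call(rbind, edges)
           else data.frame(from = character(), to = character(),
                           area_km2 = numeric(), n_targeted = integer(),
                           dominant_stratum = character(),
                           dominant_share_pct = numeric(),
                           stringsAsFactors = FALSE)
  edges <- edges[order(-edges$area_km2), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges),
            class = "transition_network")
}

#' @export
print.transition_network <- function(x, ...) {
  cat("Transition network:", nrow(x$nodes), "nodes,",
      nrow(x$edges), "targeted edges\n")
  if (nrow(x$edges)) print(utils::head(x$edges, 10), row.names = FALSE)
  invisible(x)
}

#' Convert a transition network to an igraph graph
#' @param net a [build_network()] result.
#' @return An `igraph` directed graph with node `mean_area_km2` and edge
#'   `area_km2` attributes.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                vertices = net$nodes)
}

#' Write a transition network as CSV pair + GraphML
#'
#' @param net a [build_network()] result.
#' @param dir output directory (created if needed); writes
#'   `network_nodes.csv`, `network_edges.csv`, `network.graphml`.
#' @return `dir`, invisibly.
#' @export
write_network <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(net$nodes, file.path(dir, "network_nodes.csv"),
                   row.names = FALSE)
  utils::write.csv(net$edges, file.path(dir, "network_edges.csv"),
                   row.names = FALSE)
  if (nrow(net$edges))
    igraph::write_graph(as_igraph(net),
                        file.path(dir, "network.graphml"), format = "graphml")
  invisible(dir)
}
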