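#' Stratified Intensity Analysis of a matrix series
#'
#' The package's central fit: runs the full three-level Intensity Analysis on
#' a series of per-stratum transition matrices and, when more than one
#' stratum is present, the regional decomposition of every statistic.
#'
#' @param series a [matrix_series()].
#' @param min_targeted_frac threshold passed to
#'   [select_dominant_transitions()].
#' @param min_area_km2 absolute area threshold for dominant transitions;
#'   `NULL` uses the top decile of first-to-last pair areas.
#' @param pathways optional [pathway_set()] for the pathway budget; `NULL`
#'   skips it (e.g. when the scheme lacks the default pathway categories).
#' @return An object of class `intensity_analysis` with components:
#'   `series`, `U` (continental uniform intensity, %/yr), `intervals`
#'   (per-interval table with tempo flags), `categories` (per interval x
#'   category gain/loss table), `transitions` (per interval x pair table),
#'   `stationarity` (a [stationarity_table()]), `contributions` (stratified
#'   decomposition; `NULL` for single-stratum input), `dominant` (ranked
#'   dominant transitions), `first_last` (summed-interval proxy matrix, see
#'   Details), `budget` (pathway budget or `NULL`) and `network`.
#' @details With matrices as input there is no per-cell first-vs-last
#'   cross-tabulation; the `first_last` matrix used for dominant-transition
#'   area ranking chains the interval flows by category bookkeeping
#'   (interval matrices multiplied as conditional flows). When maps are
#'   available, prefer [crosstab()] of the first and last maps and pass the
#'   result to [select_dominant_transitions()] directly.
#' @export
intensity_analysis <- function(series, min_targeted_frac = 0.5,
                               min_area_km2 = NULL, pathways = NULL) {
  stopifnot(inherits(series, "matrix_series"))
  ui <- uniform_intensity(series, "ALL")
  cats <- do.call(rbind, lapply(seq_len(n_intervals(series)), function(t) {
    m <- series_matrix(series, t, "ALL")
    ci <- category_intensities(m)
    cbind(data.frame(interval = t, from = attr(m, "from_year"),
                     to = attr(m, "to_year")), ci)
  }))
  stat <- stationarity_table(series, "ALL")
  multi <- length(series$strata) > 1
  contrib <- if (multi) contribution_table(series) else NULL
  fl <- chained_first_last(series)
  dom <- select_dominant_transitions(stat, fl, min_targeted_frac,
                                     min_area_km2)
  budget <- NULL
  if (!is.null(pathways) && multi) {
    fl_strata <- lapply(series$strata, function(s) chained_first_last(series, s))
    budget <- pathway_budget(fl_strata, pathways)
  }
  structure(list(series = series, U = ui$U, intervals = ui$intervals,
                 categories = cats, transitions = stat$statuses,
                 stationarity = stat, contributions = contrib,
                 dominant = dom, first_last = fl, budget = budget,
                 network = build_network(series)),
            class = "intensity_analysis")
}

#' First-to-last matrix chained from interval matrices
#'
#' Approximates the direct first-date vs last-date cross-tabulation by
#' composing the per-interval conditional transition proportions (each
#' interval matrix row-normalised, then chained). Exact when every cell's
#' path is Markovian in the aggregate; with map input, prefer a direct
#' [crosstab()].
#'
#' @param series a [matrix_series()].
#' @param stratum stratum label or `"ALL"`.
#' @return A [transition_matrix()] spanning the full series.
#' @export
chained_first_last <- function(series, stratum = "ALL") {
  m1 <- series_matrix(series, 1, stratum)
  start <- rowSums(unclass_tm(m1))
  P <- diag(nrow(m1))
  for (t in seq_len(n_intervals(series))) {
    m <- unclass_tm(series_matrix(series, t, stratum))
    rs <- rowSums(m)
    cond <- m / ifelse(rs > 0, rs, 1)
    zi <- which(rs == 0)
    cond[cbind(zi, zi)] <- 1                 # absent category: stays absent
    P <- P %*% cond
  }
  mat <- diag(start) %*% P
  dimnames(mat) <- dimnames(m1)
  transition_matrix(mat, series$intervals$from[1],
                    series$intervals$to[n_intervals(series)], stratum)
}

#' @export
print.intensity_analysis <- function(x, ...) {
  iv <- x$intervals
  cat("Stratified Intensity Analysis: ", nrow(iv), " interval(s), ",
      iv$from[1], "-", iv$to[nrow(iv)], ", strata: ",
      paste(x$series$strata, collapse = ", "), "\n", sep = "")
  cat(sprintf("Uniform annual change intensity U = %.4f %%/yr\n", x$U))
  cat("Intervals:\n")
  print(iv[, c("from", "to", "duration", "gross_area_km2", "gross_pct",
               "St_pct_yr", "tempo")], row.names = FALSE, digits = 4)
  cat("Dominant transitions (targeted frequency + cumulative area):\n")
  if (nrow(x$dominant)) print(x$dominant, row.names = FALSE, digits = 4)
  else cat("  none selected\n")
  invisible(x)
}

#' @export
summary.intensity_analysis <- function(object, ...) {
  cats <- object$categories
  agg <- do.call(rbind, lapply(split(cats, cats$category), function(d)
    data.frame(category = d$category[1],
               mean_G_pct_yr = mean(d$G_pct_yr, na.rm = TRUE),
               mean_L_pct_yr = mean(d$L_pct_yr, na.rm = TRUE),
               n_active_gain = sum(d$gain_status == "active"),
               n_active_loss = sum(d$loss_status == "active"),
               net_km2 = sum(d$gain_area_km2 - d$loss_area_km2),
               stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  out <- list(U = object$U, intervals = object$intervals,
              category_summary = agg,
              stationarity_counts = object$stationarity$counts,
              dominant = object$dominant)
  class(out) <- "summary.intensity_analysis"
  out
}

#' @export
print.summary.intensity_analysis <- function(x, ...) {
  cat(sprintf("Uniform annual change intensity U = %.4f %%/yr\n", x$U))
  cat(sum(x$intervals$tempo == "fast"), "fast /",
      sum(x$intervals$tempo == "slow"), "slow interval(s)\n")
  cat("\nCategory behaviour across intervals:\n")
  print(x$category_summary, row.names = FALSE, digits = 4)
  cat("\nMost persistently targeted transitions:\n")
  top <- utils::head(x$stationarity_counts[x$stationarity_counts$n_targeted > 0, ], 8)
  if (nrow(top)) print(top, row.names = FALSE, digits = 4)
  else cat("  none\n")
  invisible(x)
}

#' Plot method for an Intensity Analysis
#'
#' `which = "intervals"`: per-interval gross change bars with the S_t line
#' against the uniform baseline U. `which = "categories"`: gain/loss
#' intensity bars per category for one interval. `which = "stationarity"`:
#' the targeted/avoided status grid across intervals. `which = "network"`:
#' the targeted-transition network (igraph layout).
#'
#' @param x an `intensity_analysis`.
#' @param which one of `"intervals"`, `"categories"`, `"stationarity"`,
#'   `"network"`.
#' @param interval interval index for `which = "categories"`.
#' @param ... passed to the underlying plotting calls.
#' @return `x`, invisibly.
#' @export
plot.intensity_analysis <- function(x, which = "intervals", interval = 1,
                                    ...) {
  which <- match.arg(which, c("intervals", "categories", "stationarity",
                              "network"))
  iv <- x$intervals
  if (which == "intervals") {
    lab <- paste0(iv$from, "-", iv$to)
    op <- graphics::par(mar = c(6, 4, 2, 4))
    on.exit(graphics::par(op))
    bp <- graphics::barplot(iv$gross_pct, names.arg = lab, las = 2,
                            ylab = "gross change (% of map)",
                            col = "grey80", ...)
    graphics::par(new = TRUE)
    graphics::plot(bp, iv$St_pct_yr, type = "b", pch = 19, axes = FALSE,
                   xlab = "", ylab = "", ylim = c(0, max(iv$St_pct_yr, x$U) * 1.1))
    graphics::abline(h = x$U, lty = 2)
    graphics::axis(4)
    graphics::mtext("annual intensity (%/yr)", side = 4, line = 2)
  } else if (which == "categories") {
    d <- x$categories[x$categories$interval == interval, ]
    h <- rbind(gain = d$G_pct_yr, loss = -d$L_pct_yr)
    graphics::barplot(h, beside = TRUE, names.arg = d$category, las = 2,
                      col = c("forestgreen", "firebrick"),
                      ylab = "intensity (%/yr; loss shown negative)", ...)
    St <- iv$St_pct_yr[interval]
    graphics::abline(h = c(St, -St), lty = 2)
    graphics::legend("topright", c("gain", "loss", "S_t"), bty = "n",
                     fill = c("forestgreen", "firebrick", NA),
                     border = c("black", "black", NA),
                     lty = c(NA, NA, 2))
  } else if (which == "stationarity") {
    st <- x$stationarity$statuses
    pairs <- unique(st[, c("from", "to")])
    key <- paste(pairs$from, pairs$to)
    z <- matrix(0, nrow(pairs), max(st$interval))
    lev <- c(avoided = -1, equal = 0, undefined = 0, targeted = 1)
    z[cbind(match(paste(st$from, st$to), key), st$interval)] <- lev[st$status]
    op <- graphics::par(mar = c(4, 7, 2, 1))
    on.exit(graphics::par(op))
    graphics::image(seq_len(ncol(z)), seq_len(nrow(z)), t(z),
                    col = c("grey60", "white", "steelblue"),
                    breaks = c(-1.5, -0.5, 0.5, 1.5),
                    xlab = "interval", ylab = "", axes = FALSE, ...)
    graphics::axis(1, at = seq_len(ncol(z)))
    graphics::axis(2, at = seq_len(nrow(z)),
                   labels = paste(pairs$from, "→", pairs$to),
                   las = 2, cex.axis = 0.6)
  } else {
    net <- x$network
    if (!nrow(net$edges)) {
      graphics::plot.new()
      graphics::title("no targeted transitions")
    } else {
      g <- as_igraph(net)
      sz <- igraph::V(g)$mean_area_km2
      wd <- igraph::E(g)$area_km2
      igraph::plot.igraph(
        g, vertex.size = 10 + 20 * sz / max(sz),
        edge.width = 0.5 + 4 * wd / max(wd),
        edge.arrow.size = 0.4, layout = igraph::layout_in_circle(g), ...)
    }
  }
  invisible(x)
}

#' Write the result tables of an analysis to CSV
#'
#' Emits `intervals.csv`, `categories.csv`, `transitions.csv`,
#' `stationarity.csv` and (multi-stratum input) `contributions.csv`, plus
#' `pathway_budget.csv` and the network files when present. All areas km^2,
#' intensities %/yr.
#'
#' @param x an `intensity_analysis`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) utils::write.csv(df, file.path(dir, f),
                                        row.names = FALSE)
  w(x$intervals, "intervals.csv")
  w(x$categories, "categories.csv")
  w(x$transitions, "transitions.csv")
  w(x$stationarity$counts, "stationarity.csv")
  if (!is.null(x$contributions)) w(x$contributions, "contributions.csv")
  if (!is.null(x$budget)) w(x$budget, "pathway_budget.csv")
  w(x$dominant, "dominant_transitions.csv")
  write_network(x$network, dir)
  invisible(dir)
}
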