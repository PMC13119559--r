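# Intensity Analysis core: interval, category and transition levels.
#
# All intensities are in percent per year. Classification uses strict
# inequalities against the relevant uniform baseline; exact equality gets its
# own "equal" status, and zero denominators yield NA intensity with status
# "undefined" (e.g. a category absent from the map at the relevant date).

status_vs <- function(x, baseline, above, below) {
  ifelse(is.na(x) | is.na(baseline), "undefined",
         ifelse(x > baseline, above, ifelse(x < baseline, below, "equal")))
}

#' Interval-level change intensity
#'
#' The annual change intensity S_t of one interval: the off-diagonal (change)
#' area as a fraction of the total mapped area, divided by the interval
#' duration.
#'
#' @param m a [transition_matrix()].
#' @return A one-row data frame: `from`, `to`, `duration`, `stratum`,
#'   `gross_area_km2`, `gross_pct` (percent of the map that changed),
#'   `St_pct_yr` (annual change intensity, %/yr).
#' @export
interval_intensity <- function(m) {
  total <- sum(m)
  if (total <= 0) stop("transition matrix has zero total area")
  gross <- total - sum(diag(unclass_tm(m)))
  dy <- duration_years(m)
  data.frame(from = attr(m, "from_year"), to = attr(m, "to_year"),
             duration = dy, stratum = attr(m, "stratum"),
             gross_area_km2 = gross, gross_pct = gross / total * 100,
             St_pct_yr = gross / dy / total * 100,
             stringsAsFactors = FALSE)
}

#' Uniform intensity and fast/slow interval classification
#'
#' The uniform annual change intensity U is the rate that would hold if all
#' change over the study span were spread evenly in time: total change area
#' over all intervals divided by the duration-weighted total map area.
#' Intervals with S_t above U are "fast", below "slow".
#'
#' @param series a [matrix_series()].
#' @param stratum stratum label or `"ALL"`.
#' @return A list: `U` (%/yr) and `intervals`, the per-interval table of
#'   [interval_intensity()] with a `tempo` column (`fast`/`slow`/`equal`).
#' @export
uniform_intensity <- function(series, stratum = "ALL") {
  tabs <- lapply(seq_len(n_intervals(series)), function(t)
    interval_intensity(series_matrix(series, t, stratum)))
  tab <- do.call(rbind, tabs)
  totals <- vapply(seq_len(n_intervals(series)), function(t)
    sum(series_matrix(series, t, stratum)), numeric(1))
  U <- sum(tab$gross_area_km2) / sum(tab$duration * totals) * 100
  tab$U_pct_yr <- U
  tab$tempo <- status_vs(tab$St_pct_yr, U, "fast", "slow")
  list(U = U, intervals = tab)
}

#' Category-level gain and loss intensities
#'
#' For each category: the annual gross gain intensity G (gain area per year
#' relative to the category's end size) and gross loss intensity L (loss area
#' per year relative to its start size), classified active/dormant by strict
#' comparison with the interval intensity S_t.
#'
#' @param m a [transition_matrix()].
#' @param St interval intensity to classify against; computed from `m` when
#'   `NULL`.
#' @return A data frame, one row per category: `category`, `start_area_km2`,
#'   `end_area_km2`, `gain_area_km2`, `loss_area_km2`, `G_pct_yr`, `L_pct_yr`,
#'   `gain_status`, `loss_status`.
#' @export
category_intensities <- function(m, St = NULL) {
  if (is.null(St)) St <- interval_intensity(m)$St_pct_yr
  mm <- unclass_tm(m)
  dy <- duration_years(m)
  start <- rowSums(mm); end <- colSums(mm); pers <- diag(mm)
  gain <- end - pers; loss <- start - pers
  G <- ifelse(end > 0, gain / dy / end * 100, NA_real_)
  L <- ifelse(start > 0, loss / dy / start * 100, NA_real_)
  data.frame(category = rownames(mm),
             start_area_km2 = start, end_area_km2 = end,
             gain_area_km2 = gain, loss_area_km2 = loss,
             G_pct_yr = G, L_pct_yr = L,
             gain_status = status_vs(G, St, "active", "dormant"),
             loss_status = status_vs(L, St, "active", "dormant"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Transition-level profile of a gaining category
#'
#' For a gaining category n, the intensity R of the transition from each other
#' category m (area gained from m per year, relative to m's start size) is
#' compared with the uniform transition intensity W: the rate that would hold
#' if n gained uniformly from all non-n categories in proportion to their
#' availability. R > W marks the transition targeted, R < W avoided.
#'
#' @param m a [transition_matrix()].
#' @param gaining category abbreviation of the gaining category n.
#' @return A list: `gaining`, `W_pct_yr`, and `transitions`, a data frame with
#'   one row per losing category: `from`, `to`, `area_km2`, `start_area_km2`,
#'   `R_pct_yr`, `status` (`targeted`/`avoided`/`equal`/`undefined`).
#' @export
transition_profile <- function(m, gaining) {
  labs <- rownames(m)
  if (!gaining %in% labs) stop("unknown category: ", gaining)
  mm <- unclass_tm(m)
  dy <- duration_years(m)
  others <- setdiff(labs, gaining)
  start <- rowSums(mm)[others]
  gains <- mm[others, gaining]
  denomW <- sum(start)
  W <- if (denomW > 0) sum(gains) / dy / denomW * 100 else NA_real_
  R <- ifelse(start > 0, gains / dy / start * 100, NA_real_)
  tab <- data.frame(from = others, to = gaining, area_km2 = unname(gains),
                    start_area_km2 = unname(start), R_pct_yr = unname(R),
                    status = status_vs(unname(R), W, "targeted", "avoided"),
                    stringsAsFactors = FALSE)
  list(gaining = gaining, W_pct_yr = W, transitions = tab)
}

#' Full transition-level table for one matrix
#'
#' [transition_profile()] applied to every gaining category, bound into one
#' data frame with a `W_pct_yr` column.
#'
#' @param m a [transition_matrix()].
#' @return Data frame with one row per ordered (from, to) pair, from != to.
#' @export
transition_table <- function(m) {
  out <- lapply(rownames(m), function(n) {
    p <- transition_profile(m, n)
    p$transitions$W_pct_yr <- p$W_pct_yr
    p$transitions
  })
  do.call(rbind, out)
}

#' Cross-interval stationarity of transition statuses
#'
#' Tabulates the targeted/avoided status of every ordered category pair in
#' every interval, and counts per pair how many intervals were targeted. A
#' transition is stationary when its status is constant across intervals.
#'
#' @param series a [matrix_series()].
#' @param stratum stratum label or `"ALL"`.
#' @return A list of class `stationarity_table`: `statuses` (long data frame:
#'   `from`, `to`, `interval`, `from_year`, `to_year`, `area_km2`, `status`)
#'   and `counts` (per pair: `n_targeted`, `n_avoided`, `n_undefined`,
#'   `n_intervals`).
#' @export
stationarity_table <- function(series, stratum = "ALL") {
  Tm1 <- n_intervals(series)
  long <- do.call(rbind, lapply(seq_len(Tm1), function(t) {
    m <- series_matrix(series, t, stratum)
    tab <- transition_table(m)
    tab$interval <- t
    tab$from_year <- attr(m, "from_year")
    tab$to_year <- attr(m, "to_year")
    tab
  }))
  counts <- do.call(rbind, lapply(split(long, list(long$from, long$to),
                                        drop = TRUE), function(d)
    data.frame(from = d$from[1], to = d$to[1],
               n_targeted = sum(d$status == "targeted"),
               n_avoided = sum(d$status == "avoided"),
               n_undefined = sum(d$status == "undefined"),
               n_intervals = nrow(d),
               cum_area_km2 = sum(d$area_km2),
               stringsAsFactors = FALSE)))
  counts <- counts[order(-counts$n_targeted, -counts$cum_area_km2), ]
  rownames(counts) <- NULL
  structure(list(statuses = long, counts = counts, stratum = stratum),
            class = "stationarity_table")
}

#' @export
print.stationarity_table <- function(x, ...) {
  cat("Stationarity table [", x$stratum, "]: ",
      length(unique(paste(x$counts$from, x$counts$to))), " pairs over ",
      x$counts$n_intervals[1], " interval(s)\n", sep = "")
  top <- utils::head(x$counts[x$counts$n_targeted > 0, ], 10)
  if (nrow(top)) {
    cat("Most persistently targeted transitions:\n")
    print(top, row.names = FALSE)
  } else cat("No targeted transitions.\n")
  invisible(x)
}
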