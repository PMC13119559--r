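# Stratified (regional) decomposition of the continental change budget.
#
# Every contribution is an area share: the stratum's area for the quantity
# divided by the sum over strata, times 100. When the continental denominator
# is zero the shares are undefined (NA) and flagged, never forced to zero.

contribution_frame <- function(level, interval, target, strata, areas) {
  total <- sum(areas)
  share <- if (total > 0) areas / total * 100 else rep(NA_real_, length(areas))
  dom <- if (total > 0) {
    i <- which(share == max(share))[1]      # ties: first-declared stratum
    strata[i]
  } else NA_character_
  data.frame(level = level, interval = interval, target = target,
             stratum = strata, area_km2 = areas, share_pct = share,
             dominant = !is.na(dom) & strata == dom,
             stringsAsFactors = FALSE)
}

check_interval_mats <- function(mats) {
  if (!length(mats)) stop("no per-stratum matrices supplied")
  labs <- vapply(mats, attr, character(1), which = "stratum")
  if (anyDuplicated(labs)) stop("duplicate stratum labels")
  ref <- mats[[1]]
  for (m in mats)
    if (attr(m, "from_year") != attr(ref, "from_year") ||
        attr(m, "to_year") != attr(ref, "to_year"))
      stop("matrices cover different intervals")
  labs
}

interval_id <- function(m)
  paste0(attr(m, "from_year"), "-", attr(m, "to_year"))

#' Regional contributions to interval-level gross change
#'
#' Decomposes an interval's continental gross change area into the percentage
#' contributed by each stratum.
#'
#' @param mats list of per-stratum [transition_matrix()] objects for one
#'   interval.
#' @return A contribution data frame (`level`, `interval`, `target`,
#'   `stratum`, `area_km2`, `share_pct`, `dominant`); shares are `NA` when no
#'   change occurred anywhere.
#' @export
interval_contributions <- function(mats) {
  strata <- check_interval_mats(mats)
  areas <- vapply(mats, function(m) sum(m) - sum(diag(unclass_tm(m))),
                  numeric(1))
  contribution_frame("interval", interval_id(mats[[1]]), "gross_change",
                     strata, unname(areas))
}

#' Regional contributions to a category's gross gain or loss
#'
#' Decomposes the continental gross gain (or loss) area of one category into
#' per-stratum percentage shares.
#'
#' @param mats list of per-stratum [transition_matrix()] objects for one
#'   interval.
#' @param category category abbreviation.
#' @param side `"gain"` (column sum minus diagonal) or `"loss"` (row sum minus
#'   diagonal).
#' @return A contribution data frame; shares `NA` when the continental
#'   gain/loss of the category is zero.
#' @export
category_contributions <- function(mats, category, side = c("gain", "loss")) {
  side <- match.arg(side)
  strata <- check_interval_mats(mats)
  if (!category %in% rownames(mats[[1]]))
    stop("unknown category: ", category)
  areas <- vapply(mats, function(m) {
    mm <- unclass_tm(m)
    if (side == "gain") sum(mm[, category]) - mm[category, category]
    else sum(mm[category, ]) - mm[category, category]
  }, numeric(1))
  contribution_frame(side, interval_id(mats[[1]]),
                     category, strata, unname(areas))
}

#' Regional contributions to a specific transition
#'
#' Decomposes the continental area of the transition m -> n into per-stratum
#' percentage shares.
#'
#' @param mats list of per-stratum [transition_matrix()] objects for one
#'   interval.
#' @param from,to losing and gaining category abbreviations.
#' @return A contribution data frame; shares `NA` when the transition has zero
#'   area continentally.
#' @export
transition_contributions <- function(mats, from, to) {
  strata <- check_interval_mats(mats)
  labs <- rownames(mats[[1]])
  if (!from %in% labs || !to %in% labs)
    stop("unknown category in pair ", from, "->", to)
  areas <- vapply(mats, function(m) unclass_tm(m)[from, to], numeric(1))
  contribution_frame("transition", interval_id(mats[[1]]),
                     paste0(from, "->", to), strata, unname(areas))
}

#' Dominant stratum of a contribution table
#'
#' The stratum with the largest share; exact ties are broken by declaration
#' order (the first row wins), making the result deterministic.
#'
#' @param tbl a contribution data frame from one of the `*_contributions()`
#'   functions (one target).
#' @return A list: `stratum` (label) and `share_pct`.
#' @export
dominant_stratum <- function(tbl) {
  if (all(is.na(tbl$share_pct)))
    stop("all contributions undefined: zero continental denominator")
  i <- which(tbl$share_pct == max(tbl$share_pct, na.rm = TRUE))[1]
  list(stratum = tbl$stratum[i], share_pct = tbl$share_pct[i])
}

#' Full contribution table for a series
#'
#' Builds the complete stratified decomposition across intervals: interval
#' gross-change shares, per-category gain and loss shares, and per-pair
#' transition shares.
#'
#' @param series a [matrix_series()] with at least two strata.
#' @param transitions `"all"` for every ordered pair, or a two-column matrix /
#'   data frame of (from, to) abbreviations to restrict to.
#' @return One data frame in the [interval_contributions()] layout.
#' @export
contribution_table <- function(series, transitions = "all") {
  labs <- category_labels(series$scheme)
  pairs <- if (identical(transitions, "all")) {
    g <- expand.grid(from = labs, to = labs, stringsAsFactors = FALSE)
    g[g$from != g$to, ]
  } else as.data.frame(transitions, stringsAsFactors = FALSE)
  out <- list()
  for (t in seq_len(n_intervals(series))) {
    mats <- unname(series$mats[[t]])
    out[[length(out) + 1]] <- interval_contributions(mats)
    for (cat in labs) {
      out[[length(out) + 1]] <- category_contributions(mats, cat, "gain")
      out[[length(out) + 1]] <- category_contributions(mats, cat, "loss")
    }
    for (r in seq_len(nrow(pairs)))
      out[[length(out) + 1]] <-
        transition_contributions(mats, pairs[r, 1], pairs[r, 2])
  }
  do.call(rbind, out)
}
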