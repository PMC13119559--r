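# Stratified Markov-chain landscape generator.
#
# Each stratum has an annual row-stochastic transition kernel K; over an
# interval of dY years a cell's category evolves by K^dY, independently of
# its neighbours (Intensity Analysis consumes only the matrices, which are
# insensitive to spatial arrangement). The landscape is closed: per-stratum
# totals are exactly constant over time.

mat_pow <- function(K, n) {
  out <- diag(nrow(K))
  P <- K
  while (n > 0) {
    if (n %% 2 == 1) out <- out %*% P
    P <- P %*% P
    n <- n %/% 2
  }
  out
}

check_kernel <- function(K, J) {
  if (!is.matrix(K) || nrow(K) != J || ncol(K) != J)
    stop("kernel must be a ", J, "x", J, " matrix")
  if (any(K < 0) || any(K > 1)) stop("kernel probabilities must be in [0, 1]")
  if (any(abs(rowSums(K) - 1) > 1e-12))
    stop("kernel rows must sum to 1 (non-stochastic kernel)")
  invisible(K)
}

#' Configuration for the stratified landscape simulator
#'
#' @param scheme an [lc_scheme()] (J categories).
#' @param strata character stratum labels (K strata).
#' @param kernels list of J x J annual row-stochastic kernels, one per
#'   stratum (recycled if one is given).
#' @param init list of initial category proportions (length J, summing to 1),
#'   one per stratum (recycled if one is given).
#' @param time_points strictly increasing map years; the default is the
#'   nine-date 1985-2022 schedule with a final two-year interval.
#' @param dims cells per stratum grid as `c(nrow, ncol)`.
#' @param cell_area km^2 per cell.
#' @param boosts optional list of boost specs, each
#'   `list(stratum=, from=, to=, factor=)`, applied via [inject_target()].
#' @param seed integer seed; per-stratum substreams are derived from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(scheme, strata, kernels, init,
                       time_points = c(1985, 1990, 1995, 2000, 2005,
                                       2010, 2015, 2020, 2022),
                       dims = c(120, 120), cell_area = 1, boosts = NULL,
                       seed = 1L) {
  J <- n_categories(scheme)
  if (is.matrix(kernels)) kernels <- list(kernels)
  if (length(kernels) == 1) kernels <- rep(kernels, length(strata))
  if (length(kernels) != length(strata))
    stop("need one kernel per stratum")
  for (K in kernels) check_kernel(K, J)
  if (is.numeric(init)) init <- list(init)
  if (length(init) == 1) init <- rep(init, length(strata))
  for (p in init) {
    if (length(p) != J || any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop("initial proportions must be length J, non-negative, sum to 1")
  }
  if (any(diff(time_points) <= 0))
    stop("time points must be strictly increasing")
  if (length(time_points) < 2) stop("need at least two time points")
  cfg <- structure(
    list(scheme = scheme, strata = as.character(strata),
         kernels = stats::setNames(kernels, strata),
         init = stats::setNames(init, strata),
         time_points = as.integer(time_points),
         dims = as.integer(unlist(dims)), cell_area = cell_area,
         seed = as.integer(seed)),
    class = "sim_config")
  for (b in boosts)
    cfg <- inject_target(cfg, b$stratum, b$from, b$to, b$factor)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config: ", n_categories(x$scheme), " categories, ",
      length(x$strata), " strata (", paste(x$strata, collapse = ", "),
      "), ", length(x$time_points), " time points ",
      x$time_points[1], "-", x$time_points[length(x$time_points)],
      ", grid ", x$dims[1], "x", x$dims[2], " per stratum, seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}

#' Boost one kernel entry to create a ground-truth targeted transition
#'
#' Multiplies the annual probability of the (from, to) transition in one
#' stratum's kernel by `factor` and restores the row sum by adjusting the
#' diagonal; all other entries are unchanged.
#'
#' @param config a [sim_config()].
#' @param stratum stratum label.
#' @param from,to category abbreviations of the boosted pair.
#' @param factor multiplicative factor > 0; the adjusted diagonal must stay
#'   non-negative.
#' @return The modified `sim_config`.
#' @export
inject_target <- function(config, stratum, from, to, factor) {
  if (factor <= 0) stop("boost factor must be positive")
  labs <- category_labels(config$scheme)
  m <- match(from, labs); n <- match(to, labs)
  if (is.na(m) || is.na(n)) stop("unknown category in pair ", from, "->", to)
  if (m == n) stop("cannot boost a diagonal entry")
  k <- match(stratum, config$strata)
  if (is.na(k)) stop("unknown stratum: ", stratum)
  K <- config$kernels[[k]]
  delta <- K[m, n] * (factor - 1)
  if (K[m, n] * factor > 1 || K[m, m] - delta < 0)
    stop("boost infeasible: adjusted diagonal would be negative")
  K[m, n] <- K[m, n] * factor
  K[m, m] <- K[m, m] - delta
  config$kernels[[k]] <- K
  config
}

#' Exact expected transition matrix under the simulator's law
#'
#' The deterministic oracle for parameter recovery: for interval t in stratum
#' k, the expected area matrix is `diag(start areas) %*% K^dY`, where the
#' start areas follow from propagating the initial composition through the
#' preceding intervals.
#'
#' @param config a [sim_config()].
#' @param interval interval index (1-based).
#' @param stratum stratum label.
#' @return A [transition_matrix()] of expected areas.
#' @export
expected_matrix <- function(config, interval, stratum) {
  k <- match(stratum, config$strata)
  if (is.na(k)) stop("unknown stratum: ", stratum)
  tp <- config$time_points
  if (interval < 1 || interval > length(tp) - 1) stop("interval out of range")
  K <- check_kernel(config$kernels[[k]], n_categories(config$scheme))
  total <- prod(config$dims) * config$cell_area
  comp <- config$init[[k]] * total
  if (interval > 1)
    comp <- as.vector(comp %*% mat_pow(K, tp[interval] - tp[1]))
  dy <- tp[interval + 1] - tp[interval]
  mat <- diag(comp) %*% mat_pow(K, dy)
  labs <- category_labels(config$scheme)
  dimnames(mat) <- list(labs, labs)
  transition_matrix(mat, tp[interval], tp[interval + 1], stratum)
}

stratum_seed <- function(seed, k) (seed %% 1000000L) * 1009L + 7919L * k

#' Simulate a stratified multi-temporal categorical landscape
#'
#' Generates one grid per stratum and time point. The initial map realises
#' the configured composition exactly (deterministic rounded allocation,
#' randomly placed); each subsequent map evolves every cell independently by
#' the stratum kernel raised to the interval duration. Per-stratum substream
#' seeds are derived deterministically from the global seed, so results are
#' reproducible and independent of stratum evaluation order.
#'
#' @param config a [sim_config()].
#' @return A list: `maps` (`maps[[time]][[stratum]]`, each an [lc_map()]),
#'   `strata` labels, and `series`, the [matrix_series()] of per-stratum
#'   cross-tabulations of the generated maps.
#' @export
simulate_series <- function(config) {
  J <- n_categories(config$scheme)
  tp <- config$time_points
  ncell <- prod(config$dims)
  if (ncell < J) stop("grid too small for requested composition")
  maps <- lapply(seq_along(tp), function(i) list())
  mats <- list()
  for (k in seq_along(config$strata)) {
    s <- config$strata[k]
    K <- config$kernels[[k]]
    set.seed(stratum_seed(config$seed, k))
    # exact composition: largest-remainder allocation, random placement
    want <- config$init[[k]] * ncell
    n0 <- floor(want)
    rem <- ncell - sum(n0)
    if (rem > 0) {
      extra <- order(want - n0, decreasing = TRUE)[seq_len(rem)]
      n0[extra] <- n0[extra] + 1
    }
    state <- sample(rep.int(seq_len(J), n0))
    for (i in seq_along(tp)) {
      maps[[i]][[s]] <- lc_map(matrix(state, config$dims[1], config$dims[2]),
                               year = tp[i], cell_area = config$cell_area,
                               scheme = config$scheme)
      if (i == length(tp)) break
      P <- mat_pow(K, tp[i + 1] - tp[i])
      nxt <- integer(ncell)
      for (j in seq_len(J)) {
        idx <- which(state == j)
        if (length(idx))
          nxt[idx] <- sample.int(J, length(idx), replace = TRUE,
                                 prob = P[j, ])
      }
      state <- nxt
    }
    for (t in seq_len(length(tp) - 1))
      mats[[length(mats) + 1]] <-
        crosstab(maps[[t]][[s]], maps[[t + 1]][[s]], config$scheme,
                 strata = NULL, stratum = NULL) |>
        (\(m) transition_matrix(unclass_tm(m), attr(m, "from_year"),
                                attr(m, "to_year"), s))()
  }
  list(maps = maps, strata = config$strata,
       series = matrix_series(mats, config$scheme))
}

#' Default African-style simulation configuration
#'
#' Emulates the design of a continental multi-decadal analysis: the ten-class
#' Level-1 scheme, five strata (EAF, MED, SAF, SAH, WAF), nine time points
#' (1985-2020 every 5 years, then 2022). Per-stratum annual kernels
#' distribute each category's off-diagonal mass in proportion to the other
#' categories' initial availability, with per-stratum annual change rates
#' graded so SAF is the most dynamic and SAH/MED near-stagnant; the resulting
#' continental uniform intensity is of order 1 %/yr.
#'
#' @param seed integer seed.
#' @param dims cells per stratum.
#' @param boosts optional boost specs passed to [sim_config()].
#' @return A [sim_config()].
#' @export
default_sim_config <- function(seed = 1L, dims = c(120, 120), boosts = NULL) {
  scheme <- glc_level1_scheme()
  strata <- c("EAF", "MED", "SAF", "SAH", "WAF")
  # initial composition: vegetated classes dominant, minor classes small
  comp <- list(
    EAF = c(0.14, 0.20, 0.22, 0.22, 0.01, 0.04, 0.02, 0.10, 0.04, 0.01),
    MED = c(0.10, 0.04, 0.08, 0.10, 0.00, 0.01, 0.02, 0.60, 0.05, 0.00),
    SAF = c(0.10, 0.28, 0.30, 0.20, 0.00, 0.04, 0.01, 0.04, 0.03, 0.00),
    SAH = c(0.04, 0.01, 0.05, 0.12, 0.00, 0.01, 0.01, 0.74, 0.02, 0.00),
    WAF = c(0.18, 0.24, 0.20, 0.24, 0.00, 0.05, 0.02, 0.04, 0.03, 0.00))
  rate <- c(EAF = 0.011, MED = 0.004, SAF = 0.016, SAH = 0.003, WAF = 0.008)
  kernels <- lapply(strata, function(s)
    availability_kernel(comp[[s]], rate[[s]]))
  sim_config(scheme, strata, kernels, unname(comp[strata]),
             dims = dims, cell_area = 1, boosts = boosts, seed = seed)
}

#' Availability-proportional annual kernel
#'
#' Builds the neutral annual kernel `K[m, n] = rate * shares[n]` (for
#' `m != n`), under which every losing category feeds a gaining category at
#' the same per-area rate: the transition intensity R equals the uniform
#' intensity W in expectation for every pair, so observed targeted/avoided
#' statuses are pure sampling noise — the null case for recovery tests.
#'
#' @param shares destination-category shares (length J, summing to 1).
#' @param rate scale of the annual change probability; a cell of category m
#'   changes with annual probability `rate * (1 - shares[m])`.
#' @return A J x J row-stochastic matrix.
#' @export
availability_kernel <- function(shares, rate) {
  J <- length(shares)
  K <- rate * matrix(shares, J, J, byrow = TRUE)
  diag(K) <- 0
  diag(K) <- 1 - rowSums(K)
  K
}
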