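# Shared fixtures and independent brute-force oracles.
#
# The oracles recompute every intensity statistic with explicit elementwise
# loops, independently of the package's vectorised implementation.

abc_scheme <- function() lc_scheme(1:3, c("A", "B", "C"))

# worked 3-category fixture: dY = 5, total 300 km2
mstar <- function() {
  labs <- c("A", "B", "C")
  transition_matrix(
    matrix(c(75, 15, 10, 5, 90, 5, 0, 0, 100), 3, 3, byrow = TRUE,
           dimnames = list(labs, labs)),
    1985, 1990, "ALL")
}

# random non-negative matrix; occasionally zeroes out a category entirely
rand_tm <- function(J = 4, from = 2000, dy = 5, stratum = "ALL",
                    allow_absent = TRUE) {
  labs <- LETTERS[seq_len(J)]
  m <- matrix(stats::rexp(J * J, rate = 0.1), J, J,
              dimnames = list(labs, labs))
  diag(m) <- diag(m) + stats::rexp(J, rate = 0.01)  # persistence-dominant
  if (allow_absent && stats::runif(1) < 0.3) {
    z <- sample(J, 1)
    m[z, ] <- 0; m[, z] <- 0
  }
  transition_matrix(m, from, from + dy, stratum)
}

oracle_interval <- function(m) {
  dy <- attr(m, "to_year") - attr(m, "from_year")
  tot <- 0; gross <- 0
  for (i in rownames(m)) for (j in colnames(m)) {
    tot <- tot + m[i, j]
    if (i != j) gross <- gross + m[i, j]
  }
  list(gross = gross, fraction = gross / tot * 100,
       St = gross / dy / tot * 100)
}

oracle_category <- function(m) {
  dy <- attr(m, "to_year") - attr(m, "from_year")
  labs <- rownames(m)
  out <- list()
  for (cc in labs) {
    start <- 0; end <- 0; gain <- 0; loss <- 0
    for (j in labs) start <- start + m[cc, j]
    for (i in labs) end <- end + m[i, cc]
    for (i in labs) if (i != cc) gain <- gain + m[i, cc]
    for (j in labs) if (j != cc) loss <- loss + m[cc, j]
    out[[cc]] <- c(G = if (end > 0) gain / dy / end * 100 else NA_real_,
                   L = if (start > 0) loss / dy / start * 100 else NA_real_)
  }
  out
}

oracle_transition <- function(m, n) {
  dy <- attr(m, "to_year") - attr(m, "from_year")
  labs <- rownames(m)
  num <- 0; den <- 0
  R <- c()
  for (i in labs) if (i != n) {
    start <- 0
    for (j in labs) start <- start + m[i, j]
    num <- num + m[i, n]
    den <- den + start
    R[i] <- if (start > 0) m[i, n] / dy / start * 100 else NA_real_
  }
  list(W = if (den > 0) num / dy / den * 100 else NA_real_, R = R)
}

# minimal two-stratum series on the ABC scheme
two_stratum_series <- function() {
  labs <- c("A", "B", "C")
  m1a <- transition_matrix(matrix(c(75, 15, 10, 5, 90, 5, 0, 0, 100), 3, 3,
                                  byrow = TRUE, dimnames = list(labs, labs)),
                           1985, 1990, "S1")
  m1b <- transition_matrix(matrix(c(90, 5, 5, 0, 100, 0, 10, 0, 90), 3, 3,
                                  byrow = TRUE, dimnames = list(labs, labs)),
                           1985, 1990, "S2")
  m2a <- transition_matrix(matrix(c(88, 6, 1, 2, 96, 2, 0, 5, 100), 3, 3,
                                  byrow = TRUE, dimnames = list(labs, labs)),
                           1990, 1992, "S1")
  m2b <- transition_matrix(matrix(c(95, 5, 0, 0, 100, 0, 5, 0, 95), 3, 3,
                                  byrow = TRUE, dimnames = list(labs, labs)),
                           1990, 1992, "S2")
  matrix_series(list(m1a, m1b, m2a, m2b), abc_scheme())
}

# plain numeric matrix with dimnames only
plain <- function(m)
  matrix(as.numeric(m), nrow(m), ncol(m), dimnames = dimnames(m))

# rebuild a transition matrix with scaled entries and/or a new interval
tm_scale <- function(m, scale = 1, from = attr(m, "from_year"),
                     to = attr(m, "to_year"),
                     stratum = attr(m, "stratum"))
  transition_matrix(plain(m) * scale, from, to, stratum)

# diagonal (no-change) matrix on the given labels
diag_tm <- function(labs, val, from, to, stratum = "ALL") {
  d <- diag(length(labs)) * val
  dimnames(d) <- list(labs, labs)
  transition_matrix(d, from, to, stratum)
}

expect_tm_equal <- function(a, b, tol = 1e-12) {
  expect_equal(unclass(a)[seq_along(a)], unclass(b)[seq_along(b)],
               tolerance = tol)
  expect_identical(dimnames(a), dimnames(b))
}
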