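test_that("interval intensity matches the worked fixture and is scale invariant", {
  m <- mstar()
  iv <- interval_intensity(m)
  expect_equal(iv$gross_area_km2, 35)
  expect_equal(iv$gross_pct, 35 / 300 * 100, tolerance = 1e-12)
  expect_equal(iv$St_pct_yr, 35 / 5 / 300 * 100, tolerance = 1e-12)

  dbl <- tm_scale(m, 2)
  iv2 <- interval_intensity(dbl)
  expect_equal(iv2$gross_pct, iv$gross_pct)
  expect_equal(iv2$St_pct_yr, iv$St_pct_yr)

  diag_only <- diag_tm(rownames(m), 100, 2000, 2005)
  expect_equal(interval_intensity(diag_only)$St_pct_yr, 0)
  zero <- transition_matrix(matrix(0, 2, 2,
                                   dimnames = list(c("A", "B"), c("A", "B"))),
                            2000, 2005)
  expect_error(interval_intensity(zero), "zero total area")
})

test_that("uniform intensity and tempo flags follow the pooled definition", {
  labs <- c("A", "B", "C")
  # second interval: gross 18, total 300, dY = 2 -> S = 3.0
  m2 <- transition_matrix(matrix(c(82, 9, 9, 0, 100, 0, 0, 0, 100), 3, 3,
                                 byrow = TRUE, dimnames = list(labs, labs)),
                          1990, 1992)
  ser <- matrix_series(list(mstar(), m2), abc_scheme())
  ui <- uniform_intensity(ser)
  expect_equal(ui$U, 53 / 2100 * 100, tolerance = 1e-12)
  expect_equal(ui$intervals$tempo, c("slow", "fast"))

  # single interval: U = S_1, flagged equal
  one <- matrix_series(list(mstar()), abc_scheme())
  u1 <- uniform_intensity(one)
  expect_equal(u1$U, u1$intervals$St_pct_yr)
  expect_equal(u1$intervals$tempo, "equal")

  # identical matrices and durations in every interval: all equal
  m1 <- mstar()
  m1b <- tm_scale(m1, 1, 1990, 1995)
  same <- uniform_intensity(matrix_series(list(m1, m1b), abc_scheme()))
  expect_true(all(same$intervals$tempo == "equal"))
})

test_that("category intensities reproduce the fixture and classify undefined", {
  ci <- category_intensities(mstar())
  expect_equal(ci$L_pct_yr[ci$category == "A"], 5)
  expect_equal(ci$loss_status[ci$category == "A"], "active")
  expect_equal(ci$G_pct_yr[ci$category == "B"], 15 / 5 / 105 * 100,
               tolerance = 1e-12)
  expect_equal(ci$gain_status[ci$category == "B"], "active")
  expect_equal(ci$L_pct_yr[ci$category == "B"], 2)
  expect_equal(ci$loss_status[ci$category == "B"], "dormant")
  expect_equal(ci$G_pct_yr[ci$category == "C"], 15 / 5 / 115 * 100,
               tolerance = 1e-12)
  expect_equal(ci$gain_status[ci$category == "C"], "active")
  expect_equal(ci$G_pct_yr[ci$category == "A"], 1.25)
  expect_equal(ci$gain_status[ci$category == "A"], "dormant")
  expect_equal(ci$loss_status[ci$category == "C"], "dormant")

  # all-zero row and column -> both statuses undefined
  labs <- c("A", "B", "C")
  m <- transition_matrix(matrix(c(90, 10, 0, 5, 95, 0, 0, 0, 0), 3, 3,
                                byrow = TRUE, dimnames = list(labs, labs)),
                         2000, 2005)
  ci2 <- category_intensities(m)
  expect_equal(ci2$gain_status[ci2$category == "C"], "undefined")
  expect_equal(ci2$loss_status[ci2$category == "C"], "undefined")
  expect_true(is.na(ci2$G_pct_yr[ci2$category == "C"]))

  # diagonal matrix: all dormant vs S_t > 0, all equal when S_t = 0
  dg <- diag_tm(labs, 100, 2000, 2005)
  expect_true(all(category_intensities(dg, St = 1)$gain_status == "dormant"))
  expect_true(all(category_intensities(dg, St = 0)$gain_status == "equal"))
})

test_that("transition profile reproduces the fixture and the zero-gain case", {
  tp <- transition_profile(mstar(), "B")
  expect_equal(tp$W_pct_yr, 1.5)
  tr <- tp$transitions
  expect_equal(tr$R_pct_yr[tr$from == "A"], 3)
  expect_equal(tr$status[tr$from == "A"], "targeted")
  expect_equal(tr$R_pct_yr[tr$from == "C"], 0)
  expect_equal(tr$status[tr$from == "C"], "avoided")

  # gaining category with zero gains: W = 0, every defined R = 0, all equal
  labs <- c("A", "B", "C")
  m <- transition_matrix(matrix(c(90, 0, 10, 0, 100, 0, 0, 0, 100), 3, 3,
                                byrow = TRUE, dimnames = list(labs, labs)),
                         2000, 2005)
  tp2 <- transition_profile(m, "B")
  expect_equal(tp2$W_pct_yr, 0)
  expect_true(all(tp2$transitions$status == "equal"))

  # no non-n area at the start: W undefined, all statuses undefined
  m3 <- transition_matrix(matrix(c(0, 0, 0, 0, 0, 0, 0, 0, 100), 3, 3,
                                 byrow = TRUE, dimnames = list(labs, labs)),
                          2000, 2005)
  tp3 <- transition_profile(m3, "C")
  expect_true(is.na(tp3$W_pct_yr))
  expect_true(all(tp3$transitions$status == "undefined"))
  expect_error(transition_profile(mstar(), "Z"), "unknown category")
})

test_that("every statistic matches the brute-force oracle on random matrices", {
  set.seed(7)
  for (rep in 1:120) {
    J <- sample(3:6, 1)
    m <- rand_tm(J, dy = sample(c(1, 2, 5), 1))
    oi <- oracle_interval(m)
    iv <- interval_intensity(m)
    expect_equal(iv$gross_area_km2, oi$gross, tolerance = 1e-12)
    expect_equal(iv$St_pct_yr, oi$St, tolerance = 1e-12)
    oc <- oracle_category(m)
    ci <- category_intensities(m)
    for (cc in names(oc)) {
      expect_equal(ci$G_pct_yr[ci$category == cc], unname(oc[[cc]]["G"]),
                   tolerance = 1e-12)
      expect_equal(ci$L_pct_yr[ci$category == cc], unname(oc[[cc]]["L"]),
                   tolerance = 1e-12)
    }
    n <- sample(rownames(m), 1)
    ot <- oracle_transition(m, n)
    tp <- transition_profile(m, n)
    expect_equal(tp$W_pct_yr, ot$W, tolerance = 1e-12)
    expect_equal(stats::setNames(tp$transitions$R_pct_yr, tp$transitions$from),
                 ot$R, tolerance = 1e-12)
  }
})

test_that("weighted-mean identities hold to numerical tolerance", {
  set.seed(11)
  for (rep in 1:60) {
    m <- rand_tm(sample(3:6, 1), dy = sample(c(2, 5), 1))
    St <- interval_intensity(m)$St_pct_yr
    ci <- category_intensities(m)
    # S_t is the start-size-weighted mean of defined L and the
    # end-size-weighted mean of defined G
    dl <- !is.na(ci$L_pct_yr)
    expect_equal(sum(ci$L_pct_yr[dl] * ci$start_area_km2[dl]) /
                   sum(ci$start_area_km2[dl]), St, tolerance = 1e-10)
    dg <- !is.na(ci$G_pct_yr)
    expect_equal(sum(ci$G_pct_yr[dg] * ci$end_area_km2[dg]) /
                   sum(ci$end_area_km2[dg]), St, tolerance = 1e-10)
    # W is the start-size-weighted mean of defined R
    for (n in rownames(m)) {
      tp <- transition_profile(m, n)
      tr <- tp$transitions
      d <- !is.na(tr$R_pct_yr)
      if (any(d) && !is.na(tp$W_pct_yr)) {
        expect_equal(sum(tr$R_pct_yr[d] * tr$start_area_km2[d]) /
                       sum(tr$start_area_km2[d]),
                     tp$W_pct_yr, tolerance = 1e-10)
        # W is a weighted mean, so some R is >= W and some <= W
        expect_gte(max(tr$R_pct_yr[d]), tp$W_pct_yr - 1e-12)
        expect_lte(min(tr$R_pct_yr[d]), tp$W_pct_yr + 1e-12)
      }
    }
  }
  # equal per-interval totals: U is the duration-weighted mean of S_t
  ser <- two_stratum_series()
  ui <- uniform_intensity(ser)
  expect_equal(sum(ui$intervals$St_pct_yr * ui$intervals$duration) /
                 sum(ui$intervals$duration), ui$U, tolerance = 1e-10)
})

test_that("statuses and intensities are invariant to area rescaling", {
  set.seed(3)
  for (rep in 1:20) {
    m <- rand_tm(4)
    c <- runif(1, 0.01, 1000)
    ms <- tm_scale(m, c)
    expect_equal(interval_intensity(ms)$St_pct_yr,
                 interval_intensity(m)$St_pct_yr, tolerance = 1e-9)
    expect_equal(category_intensities(ms)[, c("G_pct_yr", "L_pct_yr",
                                              "gain_status", "loss_status")],
                 category_intensities(m)[, c("G_pct_yr", "L_pct_yr",
                                             "gain_status", "loss_status")],
                 tolerance = 1e-9)
    tp <- transition_profile(m, "B"); tps <- transition_profile(ms, "B")
    expect_equal(tps$W_pct_yr, tp$W_pct_yr, tolerance = 1e-9)
    expect_equal(tps$transitions$status, tp$transitions$status)
  }
})

test_that("stationarity table counts targeted intervals per pair", {
  # identical matrices: every pair has a constant status in all intervals
  m1 <- mstar()
  m1b <- tm_scale(m1, 1, 1990, 1995)
  m1c <- tm_scale(m1, 1, 1995, 2000)
  st <- stationarity_table(matrix_series(list(m1, m1b, m1c), abc_scheme()))
  expect_true(all(st$counts$n_targeted %in% c(0L, 3L)))
  ab <- st$counts[st$counts$from == "A" & st$counts$to == "B", ]
  expect_equal(ab$n_targeted, 3L)
  expect_equal(ab$cum_area_km2, 45)

  # A->B targeted in intervals 1 and 3 only -> count 2 of 3
  labs <- c("A", "B", "C")
  hot <- matrix(c(80, 15, 5, 95, 0, 5, 5, 5, 90), 3, 3, byrow = TRUE,
                dimnames = list(labs, labs))
  cold <- matrix(c(94, 1, 5, 95, 0, 5, 5, 15, 80), 3, 3, byrow = TRUE,
                 dimnames = list(labs, labs))
  ser2 <- matrix_series(list(
    transition_matrix(hot, 1985, 1990), transition_matrix(cold, 1990, 1995),
    transition_matrix(hot, 1995, 2000)), abc_scheme())
  st2 <- stationarity_table(ser2)
  sts <- st2$statuses
  ab_status <- sts$status[sts$from == "A" & sts$to == "B"][order(
    sts$interval[sts$from == "A" & sts$to == "B"])]
  expect_equal(ab_status, c("targeted", "avoided", "targeted"))
  expect_equal(st2$counts$n_targeted[st2$counts$from == "A" &
                                       st2$counts$to == "B"], 2L)

  # no-change series: nothing targeted
  dg <- diag_tm(labs, 100, 2000, 2005)
  st3 <- stationarity_table(matrix_series(list(dg), abc_scheme()))
  expect_true(all(st3$counts$n_targeted == 0))
})
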