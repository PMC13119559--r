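glc_pair_matrix <- function(fill = 0) {
  labs <- category_labels(glc_level1_scheme())
  matrix(fill, 10, 10, dimnames = list(labs, labs))
}

test_that("pathway sets reject overlapping or degenerate pairs", {
  pw <- default_pathways()
  expect_equal(length(unique(pw$pathway)), 6)
  expect_false(anyDuplicated(paste(pw$from, pw$to)) > 0)
  expect_error(pathway_set(a = cbind("FST", "CRP"), b = cbind("FST", "CRP")),
               "more than one pathway")
  expect_error(pathway_set(a = cbind("FST", "FST")), "must change")
  expect_error(pathway_set(cbind("FST", "CRP")), "named")
})

test_that("trajectory labelling maps pairs to pathways, persistence, other", {
  scheme <- glc_level1_scheme()
  pw <- default_pathways()
  ids <- function(...) match(c(...), category_labels(scheme))
  # 9-cell toy: 2 FST->SHR, 1 FST->CRP, 6 unchanged
  first <- lc_map(matrix(ids("FST","FST","FST", "GRS","GRS","GRS",
                             "CRP","CRP","CRP"), 3, 3), 1985)
  last <- lc_map(matrix(ids("SHR","SHR","CRP", "GRS","GRS","GRS",
                            "CRP","CRP","CRP"), 3, 3), 2022)
  tm <- label_trajectories(first, last, pw, scheme)
  cnt <- table(factor(tm$values, levels = tm$legend$code,
                      labels = tm$legend$label))
  expect_equal(unname(cnt[["Forest Degradation"]]), 2)
  expect_equal(unname(cnt[["Deforestation"]]), 1)
  expect_equal(unname(cnt[["persistence"]]), 6)

  # named pathway membership for specific pairs
  p1 <- lc_map(matrix(ids("FST", "SHR", "GRS"), 1, 3), 1985)
  p2 <- lc_map(matrix(ids("CRP", "CRP", "BAL"), 1, 3), 2022)
  tm2 <- label_trajectories(p1, p2, pw, scheme)
  lab <- tm2$legend$label[match(tm2$values, tm2$legend$code)]
  expect_equal(lab, c("Deforestation", "Agricultural Expansion",
                      "Desertification"))

  # identical maps: all persistence; unmatched change: other; nodata kept
  same <- label_trajectories(first, lc_map(first$values, 2022), pw, scheme)
  expect_true(all(same$values == 0))
  o1 <- lc_map(matrix(c(ids("WTR"), NA), 1, 2), 1985)
  o2 <- lc_map(matrix(ids("IMP", "CRP"), 1, 2), 2022)
  tm3 <- label_trajectories(o1, o2, pw, scheme)
  expect_equal(as.vector(tm3$values), c(-1L, NA))
})

test_that("trajectory counts reconcile with the first-last matrix by pathway", {
  set.seed(31)
  scheme <- glc_level1_scheme()
  pw <- default_pathways()
  v0 <- matrix(sample(1:10, 400, replace = TRUE), 20, 20)
  v1 <- matrix(ifelse(runif(400) < 0.3, sample(1:10, 400, replace = TRUE),
                      v0), 20, 20)
  area <- 0.5
  first <- lc_map(v0, 1985, cell_area = area)
  last <- lc_map(v1, 2022, cell_area = area)
  tm <- label_trajectories(first, last, pw, scheme)
  fl <- crosstab(first, last, scheme)
  for (code in unique(pw$code)) {
    prs <- pw[pw$code == code, ]
    expect_equal(sum(tm$values == code, na.rm = TRUE) * area,
                 sum(fl[cbind(prs$from, prs$to)]), tolerance = 1e-12)
  }
})

test_that("dominant-transition selection applies both thresholds monotonically", {
  labs <- c("A", "B", "C")
  hot <- matrix(c(80, 15, 5, 95, 0, 5, 5, 5, 90), 3, 3, byrow = TRUE,
                dimnames = list(labs, labs))
  cold <- matrix(c(94, 1, 5, 95, 0, 5, 5, 15, 80), 3, 3, byrow = TRUE,
                 dimnames = list(labs, labs))
  ser <- matrix_series(list(
    transition_matrix(hot, 1985, 1990), transition_matrix(cold, 1990, 1995),
    transition_matrix(hot, 1995, 2000)), abc_scheme())
  st <- stationarity_table(ser)
  fl <- chained_first_last(ser)
  sel <- select_dominant_transitions(st, fl, min_targeted_frac = 0.5,
                                     min_area_km2 = 0)
  expect_true(nrow(sel) >= 1)
  expect_equal(sel$area_km2, sort(sel$area_km2, decreasing = TRUE))
  # A->B targeted 2 of 3: excluded when full stationarity is required
  strict <- select_dominant_transitions(st, fl, min_targeted_frac = 1.0,
                                        min_area_km2 = 0)
  expect_false(any(strict$from == "A" & strict$to == "B"))
  # raising either threshold never adds a pair
  for (f in c(0.25, 0.5, 0.75, 1)) {
    lo <- select_dominant_transitions(st, fl, f, 0)
    hi <- select_dominant_transitions(st, fl, f, 50)
    expect_true(all(paste(hi$from, hi$to) %in% paste(lo$from, lo$to)))
  }
  # no-change series selects nothing
  dg <- diag_tm(labs, 100, 2000, 2005)
  ser0 <- matrix_series(list(dg), abc_scheme())
  expect_equal(nrow(select_dominant_transitions(
    stationarity_table(ser0), chained_first_last(ser0), 0.5, 0)), 0)
})

test_that("pathway budgets pool member pairs and decompose by stratum", {
  pw <- default_pathways()
  m1 <- glc_pair_matrix(); m2 <- glc_pair_matrix()
  diag(m1) <- diag(m2) <- 100
  m1["SHR", "CRP"] <- 3; m1["GRS", "CRP"] <- 2   # pooled Ag Expansion: 5
  m1["FST", "CRP"] <- 8
  m2["FST", "CRP"] <- 2
  mats <- list(transition_matrix(m1, 1985, 2022, "S1"),
               transition_matrix(m2, 1985, 2022, "S2"))
  bud <- pathway_budget(mats, pw)
  ag <- bud[bud$pathway == "Agricultural Expansion", ]
  expect_equal(unique(ag$total_km2), 5)
  expect_equal(ag$area_km2[ag$stratum == "S1"], 5)
  de <- bud[bud$pathway == "Deforestation", ]
  expect_equal(unique(de$total_km2), 10)
  expect_equal(de$share_pct, c(80, 20))
  expect_equal(de$stratum[de$dominant], "S1")
  # budget totals equal the sum of stratum budgets
  for (p in unique(bud$pathway))
    expect_equal(sum(bud$area_km2[bud$pathway == p]),
                 unique(bud$total_km2[bud$pathway == p]), tolerance = 1e-12)
  # zero conversions: zero rows
  z <- glc_pair_matrix(); diag(z) <- 100
  expect_equal(nrow(pathway_budget(list(
    transition_matrix(z, 1985, 2022, "S1")), pw)), 0)
})

test_that("network aggregates targeted transitions with dominant strata", {
  labs <- c("A", "B", "C")
  mk <- function(ab, f, t, s) transition_matrix(
    matrix(c(100 - ab, ab, 0, 0, 100, 0, 0, 0, 100), 3, 3, byrow = TRUE,
           dimnames = list(labs, labs)), f, t, s)
  # A->B targeted whenever ab > 0 (only flow into B)
  ser <- matrix_series(list(mk(5, 1985, 1990, "S1"), mk(1, 1985, 1990, "S2"),
                            mk(7, 1990, 1995, "S1"), mk(1, 1990, 1995, "S2")),
                       abc_scheme())
  net <- build_network(ser)
  expect_equal(nrow(net$edges), 1)
  e <- net$edges[1, ]
  expect_equal(e$from, "A"); expect_equal(e$to, "B")
  expect_equal(e$area_km2, 14)                       # 6 + 8 pooled over strata
  expect_equal(e$dominant_stratum, "S1")
  expect_equal(e$dominant_share_pct, 12 / 14 * 100, tolerance = 1e-12)
  # node mean area of the constant class C is its size
  expect_equal(net$nodes$mean_area_km2[net$nodes$category == "C"], 200)

  # no targeted pairs: nodes only
  dg <- diag_tm(labs, 100, 2000, 2005)
  net0 <- build_network(matrix_series(list(dg), abc_scheme()))
  expect_equal(nrow(net0$edges), 0)
  expect_equal(nrow(net0$nodes), 3)

  # edge area sums targeted intervals only unless asked otherwise
  hot <- matrix(c(80, 15, 5, 95, 0, 5, 5, 5, 90), 3, 3, byrow = TRUE,
                dimnames = list(labs, labs))
  cold <- matrix(c(94, 1, 5, 95, 0, 5, 5, 15, 80), 3, 3, byrow = TRUE,
                 dimnames = list(labs, labs))
  ser2 <- matrix_series(list(
    transition_matrix(hot, 1985, 1990), transition_matrix(cold, 1990, 1995),
    transition_matrix(hot, 1995, 2000)), abc_scheme())
  n_t <- build_network(ser2)
  n_all <- build_network(ser2, targeted_only = FALSE)
  ab_t <- n_t$edges$area_km2[n_t$edges$from == "A" & n_t$edges$to == "B"]
  ab_all <- n_all$edges$area_km2[n_all$edges$from == "A" & n_all$edges$to == "B"]
  expect_equal(ab_t, 30)                              # 15 + 15, skips cold 1
  expect_equal(ab_all, 31)
  g <- as_igraph(n_t)
  expect_true(igraph::is_directed(g))
})
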