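test_that("factor stats match hand arithmetic and order-statistic quartiles", {
  s <- factor_stats(1:8)
  expect_equal(c(s$q1, s$q2, s$q3), c(2.75, 4.5, 6.25))

  s2 <- factor_stats(c(2, 4, 6))
  expect_equal(s2$mean, 4)
  expect_equal(s2$sd, 2)               # n-1 denominator
  expect_equal(s2$cv_percent, 50)

  # degenerate constant panel
  sc <- factor_stats(rep(7, 6))
  expect_equal(sc$cv_percent, 0)
  expect_equal(c(sc$q1, sc$q2, sc$q3), c(7, 7, 7))

  expect_error(factor_stats(3), "at least 2")
  expect_error(factor_stats(c(-1, 1)), "mean is zero")
})

test_that("CV matches the two-pass oracle to 1e-12", {
  set.seed(33)
  for (i in 1:20) {
    x <- rlnorm(sample(5:50, 1), 2, 0.6)
    expect_equal(factor_stats(x)$cv_percent, 100 * oracle_cv(x),
                 tolerance = 1e-12)
    expect_equal(cv_fraction(x), oracle_cv(x), tolerance = 1e-12)
  }
})

test_that("quartile points use half-open bins promoted upward", {
  s <- factor_stats(1:8)
  # extremes always score 0 and 3
  expect_equal(assign_points(c(1, 8), s), c(0, 3))
  expect_equal(assign_points(5, s), 2)          # between q2 = 4.5 and q3 = 6.25
  expect_equal(assign_points(4.5, s), 2)        # breakpoint -> higher bin
  expect_equal(assign_points(c(-10, 100), s), c(0, 3))  # out of range clamps
  expect_error(assign_points(NA_real_, s), "finite")
})

test_that("points are invariant under affine maps of the panel", {
  set.seed(44)
  for (i in 1:20) {
    v <- rlnorm(8, 3, 0.5)
    p0 <- assign_points(v, factor_stats(v))
    v2 <- 2.5 * v + 10
    expect_identical(p0, assign_points(v2, factor_stats(v2)))
  }
})

test_that("tie-free panels with n divisible by 4 fill bins evenly", {
  set.seed(55)
  for (i in 1:50) {
    v <- rlnorm(8, 2, 0.7)
    pts <- assign_points(v, factor_stats(v))
    expect_identical(unname(pts), unname(oracle_points_by_rank(v)))
    expect_equal(as.vector(table(factor(pts, levels = 0:3))), rep(2, 4))
  }
})

test_that("the donor-320 quartile narrative totals 6 points", {
  # encode the stated placements directly: second-lowest quartile IDO1,
  # highest M-CSF, lowest CD63, second-highest CCL2 on an 8-donor panel
  base <- c(10, 20, 30, 40, 50, 60, 70, 80)
  panel <- data.frame(donor_id = c(sprintf("D%02d", 1:7), "320"))
  place <- function(rank_320) {
    v <- numeric(8); v[8] <- base[rank_320]
    v[1:7] <- base[-rank_320]
    v
  }
  panel$IDO1 <- place(3)  # ranks 3-4 = second-lowest quartile
  panel$MCSF <- place(8)  # highest quartile
  panel$CD63 <- place(1)  # lowest quartile
  panel$CCL2 <- place(6)  # ranks 5-6 = second-highest quartile
  sc <- score_panel(panel)  # unit weights
  row <- sc[sc$donor_id == "320", ]
  expect_equal(unname(unlist(row[paste0(c("IDO1", "MCSF", "CD63", "CCL2"),
                                        "_points")])),
               c(1, 3, 0, 2))
  expect_equal(row$unweighted_total, 6)
  expect_equal(row$weighted_total, 6)  # unit weights coincide

  # weighted preset: 1*2 + 3*1 + 0*2 + 2*0.5 = 6.0
  scw <- score_panel(panel, weights = "methods")
  expect_equal(scw[scw$donor_id == "320", "weighted_total"], 6.0)
  # alternative preset doubles M-CSF as well: 1*2 + 3*2 + 0*2 + 2*0.5 = 9
  scr <- score_panel(panel, weights = "results")
  expect_equal(scr[scr$donor_id == "320", "weighted_total"], 9.0)
})

test_that("scoring is indifferent to factor column order", {
  panel <- simulate_donor_panel(8, seed = 66)
  a <- score_panel(panel)
  b <- score_panel(panel[, c("donor_id", "CCL2", "CD63", "MCSF", "IDO1")])
  expect_equal(a$unweighted_total, b$unweighted_total)
  expect_equal(a$weighted_total, b$weighted_total)
})

test_that("missing factor values exclude the donor with a warning", {
  panel <- simulate_donor_panel(8, seed = 77)
  panel$CD63[3] <- NA
  expect_warning(sc <- score_panel(panel), "excluded")
  expect_true(is.na(sc$unweighted_total[3]))
  expect_equal(sum(is.na(sc$unweighted_total)), 1)
  expect_error(score_panel(panel, weights = c(BOGUS = 2)), "unknown")
})

test_that("donor ranking uses descending competition ranks", {
  sc <- data.frame(donor_id = c("a", "b", "c"),
                   unweighted_total = c(6, 9, 3),
                   weighted_total = c(6, 9, 3))
  rk <- rank_donors(sc, by = "unweighted")
  expect_equal(rk$rank[match(c("a", "b", "c"), rk$donor_id)], c(2, 1, 3))

  tied <- data.frame(donor_id = c("a", "b", "c"),
                     unweighted_total = c(6, 6, 3),
                     weighted_total = c(6, 6, 3))
  rk2 <- rank_donors(tied, by = "unweighted")
  expect_equal(rk2$rank[match(c("a", "b", "c"), rk2$donor_id)], c(1, 1, 3))
  expect_equal(rk2$donor_id, c("a", "b", "c"))  # deterministic tie order

  single <- data.frame(donor_id = "x", unweighted_total = 2,
                       weighted_total = 2)
  expect_equal(rank_donors(single, "weighted")$rank, 1L)
  expect_error(rank_donors(single[0, ]), "no donors")
})
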