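const_series <- function(from, to, mm = 1) {
  tibble::tibble(date = seq(as.Date(from), as.Date(to), by = "day"), mm = mm)
}

test_that("12-month accumulation follows the calendar (leap vs non-leap windows)", {
  s <- const_series("1998-01-01", "2002-12-31")
  # window 1999-03-01 .. 2000-02-29 contains the leap day
  expect_equal(accumulate_rainfall(s, as.Date("2000-03-01")), 366)
  # window 2000-03-01 .. 2001-02-28 does not
  expect_equal(accumulate_rainfall(s, as.Date("2001-03-01")), 365)
  # oracle: explicit day count of the half-open window
  for (dt in c("1999-03-01", "2000-07-15", "2001-01-01")) {
    d <- as.Date(dt)
    days <- as.numeric(d - (d %m-% months(12)))
    expect_equal(accumulate_rainfall(s, d), days)
  }
  z <- const_series("1998-01-01", "2002-12-31", mm = 0)
  expect_equal(accumulate_rainfall(z, as.Date("2000-03-01")), 0)
})

test_that("accumulation is additive over disjoint sub-windows", {
  set.seed(9)
  s <- const_series("1998-01-01", "2002-12-31")
  s$mm <- rexp(nrow(s), 1 / 2)
  d <- as.Date("2001-06-10")
  full <- accumulate_rainfall(s, d, months = 12)
  first6 <- accumulate_rainfall(s, d %m-% months(6), months = 6)
  last6 <- accumulate_rainfall(s, d, months = 6)
  expect_equal(first6 + last6, full)
})

test_that("coverage gaps are reported with the missing span", {
  s <- const_series("2000-01-01", "2000-12-31")
  expect_error(accumulate_rainfall(s, as.Date("2000-06-01")),
               "does not cover")
  expect_error(accumulate_rainfall(s, as.Date("2000-06-01")), "1999")
})

test_that("historical quantiles match an order-statistic oracle", {
  # constant accumulation every year
  s <- const_series("1990-01-01", "2010-12-31", mm = 2)
  q <- historical_rainfall_quantiles(s, month = 7, years = 1992:2009)
  expect_equal(unname(q), c(730, 730, 730), tolerance = 0.01)

  # accumulations that differ by construction: year y gets total ~ f(y)
  s2 <- const_series("1989-01-01", "2015-12-31")
  yr <- as.integer(format(s2$date, "%Y"))
  s2$mm <- (yr - 1989) / 365   # 12-month totals approximately 0,1,2,...
  years <- 1991:2014
  acc <- vapply(years,
                function(y) accumulate_rainfall(s2, as.Date(sprintf("%d-04-01", y))),
                numeric(1))
  q <- historical_rainfall_quantiles(s2, month = 4, years = years,
                                     probs = c(0.1, 0.5, 0.9))
  # oracle: type-7 interpolation done by hand
  manual_q7 <- function(x, p) {
    x <- sort(x)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  expect_equal(unname(q),
               vapply(c(0.1, 0.5, 0.9), function(p) manual_q7(acc, p), numeric(1)))

  expect_error(historical_rainfall_quantiles(s, 7, 1992:2009, probs = c(0, 0.5)),
               "\\(0, 1\\)")
  expect_error(historical_rainfall_quantiles(s, 7, years = 1999), "2 usable years")
})

test_that("rainfall-level imputation matches a least-squares oracle", {
  # saturated one-factor case: prediction equals the observed class mean
  obs <- tibble::tibble(
    bioregion = "b1", vegetation_class = c("c1", "c2"),
    q10 = c(100, 200), q50 = c(300, 400), q90 = c(500, 600))
  tg <- tidyr::expand_grid(bioregion = "b1", vegetation_class = c("c1", "c2"))
  out <- impute_rainfall_levels(obs, tg)
  expect_equal(out$q50, c(300, 400))
  expect_equal(out$source, c("observed", "observed"))

  # 2x2 with one missing cell, additive truth: row + column effects recover it
  mu <- 500; bio_eff <- c(b1 = 0, b2 = 120); cls_eff <- c(c1 = 0, c2 = -60)
  cells <- tidyr::expand_grid(bioregion = c("b1", "b2"),
                              vegetation_class = c("c1", "c2"))
  cells$q50 <- mu + bio_eff[cells$bioregion] + cls_eff[cells$vegetation_class]
  cells$q10 <- cells$q50 - 100
  cells$q90 <- cells$q50 + 100
  obs2 <- cells[-4, ]  # drop (b2, c2)
  out2 <- impute_rainfall_levels(obs2, cells[, 1:2])
  # oracle: direct normal-equations solve of the additive design
  X <- model.matrix(~ bioregion + vegetation_class, obs2)
  bh <- solve(t(X) %*% X, t(X) %*% obs2$q50)
  pred_missing <- sum(bh * c(1, 1, 1))
  expect_equal(out2$q50[out2$bioregion == "b2" &
                          out2$vegetation_class == "c2"], pred_missing)
  expect_equal(pred_missing, unname(mu + bio_eff["b2"] + cls_eff["c2"]))
  expect_equal(out2$source, c("observed", "observed", "observed", "imputed"))

  # invariance to row order of the observed data
  out3 <- impute_rainfall_levels(obs2[c(3, 1, 2), ], cells[, 1:2])
  expect_equal(out3$q50, out2$q50)
})

test_that("imputation errors on unestimable levels and re-sorts inverted triples", {
  obs <- tibble::tibble(bioregion = "b1", vegetation_class = "c1",
                        q10 = 100, q50 = 200, q90 = 300)
  tg <- tibble::tibble(bioregion = c("b1", "b9"), vegetation_class = "c1")
  expect_error(impute_rainfall_levels(obs, tg), "b9")

  # observed triples are consistent, but the three independent additive
  # regressions predict an inverted triple for the unobserved cell
  obs2 <- tibble::tibble(
    bioregion = c("b1", "b1", "b2"),
    vegetation_class = c("c1", "c2", "c1"),
    q10 = c(100, 400, 300),   # additive prediction for (b2, c2): 600
    q50 = c(450, 450, 450),   # prediction: 450 < 600 -> inverted
    q90 = c(500, 520, 510))
  tg2 <- tidyr::expand_grid(bioregion = c("b1", "b2"),
                            vegetation_class = c("c1", "c2"))
  expect_warning(out <- impute_rainfall_levels(obs2, tg2), "re-sorted")
  expect_true(all(out$q10 <= out$q50 & out$q50 <= out$q90))
  imp <- out[out$bioregion == "b2" & out$vegetation_class == "c2", ]
  expect_equal(imp$source, "imputed")
  expect_equal(c(imp$q10, imp$q50, imp$q90), c(450, 530, 600))
})
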