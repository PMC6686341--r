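mk_counts <- function(lek_id, years, males) {
  data.frame(lek_id = lek_id, year = years, males = males)
}
mk_assign <- function(lek_id, category = "fire_perimeter", burn_year = 2000L) {
  data.frame(lek_id = lek_id, category = category, burn_year = burn_year)
}

test_that("inclusion criteria fail in (a)-(d) order with the right reasons", {
  counts <- rbind(
    mk_counts("out", 1995:2005, 5),                       # (a) outside
    mk_counts("short", 1998:2002, 5),                     # (b) 5 years
    mk_counts("onepre", 1999:2006, 5),                    # (c) 1 pre count
    mk_counts("zeros", 1994:2003, c(3, 2, 1, 1, 0, 0, 4, 5, 6, 7)),  # (d)
    mk_counts("ok", 1994:2003, c(3, 2, 1, 1, 4, 0, 4, 5, 6, 7)))
  assign <- rbind(mk_assign("out", "outside", NA),
                  mk_assign("short"), mk_assign("onepre"),
                  mk_assign("zeros"), mk_assign("ok"))
  f <- filter_leks(counts, assign)
  expect_equal(f$reason, c("a", "b", "c", "d", "ok"))
  expect_equal(f$included, c(FALSE, FALSE, FALSE, FALSE, TRUE))
})

test_that("criterion (d) needs BOTH of the last two prefire counts to be zero", {
  counts <- mk_counts("x", 1993:2003, c(5, 4, 3, 2, 1, 4, 0, 3, 2, 2, 1))
  # fire in 2000; last two prefire years 1998 (count 4) and 1999 (count 0)
  f <- filter_leks(counts, mk_assign("x"))
  expect_true(f$included)
  # 'any_two' variant scans the whole prefire series for consecutive zeros
  counts2 <- mk_counts("x", 1993:2003, c(5, 0, 0, 2, 1, 4, 2, 3, 2, 2, 1))
  expect_true(filter_leks(counts2, mk_assign("x"))$included)
  expect_equal(filter_leks(counts2, mk_assign("x"),
                           zero_rule = "any_two")$reason, "d")
})

test_that("constant counts give a flat saturated fit", {
  cnt <- data.frame(year = 1994:2005, males = 8)
  f <- lek_trend(cnt, fire_year = 2000)
  expect_equal(unname(coef(f)), c(log(8), 0, 0, 0), tolerance = 1e-8)
  expect_equal(f$pre_slope, 0, tolerance = 1e-8)
  expect_equal(f$post_slope, 0, tolerance = 1e-8)
  expect_true(f$converged)
})

test_that("IRLS matches an independent grid search of the likelihood", {
  toy <- data.frame(year = c(-2, -1, 0, 1, 2, 3), males = c(10, 12, 9, 6, 4, 3))
  f <- lek_trend(toy, fire_year = 0)
  oracle <- grid_search_trend(toy, fire_year = 0)
  expect_equal(unname(coef(f)), oracle, tolerance = 1e-4)
  expect_equal(f$post_slope, f$coefficients[["beta1"]] + f$coefficients[["beta3"]])
})

test_that("IRLS agrees with the reference GLM fitter on random feasible series", {
  set.seed(301)
  for (i in 1:25) {
    fy <- sample(1995:2005, 1)
    yrs <- sort(sample(1985:2015, sample(8:20, 1)))
    while (sum(yrs < fy) < 2 || sum(yrs >= fy) < 2)
      yrs <- sort(sample(1985:2015, sample(8:20, 1)))
    b <- c(runif(1, 2, 4), runif(1, -0.1, 0.1), runif(1, -0.5, 0.5),
           runif(1, -0.1, 0.1))
    cnt <- simulate_lek_counts(b[1], b[2], b[3], b[4], fy, yrs)
    if (all(cnt$males[cnt$year >= fy] == 0)) next
    f <- lek_trend(cnt, fy)
    d <- transform(cnt, x1 = year - fy, x2 = as.numeric(year >= fy))
    g <- glm(males ~ x1 * x2, poisson, d,
             control = glm.control(epsilon = 1e-12))
    expect_equal(unname(coef(f)), unname(coef(g)), tolerance = 1e-6)
  }
})

test_that("slopes are invariant to recentring the year axis", {
  set.seed(17)
  cnt <- simulate_lek_counts(log(40), 0.04, -0.3, -0.1, 2000, 1990:2012)
  f1 <- lek_trend(cnt, 2000)
  shifted <- transform(cnt, year = year + 500)
  f2 <- lek_trend(shifted, 2500)
  expect_equal(f1$pre_slope, f2$pre_slope, tolerance = 1e-10)
  expect_equal(f1$post_slope, f2$post_slope, tolerance = 1e-10)
})

test_that("with no slope change, estimated pre and post slopes coincide", {
  set.seed(23)
  gap <- replicate(500, {
    cnt <- simulate_lek_counts(log(30), 0.02, -0.2, 0, 0, -99:100)
    f <- lek_trend(cnt, 0)
    abs(f$post_slope - f$pre_slope)
  })
  expect_lt(mean(gap), 0.01)
})

test_that("postfire extirpation is flagged, not silently dropped", {
  cnt <- data.frame(year = 1995:2004,
                    males = c(6, 7, 5, 6, 4, 0, 0, 0, 0, 0))
  expect_warning(f <- lek_trend(cnt, 2000, lek_id = "gone"),
                 "postfire slope is unbounded")
  expect_true(f$post_extirpated)
  expect_true(is.na(f$post_slope))
  expect_false(f$converged)
  expect_true(is.finite(f$pre_slope))
})

test_that("rank-deficient designs are refused with guidance", {
  cnt <- data.frame(year = c(1999, 2000, 2001, 2002), males = c(5, 4, 3, 2))
  expect_error(lek_trend(cnt, 2000), "rank deficient")
})

test_that("model methods are mutually consistent", {
  set.seed(4)
  cnt <- simulate_lek_counts(log(25), 0.03, -0.4, -0.12, 2000, 1990:2012)
  f <- lek_trend(cnt, 2000, lek_id = "m")
  expect_equal(fitted(f), predict(f, type = "response"))
  expect_equal(log(fitted(f)), predict(f, type = "link"))
  expect_equal(residuals(f, "response"), cnt$males - fitted(f))
  # deviance residuals square-sum to the deviance
  expect_equal(sum(residuals(f, "deviance")^2), f$deviance, tolerance = 1e-8)
  ci <- confint(f)
  expect_true(all(ci[, "lower"] <= ci[, "upper"]))
  expect_equal(unname(ci["post_slope", "upper"] - ci["post_slope", "lower"]),
               2 * 1.959964 * f$post_slope_se, tolerance = 1e-6)
  sims <- simulate(f, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(nrow(cnt), 3))
  out <- capture.output(print(summary(f)))
  expect_true(any(grepl("Postfire slope", out)))
  tab <- lek_trends(rbind(cbind(lek_id = "m", cnt)),
                    data.frame(lek_id = "m", category = "fire_perimeter",
                               fire_year = 2000L, included = TRUE))
  expect_equal(tab$post_slope, f$post_slope)
  expect_equal(tab$beta1 + tab$beta3, tab$post_slope)
})
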