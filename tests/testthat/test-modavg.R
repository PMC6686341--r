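test_that("collinearity screening flags duplicates and rank-preserved monotone maps", {
  set.seed(71)
  x <- rnorm(40)
  tab <- data.frame(a = x, b = x, c = rnorm(40))
  rep_ <- screen_collinearity(tab)
  expect_equal(rep_$spearman["a", "b"], 1)
  expect_true(is.infinite(rep_$vif[["a"]]))
  expect_true(nrow(rep_$dropped) >= 1)
  expect_false(all(c("a", "b") %in% rep_$retained))

  # monotone transform: Spearman rank correlation is exactly 1
  tab2 <- data.frame(x = x, xcubed = x^3, z = rnorm(40))
  rep2 <- screen_collinearity(tab2)
  expect_equal(rep2$spearman["x", "xcubed"], 1)

  # orthogonal (and mean-zero) columns: all VIFs equal 1
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(30 * 3), 30))))[, 2:4]
  rep3 <- screen_collinearity(as.data.frame(Q))
  expect_equal(unname(rep3$vif), rep(1, 3), tolerance = 1e-10)
  expect_length(rep3$retained, 3)

  expect_error(screen_collinearity(data.frame(a = rep(1, 10), b = rnorm(10))),
               "constant predictor")
})

test_that("standardisation yields exact zero mean and unit SD and is idempotent", {
  expect_equal(standardize_columns(data.frame(v = c(1, 2, 3)))$v, c(-1, 0, 1))
  set.seed(3)
  tab <- data.frame(a = rexp(25), b = rnorm(25, 100, 5))
  z <- standardize_columns(tab)
  expect_true(all(abs(colMeans(as.matrix(z))) < 1e-12))
  expect_equal(unname(apply(as.matrix(z), 2, sd)), c(1, 1))
  z2 <- standardize_columns(z)
  expect_equal(as.matrix(z2), as.matrix(z), tolerance = 1e-12)
  expect_equal(unname(attr(z, "center")), unname(colMeans(as.matrix(tab))))
  expect_error(standardize_columns(data.frame(a = rep(2, 5))), "constant")
})

test_that("candidate enumeration sizes follow (s+1)^v - 1", {
  expect_length(enumerate_candidates(), 63)
  expect_length(enumerate_candidates(variables = "a", scales = "s1"), 1)
  expect_length(enumerate_candidates(variables = c("a", "b"),
                                     scales = c("s1", "s2")), 8)
  # one-scale constraint holds in every model
  for (m in enumerate_candidates()) {
    stems <- sub("_[^_]+$", "", m)
    expect_false(any(duplicated(stems)))
  }
  # unconstrained all-subsets alternative
  expect_length(enumerate_candidates(one_scale_per_variable = FALSE), 511)
})

test_that("OLS coefficients match the closed-form normal equations", {
  x <- c(0.2, 1.1, 1.9, 3.2, 4.1)
  y <- c(0.5, 1.0, 2.2, 2.8, 4.4)
  f <- fit_ols_aicc(y, data.frame(x = x), "x")
  b1 <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  b0 <- mean(y) - b1 * mean(x)
  expect_equal(unname(f$coefficients), c(b0, b1), tolerance = 1e-12)
  expect_equal(f$k, 3)
})

test_that("AICc and coefficient SEs agree with the reference linear-model fitter", {
  set.seed(19)
  n <- 32
  tab <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- 0.5 * tab$a + rnorm(n)
  f <- fit_ols_aicc(y, tab, c("a", "b"))
  lmf <- lm(y ~ a + b, data = tab)
  k <- length(coef(lmf)) + 1
  aicc_ref <- AIC(lmf) + 2 * k * (k + 1) / (n - k - 1)
  expect_equal(f$aicc, aicc_ref, tolerance = 1e-8)
  expect_equal(unname(f$coefficients), unname(coef(lmf)), tolerance = 1e-10)
  expect_equal(unname(f$se), unname(summary(lmf)$coefficients[, 2]),
               tolerance = 1e-8)
})

test_that("models too small to correct are skipped with a warning", {
  expect_warning(
    out <- fit_ols_aicc(rnorm(5), as.data.frame(matrix(rnorm(20), 5)),
                        c("V1", "V2", "V3")),
    "too small")
  expect_null(out)
})

test_that("Akaike weights sum to one and are shift invariant", {
  set.seed(29)
  aicc <- runif(20, 100, 140)
  w <- akaike_weights(aicc)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(w, akaike_weights(aicc + 57.3), tolerance = 1e-12)
  expect_error(akaike_weights(c(1, NA)), "finite")
  # a duplicated model gets an identical AICc (determinism)
  y <- rnorm(20); tab <- data.frame(a = rnorm(20))
  expect_identical(fit_ols_aicc(y, tab, "a")$aicc,
                   fit_ols_aicc(y, tab, "a")$aicc)
})

test_that("model averaging limits: single model, equal-weight halving, shrinkage", {
  set.seed(37)
  n <- 30
  tab <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- 1.2 * tab$a + rnorm(n, 0, 0.3)

  single <- fit_ols_aicc(y, tab, "a")
  avg1 <- model_average(list(single))
  expect_equal(avg1$estimate, unname(single$coefficients["a"]))
  expect_equal(avg1$weight_sum, 1)

  # two models with identical AICc, term present in only one: full average
  # halves the coefficient, conditional keeps it
  f <- fit_ols_aicc(y, tab, "a")
  g <- f
  g$terms <- "b"
  g$coefficients <- c(`(Intercept)` = 0)
  g$se <- c(`(Intercept)` = 1)
  avg2 <- model_average(list(f, g), predictors = "a")
  expect_equal(avg2$estimate, unname(f$coefficients["a"]) / 2)
  avg2c <- model_average(list(f, g), predictors = "a",
                         averaging = "conditional")
  expect_equal(avg2c$estimate, unname(f$coefficients["a"]))

  # full-average shrinkage toward zero, term by term
  tab3 <- cbind(tab, data.frame(c = rnorm(n)))
  ma_full <- aicc_average(y, tab3, variables = c("a", "b", "c"),
                          scales = "", sep = "")
  ma_cond <- aicc_average(y, tab3, variables = c("a", "b", "c"),
                          scales = "", sep = "", averaging = "conditional")
  expect_true(all(abs(coef(ma_full)) <= abs(coef(ma_cond)) + 1e-12))
})

test_that("a perfectly explanatory model takes essentially all the weight", {
  set.seed(41)
  n <- 25
  tab <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- 2 * tab$a  # no noise
  fits <- list(fit_ols_aicc(y, tab, "a"), fit_ols_aicc(y, tab, "b"))
  w <- akaike_weights(vapply(fits, `[[`, numeric(1), "aicc"))
  expect_gt(w[1], 0.9999)
})

test_that("the one-call averaging interface is coherent end to end", {
  set.seed(53)
  n <- 32
  vars <- c("veg_height", "cheat_frac", "elevation")
  scales <- c("0.8km", "6.4km", "18km")
  X <- as.data.frame(matrix(rnorm(n * 9), n))
  names(X) <- as.vector(outer(vars, scales, paste, sep = "_"))
  y <- 0.4 * X$veg_height_0.8km - 0.4 * X$cheat_frac_6.4km + rnorm(n, 0, 0.6)
  ma <- aicc_average(y, X)
  expect_s3_class(ma, "lek_modavg")
  expect_equal(nrow(ma$models), 63)
  expect_equal(sum(ma$models$weight), 1, tolerance = 1e-12)
  expect_equal(nrow(ma$average), 9)
  expect_true(all(ma$average$lower <= ma$average$estimate))
  expect_true(all(ma$average$estimate <= ma$average$upper))
  # CI half-width is the 1.96-normal quantile times the SE
  expect_equal(ma$average$upper - ma$average$estimate,
               qnorm(0.975) * ma$average$se, tolerance = 1e-9)
  ci <- confint(ma)
  expect_equal(rownames(ci), ma$average$predictor)
  out <- capture.output(print(ma))
  expect_true(any(grepl("63 models", out)))
})
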