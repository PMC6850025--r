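test_that("AICc and Akaike weights match the closed formulas", {
  expect_equal(aicc(10, 10, 2), 4 + 12 / 7)
  # floor guards exact fits
  expect_equal(aicc(0, 10, 2), 10 * log(1e-12 * 10 / 10) + 4 + 12 / 7)
  # equal fit, fewer parameters, lower AICc
  expect_lt(aicc(5, 20, 2), aicc(5, 20, 3))
  expect_error(aicc(5, 4, 3), "n > k")

  expect_equal(akaike_weights(7), 1)
  w <- akaike_weights(c(0, 2))
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)))
  expect_equal(akaike_weights(c(3, 3, 3, 3)), rep(0.25, 4))

  # random values: sum to one, match hand formula, invariant to shifts
  set.seed(9)
  for (i in 1:100) {
    a <- rnorm(4, sd = 10)
    w <- akaike_weights(a)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    hand <- exp(-(a - min(a)) / 2) / sum(exp(-(a - min(a)) / 2))
    expect_equal(w, hand, tolerance = 1e-10)
    expect_equal(akaike_weights(a + 5), w, tolerance = 1e-12)
  }
})

test_that("step and linear impact models are exact on noiseless data", {
  mk <- function(delta, impact = 1980, nb = 3) {
    years <- (impact - nb):(impact + length(delta) - nb - 1)
    d <- data.frame(year = years, delta = delta, after = years >= impact)
    attr(d, "impact_year") <- impact
    class(d) <- c("difference_series", "data.frame")
    d
  }
  f1 <- fit_impact_model(mk(c(1, 1, 1, 3, 3, 3)), "step")
  expect_equal(unname(f1$coefficients["beta0"]), 1, tolerance = 1e-10)
  expect_equal(unname(f1$coefficients["alpha"]), 2, tolerance = 1e-10)
  expect_lt(f1$rss, 1e-20)

  s <- 0:5
  f2 <- fit_impact_model(mk(c(2, 2, 2, 2 + 0.5 * s), nb = 3), "linear")
  expect_equal(unname(f2$coefficients["beta0"]), 2, tolerance = 1e-10)
  expect_equal(unname(f2$coefficients["alpha"]), 0.5, tolerance = 1e-10)
  expect_lt(f2$rss, 1e-18)
})

test_that("step-model alpha equals the after-minus-before mean difference", {
  set.seed(4)
  for (i in 1:50) {
    d <- simulate_difference_series(sample(c("step", "linear", "none"), 1),
                                    beta0 = rnorm(1), amplitude = runif(1, 0, 5))
    f <- fit_impact_model(d, "step")
    expect_equal(unname(f$coefficients["alpha"]),
                 mean(d$delta[d$after]) - mean(d$delta[!d$after]),
                 tolerance = 1e-10)
    expect_equal(unname(f$coefficients["beta0"]), mean(d$delta[!d$after]),
                 tolerance = 1e-10)
  }
})

test_that("linear-model fit equals closed-form OLS on the post-impact ramp", {
  set.seed(5)
  for (i in 1:20) {
    d <- simulate_difference_series("linear", amplitude = 4)
    f <- fit_impact_model(d, "linear")
    # closed form for regression on x = s * after with an intercept
    x <- ifelse(d$after, d$year - attr(d, "impact_year"), 0)
    b <- sum((x - mean(x)) * (d$delta - mean(d$delta))) /
      sum((x - mean(x))^2)
    a <- mean(d$delta) - b * mean(x)
    expect_equal(unname(f$coefficients["alpha"]), b, tolerance = 1e-10)
    expect_equal(unname(f$coefficients["beta0"]), a, tolerance = 1e-10)
    expect_equal(f$rss, sum((d$delta - a - b * x)^2), tolerance = 1e-10)
  }
})

test_that("asymptotic parameters are recovered from noiseless data", {
  impact <- 1980
  years <- c(1975:1979, 1981:2000)
  s <- ifelse(years >= impact, years - impact, 0)
  delta <- 0 + 4 * ifelse(years >= impact, s / (s + 3), 0)
  d <- data.frame(year = years, delta = delta, after = years >= impact)
  attr(d, "impact_year") <- impact
  f <- fit_impact_model(d, "asymptotic")
  expect_equal(unname(f$coefficients["beta0"]), 0, tolerance = 1e-6)
  expect_equal(unname(f$coefficients["alpha"]), 4, tolerance = 1e-6)
  expect_equal(unname(f$coefficients["gamma"]), 3, tolerance = 1e-4)

  # independent fine-grid search oracle agrees on the optimal gamma
  rss_at <- function(g) {
    fb <- ifelse(d$after, s / (s + g), 0)
    sum(lm(delta ~ fb, data = d)$residuals^2)
  }
  grid <- seq(0.5, 20, by = 0.01)
  g_star <- grid[which.min(vapply(grid, rss_at, numeric(1)))]
  expect_equal(unname(f$coefficients["gamma"]), g_star, tolerance = 0.01)
  expect_lte(f$rss, rss_at(g_star) + 1e-9)
})

test_that("model comparison picks the generating form and normalises weights", {
  set.seed(12)
  d_step <- simulate_difference_series("step", amplitude = 3, noise_sd = 0.3)
  cmp <- compare_models(d_step)
  expect_equal(cmp$best, "step")
  expect_gt(cmp$table$weight[cmp$table$model == "step"], 0.5)
  expect_equal(sum(cmp$table$weight), 1, tolerance = 1e-12)
  expect_equal(min(cmp$table$delta_aicc), 0)

  d_lin <- simulate_difference_series("linear", amplitude = 3, noise_sd = 0.3)
  expect_equal(compare_models(d_lin)$best, "linear")

  # candidate order does not change weights or the winner
  cmp_r <- compare_models(d_step, models = c("sigmoid", "asymptotic",
                                             "linear", "step"))
  expect_equal(cmp_r$best, "step")
  expect_equal(sort(cmp_r$table$weight), sort(cmp$table$weight),
               tolerance = 1e-9)

  # constant series: no significant effect, parsimony picks the step
  d0 <- simulate_difference_series("none", noise_sd = 0)
  d0$delta <- d0$delta + 1  # exactly constant
  cmp0 <- compare_models(d0)
  expect_equal(cmp0$best, "step")
  expect_lt(abs(unname(cmp0$best_fit$coefficients["alpha"])), 1e-8)
})

test_that("best-model p-value reduces to the classical tests", {
  set.seed(21)
  d <- simulate_difference_series("step", amplitude = 2)
  cmp <- compare_models(d, models = c("step", "linear"))
  # step F-test against the constant null is the two-sample t-test
  tt <- t.test(delta ~ after, data = d, var.equal = TRUE)
  f_step <- fit_impact_model(d, "step")
  tss <- sum((d$delta - mean(d$delta))^2)
  F_ <- (tss - f_step$rss) / (f_step$rss / (nrow(d) - 2))
  expect_equal(F_, unname(tt$statistic)^2, tolerance = 1e-9)

  d_lin <- simulate_difference_series("linear", amplitude = 2)
  cmp_lin <- compare_models(d_lin)
  if (cmp_lin$best == "linear") {
    x <- ifelse(d_lin$after, d_lin$year - 1980, 0)
    sm <- summary(lm(d_lin$delta ~ x))
    expect_equal(cmp_lin$p_value, sm$coefficients[2, 4], tolerance = 1e-9)
  }
})

test_that("stationarity check reproduces a hand-rolled OLS on before-years", {
  set.seed(31)
  d <- simulate_difference_series("step")
  st <- test_stationarity(d)
  before <- d[!d$after, ]
  o <- oracle_ols(before$year, before$delta)
  expect_equal(st$slope, o$slope, tolerance = 1e-10)
  expect_equal(st$p_value, o$p, tolerance = 1e-10)
  expect_true(st$pass)

  # constructed violation: strong pre-impact trend
  d$delta[!d$after] <- d$delta[!d$after] + 2 * seq_len(sum(!d$after))
  expect_false(test_stationarity(d)$pass)

  expect_error(test_stationarity(d[d$year >= 1978, ]), "3 before")
})

test_that("warming-trend comparison matches simple-regression formulas", {
  set.seed(41)
  years <- 1989:2003
  h <- data.frame(year = years, temperature = 20 + 0.03 * (years - 1989) +
                    rnorm(15, 0, 0.4))
  r <- data.frame(year = years, temperature = 14 + 0.028 * (years - 1989) +
                    rnorm(15, 0, 0.4))
  tc <- compare_warming_trends(h, r)
  o <- oracle_ols(years, h$temperature - r$temperature)
  expect_equal(tc$slope, o$slope, tolerance = 1e-10)
  expect_equal(tc$f_statistic, o$f, tolerance = 1e-8)
  expect_equal(tc$r_squared, o$r2, tolerance = 1e-10)
  expect_equal(tc$df, c(1, 13))

  # constructed trend difference of 0.1 degC/yr, no noise
  h2 <- data.frame(year = years, temperature = 20 + 0.1 * (years - 1989))
  r2 <- data.frame(year = years, temperature = 14)
  expect_equal(compare_warming_trends(h2, r2)$slope, 0.1, tolerance = 1e-10)

  expect_error(compare_warming_trends(h[1:3, ], r[1:3, ]), "4 common")
})
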