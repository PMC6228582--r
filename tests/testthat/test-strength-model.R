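test_that("log strength floors weak promoters before the natural log", {
  expect_equal(log_strength(1), 0)
  expect_equal(log_strength(0.01), -4.60517019, tolerance = 1e-8)
  expect_equal(log_strength(0), log(1e-4))
  expect_equal(log_strength(5e-5), log(1e-4))
  expect_error(log_strength(-0.1), "negative")
})

test_that("featurize builds scores, combined column and response", {
  expect_equal(nrow(featurize(promoter_records(character(), character(),
                                               character(), numeric()))), 0)

  tab <- featurize(anderson_fixture())
  expect_equal(tab$s35[1], 6.5966)
  expect_equal(tab$s10[1], 2.398)
  expect_equal(tab$combined, tab$s35 + tab$s10)
  expect_equal(tab$y, log_strength(tab$strength))

  # with real PWMs the features are the hexamer scores
  p35 <- fixture_pwm(seed = 1); p10 <- fixture_pwm(seed = 2)
  rec <- promoter_records("x", "TTGACA", "TATAAT", 0.5)
  tab <- featurize(rec, p35, p10)
  expect_equal(tab$s35, score_hexamer(p35, "TTGACA"))
  expect_equal(tab$s10, score_hexamer(p10, "TATAAT"))
})

test_that("exact least squares recovers noiseless coefficients and satisfies the normal equations", {
  tab <- synthetic_table(n = 30, beta = c(1, 2, -3), sigma = 0)
  fit <- fit_ols(tab)
  expect_equal(unname(fit$coefficients), c(1, 2, -3), tolerance = 1e-10)

  # residuals orthogonal to each column of the design (random noisy tables)
  for (seed in 1:3) {
    tab <- synthetic_table(n = 50, beta = c(-2, 0.5, 0.3), sigma = 1,
                           seed = seed)
    fit <- fit_ols(tab)
    expect_lt(abs(sum(fit$residuals)), 1e-8)
    expect_lt(abs(sum(fit$residuals * tab$s35)), 1e-8)
    expect_lt(abs(sum(fit$residuals * tab$s10)), 1e-8)
  }

  # collinear features are refused
  bad <- synthetic_table(n = 20)
  bad$s10 <- 2 * bad$s35
  expect_error(fit_ols(bad), "collinear")
  expect_error(fit_ols(synthetic_table(n = 3)), "at least 4")
})

test_that("fit and inference agree with R's reference implementation", {
  for (seed in c(7, 8)) {
    tab <- synthetic_table(n = 25, beta = c(-4, 0.4, 0.25), sigma = 0.8,
                           seed = seed)
    fit <- fit_ols(tab)
    st <- model_stats(fit, tab)
    ref <- lm(y ~ s35 + s10, data = tab)
    expect_equal(unname(fit$coefficients), unname(coef(ref)),
                 tolerance = 1e-10)
    sref <- summary(ref)
    expect_equal(st$r2, sref$r.squared, tolerance = 1e-12)
    expect_equal(st$adj_r2, sref$adj.r.squared, tolerance = 1e-12)
    expect_equal(st$coefficients$se, unname(sref$coefficients[, 2]),
                 tolerance = 1e-10)
    expect_equal(st$coefficients$p, unname(sref$coefficients[, 4]),
                 tolerance = 1e-10)
    ci <- confint(ref)
    expect_equal(st$coefficients$ci_lower, unname(ci[, 1]), tolerance = 1e-10)
    expect_equal(st$coefficients$ci_upper, unname(ci[, 2]), tolerance = 1e-10)
    expect_equal(st$f_statistic, unname(sref$fstatistic[1]),
                 tolerance = 1e-10)
  }
})

test_that("R2 equals the squared correlation of fitted and observed", {
  tab <- synthetic_table(n = 40, sigma = 2, seed = 9)
  fit <- fit_ols(tab)
  st <- model_stats(fit, tab)
  expect_equal(st$r2, cor(fit$fitted, tab$y)^2, tolerance = 1e-10)
})

test_that("adjusted R2 penalizes model complexity per the closed form", {
  expect_equal(adjusted_r2(1, 18, 2), 1)
  expect_equal(adjusted_r2(0.5, 20, 0), 0.5)
  expect_equal(round(adjusted_r2(0.69, 18, 2), 4), 0.6487)
  expect_error(adjusted_r2(0.5, 3, 2), "n > m \\+ 1")
})

test_that("gradient descent matches the exact solution when it converges", {
  tab <- featurize(anderson_fixture())
  ols <- fit_ols(tab)
  gd <- fit_gradient_descent(tab, learning_rate = 0.015, iterations = 1e5)
  expect_equal(unname(gd$coefficients), unname(ols$coefficients),
               tolerance = 1e-3)
  expect_gte(cor(gd$fitted, ols$fitted), 0.998)
  expect_equal(gd$fit_method, "gradient_descent")
  expect_equal(gd$learning_rate, 0.015)
  # cost is non-increasing along the recorded trajectory
  expect_true(all(diff(gd$cost_trace) <= 1e-12))

  # feature scaling reaches the same raw-scale coefficients
  gds <- fit_gradient_descent(tab, learning_rate = 0.1, iterations = 2e4,
                              feature_scaling = TRUE)
  expect_equal(unname(gds$coefficients), unname(ols$coefficients),
               tolerance = 1e-6)
})

test_that("gradient descent is exact on a zero response and rejects divergence", {
  tab <- synthetic_table(n = 20, seed = 2)
  tab$y <- rep(0, 20)
  gd <- fit_gradient_descent(tab, iterations = 10)
  expect_equal(unname(gd$coefficients), c(0, 0, 0))
  expect_equal(gd$final_cost, 0)

  noisy <- synthetic_table(n = 20, sigma = 1, seed = 3)
  expect_error(fit_gradient_descent(noisy, learning_rate = 5, iterations = 1e4),
               "diverging")
})

test_that("rescaling all strengths shifts only the intercept, by ln c", {
  rec <- anderson_fixture()
  base <- fit_ols(featurize(rec))
  for (c_ in c(0.5, 0.25)) {
    scaled <- rec
    scaled$strength <- scaled$strength * c_
    fit <- fit_ols(featurize(scaled))
    expect_equal(unname(fit$coefficients[2:3]),
                 unname(base$coefficients[2:3]), tolerance = 1e-10)
    expect_equal(unname(fit$coefficients[1]),
                 unname(base$coefficients[1]) + log(c_), tolerance = 1e-10)
  }
})

test_that("predictions apply the linear map and exponentiate for strength", {
  tab <- featurize(anderson_fixture())
  fit <- fit_ols(tab)
  expect_equal(predict_strength(fit, 0, 0),
               exp(unname(fit$coefficients[1])))
  expect_equal(predict_log_strength(fit, tab$s35, tab$s10), fit$fitted)
  # noiseless model predicts exactly
  syn <- synthetic_table(n = 12, beta = c(0.5, 1, -1), sigma = 0)
  f <- fit_ols(syn)
  expect_equal(predict_log_strength(f, 2, 3), 0.5 + 2 - 3, tolerance = 1e-9)
})

test_that("perfect fits report zero-width intervals with a warning", {
  tab <- synthetic_table(n = 12, beta = c(1, 2, -3), sigma = 0)
  fit <- fit_ols(tab)
  expect_warning(st <- model_stats(fit, tab), "zero residual variance")
  expect_equal(st$coefficients$ci_lower, st$coefficients$ci_upper,
               tolerance = 1e-9)
  expect_equal(st$coefficients$estimate, c(1, 2, -3), tolerance = 1e-9)
})

test_that("variant comparison recovers an injected interaction", {
  set.seed(77)
  n <- 60
  s35 <- runif(n, 0, 8); s10 <- runif(n, -4, 8)
  y <- -2 + 0.4 * s35 + 0.3 * s10 + 0.15 * s35 * s10 + rnorm(n, 0, 0.5)
  tab <- structure(
    data.frame(id = paste0("p", 1:n), s35 = s35, s10 = s10,
               combined = s35 + s10, y = y, strength = exp(pmin(y, 0))),
    class = c("feature_table", "data.frame"))
  vm <- fit_variant_models(tab)
  expect_lt(vm$interaction$p[["s35:s10"]], 0.05)
  expect_equal(unname(vm$interaction$coefficients[4]), 0.15,
               tolerance = 0.05)
  expect_named(vm$summary, c("model", "response", "adj_r2"))
  # interaction fit nests the main model, so its raw R2 cannot be lower
  expect_gte(vm$interaction$r2, vm$main$r2)
})

test_that("a fitted model survives a JSON round trip", {
  tab <- featurize(anderson_fixture())
  fit <- fit_ols(tab)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(fit, path, stats = model_stats(fit, tab))
  back <- read_model(path)
  expect_equal(back$coefficients, fit$coefficients, tolerance = 1e-12)
  expect_equal(predict_strength(back, 9.1308, 10.086),
               predict_strength(fit, 9.1308, 10.086))
})
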