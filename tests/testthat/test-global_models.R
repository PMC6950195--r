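test_that("OLS interpolates noiseless data exactly", {
  sim <- toy_panel(S = 3, T = 10, seed = 21)
  ds <- sim$ds
  ds$data$pm25 <- 1 + 2 * ds$data$pm10
  fit <- fit_ols(ds)
  expect_equal(unname(fit$beta), c(1, 0, 0, 2, 0, 0), tolerance = 1e-8)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-8)
  expect_equal(fit$ra2, 1, tolerance = 1e-12)
})

test_that("OLS matches the explicit normal-equations solve", {
  ds <- toy_panel(S = 4, T = 20, seed = 22)$ds
  fit <- fit_ols(ds)
  X <- design_matrix(ds)
  y <- ds$data$pm25
  beta_ne <- solve(t(X) %*% X) %*% t(X) %*% y
  expect_equal(unname(fit$beta), unname(drop(beta_ne)), tolerance = 1e-8)
  # residual orthogonality to every design column
  expect_lt(max(abs(t(X) %*% fit$residuals)) / max(abs(y)), 1e-8)
})

test_that("standardized estimates follow the sd-ratio definition", {
  set.seed(23)
  x <- drop(scale(rnorm(40)))          # sd exactly 1
  data <- data.frame(city_id = 1, city_name = "a", x = 0, y = 0,
                     week = 1:40, pm10 = x, pm25 = 2 * x)
  ds <- panel_dataset(data, predictors = "pm10", response = "pm25",
                      units = c(pm10 = "ug/m3", pm25 = "ug/m3"))
  fit <- fit_ols(ds)
  expect_equal(unname(fit$standardized["pm10"]), 1, tolerance = 1e-10)
  expect_equal(unname(fit$standardized["intercept"]), 0)
})

test_that("rank-deficient designs are reported with the collinear column", {
  ds <- toy_panel(S = 3, T = 10, seed = 24)$ds
  ds$data$o3 <- ds$data$so2
  expect_error(fit_ols(ds), "rank deficient")
})

test_that("the AR(1) covariance matches its closed form and is PD", {
  expect_equal(ar1_covariance(0, 2, 4), 2 * diag(4))
  expect_equal(ar1_covariance(0.5, 1, 3),
               matrix(c(1, .5, .25, .5, 1, .5, .25, .5, 1), 3))
  for (r in c(-0.95, -0.3, 0.6, 0.99)) {
    expect_no_error(chol(ar1_covariance(r, 1.7, 12)))
  }
  expect_error(ar1_covariance(1, 1, 3), "< 1")
})

test_that("the REML objective is a pure function and matches a dense oracle", {
  ds <- toy_panel(S = 2, T = 4, seed = 25)$ds
  theta <- c(log(c(2, .5, .3, .2, 1, .1)), atanh(0.4), log(1.5))
  v1 <- reml_objective(theta, ds)
  v2 <- reml_objective(theta, ds)
  expect_identical(v1, v2)
  expect_equal(v1, dense_reml_oracle(theta, ds), tolerance = 1e-8)

  ds2 <- toy_panel(S = 3, T = 7, seed = 26)$ds
  theta2 <- c(log(c(.1, .02, .3, 1.2, .5, .04)), atanh(-0.3), log(0.7))
  expect_equal(reml_objective(theta2, ds2), dense_reml_oracle(theta2, ds2),
               tolerance = 1e-8)
})

test_that("the REML objective approaches the OLS restricted likelihood as G -> 0", {
  ds <- toy_panel(S = 3, T = 12, seed = 27)$ds
  ols <- fit_ols(ds)
  s2 <- sum(ols$residuals^2) / ols$n
  theta <- c(rep(log(1e-12), 6), atanh(0), log(s2))
  X <- design_matrix(ds)
  n <- ols$n; p <- ols$p
  # log|V| + log|X'V^-1 X| + RSS/s2 + (n-p) log 2pi  with V = s2 I
  expected <- n * log(s2) + determinant(t(X) %*% X)$modulus -
    p * log(s2) + sum(ols$residuals^2) / s2 + (n - p) * log(2 * pi)
  expect_equal(reml_objective(theta, ds), as.numeric(expected),
               tolerance = 1e-6)
})

test_that("the REML objective returns +Inf rather than erroring on overflow", {
  ds <- toy_panel(S = 2, T = 8, seed = 28)$ds
  expect_identical(reml_objective(c(rep(700, 6), 0, -700), ds), Inf)
})

test_that("the fitted optimum is a local minimum of the REML objective", {
  ds <- toy_panel(S = 4, T = 30, seed = 29)$ds
  fit <- fit_lmm(ds)
  f0 <- reml_objective(fit$theta, ds)
  set.seed(1)
  for (i in 1:10) {
    expect_gte(reml_objective(fit$theta + rnorm(8, sd = 0.15), ds),
               f0 - 1e-6)
  }
})

test_that("the mixed model reduces to OLS without random effects or AR(1)", {
  cfg <- sim_config(n_locations = 6, n_times = 30, seed = 30,
                    re_sd = rep(0, 6), ar1_r = 0)
  ds <- simulate_panel(cfg)$ds
  lmm <- fit_lmm(ds)
  ols <- fit_ols(ds)
  expect_true(all(abs(lmm$beta_fixed - ols$beta) < 2 * ols$se))
  expect_lt(abs(lmm$ar1_r), 0.15)
})

test_that("a single-draw LMM fit recovers the AR(1) correlation roughly", {
  ds <- simulate_panel(sim_config(n_locations = 8, n_times = 80,
                                  seed = 31))$ds
  fit <- fit_lmm(ds)
  expect_true(fit$converged)
  expect_lt(abs(fit$ar1_r - 0.552), 0.15)
  expect_true(all(fit$var_components >= 0))
  expect_lt(abs(fit$ar1_r), 1)
})

test_that("city-level models are the fixed effects plus BLUPs, centred", {
  ds <- simulate_panel(sim_config(n_locations = 10, n_times = 60,
                                  seed = 32))$ds
  fit <- fit_lmm(ds)
  cm <- city_models(fit)
  expect_equal(cm - fit$gamma,
               matrix(fit$beta_fixed, nrow(cm), 6, byrow = TRUE,
                      dimnames = dimnames(cm)),
               tolerance = 1e-12)
  # BLUPs average out near zero, so city models straddle the fixed effects
  expect_lt(abs(mean(cm[, "pm10"]) - fit$beta_fixed["pm10"]),
            3 * 0.095 / sqrt(10))
})

test_that("a strongly elevated city slope survives BLUP shrinkage", {
  hits <- vapply(1:20, function(s) {
    cfg <- sim_config(n_locations = 5, n_times = 24, seed = s)
    sim <- simulate_panel(cfg)
    ds <- sim$ds
    bump <- 3 * cfg$re_sd[["pm10"]]
    sel <- ds$data$city_id == 1
    ds$data$pm25[sel] <- ds$data$pm25[sel] + bump * ds$data$pm10[sel]
    fit <- fit_lmm(ds)
    city_models(fit)[1, "pm10"] > fit$beta_fixed[["pm10"]]
  }, logical(1))
  expect_gte(sum(hits), 18)
})

test_that("conditional R2 evaluates its variance decomposition exactly", {
  set.seed(33)
  x <- drop(scale(rnorm(50)))
  data <- data.frame(city_id = rep(1:2, each = 25), city_name = "a",
                     x = 0, y = 0, week = rep(1:25, 2), pm10 = x,
                     pm25 = x)
  data$city_name <- rep(c("a", "b"), each = 25)
  data$x <- rep(c(0, 1), each = 25)
  ds <- panel_dataset(data, predictors = "pm10", response = "pm25",
                      units = c(pm10 = "ug/m3", pm25 = "ug/m3"))
  fake <- structure(list(beta_fixed = c(0, 1), var_components = c(1, 0),
                         resid_var = 2), class = "lmm_fit")
  # sigma_f^2 = var(x) = 1, sigma_r^2 = 1, sigma_e^2 = 2 -> 0.5
  expect_equal(conditional_r2(fake, ds), 0.5, tolerance = 1e-12)
  fake0 <- structure(list(beta_fixed = c(0, 1), var_components = c(0, 0),
                          resid_var = 1e-12), class = "lmm_fit")
  expect_equal(conditional_r2(fake0, ds), 1, tolerance = 1e-6)
})

test_that("conditional R2 of real fits lies in [0, 1]", {
  for (s in 34:36) {
    ds <- simulate_panel(sim_config(n_locations = 5, n_times = 30,
                                    seed = s))$ds
    fit <- fit_lmm(ds)
    expect_gte(fit$rc2, 0)
    expect_lte(fit$rc2, 1)
  }
})

test_that("the REML fit agrees with nlme on a mid-size panel", {
  skip_if_not_installed("nlme")
  ds <- simulate_panel(sim_config(n_locations = 8, n_times = 60,
                                  seed = 37))$ds
  fit <- fit_lmm(ds)
  d <- ds$data
  d$city <- factor(d$city_id)
  m <- nlme::lme(pm25 ~ so2 + no2 + pm10 + co + o3,
                 random = list(city = nlme::pdDiag(~so2 + no2 + pm10 + co + o3)),
                 correlation = nlme::corAR1(form = ~week | city),
                 data = d, method = "REML",
                 control = nlme::lmeControl(opt = "optim", maxIter = 150,
                                            msMaxIter = 150))
  r_nlme <- as.numeric(stats::coef(m$modelStruct$corStruct,
                                   unconstrained = FALSE))
  expect_equal(fit$ar1_r, r_nlme, tolerance = 0.05)
  expect_equal(unname(fit$beta_fixed), unname(nlme::fixef(m)),
               tolerance = 0.15)
})
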