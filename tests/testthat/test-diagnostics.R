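test_that("fit metrics evaluate their formulas exactly", {
  y <- c(3, -4)
  expect_equal(unname(fit_metrics(y, c(0, 0), p_eff = 0)[c("rmse", "mae")]),
               c(sqrt(12.5), 3.5))

  set.seed(61)
  y2 <- rnorm(10)
  a <- sqrt(0.5)                           # residual scale leaving R^2 = 0.5
  yhat2 <- mean(y2) + (1 - a) * (y2 - mean(y2))
  expect_equal(unname(fit_metrics(y2, yhat2, p_eff = 2)["ra2"]),
               1 - 9 * 0.5 / 8, tolerance = 1e-12)

  perfect <- fit_metrics(y2, y2, p_eff = 2)
  expect_equal(unname(perfect), c(1, 0, 0))
  expect_error(fit_metrics(rep(1, 5), rnorm(5), 1), "constant")
})

test_that("Z scores standardize residuals by the sd of fitted values", {
  z <- z_scores(c(1, 1), c(0, 2))
  expect_equal(z, c(1 / sqrt(2), -1 / sqrt(2)))
  expect_equal(z_scores(c(1, 2, 3), c(1, 2, 3)), c(0, 0, 0))
  expect_error(z_scores(c(1, 2), c(3, 3)), "constant")

  ds <- toy_panel(S = 4, T = 20, seed = 62)$ds
  ols <- fit_ols(ds)
  expect_lt(abs(mean(z_scores(ds$data$pm25, ols$fitted))), 1e-10)
})

test_that("kNN weights follow the deterministic tie rule", {
  # records 2 and 3 are exactly tied at distance 1 from record 1; the tie
  # resolves to the lower (city_id, week) rank
  tri <- coord_panel(data.frame(x = c(0, 1, 0), y = c(0, 0, 1)))
  w <- knn_binary_weights(tri, 1)
  expect_equal(as.vector(w$nb), c(2L, 1L, 1L))

  sq <- coord_panel(data.frame(x = c(0, 1, 0, 1), y = c(0, 0, 1, 1)))
  w3 <- knn_binary_weights(sq, 3)
  expect_equal(w3$W, 4 * 3)
  expect_true(all(apply(w3$nb, 1, function(r) !anyDuplicated(r))))

  # co-located city records: nearest neighbours come from the same city
  ds <- toy_panel(S = 3, T = 5, seed = 63)$ds
  w4 <- knn_binary_weights(ds, 4)
  own <- ds$data$city_id[as.vector(w4$nb)]
  expect_true(all(own == rep(ds$data$city_id, 4)))
  expect_error(knn_binary_weights(tri, 3), "smaller")
})

test_that("Moran's I matches the printed two-point case and exact expectation", {
  two <- coord_panel(data.frame(x = c(0, 1), y = c(0, 0)))
  w <- knn_binary_weights(two, 1)
  m <- morans_i(c(1, -1), w)
  expect_equal(m$I, -1)
  expect_equal(m$expected, -1)
  for (n in c(2, 5, 50)) {
    dsn <- coord_panel(data.frame(x = seq_len(n), y = 0))
    expect_equal(morans_i(rnorm(n) + 1:n, knn_binary_weights(dsn, 1))$expected,
                 -1 / (n - 1))
  }
  expect_error(morans_i(rep(1, 2), w), "constant")
})

test_that("Moran's I agrees with an independent implementation", {
  skip_if_not_installed("ape")
  ds <- toy_panel(S = 5, T = 12, seed = 64)$ds
  w <- knn_binary_weights(ds, 5)
  set.seed(64)
  e <- rnorm(n_records(ds))
  A <- matrix(0, w$n, w$n)
  A[cbind(rep(seq_len(w$n), w$k), as.vector(w$nb))] <- 1
  ref <- ape::Moran.I(e, A, scaled = FALSE)
  ours <- morans_i(e, w)
  expect_equal(ours$I, ref$observed, tolerance = 1e-12)
  expect_equal(ours$expected, ref$expected, tolerance = 1e-12)
})

test_that("Moran's I is centred on -1/(n-1) under an iid null", {
  ds <- toy_panel(S = 10, T = 50, seed = 65)$ds
  w <- knn_binary_weights(ds, 8)
  set.seed(65)
  Is <- replicate(50, morans_i(rnorm(500), w)$I)
  expect_lt(abs(mean(Is) + 1 / 499), 0.01)
})

test_that("clustered residuals give positive Moran's I, detected by both methods", {
  cl <- coord_panel(data.frame(x = c(seq(0, 0.4, by = 0.1),
                                     seq(5, 5.4, by = 0.1)),
                               y = rep(0, 10)))
  w <- knn_binary_weights(cl, 4)
  e <- c(1, 1.1, 0.9, 1.2, 0.8, -1, -1.1, -0.9, -1.2, -0.8)
  ma <- morans_i(e, w, method = "analytic")
  mp <- morans_i(e, w, method = "permutation", n_perm = 499, seed = 2)
  expect_gt(ma$I, 0)
  expect_equal(mp$I, ma$I)
  expect_lt(mp$p_two_tailed, 0.05)
})

test_that("the Moran curve has one row per bandwidth and tightens with k", {
  ds <- toy_panel(S = 8, T = 25, seed = 66)$ds
  k_grid <- c(8, 20, 60, 150)
  set.seed(66)
  mc <- moran_curve(rnorm(200), ds, k_grid)
  expect_equal(nrow(mc), length(k_grid))
  expect_equal(mc$k, k_grid)

  shrink <- vapply(1:20, function(s) {
    set.seed(100 + s)
    m <- moran_curve(rnorm(200), ds, c(8, 150))
    abs(m$I[2]) <= abs(m$I[1])
  }, logical(1))
  expect_gte(sum(shrink), 16)
})

test_that("the pollutant correlation matrix is symmetric with unit diagonal", {
  ds <- toy_panel(S = 5, T = 30, seed = 67)$ds
  C <- corr_matrix(ds)
  expect_equal(diag(C), stats::setNames(rep(1, 6), colnames(C)))
  expect_equal(C, t(C), tolerance = 1e-12)

  ds$data$no2 <- ds$data$so2
  expect_equal(corr_matrix(ds)["so2", "no2"], 1)
  ds$data$o3 <- 1
  expect_error(corr_matrix(ds), "o3")
})

test_that("comparison tables report OLS-relative reductions and catch mismatches", {
  ds <- toy_panel(S = 5, T = 30, seed = 68, mode = "varying")$ds
  ols <- fit_ols(ds)
  only_ols <- compare_models(list(ols = ols), ds)
  expect_equal(nrow(only_ols), 1L)
  expect_equal(only_ols$rmse_reduction_pct, 0)
  expect_equal(only_ols$z_mean, 0, tolerance = 1e-10)

  twr <- fit_stwr(ds, kernel_config("temporal", "gaussian", k = 20))
  tab <- compare_models(list(ols = ols, twr = twr), ds)
  expect_gt(tab$r2[tab$model == "twr"], tab$r2[tab$model == "ols"])
  expect_gt(tab$rmse_reduction_pct[tab$model == "twr"], 0)

  other <- toy_panel(S = 5, T = 30, seed = 69)$ds
  expect_error(compare_models(list(ols = ols), other), "match")
})

test_that("the all-ones-weight local fit fills an identical row to OLS", {
  ds <- toy_panel(S = 5, T = 25, seed = 70)$ds
  ols <- fit_ols(ds)
  uni <- fit_stwr(ds, kernel_config("spatial", "boxcar", k = n_records(ds)))
  tab <- compare_models(list(ols = ols, uniform = uni), ds)
  for (col in c("aicc", "r2", "rmse", "mae", "z_mean", "z_std")) {
    expect_equal(tab[[col]][1], tab[[col]][2], tolerance = 1e-8)
  }
})
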