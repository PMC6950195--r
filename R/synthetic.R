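# Synthetic city-by-week pollutant panels.
#
# The generator emulates the structure of a 13-city x 210-week criteria-
# pollutant panel: seasonal cycles shared across pollutants through a
# "heating season" latent factor (loading positively on SO2, NO2, PM10, CO
# and negatively on O3, which is photochemical and peaks in summer), city
# mean offsets, AR(1) week-to-week noise, and a PM2.5 response generated
# either from a mixed model (city random effects + AR(1) errors) or from
# smoothly space-time-varying coefficients.

#' Configuration of the synthetic panel generator
#'
#' Defaults encode the emulated study design: 13 cities observed for 210
#' weeks (2730 records), a 52-week seasonal period, pollutant mean levels at
#' the study's descriptive means, response coefficients at the study's
#' global OLS estimates, city random-effect scales at the square roots of
#' its reported variance components, residual AR(1) correlation 0.552 and
#' residual standard deviation sqrt(75.11).
#'
#' @param n_locations number of cities (>= 2).
#' @param n_times number of weekly periods (>= 3).
#' @param seed integer seed; all generator randomness derives from it.
#' @param period weeks per seasonal cycle.
#' @param mean_levels named vector of predictor means (so2, no2, pm10 and o3
#'   in ug/m3; co in mg/m3).
#' @param seasonal_loadings signed amplitude with which the shared
#'   heating-season factor enters each predictor; the negative o3 loading
#'   induces the negative PM2.5-O3 correlation.
#' @param pred_city_sd per-predictor standard deviation of city mean offsets.
#' @param pred_noise_sd per-predictor standard deviation of idiosyncratic
#'   AR(1) noise.
#' @param pred_ar1 AR(1) coefficient of the predictor noise.
#' @param factor_noise_sd standard deviation of the AR(1) perturbation of the
#'   shared seasonal factor (per city).
#' @param beta global response coefficients (intercept, so2, no2, pm10, co,
#'   o3).
#' @param re_sd random-effect standard deviations per city for intercept and
#'   the five slopes (mixed mode).
#' @param ar1_r first-order autocorrelation of the response errors, |r| < 1.
#' @param resid_sd marginal standard deviation of the response errors.
#' @param nonstat_space,nonstat_time relative amplitudes of spatial/temporal
#'   coefficient variation (varying mode).
#' @param mode `"mixed"` (random effects + AR(1) errors) or `"varying"`
#'   (space-time-varying coefficients + white noise).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_locations = 13L,
                       n_times = 210L,
                       seed = 1L,
                       period = 52,
                       mean_levels = c(so2 = 16.48, no2 = 22.95, pm10 = 58.67,
                                       co = 0.72, o3 = 72.16),
                       seasonal_loadings = c(so2 = 10, no2 = 7.5, pm10 = 23,
                                             co = 0.23, o3 = -15),
                       pred_city_sd = c(so2 = 3, no2 = 3, pm10 = 8,
                                        co = 0.08, o3 = 5),
                       pred_noise_sd = c(so2 = 5, no2 = 4, pm10 = 11,
                                         co = 0.10, o3 = 8),
                       pred_ar1 = 0.4,
                       factor_noise_sd = 0.3,
                       beta = c(intercept = -4.398, so2 = 0.081, no2 = 0.380,
                                pm10 = 0.520, co = 5.640, o3 = -0.086),
                       re_sd = c(intercept = 8.837, so2 = 0.148, no2 = 0.286,
                                 pm10 = 0.095, co = 12.530, o3 = 0.032),
                       ar1_r = 0.552,
                       resid_sd = 8.667,
                       nonstat_space = 0.3,
                       nonstat_time = 0.5,
                       mode = c("mixed", "varying")) {
  mode <- match.arg(mode)
  stopifnot(
    n_locations >= 2L, n_times >= 3L,
    abs(ar1_r) < 1, abs(pred_ar1) < 1,
    all(re_sd >= 0), resid_sd >= 0, all(pred_noise_sd >= 0),
    all(pred_city_sd >= 0), factor_noise_sd >= 0,
    length(beta) == 6L, length(re_sd) == 6L,
    period > 0
  )
  structure(
    list(n_locations = as.integer(n_locations), n_times = as.integer(n_times),
         seed = as.integer(seed), period = period,
         mean_levels = mean_levels, seasonal_loadings = seasonal_loadings,
         pred_city_sd = pred_city_sd, pred_noise_sd = pred_noise_sd,
         pred_ar1 = pred_ar1, factor_noise_sd = factor_noise_sd,
         beta = beta, re_sd = re_sd, ar1_r = ar1_r, resid_sd = resid_sd,
         nonstat_space = nonstat_space, nonstat_time = nonstat_time,
         mode = mode),
    class = "sim_config"
  )
}

# Stationary AR(1) series with marginal sd `sd` and coefficient `phi`.
.ar1_series <- function(n, phi, sd) {
  if (sd == 0 || n == 0L) return(numeric(n))
  innov_sd <- sd * sqrt(1 - phi^2)
  e <- numeric(n)
  e[1L] <- stats::rnorm(1L, sd = sd)
  if (n > 1L) {
    eta <- stats::rnorm(n - 1L, sd = innov_sd)
    for (t in 2:n) e[t] <- phi * e[t - 1L] + eta[t - 1L]
  }
  e
}

#' Generate city locations on the unit square
#'
#' @param S number of cities (>= 2).
#' @param seed integer seed.
#' @return data.frame with columns `city_id`, `city_name`, `x`, `y`; the
#'   layout is a deterministic function of `seed`.
#' @export
gen_locations <- function(S, seed = 1L) {
  if (S < 2L) stop("need at least 2 locations", call. = FALSE)
  set.seed(seed)
  data.frame(
    city_id = seq_len(S),
    city_name = sprintf("city_%02d", seq_len(S)),
    x = stats::runif(S),
    y = stats::runif(S)
  )
}

#' Generate the predictor panel
#'
#' Each predictor is mean level + signed loading times a shared seasonal
#' heating factor (a sinusoid with period `cfg$period`, perturbed by AR(1)
#' noise per city) + a city offset + idiosyncratic AR(1) noise, floored at a
#' small positive constant.
#'
#' @param cfg a [sim_config()].
#' @param locations data.frame from [gen_locations()].
#' @return data.frame ordered by (city_id, week) with columns `city_id`,
#'   `week` and one column per predictor; `cfg$n_locations * cfg$n_times`
#'   rows.
#' @export
gen_predictors <- function(cfg, locations) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  S <- nrow(locations)
  T <- cfg$n_times
  preds <- names(cfg$mean_levels)
  weeks <- seq_len(T)
  season <- sin(2 * pi * weeks / cfg$period + pi / 2)

  out <- vector("list", S)
  for (s in seq_len(S)) {
    factor_st <- season + .ar1_series(T, cfg$pred_ar1, cfg$factor_noise_sd)
    block <- matrix(0, T, length(preds), dimnames = list(NULL, preds))
    for (k in preds) {
      offset <- stats::rnorm(1L, sd = cfg$pred_city_sd[[k]])
      noise <- .ar1_series(T, cfg$pred_ar1, cfg$pred_noise_sd[[k]])
      block[, k] <- cfg$mean_levels[[k]] +
        cfg$seasonal_loadings[[k]] * factor_st + offset + noise
    }
    block <- pmax(block, 0.01)
    out[[s]] <- data.frame(city_id = locations$city_id[s], week = weeks, block)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

.sim_truth <- function(beta_global, gamma, beta_local, variance_components,
                       epsilon) {
  structure(
    list(beta_global = beta_global, gamma = gamma, beta_local = beta_local,
         variance_components = variance_components, epsilon = epsilon),
    class = "sim_truth"
  )
}

#' Generate a mixed-model response
#'
#' Draws `y = X beta + Z gamma + eps` with per-city random effects
#' `gamma ~ N(0, diag(re_sd^2))` on the intercept and all five slopes, and
#' per-city AR(1) errors with coefficient `ar1_r` and marginal standard
#' deviation `resid_sd`.
#'
#' @param cfg a [sim_config()].
#' @param locations data.frame from [gen_locations()].
#' @param Xpanel predictor panel from [gen_predictors()].
#' @return list with `y` (response vector aligned with `Xpanel` rows) and
#'   `truth` (a `sim_truth`: global beta, per-city gamma, per-record
#'   effective coefficients, variance components, error draws).
#' @export
gen_response_mixed <- function(cfg, locations, Xpanel) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  preds <- names(cfg$mean_levels)
  n <- nrow(Xpanel)
  Z <- cbind(1, as.matrix(Xpanel[, preds, drop = FALSE]))
  S <- nrow(locations)

  gamma <- matrix(stats::rnorm(S * 6L), S, 6L) %*% diag(cfg$re_sd)
  dimnames(gamma) <- list(locations$city_name, c("intercept", preds))

  y <- numeric(n)
  eps_all <- numeric(n)
  beta_local <- matrix(NA_real_, n, 6L,
                       dimnames = list(NULL, c("intercept", preds)))
  for (s in seq_len(S)) {
    idx <- which(Xpanel$city_id == locations$city_id[s])
    beta_s <- cfg$beta + gamma[s, ]
    eps <- .ar1_series(length(idx), cfg$ar1_r, cfg$resid_sd)
    y[idx] <- Z[idx, , drop = FALSE] %*% beta_s + eps
    eps_all[idx] <- eps
    beta_local[idx, ] <- matrix(beta_s, length(idx), 6L, byrow = TRUE)
  }
  truth <- .sim_truth(
    beta_global = cfg$beta, gamma = gamma, beta_local = beta_local,
    variance_components = list(sigma2 = cfg$re_sd^2, r = cfg$ar1_r,
                               resid_var = cfg$resid_sd^2),
    epsilon = eps_all
  )
  list(y = y, truth = truth)
}

#' Generate a varying-coefficient response
#'
#' Each coefficient is modulated multiplicatively around its global value:
#' `beta_k(u, v, t) = beta_k * (1 + nonstat_space * g(u, v) +
#' nonstat_time * h(t))` with `g` a centred linear surface in the city
#' coordinates and `h` a centred sinusoid in the week index; the response is
#' the rowwise inner product of the local coefficients with `[1, X]` plus
#' white noise of standard deviation `resid_sd`.
#'
#' @inheritParams gen_response_mixed
#' @return list with `y` and `truth`; `truth$beta_local` holds the exact
#'   per-record coefficients used.
#' @export
gen_response_varying <- function(cfg, locations, Xpanel) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 3L)
  preds <- names(cfg$mean_levels)
  n <- nrow(Xpanel)
  X1 <- cbind(1, as.matrix(Xpanel[, preds, drop = FALSE]))

  loc <- locations[match(Xpanel$city_id, locations$city_id), ]
  g <- (loc$x - mean(locations$x)) + (loc$y - mean(locations$y))
  h <- sin(2 * pi * Xpanel$week / cfg$period)
  modulation <- 1 + cfg$nonstat_space * g + cfg$nonstat_time * h

  beta_local <- outer(modulation, cfg$beta)
  colnames(beta_local) <- c("intercept", preds)
  y <- rowSums(beta_local * X1) + stats::rnorm(n, sd = cfg$resid_sd)

  truth <- .sim_truth(
    beta_global = cfg$beta, gamma = NULL, beta_local = beta_local,
    variance_components = list(resid_var = cfg$resid_sd^2),
    epsilon = NULL
  )
  list(y = y, truth = truth)
}

#' Simulate a complete panel with ground truth
#'
#' Dispatches on `cfg$mode`: `"mixed"` draws the response from the
#' random-effects + AR(1) model, `"varying"` from space-time-varying
#' coefficients. The default configuration yields a 13-city x 210-week panel
#' of 2730 records.
#'
#' @param cfg a [sim_config()].
#' @return list with `ds` (a [panel_dataset()]) and `truth` (a `sim_truth`).
#' @export
simulate_panel <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!cfg$mode %in% c("mixed", "varying")) {
    stop("unknown simulation mode: ", cfg$mode, call. = FALSE)
  }
  locations <- gen_locations(cfg$n_locations, cfg$seed)
  Xpanel <- gen_predictors(cfg, locations)
  resp <- if (cfg$mode == "mixed") {
    gen_response_mixed(cfg, locations, Xpanel)
  } else {
    gen_response_varying(cfg, locations, Xpanel)
  }
  data <- data.frame(
    city_id = Xpanel$city_id,
    city_name = locations$city_name[match(Xpanel$city_id, locations$city_id)],
    x = locations$x[match(Xpanel$city_id, locations$city_id)],
    y = locations$y[match(Xpanel$city_id, locations$city_id)],
    week = Xpanel$week,
    Xpanel[, names(cfg$mean_levels), drop = FALSE],
    pm25 = resp$y
  )
  ds <- panel_dataset(data, predictors = names(cfg$mean_levels),
                      response = "pm25")
  list(ds = ds, truth = resp$truth)
}

#' Write a simulated panel and its ground truth to CSV
#'
#' @param sim result of [simulate_panel()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the two file paths written (`panel.csv`, `truth.csv`).
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  panel_path <- file.path(dir, "panel.csv")
  truth_path <- file.path(dir, "truth.csv")
  write_panel(sim$ds, panel_path)
  truth_df <- as.data.frame(sim$truth$beta_local)
  names(truth_df) <- paste0("beta_", names(truth_df))
  utils::write.csv(truth_df, truth_path, row.names = FALSE)
  invisible(c(panel = panel_path, truth = truth_path))
}
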