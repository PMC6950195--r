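# Fixture builders shared across test files. All panels are generated in
# code; nothing is read from disk except explicit round-trip tests.

# Small simulated panel (defaults to mixed mode).
toy_panel <- function(S = 3, T = 10, seed = 1, mode = "mixed", ...) {
  simulate_panel(sim_config(n_locations = S, n_times = T, seed = seed,
                            mode = mode, ...))
}

# Panel with hand-placed city coordinates, one or more weeks per city.
# Predictor values are arbitrary but full rank; the response is x-driven.
coord_panel <- function(coords, T = 1, seed = 1) {
  set.seed(seed)
  S <- nrow(coords)
  n <- S * T
  data <- data.frame(
    city_id = rep(seq_len(S), each = T),
    city_name = rep(sprintf("c%02d", seq_len(S)), each = T),
    x = rep(coords$x, each = T),
    y = rep(coords$y, each = T),
    week = rep(seq_len(T), S),
    so2 = rnorm(n, 15, 3), no2 = rnorm(n, 20, 3),
    pm10 = rnorm(n, 60, 10), co = rnorm(n, 0.7, 0.1),
    o3 = rnorm(n, 70, 8)
  )
  data$pm25 <- 5 + 0.5 * data$pm10 + rnorm(n, 0, 2)
  panel_dataset(data)
}

# Explicit-inverse weighted least squares, the brute-force oracle for
# local_wls: beta = (X'WX)^{-1} X'W y evaluated literally.
wls_oracle <- function(X, y, w) {
  W <- diag(w)
  solve(t(X) %*% W %*% X) %*% t(X) %*% W %*% y
}

# Dense whole-matrix REML objective (no block shortcut), the oracle for
# reml_objective.
dense_reml_oracle <- function(theta, ds) {
  X <- design_matrix(ds)
  y <- ds$data[[ds$response]]
  n <- nrow(X)
  p <- ncol(X)
  G <- diag(exp(theta[1:6]))
  r <- tanh(theta[7])
  s2 <- exp(theta[8])
  V <- matrix(0, n, n)
  for (id in unique(ds$data$city_id)) {
    idx <- which(ds$data$city_id == id)
    Z <- X[idx, , drop = FALSE]
    V[idx, idx] <- Z %*% G %*% t(Z) + ar1_covariance(r, s2, length(idx))
  }
  Vi <- solve(V)
  A <- t(X) %*% Vi %*% X
  beta <- solve(A, t(X) %*% Vi %*% y)
  res <- y - X %*% beta
  as.numeric(determinant(V)$modulus + determinant(A)$modulus +
               t(res) %*% Vi %*% res + (n - p) * log(2 * pi))
}
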