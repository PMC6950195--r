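# Unified locally weighted least-squares engine behind GWR, TWR and GTWR.

#' One locally weighted least-squares solve
#'
#' Solves `beta_i = (X'WX)^{-1} X'W y` by QR on the square-root-weighted
#' design (no explicit inverse) and returns the focal diagonal element of
#' the hat matrix, `w_focal * x_focal' (X'WX)^{-1} x_focal`.
#'
#' @param X n x p design matrix.
#' @param y response vector.
#' @param w nonnegative weight vector of length n.
#' @param focal_row the focal record's design row (length p).
#' @param focal_weight the focal record's own weight (1 under any kernel,
#'   since its distance to itself is 0).
#' @return list with `beta` (length p) and `hat` (scalar hat diagonal).
#' @export
local_wls <- function(X, y, w, focal_row, focal_weight = 1) {
  keep <- which(w > 0)
  if (length(keep) < ncol(X)) {
    stop("fewer positively weighted records than coefficients", call. = FALSE)
  }
  sw <- sqrt(w[keep])
  qrX <- qr(X[keep, , drop = FALSE] * sw)
  R <- qr.R(qrX)
  dR <- abs(diag(R))
  if (min(dR) == 0 || (max(dR) / min(dR))^2 > 1e10) {
    stop("ill-conditioned local design (condition > 1e10); increase k",
         call. = FALSE)
  }
  beta <- qr.coef(qrX, y[keep] * sw)
  u <- forwardsolve(t(R), focal_row)
  list(beta = beta, hat = sum(u^2) * focal_weight)
}

#' Fit a local model (GWR, TWR or GTWR)
#'
#' Runs [local_wls()] at every record with kernel weights from
#' [weight_vector()], accumulating the hat-matrix trace from the focal hat
#' diagonals. The AICc uses the hat trace as effective parameters
#' ([model_aicc()]); the adjusted R-squared uses `tr(S)` (or the raw
#' coefficient count, per `cfg$ra2_method`).
#'
#' @param ds a [panel_dataset()].
#' @param cfg a [kernel_config()]; in spatial mode this is GWR, temporal
#'   TWR, spatiotemporal GTWR.
#' @return An object of class `local_fit`: `coef` (n x p matrix of local
#'   coefficients), `fitted`, `residuals`, `trS`, `aicc`, `ra2`, `rmse`,
#'   `mae`, `hat`, `cfg`, `summary` (five-number summary per coefficient).
#' @export
fit_stwr <- function(ds, cfg) {
  stopifnot(inherits(cfg, "kernel_config"))
  X <- design_matrix(ds)
  y <- ds$data[[ds$response]]
  n <- nrow(X)
  p <- ncol(X)
  if (cfg$k > n) stop("k exceeds the number of records", call. = FALSE)

  coef <- matrix(NA_real_, n, p, dimnames = list(NULL, colnames(X)))
  hat <- numeric(n)
  fitted <- numeric(n)
  failures <- character(0)
  for (i in seq_len(n)) {
    w <- weight_vector(i, ds, cfg)
    res <- tryCatch(local_wls(X, y, w, X[i, ], focal_weight = w[i]),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failures <- c(failures, sprintf("record %d: %s", i, res))
      next
    }
    coef[i, ] <- res$beta
    hat[i] <- res$hat
    fitted[i] <- sum(X[i, ] * res$beta)
  }
  if (length(failures) > 0L) {
    stop("local fit failed at ", length(failures), " record(s):\n",
         paste(utils::head(failures, 10L), collapse = "\n"), call. = FALSE)
  }
  resid <- y - fitted
  trS <- sum(hat)
  rss <- sum(resid^2)
  p_eff <- if (cfg$ra2_method == "trS") trS else p
  # a constant response leaves Ra2 undefined but the fit itself valid
  met <- tryCatch(fit_metrics(y, fitted, p_eff = p_eff),
                  error = function(e) c(ra2 = NA_real_,
                                        rmse = sqrt(rss / n),
                                        mae = mean(abs(resid))))
  structure(
    list(coef = coef, fitted = fitted, residuals = resid, hat = hat,
         trS = trS, aicc = model_aicc(rss, n, trS),
         ra2 = met[["ra2"]], rmse = met[["rmse"]], mae = met[["mae"]],
         cfg = cfg, n = n, p = p,
         summary = .five_number(coef)),
    class = "local_fit"
  )
}

#' @export
print.local_fit <- function(x, ...) {
  label <- switch(x$cfg$mode, spatial = "GWR", temporal = "TWR",
                  spatiotemporal = "GTWR")
  cat(sprintf("%s fit: %d records, k = %d (%s kernel), tr(S) = %.1f\n",
              label, x$n, x$cfg$k, x$cfg$kernel, x$trS))
  print(round(x$summary, 4))
  cat(sprintf("Ra2 = %.4f  AICc = %.2f  RMSE = %.3f  MAE = %.3f\n",
              x$ra2, x$aicc, x$rmse, x$mae))
  invisible(x)
}

#' Corrected AIC of a (local) smoother
#'
#' `2n ln(sigma_hat) + n ln(2 pi) + n (n + tr(S)) / (n - 2 - tr(S))` with
#' `sigma_hat = sqrt(rss / n)`. For an unweighted OLS fit (`tr(S) = p`) this
#' equals the classical small-sample AICc with p + 1 parameters.
#'
#' @param rss residual sum of squares.
#' @param n sample size.
#' @param trS hat-matrix trace (effective parameters); requires
#'   `n > trS + 2`.
#' @return Scalar AICc.
#' @export
model_aicc <- function(rss, n, trS) {
  if (n <= trS + 2) stop("AICc undefined: n must exceed tr(S) + 2",
                         call. = FALSE)
  sigma_hat <- sqrt(rss / n)
  2 * n * log(sigma_hat) + n * log(2 * pi) + n * (n + trS) / (n - 2 - trS)
}

.five_number <- function(coef) {
  out <- t(apply(coef, 2L, stats::quantile,
                 probs = c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE))
  colnames(out) <- c("min", "q1", "median", "q3", "max")
  out
}

#' Five-number summary of the local coefficients
#'
#' Minimum, lower quartile, median, upper quartile and maximum of each
#' coefficient over the n local estimates; quartiles use the
#' linear-interpolation convention (R quantile type 7).
#'
#' @param fit a `local_fit`.
#' @return p x 5 matrix.
#' @export
coefficient_summary <- function(fit) {
  stopifnot(inherits(fit, "local_fit"))
  .five_number(fit$coef)
}
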