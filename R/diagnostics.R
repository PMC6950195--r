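# Residual diagnostics shared by every model: adjusted R-squared, RMSE,
# MAE, residual Z scores, Moran's I over k-nearest-neighbour weights, the
# pollutant correlation matrix, and the cross-model comparison table.

#' Fit metrics: adjusted R-squared, RMSE, MAE
#'
#' `Ra2 = 1 - (n-1)(1-R2)/(n-p_eff)` with `R2 = 1 - RSS/SST`;
#' `RMSE = sqrt(mean squared residual)`; `MAE = mean absolute residual`.
#'
#' @param y observed response.
#' @param yhat fitted values.
#' @param p_eff effective number of parameters (a hat-matrix trace for
#'   local smoothers, the coefficient count for global fits);
#'   `length(y)` must exceed `p_eff + 1`.
#' @return Named numeric vector `c(ra2, rmse, mae)`.
#' @export
fit_metrics <- function(y, yhat, p_eff) {
  n <- length(y)
  stopifnot(length(yhat) == n)
  if (n <= p_eff + 1) stop("n must exceed p_eff + 1", call. = FALSE)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("response is constant: SST = 0", call. = FALSE)
  rss <- sum((y - yhat)^2)
  r2 <- 1 - rss / sst
  c(ra2 = 1 - (n - 1) * (1 - r2) / (n - p_eff),
    rmse = sqrt(rss / n),
    mae = mean(abs(y - yhat)))
}

#' Residual Z scores
#'
#' `Z_i = (y_i - yhat_i) / sd(yhat)`, with the sample (n - 1 denominator)
#' standard deviation of the fitted values.
#'
#' @param y observed response.
#' @param yhat fitted values; must not be constant.
#' @return Vector of Z scores.
#' @export
z_scores <- function(y, yhat) {
  s <- stats::sd(yhat)
  if (!is.finite(s) || s == 0) {
    stop("fitted values are constant; Z scores undefined", call. = FALSE)
  }
  (y - yhat) / s
}

# Neighbour order of every record by spatial distance, self excluded.
# Ties (records of the same city share coordinates) resolve by row order,
# i.e. by (city_id, week) since panels are stored sorted.
.knn_order <- function(ds, kmax) {
  x <- ds$data$x
  y <- ds$data$y
  n <- length(x)
  if (kmax >= n) stop("k must be smaller than the number of records",
                      call. = FALSE)
  nb <- matrix(0L, n, kmax)
  for (i in seq_len(n)) {
    d2 <- (x - x[i])^2 + (y - y[i])^2
    d2[i] <- Inf
    nb[i, ] <- order(d2)[seq_len(kmax)]
  }
  nb
}

#' Binary k-nearest-neighbour spatial weights
#'
#' `w_ij = 1` if record j is among the k nearest records to i by planar
#' spatial distance (self excluded), else 0. Ties at the k-th distance are
#' broken deterministically by (city_id, week) order; the matrix is neither
#' symmetrized nor row-standardized.
#'
#' @param ds a [panel_dataset()].
#' @param k neighbour count, `k < n`.
#' @return An object of class `knn_weights`: `nb` (n x k neighbour index
#'   matrix), `n`, `k`, and the Moran variance ingredients `W` (= nk),
#'   `S1`, `S2`.
#' @export
knn_binary_weights <- function(ds, k) {
  nb <- .knn_order(ds, k)
  .knn_weights_from_order(nb, k)
}

.knn_weights_from_order <- function(nb_full, k) {
  n <- nrow(nb_full)
  nb <- nb_full[, seq_len(k), drop = FALSE]
  A <- matrix(FALSE, n, n)
  A[cbind(rep(seq_len(n), k), as.vector(nb))] <- TRUE
  W <- n * k
  S1 <- W + sum(A & t(A))            # 1/2 sum (w_ij + w_ji)^2, binary case
  ci <- tabulate(nb, nbins = n)      # column sums; row sums are all k
  S2 <- sum((k + ci)^2)
  structure(list(nb = nb, n = n, k = k, W = W, S1 = S1, S2 = S2),
            class = "knn_weights")
}

.moran_stat <- function(z, weights) {
  nbsum <- rowSums(matrix(z[weights$nb], weights$n, weights$k))
  (weights$n / weights$W) * sum(z * nbsum) / sum(z^2)
}

#' Moran's I of model residuals
#'
#' `I = (n/W) * sum_ij w_ij (e_i - ebar)(e_j - ebar) / sum_i (e_i - ebar)^2`
#' with expectation `-1/(n-1)` under the randomization null. The analytic
#' method uses the randomization (fourth-moment) variance with a two-tailed
#' normal p-value; the permutation method shuffles the residuals and
#' reports a two-tailed empirical p-value.
#'
#' @param e residual vector (non-constant).
#' @param weights a [knn_binary_weights()] object.
#' @param method `"analytic"` or `"permutation"`.
#' @param n_perm number of permutations (permutation method).
#' @param seed integer seed for the permutations.
#' @return An object of class `moran_result`: `I`, `expected`, `variance`,
#'   `z`, `p_two_tailed`, `k`, `method`.
#' @export
morans_i <- function(e, weights, method = c("analytic", "permutation"),
                     n_perm = 999L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(weights, "knn_weights"), length(e) == weights$n)
  z <- e - mean(e)
  m2 <- sum(z^2)
  if (m2 == 0) stop("residuals are constant; Moran's I undefined",
                    call. = FALSE)
  n <- weights$n
  I <- .moran_stat(z, weights)
  expected <- -1 / (n - 1)

  if (method == "analytic") {
    S0 <- weights$W
    S1 <- weights$S1
    S2 <- weights$S2
    b2 <- n * sum(z^4) / m2^2
    var_I <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
                b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
      ((n - 1) * (n - 2) * (n - 3) * S0^2) - expected^2
    zdev <- (I - expected) / sqrt(var_I)
    p <- 2 * stats::pnorm(abs(zdev), lower.tail = FALSE)
  } else {
    set.seed(seed)
    perm <- vapply(seq_len(n_perm), function(r) {
      .moran_stat(sample(z), weights)
    }, numeric(1))
    var_I <- stats::var(perm)
    zdev <- (I - mean(perm)) / stats::sd(perm)
    p_lo <- (1 + sum(perm <= I)) / (n_perm + 1)
    p_hi <- (1 + sum(perm >= I)) / (n_perm + 1)
    p <- min(1, 2 * min(p_lo, p_hi))
  }
  structure(
    list(I = I, expected = expected, variance = var_I, z = zdev,
         p_two_tailed = p, k = weights$k, method = method),
    class = "moran_result"
  )
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf(
    "Moran's I = %.4f (E = %.4f, z = %.2f, p = %.4g; k = %d, %s)\n",
    x$I, x$expected, x$z, x$p_two_tailed, x$k, x$method))
  invisible(x)
}

#' Moran's I across a grid of neighbour counts
#'
#' The bandwidth-profile diagnostic: one Moran test per neighbour count,
#' showing whether residual autocorrelation decays towards zero as the
#' weight structure densifies.
#'
#' @param e residual vector.
#' @param ds the panel the residuals come from.
#' @param k_grid strictly increasing neighbour counts, all `< n`.
#' @param method,n_perm,seed passed to [morans_i()].
#' @return data.frame with columns `k`, `I`, `z`, `p`.
#' @export
moran_curve <- function(e, ds, k_grid, method = c("analytic", "permutation"),
                        n_perm = 999L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(all(diff(k_grid) > 0), max(k_grid) < n_records(ds))
  nb_full <- .knn_order(ds, max(k_grid))
  rows <- lapply(k_grid, function(k) {
    w <- .knn_weights_from_order(nb_full, k)
    m <- morans_i(e, w, method = method, n_perm = n_perm, seed = seed)
    data.frame(k = k, I = m$I, z = m$z, p = m$p_two_tailed)
  })
  do.call(rbind, rows)
}

#' Pearson correlation matrix of pollutants
#'
#' Pairwise Pearson correlations of the five predictors and the response;
#' symmetric with unit diagonal.
#'
#' @param ds a [panel_dataset()] with at least 3 records.
#' @return 6 x 6 correlation matrix.
#' @export
corr_matrix <- function(ds) {
  stopifnot(n_records(ds) >= 3L)
  vars <- c(ds$predictors, ds$response)
  M <- as.matrix(ds$data[, vars, drop = FALSE])
  sds <- apply(M, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance column(s): ",
         paste(vars[sds == 0], collapse = ", "), call. = FALSE)
  }
  C <- stats::cor(M)
  (C + t(C)) / 2
}

# observed response reconstructed from a fit (fitted + residuals)
.fit_response <- function(fit) fit$fitted + fit$residuals

#' Cross-model comparison table
#'
#' Assembles AICc, adjusted (or conditional, for the mixed model)
#' R-squared, RMSE, MAE and the mean and standard deviation of the residual
#' Z scores for each fitted model, plus each model's percentage RMSE and
#' MAE reduction relative to the OLS benchmark (when an OLS fit is in the
#' list). All fits must come from the same panel; this is checked by
#' reconstructing the response from each fit.
#'
#' @param fits named list of `global_fit`, `lmm_fit` and/or `local_fit`
#'   objects.
#' @param ds the shared panel.
#' @return A data.frame of class `comparison_table`, one row per model:
#'   `model`, `neighbors`, `aicc`, `r2`, `rmse`, `mae`, `z_mean`, `z_std`,
#'   `rmse_reduction_pct`, `mae_reduction_pct`.
#' @export
compare_models <- function(fits, ds) {
  stopifnot(is.list(fits), length(fits) > 0L)
  if (is.null(names(fits)) || any(names(fits) == "")) {
    stop("fits must be a named list", call. = FALSE)
  }
  y <- ds$data[[ds$response]]
  scale_y <- max(abs(y), 1)
  rows <- lapply(names(fits), function(nm) {
    fit <- fits[[nm]]
    yf <- .fit_response(fit)
    if (length(yf) != length(y) || max(abs(yf - y)) > 1e-6 * scale_y) {
      stop("fit '", nm, "' does not match the supplied panel", call. = FALSE)
    }
    zs <- z_scores(y, fit$fitted)
    data.frame(
      model = nm,
      neighbors = if (inherits(fit, "local_fit")) fit$cfg$k else NA_integer_,
      aicc = fit$aicc,
      r2 = if (inherits(fit, "lmm_fit")) fit$rc2 else fit$ra2,
      rmse = fit$rmse, mae = fit$mae,
      z_mean = mean(zs), z_std = stats::sd(zs)
    )
  })
  out <- do.call(rbind, rows)
  ols_row <- which(vapply(fits, inherits, logical(1), "global_fit"))
  if (length(ols_row) >= 1L) {
    ref <- out[ols_row[1L], ]
    out$rmse_reduction_pct <- 100 * (1 - out$rmse / ref$rmse)
    out$mae_reduction_pct <- 100 * (1 - out$mae / ref$mae)
  } else {
    out$rmse_reduction_pct <- NA_real_
    out$mae_reduction_pct <- NA_real_
  }
  rownames(out) <- NULL
  class(out) <- c("comparison_table", "data.frame")
  out
}
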