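# Global models: OLS benchmark and the linear mixed model with per-city
# variance-components random effects (diagonal G) and AR(1) within-city
# residual correlation (R), fitted by REML.

#' Fit the global OLS benchmark
#'
#' Ordinary least squares of the response on the five predictors plus an
#' intercept, with classical standard errors, two-sided t tests on n - p
#' degrees of freedom, standardized estimates (slope times sd(X_k)/sd(y)),
#' the adjusted R-squared and the small-sample AICc (hat-trace p).
#'
#' @param ds a [panel_dataset()].
#' @return An object of class `global_fit` with elements `beta`, `se`,
#'   `tvals`, `pvals`, `standardized`, `fitted`, `residuals`, `ra2`, `aicc`,
#'   `rmse`, `mae`, `n`, `p`.
#' @export
fit_ols <- function(ds) {
  X <- design_matrix(ds)
  y <- ds$data[[ds$response]]
  n <- length(y)
  p <- ncol(X)
  if (n <= p) stop("need more records than coefficients", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrX, y)
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  rss <- sum(resid^2)
  sigma2 <- rss / (n - p)
  XtX_inv <- chol2inv(qr.R(qrX))
  se <- sqrt(diag(XtX_inv) * sigma2)
  names(se) <- names(beta)
  tvals <- beta / se
  pvals <- 2 * stats::pt(abs(tvals), df = n - p, lower.tail = FALSE)
  sdy <- stats::sd(y)
  standardized <- c(0, beta[-1L] * apply(X[, -1L, drop = FALSE], 2, stats::sd) / sdy)
  names(standardized) <- names(beta)

  met <- fit_metrics(y, fitted, p_eff = p)
  structure(
    list(beta = beta, se = se, tvals = tvals, pvals = pvals,
         standardized = standardized, fitted = fitted, residuals = resid,
         ra2 = met[["ra2"]], aicc = model_aicc(rss, n, p),
         rmse = met[["rmse"]], mae = met[["mae"]], n = n, p = p),
    class = "global_fit"
  )
}

#' @export
print.global_fit <- function(x, ...) {
  cat("global OLS fit:", x$n, "records,", x$p, "coefficients\n")
  print(round(cbind(estimate = x$beta, se = x$se, t = x$tvals, p = x$pvals,
                    standardized = x$standardized), 4))
  cat(sprintf("Ra2 = %.4f  AICc = %.2f\n", x$ra2, x$aicc))
  invisible(x)
}

#' AR(1) covariance matrix
#'
#' Entry (i, j) is `sigma2 * r^|i-j|`: the within-city residual covariance
#' used in the mixed model's R matrix.
#'
#' @param r first-order autocorrelation, |r| < 1.
#' @param sigma2 marginal variance, > 0.
#' @param T series length, >= 1.
#' @return T x T covariance matrix.
#' @export
ar1_covariance <- function(r, sigma2, T) {
  if (abs(r) >= 1) stop("|r| must be < 1", call. = FALSE)
  if (sigma2 <= 0) stop("sigma2 must be > 0", call. = FALSE)
  if (T < 1) stop("T must be >= 1", call. = FALSE)
  idx <- seq_len(T)
  sigma2 * r^abs(outer(idx, idx, "-"))
}

# --- internal REML machinery --------------------------------------------

# Per-city blocks: response, fixed design, random design and week gaps.
.lmm_blocks <- function(ds, Z = NULL) {
  X <- design_matrix(ds)
  if (is.null(Z)) Z <- X
  y <- ds$data[[ds$response]]
  ids <- ds$locations$city_id
  lapply(ids, function(id) {
    idx <- which(ds$data$city_id == id)
    list(y = y[idx], X = X[idx, , drop = FALSE],
         Z = Z[idx, , drop = FALSE],
         dt = diff(ds$data$week[idx]))
  })
}

# Apply the AR(1)/Markov whitening to the columns of M for one city:
# returns Lm = L M and the diagonal D of innovation variances, where the
# correlation matrix C = r^|t_i - t_j| factorizes as C^{-1} = L' D^{-1} L
# (L unit lower bidiagonal with subdiagonal -rho_i, rho_i = r^{dt_i}).
# log|C| = sum log(1 - rho_i^2).
.ar1_whiten <- function(M, dt, r) {
  T <- nrow(M)
  if (T == 1L) return(list(Lm = M, D = 1, logdetC = 0))
  rho <- r^dt
  Lm <- M
  Lm[2:T, ] <- M[2:T, , drop = FALSE] - rho * M[1:(T - 1L), , drop = FALSE]
  list(Lm = Lm, D = c(1, 1 - rho^2), logdetC = sum(log(1 - rho^2)))
}

# Core REML/ML computation for the VC + AR(1) model on precomputed blocks.
# theta = (log sigma_1^2 .. log sigma_q^2, atanh r, log sigma^2).
# Uses the Woodbury identity per city: V_c = R_c + Z_c G Z_c', so only
# q x q factorizations are needed.
.reml_core <- function(theta, blocks, want = "objective") {
  q <- length(theta) - 2L
  out <- tryCatch({
    g <- exp(theta[seq_len(q)])
    r <- tanh(theta[q + 1L])
    s2 <- exp(theta[q + 2L])
    U <- sqrt(g)
    p <- ncol(blocks[[1L]]$X)
    n <- 0L

    A <- matrix(0, p, p)      # X' V^{-1} X
    b <- numeric(p)           # X' V^{-1} y
    cc <- 0                   # y' V^{-1} y
    logdetV <- 0
    per_city <- vector("list", length(blocks))

    for (ci in seq_along(blocks)) {
      blk <- blocks[[ci]]
      T <- length(blk$y)
      n <- n + T
      M <- cbind(blk$y, blk$X, blk$Z)
      w <- .ar1_whiten(M, blk$dt, r)
      # cross-products against R^{-1} = C^{-1} / s2
      Cp <- crossprod(w$Lm / sqrt(w$D)) / s2
      iy <- 1L
      ix <- 1L + seq_len(p)
      iz <- 1L + p + seq_len(q)
      Ayy <- Cp[iy, iy]
      Axy <- Cp[ix, iy]
      Axx <- Cp[ix, ix]
      Azy <- Cp[iz, iy]
      Azx <- Cp[iz, ix, drop = FALSE]
      Azz <- Cp[iz, iz]
      K <- diag(q) + (U * t(U * Azz))   # I + U Azz U (symmetric)
      cholK <- chol(K)
      # helper: t(L)^{-1} applied to U * v for Woodbury corrections
      UZy <- U * Azy
      UZx <- U * Azx
      sy <- backsolve(cholK, forwardsolve(t(cholK), UZy))
      sx <- backsolve(cholK, forwardsolve(t(cholK), UZx))
      A <- A + Axx - crossprod(UZx, sx)
      b <- b + Axy - drop(crossprod(UZx, sy))
      cc <- cc + Ayy - sum(UZy * sy)
      logdetV <- logdetV + T * log(s2) + w$logdetC +
        2 * sum(log(diag(cholK)))
      if (want == "full") {
        per_city[[ci]] <- list(Azy = Azy, Azx = Azx, Azz = Azz,
                               cholK = cholK)
      }
    }
    cholA <- chol(A)
    beta <- backsolve(cholA, forwardsolve(t(cholA), b))
    quad <- cc - sum(b * beta)
    neg2reml <- logdetV + 2 * sum(log(diag(cholA))) + quad +
      (n - p) * log(2 * pi)
    neg2ml <- logdetV + quad + n * log(2 * pi)
    if (!is.finite(neg2reml)) stop("non-finite objective")
    res <- list(neg2reml = neg2reml, neg2ml = neg2ml, beta = beta,
                vcov_beta = chol2inv(cholA), n = n, p = p)
    if (want == "full") {
      # BLUPs: gamma_c = G Z_c' V_c^{-1} (y_c - X_c beta)
      gamma <- matrix(0, length(blocks), q)
      for (ci in seq_along(blocks)) {
        pc <- per_city[[ci]]
        Azr <- pc$Azy - drop(pc$Azx %*% beta)   # Z' R^{-1} res
        Uzr <- U * Azr
        s <- backsolve(pc$cholK, forwardsolve(t(pc$cholK), Uzr))
        # Z'V^{-1}res = Azr - Azz U K^{-1} U Azr
        ZVr <- Azr - drop(pc$Azz %*% (U * s))
        gamma[ci, ] <- g * ZVr
      }
      res$gamma <- gamma
      res$G <- g
      res$r <- r
      res$s2 <- s2
    }
    res
  }, error = function(e) NULL)
  if (is.null(out)) {
    if (want == "objective") return(Inf)
    stop("mixed-model likelihood could not be evaluated", call. = FALSE)
  }
  if (want == "objective") out$neg2reml else out
}

#' Restricted-likelihood objective of the mixed model
#'
#' Returns minus twice the restricted (REML) log-likelihood of the
#' variance-components + AR(1) model at a transformed parameter vector
#' `theta = (log sigma_1^2 .. log sigma_6^2, atanh r, log sigma^2)`.
#' Computed per city from the block-diagonal marginal covariance
#' `V_c = Z_c G Z_c' + R_c`; non-finite intermediates yield `+Inf` rather
#' than an error so optimizers can probe freely.
#'
#' @param theta numeric vector of length q + 2 (q random-effect
#'   log-variances, `atanh` of the AR(1) correlation, log residual variance).
#' @param ds a [panel_dataset()].
#' @param Zdesign optional n x q random-effects design aligned with the
#'   panel rows; defaults to the fixed design `[1, X1..X5]`.
#' @return Scalar: -2 * restricted log-likelihood.
#' @export
reml_objective <- function(theta, ds, Zdesign = NULL) {
  blocks <- .lmm_blocks(ds, Zdesign)
  q <- ncol(blocks[[1L]]$Z)
  stopifnot(length(theta) == q + 2L)
  .reml_core(theta, blocks)
}

# Numeric central-difference gradient of the REML objective.
.num_grad <- function(fn, x, eps = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- x[i] + eps
    xm[i] <- x[i] - eps
    (fn(xp) - fn(xm)) / (2 * eps)
  }, numeric(1))
}

#' Fit the linear mixed model by REML
#'
#' Fits `y = X beta + Z gamma + eps` with city random effects on the
#' intercept and all slopes (diagonal variance-components G) and AR(1)
#' within-city errors, by quasi-Newton minimization of [reml_objective()]
#' from three deterministic starts (OLS-residual-based, small-variance,
#' moderate-variance). Fixed effects and BLUPs are recovered by generalized
#' least squares at the optimum; the AICc is computed from the ML
#' log-likelihood evaluated at the REML-optimal variance parameters with
#' parameter count p + 8 (six fixed effects, six random-effect variances,
#' the AR(1) correlation and the residual variance).
#'
#' @param ds a [panel_dataset()].
#' @param opts list of optimizer options: `maxit` (default 300) and
#'   `grad_tol`, the max absolute gradient defining convergence (default
#'   0.5 on the -2 log-likelihood scale).
#' @return An object of class `lmm_fit`: `beta_fixed`, `se_fixed`, `tvals`,
#'   `pvals` (t reference on S - 1 df), `var_components` (sigma_1^2 ..
#'   sigma_6^2), `ar1_r`, `resid_var`, `gamma` (S x 6 BLUP matrix),
#'   `fitted`, `residuals`, `rc2`, `aicc`, `loglik_ml`, `loglik_reml`,
#'   `rmse`, `mae`, `converged`, `n_iter`, `trace` (objective at each start).
#' @export
fit_lmm <- function(ds, opts = list()) {
  maxit <- opts$maxit %||% 300L
  grad_tol <- opts$grad_tol %||% 0.5
  tab <- table(ds$data$city_id)
  if (any(tab < 8L)) {
    stop("every city needs at least 8 records for the AR(1) mixed model",
         call. = FALSE)
  }
  blocks <- .lmm_blocks(ds)
  q <- ncol(blocks[[1L]]$Z)
  fn <- function(th) .reml_core(th, blocks)

  ols <- fit_ols(ds)
  ve <- stats::var(ols$residuals)
  # pooled lag-1 autocorrelation of OLS residuals within city
  acf1 <- {
    num <- 0; den <- 0
    for (blk in blocks) {
      e <- blk$y - drop(blk$X %*% ols$beta)
      T <- length(e)
      num <- num + sum(e[-1] * e[-T])
      den <- den + sum(e^2)
    }
    max(min(num / den, 0.9), -0.9)
  }
  z2 <- vapply(seq_len(q), function(k) {
    mean(unlist(lapply(blocks, function(b) b$Z[, k]^2)))
  }, numeric(1))
  starts <- list(
    c(log(0.25 * ve / (q * z2)), atanh(acf1), log(0.75 * ve)),
    c(log(0.01 * ve / (q * z2)), atanh(0), log(ve)),
    c(log(ve / (q * z2)), atanh(0.3), log(0.5 * ve))
  )

  runs <- lapply(starts, function(st) {
    stats::optim(st, fn, method = "BFGS",
                 control = list(maxit = maxit, reltol = 1e-10))
  })
  objs <- vapply(runs, function(r) r$value, numeric(1))
  trace <- data.frame(start = seq_along(runs), objective = objs,
                      optim_convergence = vapply(runs, function(r)
                        r$convergence, numeric(1)))
  if (all(!is.finite(objs))) {
    err <- simpleError("mixed-model fit failed: no start reached a finite objective")
    err$trace <- trace
    stop(err)
  }
  best <- runs[[which.min(objs)]]
  grad <- .num_grad(fn, best$par)
  converged <- max(abs(grad)) < grad_tol

  full <- .reml_core(best$par, blocks, want = "full")
  beta <- full$beta
  names(beta) <- colnames(blocks[[1L]]$X)
  se <- sqrt(diag(full$vcov_beta))
  names(se) <- names(beta)
  S <- length(blocks)
  tvals <- beta / se
  pvals <- 2 * stats::pt(abs(tvals), df = S - 1L, lower.tail = FALSE)
  gamma <- full$gamma
  dimnames(gamma) <- list(ds$locations$city_name, names(beta))

  X <- design_matrix(ds)
  Zfull <- X
  fitted_fix <- drop(X %*% beta)
  re_part <- rowSums(Zfull * gamma[match(ds$data$city_id,
                                         ds$locations$city_id), ,
                                   drop = FALSE])
  fitted <- fitted_fix + re_part
  resid <- ds$data[[ds$response]] - fitted

  n <- full$n
  p <- full$p
  k <- p + 8
  aicc <- full$neg2ml + 2 * k * n / (n - k - 1)

  fit <- structure(
    list(beta_fixed = beta, se_fixed = se, tvals = tvals, pvals = pvals,
         var_components = stats::setNames(full$G, names(beta)),
         ar1_r = full$r, resid_var = full$s2, gamma = gamma,
         fitted = fitted, residuals = resid,
         rc2 = NA_real_, aicc = aicc,
         loglik_ml = -full$neg2ml / 2, loglik_reml = -full$neg2reml / 2,
         rmse = sqrt(mean(resid^2)), mae = mean(abs(resid)),
         converged = converged, n_iter = sum(vapply(runs, function(r)
           r$counts[["function"]], numeric(1))),
         trace = trace, n = n, p = p, theta = best$par),
    class = "lmm_fit"
  )
  fit$rc2 <- conditional_r2(fit, ds)
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.lmm_fit <- function(x, ...) {
  cat("linear mixed model (VC random effects + AR(1) errors), REML\n")
  print(round(cbind(estimate = x$beta_fixed, se = x$se_fixed,
                    t = x$tvals, p = x$pvals), 4))
  cat("variance components:\n")
  print(signif(x$var_components, 4))
  cat(sprintf("r = %.3f  sigma2 = %.3f  Rc2 = %.4f  AICc = %.2f  %s\n",
              x$ar1_r, x$resid_var, x$rc2, x$aicc,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Per-city coefficient table from a mixed-model fit
#'
#' Row s is `beta_fixed + gamma[s, ]`: the city-specific regression line
#' implied by the BLUPs, the per-city analogue of the global fixed effects.
#'
#' @param fit an `lmm_fit`.
#' @return S x 6 matrix, one row per city.
#' @export
city_models <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  sweep(fit$gamma, 2L, fit$beta_fixed, "+")
}

#' Conditional R-squared of a mixed-model fit
#'
#' Proportion of response variance attributed to fixed plus random effects:
#' `(sigma_f^2 + sigma_r^2) / (sigma_f^2 + sigma_r^2 + sigma_e^2)`, where
#' `sigma_f^2` is the variance of the fixed-effect predictor over records,
#' `sigma_r^2` the mean over records of `z_i' G z_i`, and `sigma_e^2` the
#' marginal residual variance.
#'
#' @param fit an `lmm_fit`.
#' @param ds the panel it was fitted on.
#' @return Scalar in `[0, 1]`.
#' @export
conditional_r2 <- function(fit, ds) {
  stopifnot(inherits(fit, "lmm_fit"))
  X <- design_matrix(ds)
  sf2 <- stats::var(drop(X %*% fit$beta_fixed))
  sr2 <- mean(drop((X^2) %*% fit$var_components))
  se2 <- fit$resid_var
  tot <- sf2 + sr2 + se2
  if (tot <= 0) stop("all variance components are zero", call. = FALSE)
  (sf2 + sr2) / tot
}
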