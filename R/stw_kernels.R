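# Spatial, temporal and spatiotemporal kernels with adaptive bandwidths.
#
# The combined squared distance is d_ST^2 = lambda * d_S^2 + mu * d_T^2
# (planar Euclidean in space, week-index difference in time); all kernels
# receive d = sqrt(d_ST^2). Under this definition the Gaussian
# spatiotemporal weight factorizes exactly into a spatial and a temporal
# Gaussian with bandwidths h^2/lambda and h^2/mu.

.kernels <- c("bisquare", "gaussian", "exponential", "boxcar")

#' Kernel configuration for the local models
#'
#' @param mode `"spatial"` (GWR: mu = 0), `"temporal"` (TWR: lambda = 0) or
#'   `"spatiotemporal"` (GTWR: lambda = 1, mu = tau).
#' @param kernel one of `"bisquare"`, `"gaussian"`, `"exponential"`,
#'   `"boxcar"`; defaults to bisquare in spatial mode and gaussian
#'   otherwise.
#' @param k adaptive neighbour count (the bandwidth at each focal record is
#'   the distance to its k-th nearest record, the focal record itself
#'   counted); must be at least p + 2 = 8.
#' @param tau temporal-to-spatial scale ratio mu/lambda used in
#'   spatiotemporal mode; only the ratio is identifiable jointly with the
#'   bandwidth, so lambda is fixed at 1.
#' @param ra2_method effective parameter count used in the adjusted
#'   R-squared: `"trS"` (hat-matrix trace, default) or `"p"` (raw
#'   coefficient count).
#' @return An object of class `kernel_config` with resolved `lambda`, `mu`.
#' @export
kernel_config <- function(mode = c("spatial", "temporal", "spatiotemporal"),
                          kernel = NULL, k = 30L, tau = 1,
                          ra2_method = c("trS", "p")) {
  mode <- match.arg(mode)
  ra2_method <- match.arg(ra2_method)
  if (is.null(kernel)) {
    kernel <- if (mode == "spatial") "bisquare" else "gaussian"
  }
  kernel <- match.arg(kernel, .kernels)
  if (k < 8L) stop("k must be at least p + 2 = 8", call. = FALSE)
  if (tau < 0) stop("tau must be >= 0", call. = FALSE)
  lambda <- switch(mode, spatial = 1, temporal = 0, spatiotemporal = 1)
  mu <- switch(mode, spatial = 0, temporal = 1, spatiotemporal = tau)
  if (lambda == 0 && mu == 0) stop("lambda and mu cannot both be 0",
                                   call. = FALSE)
  structure(
    list(mode = mode, kernel = kernel, k = as.integer(k), tau = tau,
         lambda = lambda, mu = mu, ra2_method = ra2_method),
    class = "kernel_config"
  )
}

#' Combined space-time squared distance
#'
#' `lambda * ((u_i-u_j)^2 + (v_i-v_j)^2) + mu * (t_i-t_j)^2`. Symmetric in
#' its two records and zero iff they coincide under the active scale
#' factors.
#'
#' @param rec_i,rec_j lists (or data.frame rows) with fields `u`, `v`, `t`;
#'   `rec_j` may be vectorized.
#' @param lambda,mu nonnegative spatial and temporal scale factors.
#' @return Nonnegative squared distance(s).
#' @export
st_squared_distance <- function(rec_i, rec_j, lambda = 1, mu = 1) {
  if (lambda < 0 || mu < 0) stop("scale factors must be >= 0", call. = FALSE)
  lambda * ((rec_i$u - rec_j$u)^2 + (rec_i$v - rec_j$v)^2) +
    mu * (rec_i$t - rec_j$t)^2
}

# Squared space-time distances from record i to every record of the panel.
.dist2_to_all <- function(ds, i, lambda, mu) {
  x <- ds$data$x
  y <- ds$data$y
  t <- ds$data$week
  lambda * ((x - x[i])^2 + (y - y[i])^2) + mu * (t - t[i])^2
}

#' Adaptive bandwidth at a focal record
#'
#' The bandwidth is the k-th smallest space-time distance from the focal
#' record to all records, the focal record itself included (contributing
#' distance 0). All records tied at the k-th distance fall on the bandwidth;
#' the bi-square kernel assigns them weight 0 there.
#'
#' @param focal record index.
#' @param ds a [panel_dataset()].
#' @param cfg a [kernel_config()].
#' @return Bandwidth h in distance units.
#' @export
adaptive_bandwidth <- function(focal, ds, cfg) {
  n <- n_records(ds)
  if (cfg$k > n) stop("k exceeds the number of records", call. = FALSE)
  d2 <- .dist2_to_all(ds, focal, cfg$lambda, cfg$mu)
  h2 <- sort.int(d2, partial = cfg$k)[cfg$k]
  if (h2 <= 0) {
    stop("degenerate bandwidth at record ", focal,
         ": the ", cfg$k, " nearest records coincide with it; increase k",
         call. = FALSE)
  }
  sqrt(h2)
}

#' Kernel weight
#'
#' Bi-square `[1-(d/h)^2]^2` for d < h (0 beyond), Gaussian `exp(-d^2/h^2)`,
#' exponential `exp(-d/h)`, boxcar `1 for d <= h`. All kernels give weight 1
#' at d = 0.
#'
#' @param d nonnegative distance(s).
#' @param h bandwidth, > 0.
#' @param kernel kernel name.
#' @return Weight(s) in `[0, 1]`.
#' @export
kernel_weight <- function(d, h, kernel = "bisquare") {
  if (h <= 0) stop("bandwidth must be > 0", call. = FALSE)
  kernel <- match.arg(kernel, .kernels)
  switch(kernel,
    bisquare = ifelse(d < h, (1 - (d / h)^2)^2, 0),
    gaussian = exp(-(d / h)^2),
    exponential = exp(-d / h),
    boxcar = as.numeric(d <= h)
  )
}

#' Kernel weights of all records for one focal record
#'
#' Resolves the adaptive bandwidth at the focal record, then evaluates the
#' kernel at every record's space-time distance. The focal record's own
#' weight is always 1.
#'
#' @inheritParams adaptive_bandwidth
#' @return Numeric weight vector of length `n_records(ds)`.
#' @export
weight_vector <- function(focal, ds, cfg) {
  d2 <- .dist2_to_all(ds, focal, cfg$lambda, cfg$mu)
  h2 <- sort.int(d2, partial = cfg$k)[cfg$k]
  if (h2 <= 0) {
    stop("degenerate bandwidth at record ", focal,
         ": the ", cfg$k, " nearest records coincide with it; increase k",
         call. = FALSE)
  }
  kernel_weight(sqrt(d2), sqrt(h2), cfg$kernel)
}

#' Select the neighbour count (and scale ratio) by AICc
#'
#' Evaluates [fit_stwr()] over a coarse grid of at most `n_k` neighbour
#' counts between `k_min` and `k_max` (log-spaced), crossed with a grid of
#' scale ratios `tau` in spatiotemporal mode, then refines the neighbour
#' count by integer golden-section search between the coarse minimum's grid
#' neighbours. Deterministic for fixed inputs.
#'
#' @param ds a [panel_dataset()].
#' @param cfg a [kernel_config()]; its `k` (and `tau` in spatiotemporal
#'   mode) are overridden by the search.
#' @param search_opts list: `k_min` (default p + 2 = 8), `k_max` (default
#'   n), `n_k` (coarse grid size, default 25, maximum 25), `tau_grid`
#'   (default `10^seq(-2, 2, length.out = 9)`; ignored outside
#'   spatiotemporal mode).
#' @return list with `k`, `tau`, `aicc`, `cfg` (the winning configuration)
#'   and `trace` (data.frame of every (k, tau, AICc) evaluated).
#' @export
select_bandwidth <- function(ds, cfg, search_opts = list()) {
  n <- n_records(ds)
  k_min <- as.integer(search_opts$k_min %||% 8L)
  k_max <- as.integer(search_opts$k_max %||% n)
  n_k <- min(as.integer(search_opts$n_k %||% 25L), 25L)
  stopifnot(k_min >= 8L, k_max <= n, k_min <= k_max)
  tau_grid <- if (cfg$mode == "spatiotemporal") {
    search_opts$tau_grid %||% 10^seq(-2, 2, length.out = 9)
  } else {
    cfg$tau
  }
  k_grid <- unique(round(exp(seq(log(k_min), log(k_max),
                                 length.out = n_k))))

  eval_one <- function(k, tau) {
    cfg_k <- kernel_config(cfg$mode, cfg$kernel, k = k, tau = tau,
                           ra2_method = cfg$ra2_method)
    tryCatch(fit_stwr(ds, cfg_k)$aicc, error = function(e) NA_real_)
  }

  trace <- expand.grid(k = k_grid, tau = tau_grid)
  trace$aicc <- mapply(eval_one, trace$k, trace$tau)
  if (all(is.na(trace$aicc))) {
    err <- simpleError("bandwidth selection failed for every candidate")
    err$trace <- trace
    stop(err)
  }
  best <- trace[which.min(trace$aicc), ]
  tau_star <- best$tau

  # integer golden-section refinement between the coarse minimum's grid
  # neighbours (at the fixed winning tau)
  pos <- match(best$k, k_grid)
  lo <- if (pos > 1L) k_grid[pos - 1L] else k_grid[1L]
  hi <- if (pos < length(k_grid)) k_grid[pos + 1L] else k_grid[length(k_grid)]
  cache <- stats::setNames(as.list(trace$aicc[trace$tau == tau_star]),
                           trace$k[trace$tau == tau_star])
  f <- function(k) {
    key <- as.character(k)
    if (is.null(cache[[key]])) {
      val <- eval_one(k, tau_star)
      cache[[key]] <<- val
      trace <<- rbind(trace, data.frame(k = k, tau = tau_star, aicc = val))
    }
    cache[[key]]
  }
  gr <- (sqrt(5) - 1) / 2
  while (hi - lo > 2L) {
    m1 <- round(hi - gr * (hi - lo))
    m2 <- round(lo + gr * (hi - lo))
    if (m1 >= m2) break
    v1 <- f(m1)
    v2 <- f(m2)
    if (is.na(v1) || is.na(v2)) break
    if (v1 <= v2) hi <- m2 else lo <- m1
  }
  cand <- lo:hi
  vals <- vapply(cand, f, numeric(1))
  k_star <- if (all(is.na(vals))) best$k else cand[which.min(vals)]

  cfg_star <- kernel_config(cfg$mode, cfg$kernel, k = k_star, tau = tau_star,
                            ra2_method = cfg$ra2_method)
  list(k = k_star, tau = tau_star,
       aicc = min(c(vals, best$aicc), na.rm = TRUE),
       cfg = cfg_star, trace = trace)
}
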