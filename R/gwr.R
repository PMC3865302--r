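# Geographically weighted regression: adaptive Gaussian kernel, per-cell
# weighted least squares, hat-matrix diagnostics, corrected AIC, bandwidth
# selection, and the global OLS baseline.
#
# The model has one predictor (log10 population density) plus intercept, so
# every local normal-equation system is 2x2 and the whole fit is vectorised:
# for each cell i the weighted moments S_w, S_wx, S_wxx, S_wy, S_wxy come
# from one matrix product W %*% [1, x, x^2, y, xy].

#' Kernel specification for GWR
#'
#' The adaptive Gaussian kernel sets each cell's bandwidth to the
#' great-circle distance of its k-th nearest neighbour, so the kernel widens
#' where data are sparse; the Gaussian is untruncated. `kind = "flat"` gives
#' every observation unit weight (the OLS limit), useful for equivalence
#' checks.
#'
#' @param k number of nearest neighbours defining the per-cell bandwidth
#' @param fraction alternatively, share of observations (k = round(fraction*n))
#' @param kind `"adaptive_gaussian"` (default) or `"flat"`
#' @return an object of class `gwr_kernel`
#' @export
gwr_kernel <- function(k = NULL, fraction = NULL,
                       kind = c("adaptive_gaussian", "flat")) {
  kind <- match.arg(kind)
  if (kind == "adaptive_gaussian") {
    if (is.null(k) && is.null(fraction))
      stop("gwr_kernel: supply k or fraction", call. = FALSE)
    if (!is.null(k) && k < 3)
      stop("gwr_kernel: k must be >= 3", call. = FALSE)
  }
  structure(list(k = k, fraction = fraction, kind = kind), class = "gwr_kernel")
}

resolve_k <- function(kernel, n) {
  k <- if (!is.null(kernel$k)) kernel$k else round(kernel$fraction * n)
  k <- as.integer(k)
  if (k < 3 || k > n - 1)
    stop("gwr_kernel: need 3 <= k <= n - 1 (k = ", k, ", n = ", n, ")",
         call. = FALSE)
  k
}

#' Adaptive bandwidth: distance to the k-th nearest other cell
#'
#' @param coords two-column matrix/data frame of (lon, lat) in degrees
#' @param i cell index
#' @param k neighbour order (k <= n - 1)
#' @return bandwidth in km; if the k-th neighbour distance is 0 (duplicate
#'   coordinates) the smallest positive neighbour distance is used and a
#'   warning raised
#' @export
adaptive_bandwidth_distance <- function(coords, i, k) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (k > n - 1) stop("k must be <= n - 1", call. = FALSE)
  d <- haversine_km(coords[i, 1], coords[i, 2], coords[, 1], coords[, 2])
  d <- sort(d[-i])
  b <- d[k]
  if (b <= 0) {
    pos <- d[d > 0]
    if (!length(pos))
      stop("adaptive_bandwidth_distance: all neighbours coincide with cell ",
           i, call. = FALSE)
    warning("duplicate coordinates at cell ", i,
            "; falling back to smallest positive neighbour distance")
    b <- min(pos)
  }
  b
}

# per-row k-th nearest neighbour distances from a full distance matrix
adaptive_bandwidths <- function(D, k) {
  n <- nrow(D)
  b <- numeric(n)
  for (i in seq_len(n)) {
    d <- sort(D[i, -i], partial = k)[k]
    if (d <= 0) {
      pos <- D[i, -i]; pos <- pos[pos > 0]
      if (!length(pos))
        stop("all neighbours coincide with cell ", i, call. = FALSE)
      d <- min(pos)
    }
    b[i] <- d
  }
  b
}

#' Gaussian kernel weights
#'
#' `w = exp(-0.5 * (d / b)^2)`: 1 at distance zero, `exp(-0.5)` at one
#' bandwidth, strictly decreasing in distance.
#'
#' @param d distances (km), any shape
#' @param b bandwidth (km), > 0
#' @return weights in (0, 1]
#' @export
kernel_weights <- function(d, b) {
  if (any(b <= 0)) stop("kernel_weights: bandwidth must be > 0", call. = FALSE)
  exp(-0.5 * (d / b)^2)
}

#' Local weighted least squares at one point
#'
#' Solves `beta = (X'WX)^{-1} X'W y` for a design `X` with intercept column,
#' and returns the row of the hat matrix mapping `y` to the fitted value at
#' the target cell `i` (the cell whose weight pattern `w` encodes).
#'
#' @param X design matrix (first column the intercept)
#' @param y response vector
#' @param w nonnegative weights, `sum(w) > 0`
#' @param i index of the target cell (for the hat row and fitted value)
#' @return list with `beta`, `hat_row`, `fitted`
#' @export
local_wls <- function(X, y, w, i = which.max(w)) {
  X <- as.matrix(X)
  if (sum(w) <= 0) stop("local_wls: weights sum to zero", call. = FALSE)
  XtW <- t(X * w)
  A <- XtW %*% X
  ok <- TRUE
  Ainv <- tryCatch(solve(A), error = function(e) { ok <<- FALSE; NULL })
  if (!ok || !all(is.finite(Ainv)))
    stop("local_wls: singular weighted design at cell ", i, call. = FALSE)
  C <- Ainv %*% XtW            # maps y to beta
  beta <- unname(drop(C %*% y))
  hat_row <- drop(X[i, ] %*% C)
  list(beta = beta, hat_row = hat_row, fitted = sum(X[i, ] * beta))
}

#' Corrected Akaike information criterion for GWR
#'
#' `AICc = 2n log(sigma_hat) + n log(2 pi) + n (n + trS) / (n - 2 - trS)`,
#' with `sigma_hat` the maximum-likelihood residual scale `sqrt(RSS/n)` and
#' `trS` the trace of the hat matrix. At `trS = 2` this is the small-sample
#' AICc of a straight-line fit. The `n log(2 pi)` constant is kept so OLS and
#' GWR values are directly comparable.
#'
#' @param n number of observations
#' @param sigma_hat ML residual scale
#' @param trS hat-matrix trace
#' @return AICc value
#' @export
gwr_aicc <- function(n, sigma_hat, trS) {
  if (n <= trS + 2)
    stop("gwr_aicc: undefined for n <= trS + 2", call. = FALSE)
  2 * n * log(sigma_hat) + n * log(2 * pi) + n * (n + trS) / (n - 2 - trS)
}

#' Fit a geographically weighted regression
#'
#' One weighted least-squares fit per cell, with kernel weights centred on
#' that cell. Returns per-cell coefficients, standard errors, t-statistics,
#' local R^2 and leverage, plus the hat-matrix trace terms, effective number
#' of parameters `p_eff = 2 trS - trS'S`, the residual variance
#' `RSS / (n - p_eff)`, the corrected AIC and the global adjusted R^2
#' (computed with `p_eff` model degrees of freedom).
#'
#' @param dataset a `fire_grid`
#' @param kernel a [gwr_kernel()]
#' @param D optional precomputed distance matrix (km); computed if `NULL`
#' @return an object of class `fire_gwr`
#' @export
fit_gwr <- function(dataset, kernel, D = NULL) {
  stopifnot(inherits(dataset, "fire_grid"), inherits(kernel, "gwr_kernel"))
  cells <- dataset$cells
  n <- nrow(cells)
  x <- cells$x
  y <- cells$y

  if (kernel$kind == "flat") {
    W <- matrix(1, n, n)
    k <- n - 1L
    bw <- rep(Inf, n)
  } else {
    k <- resolve_k(kernel, n)
    if (is.null(D)) D <- dist_matrix_km(cells$lon, cells$lat)
    bw <- adaptive_bandwidths(D, k)
    W <- exp(-0.5 * (D / bw)^2)   # row i: weights of cell i's local fit
  }

  core <- gwr_core_stats(W, x, y)
  if (any(!is.finite(core$beta1)))
    stop("fit_gwr: singular local fit at cell ",
         which(!is.finite(core$beta1))[1], call. = FALSE)

  resid <- y - core$fitted
  rss <- sum(resid^2)
  trS <- core$trS
  trStS <- core$trStS
  p_eff <- 2 * trS - trStS
  sigma2_hat <- rss / (n - p_eff)
  sigma_ml <- sqrt(rss / n)
  aicc <- gwr_aicc(n, sigma_ml, trS)
  tss <- sum((y - mean(y))^2)
  adj_r2 <- 1 - (rss / (n - p_eff)) / (tss / (n - 1))

  se0 <- sqrt(sigma2_hat * core$v00)
  se1 <- sqrt(sigma2_hat * core$v11)

  # local R^2: weighted, using each cell's own weight pattern and the GWR
  # fitted values
  r2loc <- local_r2_all(W, y, core$fitted, core$Swy, core$Sw)

  structure(list(
    cells = data.frame(
      lon = cells$lon, lat = cells$lat,
      beta0_hat = core$beta0, beta1_hat = core$beta1,
      se0 = se0, se1 = se1,
      t0 = core$beta0 / se0, t1 = core$beta1 / se1,
      local_r2 = r2loc, leverage = core$hat_diag,
      fitted = core$fitted, resid = resid
    ),
    n = n, bandwidth_k = k, bandwidths_km = bw,
    trS = trS, trStS = trStS, p_eff = p_eff,
    sigma2_hat = sigma2_hat, rss = rss, aicc = aicc, adj_r2 = adj_r2,
    kernel = kernel
  ), class = "fire_gwr")
}

# vectorised per-cell 2x2 WLS given the full weight matrix
gwr_core_stats <- function(W, x, y) {
  Z <- cbind(1, x, x * x, y, x * y)
  M <- W %*% Z
  Sw <- M[, 1]; Swx <- M[, 2]; Swxx <- M[, 3]; Swy <- M[, 4]; Swxy <- M[, 5]
  det <- Sw * Swxx - Swx^2
  beta1 <- (Sw * Swxy - Swx * Swy) / det
  beta0 <- (Swxx * Swy - Swx * Swxy) / det
  fitted <- beta0 + beta1 * x
  # hat row i evaluated at j: w_ij * (u_i + v_i * x_j)
  u <- (Swxx - Swx * x) / det
  v <- (Sw * x - Swx) / det
  hat_diag <- diag(W) * (u + v * x)
  trS <- sum(hat_diag)
  # tr(S'S) = sum_ij hat_ij^2 via second moments of W^2
  W2 <- W * W
  M2 <- W2 %*% cbind(1, x, x * x)
  S2w <- M2[, 1]; S2wx <- M2[, 2]; S2wxx <- M2[, 3]
  trStS <- sum(u^2 * S2w + 2 * u * v * S2wx + v^2 * S2wxx)
  # Var(beta_i) = sigma2 * [A^{-1} B A^{-1}] with B = X'W^2X
  a00 <- Swxx / det; a01 <- -Swx / det; a11 <- Sw / det
  v00 <- a00 * (a00 * S2w + a01 * S2wx) + a01 * (a00 * S2wx + a01 * S2wxx)
  v11 <- a01 * (a01 * S2w + a11 * S2wx) + a11 * (a01 * S2wx + a11 * S2wxx)
  list(beta0 = beta0, beta1 = beta1, fitted = fitted, hat_diag = hat_diag,
       trS = trS, trStS = trStS, v00 = v00, v11 = v11, Sw = Sw, Swy = Swy)
}

local_r2_all <- function(W, y, fitted, Swy, Sw) {
  rss_w <- drop(W %*% (y - fitted)^2)
  tss_w <- drop(W %*% (y * y)) - Swy^2 / Sw
  out <- 1 - rss_w / tss_w
  out[tss_w <= 0] <- NA_real_
  out
}

#' @export
print.fire_gwr <- function(x, ...) {
  cat(sprintf("fire_gwr: n = %d, k = %d (%.1f%% of n)\n",
              x$n, x$bandwidth_k, 100 * x$bandwidth_k / x$n))
  cat(sprintf("  trS = %.2f, p_eff = %.2f, AICc = %.2f, adj R^2 = %.3f\n",
              x$trS, x$p_eff, x$aicc, x$adj_r2))
  invisible(x)
}

#' Local R^2 at one cell
#'
#' `1 - sum_j w_ij (y_j - yhat_j)^2 / sum_j w_ij (y_j - ybar_w)^2` with
#' `ybar_w` the w-weighted mean; `NA` when the weighted variance is zero.
#'
#' @param dataset the `fire_grid` the fit was made on
#' @param fit a `fire_gwr`
#' @param i cell index
#' @return local R^2 value
#' @export
local_r2 <- function(dataset, fit, i) {
  cells <- dataset$cells
  d <- haversine_km(cells$lon[i], cells$lat[i], cells$lon, cells$lat)
  w <- if (fit$kernel$kind == "flat") rep(1, length(d)) else
    kernel_weights(d, fit$bandwidths_km[i])
  y <- cells$y
  yhat <- fit$cells$fitted
  ybar <- sum(w * y) / sum(w)
  tss <- sum(w * (y - ybar)^2)
  if (tss <= 0) return(NA_real_)
  1 - sum(w * (y - yhat)^2) / tss
}

#' AICc of a GWR fit at a given neighbour count, for bandwidth search
#' @keywords internal
aicc_at_k <- function(dataset, k, D, sortedD = NULL) {
  cells <- dataset$cells
  n <- nrow(cells)
  bw <- if (!is.null(sortedD)) sortedD[, k] else adaptive_bandwidths(D, k)
  bw[bw <= 0] <- NA
  if (any(is.na(bw))) bw <- adaptive_bandwidths(D, k)
  W <- exp(-0.5 * (D / bw)^2)
  core <- gwr_core_stats(W, cells$x, cells$y)
  if (any(!is.finite(core$beta1))) return(Inf)
  rss <- sum((cells$y - core$fitted)^2)
  if (rss <= 0) return(-Inf)
  if (n <= core$trS + 2) return(Inf)
  gwr_aicc(n, sqrt(rss / n), core$trS)
}

#' Select the kernel bandwidth by minimising AICc
#'
#' Golden-section search over the integer neighbour count k, followed by an
#' exhaustive sweep of +/-2 around the incumbent; ties within numerical noise
#' are broken toward larger k (the smoother model). Set
#' `method = "exhaustive"` to score every k in the range (the audit oracle).
#'
#' @param dataset a `fire_grid`
#' @param k_range integer vector `c(lo, hi)`; defaults to
#'   `[max(16, 0.01 n), 0.25 n]`
#' @param method `"golden"` (default) or `"exhaustive"`
#' @param D optional precomputed distance matrix
#' @return list with `k`, `aicc`, and `profile` (data frame of evaluated k
#'   and AICc values)
#' @export
select_bandwidth <- function(dataset, k_range = NULL,
                             method = c("golden", "exhaustive"), D = NULL) {
  stopifnot(inherits(dataset, "fire_grid"))
  method <- match.arg(method)
  n <- nrow(dataset$cells)
  if (is.null(k_range))
    k_range <- c(max(16, ceiling(0.01 * n)), max(17, floor(0.25 * n)))
  lo <- max(3L, as.integer(k_range[1]))
  hi <- min(n - 1L, as.integer(k_range[2]))
  if (lo >= hi) stop("select_bandwidth: empty k range", call. = FALSE)
  if (is.null(D)) D <- dist_matrix_km(dataset$cells$lon, dataset$cells$lat)
  # k-th neighbour distances for all k at once
  sortedD <- t(apply(D, 1, function(r) sort(r)[-1]))

  cache <- new.env(parent = emptyenv())
  score <- function(k) {
    key <- as.character(k)
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- aicc_at_k(dataset, k, D, sortedD)
    cache[[key]] <- val
    val
  }

  if (method == "exhaustive") {
    ks <- lo:hi
    vals <- vapply(ks, score, numeric(1))
    best <- ks[vals <= min(vals) + 1e-9]
    k_star <- max(best)                      # ties toward larger k
  } else {
    phi <- (sqrt(5) - 1) / 2
    a <- lo; b <- hi
    c1 <- round(b - phi * (b - a)); d1 <- round(a + phi * (b - a))
    while (b - a > 4) {
      if (score(c1) < score(d1)) {
        b <- d1
      } else {
        a <- c1
      }
      c1 <- round(b - phi * (b - a)); d1 <- round(a + phi * (b - a))
      if (c1 == d1) break
    }
    ks <- a:b
    vals <- vapply(ks, score, numeric(1))
    inc <- ks[which.min(vals)]
    sweep <- max(lo, inc - 2):min(hi, inc + 2)
    svals <- vapply(sweep, score, numeric(1))
    cand <- sweep[svals <= min(svals) + 1e-9]
    k_star <- max(cand)
  }

  ks_seen <- sort(as.integer(ls(cache)))
  profile <- data.frame(k = ks_seen,
                        aicc = vapply(as.character(ks_seen),
                                      function(key) cache[[key]], numeric(1)))
  list(k = k_star, aicc = score(k_star), profile = profile)
}

#' Global ordinary least squares baseline
#'
#' The stationary model against which GWR is compared. AIC uses the Gaussian
#' likelihood with ML sigma: `2n log(sigma_hat) + n log(2 pi) + n + 2 (p+1)`,
#' on the same scale as [gwr_aicc()].
#'
#' @param dataset a `fire_grid`
#' @return an object of class `fire_ols` with `beta0`, `beta1`, `aic`,
#'   `adj_r2`, `sigma2`, `n`
#' @export
fit_ols <- function(dataset) {
  stopifnot(inherits(dataset, "fire_grid"))
  cells <- dataset$cells
  n <- nrow(cells)
  if (n < 3) stop("fit_ols: need at least 3 cells", call. = FALSE)
  if (stats::var(cells$x) == 0)
    stop("fit_ols: predictor is constant", call. = FALSE)
  fit <- stats::lm(y ~ x, data = cells)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((cells$y - mean(cells$y))^2)
  sigma_ml <- sqrt(rss / n)
  p <- 1L
  aic <- 2 * n * log(sigma_ml) + n * log(2 * pi) + n + 2 * (p + 1)
  structure(list(
    beta0 = unname(stats::coef(fit)[1]), beta1 = unname(stats::coef(fit)[2]),
    aic = aic, adj_r2 = 1 - (rss / (n - 2)) / (tss / (n - 1)),
    sigma2 = rss / (n - 2), n = n
  ), class = "fire_ols")
}

#' @export
print.fire_ols <- function(x, ...) {
  cat(sprintf("fire_ols: n = %d, slope = %.4f, AIC = %.2f, adj R^2 = %.3f\n",
              x$n, x$beta1, x$aic, x$adj_r2))
  invisible(x)
}

#' Export a GWR fit as a per-cell table
#'
#' @param fit a `fire_gwr`
#' @param path optional CSV path; when given the table is also written there
#' @return the per-cell data frame, invisibly when written
#' @export
export_gwr <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "fire_gwr"))
  tab <- fit$cells
  if (!is.null(path)) {
    utils::write.csv(tab, path, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
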