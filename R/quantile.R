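# Continuous piecewise-linear ("broken stick") quantile regression for
# locating population-density thresholds in fire response.
#
# The check-loss minimiser over a linear basis is computed by iteratively
# reweighted least squares (an MM-style majorisation of the check loss)
# followed by a vertex polish: the optimum of this linear program
# interpolates p data points, so the lowest-|residual| points after IRLS are
# enumerated as exact interpolating bases and scored by exact check loss.

#' Quantile-regression check loss
#'
#' `sum(rho_tau(r))` with `rho_tau(r) = r * (tau - 1[r < 0])`; nonnegative,
#' zero iff all residuals are zero.
#'
#' @param residuals numeric vector
#' @param tau quantile level in (0, 1)
#' @return total check loss
#' @export
check_loss <- function(residuals, tau) {
  if (tau <= 0 || tau >= 1) stop("check_loss: tau must be in (0,1)", call. = FALSE)
  sum(residuals * (tau - (residuals < 0)))
}

# check-loss minimisation over a linear basis X; beta_init warm-starts IRLS
rq_fit_basis <- function(X, y, tau, maxit = 60, tol = 1e-10, beta_init = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  beta <- if (!is.null(beta_init) && length(beta_init) == p) beta_init else
    tryCatch(qr.solve(X, y), error = function(e)
      stop("quantile fit: degenerate design", call. = FALSE))
  delta <- 1e-9 * (stats::sd(y) + 1)
  loss <- check_loss(y - drop(X %*% beta), tau)
  for (it in seq_len(maxit)) {
    r <- y - drop(X %*% beta)
    w <- abs(tau - (r < 0)) / pmax(abs(r), delta)
    Xw <- X * w
    beta_new <- tryCatch(
      solve(crossprod(Xw, X), crossprod(Xw, y))[, 1],
      error = function(e) NULL)
    if (is.null(beta_new) || any(!is.finite(beta_new))) break
    loss_new <- check_loss(y - drop(X %*% beta_new), tau)
    if (loss_new <= loss) {
      conv <- (loss - loss_new) < tol * (loss_new + 1)
      beta <- beta_new; loss <- loss_new
      if (conv) break
    } else break
  }
  # vertex polish: exact interpolating bases among low-|residual| points
  r <- y - drop(X %*% beta)
  m <- min(n, max(2 * p + 4, 8))
  cand <- order(abs(r))[seq_len(m)]
  combos <- utils::combn(cand, p)
  for (j in seq_len(ncol(combos))) {
    idx <- combos[, j]
    Xi <- X[idx, , drop = FALSE]
    if (abs(det(Xi)) < 1e-12 * prod(pmax(1, apply(abs(Xi), 1, max)))) next
    b <- tryCatch(solve(Xi, y[idx]), error = function(e) NULL)
    if (is.null(b) || any(!is.finite(b))) next
    l <- check_loss(y - drop(X %*% b), tau)
    if (l < loss - 1e-12) { beta <- b; loss <- l }
  }
  list(coefficients = unname(beta), loss = loss)
}

#' Fit a single straight line by check-loss minimisation
#'
#' The tau-th conditional quantile line of y given x.
#'
#' @param x,y data vectors
#' @param tau quantile level in (0, 1)
#' @return list with `intercept`, `slope`, `loss`
#' @export
fit_quantile_line <- function(x, y, tau = 0.5) {
  if (length(x) < 3) stop("fit_quantile_line: need n >= 3", call. = FALSE)
  if (stats::var(x) == 0) stop("fit_quantile_line: x is constant", call. = FALSE)
  f <- rq_fit_basis(cbind(1, x), y, tau)
  list(intercept = f$coefficients[1], slope = f$coefficients[2], loss = f$loss)
}

#' Fit a continuous piecewise-linear quantile function with breakpoints
#'
#' For each candidate breakpoint set on a grid spanning the central 90% of
#' the x range, the continuous hinge basis `{1, x, (x - c)+ , ...}` is fitted
#' by check-loss minimisation; the set with minimal loss wins, ties broken
#' toward the smallest breakpoint. Candidates leaving fewer than 10 points in
#' any segment are skipped.
#'
#' @param x predictor (log10 population density)
#' @param y response (log10 burned area)
#' @param tau quantile level
#' @param n_breaks 1 or 2 breakpoints
#' @param grid number of candidate positions per breakpoint (default 101), or
#'   a numeric vector of explicit candidate positions
#' @param min_segment minimum points per segment (default 10)
#' @return object of class `fire_bstick` with `tau`, `n_breaks`,
#'   `breakpoints`, `slopes` (one per segment), `intercept`, `loss`,
#'   `candidate_grid`
#' @export
fit_broken_stick <- function(x, y, tau = 0.5, n_breaks = 1, grid = 101,
                             min_segment = 10) {
  if (!n_breaks %in% 1:2)
    stop("fit_broken_stick: n_breaks must be 1 or 2", call. = FALSE)
  rng <- range(x)
  span <- diff(rng)
  lo <- rng[1] + 0.05 * span
  hi <- rng[2] - 0.05 * span
  cand <- if (length(grid) > 1) sort(as.numeric(grid)) else
    seq(lo, hi, length.out = grid)
  ng <- length(cand)

  sets <- if (n_breaks == 1) {
    lapply(cand, function(c1) c1)
  } else {
    out <- list()
    for (i in seq_len(ng - 1)) for (j in (i + 1):ng)
      out[[length(out) + 1L]] <- c(cand[i], cand[j])
    out
  }

  best <- NULL
  warm <- NULL   # adjacent candidates give similar fits; reuse coefficients
  for (cs in sets) {
    seg_counts <- table(cut(x, breaks = c(-Inf, cs, Inf)))
    if (any(seg_counts < min_segment)) next
    X <- cbind(1, x)
    for (c1 in cs) X <- cbind(X, pmax(0, x - c1))
    f <- tryCatch(rq_fit_basis(X, y, tau, beta_init = warm),
                  error = function(e) NULL)
    if (is.null(f)) next
    warm <- f$coefficients
    better <- is.null(best) || f$loss < best$loss - 1e-12 ||
      (abs(f$loss - best$loss) <= 1e-12 && cs[1] < best$breaks[1])
    if (better) best <- list(breaks = cs, coef = f$coefficients, loss = f$loss)
  }
  if (is.null(best))
    stop("fit_broken_stick: no candidate breakpoint set is feasible", call. = FALSE)

  slopes <- cumsum(best$coef[-1])   # slope per segment from hinge increments
  structure(list(tau = tau, n_breaks = n_breaks,
                 breakpoints = best$breaks, slopes = unname(slopes),
                 intercept = best$coef[1], loss = best$loss,
                 candidate_grid = cand),
            class = "fire_bstick")
}

#' @export
print.fire_bstick <- function(x, ...) {
  cat(sprintf("fire_bstick: tau = %.2f, breakpoints (log10) = %s (= %s p/km^2)\n",
              x$tau, paste(round(x$breakpoints, 3), collapse = ", "),
              paste(round(10^x$breakpoints, 2), collapse = ", ")))
  cat(sprintf("  segment slopes: %s; check loss = %.4f\n",
              paste(round(x$slopes, 3), collapse = ", "), x$loss))
  invisible(x)
}

#' Breakpoints in population-density units
#'
#' Converts breakpoints from the log10 axis back to persons per km^2.
#'
#' @param fit a `fire_bstick`
#' @return numeric vector, `10^breakpoint`
#' @export
threshold_in_density_units <- function(fit) {
  stopifnot(inherits(fit, "fire_bstick"))
  10^fit$breakpoints
}

#' Evaluate a fitted broken-stick quantile function
#'
#' @param object a `fire_bstick`
#' @param newdata numeric vector of x values
#' @param ... unused
#' @return fitted quantile values
#' @export
predict.fire_bstick <- function(object, newdata, ...) {
  k <- object$slopes
  hinge_coefs <- c(k[1], diff(k))
  y <- object$intercept + hinge_coefs[1] * newdata
  for (i in seq_along(object$breakpoints))
    y <- y + hinge_coefs[i + 1] * pmax(0, newdata - object$breakpoints[i])
  y
}

#' Export broken-stick fits as a table
#'
#' One row per fit: tau, breakpoints in log10 and p/km^2 units, slopes, loss.
#'
#' @param fits list of `fire_bstick` objects
#' @param path optional CSV path
#' @return data frame
#' @export
export_thresholds <- function(fits, path = NULL) {
  rows <- lapply(fits, function(f) data.frame(
    tau = f$tau,
    breakpoints_log10 = paste(signif(f$breakpoints, 6), collapse = ";"),
    breakpoints_pkm2 = paste(signif(10^f$breakpoints, 6), collapse = ";"),
    slopes = paste(signif(f$slopes, 6), collapse = ";"),
    loss = f$loss, stringsAsFactors = FALSE))
  tab <- do.call(rbind, rows)
  if (!is.null(path)) utils::write.csv(tab, path, row.names = FALSE)
  tab
}
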