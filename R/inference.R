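# Significance machinery: family-wise alpha correction, per-cell t-tests,
# Monte Carlo permutation test of coefficient nonstationarity, and the
# slope-sign x intercept-sign classification.

#' Family-wise alpha correction for the many per-cell tests
#'
#' GWR produces one t-test per cell per coefficient; the family-wise error
#' rate `xi0` is converted into a per-test level by dividing by the effective
#' number of independent tests `p_e / p`:
#' `alpha = xi0 * p / p_e` (the default form). When the model complexity
#' equals the parameter count (`p_e = p`) there is no multiplicity and
#' `alpha = xi0`. Alternative corrections can be supplied via `form`.
#'
#' @param xi0 desired family-wise error rate (default 0.05)
#' @param p_e effective number of parameters of the GWR fit
#' @param p parameters per local model (2 for intercept + slope)
#' @param n number of observations
#' @param form optional function `(xi0, p_e, p, n) -> alpha` replacing the
#'   default
#' @return object of class `alpha_correction` with fields `xi0, p_e, p, n,
#'   alpha`
#' @export
corrected_alpha <- function(xi0 = 0.05, p_e, p = 2, n, form = NULL) {
  if (p < 1) stop("corrected_alpha: p must be >= 1", call. = FALSE)
  if (p_e < p) stop("corrected_alpha: p_e must be >= p", call. = FALSE)
  if (!missing(n) && !is.null(n) && n <= p_e)
    stop("corrected_alpha: need n > p_e", call. = FALSE)
  alpha <- if (is.null(form)) xi0 * p / p_e else form(xi0, p_e, p, n)
  if (alpha <= 0 || alpha > xi0 + 1e-12)
    stop("corrected_alpha: correction must give 0 < alpha <= xi0", call. = FALSE)
  structure(list(xi0 = xi0, p_e = p_e, p = p,
                 n = if (missing(n)) NA_integer_ else n, alpha = alpha),
            class = "alpha_correction")
}

#' Per-cell t-tests of the local coefficients
#'
#' Two-sided tests of `beta = 0` using `t = beta_hat / se` against a
#' t reference with `n - p_eff` degrees of freedom. Cells with nonpositive
#' or nonfinite standard errors are flagged unreliable and excluded from the
#' significant set.
#'
#' @param fit a `fire_gwr`
#' @param alpha per-test significance level, or an `alpha_correction`
#' @return data frame with logical columns `sig0`, `sig1` (intercept/slope
#'   significance), `reliable`, and the critical value as attribute `t_crit`
#' @export
local_t_tests <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "fire_gwr"))
  if (inherits(alpha, "alpha_correction")) alpha <- alpha$alpha
  df <- fit$n - fit$p_eff
  if (df <= 0) stop("local_t_tests: nonpositive residual df", call. = FALSE)
  t_crit <- stats::qt(1 - alpha / 2, df)
  reliable <- is.finite(fit$cells$se0) & fit$cells$se0 > 0 &
    is.finite(fit$cells$se1) & fit$cells$se1 > 0
  out <- data.frame(
    sig0 = reliable & abs(fit$cells$t0) > t_crit,
    sig1 = reliable & abs(fit$cells$t1) > t_crit,
    reliable = reliable
  )
  attr(out, "t_crit") <- t_crit
  attr(out, "alpha") <- alpha
  attr(out, "df") <- df
  out
}

#' Monte Carlo permutation test of coefficient nonstationarity
#'
#' Tests whether the spatial variability of the local coefficient estimates
#' exceeds what a stationary relationship would produce: the (x, y) pairs are
#' randomly permuted across the fixed cell locations, the GWR is refitted at
#' the same bandwidth, and the spatial variance of each local coefficient is
#' recorded. The p-value is `(1 + #{null >= observed}) / (n_perm + 1)`.
#' Permutations that give a singular fit are redrawn (count reported).
#'
#' @param dataset a `fire_grid`
#' @param kernel a [gwr_kernel()]
#' @param n_perm number of permutations (>= 99)
#' @param seed integer seed
#' @return object of class `perm_test`: data frame with one row per
#'   coefficient (`intercept`, `slope`) carrying `observed_variance`,
#'   `p_value`, `n_perm`, `n_redrawn`, `seed`; the null variances are kept in
#'   `attr(, "null_variances")`
#' @export
monte_carlo_nonstationarity <- function(dataset, kernel, n_perm = 99, seed = 1L) {
  stopifnot(inherits(dataset, "fire_grid"))
  if (n_perm < 99) stop("monte_carlo_nonstationarity: n_perm must be >= 99",
                        call. = FALSE)
  cells <- dataset$cells
  n <- nrow(cells)
  k <- if (kernel$kind == "flat") n - 1L else resolve_k(kernel, n)
  D <- dist_matrix_km(cells$lon, cells$lat)
  W <- if (kernel$kind == "flat") matrix(1, n, n) else {
    bw <- adaptive_bandwidths(D, k)
    exp(-0.5 * (D / bw)^2)
  }

  coef_vars <- function(x, y) {
    core <- gwr_core_stats(W, x, y)
    if (any(!is.finite(core$beta0)) || any(!is.finite(core$beta1)))
      return(NULL)
    c(stats::var(core$beta0), stats::var(core$beta1))
  }

  obs <- coef_vars(cells$x, cells$y)
  if (is.null(obs))
    stop("monte_carlo_nonstationarity: singular fit on observed data",
         call. = FALSE)

  set.seed(seed)
  null_v <- matrix(NA_real_, n_perm, 2)
  n_redrawn <- 0L
  for (b in seq_len(n_perm)) {
    repeat {
      idx <- sample.int(n)
      v <- coef_vars(cells$x[idx], cells$y[idx])
      if (!is.null(v)) break
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > 10 * n_perm)
        stop("monte_carlo_nonstationarity: too many singular permutations",
             call. = FALSE)
    }
    null_v[b, ] <- v
  }

  p_val <- vapply(1:2, function(j) (1 + sum(null_v[, j] >= obs[j])) / (n_perm + 1),
                  numeric(1))
  out <- data.frame(coefficient = c("intercept", "slope"),
                    observed_variance = obs, p_value = p_val,
                    n_perm = n_perm, n_redrawn = n_redrawn, seed = seed,
                    stringsAsFactors = FALSE)
  attr(out, "null_variances") <- null_v
  class(out) <- c("perm_test", "data.frame")
  out
}

#' Classify cells by significant slope and intercept signs
#'
#' Sign comes from the point estimate, membership from the t-test. Joint
#' classes follow the four slope-sign x intercept-sign combinations (both
#' positive; positive slope / negative intercept; negative slope / positive
#' intercept; both negative), with `nonsignificant` when either test fails.
#'
#' @param fit a `fire_gwr`
#' @param tests output of [local_t_tests()]
#' @return object of class `fire_sigmap`: data frame with `lon`, `lat`,
#'   `slope_class`, `intercept_class`, `joint_class`
#' @export
classify_cells <- function(fit, tests) {
  stopifnot(inherits(fit, "fire_gwr"), nrow(tests) == nrow(fit$cells))
  sgn <- function(est, sig)
    ifelse(!sig, "nonsignificant", ifelse(est > 0, "positive", "negative"))
  slope_class <- sgn(fit$cells$beta1_hat, tests$sig1)
  intercept_class <- sgn(fit$cells$beta0_hat, tests$sig0)
  joint <- ifelse(
    slope_class == "nonsignificant" | intercept_class == "nonsignificant",
    "nonsignificant",
    paste0(ifelse(slope_class == "positive", "pos_slope", "neg_slope"), "/",
           ifelse(intercept_class == "positive", "pos_intercept", "neg_intercept")))
  out <- data.frame(lon = fit$cells$lon, lat = fit$cells$lat,
                    slope_class = slope_class,
                    intercept_class = intercept_class,
                    joint_class = joint, stringsAsFactors = FALSE)
  class(out) <- c("fire_sigmap", "data.frame")
  out
}

#' One-row summary of a GWR/OLS comparison
#'
#' Reports, in the layout of a per-continent comparison table: the number of
#' observations, the percentage of cells with significant slopes, the
#' percentage of those that are positive, the OLS AIC, the GWR AICc, and
#' both adjusted R^2 values. `% positive` is `NA` when nothing is
#' significant.
#'
#' @param fit a `fire_gwr`
#' @param map a `fire_sigmap` from [classify_cells()]
#' @param ols a `fire_ols`
#' @param label optional row label (e.g. continent)
#' @return one-row data frame
#' @export
summarize_run <- function(fit, map, ols, label = NA_character_) {
  stopifnot(inherits(fit, "fire_gwr"), inherits(map, "fire_sigmap"),
            inherits(ols, "fire_ols"))
  n <- fit$n
  sig <- map$slope_class != "nonsignificant"
  pct_sig <- 100 * mean(sig)
  pct_pos <- if (any(sig)) 100 * mean(map$slope_class[sig] == "positive") else NA_real_
  data.frame(label = label, n = n,
             pct_significant_slopes = pct_sig,
             pct_positive_slopes = pct_pos,
             aic_ols = ols$aic, aic_gwr = fit$aicc,
             adj_r2_ols = ols$adj_r2, adj_r2_gwr = fit$adj_r2,
             bandwidth_k = fit$bandwidth_k,
             bandwidth_fraction = fit$bandwidth_k / n,
             stringsAsFactors = FALSE)
}
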