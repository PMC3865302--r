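# gwr_core: kernel, local WLS, diagnostics, AICc, bandwidth selection, OLS

test_that("adaptive bandwidth is the k-th neighbour distance", {
  # three collinear equally spaced points along the equator
  coords <- cbind(c(0, 1, 2), c(0, 0, 0))
  spacing <- haversine_km(0, 0, 1, 0)
  expect_equal(adaptive_bandwidth_distance(coords, 2, 1), spacing)
  expect_equal(adaptive_bandwidth_distance(coords, 1, 2),
               haversine_km(0, 0, 2, 0))  # k = n - 1: the maximum

  set.seed(11)
  coords <- cbind(stats::runif(20, -10, 10), stats::runif(20, -10, 10))
  # full-sort brute force oracle
  d <- haversine_km(coords[7, 1], coords[7, 2], coords[, 1], coords[, 2])
  expect_equal(adaptive_bandwidth_distance(coords, 7, 5), sort(d[-7])[5])
  expect_error(adaptive_bandwidth_distance(coords, 1, 20), "n - 1")

  # duplicate coordinates fall back to the smallest positive distance
  dup <- cbind(c(0, 0, 1), c(0, 0, 0))
  expect_warning(b <- adaptive_bandwidth_distance(dup, 1, 1), "duplicate")
  expect_equal(b, haversine_km(0, 0, 1, 0))
})

test_that("Gaussian kernel weights take their closed-form values", {
  expect_equal(kernel_weights(0, 100), 1)
  expect_equal(kernel_weights(100, 100), exp(-0.5))
  expect_equal(kernel_weights(200, 100), exp(-2))
  d <- seq(0, 500, by = 50)
  expect_true(all(diff(kernel_weights(d, 120)) < 0))
  expect_error(kernel_weights(10, 0), "bandwidth")
})

test_that("local_wls solves the weighted normal equations", {
  # hand-solved oracle by explicit 2x2 inversion
  wls_oracle <- function(x, y, w) {
    sw <- sum(w); swx <- sum(w * x); swxx <- sum(w * x^2)
    swy <- sum(w * y); swxy <- sum(w * x * y)
    det <- sw * swxx - swx^2
    c((swxx * swy - swx * swxy) / det, (sw * swxy - swx * swy) / det)
  }
  x <- c(0, 1, 2, 3, 4); y <- c(1.2, 0.8, 2.5, 2.9, 4.1)
  w <- c(1, .8, .5, .2, .1)
  f <- local_wls(cbind(1, x), y, w, i = 1)
  expect_equal(f$beta, wls_oracle(x, y, w), tolerance = 1e-12)

  # uniform weights reduce to OLS
  lmfit <- stats::lm(y ~ x)
  f_unif <- local_wls(cbind(1, x), y, rep(1, 5), i = 3)
  expect_equal(f_unif$beta, unname(stats::coef(lmfit)), tolerance = 1e-12)
  expect_equal(f_unif$fitted, unname(stats::fitted(lmfit)[3]), tolerance = 1e-12)

  # two points: interpolating line regardless of the positive weights
  f2 <- local_wls(cbind(1, c(0, 2)), c(1, 5), c(0.3, 1.7), i = 1)
  expect_equal(f2$beta, c(1, 2), tolerance = 1e-12)

  # hat row maps y to the fitted value
  expect_equal(sum(f$hat_row * y), f$fitted, tolerance = 1e-12)

  # rank deficiency carries the cell index
  expect_error(local_wls(cbind(1, c(1, 1, 1)), 1:3, rep(1, 3), i = 2),
               "singular.*2")
})

test_that("50 random 5-point fixtures match the normal-equation oracle", {
  set.seed(99)
  max_rel <- 0
  for (r in 1:50) {
    x <- stats::rnorm(5); y <- stats::rnorm(5); w <- stats::runif(5, 0.05, 1)
    sw <- sum(w); swx <- sum(w * x); swxx <- sum(w * x^2)
    det <- sw * swxx - swx^2
    oracle <- c((swxx * sum(w * y) - swx * sum(w * x * y)) / det,
                (sw * sum(w * x * y) - swx * sum(w * y)) / det)
    got <- local_wls(cbind(1, x), y, w, i = 1)$beta
    max_rel <- max(max_rel, abs(got - oracle) / pmax(abs(oracle), 1e-12))
  }
  expect_lt(max_rel, 1e-10)
})

test_that("flat-kernel GWR equals OLS at every cell", {
  w <- simulate_gwr_world(gwr_scenario(n_lon = 15, n_lat = 15, seed = 1))
  fit <- fit_gwr(w$data, gwr_kernel(kind = "flat"))
  ols <- fit_ols(w$data)
  expect_lt(max(abs(fit$cells$beta0_hat - ols$beta0)), 1e-6)
  expect_lt(max(abs(fit$cells$beta1_hat - ols$beta1)), 1e-6)
  # hat trace of the OLS limit is the parameter count
  expect_equal(fit$trS, 2, tolerance = 1e-8)
})

test_that("fit_gwr agrees with a per-cell local_wls loop", {
  w <- simulate_gwr_world(gwr_scenario(n_lon = 8, n_lat = 8, seed = 3,
                                       mask_fraction = 0))
  ds <- w$data
  k <- 10
  fit <- fit_gwr(ds, gwr_kernel(k = k))
  n <- nrow(ds$cells)
  D <- dist_matrix_km(ds$cells$lon, ds$cells$lat)
  X <- cbind(1, ds$cells$x)
  hat <- matrix(NA_real_, n, n)
  for (i in 1:n) {
    b <- sort(D[i, -i])[k]
    wts <- kernel_weights(D[i, ], b)
    f <- local_wls(X, ds$cells$y, wts, i = i)
    expect_equal(unname(c(fit$cells$beta0_hat[i], fit$cells$beta1_hat[i])),
                 unname(f$beta), tolerance = 1e-9)
    hat[i, ] <- f$hat_row
  }
  expect_equal(fit$trS, sum(diag(hat)), tolerance = 1e-9)
  expect_equal(fit$trStS, sum(hat^2), tolerance = 1e-9)
})

test_that("zero-noise constant world is recovered exactly", {
  sc <- gwr_scenario(n_lon = 12, n_lat = 12, resolution = 1.0,
                     beta0_surface = function(lon, lat) rep(-2, length(lon)),
                     beta1_surface = function(lon, lat) rep(0.7, length(lon)),
                     noise_sd = 0, pop_logmean = 0, pop_logsd = 0.3,
                     mask_fraction = 0, seed = 6)
  w <- simulate_gwr_world(sc)
  fit <- fit_gwr(w$data, gwr_kernel(k = 20))
  expect_equal(fit$cells$beta1_hat, rep(0.7, fit$n), tolerance = 1e-8)
  expect_lt(fit$rss, 1e-12)
})

test_that("sign of the estimated slope matches the planted sigmoid surface", {
  sc <- gwr_scenario(n_lon = 15, n_lat = 15, noise_sd = 0, mask_fraction = 0,
                     seed = 12)
  w <- simulate_gwr_world(sc)
  fit <- fit_gwr(w$data, gwr_kernel(k = 20))
  agree <- sign(fit$cells$beta1_hat) == sign(w$truth$beta1)
  # cells whose true slope is essentially zero (the sigmoid crossing) have an
  # ill-defined sign; where the sign is determined it must be recovered
  determined <- abs(w$truth$beta1) > 0.1
  expect_gt(mean(determined), 0.8)
  expect_gte(mean(agree[determined]), 0.95)
  expect_gte(mean(agree), 0.90)
})

test_that("hat-trace bounds and effective parameters hold across kernels", {
  w <- simulate_gwr_world(gwr_scenario(n_lon = 10, n_lat = 10, seed = 7,
                                       mask_fraction = 0))
  for (k in c(5, 15, 50, 99)) {
    fit <- fit_gwr(w$data, gwr_kernel(k = k))
    expect_gte(fit$trS, 2 - 1e-9)
    expect_lte(fit$trS, fit$n)
    expect_gte(fit$p_eff, 2 - 1e-9)
    expect_true(all(fit$cells$local_r2 <= 1 + 1e-12, na.rm = TRUE))
  }
})

test_that("AICc formula: OLS-limit identity, monotone penalty, frozen value", {
  # at trS = 2 the formula reduces to the standard small-sample AICc of a
  # straight-line Gaussian model with 3 parameters (intercept, slope, sigma)
  for (n in c(20, 100, 500)) {
    sig <- 0.7
    std <- 2 * n * log(sig) + n * log(2 * pi) + n + 6 + 24 / (n - 4)
    expect_equal(gwr_aicc(n, sig, 2), std, tolerance = 1e-12)
  }
  tr <- seq(2, 40, by = 0.5)
  vals <- sapply(tr, function(t) gwr_aicc(100, 0.5, t))
  expect_true(all(diff(vals) > 0))
  # independent hand evaluation: 200 ln 0.5 + 100 ln 2pi + 100*110/88
  expect_equal(gwr_aicc(100, 0.5, 10), 170.158271, tolerance = 1e-6)
  expect_error(gwr_aicc(10, 0.5, 8), "undefined")
})

test_that("golden-section bandwidth matches exhaustive search", {
  for (s in 1:3) {
    w <- simulate_gwr_world(gwr_scenario(n_lon = 15, n_lat = 15, seed = s))
    g <- select_bandwidth(w$data, method = "golden")
    e <- select_bandwidth(w$data, method = "exhaustive")
    expect_lte(abs(g$aicc - e$aicc), 2)
    expect_true(all(diff(g$profile$k) > 0))
  }
})

test_that("stationary worlds prefer wide bandwidths, nonstationary narrow", {
  ws <- simulate_stationary_world(15, 15, 0, 1, 0.3, seed = 2)
  es <- select_bandwidth(ws$data, method = "exhaustive")
  hi <- floor(0.25 * nrow(ws$data$cells))
  expect_gte(es$k, hi - 5)

  wn <- simulate_gwr_world(gwr_scenario(n_lon = 15, n_lat = 15, noise_sd = 0,
                                        mask_fraction = 0, seed = 3))
  D <- dist_matrix_km(wn$data$cells$lon, wn$data$cells$lat)
  n <- nrow(wn$data$cells)
  expect_lt(popfire:::aicc_at_k(wn$data, 16, D),
            popfire:::aicc_at_k(wn$data, n - 1, D))
})

test_that("OLS baseline: slope oracle and near-zero adjusted R2 under the null", {
  x <- c(0, 1, 2, 3, 4); y <- c(1.2, 0.8, 2.5, 2.9, 4.1)
  g <- lattice_coords(5, 1)
  ds <- grid_dataset(make_cells(g$lon, g$lat, burned_area = 10^(y - 3),
                                pop_density = 10^x))
  # scaling burned area by a constant shifts the intercept only
  y <- y - 3
  ols <- fit_ols(ds)
  expect_equal(ols$beta1, stats::cov(x, y) / stats::var(x), tolerance = 1e-9)

  wnull <- simulate_stationary_world(45, 45, beta0 = 0, beta1 = 0,
                                     noise_sd = 0.5, seed = 31,
                                     mask_fraction = 0)
  onull <- fit_ols(wnull$data)
  expect_lt(abs(onull$adj_r2), 0.02)
  const <- grid_dataset(make_cells(g$lon, g$lat, burned_area = 2,
                                   pop_density = 5))
  expect_error(fit_ols(const), "constant")
})

test_that("local R2 matches its defining formula and edge cases", {
  w <- simulate_gwr_world(gwr_scenario(n_lon = 8, n_lat = 8, seed = 13,
                                       mask_fraction = 0))
  ds <- w$data
  fit <- fit_gwr(ds, gwr_kernel(k = 12))
  i <- 10
  # spreadsheet-style direct evaluation
  d <- haversine_km(ds$cells$lon[i], ds$cells$lat[i], ds$cells$lon, ds$cells$lat)
  wts <- exp(-0.5 * (d / fit$bandwidths_km[i])^2)
  ybar <- sum(wts * ds$cells$y) / sum(wts)
  direct <- 1 - sum(wts * (ds$cells$y - fit$cells$fitted)^2) /
    sum(wts * (ds$cells$y - ybar)^2)
  expect_equal(local_r2(ds, fit, i), direct, tolerance = 1e-10)
  expect_equal(fit$cells$local_r2[i], direct, tolerance = 1e-10)

  # perfect local fit: zero-noise constant world
  w0 <- simulate_gwr_world(gwr_scenario(
    n_lon = 8, n_lat = 8, resolution = 1.0,
    beta0_surface = function(lon, lat) rep(0, length(lon)),
    beta1_surface = function(lon, lat) rep(1, length(lon)),
    noise_sd = 0, pop_logmean = 0, pop_logsd = 0.3, mask_fraction = 0,
    seed = 14))
  f0 <- fit_gwr(w0$data, gwr_kernel(k = 10))
  expect_equal(f0$cells$local_r2, rep(1, f0$n), tolerance = 1e-8)
})
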