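# Synthetic gridded worlds with known spatially varying regression structure,
# stationary nulls, broken-stick quantile structure and anthrome mosaics.

#' Scenario for a spatially varying coefficient world
#'
#' Defines a lon/lat grid and the true local intercept/slope surfaces of the
#' generative model `y = beta0(u,v) + beta1(u,v) * x + e`, on the
#' log10-log10 scale, with `e ~ N(0, noise_sd^2)` and `x` a log-normal
#' population-density field (log10 density Gaussian, spatially smoothed by a
#' 3x3 moving average so the predictor carries spatial autocorrelation).
#'
#' Default surfaces: `beta1` is a tanh sigmoid along longitude crossing zero
#' at mid-grid (coexisting positive and negative slope regions); `beta0`
#' varies linearly with latitude from -1.5 (south edge) to 0.5 (north edge).
#'
#' @param n_lon,n_lat grid dimensions
#' @param resolution cell edge in degrees
#' @param beta0_surface,beta1_surface functions of (lon, lat) returning the
#'   true local coefficients; `NULL` selects the defaults above
#' @param noise_sd standard deviation of the Gaussian error, log10 units
#' @param pop_logmean,pop_logsd mean/sd of log10 population density
#' @param mask_fraction share of cells marked non-combustible
#' @param seed integer seed; generation is a pure function of the scenario
#' @return an object of class `gwr_scenario`
#' @export
gwr_scenario <- function(n_lon = 50, n_lat = 50, resolution = 0.5,
                         beta0_surface = NULL, beta1_surface = NULL,
                         noise_sd = 0.3, pop_logmean = 0.5, pop_logsd = 0.6,
                         mask_fraction = 0.1, seed = 1L) {
  stopifnot(noise_sd >= 0, mask_fraction >= 0, mask_fraction < 1)
  if (n_lon * n_lat < 10)
    stop("gwr_scenario: grid must have at least 10 cells", call. = FALSE)
  lon_span <- n_lon * resolution
  lat_span <- n_lat * resolution
  lon0 <- -lon_span / 2
  lat0 <- -lat_span / 2
  if (is.null(beta1_surface)) {
    mid <- lon0 + lon_span / 2
    scl <- lon_span / 8
    beta1_surface <- function(lon, lat) tanh((lon - mid) / scl)
  }
  if (is.null(beta0_surface)) {
    beta0_surface <- function(lon, lat) -1.5 + 2 * (lat - lat0) / lat_span
  }
  structure(list(n_lon = n_lon, n_lat = n_lat, resolution = resolution,
                 lon0 = lon0, lat0 = lat0,
                 beta0_surface = beta0_surface, beta1_surface = beta1_surface,
                 noise_sd = noise_sd, pop_logmean = pop_logmean,
                 pop_logsd = pop_logsd, mask_fraction = mask_fraction,
                 seed = as.integer(seed)),
            class = "gwr_scenario")
}

# 3x3 moving-average smoothing on a matrix (edge cells average fewer cells)
smooth_3x3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0, nr + 2, nc + 2)
  cnt <- matrix(0, nr + 2, nc + 2)
  core <- 2:(nr + 1)
  corec <- 2:(nc + 1)
  acc <- matrix(0, nr, nc); n <- matrix(0, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    pad[,] <- 0; cnt[,] <- 0
    pad[core + di, corec + dj] <- m
    cnt[core + di, corec + dj] <- 1
    acc <- acc + pad[core, corec]
    n <- n + cnt[core, corec]
  }
  acc / n
}

#' Simulate a world with spatially varying regression coefficients
#'
#' Draws the population field, evaluates the true coefficient surfaces at the
#' cell centroids, and generates `y = beta0 + beta1 * x + e`. Burned area is
#' `10^y` km^2, capped at 99.9% of the cell area if it would exceed it (the
#' cap count is reported; it is zero under the default scenario).
#'
#' @param scenario a [gwr_scenario()]
#' @return list with `data` (a `fire_grid` of the combustible cells),
#'   `truth` (data frame of lon, lat, beta0, beta1 for the retained cells),
#'   `n_capped`
#' @export
simulate_gwr_world <- function(scenario) {
  stopifnot(inherits(scenario, "gwr_scenario"))
  s <- scenario
  set.seed(s$seed)
  lon <- s$lon0 + (seq_len(s$n_lon) - 0.5) * s$resolution
  lat <- s$lat0 + (seq_len(s$n_lat) - 0.5) * s$resolution
  g <- expand.grid(lon = lon, lat = lat)
  n <- nrow(g)

  logpop <- matrix(stats::rnorm(n, s$pop_logmean, s$pop_logsd),
                   nrow = s$n_lon, ncol = s$n_lat)
  # smoothing shrinks the marginal sd; rescale to keep it at pop_logsd
  sm <- smooth_3x3(logpop)
  sm <- s$pop_logmean + (sm - mean(sm)) * (s$pop_logsd / stats::sd(as.vector(sm)))
  x <- as.vector(sm)

  b0 <- s$beta0_surface(g$lon, g$lat)
  b1 <- s$beta1_surface(g$lon, g$lat)
  if (any(!is.finite(b0)) || any(!is.finite(b1)))
    stop("simulate_gwr_world: coefficient surfaces must be finite", call. = FALSE)
  y <- b0 + b1 * x + stats::rnorm(n, 0, s$noise_sd)

  area <- cell_area(g$lat, s$resolution)
  ba <- 10^y
  capped <- ba > 0.999 * area
  ba[capped] <- 0.999 * area[capped]

  mask <- rep(TRUE, n)
  if (s$mask_fraction > 0)
    mask[sample.int(n, round(s$mask_fraction * n))] <- FALSE

  cells <- data.frame(lon = g$lon, lat = g$lat,
                      burned_area = ba, pop_density = 10^x,
                      combustible = mask,
                      anthrome = NA_character_, continent = "Africa",
                      cell_area = area, stringsAsFactors = FALSE)
  data <- grid_dataset(cells, zero_policy = "drop", resolution = s$resolution)
  truth <- data.frame(lon = g$lon, lat = g$lat, beta0 = b0, beta1 = b1)
  truth <- truth[order(truth$lat, truth$lon), ]
  key_all <- paste(truth$lon, truth$lat)
  key_kept <- paste(data$cells$lon, data$cells$lat)
  truth <- truth[match(key_kept, key_all), ]
  rownames(truth) <- NULL
  list(data = data, truth = truth, n_capped = sum(capped))
}

#' Simulate a stationary (constant-coefficient) world
#'
#' Null model for the nonstationarity permutation test: a special case of
#' [simulate_gwr_world()] with constant surfaces.
#'
#' @param n_lon,n_lat grid dimensions
#' @param beta0,beta1 constant true coefficients
#' @param noise_sd error standard deviation
#' @param seed integer seed
#' @param ... further arguments to [gwr_scenario()]
#' @return as [simulate_gwr_world()]
#' @export
simulate_stationary_world <- function(n_lon = 20, n_lat = 20, beta0 = 0,
                                      beta1 = 1, noise_sd = 0.3, seed = 1L, ...) {
  stopifnot(is.finite(beta0), is.finite(beta1))
  sc <- gwr_scenario(n_lon = n_lon, n_lat = n_lat,
                     beta0_surface = function(lon, lat) rep(beta0, length(lon)),
                     beta1_surface = function(lon, lat) rep(beta1, length(lon)),
                     noise_sd = noise_sd, seed = seed, ...)
  simulate_gwr_world(sc)
}

#' Scenario for broken-stick quantile structure
#'
#' Defines samples whose conditional quantiles of log10 burned area follow a
#' continuous piecewise-linear function of log10 population density. The
#' default plants one breakpoint at 7 p/km^2 (log10 ~ 0.845) with slopes
#' +0.8 then -0.5 and homoskedastic Gaussian noise, emulating the
#' rise-peak-decline shape of fire response to population. The
#' `"location_scale"` noise model makes the noise sd grow linearly with x so
#' upper-quantile slopes differ from the median's.
#'
#' @param n sample size
#' @param breakpoints strictly increasing breakpoint(s), log10 p/km^2
#' @param slopes per-segment slopes (one more than breakpoints)
#' @param intercept first-segment intercept at x = 0
#' @param noise_sd error scale, log10 units
#' @param noise `"gaussian"` or `"location_scale"`
#' @param x_range range of log10 population density (x is uniform over it)
#' @param seed integer seed
#' @export
broken_stick_scenario <- function(n = 2000, breakpoints = log10(7),
                                  slopes = c(0.8, -0.5), intercept = 0,
                                  noise_sd = 0.2,
                                  noise = c("gaussian", "location_scale"),
                                  x_range = c(-1, 2.5), seed = 1L) {
  noise <- match.arg(noise)
  if (is.unsorted(breakpoints, strictly = TRUE))
    stop("breakpoints must be strictly increasing", call. = FALSE)
  if (length(slopes) != length(breakpoints) + 1L)
    stop("need exactly one more slope than breakpoints", call. = FALSE)
  stopifnot(noise_sd >= 0, length(x_range) == 2, x_range[1] < x_range[2])
  structure(list(n = n, breakpoints = breakpoints, slopes = slopes,
                 intercept = intercept, noise_sd = noise_sd, noise = noise,
                 x_range = x_range, seed = as.integer(seed)),
            class = "broken_stick_scenario")
}

#' Evaluate a continuous piecewise-linear (hinge-basis) polyline
#'
#' `f(x) = intercept + slopes[1]*x + sum_k (slopes[k+1]-slopes[k]) * (x-c_k)+`
#'
#' @param x evaluation points
#' @param breakpoints,slopes,intercept polyline parameters
#' @return f(x)
#' @export
polyline_eval <- function(x, breakpoints, slopes, intercept = 0) {
  y <- intercept + slopes[1] * x
  for (k in seq_along(breakpoints))
    y <- y + (slopes[k + 1] - slopes[k]) * pmax(0, x - breakpoints[k])
  y
}

#' Simulate samples with broken-stick conditional quantiles
#'
#' @param scenario a [broken_stick_scenario()]
#' @return data frame with columns `x` (log10 p/km^2) and `y` (log10 km^2);
#'   the true polyline is the conditional median under `"gaussian"` noise
#' @export
simulate_broken_stick <- function(scenario) {
  stopifnot(inherits(scenario, "broken_stick_scenario"))
  s <- scenario
  set.seed(s$seed)
  x <- stats::runif(s$n, s$x_range[1], s$x_range[2])
  mu <- polyline_eval(x, s$breakpoints, s$slopes, s$intercept)
  sd <- if (s$noise == "gaussian") rep(s$noise_sd, s$n) else
    s$noise_sd * (1 + (x - s$x_range[1]) / diff(s$x_range))
  data.frame(x = x, y = mu + stats::rnorm(s$n, 0, sd))
}

#' Assign anthrome labels in contiguous patches
#'
#' `"bands"` splits the grid into 6 equal latitude bands, one major type per
#' band (south to north in canonical order). `"blocks"` draws `n_blocks`
#' seed cells and assigns each cell the type of its nearest seed (planar
#' Euclidean on lon/lat), cycling seed types through the 6 major types, which
#' yields convex, hence contiguous, patches.
#'
#' @param dataset a `fire_grid`
#' @param layout `"blocks"` or `"bands"`
#' @param n_blocks number of Voronoi seeds under `"blocks"`
#' @param seed integer seed
#' @return the dataset with `anthrome` filled in (both `cells` and `raw`)
#' @export
assign_anthromes <- function(dataset, layout = c("blocks", "bands"),
                             n_blocks = 12, seed = 1L) {
  stopifnot(inherits(dataset, "fire_grid"))
  layout <- match.arg(layout)
  label_for <- function(lon, lat) {
    if (layout == "bands") {
      lo <- min(dataset$raw$lat); hi <- max(dataset$raw$lat)
      band <- pmin(5, floor(6 * (lat - lo) / (hi - lo + 1e-9)))
      anthrome_major_types[band + 1]
    } else {
      set.seed(seed)
      idx <- sample.int(nrow(dataset$raw), n_blocks)
      sx <- dataset$raw$lon[idx]; sy <- dataset$raw$lat[idx]
      d2 <- outer(lon, sx, "-")^2 + outer(lat, sy, "-")^2
      nearest <- max.col(-d2, ties.method = "first")
      anthrome_major_types[((nearest - 1) %% 6) + 1]
    }
  }
  dataset$raw$anthrome <- label_for(dataset$raw$lon, dataset$raw$lat)
  dataset$cells$anthrome <- label_for(dataset$cells$lon, dataset$cells$lat)
  dataset
}
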