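# Gridded cell records: masking, latitude-corrected areas, decimal-log
# transforms, distances, resolution aggregation and CSV I/O.

#' Authalic Earth radius (km) used for all spherical geometry
#' @keywords internal
EARTH_RADIUS_KM <- 6371.0

#' Major anthrome types
#'
#' The six major anthropogenic-biome (anthrome) groups used throughout the
#' package, in their canonical integer coding (1-6).
#'
#' @export
anthrome_major_types <- c("DenseSettlement", "Villages", "Croplands",
                          "Rangelands", "Forest", "Wildlands")

#' Continent labels recognised in input tables
#' @export
continent_labels <- c("Africa", "Asia", "NAmerica", "SAmerica",
                      "Europe", "Australia")

#' Latitude-corrected grid cell area
#'
#' Area of a `resolution` x `resolution` degree cell centred at latitude
#' `lat`, on a sphere of radius 6371 km: `(R*d) * (R*d*cos(lat))` with `d`
#' the resolution in radians. Symmetric in +/-lat and strictly decreasing in
#' |lat|.
#'
#' @param lat latitude of the cell centroid, degrees; must satisfy |lat| < 90
#' @param resolution cell edge, degrees (> 0)
#' @return cell area in km^2 (vectorised over `lat`)
#' @examples
#' cell_area(0, 0.5)    # ~3091 km^2 at the equator
#' cell_area(60, 0.5)   # exactly half of the equatorial value
#' @export
cell_area <- function(lat, resolution) {
  if (any(!is.finite(lat)) || any(abs(lat) >= 90))
    stop("cell_area: |lat| must be < 90 degrees", call. = FALSE)
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0)
    stop("cell_area: resolution must be a single positive number", call. = FALSE)
  d <- resolution * pi / 180
  (EARTH_RADIUS_KM * d)^2 * cos(lat * pi / 180)
}

#' Decimal logarithm with a zero-handling policy
#'
#' Burned area and population density are both log10-transformed before
#' regression; zeros are undefined under the decimal log, so a policy is
#' required. Under `"drop"` zeros are returned as `NA` (flagged for removal
#' by [grid_dataset()]); under `"floor"` zeros map to `log10(eps)`.
#'
#' @param values nonnegative numeric vector
#' @param zero_policy `"drop"` (default) or `"floor"`
#' @param eps positive floor value used when `zero_policy = "floor"`
#' @return numeric vector, same length and order as `values`
#' @export
log10_transform <- function(values, zero_policy = c("drop", "floor"), eps = 0.01) {
  zero_policy <- match.arg(zero_policy)
  if (any(values < 0, na.rm = TRUE))
    stop("log10_transform: negative values are not allowed", call. = FALSE)
  out <- rep(NA_real_, length(values))
  pos <- !is.na(values) & values > 0
  out[pos] <- log10(values[pos])
  zero <- !is.na(values) & values == 0
  if (any(zero)) {
    if (zero_policy == "floor") {
      if (!is.numeric(eps) || eps <= 0)
        stop("log10_transform: eps must be > 0 under the floor policy", call. = FALSE)
      out[zero] <- log10(eps)
    } # drop: leave NA
  }
  out
}

# validate a raw cell table and coerce types; used by grid_dataset and I/O
validate_cells <- function(cells) {
  required <- c("lon", "lat", "burned_area", "pop_density", "combustible",
                "anthrome", "continent", "cell_area")
  missing <- setdiff(required, names(cells))
  if (length(missing))
    stop("cell table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  cells <- as.data.frame(cells)[required]
  if (any(cells$lon < -180 | cells$lon >= 180))
    stop("lon must satisfy -180 <= lon < 180", call. = FALSE)
  if (any(abs(cells$lat) >= 90))
    stop("lat must satisfy -90 < lat < 90", call. = FALSE)
  if (any(cells$burned_area < 0, na.rm = TRUE))
    stop("burned_area must be >= 0", call. = FALSE)
  if (any(cells$pop_density < 0, na.rm = TRUE))
    stop("pop_density must be >= 0", call. = FALSE)
  if (any(cells$cell_area <= 0))
    stop("cell_area must be > 0", call. = FALSE)
  if (any(cells$burned_area > cells$cell_area + 1e-9, na.rm = TRUE))
    stop("burned_area must not exceed cell_area", call. = FALSE)
  bad_anthro <- !is.na(cells$anthrome) & !(cells$anthrome %in% anthrome_major_types)
  if (any(bad_anthro))
    stop("unknown anthrome label(s): ",
         paste(unique(cells$anthrome[bad_anthro]), collapse = ", "), call. = FALSE)
  bad_cont <- !is.na(cells$continent) & !(cells$continent %in% continent_labels)
  if (any(bad_cont))
    stop("unknown continent label(s): ",
         paste(unique(cells$continent[bad_cont]), collapse = ", "), call. = FALSE)
  cells
}

#' Build an analysis-ready grid dataset
#'
#' Applies the combustibility mask, the decimal-log transform of burned area
#' (response `y`) and population density (predictor `x`), and the zero policy.
#' Cells are ordered by (lat, lon) so ordering is stable across operations.
#' The raw pre-mask table is retained so resolution aggregation can be redone
#' from the original records.
#'
#' @param cells data frame with columns `lon, lat, burned_area, pop_density,
#'   combustible, anthrome, continent, cell_area`
#' @param zero_policy see [log10_transform()]
#' @param eps floor constant for `zero_policy = "floor"`
#' @param resolution cell edge in degrees; inferred from coordinate spacing
#'   when `NULL`
#' @return an object of class `fire_grid`: a list with elements `cells`
#'   (retained rows with `x`, `y` appended), `raw` (all input rows),
#'   `resolution`, `transform_meta`, `n_removed_mask`, `n_removed_zero`
#' @export
grid_dataset <- function(cells, zero_policy = c("drop", "floor"), eps = 0.01,
                         resolution = NULL) {
  zero_policy <- match.arg(zero_policy)
  raw <- validate_cells(cells)
  raw <- raw[order(raw$lat, raw$lon), , drop = FALSE]
  rownames(raw) <- NULL

  if (is.null(resolution)) {
    ulon <- sort(unique(raw$lon))
    ulat <- sort(unique(raw$lat))
    steps <- c(diff(ulon), diff(ulat))
    steps <- steps[steps > 1e-9]
    resolution <- if (length(steps)) min(steps) else 0.5
  }

  keep <- raw$combustible
  n_removed_mask <- sum(!keep)
  kept <- raw[keep, , drop = FALSE]

  y <- log10_transform(kept$burned_area, zero_policy, eps)
  x <- log10_transform(kept$pop_density, zero_policy, eps)
  finite <- is.finite(y) & is.finite(x)
  n_removed_zero <- sum(!finite)
  kept <- kept[finite, , drop = FALSE]
  kept$y <- y[finite]
  kept$x <- x[finite]
  rownames(kept) <- NULL

  if (nrow(kept) == 0L)
    stop("grid_dataset: no cells remain after masking and zero handling",
         call. = FALSE)

  structure(list(
    cells = kept,
    raw = raw,
    resolution = resolution,
    transform_meta = list(zero_policy = zero_policy, eps = eps),
    n_removed_mask = n_removed_mask,
    n_removed_zero = n_removed_zero
  ), class = "fire_grid")
}

#' @export
print.fire_grid <- function(x, ...) {
  cat(sprintf("fire_grid: %d cells at %.3g deg (%d masked, %d zero-dropped)\n",
              nrow(x$cells), x$resolution, x$n_removed_mask, x$n_removed_zero))
  cat(sprintf("  y = log10(burned area km^2): [%.3g, %.3g]\n",
              min(x$cells$y), max(x$cells$y)))
  cat(sprintf("  x = log10(pop density p/km^2): [%.3g, %.3g]\n",
              min(x$cells$x), max(x$cells$x)))
  invisible(x)
}

#' Great-circle distance (haversine)
#'
#' Distance in km between points on a sphere of radius 6371 km. Vectorised;
#' arguments recycle as usual.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in degrees
#' @return distance in km
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

#' All-pairs great-circle distance matrix
#'
#' @param lon,lat coordinate vectors of equal length n
#' @return n x n symmetric matrix of km distances
#' @export
dist_matrix_km <- function(lon, lat) {
  n <- length(lon)
  to_rad <- pi / 180
  phi <- lat * to_rad
  lam <- lon * to_rad
  sin_dphi <- sin(outer(phi, phi, "-") / 2)
  sin_dlam <- sin(outer(lam, lam, "-") / 2)
  a <- sin_dphi^2 + (cos(phi) %o% cos(phi)) * sin_dlam^2
  d <- 2 * EARTH_RADIUS_KM * asin(pmin(sqrt(a), 1))
  diag(d) <- 0
  d
}

#' Aggregate a grid dataset to a coarser resolution
#'
#' Children are grouped into `factor` x `factor` parents aligned to the
#' original grid origin. Burned area is summed, population density is a
#' cell-area-weighted mean, anthrome and continent are taken by majority
#' area, a parent is combustible if any child is, and parent cell areas are
#' summed. Transforms and masking are re-applied to the aggregated records
#' with the dataset's own zero policy.
#'
#' @param dataset a `fire_grid`
#' @param factor integer >= 2 (or 1 for the identity)
#' @return a `fire_grid` at resolution `resolution * factor`
#' @export
aggregate_resolution <- function(dataset, factor) {
  stopifnot(inherits(dataset, "fire_grid"))
  if (factor != round(factor) || factor < 1)
    stop("aggregate_resolution: factor must be a positive integer", call. = FALSE)
  factor <- as.integer(factor)
  if (factor == 1L) return(dataset)

  raw <- dataset$raw
  res <- dataset$resolution
  # index children on the fine lattice; centroids sit at half-cell offsets
  ix <- (raw$lon + 180) / res - 0.5
  iy <- (raw$lat + 90) / res - 0.5
  if (max(abs(ix - round(ix))) > 1e-6 || max(abs(iy - round(iy))) > 1e-6)
    stop("aggregate_resolution: cells do not align to a regular grid at ",
         res, " degrees", call. = FALSE)
  ix <- round(ix); iy <- round(iy)
  px <- ix %/% factor
  py <- iy %/% factor
  key <- paste(px, py)

  agg_one <- function(rows) {
    a <- raw$cell_area[rows]
    anth <- raw$anthrome[rows]
    cont <- raw$continent[rows]
    maj <- function(lab) {
      ok <- !is.na(lab)
      if (!any(ok)) return(NA_character_)
      s <- tapply(a[ok], lab[ok], sum)
      names(s)[which.max(s)]
    }
    data.frame(
      lon = -180 + (mean(range(ix[rows])) + 0.5) * res,
      lat = -90 + (mean(range(iy[rows])) + 0.5) * res,
      burned_area = sum(raw$burned_area[rows]),
      pop_density = sum(raw$pop_density[rows] * a) / sum(a),
      combustible = any(raw$combustible[rows]),
      anthrome = maj(anth),
      continent = maj(cont),
      cell_area = sum(a),
      stringsAsFactors = FALSE
    )
  }

  groups <- split(seq_len(nrow(raw)), key)
  parent <- do.call(rbind, lapply(groups, agg_one))
  # recompute parent centroids exactly from the parent lattice
  pxu <- vapply(groups, function(rows) px[rows[1]], numeric(1))
  pyu <- vapply(groups, function(rows) py[rows[1]], numeric(1))
  parent$lon <- -180 + (pxu + 0.5) * res * factor
  parent$lat <- -90 + (pyu + 0.5) * res * factor

  grid_dataset(parent,
               zero_policy = dataset$transform_meta$zero_policy,
               eps = dataset$transform_meta$eps,
               resolution = res * factor)
}

#' Read a grid dataset from a CSV table
#'
#' The table must carry one row per cell with columns `lon, lat, burned_area,
#' pop_density, combustible, anthrome, continent, cell_area` (UTF-8, comma
#' separated, header row). `combustible` is encoded 0/1; `anthrome` either as
#' the major-type name or its 1-6 integer code.
#'
#' @param path file path
#' @param format currently only `"csv"`
#' @param ... passed to [grid_dataset()] (`zero_policy`, `eps`, `resolution`)
#' @return a `fire_grid`
#' @export
read_grid <- function(path, format = c("csv", "geotiff", "netcdf"), ...) {
  format <- match.arg(format)
  if (format != "csv")
    stop("read_grid: format '", format, "' is not supported; use 'csv'",
         call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("lon", "lat", "burned_area", "pop_density", "combustible",
                "anthrome", "continent", "cell_area")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("read_grid: file '", path, "' is missing layer(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  tab$combustible <- as.logical(tab$combustible)
  if (is.numeric(tab$anthrome)) {
    code <- tab$anthrome
    bad <- !is.na(code) & !(code %in% 1:6)
    if (any(bad)) stop("read_grid: anthrome codes must be 1-6", call. = FALSE)
    tab$anthrome <- ifelse(is.na(code), NA_character_, anthrome_major_types[code])
  }
  tab$anthrome[!is.na(tab$anthrome) & tab$anthrome == ""] <- NA_character_
  tab$continent[!is.na(tab$continent) & tab$continent == ""] <- NA_character_
  grid_dataset(tab, ...)
}

#' Write a grid dataset to a CSV table
#'
#' Writes the raw (pre-mask) cell records ordered by (lat, lon), with
#' `combustible` as 0/1 and `anthrome` as its 1-6 integer code, so that
#' `read_grid(write_grid(x, p))` reproduces the records exactly.
#'
#' @param dataset a `fire_grid`
#' @param path output file path
#' @param format currently only `"csv"`
#' @return `path`, invisibly
#' @export
write_grid <- function(dataset, path, format = c("csv", "geotiff", "netcdf")) {
  format <- match.arg(format)
  if (format != "csv")
    stop("write_grid: format '", format, "' is not supported; use 'csv'",
         call. = FALSE)
  stopifnot(inherits(dataset, "fire_grid"))
  tab <- dataset$raw
  tab$combustible <- as.integer(tab$combustible)
  tab$anthrome <- match(tab$anthrome, anthrome_major_types)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
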