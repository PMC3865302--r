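# Shared fixture builders: everything is generated in code at test time.

# raw cell table on a regular half-cell-offset lattice
make_cells <- function(lon, lat, burned_area, pop_density,
                       combustible = TRUE, anthrome = NA_character_,
                       continent = "Africa", resolution = 0.5) {
  data.frame(lon = lon, lat = lat,
             burned_area = burned_area, pop_density = pop_density,
             combustible = combustible, anthrome = anthrome,
             continent = continent,
             cell_area = cell_area(lat, resolution),
             stringsAsFactors = FALSE)
}

# small aligned grid of cell centroids at a given resolution
lattice_coords <- function(n_lon, n_lat, resolution = 0.5,
                           lon0 = 0, lat0 = 0) {
  lon <- lon0 + (seq_len(n_lon) - 0.5) * resolution
  lat <- lat0 + (seq_len(n_lat) - 0.5) * resolution
  expand.grid(lon = lon, lat = lat)
}

# brute-force check-loss line fit: the optimum interpolates two data points,
# so enumerate all pairs (exact LP oracle for small n)
rq_line_bruteforce <- function(x, y, tau) {
  n <- length(x)
  best <- NULL
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (x[i] == x[j]) next
    b1 <- (y[j] - y[i]) / (x[j] - x[i])
    b0 <- y[i] - b1 * x[i]
    l <- check_loss(y - b0 - b1 * x, tau)
    if (is.null(best) || l < best$loss)
      best <- list(intercept = b0, slope = b1, loss = l)
  }
  best
}

# connected components of equal labels on a grid (rook adjacency)
count_label_patches <- function(lon, lat, labels, resolution) {
  ix <- round((lon - min(lon)) / resolution)
  iy <- round((lat - min(lat)) / resolution)
  nx <- max(ix) + 1
  id <- iy * nx + ix
  lookup <- new.env(parent = emptyenv())
  for (m in seq_along(id)) assign(as.character(id[m]), m, envir = lookup)
  seen <- rep(FALSE, length(id))
  patches <- 0L
  for (m in seq_along(id)) {
    if (seen[m]) next
    patches <- patches + 1L
    queue <- m; seen[m] <- TRUE
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        nid <- as.character((iy[cur] + d[2]) * nx + ix[cur] + d[1])
        if (ix[cur] + d[1] < 0 || ix[cur] + d[1] >= nx) next
        nb <- mget(nid, envir = lookup, ifnotfound = list(NULL))[[1]]
        if (!is.null(nb) && !seen[nb] && labels[nb] == labels[cur]) {
          seen[nb] <- TRUE; queue <- c(queue, nb)
        }
      }
    }
  }
  patches
}
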