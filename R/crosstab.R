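# Cross-tabulation of significant slope signs against major anthrome types.

# the 21 anthrome classes and their major types
ANTHROME_21 <- c(
  "Urban" = "DenseSettlement",
  "Dense settlements" = "DenseSettlement",
  "Rice villages" = "Villages",
  "Irrigated villages" = "Villages",
  "Cropped and pastoral villages" = "Villages",
  "Pastoral villages" = "Villages",
  "Rainfed villages" = "Villages",
  "Rainfed mosaic villages" = "Villages",
  "Residential irrigated cropland" = "Croplands",
  "Residential rainfed mosaic cropland" = "Croplands",
  "Populated irrigated cropland" = "Croplands",
  "Populated rainfed cropland" = "Croplands",
  "Remote croplands" = "Croplands",
  "Residential rangelands" = "Rangelands",
  "Populated rangelands" = "Rangelands",
  "Remote rangelands" = "Rangelands",
  "Populated forest" = "Forest",
  "Remote forest" = "Forest",
  "Wild forest" = "Wildlands",
  "Sparse trees" = "Wildlands",
  "Barren" = "Wildlands")

#' Map one of the 21 anthrome classes to its major type
#'
#' Total over the 21 anthropogenic-biome classes (by name, or by 1-21 integer
#' code in the order Urban ... Barren); unknown classes raise an error naming
#' the offender.
#'
#' @param anthrome character names or integer codes
#' @return major type, one of [anthrome_major_types]
#' @export
map_anthrome_to_major <- function(anthrome) {
  if (is.numeric(anthrome)) {
    bad <- !is.na(anthrome) & !(anthrome %in% seq_along(ANTHROME_21))
    if (any(bad))
      stop("map_anthrome_to_major: unknown anthrome code(s): ",
           paste(unique(anthrome[bad]), collapse = ", "), call. = FALSE)
    return(unname(ANTHROME_21[anthrome]))
  }
  out <- ANTHROME_21[anthrome]
  bad <- !is.na(anthrome) & is.na(out)
  if (any(bad))
    stop("map_anthrome_to_major: unknown anthrome class(es): ",
         paste(unique(anthrome[bad]), collapse = ", "), call. = FALSE)
  unname(out)
}

#' Cross-tabulate significant slope signs against anthrome types
#'
#' For each slope sign (positive, negative), the share of total classified
#' land area (or cell count) falling in each of the six major anthrome types.
#' Nonsignificant cells are excluded; significant cells without an anthrome
#' label are reported in a residual `"(missing)"` class.
#'
#' @param map a `fire_sigmap` from [classify_cells()]
#' @param cells the retained cell table of the `fire_grid` the map was
#'   computed on (must align row-for-row with the map)
#' @param basis `"area"` (default; shares of summed cell area) or `"count"`
#' @return object of class `fire_crosstab`: data frame with `sign`,
#'   `anthrome`, `share`; within each sign shares sum to 1
#' @export
crosstab_anthromes <- function(map, cells, basis = c("area", "count")) {
  stopifnot(inherits(map, "fire_sigmap"))
  basis <- match.arg(basis)
  if (nrow(cells) != nrow(map))
    stop("crosstab_anthromes: map and cells are misaligned", call. = FALSE)
  rows <- list()
  for (sg in c("positive", "negative")) {
    sel <- map$slope_class == sg
    if (!any(sel)) next
    lab <- cells$anthrome[sel]
    lab[is.na(lab)] <- "(missing)"
    wt <- if (basis == "area") cells$cell_area[sel] else rep(1, sum(sel))
    tot <- tapply(wt, lab, sum)
    rows[[sg]] <- data.frame(sign = sg, anthrome = names(tot),
                             share = as.numeric(tot) / sum(wt),
                             stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    warning("crosstab_anthromes: no significant cells")
    out <- data.frame(sign = character(), anthrome = character(),
                      share = numeric(), stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
  }
  attr(out, "basis") <- basis
  class(out) <- c("fire_crosstab", "data.frame")
  out
}

#' Write a crosstab to CSV or JSON
#'
#' @param tab a `fire_crosstab`
#' @param path output path; `.json` extension selects JSON (needs jsonlite)
#' @return `path`, invisibly
#' @export
export_crosstab <- function(tab, path) {
  stopifnot(inherits(tab, "fire_crosstab"))
  if (grepl("\\.json$", path)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("jsonlite is required for JSON export", call. = FALSE)
    jsonlite::write_json(tab, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  } else {
    utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  }
  invisible(path)
}
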