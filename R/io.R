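# Readers and writers for the plain-text interchange formats used by the
# pipeline: GeoJSON transects and shorelines, CSV sightings / buoy / NAO
# tables, and ESRI ASCII bathymetry grids.

#' Construct a transect
#'
#' @param transect_id identifier.
#' @param year survey year (integer).
#' @param path matrix of ordered vertex coordinates, two columns. Geographic
#'   (lon/lat degrees) on disk; projected meters once inside the pipeline.
#' @param survey_dates character vector of survey dates (`YYYY-MM-DD`).
#' @return An object of class `transect`.
#' @export
transect <- function(transect_id, year, path, survey_dates) {
  path <- as.matrix(path)
  if (nrow(path) < 2)
    stop("transect '", transect_id, "': path needs at least 2 vertices")
  if (length(survey_dates) < 1)
    stop("transect '", transect_id, "': survey_dates must be non-empty")
  structure(list(transect_id = as.character(transect_id),
                 year = as.integer(year),
                 path = unname(path),
                 survey_dates = as.character(survey_dates)),
            class = "transect")
}

#' Write transects to GeoJSON
#'
#' One `LineString` feature per transect with `transect_id`, `year` and
#' `dates` properties. Coordinates are written as given (lon/lat expected).
#'
#' @param transects list of [transect()] objects with geographic paths.
#' @param file output path.
#' @export
write_transects <- function(transects, file) {
  feats <- lapply(transects, function(tr) {
    list(type = "Feature",
         properties = list(transect_id = tr$transect_id,
                           year = tr$year,
                           dates = as.list(tr$survey_dates)),
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(tr$path)),
                                              function(i) as.list(unname(tr$path[i, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       file, auto_unbox = TRUE, digits = 10)
  invisible(file)
}

#' Read transects from GeoJSON
#'
#' @param file GeoJSON `FeatureCollection` of `LineString`s as written by
#'   [write_transects()].
#' @return List of [transect()] objects (paths in lon/lat degrees).
#' @export
read_transects <- function(file) {
  gj <- jsonlite::read_json(file)
  lapply(gj$features, function(f) {
    coords <- do.call(rbind, lapply(f$geometry$coordinates,
                                    function(p) c(p[[1]], p[[2]])))
    transect(f$properties$transect_id, f$properties$year, coords,
             unlist(f$properties$dates))
  })
}

#' Write a shoreline (list of polylines) to GeoJSON
#'
#' @param polylines list of two-column lon/lat matrices.
#' @param file output path.
#' @export
write_shoreline <- function(polylines, file) {
  feats <- lapply(polylines, function(pl) {
    list(type = "Feature", properties = list(),
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(pl)),
                                              function(i) as.list(unname(pl[i, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       file, auto_unbox = TRUE, digits = 10)
  invisible(file)
}

#' Read a shoreline from GeoJSON
#'
#' Accepts `LineString` and `MultiLineString` features.
#'
#' @param file GeoJSON path.
#' @return List of two-column lon/lat matrices.
#' @export
read_shoreline <- function(file) {
  gj <- jsonlite::read_json(file)
  out <- list()
  to_mat <- function(cc) do.call(rbind, lapply(cc, function(p) c(p[[1]], p[[2]])))
  for (f in gj$features) {
    g <- f$geometry
    if (g$type == "LineString") {
      out[[length(out) + 1L]] <- to_mat(g$coordinates)
    } else if (g$type == "MultiLineString") {
      for (part in g$coordinates) out[[length(out) + 1L]] <- to_mat(part)
    } else {
      stop("unsupported shoreline geometry type: ", g$type)
    }
  }
  if (length(out) == 0) stop("no shoreline features found in ", file)
  out
}

#' Read / write sightings CSV
#'
#' Columns: `transect_id, year, lat, lon, species, count`.
#'
#' @param file CSV path.
#' @return data.frame of sightings.
#' @export
read_sightings <- function(file) {
  s <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("transect_id", "year", "lat", "lon", "species", "count")
  miss <- setdiff(need, names(s))
  if (length(miss)) stop("sightings file missing columns: ", paste(miss, collapse = ", "))
  if (any(s$count < 0)) stop("sightings with negative count")
  s
}

#' @rdname read_sightings
#' @param sightings data.frame with the sightings columns.
#' @export
write_sightings <- function(sightings, file) {
  utils::write.csv(sightings, file, row.names = FALSE)
  invisible(file)
}

#' ESRI ASCII raster grid
#'
#' A minimal in-memory raster: a value matrix stored north-to-south plus the
#' lower-left corner, square cell size, and a missing-value sentinel. Mirrors
#' the ETOPO-style elevation convention (sea floor negative).
#'
#' @param values numeric matrix, row 1 = northernmost row.
#' @param xll,yll coordinates of the lower-left corner of the grid.
#' @param cellsize cell edge length (same units as `xll`/`yll`).
#' @param nodata missing-value sentinel used on disk.
#' @return Object of class `ascii_grid`.
#' @export
ascii_grid <- function(values, xll, yll, cellsize, nodata = -9999) {
  values <- as.matrix(values)
  stopifnot(cellsize > 0, is.numeric(values))
  structure(list(values = values, xll = xll, yll = yll,
                 cellsize = cellsize, nodata = nodata,
                 nrow = nrow(values), ncol = ncol(values)),
            class = "ascii_grid")
}

# cell-center coordinate vectors (x west->east, y listed north->south to
# match the row order of `values`)
grid_x_centers <- function(g) g$xll + (seq_len(g$ncol) - 0.5) * g$cellsize
grid_y_centers <- function(g) g$yll + (g$nrow - seq_len(g$nrow) + 0.5) * g$cellsize

#' Read / write an ESRI ASCII grid
#'
#' @param file path to an `.asc` file.
#' @return An [ascii_grid()] object; sentinel values become `NA`.
#' @export
read_ascii_grid <- function(file) {
  hdr <- readLines(file, n = 6L)
  kv <- lapply(strsplit(trimws(hdr), "\\s+"), function(p) p)
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(vapply(kv, `[`, "", 2L))
  names(vals) <- keys
  ncol <- as.integer(vals[["ncols"]]); nrow <- as.integer(vals[["nrows"]])
  xll <- if ("xllcorner" %in% keys) vals[["xllcorner"]] else vals[["xllcenter"]] - vals[["cellsize"]] / 2
  yll <- if ("yllcorner" %in% keys) vals[["yllcorner"]] else vals[["yllcenter"]] - vals[["cellsize"]] / 2
  nodata <- if ("nodata_value" %in% keys) vals[["nodata_value"]] else -9999
  dat <- scan(file, skip = 6L, quiet = TRUE)
  if (length(dat) != nrow * ncol)
    stop("ASCII grid ", file, ": expected ", nrow * ncol, " values, got ", length(dat))
  m <- matrix(dat, nrow = nrow, ncol = ncol, byrow = TRUE)
  m[m == nodata] <- NA_real_
  ascii_grid(m, xll, yll, vals[["cellsize"]], nodata)
}

#' @rdname read_ascii_grid
#' @param g an [ascii_grid()].
#' @export
write_ascii_grid <- function(g, file) {
  stopifnot(inherits(g, "ascii_grid"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", g$ncol), paste("nrows", g$nrow),
               paste("xllcorner", format(g$xll, digits = 12)),
               paste("yllcorner", format(g$yll, digits = 12)),
               paste("cellsize", format(g$cellsize, digits = 12)),
               paste("NODATA_value", g$nodata)), con)
  v <- g$values
  v[is.na(v)] <- g$nodata
  for (i in seq_len(g$nrow))
    writeLines(paste(format(v[i, ], trim = TRUE, digits = 8), collapse = " "), con)
  invisible(file)
}

#' Read a buoy observation table
#'
#' Daily buoy records with columns
#' `buoy_id, lat, lon, date, wind_speed_ms, wave_period_s`; a buoy reporting
#' only one of the two variables carries `NA` in the other column.
#'
#' @param file CSV path.
#' @return data.frame of buoy observations.
#' @export
read_buoys <- function(file) {
  b <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("buoy_id", "lat", "lon", "date", "wind_speed_ms", "wave_period_s")
  miss <- setdiff(need, names(b))
  if (length(miss)) stop("buoy file missing columns: ", paste(miss, collapse = ", "))
  if (any(b$wind_speed_ms < 0, na.rm = TRUE)) stop("negative wind speed in buoy file")
  if (any(b$wave_period_s <= 0, na.rm = TRUE)) stop("non-positive wave period in buoy file")
  b
}

#' @rdname read_buoys
#' @param buoys data.frame of buoy observations.
#' @export
write_buoys <- function(buoys, file) {
  utils::write.csv(buoys, file, row.names = FALSE)
  invisible(file)
}

#' Read a monthly NAO index table
#'
#' @param file CSV with columns `year, month, value`.
#' @return data.frame of monthly index values.
#' @export
read_nao <- function(file) {
  n <- utils::read.csv(file, stringsAsFactors = FALSE)
  miss <- setdiff(c("year", "month", "value"), names(n))
  if (length(miss)) stop("NAO file missing columns: ", paste(miss, collapse = ", "))
  n
}

#' @rdname read_nao
#' @param nao data.frame with columns `year, month, value`.
#' @export
write_nao <- function(nao, file) {
  utils::write.csv(nao, file, row.names = FALSE)
  invisible(file)
}
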