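# Covariate construction: ocean floor slope from bathymetry, distance to
# shore, inverse-distance-weighted buoy surfaces, survey-window averaging,
# standardization, collinearity screening, and design-matrix assembly.

#' Ocean floor slope from a bathymetry raster
#'
#' Differences neighboring cells: central differences in x and y over the
#' four rook neighbors (one-sided at edges), gradient magnitude
#' `g = sqrt(gx^2 + gy^2)`, slope `atan(g)` in degrees. Bathymetry is in
#' meters (elevation convention, sea floor negative); cell sizes are in
#' meters so the gradient is dimensionless.
#'
#' @param bathy an [ascii_grid()] of elevations (m).
#' @param cellsize_x_m,cellsize_y_m physical cell sizes (m). For a raster in
#'   geographic degrees use the metric sizes at the study latitude.
#' @return An [ascii_grid()] of slopes in degrees, values in `[0, 90)`.
#' @export
compute_slope <- function(bathy, cellsize_x_m, cellsize_y_m = cellsize_x_m) {
  stopifnot(inherits(bathy, "ascii_grid"), cellsize_x_m > 0, cellsize_y_m > 0)
  z <- bathy$values
  if (nrow(z) < 2 || ncol(z) < 2)
    stop("slope needs a raster with at least 2 rows and 2 columns")
  nr <- nrow(z); nc <- ncol(z)
  # x: column direction; central difference over 2 cells, one-sided at edges
  gx <- z
  gx[, 2:(nc - 1)] <- (z[, 3:nc] - z[, 1:(nc - 2)]) / (2 * cellsize_x_m)
  gx[, 1] <- (z[, 2] - z[, 1]) / cellsize_x_m
  gx[, nc] <- (z[, nc] - z[, nc - 1]) / cellsize_x_m
  # y: rows run north to south, so row i+1 lies south of row i
  gy <- z
  if (nr > 2) gy[2:(nr - 1), ] <- (z[1:(nr - 2), ] - z[3:nr, ]) / (2 * cellsize_y_m)
  gy[1, ] <- (z[1, ] - z[2, ]) / cellsize_y_m
  gy[nr, ] <- (z[nr - 1, ] - z[nr, ]) / cellsize_y_m
  slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  ascii_grid(slope, bathy$xll, bathy$yll, bathy$cellsize, bathy$nodata)
}

#' Sample raster values at point locations
#'
#' Bilinear interpolation between the four surrounding cell centers; points
#' in the outer half-cell margin are clamped to the edge centers.
#'
#' @param g an [ascii_grid()].
#' @param x,y point coordinates in the raster's coordinate system.
#' @return Numeric vector of interpolated values.
#' @export
raster_extract <- function(g, x, y) {
  stopifnot(inherits(g, "ascii_grid"))
  xs <- grid_x_centers(g)
  ys_desc <- grid_y_centers(g)        # north -> south
  ys <- rev(ys_desc)                  # ascending for interval lookup
  cx <- pmin(pmax(x, xs[1]), xs[g$ncol])
  cy <- pmin(pmax(y, ys[1]), ys[g$nrow])
  j0 <- pmin(pmax(findInterval(cx, xs), 1L), g$ncol - 1L)
  i0a <- pmin(pmax(findInterval(cy, ys), 1L), g$nrow - 1L)  # ascending index
  tx <- (cx - xs[j0]) / g$cellsize
  ty <- (cy - ys[i0a]) / g$cellsize
  # ascending index k corresponds to matrix row nrow - k + 1
  r0 <- g$nrow - i0a + 1L   # southern row
  r1 <- r0 - 1L             # northern row
  v00 <- g$values[cbind(r0, j0)]
  v10 <- g$values[cbind(r0, j0 + 1L)]
  v01 <- g$values[cbind(r1, j0)]
  v11 <- g$values[cbind(r1, j0 + 1L)]
  (1 - ty) * ((1 - tx) * v00 + tx * v10) + ty * ((1 - tx) * v01 + tx * v11)
}

#' Euclidean distance to shore
#'
#' Minimum planar distance from each point to any shoreline segment,
#' returned in kilometers.
#'
#' @param points n x 2 matrix of projected point coordinates (m).
#' @param shoreline list of projected shoreline polylines (two-column
#'   matrices, m).
#' @return Numeric vector of distances (km).
#' @export
distance_to_shore <- function(points, shoreline) {
  if (length(shoreline) == 0) stop("empty shoreline")
  min_dist_to_polylines(points, shoreline) / 1000
}

#' Inverse-distance-weighted interpolation
#'
#' `value(t) = sum_b w_b z_b / sum_b w_b` with `w_b = d(t, b)^(-power)`;
#' a target coincident with an observation site returns that observation
#' exactly. Distances are computed in km on the projected plane.
#'
#' @param obs_xy n_b x 2 matrix of observation locations (projected m).
#' @param values numeric vector of observed values (`NA` allowed; dropped).
#' @param target_xy n_t x 2 matrix of target locations (projected m).
#' @param power positive IDW exponent (default 2).
#' @return Numeric vector of interpolated values at the targets.
#' @export
idw_surface <- function(obs_xy, values, target_xy, power = 2) {
  stopifnot(power > 0)
  obs_xy <- rbind(obs_xy); target_xy <- rbind(target_xy)
  keep <- !is.na(values)
  if (!any(keep)) stop("IDW: all observations missing")
  obs_xy <- obs_xy[keep, , drop = FALSE]
  values <- values[keep]
  out <- numeric(nrow(target_xy))
  for (t in seq_len(nrow(target_xy))) {
    d <- sqrt((obs_xy[, 1] - target_xy[t, 1])^2 +
              (obs_xy[, 2] - target_xy[t, 2])^2) / 1000
    hit <- d < 1e-9
    if (any(hit)) {
      out[t] <- values[which(hit)[1]]
    } else {
      w <- d^(-power)
      out[t] <- sum(w * values) / sum(w)
    }
  }
  out
}

#' Average interpolated surfaces over the survey window
#'
#' @param daily_surfaces named list (one entry per date) of per-cell value
#'   vectors of equal length.
#' @param survey_dates character vector of dates to average over; every date
#'   must be present in `daily_surfaces`.
#' @return Per-cell arithmetic mean across the listed dates.
#' @export
average_survey_window <- function(daily_surfaces, survey_dates) {
  miss <- setdiff(survey_dates, names(daily_surfaces))
  if (length(miss))
    stop("no interpolated surface for survey date(s): ", paste(miss, collapse = ", "))
  m <- do.call(cbind, daily_surfaces[survey_dates])
  rowMeans(m)
}

#' Standardize covariate columns
#'
#' Centers and scales each named column to mean 0 and standard deviation 1
#' (sample sd, denominator n - 1, by default), appending `z_<col>` columns.
#' The constants (and observed ranges, used to flag extrapolation in
#' prediction) are stored so that new data can be placed on the fitted scale.
#'
#' @param table data.frame of raw covariates.
#' @param cols character vector of columns to standardize.
#' @param constants optional constants from a previous call (data.frame with
#'   `col, mean, sd`); when supplied they are reused instead of recomputed.
#' @param population_sd use the population (denominator n) sd instead.
#' @return `table` with `z_` columns added; attribute `"constants"` holds a
#'   data.frame `col, mean, sd, min, max`.
#' @export
standardize_covariates <- function(table, cols, constants = NULL,
                                   population_sd = FALSE) {
  if (any(!cols %in% names(table)))
    stop("missing covariate columns: ", paste(setdiff(cols, names(table)), collapse = ", "))
  if (anyNA(table[cols])) stop("missing values among modeled covariate rows")
  if (is.null(constants)) {
    n <- nrow(table)
    mu <- vapply(table[cols], mean, 0)
    sd <- vapply(table[cols], stats::sd, 0)
    if (population_sd) sd <- sd * sqrt((n - 1) / n)
    bad <- cols[sd == 0 | !is.finite(sd)]
    if (length(bad)) stop("zero-variance covariate column(s): ", paste(bad, collapse = ", "))
    constants <- data.frame(col = cols, mean = unname(mu), sd = unname(sd),
                            min = vapply(table[cols], min, 0),
                            max = vapply(table[cols], max, 0),
                            row.names = NULL, stringsAsFactors = FALSE)
  } else {
    if (any(!cols %in% constants$col))
      stop("standardization constants missing for: ",
           paste(setdiff(cols, constants$col), collapse = ", "))
  }
  for (cl in cols) {
    k <- match(cl, constants$col)
    table[[paste0("z_", cl)]] <- (table[[cl]] - constants$mean[k]) / constants$sd[k]
  }
  attr(table, "constants") <- constants
  table
}

#' Invert standardization for one column
#'
#' @param z standardized values.
#' @param col column name.
#' @param constants constants data.frame from [standardize_covariates()].
#' @return Values on the raw scale.
#' @export
unstandardize <- function(z, col, constants) {
  k <- match(col, constants$col)
  if (is.na(k)) stop("no standardization constants for column '", col, "'")
  z * constants$sd[k] + constants$mean[k]
}

#' Absolute pairwise collinearity
#'
#' Absolute Pearson correlations between covariate columns; emits a warning
#' (not an error) if any off-diagonal value reaches the 0.6 screening
#' threshold used to admit predictors into the model.
#'
#' @param table data.frame of covariates.
#' @param cols columns to include.
#' @param threshold warning threshold (default 0.6).
#' @return Symmetric matrix of `|r|` values.
#' @export
pairwise_collinearity <- function(table, cols, threshold = 0.6) {
  stopifnot(length(cols) >= 2, nrow(table) >= 3)
  sds <- vapply(table[cols], stats::sd, 0)
  if (any(sds == 0))
    stop("constant column(s): ", paste(cols[sds == 0], collapse = ", "))
  r <- abs(stats::cor(table[cols]))
  off <- r[upper.tri(r)]
  if (any(off >= threshold))
    warning("pairwise collinearity >= ", threshold, " between some covariates")
  r
}

# the fixed design-matrix column order (intercept + 13 predictor terms)
design_columns <- function() {
  c("intercept", "nao", "bathy", "bathy2", "slope", "dist", "dist2",
    "wind", "wind2", "wave", "wave2", "latitude", "nao_x_bathy", "nao_x_dist")
}

#' Assemble the model design matrix
#'
#' Builds the 14-column design matrix of the abundance model: an intercept,
#' seven standardized linear covariates (NAO, bathymetry, slope, distance to
#' shore, wind speed, wave period, latitude), four quadratics (bathymetry,
#' distance, wind, wave) and the NAO x bathymetry and NAO x distance
#' interactions. Quadratic and interaction columns are plain products of the
#' standardized linear columns (they are not re-standardized).
#'
#' @param table covariate table from [standardize_covariates()] holding
#'   `z_nao, z_bathy, z_slope, z_dist, z_wind, z_wave, z_lat`.
#' @param cells cell table aligned row-wise with `table`; its `count` column
#'   becomes the response `y`. Pass `NULL` for prediction-only matrices.
#' @return An object of class `scoter_design`: list with `y`, `X` (n x 14),
#'   `terms` ([model_terms()]), `constants`, and `meta` (`cell_id`, `year`).
#' @export
build_design_matrix <- function(table, cells = NULL) {
  zc <- c("z_nao", "z_bathy", "z_slope", "z_dist", "z_wind", "z_wave", "z_lat")
  miss <- setdiff(zc, names(table))
  if (length(miss))
    stop("standardized columns missing (run standardize_covariates): ",
         paste(miss, collapse = ", "))
  y <- NULL
  if (!is.null(cells)) {
    if (nrow(cells) != nrow(table))
      stop("row-count mismatch: ", nrow(table), " covariate rows vs ",
           nrow(cells), " cells")
    y <- as.integer(cells$count)
  }
  X <- cbind(intercept = 1,
             nao = table$z_nao,
             bathy = table$z_bathy,
             bathy2 = table$z_bathy^2,
             slope = table$z_slope,
             dist = table$z_dist,
             dist2 = table$z_dist^2,
             wind = table$z_wind,
             wind2 = table$z_wind^2,
             wave = table$z_wave,
             wave2 = table$z_wave^2,
             latitude = table$z_lat,
             nao_x_bathy = table$z_nao * table$z_bathy,
             nao_x_dist = table$z_nao * table$z_dist)
  meta <- if (!is.null(table$cell_id))
    data.frame(cell_id = table$cell_id, year = table$year,
               stringsAsFactors = FALSE) else NULL
  structure(list(y = y, X = X, terms = model_terms(),
                 constants = attr(table, "constants"), meta = meta),
            class = "scoter_design")
}
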