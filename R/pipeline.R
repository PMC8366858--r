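# End-to-end orchestration: read the survey inputs, grid the transects,
# build covariates, fit the model, check it, and predict.

# the projection origin used for a set of geographic transects: the
# southwest corner of their bounding box (shared by the generator and the
# pipeline so both produce identical planar geometry)
pipeline_origin <- function(transects) {
  c(min(vapply(transects, function(t) min(t$path[, 1]), 0)),
    min(vapply(transects, function(t) min(t$path[, 2]), 0)))
}

#' Project transect paths into the working plane
#'
#' @param transects list of [transect()] objects with lon/lat paths.
#' @param origin projection origin `c(lon0, lat0)`.
#' @return The same list with paths in projected meters.
#' @export
project_transects <- function(transects, origin) {
  lapply(transects, function(tr) {
    tr$path <- unname(project_lonlat(tr$path[, 1], tr$path[, 2], origin))
    tr
  })
}

#' Assemble the raw covariate table for a cell table
#'
#' One row per cell-year with the seven model covariates on their raw
#' scales: bathymetry (m, bilinear at the cell center), ocean floor slope
#' (degrees, from the bathymetry raster), distance to shore (km, Euclidean
#' from the cell center), latitude (degrees), survey-window-averaged
#' inverse-distance-weighted wind speed (m/s) and wave period (s), and the
#' February NAO index of the survey year.
#'
#' @param cells cell table from [segment_transects()] (projected meters).
#' @param bathy bathymetry [ascii_grid()] in geographic degrees.
#' @param shoreline list of lon/lat shoreline polylines.
#' @param buoys daily buoy data.frame (see [read_buoys()]).
#' @param nao_monthly data.frame `year, month, value`.
#' @param transects projected transects (supply the survey dates).
#' @param origin projection origin used for `cells`.
#' @param idw_power IDW exponent (default 2).
#' @param nao_month calendar month of the NAO value used per year
#'   (default 2, the survey month).
#' @return data.frame `cell_id, year, nao, bathy, slope, dist, lat, wind,
#'   wave`.
#' @export
covariate_table <- function(cells, bathy, shoreline, buoys, nao_monthly,
                            transects, origin, idw_power = 2,
                            nao_month = 2) {
  ctr_ll <- unproject_xy(cells$center_x, cells$center_y, origin)
  lat_mid <- mean(range(ctr_ll[, "lat"]))
  csx_m <- bathy$cellsize * .M_PER_DEG * cos(lat_mid * pi / 180)
  csy_m <- bathy$cellsize * .M_PER_DEG

  bath_v <- raster_extract(bathy, ctr_ll[, "lon"], ctr_ll[, "lat"])
  slope_g <- compute_slope(bathy, csx_m, csy_m)
  slope_v <- raster_extract(slope_g, ctr_ll[, "lon"], ctr_ll[, "lat"])

  shore_xy <- lapply(shoreline, function(pl)
    unname(project_lonlat(pl[, 1], pl[, 2], origin)))
  dist_v <- distance_to_shore(cbind(cells$center_x, cells$center_y), shore_xy)

  buoy_xy <- project_lonlat(buoys$lon, buoys$lat, origin)
  dates_by_year <- split(
    unlist(lapply(transects, function(t) t$survey_dates)),
    unlist(lapply(transects, function(t) rep(t$year, length(t$survey_dates)))))
  dates_by_year <- lapply(dates_by_year, function(d) sort(unique(d)))

  wind_v <- numeric(nrow(cells))
  wave_v <- numeric(nrow(cells))
  for (yr in unique(cells$year)) {
    rows <- which(cells$year == yr)
    targets <- cbind(cells$center_x[rows], cells$center_y[rows])
    dts <- dates_by_year[[as.character(yr)]]
    if (is.null(dts)) stop("no survey dates found for year ", yr)
    surf <- function(var) {
      out <- list()
      for (d in dts) {
        sel <- buoys$date == d & !is.na(buoys[[var]])
        if (!any(sel))
          stop("no ", var, " buoy observations on ", d)
        out[[d]] <- idw_surface(buoy_xy[sel, , drop = FALSE],
                                buoys[[var]][sel], targets,
                                power = idw_power)
      }
      out
    }
    wind_v[rows] <- average_survey_window(surf("wind_speed_ms"), dts)
    wave_v[rows] <- average_survey_window(surf("wave_period_s"), dts)
  }

  nao_v <- vapply(cells$year, function(yr) {
    k <- which(nao_monthly$year == yr & nao_monthly$month == nao_month)
    if (length(k) != 1)
      stop("NAO value for year ", yr, ", month ", nao_month, " not found")
    nao_monthly$value[k]
  }, 0)

  data.frame(cell_id = cells$cell_id, year = cells$year,
             nao = nao_v, bathy = bath_v, slope = slope_v, dist = dist_v,
             lat = ctr_ll[, "lat"], wind = wind_v, wave = wave_v,
             stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline on a survey data directory
#'
#' Reads the survey files (`transects.geojson`, `sightings.csv`,
#' `bathymetry.asc`, `shoreline.geojson`, `buoys.csv`, `nao.csv`), grids
#' the transects, aggregates counts, builds and standardizes covariates,
#' fits the spike-and-slab count regression, runs the Freeman-Tukey
#' posterior-predictive check, and (optionally) produces the abundance
#' surface and NAO x bathymetry response curves.
#'
#' @param dir data directory.
#' @param family count family (default `"nb"`).
#' @param priors a [prior_spec()].
#' @param config an [mcmc_config()].
#' @param cell_length_m,half_width_m,partial gridding parameters.
#' @param species target species code.
#' @param idw_power,nao_month covariate parameters.
#' @param ppc_seed seed of the posterior-predictive simulations (defaults
#'   to `config$seed + 500`, independent of the sampler's streams).
#' @param predict compute the abundance surface and interaction curves.
#' @param curve_nao NAO levels for the response curves.
#' @return List of class `scoter_pipeline`: `cells`, `count_summary`,
#'   `covariates`, `collinearity`, `design`, `fit`, `ppc`, `surface`,
#'   `curves`, `origin`.
#' @export
run_pipeline <- function(dir, family = "nb", priors = prior_spec(),
                         config = mcmc_config(), cell_length_m = 1000,
                         half_width_m = 275, partial = "keep",
                         species = "BLSC", idw_power = 2, nao_month = 2,
                         ppc_seed = NULL, predict = TRUE,
                         curve_nao = c(-3.9, -1.4, 2.8)) {
  transects <- read_transects(file.path(dir, "transects.geojson"))
  sightings <- read_sightings(file.path(dir, "sightings.csv"))
  bathy <- read_ascii_grid(file.path(dir, "bathymetry.asc"))
  shoreline <- read_shoreline(file.path(dir, "shoreline.geojson"))
  buoys <- read_buoys(file.path(dir, "buoys.csv"))
  nao_monthly <- read_nao(file.path(dir, "nao.csv"))

  origin <- pipeline_origin(transects)
  tr_xy <- project_transects(transects, origin)
  cells <- segment_transects(tr_xy, cell_length_m, half_width_m,
                             partial = partial)
  sxy <- project_lonlat(sightings$lon, sightings$lat, origin)
  sightings$x <- sxy[, 1]
  sightings$y <- sxy[, 2]
  cells <- assign_sightings(sightings, cells, tr_xy, species = species)

  covtab <- covariate_table(cells, bathy, shoreline, buoys, nao_monthly,
                            tr_xy, origin, idw_power = idw_power,
                            nao_month = nao_month)
  covcols <- c("nao", "bathy", "slope", "dist", "wind", "wave", "lat")
  covtab <- standardize_covariates(covtab, covcols)
  collin <- pairwise_collinearity(covtab, covcols)
  design <- build_design_matrix(covtab, cells)

  fit <- fit_nbssvs(design, family = family, priors = priors, config = config)
  ppc <- ppc_pvalue(fit, design, seed = ppc_seed %||% (config$seed + 500L))

  surface <- NULL
  curves <- NULL
  if (predict) {
    surface <- predict_abundance(fit, design)
    cst <- design$constants
    brange <- unlist(cst[cst$col == "bathy", c("min", "max")])
    curves <- interaction_curve(fit,
                                bathy_m = seq(brange[1], brange[2],
                                              length.out = 36),
                                nao_values = curve_nao)
  }

  structure(list(cells = cells, count_summary = summarize_counts(cells),
                 covariates = covtab, collinearity = collin,
                 design = design, fit = fit, ppc = ppc,
                 surface = surface, curves = curves, origin = origin),
            class = "scoter_pipeline")
}

#' @export
print.scoter_pipeline <- function(x, ...) {
  cat("scoterhab pipeline result\n\n")
  print(x$count_summary)
  cat("\n")
  print(x$fit)
  cat("\n")
  print(x$ppc)
  invisible(x)
}
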