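# The synthetic-data generator: seascape structure, buoy series, count
# simulation, presets and serialization.

test_that("seascapes are deterministic in the seed", {
  sc <- preset_scenario("null", seed = 4)
  s1 <- generate_seascape(sc)
  s2 <- generate_seascape(sc)
  expect_identical(s1$bathy$values, s2$bathy$values)
  expect_identical(s1$transects[[3]]$path, s2$transects[[3]]$path)
  s3 <- generate_seascape(preset_scenario("null", seed = 5))
  expect_false(identical(s1$bathy$values, s3$bathy$values))
})

test_that("noise-free linear bathymetry is planar with constant slope", {
  sc <- preset_scenario("null", seed = 1, noise_sd_m = 0,
                        depth_profile = "linear", depth_amp = 0,
                        coast_amp_deg = 0)
  sea <- generate_seascape(sc)
  lat_mid <- mean(sc$lat_range)
  cs_x <- sea$bathy$cellsize * 111194.93 * cos(lat_mid * pi / 180)
  cs_y <- sea$bathy$cellsize * 111194.93
  sl <- compute_slope(sea$bathy, cs_x, cs_y)$values
  # interior offshore block: constant gradient = depth_base m/km
  block <- sl[20:60, 40:60]
  expect_lt(diff(range(block)), 1e-6)
  expect_equal(block[1, 1], atan(sc$depth_base / 1000) * 180 / pi,
               tolerance = 1e-3)
})

test_that("depth is ~0 at the coast and deepens monotonically offshore", {
  sc <- preset_scenario("null", seed = 2, noise_sd_m = 0)
  sea <- generate_seascape(sc)
  z <- sea$bathy$values
  row <- 40
  offshore <- z[row, ]
  j0 <- max(which(offshore == 0))           # last land/coast column
  expect_lt(abs(offshore[j0 + 1]), 5)       # first wet cell-center shallow
  expect_true(all(diff(offshore[(j0 + 1):ncol(z)]) < 0))
  expect_true(all(z <= 0))
})

test_that("transect design follows the spacing and length rules", {
  sc <- preset_scenario("null", seed = 3)
  sea <- generate_seascape(sc)
  yrs <- vapply(sea$transects, function(t) t$year, 0L)
  lat_of <- vapply(sea$transects, function(t) t$path[1, 2], 0)
  # 5 nm spacing in ordinary years, 2.5 nm in the intensive year
  expect_equal(diff(sort(lat_of[yrs == 2009]))[1], 5 / 60, tolerance = 1e-9)
  expect_equal(diff(sort(lat_of[yrs == 2012]))[1], 2.5 / 60, tolerance = 1e-9)
  # intensive year covers the southern half only
  expect_lt(max(lat_of[yrs == 2012]), mean(sc$lat_range) + 1e-9)
  # lengths: >= 14.8 km ordinary years; fixed ~18.5 nm intensive
  kx_km <- 111.19493 * cos(mean(sc$lat_range) * pi / 180)
  len_km <- vapply(sea$transects,
                   function(t) diff(range(t$path[, 1])) * kx_km, 0)
  expect_true(all(len_km[yrs != 2012] >= 14.8 - 1e-6))
  expect_equal(unique(round(len_km[yrs == 2012], 6)), sc$fixed_length_km,
               tolerance = 1e-6)
})

test_that("buoy networks have 20 wind and 9 wave buoys with valid series", {
  sc <- preset_scenario("null", seed = 6)
  sea <- generate_seascape(sc)
  b <- generate_buoy_series(sc, sea$transects)
  expect_equal(length(unique(b$buoy_id[!is.na(b$wind_speed_ms)])), 20)
  expect_equal(length(unique(b$buoy_id[!is.na(b$wave_period_s)])), 9)
  expect_true(all(b$wind_speed_ms >= 0, na.rm = TRUE))
  expect_true(all(b$wave_period_s > 0, na.rm = TRUE))
  # every survey date of every year is covered
  expect_equal(sort(unique(b$date[!is.na(b$wind_speed_ms)])),
               sort(unique(unlist(lapply(sea$transects,
                                         function(t) t$survey_dates)))))
  expect_identical(b, generate_buoy_series(sc, sea$transects))
})

test_that("a degenerate series reduces to the latitudinal mean field", {
  sc <- preset_scenario("null", seed = 7, wind_day_sd = 0, wind_year_sd = 0,
                        wind_site_sd = 0, wind_ar = 0)
  sea <- generate_seascape(sc)
  b <- generate_buoy_series(sc, sea$transects)
  w <- b[!is.na(b$wind_speed_ms), ]
  expect_equal(w$wind_speed_ms,
               sc$wind_base + sc$wind_lat_slope * (w$lat - mean(sc$lat_range)),
               tolerance = 1e-10)
})

test_that("count simulation matches its closed-form moments", {
  d <- make_design(16742, seed = 20)
  # no effects, near-Poisson: sample mean ~ exp(beta0) = 2.3
  t1 <- make_truth(beta0 = log(2.3), active = c(), r = 9.5)
  y1 <- simulate_counts(d$X, t1, seed = 30)
  expect_equal(mean(y1), 2.3, tolerance = 0.05)
  # tiny r: overwhelming zero mass, matching the exact P(0) = p^r
  t2 <- make_truth(beta0 = 0, active = c(), r = 0.005)
  y2 <- simulate_counts(d$X, t2, seed = 31)
  p0 <- (0.005 / (0.005 + 1))^0.005
  expect_gt(mean(y2 == 0), 0.9)
  expect_equal(mean(y2 == 0), p0, tolerance = 0.01)
  expect_identical(y2, simulate_counts(d$X, t2, seed = 31))
})

test_that("count simulation rejects non-finite means", {
  X <- matrix(1, 2, 14)
  X[2, 2] <- 1e4
  tr <- make_truth(active = c(nao = 1), r = 0.5)
  expect_error(simulate_counts(X, tr, seed = 1), "row")
})

test_that("presets satisfy heredity and serialize losslessly", {
  for (nm in c("null", "survey_like", "dense")) {
    sc <- preset_scenario(nm, seed = 9)
    expect_equal(heredity_adjust(unname(sc$truth$gamma)),
                 unname(sc$truth$gamma))
    expect_true(sc$truth$r > 0 && sc$truth$r < 10)
    f <- tempfile(fileext = ".json")
    write_scenario(sc, f)
    rt <- read_scenario(f)
    expect_equal(unclass(rt)[names(unclass(sc))], unclass(sc),
                 tolerance = 1e-12)
    unlink(f)
  }
  pl <- preset_scenario("survey_like")
  expect_lt(pl$truth$delta[["slope"]], 0)
  expect_gt(pl$truth$delta[["wave"]], 0)
})

test_that("survey_like counts are zero-heavy and right-skewed", {
  sim <- simulate_survey(preset_scenario("survey_like", seed = 13),
                         td <- tempfile())
  unlink(td, recursive = TRUE)
  y <- sim$y
  expect_gt(mean(y == 0), 0.5)
  expect_equal(median(y), 0)
  expect_gt(max(y), 100)
  expect_gt(mean(y), 1)
})
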