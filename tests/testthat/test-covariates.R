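# Covariate engine: slope, distance to shore, IDW, averaging,
# standardization, collinearity and design-matrix assembly.

test_that("slope of a constant field is zero and of a plane is analytic", {
  flat <- ascii_grid(matrix(-20, 10, 12), 0, 0, 100)
  expect_equal(compute_slope(flat, 100)$values, matrix(0, 10, 12))

  # plane dropping 1 m per 100 m of easting
  z <- matrix(rep(-(seq_len(12)) * 1, each = 10), 10, 12)
  plane <- ascii_grid(z, 0, 0, 100)
  sl <- compute_slope(plane, 100)$values
  expect_equal(sl[3:8, 2:11],
               matrix(atan(1 / 100) * 180 / pi, 6, 10), tolerance = 1e-12)
})

test_that("slope values lie in [0, 90) for rough terrain", {
  set.seed(1)
  g <- ascii_grid(matrix(rnorm(400, -30, 20), 20, 20), 0, 0, 50)
  sl <- compute_slope(g, 50)$values
  expect_true(all(sl >= 0 & sl < 90))
  expect_error(compute_slope(ascii_grid(matrix(1, 1, 5), 0, 0, 10), 10),
               "at least 2")
})

test_that("distance to shore is exact on vertices and perpendiculars", {
  shore <- list(cbind(c(0, 0), c(-5000, 5000)))  # x = 0 segment
  expect_equal(distance_to_shore(cbind(0, -5000), shore), 0)
  expect_equal(distance_to_shore(cbind(3000, 0), shore), 3)
  expect_error(distance_to_shore(cbind(0, 0), list()), "empty")
})

test_that("distance to a jagged coast matches a dense-sampling oracle", {
  set.seed(5)
  coast <- cbind(cumsum(runif(12, 200, 900)) - 3000,
                 seq(-4000, 4000, length.out = 12))
  pts <- cbind(runif(100, -4000, 4000), runif(100, -5000, 5000))
  got <- distance_to_shore(pts, list(coast))
  # oracle: minimum distance to points densely sampled along every segment
  dense <- NULL
  for (i in seq_len(nrow(coast) - 1)) {
    t <- seq(0, 1, length.out = 2000)
    dense <- rbind(dense, cbind(coast[i, 1] + t * (coast[i + 1, 1] - coast[i, 1]),
                                coast[i, 2] + t * (coast[i + 1, 2] - coast[i, 2])))
  }
  oracle <- apply(pts, 1, function(p)
    sqrt(min((dense[, 1] - p[1])^2 + (dense[, 2] - p[2])^2)) / 1000)
  expect_equal(got, oracle, tolerance = 1e-3)
})

test_that("IDW is exact at sites, symmetric, and matches the formula", {
  obs <- cbind(c(0, 10000), c(0, 0))
  vals <- c(4, 8)
  expect_equal(idw_surface(obs, vals, cbind(0, 0)), 4)
  expect_equal(idw_surface(obs, vals, cbind(5000, 0)), 6)      # equidistant
  expect_equal(idw_surface(obs, vals, cbind(5000, 3000), power = 7), 6)

  set.seed(3)
  b <- cbind(runif(5, 0, 5e4), runif(5, 0, 5e4))
  z <- rnorm(5, 10, 3)
  t <- cbind(runif(10, 0, 5e4), runif(10, 0, 5e4))
  got <- idw_surface(b, z, t, power = 2)
  oracle <- apply(t, 1, function(p) {
    w <- ((p[1] - b[, 1])^2 + (p[2] - b[, 2])^2)^(-1)  # d^-2 in any unit
    sum(w * z) / sum(w)
  })
  expect_equal(got, oracle, tolerance = 1e-10)
  expect_true(all(got >= min(z) & got <= max(z)))
  expect_error(idw_surface(b, rep(NA_real_, 5), t), "missing")
})

test_that("survey-window averaging is the arithmetic mean over dates", {
  s <- list("2009-02-10" = c(2, 4), "2009-02-11" = c(4, 4))
  expect_equal(average_survey_window(s, names(s)), c(3, 4))
  expect_equal(average_survey_window(s["2009-02-10"], "2009-02-10"), c(2, 4))
  set.seed(2)
  s5 <- lapply(1:5, function(i) rnorm(7))
  names(s5) <- paste0("d", 1:5)
  expect_equal(average_survey_window(s5, names(s5)),
               Reduce(`+`, s5) / 5)
  expect_error(average_survey_window(s, c(names(s), "2009-02-12")),
               "2009-02-12")
})

test_that("standardization hits mean 0 / sd 1 and round-trips", {
  tab <- data.frame(bathy = c(1, 2, 3), dist = c(5, 1, 0))
  out <- standardize_covariates(tab, c("bathy", "dist"))
  expect_equal(out$z_bathy, c(-1, 0, 1))
  cst <- attr(out, "constants")
  for (cl in c("bathy", "dist")) {
    z <- out[[paste0("z_", cl)]]
    expect_lt(abs(mean(z)), 1e-10)
    expect_lt(abs(sd(z) - 1), 1e-10)
    expect_equal(unstandardize(z, cl, cst), tab[[cl]], tolerance = 1e-10)
  }
  # reusing stored constants is idempotent
  again <- standardize_covariates(out, c("bathy", "dist"), constants = cst)
  expect_equal(again$z_bathy, out$z_bathy)
  expect_error(standardize_covariates(data.frame(a = rep(2, 5)), "a"),
               "zero-variance.*a")
})

test_that("collinearity matrix is absolute, symmetric, and warns at 0.6", {
  set.seed(11)
  tab <- data.frame(a = rnorm(10000), b = rnorm(10000))
  tab$c <- -tab$a
  r <- suppressWarnings(pairwise_collinearity(tab, c("a", "b", "c")))
  expect_equal(diag(r), c(a = 1, b = 1, c = 1))
  expect_equal(r["a", "c"], 1)           # sign invariance
  expect_lt(r["a", "b"], 0.05)           # independent columns
  expect_warning(pairwise_collinearity(tab, c("a", "b", "c")), "0.6")
  tab$d <- 1
  expect_error(pairwise_collinearity(tab, c("a", "d")), "constant")
})

test_that("the design matrix has the 14 fixed columns built from products", {
  d <- make_design(50, seed = 4)
  expect_equal(ncol(d$X), 14)
  expect_equal(colnames(d$X),
               c("intercept", "nao", "bathy", "bathy2", "slope", "dist",
                 "dist2", "wind", "wind2", "wave", "wave2", "latitude",
                 "nao_x_bathy", "nao_x_dist"))
  expect_equal(d$X[, "bathy2"], d$X[, "bathy"]^2)
  expect_equal(d$X[, "dist2"], d$X[, "dist"]^2)
  expect_equal(d$X[, "nao_x_bathy"], d$X[, "nao"] * d$X[, "bathy"])
  expect_equal(d$X[, "nao_x_dist"], d$X[, "nao"] * d$X[, "dist"])
  expect_equal(d$X[, "intercept"], rep(1, 50))
})

test_that("a zero covariate row maps to the (1, 0, ..., 0) predictor row", {
  tab <- data.frame(nao = c(0, 1, -1), bathy = c(0, 2, -2),
                    slope = c(0, 1, -1), dist = c(0, 3, -3),
                    wind = c(0, 1, -1), wave = c(0, 2, -2),
                    lat = c(0, 1, -1))
  tab <- standardize_covariates(tab, names(tab))
  X <- build_design_matrix(tab)$X
  expect_equal(X[1, ], c(intercept = 1, nao = 0, bathy = 0, bathy2 = 0,
                         slope = 0, dist = 0, dist2 = 0, wind = 0,
                         wind2 = 0, wave = 0, wave2 = 0, latitude = 0,
                         nao_x_bathy = 0, nao_x_dist = 0))
})

test_that("row-count mismatches between covariates and cells are errors", {
  d <- data.frame(nao = rnorm(5), bathy = rnorm(5), slope = rnorm(5),
                  dist = rnorm(5), wind = rnorm(5), wave = rnorm(5),
                  lat = rnorm(5))
  d <- standardize_covariates(d, names(d))
  expect_error(build_design_matrix(d, data.frame(count = 1:4)), "mismatch")
})

test_that("raster extraction interpolates bilinearly", {
  # values form the plane z = x + 2 y over cell centers
  g <- ascii_grid(outer(4:1, 1:5, function(i, j) j + 2 * i), 0, 0, 1)
  # centers at x = 0.5..4.5 (cols), y = 0.5..3.5 (rows south->north)
  expect_equal(raster_extract(g, 1.0, 1.0), 1.5 + 2 * 1.5)
  expect_equal(raster_extract(g, 2.25, 2.75), 2.75 + 2 * 3.25)
})
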