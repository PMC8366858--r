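# Shared fixtures: small design matrices built in code, straight transects,
# and short MCMC configurations for tests that only need a working chain.

# a straight eastward transect of given length (meters), projected plane
straight_transect <- function(id = "T01", year = 2009, length_m = 10000,
                              y0 = 0, dates = "2009-02-10") {
  transect(id, year, cbind(c(0, length_m), c(y0, y0)), dates)
}

# standardized 7-covariate table + design matrix from iid normals
make_design <- function(n, seed = 1) {
  set.seed(seed)
  tab <- data.frame(nao = rnorm(n), bathy = rnorm(n), slope = rnorm(n),
                    dist = rnorm(n), wind = rnorm(n), wave = rnorm(n),
                    lat = rnorm(n))
  tab <- standardize_covariates(tab, names(tab))
  build_design_matrix(tab)
}

# truth with a named subset of active terms (heredity-consistent)
make_truth <- function(beta0 = 0.6, active = c(slope = -0.8), r = 0.2,
                       w = 0) {
  tm <- model_terms()
  g <- stats::setNames(rep(0, nrow(tm)), tm$name)
  d <- g
  g[names(active)] <- 1
  d[names(active)] <- active
  # switch on any parents required by heredity
  for (nm in names(active))
    g[tm$parents[[match(nm, tm$name)]]] <- 1
  list(beta0 = beta0, gamma = g, delta = d, sigma = 1, r = r, w = w)
}

# attach a simulated response to a design object
d_with_y <- function(d, y) {
  d$y <- as.integer(y)
  d
}

quick_cfg <- function(seed = 1, n_chains = 1, n_adapt = 300, n_burn = 300,
                      n_iter = 600) {
  mcmc_config(n_chains = n_chains, n_adapt = n_adapt, n_burn = n_burn,
              n_iter = n_iter, seed = seed)
}

# tiny synthetic scenario for fast end-to-end runs (~2 short years)
tiny_scenario <- function(seed = 1, ...) {
  preset_scenario("survey_like", seed = seed,
                  lat_range = c(30.6, 31.3),
                  lon_range = c(-81.4, -80.2),
                  years = 2009:2010, spacing_nm = c(5, 5),
                  intensive = c(FALSE, TRUE), ...)
}
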