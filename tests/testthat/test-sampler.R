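# The Metropolis-within-Gibbs sampler: determinism, internal consistency,
# no-information limits, parameter recovery, and an independent
# Gibbs-sampler oracle for the posterior.

test_that("identical seeds give bit-identical draws", {
  d <- make_design(150, seed = 3)
  y <- simulate_counts(d$X, make_truth(active = c(bathy = 0.5), r = 0.5),
                       seed = 9)
  cfg <- quick_cfg(seed = 42, n_adapt = 100, n_burn = 100, n_iter = 200)
  f1 <- fit_nbssvs(y, d$X, config = cfg)
  f2 <- fit_nbssvs(y, d$X, config = cfg)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_nbssvs(y, d$X, config = quick_cfg(seed = 43, n_adapt = 100,
                                              n_burn = 100, n_iter = 200))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("stored draws satisfy the heredity and spike-slab identities", {
  d <- make_design(200, seed = 6)
  y <- simulate_counts(d$X, make_truth(active = c(nao_x_bathy = 0.5,
                                                  slope = -0.6), r = 0.3),
                       seed = 2)
  fit <- fit_nbssvs(y, d$X, config = quick_cfg(seed = 5))
  dr <- fit$draws
  tm <- fit$terms
  for (k in seq_len(nrow(tm))) {
    gadj <- dr[, paste0("gamma.", tm$name[k])]
    for (p in tm$parents[[k]]) gadj <- gadj * dr[, paste0("gamma.", p)]
    expect_equal(dr[, paste0("gamma_adj.", tm$name[k])], gadj)
    expect_equal(dr[, paste0("beta.", tm$name[k])],
                 gadj * dr[, paste0("delta.", tm$name[k])])
  }
  expect_true(all(dr[, "r"] > 0 & dr[, "r"] < 10))
  expect_true(all(dr[, "sigma"] > 0))
})

test_that("a zero covariate column keeps its indicator at the prior", {
  # a column that never varies carries no information, so the Bernoulli(0.5)
  # full conditional reduces to the prior and inclusion sits near 0.5
  d <- make_design(300, seed = 7)
  X <- d$X
  X[, "latitude"] <- 0
  y <- simulate_counts(X, make_truth(beta0 = 0.8, active = c(bathy = 0.4),
                                     r = 0.5), seed = 3)
  fit <- fit_nbssvs(y, X, config = quick_cfg(seed = 11, n_iter = 2000))
  incl <- inclusion_probabilities(fit)
  expect_gt(incl["latitude"], 0.4)
  expect_lt(incl["latitude"], 0.6)
})

test_that("a strong single effect is recovered with high inclusion", {
  d <- make_design(2000, seed = 12)
  y <- simulate_counts(d$X, make_truth(beta0 = 0.6,
                                       active = c(slope = -0.8), r = 0.3),
                       seed = 21)
  fit <- fit_nbssvs(y, d$X, config = quick_cfg(seed = 31, n_adapt = 500,
                                               n_burn = 500, n_iter = 1500))
  incl <- inclusion_probabilities(fit)
  expect_gt(incl["slope"], 0.9)
  expect_lt(abs(mean(fit$draws[, "beta.slope"]) + 0.8), 0.15)
  expect_lt(abs(mean(fit$draws[, "beta0"]) - 0.6), 0.15)
  # a symmetric-null term shows no directional preference
  pp <- prob_positive(fit)
  expect_lt(pp["wind"], 0.6)
  # the strong negative effect is recognized as negative
  expect_lt(pp["slope"], 0.05)
  expect_equal(unname(prob_positive(fit, "slope", conditional = TRUE)),
               unname(mean(fit$draws[fit$draws[, "gamma_adj.slope"] > 0,
                                     "beta.slope"] > 0)))
})

test_that("inclusion probabilities are means of adjusted indicators", {
  d <- make_design(100, seed = 1)
  y <- simulate_counts(d$X, make_truth(active = c(wave = 0.5), r = 1),
                       seed = 1)
  fit <- fit_nbssvs(y, d$X, config = quick_cfg(seed = 2, n_adapt = 100,
                                               n_burn = 100, n_iter = 200))
  expect_equal(unname(inclusion_probabilities(fit)),
               unname(colMeans(fit$draws[, paste0("gamma_adj.",
                                                  fit$terms$name)])))
})

test_that("the posterior matches an independent JAGS oracle", {
  skip_if_not_installed("rjags")
  # one active covariate, all indicators forced on: both samplers then
  # target the same hierarchical posterior (shared slab variance, uniform
  # r), and their marginal means must agree up to Monte Carlo error
  d <- make_design(250, seed = 14)
  y <- simulate_counts(d$X, make_truth(beta0 = 0.5, active = c(dist = 0.6),
                                       r = 0.8), seed = 4)
  fit <- fit_nbssvs(y, d$X, priors = prior_spec(pi = 1),
                    config = mcmc_config(n_chains = 2, n_adapt = 1000,
                                         n_burn = 1000, n_iter = 4000,
                                         seed = 77))
  m <- "model {
    for (i in 1:n) {
      y[i] ~ dnegbin(p[i], r)
      p[i] <- r / (r + mu[i])
      log(mu[i]) <- inprod(X[i, ], b[])
    }
    b[1] ~ dnorm(0, 0.01)
    for (k in 2:14) { b[k] ~ dnorm(0, tau) }
    tau ~ dgamma(1, 1)     # sigma = 1/tau ~ InvGamma(1, 1)
    r ~ dunif(0, 10)
  }"
  rj <- rjags::jags.model(textConnection(m),
                          data = list(y = y, X = d$X, n = length(y)),
                          n.chains = 1, n.adapt = 1000, quiet = TRUE)
  sm <- rjags::coda.samples(rj, c("b", "r"), n.iter = 6000)[[1]]
  ours <- colMeans(fit$draws[, c("beta0", paste0("beta.", fit$terms$name),
                                 "r")])
  theirs <- colMeans(sm[, c(paste0("b[", 1:14, "]"), "r")])
  expect_lt(max(abs(unname(ours) - unname(theirs))), 0.05)
})

test_that("non-convergence is flagged rather than silently ignored", {
  d <- make_design(80, seed = 9)
  y <- simulate_counts(d$X, make_truth(active = c(nao = 0.4), r = 0.3),
                       seed = 5)
  # two draws per chain cannot mix; expect the warning path
  expect_warning(
    fit <- fit_nbssvs(y, d$X, config = mcmc_config(n_chains = 3,
                                                   n_adapt = 30, n_burn = 0,
                                                   n_iter = 30, seed = 1)),
    "convergence")
  expect_false(fit$converged)
})

test_that("sampler inputs are validated", {
  d <- make_design(30, seed = 2)
  expect_error(fit_nbssvs(c(-1L, rep(0L, 29)), d$X), "negative")
  Xbad <- d$X
  Xbad[3, 4] <- NA
  expect_error(fit_nbssvs(rep(0L, 30), Xbad), "non-finite")
  expect_error(fit_nbssvs(rep(0L, 30), d$X[, 1:10]), "columns")
})
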