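# Posterior abundance predictions and NAO x bathymetry response curves.

# craft a fit object with known draws for closed-form checks
fake_fit <- function(draws_list, constants = NULL) {
  tm <- model_terms()
  K <- nrow(tm)
  n_d <- length(draws_list$beta0)
  beta <- if (is.null(draws_list[["beta"]])) matrix(0, n_d, K)
          else draws_list[["beta"]]
  colnames(beta) <- paste0("beta.", tm$name)
  gadj <- (beta != 0) * 1
  colnames(gadj) <- paste0("gamma_adj.", tm$name)
  gamma <- gadj
  colnames(gamma) <- paste0("gamma.", tm$name)
  delta <- beta
  colnames(delta) <- paste0("delta.", tm$name)
  d <- cbind(chain = 1, beta0 = draws_list$beta0, delta, gamma,
             sigma = 1,
             r = if (is.null(draws_list[["r"]])) rep(1, n_d) else draws_list[["r"]],
             w = 0,
             loglik = 0, gadj, beta)
  structure(list(draws = d, chains = list(d), terms = tm, family = "nb",
                 priors = prior_spec(), config = mcmc_config(n_chains = 1),
                 rhat = c(beta0 = 1), converged = TRUE,
                 inclusion = colMeans(gadj), constants = constants,
                 n_obs = 0),
            class = "nbssvs_fit")
}


test_that("an all-zero standardized row predicts exp(beta0)", {
  fit <- fake_fit(list(beta0 = c(0, log(2), log(4))))
  X <- matrix(c(1, rep(0, 13)), 1, 14)
  pr <- predict_abundance(fit, X)
  expect_equal(pr$mean, mean(c(1, 2, 4)))
  expect_equal(pr$lower, unname(quantile(c(1, 2, 4), 0.025)))
  expect_true(pr$lower <= pr$mean && pr$mean <= pr$upper)
})

test_that("a single draw reproduces the hand-computed linear predictor", {
  tm <- model_terms()
  beta <- matrix(0, 1, nrow(tm))
  beta[1, match(c("bathy", "slope"), tm$name)] <- c(0.5, -1)
  fit <- fake_fit(list(beta0 = 0.2, beta = beta))
  X <- matrix(0, 2, 14)
  X[, 1] <- 1
  X[1, match("bathy", tm$name) + 1] <- 1.5
  X[2, match("slope", tm$name) + 1] <- 2
  pr <- predict_abundance(fit, X)
  expect_equal(pr$mean, c(exp(0.2 + 0.75), exp(0.2 - 2)))
  expect_equal(pr$lower, pr$upper)  # single draw: degenerate interval
})

test_that("predictions are invariant to draw and row order", {
  set.seed(6)
  tm <- model_terms()
  nd <- 50
  beta <- matrix(rnorm(nd * nrow(tm), 0, 0.1), nd)
  fit1 <- fake_fit(list(beta0 = rnorm(nd, 0.3, 0.2), beta = beta))
  perm <- sample(nd)
  fit2 <- fake_fit(list(beta0 = fit1$draws[perm, "beta0"],
                        beta = beta[perm, ]))
  X <- cbind(1, matrix(rnorm(10 * 13), 10, 13))
  p1 <- predict_abundance(fit1, X)
  p2 <- predict_abundance(fit2, X)
  expect_equal(p1, p2)
  rp <- sample(10)
  p3 <- predict_abundance(fit1, X[rp, ])
  expect_equal(p3$mean, p1$mean[rp])
})

test_that("response curves collapse when the interaction terms are off", {
  cst <- data.frame(col = c("nao", "bathy"), mean = c(-1, -12),
                    sd = c(2, 6), min = c(-4, -30), max = c(3, 0))
  fit <- fake_fit(list(beta0 = c(0.1, 0.4)), constants = cst)
  cur <- interaction_curve(fit, bathy_m = seq(-30, 0, by = 5))
  expect_equal(sort(unique(cur$nao_level)), sort(c(-3.9, -1.4, 2.8)))
  by_nao <- split(cur$mean, cur$nao_level)
  expect_equal(by_nao[[1]], by_nao[[2]])
  expect_equal(by_nao[[2]], by_nao[[3]])
})

test_that("a negative interaction reverses the depth ordering across NAO", {
  tm <- model_terms()
  beta <- matrix(0, 1, nrow(tm))
  beta[1, match("nao_x_bathy", tm$name)] <- -0.8
  cst <- data.frame(col = c("nao", "bathy"), mean = c(0, -15), sd = c(2, 8),
                    min = c(-4, -35), max = c(3, 0))
  fit <- fake_fit(list(beta0 = 0, beta = beta), constants = cst)
  cur <- interaction_curve(fit, bathy_m = seq(-35, 0, by = 5),
                           nao_values = c(-3.9, 2.8))
  lo <- cur[cur$nao_level == -3.9, ]
  hi <- cur[cur$nao_level == 2.8, ]
  # negative coefficient: at low NAO the curve rises with depth value,
  # at high NAO it falls (orderings reverse across the grid)
  expect_gt(lo$mean[nrow(lo)], lo$mean[1])
  expect_lt(hi$mean[nrow(hi)], hi$mean[1])
})

test_that("extrapolation beyond the fitted range warns", {
  cst <- data.frame(col = c("nao", "bathy"), mean = c(0, -10), sd = c(1, 4),
                    min = c(-2, -20), max = c(2, 0))
  fit <- fake_fit(list(beta0 = 0), constants = cst)
  expect_warning(interaction_curve(fit, bathy_m = seq(-40, 0, by = 10)),
                 "extrapolat")
  expect_error(interaction_curve(fit, bathy_m = c(0, -10, -20)),
               "increasing")
})

test_that("mismatched standardization constants are rejected", {
  d <- make_design(40, seed = 2)
  y <- simulate_counts(d$X, make_truth(active = c(wave = 0.5), r = 0.5),
                       seed = 1)
  fit <- fit_nbssvs(d_with_y(d, y), config = quick_cfg(seed = 3,
                                                       n_adapt = 100,
                                                       n_burn = 100,
                                                       n_iter = 100))
  d2 <- d
  d2$constants$mean <- d2$constants$mean + 1
  expect_error(predict_abundance(fit, d2), "constants")
  # the same design round-trips: fitted-cell predictions reproduce exactly
  p1 <- predict_abundance(fit, d)
  p2 <- predict_abundance(fit, d$X)
  expect_equal(p1$mean, p2$mean)
})
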