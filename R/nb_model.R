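# Bayesian negative binomial regression with Bernoulli indicator
# (spike-and-slab) variable selection under strong heredity, fitted by the
# compiled Metropolis-within-Gibbs sampler, plus zero-inflated comparison
# variants and posterior summaries.

#' Negative binomial probability mass function
#'
#' The model's observation distribution: `y ~ NegBinom(p, r)` with
#' `p = r/(r + mu)`, so `P(Y = y) = Gamma(y + r)/(Gamma(r) y!) p^r (1-p)^y`,
#' mean `mu` and variance `mu + mu^2/r`. `r` is the (continuous)
#' overdispersion parameter; small `r` means extreme clumping.
#'
#' @param y non-negative integer counts.
#' @param mu positive mean(s).
#' @param r positive overdispersion parameter.
#' @param log return log-probabilities.
#' @return Probabilities (or log-probabilities) of `y`.
#' @export
nb_pmf <- function(y, mu, r, log = FALSE) {
  if (any(y < 0) || any(y != floor(y))) stop("y must be non-negative integers")
  stopifnot(all(mu > 0), all(r > 0))
  stats::dnbinom(y, size = r, mu = mu, log = log)
}

#' Log-likelihood of the count models
#'
#' Vectorized reference likelihood for the negative binomial and its
#' zero-inflated comparison variants. The zero-inflated families mix a point
#' mass at zero (weight `w`) with the count distribution.
#'
#' @param y observed counts.
#' @param mu per-observation means.
#' @param r overdispersion parameter (ignored for `"zip"`).
#' @param w zero-inflation weight in `[0, 1)` (ignored for `"nb"`).
#' @param family `"nb"`, `"zip"` or `"zinb"`.
#' @return Total log-likelihood (a scalar).
#' @export
count_loglik <- function(y, mu, r = NULL, w = 0, family = c("nb", "zip", "zinb")) {
  family <- match.arg(family)
  stopifnot(length(mu) == length(y))
  if (any(!is.finite(mu)))
    stop("non-finite mean at row(s) ", paste(utils::head(which(!is.finite(mu)), 5), collapse = ", "))
  if (family == "nb") {
    return(sum(nb_pmf(y, mu, r, log = TRUE)))
  }
  z <- y == 0
  if (family == "zip") {
    ll0 <- log(w + (1 - w) * exp(-mu[z]))
    ll1 <- log1p(-w) + stats::dpois(y[!z], mu[!z], log = TRUE)
  } else {
    p0 <- (r / (r + mu[z]))^r
    ll0 <- log(w + (1 - w) * p0)
    ll1 <- log1p(-w) + nb_pmf(y[!z], mu[!z], r, log = TRUE)
  }
  sum(ll0) + sum(ll1)
}

#' Log-likelihood at a model state
#'
#' @param y counts.
#' @param X design matrix (n x 14, intercept first).
#' @param beta0 intercept.
#' @param beta vector of 13 term coefficients (`gamma_adj * delta`).
#' @param r overdispersion parameter.
#' @param w zero-inflation weight.
#' @inheritParams count_loglik
#' @return Scalar log-likelihood.
#' @export
nb_loglik <- function(y, X, beta0, beta, r, w = 0, family = "nb") {
  stopifnot(ncol(X) == length(beta) + 1, nrow(X) == length(y))
  eta <- drop(X %*% c(beta0, beta))
  if (any(!is.finite(eta)))
    stop("non-finite linear predictor at row(s) ",
         paste(utils::head(which(!is.finite(eta)), 5), collapse = ", "))
  count_loglik(y, exp(eta), r = r, w = w, family = family)
}

#' Prior specification
#'
#' Vague priors of the abundance model: `beta0 ~ Normal(0, 0.01)` read under
#' the chosen convention, `delta_k ~ Normal(0, sigma)` with variance `sigma`
#' and conjugate `sigma ~ InvGamma(1, 1)`, inclusion indicators
#' `gamma ~ Bernoulli(0.5)`, `r ~ Unif(0, 10)`, and (zero-inflated variants)
#' `w ~ Unif(0, 1)`.
#'
#' Gibbs-sampler dialects disagree on what Normal(0, 0.01) means. Under the
#' default `"bugs-precision"` convention the second argument is a precision,
#' so the intercept prior sd is 10; under `"moment"` it is a variance (sd
#' 0.1). The slab is parameterized by its variance `sigma` in both so the
#' inverse-gamma update stays conjugate. The convention used is recorded in
#' every fit.
#'
#' @param convention `"bugs-precision"` (default) or `"moment"`.
#' @param beta0_mean intercept prior mean.
#' @param beta0_scale second argument of the intercept's Normal prior,
#'   interpreted per `convention`.
#' @param sigma_shape,sigma_rate inverse-gamma hyperparameters of the slab
#'   variance.
#' @param pi prior inclusion probability of each indicator; `0` or `1` fixes
#'   all indicators (useful for diagnostic runs).
#' @param r_upper upper bound of the uniform prior on `r`.
#' @return List of class `prior_spec`.
#' @export
prior_spec <- function(convention = c("bugs-precision", "moment"),
                       beta0_mean = 0, beta0_scale = 0.01,
                       sigma_shape = 1, sigma_rate = 1,
                       pi = 0.5, r_upper = 10) {
  convention <- match.arg(convention)
  stopifnot(beta0_scale > 0, sigma_shape > 0, sigma_rate > 0,
            pi >= 0, pi <= 1, r_upper > 0)
  beta0_sd <- if (convention == "bugs-precision") 1 / sqrt(beta0_scale)
              else sqrt(beta0_scale)
  structure(list(convention = convention, beta0_mean = beta0_mean,
                 beta0_scale = beta0_scale, beta0_sd = beta0_sd,
                 sigma_shape = sigma_shape, sigma_rate = sigma_rate,
                 pi = pi, r_upper = r_upper),
            class = "prior_spec")
}

#' MCMC configuration
#'
#' @param n_chains number of chains run from dispersed starts (default 3).
#' @param n_adapt iterations of the discarded adaptation phase during which
#'   random-walk proposal scales are tuned toward a 20-50% acceptance rate
#'   and then frozen.
#' @param n_burn post-adaptation burn-in iterations (discarded).
#' @param n_iter retained iterations per chain (before thinning).
#' @param thin thinning interval.
#' @param seed integer seed; every source of randomness in a fit derives
#'   from it, and re-running with the same seed reproduces draws exactly.
#' @return List of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3, n_adapt = 1000, n_burn = 1000,
                        n_iter = 2000, thin = 1, seed = 1) {
  stopifnot(n_chains >= 1, n_adapt >= 0, n_burn >= 0, n_iter >= 1, thin >= 1)
  structure(list(n_chains = as.integer(n_chains), n_adapt = as.integer(n_adapt),
                 n_burn = as.integer(n_burn), n_iter = as.integer(n_iter),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Fit the spike-and-slab count regression
#'
#' Metropolis-within-Gibbs sampling of the posterior of
#' `(beta0, delta, gamma, sigma, r)` (plus `w` for the zero-inflated
#' variants). Coefficients follow the Kuo-Mallick parameterization
#' `beta_k = gamma_adj_k * delta_k`: when a term is gated out its `delta` is
#' refreshed from the slab prior, and each `gamma_k` is flipped by its
#' Bernoulli full conditional with the strong-heredity adjustment recomputed.
#' `sigma` has a conjugate inverse-gamma update and `r` a random walk on the
#' log scale bounded by its uniform prior.
#'
#' @param y integer response counts, or a `scoter_design` from
#'   [build_design_matrix()] (in which case `X` is taken from it).
#' @param X design matrix (n x 14, intercept first) when `y` is a vector.
#' @param terms term table ([model_terms()]).
#' @param family `"nb"` (default), `"zip"` or `"zinb"`.
#' @param priors a [prior_spec()].
#' @param config an [mcmc_config()].
#' @return Object of class `nbssvs_fit` with elements `draws` (matrix of all
#'   retained draws across chains, with `chain`, `beta0`, `delta.*`,
#'   `gamma.*`, `gamma_adj.*`, `beta.*`, `sigma`, `r`, `w`, `loglik`
#'   columns), `accept`, `rhat`, `converged`, and the configuration used.
#'   Non-convergence (split-chain R-hat above 1.1) is flagged in
#'   `converged`/`rhat`, not silently ignored.
#' @export
fit_nbssvs <- function(y, X = NULL, terms = model_terms(),
                       family = c("nb", "zip", "zinb"),
                       priors = prior_spec(), config = mcmc_config()) {
  family <- match.arg(family)
  design <- NULL
  if (inherits(y, "scoter_design")) {
    design <- y
    X <- design$X
    terms <- design$terms
    y <- design$y
    if (is.null(y)) stop("design matrix carries no response counts")
  }
  y <- as.integer(y)
  if (any(y < 0)) stop("negative counts in y")
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("non-finite values in the design matrix")
  K <- nrow(terms)
  if (ncol(X) != K + 1)
    stop("design matrix must have ", K + 1, " columns (intercept + terms)")
  validate_terms(terms)
  fam_code <- match(family, c("nb", "zip", "zinb")) - 1L
  parents0 <- lapply(terms$parents,
                     function(p) as.integer(match(p, terms$name) - 1L))

  chains <- vector("list", config$n_chains)
  accept <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + 1009L * (ch - 1L))
    beta0_init <- stats::rnorm(1, log(mean(y) + 0.5), 0.5)
    delta_init <- stats::rnorm(K, 0, 0.5)
    gamma_init <- if (priors$pi <= 0) rep(0L, K)
                  else if (priors$pi >= 1) rep(1L, K)
                  else stats::rbinom(K, 1, 0.5)
    sigma_init <- stats::runif(1, 0.5, 2)
    r_init <- stats::runif(1, 0.05, min(5, priors$r_upper * 0.9))
    w_init <- stats::runif(1, 0.1, 0.9)
    res <- .nbssvs_chain(y, X, parents0, fam_code,
                         priors$beta0_mean, priors$beta0_sd,
                         priors$sigma_shape, priors$sigma_rate,
                         priors$pi, priors$r_upper,
                         config$n_adapt, config$n_burn, config$n_iter,
                         config$thin,
                         beta0_init, delta_init, as.integer(gamma_init),
                         sigma_init, r_init, w_init)
    m <- res$draws
    colnames(m) <- c("beta0", paste0("delta.", terms$name),
                     paste0("gamma.", terms$name), "sigma", "r", "w", "loglik")
    chains[[ch]] <- m
    accept[[ch]] <- res$accept
  }

  # derived columns: heredity-adjusted indicators and beta = gamma_adj * delta
  gname <- paste0("gamma.", terms$name)
  for (ch in seq_along(chains)) {
    m <- chains[[ch]]
    gadj <- m[, gname, drop = FALSE]
    for (k in seq_len(K)) {
      for (p in terms$parents[[k]])
        gadj[, k] <- gadj[, k] * m[, paste0("gamma.", p)]
    }
    colnames(gadj) <- paste0("gamma_adj.", terms$name)
    beta <- gadj * m[, paste0("delta.", terms$name), drop = FALSE]
    colnames(beta) <- paste0("beta.", terms$name)
    chains[[ch]] <- cbind(m, gadj, beta)
  }
  combined <- do.call(rbind, chains)
  combined <- cbind(chain = rep(seq_along(chains), vapply(chains, nrow, 0L)),
                    combined)

  # convergence: R-hat on beta0, sigma, r (and w), plus coefficients whose
  # inclusion probability exceeds 0.2
  incl <- colMeans(combined[, paste0("gamma_adj.", terms$name), drop = FALSE])
  names(incl) <- terms$name
  tracked <- terms$name[incl > 0.2]
  monitor <- c("beta0", "sigma", if (family != "zip") "r",
               if (family != "nb") "w",
               if (length(tracked)) paste0("beta.", tracked))
  rhat <- vapply(monitor, function(p) {
    split_rhat(sapply(chains, function(m) m[, p]))
  }, 0)
  converged <- all(is.finite(rhat) & rhat < 1.1)
  if (config$n_chains >= 2 && !converged)
    warning("convergence not reached: max R-hat = ",
            round(max(rhat, na.rm = TRUE), 3))

  structure(list(draws = combined, chains = chains, terms = terms,
                 family = family, priors = priors, config = config,
                 accept = accept, rhat = rhat, converged = converged,
                 inclusion = incl,
                 constants = if (!is.null(design)) design$constants else NULL,
                 n_obs = length(y)),
            class = "nbssvs_fit")
}

#' @export
print.nbssvs_fit <- function(x, ...) {
  cat("Spike-and-slab", toupper(x$family), "count regression\n")
  cat(sprintf("  %d observations, %d chains x %d retained draws (seed %d)\n",
              x$n_obs, x$config$n_chains, nrow(x$chains[[1]]), x$config$seed))
  cat(sprintf("  prior convention: %s; converged: %s (max R-hat %.3f)\n",
              x$priors$convention, x$converged, max(x$rhat, na.rm = TRUE)))
  cat("  inclusion probabilities:\n")
  print(round(x$inclusion, 3))
  invisible(x)
}

#' @export
summary.nbssvs_fit <- function(object, ...) {
  d <- object$draws
  bn <- paste0("beta.", object$terms$name)
  qs <- t(apply(d[, c("beta0", bn, "sigma", "r"), drop = FALSE], 2,
                stats::quantile, c(0.025, 0.5, 0.975)))
  out <- data.frame(mean = colMeans(d[, c("beta0", bn, "sigma", "r"), drop = FALSE]),
                    qs, check.names = FALSE)
  names(out) <- c("mean", "q025", "median", "q975")
  out$inclusion <- c(NA, object$inclusion, NA, NA)
  out
}

#' Posterior inclusion probabilities
#'
#' Per term, the mean over retained draws of the heredity-adjusted indicator
#' `gamma_adj`.
#'
#' @param fit an `nbssvs_fit`.
#' @return Named numeric vector.
#' @export
inclusion_probabilities <- function(fit) {
  stopifnot(inherits(fit, "nbssvs_fit"))
  fit$inclusion
}

#' Posterior probability that a coefficient is positive
#'
#' Fraction of all retained draws with `beta_k` strictly positive; spike
#' draws (`beta_k` exactly 0 because the term is excluded) count as not
#' positive. With `conditional = TRUE` the fraction is computed over the
#' slab draws only (those with the term included).
#'
#' @param fit an `nbssvs_fit`.
#' @param terms term names (default all).
#' @param conditional condition on inclusion.
#' @return Named numeric vector of probabilities.
#' @export
prob_positive <- function(fit, terms = NULL, conditional = FALSE) {
  stopifnot(inherits(fit, "nbssvs_fit"))
  if (is.null(terms)) terms <- fit$terms$name
  vapply(terms, function(tn) {
    b <- fit$draws[, paste0("beta.", tn)]
    if (conditional) {
      g <- fit$draws[, paste0("gamma_adj.", tn)]
      if (!any(g > 0)) return(NA_real_)
      mean(b[g > 0] > 0)
    } else {
      mean(b > 0)
    }
  }, 0)
}
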