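# Posterior-predictive goodness of fit via the Freeman-Tukey discrepancy,
# and Gelman-Rubin convergence diagnostics.

#' Freeman-Tukey discrepancy
#'
#' `T(y, mu) = sum_i (sqrt(y_i) - sqrt(mu_i))^2`, a variance-stabilized
#' discrepancy for counts. Zero iff `y = mu` elementwise.
#'
#' @param y observed (or replicated) counts.
#' @param mu expected values (positive).
#' @return Scalar discrepancy.
#' @export
freeman_tukey <- function(y, mu) {
  if (length(y) != length(mu)) stop("y and mu lengths differ")
  if (any(y < 0)) stop("negative counts")
  if (any(mu <= 0)) stop("non-positive expected values")
  sum((sqrt(y) - sqrt(mu))^2)
}

#' Posterior-predictive Bayesian p-value
#'
#' For each retained draw, computes the fitted means `mu`, simulates a
#' replicate data set from the fitted family at that draw, and compares the
#' Freeman-Tukey discrepancy of the observed and replicated data:
#' `p = mean(T_rep >= T_obs)` (ties counted, the conservative convention).
#' Values near 0 or 1 flag misfit; the lack-of-fit flag uses the two-sided
#' 0.1 / 0.9 thresholds.
#'
#' @param fit an `nbssvs_fit`.
#' @param y observed counts the model was fitted to.
#' @param X the design matrix used in the fit.
#' @param seed seed for the replicate simulations (independent of the
#'   sampler's seed).
#' @param simulator optional function `(mu, draw)` returning a replicate
#'   count vector; overrides the family simulator (used for degenerate
#'   checks).
#' @return Object of class `ppc_result`: `t_obs`, `t_rep` (per draw),
#'   `p_value`, `n_draws`, `flag`, `seed`.
#' @export
ppc_pvalue <- function(fit, y, X, seed = 1, simulator = NULL) {
  stopifnot(inherits(fit, "nbssvs_fit"))
  if (inherits(y, "scoter_design")) {
    X <- y$X
    y <- y$y
  }
  X <- as.matrix(X)
  d <- fit$draws
  if (nrow(X) != length(y)) stop("y and X are dimensionally inconsistent")
  if (ncol(X) != nrow(fit$terms) + 1)
    stop("design matrix does not match the fitted terms")
  bn <- c("beta0", paste0("beta.", fit$terms$name))
  n_draws <- nrow(d)
  t_obs <- numeric(n_draws)
  t_rep <- numeric(n_draws)
  n <- length(y)
  set.seed(seed)
  coefs <- t(d[, bn, drop = FALSE])   # (K+1) x draws
  for (j in seq_len(n_draws)) {
    mu <- exp(drop(X %*% coefs[, j]))
    y_rep <- if (!is.null(simulator)) {
      simulator(mu, d[j, ])
    } else if (fit$family == "nb") {
      stats::rnbinom(n, size = d[j, "r"], mu = mu)
    } else if (fit$family == "zip") {
      ifelse(stats::runif(n) < d[j, "w"], 0L, stats::rpois(n, mu))
    } else {
      ifelse(stats::runif(n) < d[j, "w"], 0L,
             stats::rnbinom(n, size = d[j, "r"], mu = mu))
    }
    t_obs[j] <- freeman_tukey(y, mu)
    t_rep[j] <- freeman_tukey(y_rep, mu)
  }
  p <- mean(t_rep >= t_obs)
  structure(list(t_obs = t_obs, t_rep = t_rep, p_value = p,
                 n_draws = n_draws, flag = (p < 0.1 || p > 0.9), seed = seed),
            class = "ppc_result")
}

#' @export
print.ppc_result <- function(x, ...) {
  cat(sprintf("Posterior-predictive check (Freeman-Tukey), %d draws\n", x$n_draws))
  cat(sprintf("  Bayesian p-value: %.3f%s\n", x$p_value,
              if (x$flag) "  ** lack of fit (outside 0.1-0.9) **" else ""))
  invisible(x)
}

# split-chain potential scale reduction factor; x is a matrix with one
# column per chain (a vector is treated as a single chain). Each chain is
# split in half, so the statistic is defined even for a single chain.
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  sub <- cbind(x[seq_len(half), , drop = FALSE],
               x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, stats::var)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W == 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Gelman-Rubin convergence diagnostic
#'
#' Split-chain potential scale reduction factor (each chain is split in
#' half before computing the between/within variance ratio); values near 1
#' indicate convergence, values above ~1.1 indicate the chains have not
#' mixed.
#'
#' @param x an `nbssvs_fit`, or a matrix with one column per chain.
#' @param parameter column name of the monitored parameter when `x` is a
#'   fit (e.g. `"beta0"`, `"sigma"`, `"r"`, `"beta.slope"`).
#' @return Scalar R-hat (>= 1 up to Monte Carlo error).
#' @export
gelman_rubin <- function(x, parameter = NULL) {
  if (inherits(x, "nbssvs_fit")) {
    if (x$config$n_chains < 2)
      stop("R-hat needs at least 2 chains; rerun with n_chains >= 2")
    if (is.null(parameter)) stop("name the parameter to diagnose")
    x <- sapply(x$chains, function(m) m[, parameter])
  }
  x <- as.matrix(x)
  if (ncol(x) < 2)
    stop("R-hat needs at least 2 chains; rerun with n_chains >= 2")
  if (nrow(x) < 10) stop("need at least 10 retained draws per chain")
  split_rhat(x)
}
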