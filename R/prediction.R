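# Posterior predictions of relative abundance and interaction-response
# curves. "Relative abundance" is the posterior expected count per survey
# grid cell (the model's native 1,000 m x 550 m unit); no density rescaling.

#' Posterior prediction of relative abundance
#'
#' Per prediction row and retained draw, `mu = exp(beta0 + X beta)`;
#' summaries are the posterior mean, sd, and the equal-tailed 95% credible
#' interval over draws. New rows must be built with the same
#' standardization constants as the fitted design matrix.
#'
#' @param fit an `nbssvs_fit`.
#' @param X_new prediction design matrix (same 14 columns as the fit) or a
#'   `scoter_design`.
#' @param level credible level (default 0.95).
#' @return data.frame with columns `mean`, `sd`, `lower`, `upper` (one row
#'   per prediction row), plus `cell_id`/`year` when available.
#' @export
predict_abundance <- function(fit, X_new, level = 0.95) {
  stopifnot(inherits(fit, "nbssvs_fit"))
  meta <- NULL
  if (inherits(X_new, "scoter_design")) {
    if (!is.null(fit$constants) && !is.null(X_new$constants) &&
        !isTRUE(all.equal(fit$constants[c("col", "mean", "sd")],
                          X_new$constants[c("col", "mean", "sd")],
                          tolerance = 1e-12)))
      stop("standardization constants of the prediction design do not match the fit")
    meta <- X_new$meta
    X_new <- X_new$X
  }
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != nrow(fit$terms) + 1)
    stop("prediction matrix must have ", nrow(fit$terms) + 1, " columns")
  coefs <- t(fit$draws[, c("beta0", paste0("beta.", fit$terms$name)), drop = FALSE])
  a <- (1 - level) / 2
  m <- nrow(X_new)
  out <- data.frame(mean = numeric(m), sd = numeric(m),
                    lower = numeric(m), upper = numeric(m))
  chunk <- max(1L, floor(2e6 / ncol(coefs)))
  for (s in seq(1L, m, by = chunk)) {
    idx <- s:min(m, s + chunk - 1L)
    mu <- exp(X_new[idx, , drop = FALSE] %*% coefs)  # rows x draws
    out$mean[idx] <- rowMeans(mu)
    out$sd[idx] <- apply(mu, 1, stats::sd)
    qs <- t(apply(mu, 1, stats::quantile, c(a, 1 - a)))
    out$lower[idx] <- qs[, 1]
    out$upper[idx] <- qs[, 2]
  }
  if (!is.null(meta)) out <- cbind(meta, out)
  out
}

#' NAO x bathymetry interaction-response curves
#'
#' Predicted relative abundance along a grid of raw bathymetry values
#' (meters, elevation convention: deeper is more negative) at fixed NAO
#' index levels, with every other covariate held at its survey mean
#' (standardized 0). The default NAO levels are the low / moderate / high
#' phases observed across the survey years (-3.9, -1.4, 2.8).
#'
#' @param fit an `nbssvs_fit` carrying standardization constants (fitted
#'   from a `scoter_design`), or supply `constants`.
#' @param bathy_m numeric grid of raw bathymetry values (m).
#' @param nao_values raw NAO index levels to condition on.
#' @param constants standardization constants (data.frame `col, mean, sd`),
#'   defaulting to those stored in the fit.
#' @param level credible level.
#' @return data.frame with columns `nao_level`, `bathymetry_m`, `mean`,
#'   `lower`, `upper`.
#' @export
interaction_curve <- function(fit, bathy_m = seq(-35, 0, by = 1),
                              nao_values = c(-3.9, -1.4, 2.8),
                              constants = NULL, level = 0.95) {
  stopifnot(inherits(fit, "nbssvs_fit"))
  if (is.null(constants)) constants <- fit$constants
  if (is.null(constants))
    stop("no standardization constants available; pass `constants`")
  if (is.unsorted(bathy_m, strictly = TRUE))
    stop("bathy_m must be a strictly increasing grid")
  zb <- (bathy_m - constants$mean[constants$col == "bathy"]) /
    constants$sd[constants$col == "bathy"]
  zn <- (nao_values - constants$mean[constants$col == "nao"]) /
    constants$sd[constants$col == "nao"]
  if (all(c("min", "max") %in% names(constants))) {
    rb <- constants[constants$col == "bathy", c("min", "max")]
    rn <- constants[constants$col == "nao", c("min", "max")]
    if (any(bathy_m < rb$min | bathy_m > rb$max) ||
        any(nao_values < rn$min | nao_values > rn$max))
      warning("extrapolating beyond the fitted covariate range")
  }
  out <- NULL
  for (v in seq_along(nao_values)) {
    X <- matrix(0, length(bathy_m), nrow(fit$terms) + 1)
    colnames(X) <- c("intercept", fit$terms$name)
    X[, "intercept"] <- 1
    X[, "nao"] <- zn[v]
    X[, "bathy"] <- zb
    X[, "bathy2"] <- zb^2
    X[, "nao_x_bathy"] <- zn[v] * zb
    pr <- predict_abundance(fit, X, level = level)
    out <- rbind(out, data.frame(nao_level = nao_values[v],
                                 bathymetry_m = bathy_m,
                                 mean = pr$mean, lower = pr$lower,
                                 upper = pr$upper))
  }
  out
}
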