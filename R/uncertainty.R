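# Uncertainty for the delta-GLM annual index.
#
# Two samplers with the same large-sample behaviour:
#  - "bootstrap": nonparametric resampling of hauls stratified by year, each
#    resample refit with the already-selected covariate sets;
#  - "posterior": multivariate-normal draws of both submodels' coefficients
#    about their MLEs (an asymptotic stand-in for a vague-prior Bayesian fit).
# Summary conventions follow ecosystem-report practice: se_log is the SD of
# log-scale index draws excluding zeros and not adding 1; the 95% interval is
# the 2.5/97.5 percentile of log(x + 1) draws.

index_draws_from_coefs <- function(fit_obj, n_draws) {
  years <- as.character(fit_obj$years)
  draw_eta <- function(fit) {
    beta <- coef(fit)
    ok <- !is.na(beta)
    V <- vcov(fit)
    B <- MASS::mvrnorm(n_draws, beta[ok], V)  # n_draws x p
    X <- model.matrix(fit)
    cm <- colMeans(X)[ok]
    yl <- fit$xlevels[["fyear"]]
    ycols <- paste0("fyear", yl[-1])
    eta <- matrix(NA_real_, n_draws, length(yl), dimnames = list(NULL, yl))
    for (y in yl) {
      v <- cm
      v[intersect(ycols, names(v))] <- 0
      col <- paste0("fyear", y)
      if (col %in% names(v)) v[col] <- 1
      eta[, y] <- as.vector(B %*% v)
    }
    eta
  }
  if (is.null(fit_obj$binomial_fit)) {
    p <- matrix(1, n_draws, length(years), dimnames = list(NULL, years))
  } else {
    p <- plogis(draw_eta(fit_obj$binomial_fit))
  }
  mu <- matrix(NA_real_, n_draws, length(years), dimnames = list(NULL, years))
  mp <- exp(draw_eta(fit_obj$positive_fit))
  mu[, colnames(mp)] <- mp
  x <- p[, years, drop = FALSE] * mu
  x[is.na(x)] <- 0  # years with no positive catches
  x
}

refit_index_point <- function(d, bin_terms, pos_terms, years,
                              binomial_degenerate) {
  if (binomial_degenerate || all(d$present == 1L)) {
    p_hat <- setNames(rep(1, length(years)), years)
  } else {
    bfit <- suppressWarnings(glm(submodel_formula("present", bin_terms),
                                 data = d, family = binomial()))
    p_hat <- plogis(profile_year_eta(bfit))[years]
    names(p_hat) <- years
    p_hat[is.na(p_hat)] <- 0
  }
  pos <- droplevels(d[d$present == 1L, , drop = FALSE])
  if (nrow(pos) < 2L) return(setNames(rep(NA_real_, length(years)), years))
  pos$logcpue <- log(pos$cpue)
  pfit <- suppressWarnings(glm(submodel_formula("logcpue", pos_terms),
                               data = pos, family = gaussian()))
  mu <- profile_year_eta(pfit)
  x <- setNames(rep(0, length(years)), years)
  common <- intersect(names(mu), years)
  x[common] <- p_hat[common] * exp(mu[common])
  x
}

#' Estimate uncertainty of the annual index
#'
#' Produces per-year draws of the index and summarizes them into `se_log`
#' (SD of log-scale draws, excluding zero draws and not adding 1) and a 95%
#' interval (2.5/97.5 percentiles of `log(x + 1)` draws).
#'
#' @param fit A `delta_glm_fit`.
#' @param method `"bootstrap"` (year-stratified nonparametric, the default) or
#'   `"posterior"` (asymptotic-normal coefficient draws; much faster).
#' @param n_draws Number of draws (>= 200).
#' @param seed Integer seed.
#' @param baseline_years Baseline for z-scores (default: all years).
#' @param max_drop_frac Error if more than this fraction of bootstrap
#'   resamples fail to fit (default 0.2).
#' @return An `index_series` with `se_log`, `lower`, `upper` filled; the draw
#'   matrix is attached as attribute `"draws"` (arithmetic index scale).
#' @export
estimate_uncertainty <- function(fit, method = c("bootstrap", "posterior"),
                                 n_draws = 500, seed = 1,
                                 baseline_years = NULL,
                                 max_drop_frac = 0.2) {
  stopifnot(inherits(fit, "delta_glm_fit"))
  method <- match.arg(method)
  if (n_draws < 200) stop("n_draws must be >= 200", call. = FALSE)
  set.seed(seed)
  years <- as.character(fit$years)

  if (method == "posterior") {
    draws <- index_draws_from_coefs(fit, n_draws)
    dropped <- 0L
  } else {
    d <- fit$data
    idx_by_year <- split(seq_len(nrow(d)), d$fyear)
    degen <- is.null(fit$binomial_fit)
    draws <- matrix(NA_real_, n_draws, length(years),
                    dimnames = list(NULL, years))
    dropped <- 0L
    for (b in seq_len(n_draws)) {
      take <- unlist(lapply(idx_by_year, function(ii) {
        ii[sample.int(length(ii), length(ii), replace = TRUE)]
      }), use.names = FALSE)
      x <- try(refit_index_point(d[take, , drop = FALSE],
                                 fit$selected_covariates$binomial,
                                 fit$selected_covariates$positive,
                                 years, degen), silent = TRUE)
      if (inherits(x, "try-error") || all(is.na(x))) {
        dropped <- dropped + 1L
      } else {
        draws[b, ] <- x
      }
    }
    if (dropped > max_drop_frac * n_draws) {
      stop(sprintf("%d of %d bootstrap resamples failed to fit", dropped,
                   n_draws), call. = FALSE)
    }
    if (dropped > 0L) {
      message(sprintf("dropped %d non-convergent resamples", dropped))
      draws <- draws[rowSums(is.na(draws)) == 0L, , drop = FALSE]
    }
  }

  se_log <- apply(draws, 2, function(v) {
    v <- v[v > 0]
    if (length(v) < 2L) NA_real_ else sd(log(v))
  })
  lims <- apply(log1p(draws), 2, quantile, probs = c(0.025, 0.975),
                na.rm = TRUE)

  out <- compute_index(fit, baseline_years = baseline_years)
  out$se_log <- unname(se_log[as.character(out$year)])
  out$lower <- unname(lims[1, as.character(out$year)])
  out$upper <- unname(lims[2, as.character(out$year)])
  attr(out, "draws") <- draws
  attr(out, "n_dropped") <- dropped
  attr(out, "method") <- method
  out
}
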