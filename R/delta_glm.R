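# Delta-GLM (hurdle) standardization of haul-level CPUE.
#
# The two-part model fits (i) a binomial GLM to presence/absence over all
# hauls and (ii) a gaussian GLM to log catch over positive hauls only. Year
# enters both parts as a fixed factor; spatial (and optionally seasonal)
# covariates are chosen by AIC independently for each part. Back-transformed
# year coefficients are multiplied into the annual index.

#' Default candidate covariate sets for delta-GLM selection
#'
#' Mirrors the survey's standard candidate set: nothing, station, region,
#' depth stratum, region + depth, and region x depth interaction; when
#' `seasonal = TRUE` each set is also offered with a 10-day Julian-day bin
#' term. Sets are ordered by complexity so AIC ties resolve to the smaller
#' set.
#'
#' @param seasonal Offer the Julian-day bin covariate (rockfish-like taxa).
#' @return List of character vectors of model terms.
#' @export
default_candidate_sets <- function(seasonal = FALSE) {
  base <- list(
    character(0),
    "region",
    "depth_stratum",
    "station_id",
    c("region", "depth_stratum"),
    c("region", "depth_stratum", "region:depth_stratum")
  )
  if (seasonal) {
    base <- c(base, lapply(base, function(s) c(s, "jday_bin")))
  }
  base[order(vapply(base, length, integer(1)))]
}

prepare_model_data <- function(hauls, stations, taxon) {
  col <- cpue_column(hauls, taxon)
  keep <- c("station_id", "region", "depth_stratum", "bottom_depth_m",
            "distance_to_shore_km")
  d <- merge(as.data.frame(hauls),
             as.data.frame(stations)[, intersect(keep, names(stations))],
             by = "station_id", sort = FALSE)
  d$cpue <- d[[col]]
  if (any(d$cpue < 0)) stop("negative CPUE in haul table", call. = FALSE)
  d$present <- as.integer(d$cpue > 0)
  d$fyear <- factor(d$year)
  d$station_id <- factor(d$station_id)
  d$region <- factor(d$region)
  d$depth_stratum <- factor(d$depth_stratum,
                            levels = intersect(stratum_levels,
                                               unique(d$depth_stratum)))
  d$jday_bin <- factor(10L * (d$julian_day %/% 10L))
  d[order(d$year, d$julian_day, d$haul_id), , drop = FALSE]
}

# Terms usable in this data set (factors need >= 2 observed levels).
usable_term <- function(term, d) {
  vars <- strsplit(term, ":", fixed = TRUE)[[1]]
  all(vapply(vars, function(v) nlevels(droplevels(d[[v]])) >= 2L, logical(1)))
}

submodel_formula <- function(lhs, terms) {
  as.formula(paste(lhs, "~", paste(c("fyear", terms), collapse = " + ")))
}

# Effort-weighted year profile on the link scale: the year coefficient plus
# the mean over reference hauls of all non-year linear-predictor
# contributions. Computed from the fitted model matrix, so with year as the
# only covariate this reproduces the closed-form MLEs exactly.
profile_year_eta <- function(fit) {
  X <- model.matrix(fit)
  beta <- coef(fit)
  beta[is.na(beta)] <- 0
  cm <- colMeans(X)
  yl <- fit$xlevels[["fyear"]]
  ycols <- paste0("fyear", yl[-1])
  eta <- vapply(yl, function(y) {
    v <- cm
    v[intersect(ycols, names(v))] <- 0
    col <- paste0("fyear", y)
    if (col %in% names(v)) v[col] <- 1
    sum(v * beta)
  }, numeric(1))
  names(eta) <- yl
  eta
}

fit_best_submodel <- function(d, lhs, family, candidates, label) {
  ok <- vapply(candidates, function(s) all(vapply(s, usable_term, logical(1),
                                                  d = d)), logical(1))
  if (!any(ok)) stop("no usable candidate covariate set", call. = FALSE)
  if (any(!ok)) {
    candidates <- candidates[ok]
  }
  aic <- rep(NA_real_, length(candidates))
  fits <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    f <- submodel_formula(lhs, candidates[[i]])
    fit <- try(suppressWarnings(glm(f, data = d, family = family)),
               silent = TRUE)
    if (!inherits(fit, "try-error")) {
      fits[[i]] <- fit
      aic[i] <- AIC(fit)
    }
  }
  if (all(is.na(aic))) stop(sprintf("%s submodel failed for every candidate set",
                                    label), call. = FALSE)
  sel <- which(aic <= min(aic, na.rm = TRUE) + 1e-8)[1]  # ties -> smaller set
  list(
    fit = fits[[sel]],
    terms = candidates[[sel]],
    aic_table = data.frame(
      submodel = label,
      covariates = vapply(candidates, function(s) {
        if (length(s) == 0L) "(year only)" else paste(s, collapse = " + ")
      }, character(1)),
      aic = aic,
      selected = seq_along(candidates) == sel,
      stringsAsFactors = FALSE
    )
  )
}

#' Fit a delta-GLM (hurdle) standardization model
#'
#' Fits the binomial occurrence part on all hauls and the lognormal positive
#' part on positive hauls only, with year always a fixed factor and the
#' spatial/seasonal covariate set chosen independently per part by minimum
#' AIC (ties to the smaller set).
#'
#' @param hauls A `haul_table`.
#' @param stations The matching `station_table` (supplies region and depth
#'   stratum).
#' @param taxon Taxon whose `cpue_<taxon>` column is standardized.
#' @param candidate_covariates List of candidate term sets; default
#'   [default_candidate_sets()].
#' @param seasonal Offer Julian-day bins as a covariate (taxa with strong
#'   within-season availability trends).
#'
#' @return A `delta_glm_fit` with per-year occurrence (`p_hat`) and positive
#'   log-mean (`mu_hat`) profiles, selected covariates, full AIC tables,
#'   residual sigma, haul counts, and the fitted submodels.
#' @export
fit_delta_glm <- function(hauls, stations, taxon,
                          candidate_covariates = NULL,
                          seasonal = FALSE) {
  d <- prepare_model_data(hauls, stations, taxon)
  if (nlevels(d$fyear) < 2L) stop("need >= 2 years of data", call. = FALSE)
  if (all(d$present == 0L)) {
    stop(sprintf("taxon '%s' never caught: no index estimable", taxon),
         call. = FALSE)
  }
  candidates <- candidate_covariates %||% default_candidate_sets(seasonal)

  pos <- droplevels(d[d$present == 1L, , drop = FALSE])
  if (nrow(pos) < 2L) {
    stop(sprintf("taxon '%s': fewer than 2 positive hauls; cannot fit the positive model",
                 taxon), call. = FALSE)
  }
  pos$logcpue <- log(pos$cpue)

  years <- levels(d$fyear)
  n_hauls <- as.integer(table(d$fyear))
  n_pos <- as.integer(table(factor(pos$fyear, levels = years)))

  # Occurrence part; degenerate when presence is constant.
  if (all(d$present == 1L)) {
    bin <- NULL
    p_hat <- setNames(rep(1, length(years)), years)
    bin_terms <- character(0)
    bin_aic <- NULL
  } else {
    b <- fit_best_submodel(d, "present", binomial(), candidates, "binomial")
    bin <- b$fit
    bin_terms <- b$terms
    bin_aic <- b$aic_table
    p_hat <- plogis(profile_year_eta(bin))
  }

  p <- fit_best_submodel(pos, "logcpue", gaussian(), candidates, "positive")
  mu_pos <- profile_year_eta(p$fit)
  mu_hat <- setNames(rep(NA_real_, length(years)), years)
  mu_hat[names(mu_pos)] <- mu_pos

  structure(list(
    taxon = taxon,
    years = as.integer(years),
    selected_covariates = list(binomial = bin_terms, positive = p$terms),
    p_hat = p_hat,
    mu_hat = mu_hat,
    residual_sigma = sqrt(deviance(p$fit) / df.residual(p$fit)),
    aic_table = rbind(bin_aic, p$aic_table),
    binomial_fit = bin,
    positive_fit = p$fit,
    n_hauls = setNames(n_hauls, years),
    n_pos = setNames(n_pos, years),
    data = d,
    converged = (is.null(bin) || bin$converged) && p$fit$converged
  ), class = "delta_glm_fit")
}

#' @export
print.delta_glm_fit <- function(x, ...) {
  cat(sprintf("Delta-GLM fit for '%s': %d years, %d hauls (%d positive)\n",
              x$taxon, length(x$years), sum(x$n_hauls), sum(x$n_pos)))
  cat("  binomial covariates:",
      if (length(x$selected_covariates$binomial)) {
        paste(x$selected_covariates$binomial, collapse = " + ")
      } else if (is.null(x$binomial_fit)) "(degenerate: all hauls positive)"
      else "(year only)", "\n")
  cat("  positive covariates:",
      if (length(x$selected_covariates$positive)) {
        paste(x$selected_covariates$positive, collapse = " + ")
      } else "(year only)", "\n")
  cat(sprintf("  residual sigma (log scale): %.3f\n", x$residual_sigma))
  invisible(x)
}

new_index_series <- function(taxon, year, point_index, log_index, se_log,
                             lower, upper, z_score, n_hauls, low_info) {
  out <- data.frame(year = year, point_index = point_index,
                    log_index = log_index, se_log = se_log,
                    lower = lower, upper = upper, z_score = z_score,
                    n_hauls = n_hauls, low_info = low_info,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "taxon") <- taxon
  class(out) <- c("index_series", "data.frame")
  out
}

#' Compute the annual abundance index from a delta-GLM fit
#'
#' Back-transforms the effort-weighted year profiles and multiplies them:
#' `x_y = p_hat_y * exp(mu_hat_y)`. The index is reported on the arithmetic
#' CPUE scale plus its `log(x + 1)` transform and z-score anomalies over the
#' baseline years. Years with no positive catches get `x_y = 0` with a
#' low-information flag. No lognormal back-transform bias correction is
#' applied (`bias_correct = TRUE` adds `exp(sigma^2/2)`, a constant multiplier
#' under homoscedastic sigma that cancels in a relative index).
#'
#' @param fit A `delta_glm_fit`.
#' @param baseline_years Years over which z-scores are standardized (default:
#'   all years in the fit).
#' @param bias_correct Apply the lognormal mean correction (default FALSE).
#' @return An `index_series` data frame.
#' @export
compute_index <- function(fit, baseline_years = NULL, bias_correct = FALSE) {
  stopifnot(inherits(fit, "delta_glm_fit"))
  if (!fit$converged) warning("delta-GLM fit did not fully converge")
  x <- fit$p_hat * exp(fit$mu_hat)
  if (bias_correct) x <- x * exp(fit$residual_sigma^2 / 2)
  low <- !is.finite(x)
  x[low] <- 0
  li <- log1p(x)
  baseline_years <- baseline_years %||% fit$years
  z <- zscore(li, fit$years %in% baseline_years)
  new_index_series(fit$taxon, fit$years, unname(x), unname(li),
                   NA_real_, NA_real_, NA_real_, z,
                   unname(fit$n_hauls), unname(low))
}

#' Naive design-based index: per-year mean of log(CPUE + 1)
#'
#' The survey's historical index: average `log(CPUE + 1)` over all available
#' hauls in a year, with its standard error, and no covariate adjustment.
#' `log_index` holds the mean-log value itself (the index's native scale);
#' `point_index` is its back-transform `expm1(log_index)` for completeness.
#'
#' @param hauls A `haul_table`.
#' @param taxon Taxon name.
#' @param baseline_years Years used to standardize z-scores.
#' @return An `index_series` data frame.
#' @export
naive_index <- function(hauls, taxon, baseline_years = NULL) {
  col <- cpue_column(hauls, taxon)
  yrs <- sort(unique(hauls$year))
  lx <- log1p(hauls[[col]])
  m <- vapply(yrs, function(y) mean(lx[hauls$year == y]), numeric(1))
  se <- vapply(yrs, function(y) {
    v <- lx[hauls$year == y]
    if (length(v) < 2L) NA_real_ else sd(v) / sqrt(length(v))
  }, numeric(1))
  n <- vapply(yrs, function(y) sum(hauls$year == y), integer(1))
  baseline_years <- baseline_years %||% yrs
  z <- zscore(m, yrs %in% baseline_years)
  new_index_series(taxon, yrs, expm1(m), m, se,
                   m - 1.96 * se, m + 1.96 * se, z, n, n < 1L)
}
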