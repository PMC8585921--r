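# Survey effort reduction machinery: focal-year subsetting, relative-bias
# simulation, SE = SD/sqrt(n) extrapolation, and random-exclusion validation.

#' Reduce a focal year to its station-subset hauls
#'
#' Removes all focal-year trawls except the last trawl taken at each station
#' in `station_subset` ("last" resolved by `(julian_day, haul_id)` order).
#' All other years are untouched. Deterministic and idempotent.
#'
#' @param hauls A `haul_table`.
#' @param focal_year Year to reduce.
#' @param station_subset Character vector of station ids (e.g. the flagged
#'   reduced-year stations).
#' @return The reduced `haul_table`.
#' @export
subset_focal_year <- function(hauls, focal_year, station_subset) {
  if (!focal_year %in% hauls$year) {
    stop(sprintf("focal year %s not present in haul table", focal_year),
         call. = FALSE)
  }
  foc <- hauls[hauls$year == focal_year & hauls$station_id %in% station_subset, ,
               drop = FALSE]
  if (nrow(foc) == 0L) {
    stop(sprintf("no focal-year (%s) haul at any subset station", focal_year),
         call. = FALSE)
  }
  foc <- foc[order(foc$station_id, foc$julian_day, foc$haul_id), , drop = FALSE]
  last <- !duplicated(foc$station_id, fromLast = TRUE)
  out <- rbind(hauls[hauls$year != focal_year, , drop = FALSE], foc[last, ,
                                                                    drop = FALSE])
  out <- out[order(out$year, out$julian_day, out$haul_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(hauls)
  out
}

bias_value <- function(x, scale) {
  if (scale == "log1p") log1p(x) else x
}

#' Relative bias of reduced-effort indices across past focal years
#'
#' For each focal year, taxon and estimator, recomputes the index with the
#' focal year reduced to the station subset (model-based refits include the
#' complete data for all non-focal years) and reports the relative bias
#' `(x_sub - x_all)/x_all`. Following the survey's reporting convention, both
#' estimators enter the formula on the log(x + 1) index scale by default
#' (the naive index is itself a mean of log(CPUE + 1)); `scale =
#' "arithmetic"` uses raw point estimates instead.
#'
#' For the model-based estimator, covariates are AIC-selected once per taxon
#' on the full data and held fixed across focal-year refits.
#'
#' @param hauls Full `haul_table`.
#' @param stations Matching `station_table`.
#' @param taxa Character vector of taxa (default: every `cpue_` column).
#' @param focal_years Years to subject to effort reduction (default: all but
#'   the last year, which in a 2020-like scenario is already reduced).
#' @param station_subset Station ids retained in the focal year (default:
#'   flagged stations).
#' @param estimators Subset of `c("naive", "model_based")`.
#' @param candidate_covariates Candidate sets for the model-based estimator.
#' @param seasonal_taxa Taxa for which Julian-day bins are offered.
#' @param scale `"log1p"` (default) or `"arithmetic"`.
#' @return An `effort_reduction_result` data frame: `taxon`, `year`,
#'   `estimator`, `x_sub`, `x_all`, `relative_bias` (NA-flagged where
#'   `x_all = 0`).
#' @export
run_bias_simulation <- function(hauls, stations, taxa = NULL,
                                focal_years = NULL,
                                station_subset = NULL,
                                estimators = c("naive", "model_based"),
                                candidate_covariates = NULL,
                                seasonal_taxa = character(0),
                                scale = c("log1p", "arithmetic")) {
  scale <- match.arg(scale)
  estimators <- match.arg(estimators, several.ok = TRUE)
  taxa <- taxa %||% taxa_in_hauls(hauls)
  yrs <- sort(unique(hauls$year))
  focal_years <- focal_years %||% yrs[-length(yrs)]
  station_subset <- station_subset %||%
    stations$station_id[stations$reduced_year_flag]

  res <- list()
  for (tx in taxa) {
    col <- cpue_column(hauls, tx)
    full_fit <- NULL
    x_all_model <- NULL
    if ("model_based" %in% estimators) {
      full_fit <- fit_delta_glm(hauls, stations, tx,
                                candidate_covariates = candidate_covariates,
                                seasonal = tx %in% seasonal_taxa)
      x_all_model <- compute_index(full_fit)
    }
    naive_all <- if ("naive" %in% estimators) naive_index(hauls, tx) else NULL

    for (fy in focal_years) {
      sub <- try(subset_focal_year(hauls, fy, station_subset), silent = TRUE)
      if (inherits(sub, "try-error")) {
        warning(sprintf("focal year %s: %s", fy, attr(sub, "condition")$message))
        next
      }
      if ("naive" %in% estimators) {
        foc <- sub[sub$year == fy, , drop = FALSE]
        x_sub <- mean(log1p(foc[[col]]))
        x_all <- naive_all$log_index[naive_all$year == fy]
        if (scale == "arithmetic") {
          x_sub <- expm1(x_sub)
          x_all <- expm1(x_all)
        }
        res[[length(res) + 1L]] <- data.frame(
          taxon = tx, year = fy, estimator = "naive",
          x_sub = x_sub, x_all = x_all, stringsAsFactors = FALSE)
      }
      if ("model_based" %in% estimators) {
        dsub <- prepare_model_data(sub, stations, tx)
        x <- try(refit_index_point(dsub,
                                   full_fit$selected_covariates$binomial,
                                   full_fit$selected_covariates$positive,
                                   as.character(fy),
                                   is.null(full_fit$binomial_fit)),
                 silent = TRUE)
        if (inherits(x, "try-error")) {
          warning(sprintf("model refit failed for %s year %s", tx, fy))
          next
        }
        res[[length(res) + 1L]] <- data.frame(
          taxon = tx, year = fy, estimator = "model_based",
          x_sub = bias_value(unname(x), scale),
          x_all = bias_value(x_all_model$point_index[x_all_model$year == fy],
                             scale),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, res)
  out$relative_bias <- ifelse(out$x_all == 0, NA_real_,
                              (out$x_sub - out$x_all) / out$x_all)
  n_und <- sum(is.na(out$relative_bias))
  if (n_und > 0L) {
    message(sprintf("%d cell(s) with x_all = 0 flagged NA and excluded from summaries",
                    n_und))
  }
  attr(out, "scale") <- scale
  class(out) <- c("effort_reduction_result", "data.frame")
  out
}

#' Summarize relative-bias results as boxplot statistics
#'
#' Median, quartiles and 1.5 x IQR whiskers of relative bias per taxon and
#' estimator, the summary displayed in effort-reduction boxplots.
#'
#' @param object An `effort_reduction_result`.
#' @param ... Unused.
#' @return Data frame of per-taxon x estimator boxplot statistics.
#' @export
summary.effort_reduction_result <- function(object, ...) {
  ok <- !is.na(object$relative_bias)
  sp <- split(object[ok, , drop = FALSE],
              list(object$taxon[ok], object$estimator[ok]), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(g) {
    q <- quantile(g$relative_bias, c(0.25, 0.5, 0.75))
    iqr <- q[3] - q[1]
    v <- g$relative_bias
    data.frame(taxon = g$taxon[1], estimator = g$estimator[1],
               n = nrow(g), q1 = q[1], median = q[2], q3 = q[3],
               whisker_lo = min(v[v >= q[1] - 1.5 * iqr]),
               whisker_hi = max(v[v <= q[3] + 1.5 * iqr]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Extrapolate an observed index SE to other sample sizes
#'
#' Applies the standard scaling relationship SE = SD/sqrt(n): the implied SD
#' is `se_obs * sqrt(n_obs)` and the predicted SE at any n is
#' `sd_implied/sqrt(n)`, exactly interpolating the observation at `n_obs`.
#'
#' @param index An `index_series` with `se_log` filled (see
#'   [estimate_uncertainty()] or [naive_index()]).
#' @param year Year whose observed SE anchors the curve.
#' @param n_grid Sample sizes to evaluate (default spans 10-120 trawls).
#' @param reference_n Reference n for percent-change reporting (default
#'   `n_obs`).
#' @return A `precision_curve` list: `taxon`, `year`, `n_obs`, `se_obs`,
#'   `sd_implied`, `mean_log_index`, and a `curve` data frame of `n`,
#'   `predicted_se`, `pct_change_vs_ref`.
#' @export
se_extrapolation <- function(index, year,
                             n_grid = c(10, 15, 20, 30, 40, 62, 90, 120),
                             reference_n = NULL) {
  stopifnot(inherits(index, "data.frame"))
  if (any(n_grid <= 0)) stop("n must be positive", call. = FALSE)
  row <- index[index$year == year, , drop = FALSE]
  if (nrow(row) != 1L || !is.finite(row$se_log)) {
    stop("year must have a known se_log and n_hauls", call. = FALSE)
  }
  n_obs <- row$n_hauls
  se_obs <- row$se_log
  sd_implied <- se_obs * sqrt(n_obs)
  reference_n <- reference_n %||% n_obs
  pred <- sd_implied / sqrt(n_grid)
  ref_se <- sd_implied / sqrt(reference_n)
  structure(list(
    taxon = attr(index, "taxon"),
    year = year,
    n_obs = n_obs,
    se_obs = se_obs,
    sd_implied = sd_implied,
    mean_log_index = row$log_index,
    reference_n = reference_n,
    curve = data.frame(n = n_grid, predicted_se = pred,
                       pct_change_vs_ref = 100 * (pred / ref_se - 1))
  ), class = "precision_curve")
}

#' @export
print.precision_curve <- function(x, ...) {
  cat(sprintf("SE extrapolation (%s, year %s): n_obs = %d, se_obs = %.4f, implied SD = %.4f\n",
              x$taxon %||% "?", x$year, x$n_obs, x$se_obs, x$sd_implied))
  print(x$curve, row.names = FALSE)
  invisible(x)
}

#' Random-exclusion validation of the SE scaling law
#'
#' Randomly excludes all but n trawls from a focal year and recomputes the
#' index SE, for a range of n, comparing the mean recomputed SE against the
#' SD/sqrt(n) prediction anchored at full effort. Two exclusion modes:
#' purely random hauls, or the operationally realistic consecutive trawls
#' from randomly selected nights up to n trawls.
#'
#' @param hauls A `haul_table`.
#' @param taxon Taxon name.
#' @param focal_year Year to subsample.
#' @param n_list Sample sizes (each <= hauls in the focal year).
#' @param mode One or both of `c("purely_random", "consecutive_nights")`.
#' @param reps Replicates per n (>= 20).
#' @param seed Integer seed.
#' @return Data frame of `mode`, `n`, `mean_se`, `sd_se`, `mc_se` (Monte
#'   Carlo error of the mean), `predicted_se`, `reps`.
#' @export
random_exclusion_experiment <- function(hauls, taxon, focal_year,
                                        n_list = c(10, 15, 20, 30, 40),
                                        mode = c("purely_random",
                                                 "consecutive_nights"),
                                        reps = 50, seed = 1) {
  mode <- match.arg(mode, several.ok = TRUE)
  if (reps < 20) stop("reps must be >= 20", call. = FALSE)
  col <- cpue_column(hauls, taxon)
  foc <- hauls[hauls$year == focal_year, , drop = FALSE]
  foc <- foc[order(foc$julian_day, foc$haul_id), , drop = FALSE]
  if (any(n_list > nrow(foc))) {
    stop("n_list values must not exceed the focal-year haul count",
         call. = FALSE)
  }
  lx <- log1p(foc[[col]])
  se_of <- function(idx) sd(lx[idx]) / sqrt(length(idx))
  se_full <- se_of(seq_len(nrow(foc)))
  sd_implied <- se_full * sqrt(nrow(foc))
  nights <- split(seq_len(nrow(foc)), foc$night_id)

  set.seed(seed)
  out <- list()
  for (md in mode) {
    for (n in n_list) {
      ses <- numeric(reps)
      for (r in seq_len(reps)) {
        if (n == nrow(foc)) {
          idx <- seq_len(nrow(foc))
        } else if (md == "purely_random") {
          idx <- sample.int(nrow(foc), n)
        } else {
          ord <- sample(length(nights))
          idx <- integer(0)
          for (k in ord) {
            idx <- c(idx, nights[[k]])
            if (length(idx) >= n) break
          }
          if (length(idx) < n) {
            stop("fewer nights than needed for consecutive_nights mode",
                 call. = FALSE)
          }
          idx <- idx[seq_len(n)]
        }
        ses[r] <- se_of(idx)
      }
      out[[length(out) + 1L]] <- data.frame(
        mode = md, n = n, mean_se = mean(ses), sd_se = sd(ses),
        mc_se = sd(ses) / sqrt(reps),
        predicted_se = sd_implied / sqrt(n), reps = reps,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "se_full") <- se_full
  attr(res, "n_full") <- nrow(foc)
  res
}
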