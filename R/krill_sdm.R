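# Boosted-regression-tree species distribution model for krill: response is
# ln(CPUE + 1) at sampled station-years; covariates are static geomorphic
# features (depth, distance to shore) and dynamic ocean-state proxies.
# Cross-validation folds are blocked by year, because interannual
# transferability is the model's use case.

default_sdm_covariates <- c("depth_m", "distance_to_shore_km", "win_pre",
                            "spr_oce")

sdm_design_matrix <- function(rows, env, covariates) {
  key_env <- paste(env$cell_id, env$year)
  idx <- match(paste(rows$cell_id, rows$year), key_env)
  if (anyNA(idx)) {
    stop("some station-years have no matching environmental cell-year",
         call. = FALSE)
  }
  missing <- setdiff(covariates, names(env))
  if (length(missing)) {
    stop(sprintf("covariate(s) missing from environmental grid: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  as.matrix(env[idx, covariates, drop = FALSE])
}

year_blocked_folds <- function(years, k) {
  uy <- sort(unique(years))
  if (length(uy) < k) k <- length(uy)
  grp <- rep(seq_len(k), length.out = length(uy))  # round-robin over years
  lapply(seq_len(k), function(g) which(years %in% uy[grp == g]))
}

#' Train a boosted-regression-tree krill SDM
#'
#' Gradient-boosted regression trees on `ln(CPUE + 1)` with conventional BRT
#' settings (learning rate 0.01, interaction depth 3, bag fraction 0.5) and
#' the tree count chosen by year-blocked cross-validation with early
#' stopping. A constant response is flagged degenerate (the model then
#' predicts that constant).
#'
#' @param samples Station-level krill `haul_table` with `cell_id`, `year` and
#'   a `cpue_<species>` column (see [simulate_env_and_krill()]).
#' @param env An `env_grid` covering the sampled cell-years.
#' @param species Species name.
#' @param covariates Covariate columns of `env` (default: depth, distance to
#'   shore, winter-preconditioning and spring ocean-state proxies).
#' @param hyper List of `eta`, `max_depth`, `subsample`, `nrounds_max`,
#'   `early_stopping`.
#' @param cv_folds Number of year-blocked folds (default 5).
#' @param seed Integer seed.
#' @return An `sdm_model`: booster, covariates, CV score (held-out RMSE),
#'   chosen tree count, permutation covariate importances, training years.
#' @export
train_sdm <- function(samples, env, species,
                      covariates = default_sdm_covariates,
                      hyper = list(), cv_folds = 5, seed = 1) {
  hy <- modifyList(list(eta = 0.01, max_depth = 3, subsample = 0.5,
                        nrounds_max = 1500, early_stopping = 50), hyper)
  col <- cpue_column(samples, species)
  X <- sdm_design_matrix(samples, env, covariates)
  y <- log1p(samples[[col]])
  train_years <- sort(unique(samples$year))

  if (sd(y) == 0) {
    return(structure(list(species = species, covariates = covariates,
                          degenerate = TRUE, constant = y[1],
                          hyper = hy, training_years = train_years,
                          cv_score = 0, best_nrounds = 0L,
                          importance = setNames(rep(0, length(covariates)),
                                                covariates)),
                     class = "sdm_model"))
  }

  params <- list(objective = "reg:squarederror", eta = hy$eta,
                 max_depth = hy$max_depth, subsample = hy$subsample,
                 nthread = 1, seed = seed)
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  folds <- year_blocked_folds(samples$year, cv_folds)
  set.seed(seed)
  cv <- xgboost::xgb.cv(params = params, data = dtrain,
                        nrounds = hy$nrounds_max, folds = folds,
                        early_stopping_rounds = hy$early_stopping,
                        verbose = 0)
  best <- cv$early_stop$best_iteration %||% cv$best_iteration %||% cv$niter
  cv_score <- min(cv$evaluation_log$test_rmse_mean)
  booster <- xgboost::xgb.train(params = params, data = dtrain, nrounds = best,
                                verbose = 0)

  # Permutation importance: training-RMSE increase when one covariate is
  # shuffled.
  base_rmse <- sqrt(mean((predict(booster, X) - y)^2))
  set.seed(seed + 1L)
  imp <- vapply(seq_along(covariates), function(j) {
    Xp <- X
    Xp[, j] <- Xp[sample.int(nrow(Xp)), j]
    sqrt(mean((predict(booster, Xp) - y)^2)) - base_rmse
  }, numeric(1))
  names(imp) <- covariates

  structure(list(species = species, covariates = covariates,
                 degenerate = FALSE, booster = booster, hyper = hy,
                 training_years = train_years, cv_score = cv_score,
                 best_nrounds = best, cv_log = cv$evaluation_log,
                 importance = imp),
            class = "sdm_model")
}

#' @export
print.sdm_model <- function(x, ...) {
  cat(sprintf("Krill SDM for '%s' (%d training years)\n", x$species,
              length(x$training_years)))
  if (isTRUE(x$degenerate)) {
    cat(sprintf("  degenerate: constant response %.3f\n", x$constant))
  } else {
    cat(sprintf("  %d trees (year-blocked CV), held-out RMSE %.3f\n",
                x$best_nrounds, x$cv_score))
    cat("  permutation importance:",
        paste(sprintf("%s=%.3f", names(x$importance), x$importance),
              collapse = ", "), "\n")
  }
  invisible(x)
}

sdm_predict_matrix <- function(model, X) {
  if (isTRUE(model$degenerate)) rep(model$constant, nrow(X))
  else predict(model$booster, X)
}

#' Predict gridded abundance, climatology and anomalies
#'
#' Predicts `ln(CPUE + 1)` on every grid cell for the requested years, floors
#' predictions at 0 (a negative ln(CPUE + 1) is uninterpretable), computes
#' the per-cell climatology as the mean prediction over `baseline_years`, and
#' reports anomalies (prediction minus climatology, so the anomaly mean over
#' baseline years is exactly zero per cell). Cells beyond `mask_km` from
#' shore are flagged outside the reporting domain. When `stations` (with
#' `cell_id`) is supplied, a per-year mean prediction over those core
#' stations is returned as the SDM index series.
#'
#' @param model An `sdm_model`.
#' @param env An `env_grid`.
#' @param years Years to predict (all must be present in `env`).
#' @param baseline_years Climatology years (subset of `years`).
#' @param stations Optional station table with `cell_id`.
#' @param mask_km Coastal domain half-width (default 150 km).
#' @return An `sdm_prediction`: `grid` (cell x year `pred`, `climatology`,
#'   `anomaly`, `in_domain`), `station_series` (`year`, `mean_pred`), plus
#'   metadata.
#' @export
predict_anomaly <- function(model, env, years, baseline_years,
                            stations = NULL, mask_km = 150) {
  stopifnot(inherits(model, "sdm_model"))
  if (!all(years %in% env$year)) {
    stop(sprintf("environmental grid missing year(s): %s",
                 paste(setdiff(years, env$year), collapse = ", ")),
         call. = FALSE)
  }
  if (!all(baseline_years %in% years)) {
    stop("baseline_years must be a subset of the predicted years",
         call. = FALSE)
  }
  e <- env[env$year %in% years, , drop = FALSE]
  X <- as.matrix(e[, model$covariates, drop = FALSE])
  if (anyNA(X)) {
    bad <- model$covariates[colSums(is.na(X)) > 0]
    stop(sprintf("covariate(s) with missing values: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  pred <- pmax(0, sdm_predict_matrix(model, X))
  grid <- data.frame(cell_id = e$cell_id, year = e$year,
                     distance_to_shore_km = e$distance_to_shore_km,
                     pred = pred, stringsAsFactors = FALSE)
  clim <- tapply(grid$pred[grid$year %in% baseline_years],
                 grid$cell_id[grid$year %in% baseline_years], mean)
  grid$climatology <- as.vector(clim[grid$cell_id])
  grid$anomaly <- grid$pred - grid$climatology
  grid$in_domain <- grid$distance_to_shore_km <= mask_km

  station_series <- NULL
  if (!is.null(stations)) {
    sub <- grid[grid$cell_id %in% stations$cell_id, , drop = FALSE]
    # Weight cells by how many core stations they host.
    w <- table(stations$cell_id)
    sub$w <- as.vector(w[sub$cell_id])
    station_series <- do.call(rbind, lapply(split(sub, sub$year), function(g) {
      data.frame(year = g$year[1],
                 mean_pred = weighted.mean(g$pred, g$w))
    }))
    rownames(station_series) <- NULL
  }

  structure(list(species = model$species, grid = grid,
                 station_series = station_series,
                 baseline_years = baseline_years, mask_km = mask_km),
            class = "sdm_prediction")
}

#' Partial dependence of the SDM on one covariate
#'
#' Average model prediction over the training covariate distribution as one
#' covariate sweeps a grid of values (default: its distinct observed values).
#'
#' @param model An `sdm_model`.
#' @param samples,env Training samples and environmental grid (to rebuild the
#'   covariate distribution).
#' @param covariate Covariate name.
#' @param grid Optional values to sweep.
#' @return Data frame `value`, `partial_dependence`.
#' @export
partial_dependence <- function(model, samples, env, covariate, grid = NULL) {
  stopifnot(covariate %in% model$covariates)
  X <- sdm_design_matrix(samples, env, model$covariates)
  grid <- grid %||% sort(unique(X[, covariate]))
  pd <- vapply(grid, function(v) {
    Xv <- X
    Xv[, covariate] <- v
    mean(sdm_predict_matrix(model, Xv))
  }, numeric(1))
  data.frame(value = grid, partial_dependence = pd)
}

#' Compare the SDM station series with the delta-GLM index
#'
#' Standardizes both series to z-scores over their overlapping years and
#' reports the Pearson correlation with its p-value, plus per-year flags for
#' sign disagreement between the two approaches (one says above-average, the
#' other below-average).
#'
#' @param pred An `sdm_prediction` carrying a `station_series`.
#' @param glm_index An `index_series` from the delta-GLM.
#' @param min_overlap Minimum overlapping years (default 5).
#' @return An `sdm_glm_comparison` list: `r`, `p_value`, `n_years`, and a
#'   per-year data frame with both z-scores and `sign_disagreement`.
#' @export
station_series_compare <- function(pred, glm_index, min_overlap = 5) {
  stopifnot(inherits(pred, "sdm_prediction"))
  if (is.null(pred$station_series)) {
    stop("prediction carries no station series (pass `stations` to predict_anomaly)",
         call. = FALSE)
  }
  yrs <- intersect(pred$station_series$year, glm_index$year)
  if (length(yrs) < min_overlap) {
    stop(sprintf("only %d overlapping years (need >= %d)", length(yrs),
                 min_overlap), call. = FALSE)
  }
  s <- pred$station_series$mean_pred[match(yrs, pred$station_series$year)]
  g <- glm_index$log_index[match(yrs, glm_index$year)]
  zs <- zscore(s)
  zg <- zscore(g)
  ct <- suppressWarnings(cor.test(s, g))
  tab <- data.frame(year = yrs, z_sdm = zs, z_glm = zg,
                    sign_disagreement = sign(zs) != sign(zg))
  structure(list(species = pred$species,
                 r = unname(ct$estimate), p_value = ct$p.value,
                 n_years = length(yrs), by_year = tab,
                 flagged_years = yrs[tab$sign_disagreement]),
            class = "sdm_glm_comparison")
}

#' @export
print.sdm_glm_comparison <- function(x, ...) {
  cat(sprintf("SDM vs delta-GLM series ('%s', %d years): r = %.2f, p = %.3g\n",
              x$species, x$n_years, x$r, x$p_value))
  if (length(x$flagged_years)) {
    cat("  sign disagreement in:", paste(x$flagged_years, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Patchiness diagnostics: observed vs predicted station CPUE
#'
#' Per year: the coefficient of variation of observed station CPUE, the CV of
#' SDM-predicted CPUE at the same stations, and summaries of the residual
#' (predicted minus observed, CPUE scale). A smooth SDM cannot capture
#' swarm-scale patchiness, so its CV is expected to sit below the observed CV
#' when patchiness noise is present.
#'
#' @param observed Station krill `haul_table` with `cell_id` and a
#'   `cpue_<species>` column.
#' @param pred An `sdm_prediction` for the same species.
#' @return Data frame `year`, `n`, `cv_obs`, `cv_pred`, `resid_mean`,
#'   `resid_sd`.
#' @export
patchiness_diagnostics <- function(observed, pred) {
  stopifnot(inherits(pred, "sdm_prediction"))
  col <- cpue_column(observed, pred$species)
  key <- paste(pred$grid$cell_id, pred$grid$year)
  idx <- match(paste(observed$cell_id, observed$year), key)
  if (anyNA(idx)) stop("observed station-years not covered by the prediction",
                       call. = FALSE)
  obs <- observed[[col]]
  prd <- expm1(pred$grid$pred[idx])  # back to the CPUE scale
  resid <- prd - obs
  cv <- function(v) if (mean(v) == 0) NA_real_ else sd(v) / mean(v)
  out <- do.call(rbind, lapply(split(seq_along(obs), observed$year),
                               function(ii) {
    data.frame(year = observed$year[ii[1]], n = length(ii),
               cv_obs = cv(obs[ii]), cv_pred = cv(prd[ii]),
               resid_mean = mean(resid[ii]), resid_sd = sd(resid[ii]))
  }))
  rownames(out) <- NULL
  out
}
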