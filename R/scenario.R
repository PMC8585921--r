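# Scenario configuration: a structured-text (YAML) file fully determines a
# simulation + analysis run, and every output carries its hash.

#' Build a scenario configuration
#'
#' Collects the seed, survey design, per-taxon ground truth, effort schedule
#' and analysis options into a single validated list that round-trips
#' losslessly through [write_scenario()]/[read_scenario()].
#'
#' @param seed Master seed.
#' @param years Survey years.
#' @param n_stations,strata_spec Design arguments (see [make_design()]).
#' @param hauls_per_year Effort in normal years.
#' @param reduced_years Years restricted to the flagged station subset.
#' @param taxa List of [taxon_params()].
#' @param estimator Options list: `candidate_covariates` (NULL = defaults),
#'   `seasonal_taxa`, `uncertainty_method`, `n_draws`.
#' @param effort Options list: `n_grid`, `reps`.
#' @param calibration Options list: `slope`, `intercept`, `noise_sd`,
#'   `pairing_years` (NULL = all).
#' @param sdm Options list: `hyper`, `baseline_years`, `mask_km`,
#'   `patchiness_sd`.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(seed = 1,
                            years = 1990:2020,
                            n_stations = 35,
                            strata_spec = c(shelf = 0.6, slope = 0.3,
                                            deep = 0.1),
                            hauls_per_year = 62,
                            reduced_years = max(years),
                            taxa = default_taxa(years),
                            estimator = list(),
                            effort = list(),
                            calibration = list(),
                            sdm = list()) {
  estimator <- modifyList(list(candidate_covariates = NULL,
                               seasonal_taxa = "yoy_rockfish",
                               uncertainty_method = "bootstrap",
                               n_draws = 500), estimator)
  effort <- modifyList(list(n_grid = c(10, 15, 20, 30, 40, 62, 90, 120),
                            reps = 50), effort)
  calibration <- modifyList(list(slope = 0.15, intercept = 0.05,
                                 noise_sd = 0.05, pairing_years = NULL),
                            calibration)
  sdm <- modifyList(list(hyper = list(), baseline_years = NULL,
                         mask_km = 150, patchiness_sd = 0.6), sdm)
  # NULL-valued options mean "package default"; drop them so the config is
  # canonical and round-trips through YAML unchanged.
  drop_nulls <- function(x) x[!vapply(x, is.null, logical(1))]
  estimator <- drop_nulls(estimator)
  effort <- drop_nulls(effort)
  calibration <- drop_nulls(calibration)
  sdm <- drop_nulls(sdm)
  for (tx in taxa) stopifnot(inherits(tx, "taxon_params"))
  if (!all(reduced_years %in% years)) {
    stop("reduced_years must be within years", call. = FALSE)
  }
  structure(list(
    seed = as.integer(seed),
    years = as.integer(years),
    n_stations = as.integer(n_stations),
    strata_spec = strata_spec,
    hauls_per_year = as.integer(hauls_per_year),
    reduced_years = as.integer(reduced_years),
    taxa = taxa,
    estimator = estimator, effort = effort,
    calibration = calibration, sdm = sdm
  ), class = "scenario_config")
}

#' Default 31-year scenario
#'
#' The package's reference conditions: a 35-station core-area design, 31
#' survey years at 62 hauls per year, the final year reduced to one haul at
#' each of the 15 flagged inshore stations, and the four default taxa
#' spanning nearshore, offshore and neutral depth associations.
#'
#' @param seed Master seed.
#' @return A `scenario_config`.
#' @export
default_scenario <- function(seed = 1) scenario_config(seed = seed)

#' Write / read a scenario configuration (YAML)
#'
#' @param config A `scenario_config`.
#' @param path File path.
#' @export
write_scenario <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  ser <- unclass(config)
  ser$strata_spec <- as.list(ser$strata_spec)
  ser$taxa <- lapply(ser$taxa, function(tx) {
    t2 <- unclass(tx)
    t2$year_effects <- as.list(t2$year_effects)
    t2$region_effects <- as.list(t2$region_effects)
    t2
  })
  yaml::write_yaml(ser, path, precision = 15)
  invisible(path)
}

#' @rdname write_scenario
#' @return `read_scenario()` returns the reconstructed `scenario_config`.
#' @export
read_scenario <- function(path) {
  ser <- yaml::read_yaml(path)
  taxa <- lapply(ser$taxa, function(t2) {
    taxon_params(
      taxon = t2$taxon,
      year_effects = unlist(t2$year_effects),
      occurrence_intercept = t2$occurrence_intercept,
      depth_association = t2$depth_association,
      region_effects = unlist(t2$region_effects),
      sigma_log = t2$sigma_log,
      patchiness_cv = t2$patchiness_cv,
      seasonal_slope = t2$seasonal_slope
    )
  })
  scenario_config(
    seed = ser$seed, years = ser$years, n_stations = ser$n_stations,
    strata_spec = unlist(ser$strata_spec),
    hauls_per_year = ser$hauls_per_year,
    reduced_years = ser$reduced_years,
    taxa = taxa,
    estimator = ser$estimator %||% list(),
    effort = ser$effort %||% list(),
    calibration = ser$calibration %||% list(),
    sdm = ser$sdm %||% list()
  )
}

#' Hash of a scenario configuration
#'
#' MD5 of the canonical YAML serialization; stamped into every output file
#' for provenance checks.
#'
#' @param config A `scenario_config`.
#' @return Hex string.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  write_scenario(config, tf)
  unname(tools::md5sum(tf))
}

#' Simulate a full scenario
#'
#' Runs [make_design()] and [simulate_hauls()] under the configuration.
#'
#' @param config A `scenario_config`.
#' @return List with `config`, `stations`, `hauls`.
#' @export
simulate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  stations <- make_design(config$n_stations, config$strata_spec,
                          seed = config$seed)
  hauls <- simulate_hauls(stations, config$taxa, config$years,
                          hauls_per_year = config$hauls_per_year,
                          reduced_years = config$reduced_years,
                          seed = config$seed + 1L)
  list(config = config, stations = stations, hauls = hauls)
}

#' Run a scenario end-to-end and write its artifacts
#'
#' Simulates the survey, fits the delta-GLM index (with uncertainty) and the
#' naive index for every taxon, runs the effort-reduction bias simulation,
#' and writes CSV outputs plus a run log carrying the seed and config hash.
#'
#' @param config A `scenario_config`.
#' @param out_dir Output directory (created if needed).
#' @param uncertainty Compute index uncertainty (default TRUE; the slowest
#'   stage).
#' @return Invisibly, a list of the in-memory results.
#' @export
run_scenario <- function(config, out_dir, uncertainty = TRUE) {
  stopifnot(inherits(config, "scenario_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  logf <- file.path(out_dir, "run_log.txt")
  logline <- function(...) cat(sprintf(...), "\n", file = logf, append = TRUE,
                               sep = "")
  cat(sprintf("trawlindex %s run\nconfig_hash: %s\nseed: %d\nstarted: %s\n",
              as.character(utils::packageVersion("trawlindex")), hash,
              config$seed, format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
      file = logf)

  sim <- simulate_scenario(config)
  write_scenario(config, file.path(out_dir, "scenario.yaml"))
  write_station_table(sim$stations, file.path(out_dir, "stations.csv"))
  write_haul_table(sim$hauls, file.path(out_dir, "hauls.csv"))
  logline("INFO simulated %d hauls over %d years", nrow(sim$hauls),
          length(config$years))

  indices <- list()
  for (nm in names(config$taxa)) {
    fit <- fit_delta_glm(sim$hauls, sim$stations, nm,
                         candidate_covariates = config$estimator$candidate_covariates,
                         seasonal = nm %in% config$estimator$seasonal_taxa)
    idx <- if (uncertainty) {
      estimate_uncertainty(fit, method = config$estimator$uncertainty_method,
                           n_draws = config$estimator$n_draws,
                           seed = config$seed + 2L)
    } else {
      compute_index(fit)
    }
    nv <- naive_index(sim$hauls, nm)
    indices[[nm]] <- list(fit = fit, model = idx, naive = nv)
    write_index_series(idx, file.path(out_dir, sprintf("index_%s.csv", nm)))
    write_index_series(nv, file.path(out_dir, sprintf("naive_index_%s.csv",
                                                      nm)))
    logline("INFO fitted %s: covariates [%s | %s]", nm,
            paste(fit$selected_covariates$binomial, collapse = "+"),
            paste(fit$selected_covariates$positive, collapse = "+"))
  }

  bias <- run_bias_simulation(sim$hauls, sim$stations,
                              taxa = names(config$taxa),
                              seasonal_taxa = config$estimator$seasonal_taxa,
                              candidate_covariates = config$estimator$candidate_covariates)
  write.csv(cbind(as.data.frame(bias), config_hash = hash),
            file.path(out_dir, "effort_bias.csv"), row.names = FALSE)
  logline("INFO effort-reduction bias table: %d cells (%d NA)", nrow(bias),
          sum(is.na(bias$relative_bias)))
  logline("INFO done: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  invisible(list(sim = sim, indices = indices, bias = bias,
                 config_hash = hash))
}
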