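#' Ground-truth parameters for a simulated taxon
#'
#' Bundles the generative parameters of one taxon under the hurdle
#' (delta-lognormal) catch model: a Bernoulli occurrence part and a lognormal
#' positive-catch part. The per-year log-abundance effects `year_effects` drive
#' the positive-catch mean; `depth_association` and `region_effects` act on
#' both hurdle parts, so a `depth_stratum` + `region` covariate set is the
#' correctly specified spatial model for data simulated from these parameters.
#'
#' @param taxon Taxon name (used to label the `cpue_<taxon>` column).
#' @param year_effects Named numeric vector of true per-year log-abundance
#'   effects (names are years); must be finite.
#' @param occurrence_intercept Logit-scale occurrence intercept.
#' @param depth_association Signed coefficient on the nearshore depth score
#'   (shelf +1, slope -0.5, deep -1): positive = nearshore, negative =
#'   offshore association.
#' @param region_effects Optional named offsets per region (log / logit scale);
#'   unnamed regions get 0.
#' @param sigma_log Positive SD of the log positive catch.
#' @param patchiness_cv Target coefficient of variation of a multiplicative
#'   station-by-year patch effect (0 = smooth field).
#' @param seasonal_slope Per-day slope of log abundance around day 150
#'   (rockfish-like taxa with strongly seasonal availability; 0 otherwise).
#'
#' @return A `taxon_params` list.
#' @export
taxon_params <- function(taxon,
                         year_effects,
                         occurrence_intercept = 1.5,
                         depth_association = 0,
                         region_effects = NULL,
                         sigma_log = 0.9,
                         patchiness_cv = 0,
                         seasonal_slope = 0) {
  stopifnot(is.character(taxon), length(taxon) == 1L)
  if (!is.numeric(year_effects) || is.null(names(year_effects)) ||
      any(!is.finite(year_effects))) {
    stop("year_effects must be a named, finite numeric vector", call. = FALSE)
  }
  assert_scalar_number(sigma_log, "sigma_log", lower = 1e-12)
  assert_scalar_number(patchiness_cv, "patchiness_cv", lower = 0)
  structure(list(
    taxon = taxon,
    year_effects = year_effects,
    occurrence_intercept = occurrence_intercept,
    depth_association = depth_association,
    region_effects = region_effects %||% c(north = 0, central = 0, south = 0),
    sigma_log = sigma_log,
    patchiness_cv = patchiness_cv,
    seasonal_slope = seasonal_slope
  ), class = "taxon_params")
}

#' Default four-taxon community spanning habitat associations
#'
#' Builds the standard simulated community used throughout the package:
#' a seasonal nearshore rockfish-like taxon, a strongly nearshore anchovy-like
#' taxon, an offshore myctophid-like taxon and a depth-neutral sanddab-like
#' taxon. Year effects follow a smoothed random walk so that abundance shows
#' multi-year persistence, as forage time series do.
#'
#' @param years Integer vector of survey years.
#' @param seed Seed for the year-effect random walks.
#' @return Named list of [taxon_params()] objects.
#' @export
default_taxa <- function(years, seed = 42) {
  set.seed(seed)
  walk <- function(base, sd = 0.35) {
    w <- base + cumsum(rnorm(length(years), 0, sd))
    w <- w - mean(w) + base
    names(w) <- years
    w
  }
  list(
    yoy_rockfish = taxon_params("yoy_rockfish", walk(2.2),
                                occurrence_intercept = 1.6,
                                depth_association = 1.0,
                                sigma_log = 0.9,
                                patchiness_cv = 0.3,
                                seasonal_slope = -0.015),
    anchovy = taxon_params("anchovy", walk(1.8, 0.45),
                           occurrence_intercept = 1.2,
                           depth_association = 1.3,
                           sigma_log = 1.0,
                           patchiness_cv = 0.3),
    myctophids = taxon_params("myctophids", walk(2.0, 0.3),
                              occurrence_intercept = 1.4,
                              depth_association = -1.3,
                              sigma_log = 0.9,
                              patchiness_cv = 0.3),
    sanddab = taxon_params("sanddab", walk(2.0, 0.3),
                           occurrence_intercept = 1.5,
                           depth_association = 0,
                           sigma_log = 0.9,
                           patchiness_cv = 0.3)
  )
}

#' Simulate haul-level trawl catches under the hurdle model
#'
#' Draws one row per 15-minute standardized tow. Normal years spread
#' `hauls_per_year` hauls across the whole design (stations revisited in
#' rotation); reduced years conduct exactly one haul at each flagged station,
#' later in the season, emulating a year in which only the inshore subset
#' could be sampled. Catch for each taxon is Bernoulli(occurrence) x
#' LogNormal(year + depth + region [+ season + patch] effects, sigma_log),
#' optionally rounded to integer counts; hauls whose rounded count is 0 are
#' zeros in the hurdle sense.
#'
#' @param design A `station_table` from [make_design()].
#' @param taxa List of [taxon_params()].
#' @param years Integer years to simulate.
#' @param hauls_per_year Hauls per normal year (default 62, the survey's
#'   long-term core-area average). May be a vector matched to `years`.
#' @param reduced_years Years restricted to the flagged station subset.
#' @param seed Integer seed; output is byte-identical given it.
#' @param round_counts Round continuous catches to integer counts (default
#'   TRUE). Turn off when an exactly lognormal positive part is wanted.
#' @param season,reduced_season Day-of-year windows (defaults 121-180 and the
#'   late 160-177 window for reduced years).
#'
#' @return A `haul_table` data frame: `haul_id`, `year`, `julian_day`,
#'   `night_id`, `station_id`, and one `cpue_<taxon>` column per taxon.
#' @export
simulate_hauls <- function(design, taxa, years,
                           hauls_per_year = 62,
                           reduced_years = integer(),
                           seed = 1,
                           round_counts = TRUE,
                           season = c(121, 180),
                           reduced_season = c(160, 177)) {
  stopifnot(inherits(design, "data.frame"), length(years) >= 1L)
  if (!all(reduced_years %in% years)) {
    stop("reduced_years must be a subset of years", call. = FALSE)
  }
  hauls_per_year <- rep_len(hauls_per_year, length(years))
  if (any(hauls_per_year < 1)) stop("hauls_per_year must be >= 1", call. = FALSE)
  for (tx in taxa) {
    if (!inherits(tx, "taxon_params")) stop("taxa must be taxon_params objects",
                                            call. = FALSE)
    if (!all(as.character(years) %in% names(tx$year_effects))) {
      stop(sprintf("taxon '%s' lacks year effects for some requested years",
                   tx$taxon), call. = FALSE)
    }
  }

  set.seed(seed)
  flagged <- design$station_id[design$reduced_year_flag]
  rows <- vector("list", length(years))

  for (i in seq_along(years)) {
    yr <- years[i]
    reduced <- yr %in% reduced_years
    if (reduced) {
      st <- flagged
      win <- reduced_season
    } else {
      st <- rep(design$station_id, length.out = hauls_per_year[i])
      win <- season
    }
    n <- length(st)
    # Hauls proceed station-by-station through the grid; days increase with
    # haul order, ~3 hauls per night.
    day <- sort(round(seq(win[1], win[2], length.out = n) +
                        runif(n, -1.5, 1.5)))
    day <- pmin(win[2], pmax(win[1], day))
    night <- sprintf("%d_N%02d", yr, ceiling(seq_len(n) / 3))
    h <- data.frame(
      haul_id = sprintf("%d_H%03d", yr, seq_len(n)),
      year = yr,
      julian_day = day,
      night_id = night,
      station_id = st,
      stringsAsFactors = FALSE
    )
    rows[[i]] <- h
  }
  hauls <- do.call(rbind, rows)
  rownames(hauls) <- NULL

  idx <- match(hauls$station_id, design$station_id)
  zdep <- stratum_score[design$depth_stratum[idx]]
  reg <- design$region[idx]

  for (tx in taxa) {
    regeff <- tx$region_effects[reg]
    regeff[is.na(regeff)] <- 0
    eta_occ <- tx$occurrence_intercept + tx$depth_association * zdep + regeff
    lam <- tx$year_effects[as.character(hauls$year)]
    mu <- lam + tx$depth_association * zdep + regeff +
      tx$seasonal_slope * (hauls$julian_day - 150)
    if (tx$patchiness_cv > 0) {
      sd_patch <- sqrt(log(1 + tx$patchiness_cv^2))
      key <- paste(hauls$station_id, hauls$year)
      uk <- unique(key)
      patch <- rnorm(length(uk), -sd_patch^2 / 2, sd_patch)
      names(patch) <- uk
      mu <- mu + patch[key]
    }
    occ <- rbinom(nrow(hauls), 1L, plogis(eta_occ))
    pos <- rlnorm(nrow(hauls), meanlog = mu, sdlog = tx$sigma_log)
    catch <- occ * pos
    if (round_counts) catch <- round(catch)
    hauls[[paste0("cpue_", tx$taxon)]] <- catch
  }
  class(hauls) <- c("haul_table", "data.frame")
  hauls
}
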