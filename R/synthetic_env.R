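#' Default krill-like species response surfaces
#'
#' Two euphausiid archetypes on the ln(CPUE+1) scale: a neritic species with a
#' nearshore distance-to-shore dome and a strong response to the
#' winter-preconditioning covariate, and an offshore species peaking over the
#' outer slope with a stronger spring ocean-state response.
#'
#' @return Named list of response-parameter lists with elements `species`,
#'   `peak_km`, `width_km`, `amp`, `beta_winter`, `beta_spring`.
#' @export
default_krill_species <- function() {
  list(
    tspin = list(species = "tspin", peak_km = 12, width_km = 18, amp = 3.5,
                 beta_winter = 0.5, beta_spring = 0.2),
    epac = list(species = "epac", peak_km = 45, width_km = 25, amp = 3.8,
                beta_winter = 0.15, beta_spring = 0.35)
  )
}

krill_truth_ln <- function(sp, dist, win, spr, year_term) {
  pmax(0, sp$amp * exp(-(dist - sp$peak_km)^2 / (2 * sp$width_km^2)) +
         sp$beta_winter * win + sp$beta_spring * spr + year_term)
}

#' Simulate environmental fields and krill station samples with known truth
#'
#' Builds a coastal grid (static depth and distance-to-shore plus two dynamic
#' covariates: a winter-preconditioning proxy and a spring ocean-state proxy),
#' evaluates each species' smooth response surface on it to obtain a true
#' ln(CPUE+1) abundance field, and samples the core stations with
#' multiplicative lognormal patchiness noise — the swarm-scale variability a
#' fixed-station trawl sees but a smooth SDM cannot.
#'
#' @param stations A `station_table`; each station is assigned the grid cell
#'   nearest to it in cross-shore distance. Stations beyond the grid extent
#'   are an error.
#' @param species List of response-parameter lists (see
#'   [default_krill_species()]), or functions `f(dist, win, spr, year_term)`
#'   returning truth on the ln(CPUE+1) scale.
#' @param years Years to simulate (>= 10 recommended for train/holdout use).
#' @param grid_spec List with `nx` (cross-shore cells), `ny` (alongshore
#'   rows), `max_dist_km` (grid extent).
#' @param patchiness_sd SD (log scale) of the mean-one multiplicative
#'   lognormal noise on station samples; 0 returns truth exactly.
#' @param year_terms Optional named-list override, per species, of the
#'   interannual term (named by year); defaults to N(0, year_term_sd) draws.
#' @param year_levels Optional data frame `year`, `win_pre`, `spr_oce` fixing
#'   the yearly levels of the dynamic covariates; defaults to N(0,1) draws.
#' @param year_term_sd SD of the default interannual term (default 0.2, so
#'   interannual signal is carried mostly by the dynamic covariates).
#' @param seed Integer seed.
#'
#' @return List with `env` (an `env_grid`: one row per cell x year with
#'   covariate columns), `truth` (cell x year x species ln(CPUE+1)), `hauls`
#'   (a station-level krill `haul_table` with `cell_id`), `stations` (input
#'   table plus `cell_id`), `year_levels`, and `year_terms`.
#' @export
simulate_env_and_krill <- function(stations,
                                   species = default_krill_species(),
                                   years = 2002:2020,
                                   grid_spec = list(nx = 24, ny = 8,
                                                    max_dist_km = 180),
                                   patchiness_sd = 0.6,
                                   year_terms = NULL,
                                   year_levels = NULL,
                                   year_term_sd = 0.2,
                                   seed = 1) {
  stopifnot(length(years) >= 2L, length(species) >= 1L)
  assert_scalar_number(patchiness_sd, "patchiness_sd", lower = 0)
  nx <- grid_spec$nx %||% 24
  ny <- grid_spec$ny %||% 8
  max_dist <- grid_spec$max_dist_km %||% 180

  set.seed(seed)
  dist_axis <- seq(3, max_dist, length.out = nx)
  cells <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  cells$cell_id <- sprintf("C%02d_%02d", cells$ix, cells$iy)
  cells$distance_to_shore_km <- dist_axis[cells$ix]
  # Depth deepens quadratically offshore; cell-level lognormal relief
  # (canyons, banks) keeps depth from being a pure function of distance.
  cells$depth_m <- round(pmin(3500, (25 + 2900 *
                                       (cells$distance_to_shore_km / max_dist)^2) *
                                exp(rnorm(nrow(cells), 0, 0.35))), 1)
  cells$longitude <- round(-123 - cells$distance_to_shore_km / 85, 4)
  cells$latitude <- round(36 + 2 * (cells$iy - 1) / max(1, ny - 1), 4)

  if (is.null(year_levels)) {
    year_levels <- data.frame(year = years,
                              win_pre = rnorm(length(years)),
                              spr_oce = rnorm(length(years)))
  } else {
    if (!all(years %in% year_levels$year)) {
      stop("year_levels must cover every simulated year", call. = FALSE)
    }
    year_levels <- year_levels[match(years, year_levels$year), ]
  }

  env <- do.call(rbind, lapply(seq_along(years), function(i) {
    e <- cells[c("cell_id", "longitude", "latitude", "depth_m",
                 "distance_to_shore_km")]
    e$year <- years[i]
    # Dynamic fields: yearly level plus a smooth cross-shore gradient.
    e$win_pre <- round(year_levels$win_pre[i] +
                         0.25 * cos(pi * cells$ix / nx), 4)
    e$spr_oce <- round(year_levels$spr_oce[i] +
                         0.25 * sin(pi * cells$iy / ny), 4)
    e
  }))
  rownames(env) <- NULL
  class(env) <- c("env_grid", "data.frame")

  if (is.null(year_terms)) {
    year_terms <- lapply(species, function(sp) {
      yt <- rnorm(length(years), 0, year_term_sd)
      names(yt) <- years
      yt
    })
  } else {
    year_terms <- lapply(year_terms, function(yt) {
      if (!all(as.character(years) %in% names(yt))) {
        stop("year_terms must be named by every simulated year", call. = FALSE)
      }
      yt
    })
  }

  truth <- env[c("cell_id", "year", "distance_to_shore_km")]
  for (k in seq_along(species)) {
    sp <- species[[k]]
    yt <- year_terms[[k]][as.character(env$year)]
    L <- if (is.function(sp)) {
      sp(env$distance_to_shore_km, env$win_pre, env$spr_oce, yt)
    } else {
      krill_truth_ln(sp, env$distance_to_shore_km, env$win_pre, env$spr_oce, yt)
    }
    nm <- if (is.function(sp)) names(species)[k] else sp$species
    truth[[paste0("ln_", nm)]] <- L
  }

  # Map stations to nearest cross-shore cell, alongshore row round-robin.
  if (any(stations$distance_to_shore_km > max_dist)) {
    bad <- stations$station_id[stations$distance_to_shore_km > max_dist]
    stop(sprintf("station(s) outside grid extent (> %g km from shore): %s",
                 max_dist, paste(bad, collapse = ", ")), call. = FALSE)
  }
  st <- as.data.frame(stations)
  ixs <- vapply(st$distance_to_shore_km,
                function(d) which.min(abs(dist_axis - d)), integer(1))
  iys <- rep(seq_len(ny), length.out = nrow(st))
  st$cell_id <- sprintf("C%02d_%02d", ixs, iys)

  hauls <- do.call(rbind, lapply(seq_along(years), function(i) {
    data.frame(
      haul_id = sprintf("%d_K%02d", years[i], seq_len(nrow(st))),
      year = years[i],
      julian_day = 150L,
      night_id = sprintf("%d_N%02d", years[i], ceiling(seq_len(nrow(st)) / 3)),
      station_id = st$station_id,
      cell_id = st$cell_id,
      stringsAsFactors = FALSE
    )
  }))
  rownames(hauls) <- NULL
  key_truth <- paste(truth$cell_id, truth$year)
  key_haul <- paste(hauls$cell_id, hauls$year)
  for (k in seq_along(species)) {
    nm <- if (is.function(species[[k]])) names(species)[k] else species[[k]]$species
    L <- truth[[paste0("ln_", nm)]][match(key_haul, key_truth)]
    noise <- if (patchiness_sd > 0) {
      rlnorm(nrow(hauls), -patchiness_sd^2 / 2, patchiness_sd)
    } else 1
    hauls[[paste0("cpue_", nm)]] <- expm1(L) * noise
  }
  class(hauls) <- c("haul_table", "data.frame")

  list(env = env, truth = truth, hauls = hauls, stations = st,
       year_levels = year_levels, year_terms = year_terms)
}
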