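#' Generate a stratified fixed-station survey design
#'
#' Lays out a core-area station grid spanning continental shelf, outer slope
#' and deep strata, and flags the 15-station inshore-biased subset that a
#' degraded ("pandemic-year") survey would be restricted to. Flagged stations
#' are the shallowest in the design, so a reduced year is always spatially
#' biased towards inshore (shallow) stations.
#'
#' @param n_stations Total number of stations (>= `n_reduced`). Defaults to 35,
#'   a core-area-sized grid.
#' @param strata_spec Named proportions over `c("shelf","slope","deep")`
#'   summing to 1. Strata follow the survey's depth conventions: shelf < 200 m,
#'   slope 200-1500 m, deep > 1500 m.
#' @param n_reduced Size of the reduced-year station subset (default 15).
#' @param seed Integer seed; the design is deterministic given it.
#'
#' @return A `station_table` data frame with columns `station_id`, `region`,
#'   `depth_stratum`, `bottom_depth_m`, `distance_to_shore_km`,
#'   `reduced_year_flag`.
#' @export
make_design <- function(n_stations = 35,
                        strata_spec = c(shelf = 0.6, slope = 0.3, deep = 0.1),
                        n_reduced = 15,
                        seed = 1) {
  if (n_stations < n_reduced) {
    stop(sprintf(paste0("n_stations (%d) < %d: design cannot host the ",
                        "reduced-year station subset"), n_stations, n_reduced),
         call. = FALSE)
  }
  if (is.null(names(strata_spec)) || !all(names(strata_spec) %in% stratum_levels)) {
    stop("strata_spec must be named with levels shelf/slope/deep", call. = FALSE)
  }
  if (abs(sum(strata_spec) - 1) > 1e-8) {
    stop("strata_spec proportions must sum to 1", call. = FALSE)
  }
  strata_spec <- strata_spec[strata_spec > 0]

  set.seed(seed)
  # Integer allocation preserving the total exactly.
  cum <- round(cumsum(strata_spec) * n_stations)
  counts <- diff(c(0L, cum))
  stratum <- rep(names(strata_spec), counts)

  depth <- vapply(stratum, function(s) {
    r <- stratum_depth_range[[s]]
    exp(runif(1, log(r[1]), log(r[2])))  # log-uniform within stratum
  }, numeric(1))

  # Distance from shore grows with depth on this margin, plus mesoscale scatter.
  dist <- 2 + 55 * (log(depth) - log(25)) / (log(3000) - log(25)) +
    rnorm(n_stations, 0, 4)
  dist <- pmax(0.5, dist)

  region <- rep(c("north", "central", "south"), length.out = n_stations)
  region <- sample(region)  # decouple region from stratum ordering

  st <- data.frame(
    station_id = sprintf("S%02d", seq_len(n_stations)),
    region = region,
    depth_stratum = stratum,
    bottom_depth_m = round(depth, 1),
    distance_to_shore_km = round(dist, 2),
    reduced_year_flag = FALSE,
    stringsAsFactors = FALSE
  )
  rownames(st) <- NULL
  st$reduced_year_flag <- rank(st$bottom_depth_m, ties.method = "first") <= n_reduced
  class(st) <- c("station_table", "data.frame")
  st
}
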