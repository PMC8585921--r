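# Shared fixture builders; everything is generated in code at test time.

# The 2-year x 4-haul worked example with closed-form year-only MLEs:
# p = (0.5, 0.5), mu = (mean log{3,9}, mean log{2,2}),
# x = (0.5 * sqrt(27), 1.0).
worked_example <- function() {
  stations <- data.frame(
    station_id = paste0("S", 1:4), region = "central",
    depth_stratum = "shelf", bottom_depth_m = 100,
    distance_to_shore_km = 10, reduced_year_flag = FALSE,
    stringsAsFactors = FALSE)
  hauls <- data.frame(
    haul_id = sprintf("H%d", 1:8), year = rep(1:2, each = 4),
    julian_day = rep(130:133, 2), night_id = rep(c("n1", "n2"), each = 4),
    station_id = rep(stations$station_id, 2),
    cpue_t = c(0, 0, 3, 9, 0, 2, 2, 0), stringsAsFactors = FALSE)
  list(stations = stations, hauls = hauls)
}

# A compact survey scenario for module tests.
small_scenario <- function(years = 2000:2005, hauls_per_year = 40,
                           reduced_years = integer(), seed = 2,
                           taxa = NULL, n_stations = 30, ...) {
  stations <- make_design(n_stations, seed = seed)
  taxa <- taxa %||% default_taxa(years, seed = seed + 100)
  hauls <- simulate_hauls(stations, taxa, years,
                          hauls_per_year = hauls_per_year,
                          reduced_years = reduced_years, seed = seed + 1, ...)
  list(stations = stations, taxa = taxa, hauls = hauls, years = years)
}

# One taxon with no covariate structure: the year-only delta-GLM is exactly
# correctly specified and the generative truth is p * exp(lambda).
flat_taxon <- function(years, lambda, occ = 1.5, sigma = 0.8, name = "flat") {
  le <- rep_len(lambda, length(years))
  names(le) <- years
  taxon_params(name, le, occurrence_intercept = occ, depth_association = 0,
               sigma_log = sigma, patchiness_cv = 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
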