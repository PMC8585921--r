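# Plain-CSV readers/writers with validation. All tables are UTF-8 CSV with a
# header row; unknown columns are preserved. The gridded environment uses a
# long format (cell_id, year, covariate, value; static covariates carry an
# empty year) to avoid binary-format commitments.

read_validated_csv <- function(path, required, label) {
  if (!file.exists(path)) stop(sprintf("%s file not found: %s", label, path),
                               call. = FALSE)
  d <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  miss <- setdiff(required, names(d))
  if (length(miss)) {
    stop(sprintf("%s file %s is missing required column(s): %s", label, path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  d
}

#' Read / write a haul table
#'
#' CSV schema: `haul_id`, `year`, `julian_day`, `station_id`, plus one or
#' more `cpue_<taxon>` columns (and optionally `night_id`). Malformed rows
#' are reported with their row numbers; negative CPUE is a validation error.
#'
#' @param path CSV path.
#' @return A `haul_table` data frame.
#' @export
read_haul_table <- function(path) {
  d <- read_validated_csv(path, c("haul_id", "year", "julian_day",
                                  "station_id"), "haul table")
  cols <- grep("^cpue_", names(d), value = TRUE)
  if (length(cols) == 0L) {
    stop(sprintf("haul table %s has no cpue_<taxon> column", path),
         call. = FALSE)
  }
  for (cc in cols) {
    bad <- which(!is.finite(d[[cc]]) | d[[cc]] < 0)
    if (length(bad)) {
      stop(sprintf("haul table %s: negative or non-numeric CPUE in column %s, row(s) %s",
                   path, cc, paste(head(bad, 5), collapse = ", ")),
           call. = FALSE)
    }
  }
  class(d) <- c("haul_table", "data.frame")
  d
}

#' @rdname read_haul_table
#' @param table Table to write.
#' @export
write_haul_table <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a station table
#' @param path CSV path.
#' @return A `station_table` data frame.
#' @export
read_station_table <- function(path) {
  d <- read_validated_csv(path, c("station_id", "region", "depth_stratum",
                                  "bottom_depth_m", "distance_to_shore_km"),
                          "station table")
  if (anyDuplicated(d$station_id)) {
    stop(sprintf("station table %s: duplicated station_id", path),
         call. = FALSE)
  }
  if ("reduced_year_flag" %in% names(d)) {
    d$reduced_year_flag <- as.logical(d$reduced_year_flag)
  }
  class(d) <- c("station_table", "data.frame")
  d
}

#' @rdname read_station_table
#' @param table Table to write.
#' @export
write_station_table <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a diet series
#' @param path CSV path.
#' @return A `diet_series` data frame.
#' @export
read_diet_series <- function(path) {
  d <- read_validated_csv(path, c("year", "prey_group", "mean_proportion"),
                          "diet series")
  bad <- which(d$mean_proportion < 0 | d$mean_proportion > 1)
  if (length(bad)) {
    stop(sprintf("diet series %s: proportions outside [0,1] in row(s) %s",
                 path, paste(head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  class(d) <- c("diet_series", "data.frame")
  d
}

#' @rdname read_diet_series
#' @param table Table to write.
#' @export
write_diet_series <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

env_static_cols <- c("longitude", "latitude", "depth_m",
                     "distance_to_shore_km")

#' Read / write an environmental grid (long CSV)
#'
#' Long format: `cell_id`, `year`, `covariate`, `value`. Static covariates
#' (longitude, latitude, depth, distance to shore) are written once per cell
#' with an empty `year`; dynamic covariates once per cell-year. Reading
#' reconstructs the wide per-cell-per-year `env_grid`.
#'
#' @param path CSV path.
#' @return An `env_grid` data frame.
#' @export
read_env_grid <- function(path) {
  d <- read_validated_csv(path, c("cell_id", "year", "covariate", "value"),
                          "environmental grid")
  stat <- d[is.na(d$year), , drop = FALSE]
  dyn <- d[!is.na(d$year), , drop = FALSE]
  wide_stat <- reshape(stat[, c("cell_id", "covariate", "value")],
                       idvar = "cell_id", timevar = "covariate",
                       direction = "wide")
  names(wide_stat) <- sub("^value\\.", "", names(wide_stat))
  wide_dyn <- reshape(dyn, idvar = c("cell_id", "year"),
                      timevar = "covariate", direction = "wide")
  names(wide_dyn) <- sub("^value\\.", "", names(wide_dyn))
  out <- merge(wide_dyn, wide_stat, by = "cell_id", sort = FALSE)
  out <- out[order(out$year, out$cell_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("env_grid", "data.frame")
  out
}

#' @rdname read_env_grid
#' @param env Wide `env_grid` to write.
#' @export
write_env_grid <- function(env, path) {
  e <- as.data.frame(env)
  stat_cols <- intersect(env_static_cols, names(e))
  dyn_cols <- setdiff(names(e), c("cell_id", "year", stat_cols))
  first <- e[!duplicated(e$cell_id), , drop = FALSE]
  longs <- list()
  for (cc in stat_cols) {
    longs[[length(longs) + 1L]] <- data.frame(
      cell_id = first$cell_id, year = NA_integer_, covariate = cc,
      value = first[[cc]], stringsAsFactors = FALSE)
  }
  for (cc in dyn_cols) {
    longs[[length(longs) + 1L]] <- data.frame(
      cell_id = e$cell_id, year = e$year, covariate = cc, value = e[[cc]],
      stringsAsFactors = FALSE)
  }
  write.csv(do.call(rbind, longs), path, row.names = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write an index series
#' @param path CSV path.
#' @return An `index_series` data frame.
#' @export
read_index_series <- function(path) {
  d <- read_validated_csv(path, c("year", "point_index", "log_index"),
                          "index series")
  tx <- if ("taxon" %in% names(d)) d$taxon[1] else NA_character_
  d$taxon <- NULL
  attr(d, "taxon") <- tx
  class(d) <- c("index_series", "data.frame")
  d
}

#' @rdname read_index_series
#' @param index Series to write.
#' @export
write_index_series <- function(index, path) {
  d <- as.data.frame(index)
  d <- cbind(taxon = attr(index, "taxon") %||% NA_character_, d)
  write.csv(d, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
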