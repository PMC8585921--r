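# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp01 <- function(x) pmin(1, pmax(0, x))

# z-score a series over a baseline subset; sd uses the n-1 denominator.
zscore <- function(x, baseline = rep(TRUE, length(x))) {
  b <- x[baseline]
  b <- b[is.finite(b)]
  if (length(b) < 2L || sd(b) == 0) return(rep(NA_real_, length(x)))
  (x - mean(b)) / sd(b)
}

# Depth-stratum conventions used by the generator and the estimators.
stratum_levels <- c("shelf", "slope", "deep")

# Signed nearshore score: positive = shallow/nearshore, negative = offshore.
stratum_score <- c(shelf = 1, slope = -0.5, deep = -1)

stratum_depth_range <- list(
  shelf = c(30, 200),
  slope = c(200, 1500),
  deep  = c(1500, 3000)
)

assert_scalar_number <- function(x, name, lower = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower) {
    stop(sprintf("`%s` must be a finite number >= %s", name, lower), call. = FALSE)
  }
  invisible(x)
}

cpue_column <- function(hauls, taxon) {
  col <- paste0("cpue_", taxon)
  if (!col %in% names(hauls)) {
    stop(sprintf("no CPUE column `%s` for taxon '%s' in haul table", col, taxon),
         call. = FALSE)
  }
  col
}

taxa_in_hauls <- function(hauls) {
  sub("^cpue_", "", grep("^cpue_", names(hauls), value = TRUE))
}
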