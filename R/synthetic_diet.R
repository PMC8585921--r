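#' Simulate a predator chick-diet series linked to an abundance index
#'
#' Generates per-year mean diet proportions of one prey group as a linear
#' function of the prey's log abundance index plus Gaussian observation noise,
#' clamped to [0, 1]. This is the generative mirror of the assumption that
#' seabird diet varies with relative prey abundance in the surrounding
#' ecosystem, which underlies [fit_calibration()].
#'
#' @param index An `index_series` (or any data frame with `year` and
#'   `log_index`).
#' @param prey_group Label for the simulated prey group.
#' @param slope,intercept Linear link from log index to diet proportion.
#' @param noise_sd Non-negative SD of the Gaussian noise (before clamping).
#' @param n_obs Nominal number of feeding observations behind each yearly mean.
#' @param seed Integer seed.
#'
#' @return A `diet_series` data frame: `year`, `prey_group`,
#'   `mean_proportion`, `n_obs`.
#' @export
simulate_diet <- function(index, prey_group = "prey",
                          slope = 0.15, intercept = 0.05,
                          noise_sd = 0.05, n_obs = 300, seed = 1) {
  if (is.null(index) || nrow(index) == 0L) {
    stop("empty index series: nothing to link diet to", call. = FALSE)
  }
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  set.seed(seed)
  p <- intercept + slope * index$log_index + rnorm(nrow(index), 0, noise_sd)
  out <- data.frame(
    year = index$year,
    prey_group = prey_group,
    mean_proportion = clamp01(p),
    n_obs = n_obs,
    stringsAsFactors = FALSE
  )
  class(out) <- c("diet_series", "data.frame")
  out
}
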