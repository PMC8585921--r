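# Predator-diet calibration: ordinary least squares linking seabird
# chick-diet proportions to trawl-based log abundance indices, inverted to
# predict indices (with uncertainty) in survey-poor years.

#' Fit the diet-proportion / log-index calibration regression
#'
#' Ordinary least squares with the log abundance index (`log_index` of the
#' trawl series) as response and the mean diet proportion of the prey group
#' as predictor, over the paired training years. Proportions enter as-is
#' (linear models fit these series well; a logit transform of the predictor
#' is available but off by default).
#'
#' @param diet A `diet_series`.
#' @param index An `index_series` for the matching taxon.
#' @param prey_group Prey group to pair (default: the single group present).
#' @param years Optional restriction of training years (e.g. a later start
#'   when early counts were unstandardized).
#' @param logit_predictor Use `qlogis(p)` of the (slightly shrunk) proportion
#'   as predictor instead of `p` (default FALSE).
#' @return A `calibration_model` with slope, intercept, `r_squared`,
#'   `p_value`, `residual_se`, training years and the underlying `lm` fit.
#' @export
fit_calibration <- function(diet, index, prey_group = NULL, years = NULL,
                            logit_predictor = FALSE) {
  prey_group <- prey_group %||% unique(diet$prey_group)[1]
  dd <- diet[diet$prey_group == prey_group, , drop = FALSE]
  yrs <- intersect(dd$year, index$year)
  if (!is.null(years)) yrs <- intersect(yrs, years)
  if (length(yrs) < 10L) {
    stop(sprintf("only %d paired years; need >= 10 to calibrate", length(yrs)),
         call. = FALSE)
  }
  prop <- dd$mean_proportion[match(yrs, dd$year)]
  li <- index$log_index[match(yrs, index$year)]
  if (sd(prop) == 0) {
    stop("zero variance in diet proportions: degenerate calibration",
         call. = FALSE)
  }
  x <- if (logit_predictor) qlogis(pmin(0.999, pmax(0.001, prop))) else prop
  df <- data.frame(log_index = li, proportion = x)
  fit <- lm(log_index ~ proportion, data = df)
  sm <- summary(fit)
  structure(list(
    prey_group = prey_group,
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = sm$r.squared,
    p_value = unname(sm$coefficients[2, 4]),
    residual_se = sm$sigma,
    slope_se = unname(sm$coefficients[2, 2]),
    training_years = yrs,
    prop_mean = mean(x),
    prop_range = range(x),
    logit_predictor = logit_predictor,
    fit = fit
  ), class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("Diet calibration for '%s' (%d training years)\n", x$prey_group,
              length(x$training_years)))
  cat(sprintf("  log_index = %.3f + %.3f * proportion   (r^2 = %.2f, p = %.3g)\n",
              x$intercept, x$slope, x$r_squared, x$p_value))
  invisible(x)
}

#' Predict a log abundance index from a diet proportion
#'
#' Inverts the calibration: point prediction on the log-index scale with a
#' 95% interval. The default prediction interval carries both coefficient and
#' residual uncertainty (appropriate for a new year); `interval =
#' "confidence"` gives the fitted-line band instead. Proportions outside the
#' training range are flagged as extrapolation.
#'
#' @param model A `calibration_model`.
#' @param proportion Diet proportion(s) in [0, 1].
#' @param interval `"prediction"` (default) or `"confidence"`.
#' @param level Interval level (default 0.95).
#' @return Data frame: `proportion`, `fit`, `lwr`, `upr`, `extrapolated`.
#' @export
predict_index <- function(model, proportion,
                          interval = c("prediction", "confidence"),
                          level = 0.95) {
  stopifnot(inherits(model, "calibration_model"))
  interval <- match.arg(interval)
  if (any(proportion < 0 | proportion > 1)) {
    stop("proportion must lie in [0, 1]", call. = FALSE)
  }
  x <- if (model$logit_predictor) {
    qlogis(pmin(0.999, pmax(0.001, proportion)))
  } else proportion
  pr <- suppressWarnings(
    predict(model$fit, newdata = data.frame(proportion = x),
            interval = interval, level = level))
  data.frame(
    proportion = proportion,
    fit = pr[, "fit"],
    lwr = pr[, "lwr"],
    upr = pr[, "upr"],
    extrapolated = x < model$prop_range[1] | x > model$prop_range[2]
  )
}

#' Assess agreement between a diet-based prediction and a trawl estimate
#'
#' Compares two interval estimates on the same log-index scale: signed
#' discrepancy, interval overlap, and mutual containment of point estimates.
#' `agreement` is TRUE when each point estimate lies inside the other's 95%
#' interval.
#'
#' @param prediction One-row data frame with `fit`, `lwr`, `upr` (e.g. from
#'   [predict_index()]).
#' @param trawl One-row data frame with a point estimate (`log_index` or
#'   `fit`) and interval bounds (`lower`/`upper` or `lwr`/`upr`).
#' @return An `agreement_report` list.
#' @export
assess_agreement <- function(prediction, trawl) {
  getf <- function(x, nms) {
    nm <- intersect(nms, names(x))
    if (length(nm) == 0L) {
      stop(sprintf("expected one of [%s]: are both estimates on the log-index scale with intervals?",
                   paste(nms, collapse = ", ")), call. = FALSE)
    }
    v <- x[[nm[1]]]
    if (length(v) != 1L || !is.finite(v)) stop("need one finite value",
                                               call. = FALSE)
    v
  }
  p_fit <- getf(prediction, c("fit", "log_index"))
  p_lo <- getf(prediction, c("lwr", "lower"))
  p_hi <- getf(prediction, c("upr", "upper"))
  t_fit <- getf(trawl, c("log_index", "fit"))
  t_lo <- getf(trawl, c("lower", "lwr"))
  t_hi <- getf(trawl, c("upper", "upr"))
  structure(list(
    discrepancy = p_fit - t_fit,
    intervals_overlap = max(p_lo, t_lo) <= min(p_hi, t_hi),
    trawl_in_prediction_interval = t_fit >= p_lo & t_fit <= p_hi,
    prediction_in_trawl_interval = p_fit >= t_lo & p_fit <= t_hi,
    agreement = (t_fit >= p_lo & t_fit <= p_hi) &&
      (p_fit >= t_lo & p_fit <= t_hi)
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("discrepancy (diet - trawl, log scale): %+.3f\n", x$discrepancy))
  cat(sprintf("intervals overlap: %s; mutual containment: %s\n",
              x$intervals_overlap, x$agreement))
  invisible(x)
}
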