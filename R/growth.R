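## Growth kinetics from plate-reader optical density curves.

#' Plate-reader growth curve
#'
#' @param time_min Strictly increasing sampling times in minutes.
#' @param od Optical densities (OD550); must be positive, since the
#'   growth rate is estimated on the natural-log scale. Blank subtraction
#'   is the caller's responsibility and must not produce non-positive
#'   values.
#' @param well_id Well label.
#' @return An object of class `growth_curve`.
#' @export
growth_curve <- function(time_min, od, well_id = "well") {
  if (length(time_min) != length(od))
    stop("time_min and od must have equal length")
  if (length(od) < 2) stop("a growth curve needs at least two points")
  if (any(diff(time_min) <= 0))
    stop("time_min must be strictly increasing")
  if (any(!is.finite(od)) || any(od <= 0))
    stop("od values must be positive (check blank subtraction)")
  structure(list(time_min = as.numeric(time_min), od = as.numeric(od),
                 well_id = as.character(well_id)),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("growth curve '%s': %d points over %.0f min, OD %.3f -> %.3f\n",
              x$well_id, length(x$od), diff(range(x$time_min)),
              x$od[1], x$od[length(x$od)]))
  invisible(x)
}

#' Maximum specific growth rate from an OD curve
#'
#' ln-transforms the OD series and fits an ordinary least-squares slope
#' within every contiguous sliding window of `window` points (slide step
#' one point); the maximum slope across windows is the maximum specific
#' growth rate, in units of 1/min. The estimate may be zero or negative
#' for non-growing cultures. No correction is applied for the
#' non-linearity of OD at high density, so the estimate can be biased
#' downward in saturating batch cultures.
#'
#' @param curve A [growth_curve()].
#' @param window Window size in points (default 50, i.e. 245 minutes at
#'   5-minute sampling).
#' @return Maximum window slope of ln(OD) vs time (per minute).
#' @export
#' @examples
#' tm <- seq(0, 600, by = 5)
#' mu_max(growth_curve(tm, 0.05 * exp(0.006 * tm)))  # 0.006
mu_max <- function(curve, window = 50) {
  stopifnot(inherits(curve, "growth_curve"))
  n <- length(curve$od)
  if (window < 2) stop("window must be at least 2 points")
  if (n < window)
    stop(sprintf("curve has %d points but the window needs %d", n, window))
  x <- curve$time_min
  y <- log(curve$od)
  # rolling OLS slope via cumulative sums
  csx <- cumsum(x); csy <- cumsum(y)
  csxx <- cumsum(x * x); csxy <- cumsum(x * y)
  w <- window
  i2 <- w:n
  roll <- function(cs) cs[i2] - c(0, cs)[i2 - w + 1]
  sx <- roll(csx); sy <- roll(csy); sxx <- roll(csxx); sxy <- roll(csxy)
  slope <- (w * sxy - sx * sy) / (w * sxx - sx * sx)
  max(slope)
}

#' Doubling time from a specific growth rate
#'
#' @param mu Specific growth rate (1/min), must be positive.
#' @return `ln(2) / mu`, in minutes.
#' @export
#' @examples
#' doubling_time(log(2) / 140)  # 140
doubling_time <- function(mu) {
  if (any(mu <= 0)) stop("doubling time is undefined for mu <= 0")
  log(2) / mu
}

#' CFU fold change over a crossing experiment
#'
#' Relative growth during a mating experiment, measured as the ratio of
#' colony-forming-unit counts at the final and initial timepoints.
#'
#' @param cfu_t0 Initial CFU count (> 0).
#' @param cfu_t20 Final CFU count.
#' @return `cfu_t20 / cfu_t0`.
#' @export
#' @examples
#' cfu_fold_change(2e5, 2e6)  # 10
cfu_fold_change <- function(cfu_t0, cfu_t20) {
  if (any(cfu_t0 <= 0)) stop("initial CFU count must be positive")
  if (any(cfu_t20 < 0)) stop("final CFU count must be non-negative")
  cfu_t20 / cfu_t0
}
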