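#' Define a dosing regimen
#'
#' Intermittent regimens are zero-order infusions of \code{dose} mg over
#' \code{duration} h repeated every \code{interval} h; continuous regimens
#' deliver \code{daily_dose} mg over each 24 h at a constant rate.
#'
#' @param dose Dose per administration (mg), intermittent mode.
#' @param interval Dosing interval (h); must divide evenly into a day for
#'   the 24-h target-attainment window to be exact (6, 8 and 12 h are used
#'   throughout).
#' @param duration Infusion duration (h), \code{duration <= interval}.
#' @param daily_dose Total daily dose (mg); supplying this selects
#'   continuous mode and the other arguments are ignored.
#' @return An object of class \code{regimen}.
#' @examples
#' regimen(4000, interval = 6, duration = 0.5)   # 4 g q6h, 30-min infusion
#' regimen(daily_dose = 16000)                   # 16 g/day continuous
#' @export
regimen <- function(dose = NULL, interval = NULL, duration = NULL,
                    daily_dose = NULL) {
  if (!is.null(daily_dose)) {
    if (daily_dose <= 0) stop("daily_dose must be positive")
    out <- list(mode = "continuous", daily_dose = daily_dose,
                rate = daily_dose / 24)
  } else {
    if (is.null(dose) || is.null(interval) || is.null(duration))
      stop("intermittent regimens need dose, interval and duration")
    if (dose <= 0 || interval <= 0 || duration <= 0)
      stop("dose, interval and duration must be positive")
    if (duration > interval)
      stop("infusion duration must not exceed the dosing interval")
    out <- list(mode = "intermittent", dose = dose, interval = interval,
                duration = duration, rate = dose / duration)
  }
  structure(out, class = "regimen")
}

#' @export
print.regimen <- function(x, ...) {
  if (x$mode == "continuous")
    cat(sprintf("Continuous infusion: %g g/day (%.1f mg/h)\n",
                x$daily_dose / 1000, x$rate))
  else
    cat(sprintf("Intermittent: %g g q%gh, %g-h infusion (%.0f mg/h)\n",
                x$dose / 1000, x$interval, x$duration, x$rate))
  invisible(x)
}

#' @export
format.regimen <- function(x, ...) {
  if (x$mode == "continuous") sprintf("CI %gg/day", x$daily_dose / 1000)
  else sprintf("%gg q%gh inf %gh", x$dose / 1000, x$interval, x$duration)
}
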