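#' Convert between days and years
#'
#' The dynamical tumor model runs in years while all radionuclide kinetics
#' and linear-quadratic quantities are tabulated in days.  Every unit bridge
#' in the package goes through these two helpers so that the conversion
#' factor appears in exactly one place.
#'
#' @param x numeric vector of times or rates.
#' @param days_per_year days per year used by the bridge; 365 by default,
#'   365.25 selectable.
#' @return numeric vector in the target unit.
#' @examples
#' years_to_days(1)          # 365
#' days_to_years(730)        # 2
#' @export
days_to_years <- function(x, days_per_year = 365) x / days_per_year

#' @rdname days_to_years
#' @export
years_to_days <- function(x, days_per_year = 365) x * days_per_year

#' Normalize an extrapolated initial dose rate to Gy/day
#'
#' Dose rates appear in the literature both as Gy/day (dose-rate kinetics)
#' and Gy/year (therapy scenarios).  All internal computations use Gy/day.
#'
#' @param r0 non-negative dose rate.
#' @param unit unit tag of `r0`, `"Gy/day"` or `"Gy/year"`.
#' @inheritParams days_to_years
#' @return dose rate in Gy/day.
#' @export
r0_per_day <- function(r0, unit = c("Gy/day", "Gy/year"), days_per_year = 365) {
  unit <- match.arg(unit)
  stopifnot(is.numeric(r0), all(r0 >= 0))
  if (unit == "Gy/year") r0 / days_per_year else r0
}
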