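## Agronomic weather indices computed from daily records: cumulative
## precipitation (PPT, mm), the rainfall Shannon diversity index (SDI,
## unitless in [0, 1]) and growing degree-days (GDD, degC day).

## Validate a daily series given as rainfall and/or temperature vectors.
checkSeries <- function(rain = NULL, tmean = NULL) {
  n <- max(length(rain), length(tmean))
  if (n < 2)
    sbiError("invalidWeatherError", "need at least 2 days, got %d", n)
  if (!is.null(rain) && (any(!is.finite(rain)) || any(rain < 0)))
    sbiError("invalidWeatherError", "rainfall must be finite and >= 0")
  if (!is.null(tmean) && any(!is.finite(tmean)))
    sbiError("invalidWeatherError", "temperatures must be finite")
  invisible(n)
}

#' Cumulative precipitation
#'
#' @param rain daily rainfall in mm (length >= 2, non-negative).
#' @return total precipitation PPT in mm.
#' @export
cumulativePrecipitation <- function(rain) {
  checkSeries(rain = rain)
  sum(rain)
}

#' Rainfall Shannon diversity index
#'
#' Entropy of the daily rainfall proportions normalized by `ln(n)`:
#' `SDI = -sum(P_i ln P_i) / ln(n)` with `P_i = Rd_i / PPT` and the
#' convention `0 * ln 0 = 0`. Equals 1 when rain falls evenly on every
#' day and 0 when the whole period's rain falls on a single day. The
#' index is undefined (an error, not 0) for a completely dry period.
#'
#' @param rain daily rainfall in mm (length >= 2, non-negative, total > 0).
#' @return SDI in [0, 1] (unitless).
#' @export
rainfallSDI <- function(rain) {
  n <- checkSeries(rain = rain)
  ppt <- sum(rain)
  if (ppt == 0)
    sbiError("undefinedIndexError",
             "SDI undefined for a period with zero total rainfall")
  p <- rain / ppt
  p <- p[p > 0]                         # 0 * ln 0 = 0
  -sum(p * log(p)) / log(n) + 0         # + 0 normalizes IEEE -0
}

#' Growing degree-days
#'
#' Thermal accumulation over a 7 degC base. The default follows the
#' source formula literally: each day contributes its full mean
#' temperature `Tm_i` when `Tm_i >= 7` and 0 otherwise. The textbook
#' variant summing the excess `(Tm_i - 7)` above the base is available
#' with `conventional = TRUE`.
#'
#' @param tmean daily mean temperatures in degC (length >= 2).
#' @param base base temperature in degC (default 7).
#' @param conventional logical; sum `Tm_i - base` instead of `Tm_i` on
#'   days at or above the base (default `FALSE`).
#' @return GDD in degC day.
#' @export
growingDegreeDays <- function(tmean, base = 7, conventional = FALSE) {
  checkSeries(tmean = tmean)
  warm <- tmean >= base
  if (conventional) sum(tmean[warm] - base) else sum(tmean[warm])
}

#' Weather indices per field
#'
#' Computes PPT, SDI and GDD for each field from a long daily weather
#' table, optionally restricted to a date window.
#'
#' @param weather data.frame with columns `field_id`, `date` (Date or
#'   ISO-8601 character), `rain_mm`, `tmean_c`.
#' @param window optional length-2 vector of inclusive start/end dates.
#' @param conventional passed to [growingDegreeDays()].
#' @return data.frame with one row per field: `field_id`, `PPT`, `SDI`,
#'   `GDD`.
#' @export
weatherIndices <- function(weather, window = NULL, conventional = FALSE) {
  stopifnot(all(c("field_id", "date", "rain_mm", "tmean_c")
                %in% names(weather)))
  weather$date <- as.Date(weather$date)
  if (!is.null(window)) {
    window <- as.Date(window)
    weather <- weather[weather$date >= window[1] & weather$date <= window[2], ]
  }
  out <- lapply(split(weather, weather$field_id), function(df) {
    df <- df[order(df$date), ]
    if (any(diff(df$date) != 1))
      sbiError("invalidWeatherError",
               "dates for field '%s' are not contiguous daily records",
               df$field_id[1])
    data.frame(field_id = df$field_id[1],
               PPT = cumulativePrecipitation(df$rain_mm),
               SDI = rainfallSDI(df$rain_mm),
               GDD = growingDegreeDays(df$tmean_c,
                                       conventional = conventional))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
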