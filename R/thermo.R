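# Humidity thermodynamics: saturation vapor pressure (Bolton form over liquid
# water), dew point from specific humidity and pressure, relative humidity,
# and the US NWS heat index.

# Constants, kept in one place for auditability.
.thermo <- list(
  epsilon     = 0.622,   # ratio of molar mass of water vapor to dry air
  es0_hpa     = 6.112,   # saturation vapor pressure at 0 degC, hPa
  bolton_a    = 17.67,
  bolton_b    = 243.5,   # degC
  hi_threshold_f = 80,   # switch from simple Steadman average to Rothfusz
  hi_lowrh_max_f = 112,  # low-RH adjustment applies for T in [80, 112] F
  hi_highrh_max_f = 87   # high-RH adjustment applies for T in [80, 87] F
)

#' Kelvin / Celsius / Fahrenheit conversions
#'
#' Exact affine unit maps used throughout the package.
#'
#' @param k,c,f Temperatures in kelvin, degrees Celsius, degrees Fahrenheit.
#' @return Numeric vector in the target unit.
#' @examples
#' kelvin_to_fahrenheit(306.483)  # ~92 F
#' @export
kelvin_to_celsius <- function(k) k - 273.15

#' @rdname kelvin_to_celsius
#' @export
celsius_to_kelvin <- function(c) c + 273.15

#' @rdname kelvin_to_celsius
#' @export
celsius_to_fahrenheit <- function(c) c * 9 / 5 + 32

#' @rdname kelvin_to_celsius
#' @export
fahrenheit_to_celsius <- function(f) (f - 32) * 5 / 9

#' @rdname kelvin_to_celsius
#' @export
kelvin_to_fahrenheit <- function(k) celsius_to_fahrenheit(kelvin_to_celsius(k))

#' @rdname kelvin_to_celsius
#' @export
fahrenheit_to_kelvin <- function(f) celsius_to_kelvin(fahrenheit_to_celsius(f))

#' Saturation vapor pressure over liquid water
#'
#' Bolton (1980) exponential approximation, used consistently for all
#' temperatures (no ice-phase branch).
#'
#' @param t_k Temperature, kelvin.
#' @return Saturation vapor pressure, hPa.
#' @export
saturation_vapor_pressure_hpa <- function(t_k) {
  stopifnot(all(is.finite(t_k)), all(t_k > 0))
  tc <- kelvin_to_celsius(t_k)
  .thermo$es0_hpa * exp(.thermo$bolton_a * tc / (tc + .thermo$bolton_b))
}

# Inverse of the Bolton formula: temperature (K) at which e_s equals e (hPa).
.dewpoint_from_vapor_pressure_hpa <- function(e_hpa) {
  x <- log(e_hpa / .thermo$es0_hpa)
  tc <- .thermo$bolton_b * x / (.thermo$bolton_a - x)
  celsius_to_kelvin(tc)
}

#' Dew point from specific humidity and pressure
#'
#' Converts specific humidity to vapor pressure,
#' e = q p / (eps + (1 - eps) q), then inverts the Bolton saturation curve.
#' Strictly increasing in \code{q} at fixed \code{p}.
#'
#' @param q Specific humidity, kg/kg, in (0, 1).
#' @param p Air pressure, Pa, > 0.
#' @return Dew point, kelvin.
#' @seealso [specific_humidity_from_dewpoint()] for the forward map.
#' @export
dewpoint_from_specific_humidity <- function(q, p) {
  if (!all(is.finite(q)) || any(q <= 0) || any(q >= 1))
    stop("specific humidity must lie strictly within (0, 1) kg/kg")
  if (!all(is.finite(p)) || any(p <= 0))
    stop("pressure must be positive")
  eps <- .thermo$epsilon
  e_hpa <- q * (p / 100) / (eps + (1 - eps) * q)
  .dewpoint_from_vapor_pressure_hpa(e_hpa)
}

#' Specific humidity from dew point and pressure
#'
#' Forward map inverted by [dewpoint_from_specific_humidity()]:
#' q = eps e / (p - (1 - eps) e) with e the saturation vapor pressure at the
#' dew point.
#'
#' @param td_k Dew point, kelvin.
#' @param p Air pressure, Pa.
#' @return Specific humidity, kg/kg.
#' @export
specific_humidity_from_dewpoint <- function(td_k, p) {
  stopifnot(all(p > 0))
  eps <- .thermo$epsilon
  e_pa <- saturation_vapor_pressure_hpa(td_k) * 100
  eps * e_pa / (p - (1 - eps) * e_pa)
}

#' Relative humidity from temperature and dew point
#'
#' RH = 100 e_s(Td) / e_s(T). Supersaturated inputs (Td > T) are clipped to
#' 100 with a warning rather than rejected, consistent with the observation
#' cleaning policy of flagging but not dropping such records.
#'
#' @param t_k Air temperature, kelvin.
#' @param td_k Dew point, kelvin.
#' @return Relative humidity in percent, in (0, 100].
#' @export
relative_humidity <- function(t_k, td_k) {
  if (any(t_k <= 0) || any(td_k <= 0)) stop("nonphysical temperature (<= 0 K)")
  rh <- 100 * saturation_vapor_pressure_hpa(td_k) /
    saturation_vapor_pressure_hpa(t_k)
  if (any(rh > 100)) {
    warning("supersaturated input (dew point above temperature); RH clipped to 100%")
    rh <- pmin(rh, 100)
  }
  rh
}

# Rothfusz regression for heat index, all in Fahrenheit / percent RH,
# including the published low-RH and high-RH adjustments.
.rothfusz_f <- function(t_f, rh) {
  hi <- -42.379 + 2.04901523 * t_f + 10.14333127 * rh -
    0.22475541 * t_f * rh - 6.83783e-3 * t_f^2 - 5.481717e-2 * rh^2 +
    1.22874e-3 * t_f^2 * rh + 8.5282e-4 * t_f * rh^2 -
    1.99e-6 * t_f^2 * rh^2
  low <- rh < 13 & t_f >= 80 & t_f <= .thermo$hi_lowrh_max_f
  if (any(low)) {
    adj <- ((13 - rh[low]) / 4) * sqrt((17 - abs(t_f[low] - 95)) / 17)
    hi[low] <- hi[low] - adj
  }
  high <- rh > 85 & t_f >= 80 & t_f <= .thermo$hi_highrh_max_f
  if (any(high)) {
    adj <- ((rh[high] - 85) / 10) * ((87 - t_f[high]) / 5)
    hi[high] <- hi[high] + adj
  }
  hi
}

# Simple Steadman average used below the hot threshold.
.steadman_f <- function(t_f, rh) {
  0.5 * (t_f + 61 + (t_f - 68) * 1.2 + 0.094 * rh)
}

#' Heat index from daily mean temperature and dew point
#'
#' Applies the US National Weather Service convention: relative humidity is
#' derived from temperature and dew point, then below 80 F the simple
#' Steadman average is used, and at or above 80 F the Rothfusz regression
#' with the published low-RH and high-RH adjustment terms.
#'
#' @param t_k Daily mean air temperature, kelvin.
#' @param td_k Daily mean dew point, kelvin.
#' @return Heat index, kelvin.
#' @export
heat_index <- function(t_k, td_k) {
  if (any(!is.finite(t_k)) || any(!is.finite(td_k)) ||
      any(t_k <= 0) || any(td_k <= 0))
    stop("nonphysical temperature input")
  rh <- suppressWarnings(pmin(100 * saturation_vapor_pressure_hpa(td_k) /
                                saturation_vapor_pressure_hpa(t_k), 100))
  t_f <- kelvin_to_fahrenheit(t_k)
  hi_f <- .steadman_f(t_f, rh)
  hot <- t_f >= .thermo$hi_threshold_f
  if (any(hot)) hi_f[hot] <- .rothfusz_f(t_f[hot], rh[hot])
  fahrenheit_to_kelvin(hi_f)
}
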