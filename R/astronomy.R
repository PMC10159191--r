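# Low-precision solar and lunar ephemerides. Accuracy targets: sun times to
# ~1 min, lunar illuminated fraction to ~0.001 -- ample for diel windows and
# moon-phase covariates; not intended for navigation-grade work.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Julian day number from POSIXct (UTC)
julian_day <- function(t) {
  as.numeric(t, units = "secs") / 86400 + 2440587.5
}

#' Sunrise and sunset times for a date and location
#'
#' Computes apparent sunrise and sunset (solar zenith 90.833 degrees,
#' i.e. including standard refraction and the solar radius) using the NOAA
#' solar-position equations: a Fourier expansion of the equation of time and
#' solar declination in the fractional year.
#'
#' @param date `Date` vector.
#' @param lat,lon Latitude and longitude in decimal degrees (east positive).
#' @return A tibble with columns `date`, `sunrise`, `sunset` (`POSIXct`, UTC).
#'   Polar day or night (sun never crossing the horizon) is an error.
#' @examples
#' sun_times(as.Date("2018-03-20"), lat = 27.86, lon = -80.47)
#' @export
sun_times <- function(date, lat, lon) {
  stopifnot(inherits(date, "Date"), abs(lat) <= 90, abs(lon) <= 180)
  doy <- as.numeric(format(date, "%j"))
  # fractional year (radians), evaluated at solar noon
  g <- 2 * pi / 365 * (doy - 1 + 0.5)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
    0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  latr <- deg2rad(lat)
  cos_ha <- cos(deg2rad(90.833)) / (cos(latr) * cos(decl)) -
    tan(latr) * tan(decl)
  if (any(abs(cos_ha) > 1)) {
    stop("sun does not cross the horizon at this latitude/date (polar day or night)")
  }
  ha <- rad2deg(acos(cos_ha))
  midnight <- lubridate::as_datetime(date, tz = "UTC")
  sunrise <- midnight + 60 * (720 - 4 * (lon + ha) - eqtime)
  sunset <- midnight + 60 * (720 - 4 * (lon - ha) - eqtime)
  tibble::tibble(date = date, sunrise = sunrise, sunset = sunset)
}

#' Illuminated fraction of the lunar disc
#'
#' Low-precision lunar phase from the polynomial mean elements of the Moon
#' (mean elongation, solar and lunar mean anomalies) with the principal
#' periodic corrections to the phase angle, after the classical
#' astronomical-algorithms treatment. Returns `(1 + cos i) / 2` where `i` is
#' the phase angle: 0 at new moon, 1 at full moon.
#'
#' @param t `POSIXct` vector (any timezone; converted to UTC internally).
#' @return Numeric vector in `[0, 1]`.
#' @examples
#' moon_fraction(as.POSIXct("2018-01-02 02:24:00", tz = "UTC")) # full moon
#' @export
moon_fraction <- function(t) {
  stopifnot(inherits(t, "POSIXct"))
  T <- (julian_day(t) - 2451545.0) / 36525
  # mean elongation of the Moon, sun mean anomaly, moon mean anomaly (deg)
  D <- (297.8501921 + 445267.1114034 * T) %% 360
  M <- (357.5291092 + 35999.0502909 * T) %% 360
  Mp <- (134.9633964 + 477198.8675055 * T) %% 360
  i <- 180 - D -
    6.289 * sin(deg2rad(Mp)) +
    2.100 * sin(deg2rad(M)) -
    1.274 * sin(deg2rad(2 * D - Mp)) -
    0.658 * sin(deg2rad(2 * D)) -
    0.214 * sin(deg2rad(2 * Mp)) -
    0.110 * sin(deg2rad(D))
  (1 + cos(deg2rad(i))) / 2
}
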