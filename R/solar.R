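#' Solar altitude above the horizon
#'
#' NOAA-style solar position approximation (fractional-year Fourier series
#' for declination and the equation of time, hour angle from true solar
#' time). Accuracy is within about half a degree for contemporary dates,
#' ample for the +/-18 degree diel banding. No atmospheric refraction.
#'
#' @param timeUtc POSIXct time(s), UTC.
#' @param lat,lon decimal degrees (vectorized with `timeUtc`).
#' @return solar altitude in degrees (negative below the horizon).
#' @examples
#' solarAltitude(as.POSIXct("2014-03-20 12:07:00", tz = "UTC"), 0, 0)
#' @export
solarAltitude <- function(timeUtc, lat, lon) {
  if (any(is.na(timeUtc))) stop("invalid date")
  lt <- as.POSIXlt(timeUtc, tz = "UTC")
  hh <- lt$hour + lt$min / 60 + lt$sec / 3600
  gamma <- 2 * pi / 365 * (lt$yday + (hh - 12) / 24)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(gamma) -
                        0.032077 * sin(gamma) - 0.014615 * cos(2 * gamma) -
                        0.040849 * sin(2 * gamma))
  decl <- 0.006918 - 0.399912 * cos(gamma) + 0.070257 * sin(gamma) -
    0.006758 * cos(2 * gamma) + 0.000907 * sin(2 * gamma) -
    0.002697 * cos(3 * gamma) + 0.00148 * sin(3 * gamma)
  tst <- hh * 60 + eqtime + 4 * lon          # true solar time, minutes
  ha <- (tst / 4 - 180) * pi / 180           # hour angle, radians
  latr <- lat * pi / 180
  cosZen <- sin(latr) * sin(decl) + cos(latr) * cos(decl) * cos(ha)
  90 - acos(pmin(pmax(cosZen, -1), 1)) * 180 / pi
}

#' Diel label from solar altitude
#'
#' `day` at or above +band, `night` at or below -band, `transition`
#' strictly inside (-band, +band); transitions are excluded from diel
#' comparisons because vertical migration is underway.
#'
#' @param altitudeDeg solar altitude(s), degrees.
#' @param bandDeg transition half-width, degrees (default 18, the
#'   astronomical-twilight limit).
#' @return factor with levels day/night/transition.
#' @export
dielLabel <- function(altitudeDeg, bandDeg = 18) {
  if (any(!is.finite(altitudeDeg))) stop("altitude must be finite")
  factor(ifelse(altitudeDeg >= bandDeg, "day",
                ifelse(altitudeDeg <= -bandDeg, "night", "transition")),
         levels = c("day", "night", "transition"))
}

#' Day/night summaries of ESU biomass
#'
#' Drops transition ESUs, then summarizes `B_mg_m2` per diel period.
#'
#' @param esus ESU table from [integrateEsu()] (needs `diel`, `B_mg_m2`).
#' @return list with `day` and `night`, each a list
#'   (n, mean, sd, median, q1, q3, empty); `empty = TRUE` flags a period
#'   with no ESUs.
#' @export
dielAggregate <- function(esus) {
  stopifnot(all(c("diel", "B_mg_m2") %in% names(esus)))
  one <- function(period) {
    b <- esus$B_mg_m2[esus$diel == period]
    if (!length(b))
      return(list(n = 0L, mean = NA_real_, sd = NA_real_, median = NA_real_,
                  q1 = NA_real_, q3 = NA_real_, empty = TRUE))
    list(n = length(b), mean = mean(b), sd = stats::sd(b),
         median = stats::median(b),
         q1 = unname(stats::quantile(b, 0.25)),
         q3 = unname(stats::quantile(b, 0.75)), empty = FALSE)
  }
  list(day = one("day"), night = one("night"))
}
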