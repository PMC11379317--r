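#' Convert between decibels and linear units
#'
#' Volume backscatter arithmetic (averaging, integration) is carried out on the
#' linear coefficient `sv`; thresholds and reported values live in dB
#' (`Sv = 10 log10(sv)` re 1 m^-1).
#'
#' @param db values in dB.
#' @param x linear values (>= 0).
#' @return numeric vector.
#' @examples
#' dbToLinear(-70)
#' linearToDb(1e-7)
#' @export
dbToLinear <- function(db) 10^(db / 10)

#' @rdname dbToLinear
#' @export
linearToDb <- function(x) 10 * log10(x)

## Great-circle distance in kilometres between successive or all pairs of
## points; thin wrappers so the metric is defined in one place.
.gcDistKm <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2)) / 1000
}

.gcDistMatrixKm <- function(lon, lat) {
  geosphere::distm(cbind(lon, lat), fun = geosphere::distHaversine) / 1000
}

## mean earth radius [m], consistent with the haversine calls above
.EARTH_RADIUS_M <- 6371008.8

.assertFinite <- function(x, name) {
  if (!all(is.finite(x))) stop(name, " must be finite", call. = FALSE)
  invisible(x)
}
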