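#' Numerical density of scatterers in one cell
#'
#' `Nf = 10^((Sv - TS) / 10)` (ind m^-3): the mean volume backscatter divided
#' by one individual's backscattering cross-section, in the dB domain.
#'
#' @param mvbsF cell MVBS at the inversion frequency, dB re 1 m^-1.
#' @param tsF individual target strength at the same frequency, dB re 1 m^2.
#' @return ind m^-3 (vectorized).
#' @examples
#' cellDensity(-80, -110)  # 1000 ind m^-3
#' @export
cellDensity <- function(mvbsF, tsF) {
  .assertFinite(mvbsF[!is.na(mvbsF)], "mvbsF")
  10^((mvbsF - tsF) / 10)
}

#' Invert copepod-classified cells to size and density
#'
#' For each COPEPOD cell: equivalent spherical radius from the
#' \eqn{\Delta}MVBS inversion on `band`, model target strengths at both
#' frequencies, and numerical density from the chosen frequency's MVBS and
#' TS. All other cells are invalid.
#'
#' @param grid a [BiFreqCellGrid-class].
#' @param mask the matching [ClassMask-class].
#' @param params a [FluidSphereParams-class].
#' @param band a [SizeBand-class] (default the copepod band of `params`).
#' @param inversionFrequency kHz; must equal `params@fLow` or `params@fHigh`
#'   (default the high frequency, where fluid-like scatterers are strongest).
#' @return a [DensityGrid-class].
#' @export
gridDensity <- function(grid, mask, params = fluidSphereParams(),
                        band = sizeBand(params),
                        inversionFrequency = params@fHigh) {
  stopifnot(is(grid, "BiFreqCellGrid"), is(mask, "ClassMask"))
  if (!identical(dim(mask@labels), dim(mvbs38(grid))))
    stop("mask and grid are not congruent")
  if (!inversionFrequency %in% c(params@fLow, params@fHigh))
    stop("inversionFrequency must be one of the model's two frequencies")
  d <- dim(mvbs38(grid))
  esr <- ts38 <- ts120 <- nf <- matrix(NA_real_, d[1], d[2])
  clamped <- matrix(FALSE, d[1], d[2])
  valid <- mask@labels == "COPEPOD"
  if (any(valid)) {
    inv <- suppressWarnings(
      invertSize(deltaMvbs(grid)[valid], params, band))
    esr[valid] <- inv$esr
    clamped[valid] <- inv$clamped
    ts38[valid] <- targetStrength(inv$esr, params@fLow, params)
    ts120[valid] <- targetStrength(inv$esr, params@fHigh, params)
    mv <- if (inversionFrequency == params@fHigh) mvbs120(grid) else mvbs38(grid)
    tsSel <- if (inversionFrequency == params@fHigh) ts120 else ts38
    nf[valid] <- cellDensity(mv[valid], tsSel[valid])
  }
  new("DensityGrid", esr = esr, ts38 = ts38, ts120 = ts120, nf = nf,
      valid = valid, clamped = clamped,
      inversionFrequency = inversionFrequency,
      depthEdges = grid@depthEdges, pings = grid@pings)
}

#' Nautical area scattering coefficient over a depth span
#'
#' `s_A = 4 pi 1852^2 sum(sv dz)`, m^2 nmi^-2: the depth-integrated linear
#' backscatter scaled to one square nautical mile of sea surface.
#'
#' @param sv linear volume backscattering coefficients (>= 0; NA skipped).
#' @param binHeights matching bin heights, m (recycled if scalar).
#' @return s_A in m^2 nmi^-2.
#' @examples
#' nasc(1e-7, 1)  # 4.31 m^2 nmi^-2
#' @export
nasc <- function(sv, binHeights) {
  if (any(sv < 0, na.rm = TRUE)) stop("negative sv")
  if (length(binHeights) == 1L) binHeights <- rep(binHeights, length(sv))
  4 * pi * 1852^2 * sum(sv * binHeights, na.rm = TRUE)
}

#' Integrate a density grid into elementary sampling units
#'
#' Depth-integrates per-cell density by the rectangle rule
#' (`N = sum(nf dz)`, ind m^-2), partitions ping blocks into along-track
#' ESUs of `esuLengthNmi` by cumulative great-circle distance, and converts
#' areal abundance to dry-mass biomass with the mean individual dry mass
#' (`B = N DM_m`, mg m^-2). Copepod-cell NASC at the inversion frequency and
#' a solar-altitude diel label accompany each ESU.
#'
#' @param density a [DensityGrid-class].
#' @param grid the matching [BiFreqCellGrid-class] (for NASC).
#' @param esuLengthNmi ESU length, nautical miles (> 0; default 0.001).
#' @param depthRange integration window, m (within the analysis range).
#' @param dmMeanUg mean individual dry mass, micrograms (default 217).
#' @param dielBandDeg half-width of the solar transition band, degrees
#'   (default 18).
#' @return data.frame with one row per ESU: `esu_index`, `time_utc`, `lat`,
#'   `lon`, `diel`, `N_ind_m2`, `B_mg_m2`, `nasc`.
#' @export
integrateEsu <- function(density, grid, esuLengthNmi = 0.001,
                         depthRange = c(10, 200), dmMeanUg = 217,
                         dielBandDeg = 18) {
  stopifnot(is(density, "DensityGrid"))
  if (esuLengthNmi <= 0) stop("esuLengthNmi must be > 0")
  if (dmMeanUg <= 0) stop("dmMeanUg must be > 0")
  e <- density@depthEdges
  h <- diff(e)
  mid <- (e[-1] + e[-length(e)]) / 2
  useBin <- mid >= depthRange[1] & mid <= depthRange[2]

  nfz <- density@nf
  nfz[!density@valid] <- 0
  nfz[is.na(nfz)] <- 0
  Ncol <- as.vector(nfz[, useBin, drop = FALSE] %*% h[useBin])

  stopifnot(is(grid, "BiFreqCellGrid"))
  svc <- dbToLinear(if (density@inversionFrequency >= grid@fHigh)
    mvbs120(grid) else mvbs38(grid))
  svc[!density@valid] <- 0
  svc[is.na(svc)] <- 0
  nascCol <- 4 * pi * 1852^2 *
    as.vector(svc[, useBin, drop = FALSE] %*% h[useBin])

  p <- density@pings
  n <- nrow(p)
  step <- if (n > 1)
    c(0, .gcDistKm(p$lon[-n], p$lat[-n], p$lon[-1], p$lat[-1]) * 1000)
  else 0
  esuId <- floor(cumsum(step) / (esuLengthNmi * 1852)) + 1L
  esuId <- match(esuId, unique(esuId))

  agg <- function(x) as.vector(tapply(x, esuId, mean))
  tm <- as.POSIXct(agg(as.numeric(p$time_utc)), origin = "1970-01-01",
                   tz = "UTC")
  lat <- agg(p$lat); lon <- agg(p$lon)
  alt <- solarAltitude(tm, lat, lon)
  out <- data.frame(
    esu_index = seq_along(unique(esuId)),
    time_utc = tm, lat = lat, lon = lon,
    diel = dielLabel(alt, bandDeg = dielBandDeg),
    N_ind_m2 = agg(Ncol),
    B_mg_m2 = agg(Ncol) * dmMeanUg * 1e-3,
    nasc = agg(nascCol))
  out
}
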