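#' Seawater sound speed (Mackenzie nine-term formula)
#'
#' Evaluates the Mackenzie (1981) nine-term polynomial in temperature,
#' salinity and depth. At 14.9 degC, 35.7 PSU and 50 m it returns
#' 1508.0 m s^-1 (to 0.1), the reference value used by the scattering model.
#'
#' @param temperature degC, between -2 and 35.
#' @param salinity PSU, between 0 and 42.
#' @param depth m, >= 0.
#' @return sound speed in m s^-1.
#' @examples
#' soundSpeed(14.9, 35.7, 50)
#' @export
soundSpeed <- function(temperature, salinity = 35, depth = 0) {
  if (any(temperature < -2 | temperature > 35))
    stop("temperature out of range [-2, 35] degC")
  if (any(salinity < 0 | salinity > 42))
    stop("salinity out of range [0, 42] PSU")
  if (any(depth < 0)) stop("depth must be >= 0")
  T <- temperature; S <- salinity; D <- depth
  1448.96 + 4.591 * T - 5.304e-2 * T^2 + 2.374e-4 * T^3 +
    1.340 * (S - 35) + 1.630e-2 * D + 1.675e-7 * D^2 -
    1.025e-2 * T * (S - 35) - 7.139e-13 * T * D^3
}

#' Construct fluid-sphere scattering parameters
#'
#' @param g density contrast (default 1.02).
#' @param h sound-speed contrast (default 1.058).
#' @param soundSpeed seawater sound speed, m s^-1 (default 1508). Ignored if
#'   `temperature` is given, in which case the Mackenzie formula is evaluated
#'   at (`temperature`, `salinity`, `depth`).
#' @param fLow,fHigh frequency pair, kHz (defaults 38 and 120).
#' @param temperature,salinity,depth optional hydrography for [soundSpeed()];
#'   `depth` defaults to a 50 m reference.
#' @return a [FluidSphereParams-class].
#' @examples
#' fluidSphereParams()
#' fluidSphereParams(temperature = 14.9, salinity = 35.7)
#' @export
fluidSphereParams <- function(g = 1.02, h = 1.058, soundSpeed = 1508,
                              fLow = 38, fHigh = 120,
                              temperature = NULL, salinity = 35, depth = 50) {
  if (!is.null(temperature))
    soundSpeed <- zoosonde::soundSpeed(temperature, salinity, depth)
  new("FluidSphereParams", g = g, h = h, soundSpeed = soundSpeed,
      fLow = fLow, fHigh = fHigh)
}

setMethod("show", "FluidSphereParams", function(object) {
  cat(sprintf(
    "FluidSphereParams: g=%.4g h=%.4g c=%.6g m/s, %g/%g kHz (R=%.4g, alpha=%.4g)\n",
    object@g, object@h, object@soundSpeed, object@fLow, object@fHigh,
    reflectionCoefficient(object), alphaPis(object)))
})

#' Plane-wave reflection coefficient of the fluid sphere
#'
#' `R = (g h - 1) / (g h + 1)`: zero for no impedance contrast, with the sign
#' of `g h - 1`.
#'
#' @param params a [FluidSphereParams-class].
#' @return dimensionless scalar.
#' @export
reflectionCoefficient <- function(params) {
  gh <- params@g * params@h
  (gh - 1) / (gh + 1)
}

#' Rayleigh scattering contrast term of the fluid sphere
#'
#' `alpha = (1 - g h^2) / (3 g h^2) + (1 - g) / (1 + 2 g)`: the
#' compressibility-plus-density contrast that scales the Rayleigh (small-ka)
#' limit; zero for a neutrally buoyant, contrast-free body.
#'
#' @param params a [FluidSphereParams-class].
#' @return dimensionless scalar.
#' @export
alphaPis <- function(params) {
  g <- params@g; h <- params@h
  (1 - g * h^2) / (3 * g * h^2) + (1 - g) / (1 + 2 * g)
}

## wavenumber [1/m] at f [kHz]
.waveNumber <- function(frequencyKhz, params) {
  2 * pi * frequencyKhz * 1000 / params@soundSpeed
}

#' High-pass fluid-sphere backscattering cross-section
#'
#' `sigma_bs = a^2 (ka)^4 alpha^2 / (1 + 4 (ka)^4 alpha^2 / R^2)`: follows
#' Rayleigh `(ka)^4` scaling for small `ka` and plateaus at `a^2 R^2 / 4`
#' for large `ka`.
#'
#' @param esr equivalent spherical radius, mm (> 0; vectorized).
#' @param frequency kHz.
#' @param params a [FluidSphereParams-class].
#' @return backscattering cross-section in m^2.
#' @examples
#' sigmaBs(0.9, 120, fluidSphereParams())
#' @export
sigmaBs <- function(esr, frequency, params) {
  if (any(esr <= 0)) stop("esr must be > 0")
  if (any(frequency <= 0)) stop("frequency must be > 0")
  a <- esr * 1e-3
  ka <- .waveNumber(frequency, params) * a
  alpha <- alphaPis(params)
  R <- reflectionCoefficient(params)
  if (R == 0 && alpha != 0)
    stop("model undefined: zero reflection coefficient with nonzero contrast")
  if (R == 0 && alpha == 0) return(rep(0, length(ka)))
  a^2 * ka^4 * alpha^2 / (1 + 4 * ka^4 * alpha^2 / R^2)
}

#' Target strength of a fluid-sphere scatterer
#'
#' `TS = 10 log10(sigma_bs)`, dB re 1 m^2.
#'
#' @inheritParams sigmaBs
#' @return dB re 1 m^2.
#' @export
targetStrength <- function(esr, frequency, params) {
  s <- sigmaBs(esr, frequency, params)
  if (any(s == 0)) stop("TS undefined for sigma_bs = 0")
  linearToDb(s)
}

#' Frequency difference in target strength
#'
#' `deltaTS(esr) = TS(esr, fHigh) - TS(esr, fLow)`. Strictly decreasing in
#' size, from the Rayleigh ceiling `40 log10(fHigh/fLow)` (19.98 dB for
#' 120/38 kHz) toward 0 as both frequencies reach the geometric plateau.
#' This is the forward curve the \eqn{\Delta}MVBS size inversion inverts.
#'
#' @inheritParams sigmaBs
#' @return dB.
#' @examples
#' deltaTS(0.5, fluidSphereParams())
#' @export
deltaTS <- function(esr, params) {
  targetStrength(esr, params@fHigh, params) -
    targetStrength(esr, params@fLow, params)
}

#' Dimensionless size ka at the geometric-mean frequency
#'
#' `ka = 2 pi sqrt(fLow fHigh) a / c`, the dimensionless size governing the
#' scattering regime, evaluated at `fm = sqrt(fLow * fHigh)`.
#'
#' @inheritParams sigmaBs
#' @return dimensionless; linear in `esr`.
#' @export
kaValue <- function(esr, params) {
  if (any(esr <= 0)) stop("esr must be > 0")
  .waveNumber(sqrt(params@fLow * params@fHigh), params) * esr * 1e-3
}

## solve deltaTS(esr) == target by bisection; deltaTS is globally strictly
## decreasing in esr for this model, so the bracket [lo, hi] mm always works.
.solveDelta <- function(target, params, lo = 1e-3, hi = 100, tol = 1e-7) {
  flo <- deltaTS(lo, params); fhi <- deltaTS(hi, params)
  if (target >= flo || target <= fhi)
    stop("deltaTS target outside solvable range")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (deltaTS(mid, params) > target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Construct the invertible size band from dB-difference edges
#'
#' Maps a \eqn{\Delta}TS window (default the copepod analysis band
#'  7.0-19.7 dB) to its equivalent-spherical-radius limits under the model,
#' rather than fixing printed sizes: the band edges are wherever the forward
#' curve crosses the stated dB values.
#'
#' @param params a [FluidSphereParams-class].
#' @param deltaDbLow lower dB edge (maps to `esrMax`), default 7.0.
#' @param deltaDbHigh upper dB edge (maps to `esrMin`), default 19.7.
#' @return a [SizeBand-class].
#' @examples
#' sizeBand(fluidSphereParams())
#' @export
sizeBand <- function(params, deltaDbLow = 7.0, deltaDbHigh = 19.7) {
  if (deltaDbLow >= deltaDbHigh) stop("need deltaDbLow < deltaDbHigh")
  esrMin <- .solveDelta(deltaDbHigh, params)
  esrMax <- .solveDelta(deltaDbLow, params)
  new("SizeBand", esrMin = esrMin, esrMax = esrMax,
      deltaDbAtMin = deltaDbHigh, deltaDbAtMax = deltaDbLow,
      kaMin = kaValue(esrMin, params), kaMax = kaValue(esrMax, params))
}

setMethod("show", "SizeBand", function(object) {
  cat(sprintf(
    "SizeBand: deltaTS [%.2f, %.2f] dB -> ESR [%.3f, %.3f] mm, ka [%.3f, %.3f]\n",
    object@deltaDbAtMax, object@deltaDbAtMin,
    object@esrMin, object@esrMax, object@kaMin, object@kaMax))
})

#' Invert a dB difference to equivalent spherical radius
#'
#' Monotone bracketing (bisection) inversion of [deltaTS()] on a
#' [SizeBand-class], to 1e-4 mm. Values above the band's upper dB edge clamp
#' to `esrMin`, below the lower edge to `esrMax`; clamped entries are flagged
#' and a warning is raised.
#'
#' @param deltaDb dB difference(s) to invert (vectorized).
#' @param params a [FluidSphereParams-class].
#' @param band a [SizeBand-class] (default the copepod band of `params`).
#' @param tol bisection tolerance in mm.
#' @return list with `esr` (mm) and `clamped` (logical), same length as
#'   `deltaDb`; NA in, NA out.
#' @examples
#' p <- fluidSphereParams()
#' invertSize(deltaTS(1.0, p), p)$esr  # round-trips to 1.0 mm
#' @export
invertSize <- function(deltaDb, params, band = sizeBand(params), tol = 1e-4) {
  if (deltaTS(band@esrMin, params) <= deltaTS(band@esrMax, params))
    stop("non-monotone band configuration")
  n <- length(deltaDb)
  esr <- rep(NA_real_, n)
  clamped <- rep(FALSE, n)
  ok <- !is.na(deltaDb)
  hiClamp <- ok & deltaDb >= band@deltaDbAtMin
  loClamp <- ok & deltaDb <= band@deltaDbAtMax
  esr[hiClamp] <- band@esrMin
  esr[loClamp] <- band@esrMax
  clamped[ (ok & deltaDb > band@deltaDbAtMin) |
           (ok & deltaDb < band@deltaDbAtMax) ] <- TRUE
  solve <- ok & !hiClamp & !loClamp
  if (any(solve)) {
    lo <- rep(band@esrMin, sum(solve))
    hi <- rep(band@esrMax, sum(solve))
    tgt <- deltaDb[solve]
    while (max(hi - lo) > tol) {
      mid <- (lo + hi) / 2
      up <- deltaTS(mid, params) > tgt   # still left of the crossing
      lo[up] <- mid[up]
      hi[!up] <- mid[!up]
    }
    esr[solve] <- (lo + hi) / 2
  }
  if (any(clamped))
    warning(sum(clamped), " dB difference(s) outside the size band; clamped")
  list(esr = esr, clamped = clamped)
}
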