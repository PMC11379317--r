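## Central S4 containers. All grids share the (ping, depth-bin) lattice
## convention: matrices are n_pings x n_bins, depth positive down, bin
## intervals half-open [top, bottom).

.checkPings <- function(pings, n) {
  req <- c("ping_index", "time_utc", "lat", "lon")
  if (!all(req %in% names(pings)))
    return(paste("pings must have columns", paste(req, collapse = ", ")))
  if (nrow(pings) != n)
    return("pings rows must match matrix rows")
  if (nrow(pings) > 1) {
    tt <- as.numeric(pings$time_utc)
    if (any(diff(tt) <= 0)) return("ping times must be strictly increasing")
    if (any(diff(pings$ping_index) <= 0))
      return("ping_index must be strictly increasing")
  }
  if (any(abs(pings$lat) > 90, na.rm = TRUE)) return("|lat| must be <= 90")
  if (any(abs(pings$lon) > 180, na.rm = TRUE)) return("|lon| must be <= 180")
  TRUE
}

#' SvGrid: a single-frequency volume-backscatter lattice
#'
#' Holds the linear volume backscattering coefficient `sv` (m^-1) on a
#' (ping, depth-bin) lattice, with per-ping time/position and depth-bin edges.
#' Missing samples are `NA`. Use [mvbs()] for the dB view.
#'
#' @slot frequency acoustic frequency in kHz.
#' @slot sv numeric matrix, n_pings x n_bins, linear sv (>= 0 or NA).
#' @slot depthEdges strictly increasing bin edges in m (positive down),
#'   length n_bins + 1.
#' @slot pings data.frame with columns `ping_index`, `time_utc` (POSIXct, UTC),
#'   `lat`, `lon`.
#' @seealso [svGrid()], [resampleToCells()], [alignBifreq()]
#' @export
setClass("SvGrid",
  slots = c(frequency = "numeric", sv = "matrix",
            depthEdges = "numeric", pings = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (length(object@frequency) != 1L || object@frequency <= 0)
      msg <- c(msg, "frequency must be a single positive number (kHz)")
    ne <- length(object@depthEdges)
    if (ne < 2L || any(diff(object@depthEdges) <= 0))
      msg <- c(msg, "depthEdges must be strictly increasing, length >= 2")
    if (ncol(object@sv) != ne - 1L)
      msg <- c(msg, "ncol(sv) must equal length(depthEdges) - 1")
    if (any(object@sv < 0, na.rm = TRUE))
      msg <- c(msg, "sv values must be >= 0 or NA")
    pm <- .checkPings(object@pings, nrow(object@sv))
    if (!isTRUE(pm)) msg <- c(msg, pm)
    if (length(msg)) msg else TRUE
  })

#' BiFreqCellGrid: co-registered 38/120 kHz analysis cells
#'
#' The two-frequency echo-integration lattice on which discrimination and
#' inversion operate. Cells missing in either channel are excluded. The
#' discriminant scores \eqn{\Sigma}MVBS (`mvbs120 + mvbs38`) and
#' \eqn{\Delta}MVBS (`mvbs120 - mvbs38`) are recomputed from the channels on
#' access, so they are exact by construction.
#'
#' @slot mvbs38,mvbs120 dB matrices (n_cells_ping x n_cells_depth), NA where
#'   the channel is missing.
#' @slot fLow,fHigh the two frequencies in kHz.
#' @slot depthEdges cell depth edges, m.
#' @slot pings per-cell-block geometry (mean time/position of member pings).
#' @seealso [alignBifreq()], [sumMvbs()], [deltaMvbs()], [excludedMask()]
#' @export
setClass("BiFreqCellGrid",
  slots = c(mvbs38 = "matrix", mvbs120 = "matrix",
            fLow = "numeric", fHigh = "numeric",
            depthEdges = "numeric", pings = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@mvbs38), dim(object@mvbs120)))
      msg <- c(msg, "mvbs38 and mvbs120 must have identical dimensions")
    if (length(object@depthEdges) != ncol(object@mvbs38) + 1L)
      msg <- c(msg, "depthEdges length must be ncol + 1")
    if (any(diff(object@depthEdges) <= 0))
      msg <- c(msg, "depthEdges must be strictly increasing")
    if (object@fHigh <= object@fLow || object@fLow <= 0)
      msg <- c(msg, "need fHigh > fLow > 0")
    pm <- .checkPings(object@pings, nrow(object@mvbs38))
    if (!isTRUE(pm)) msg <- c(msg, pm)
    if (length(msg)) msg else TRUE
  })

.MASK_LEVELS <- c("FISH", "KRILL", "COPEPOD", "OTHER", "EXCLUDED")
.PROV_LEVELS <- c("primary", "rescued", "clamped")

#' ClassMask: per-cell scatterer labels
#'
#' One label per analysis cell: `FISH`, `KRILL`, `COPEPOD`, `OTHER` or
#' `EXCLUDED` (missing input). Provenance records whether the label came from
#' the primary cascade, the fluid-in-fish rescue pass, or the upper-threshold
#' clamp.
#'
#' @slot labels character matrix over the mask levels.
#' @slot provenance character matrix over `primary`, `rescued`, `clamped`.
#' @seealso [classifyCells()], [rescueFluidInFish()], [maskLabels()]
#' @export
setClass("ClassMask",
  slots = c(labels = "matrix", provenance = "matrix"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@labels), dim(object@provenance)))
      msg <- c(msg, "labels and provenance must share dimensions")
    if (!all(object@labels %in% .MASK_LEVELS))
      msg <- c(msg, paste("labels must be in", paste(.MASK_LEVELS, collapse = "/")))
    if (!all(object@provenance %in% .PROV_LEVELS))
      msg <- c(msg, "invalid provenance value")
    if (length(msg)) msg else TRUE
  })

#' DensityGrid: per-cell inversion results
#'
#' For every copepod-classified cell: equivalent spherical radius from the
#' \eqn{\Delta}MVBS inversion, model target strengths at both frequencies, and
#' numerical density `nf = 10^((Sv - TS)/10)` (ind m^-3). Non-copepod cells
#' are invalid (`NA`).
#'
#' @slot esr mm; @slot ts38,ts120 dB re 1 m^2; @slot nf ind m^-3.
#' @slot valid logical matrix, TRUE where the cell was inverted.
#' @slot clamped logical matrix, TRUE where \eqn{\Delta}MVBS fell outside the
#'   size band and was clamped to a band edge.
#' @slot inversionFrequency kHz used for the density inversion.
#' @slot depthEdges,pings cell geometry (as in the parent grid).
#' @seealso [gridDensity()], [integrateEsu()]
#' @export
setClass("DensityGrid",
  slots = c(esr = "matrix", ts38 = "matrix", ts120 = "matrix", nf = "matrix",
            valid = "matrix", clamped = "matrix",
            inversionFrequency = "numeric",
            depthEdges = "numeric", pings = "data.frame"),
  validity = function(object) {
    msg <- character()
    dd <- dim(object@nf)
    for (s in c("esr", "ts38", "ts120", "valid", "clamped"))
      if (!identical(dim(slot(object, s)), dd))
        msg <- c(msg, paste(s, "dimensions must match nf"))
    if (any(object@nf < 0, na.rm = TRUE)) msg <- c(msg, "nf must be >= 0")
    if (any(!is.finite(object@nf[object@valid])))
      msg <- c(msg, "nf must be finite wherever valid")
    if (length(msg)) msg else TRUE
  })

#' FluidSphereParams: physical constants of the scattering model
#'
#' Density contrast `g`, sound-speed contrast `h`, seawater sound speed and
#' the frequency pair of the high-pass fluid-sphere model. Defaults are the
#' standard fluid-like crustacean values g = 1.02, h = 1.058 with
#' c = 1508 m s^-1 and the 38/120 kHz pair.
#'
#' @slot g density contrast (dimensionless, fluid-like plankton ~1).
#' @slot h sound-speed contrast (dimensionless).
#' @slot soundSpeed seawater sound speed, m s^-1.
#' @slot fLow,fHigh frequencies, kHz.
#' @seealso [fluidSphereParams()], [sigmaBs()], [deltaTS()]
#' @export
setClass("FluidSphereParams",
  slots = c(g = "numeric", h = "numeric", soundSpeed = "numeric",
            fLow = "numeric", fHigh = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@g <= 0.9 || object@g >= 1.2)
      msg <- c(msg, "g must lie in (0.9, 1.2) for fluid-like plankton")
    if (object@h <= 0.9 || object@h >= 1.2)
      msg <- c(msg, "h must lie in (0.9, 1.2) for fluid-like plankton")
    if (object@soundSpeed <= 1400 || object@soundSpeed >= 1600)
      msg <- c(msg, "soundSpeed must lie in (1400, 1600) m/s")
    if (object@fHigh <= object@fLow || object@fLow <= 0)
      msg <- c(msg, "need fHigh > fLow > 0")
    if (length(msg)) msg else TRUE
  })

#' SizeBand: the invertible \eqn{\Delta}TS window
#'
#' The dB-difference band over which the fluid-sphere \eqn{\Delta}TS curve is
#' monotone and used for size inversion, together with the equivalent
#' spherical radii and `ka` values (geometric-mean frequency) at its edges.
#' `deltaDbAtMin` is the (larger) dB difference at `esrMin`.
#'
#' @seealso [sizeBand()], [invertSize()]
#' @export
setClass("SizeBand",
  slots = c(esrMin = "numeric", esrMax = "numeric",
            deltaDbAtMin = "numeric", deltaDbAtMax = "numeric",
            kaMin = "numeric", kaMax = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@esrMin >= object@esrMax) msg <- c(msg, "need esrMin < esrMax")
    if (object@deltaDbAtMin <= object@deltaDbAtMax)
      msg <- c(msg, "deltaDb must decrease from esrMin to esrMax")
    if (length(msg)) msg else TRUE
  })

#' VariogramModel: fitted semivariance structure
#'
#' @slot model "spherical" or "exponential".
#' @slot nugget,psill,range semivariance parameters; range in km
#'   (great-circle metric).
#' @slot flat TRUE when the fit collapsed to no spatial structure.
#' @seealso [fitVariogram()], [ordinaryKrige()]
#' @export
setClass("VariogramModel",
  slots = c(model = "character", nugget = "numeric", psill = "numeric",
            range = "numeric", flat = "logical"),
  validity = function(object) {
    msg <- character()
    if (!object@model %in% c("spherical", "exponential"))
      msg <- c(msg, "model must be spherical or exponential")
    if (object@nugget < 0) msg <- c(msg, "nugget must be >= 0")
    if (object@psill <= 0) msg <- c(msg, "partial sill must be > 0")
    if (object@range <= 0) msg <- c(msg, "range must be > 0")
    if (length(msg)) msg else TRUE
  })

#' KrigedField: ordinary-kriging predictions on a regular lon/lat grid
#'
#' @slot grid data.frame with columns `lon`, `lat`, `pred` (mg m^-2),
#'   `var` (kriging variance), `area` (cell area, m^2, cos-latitude scaled),
#'   `negWeights` (count of negative kriging weights at the node).
#' @slot gridStep grid spacing in decimal degrees.
#' @slot vgm the [VariogramModel-class] used.
#' @seealso [ordinaryKrige()], [totalBiomass()]
#' @export
setClass("KrigedField",
  slots = c(grid = "data.frame", gridStep = "numeric", vgm = "VariogramModel"),
  validity = function(object) {
    req <- c("lon", "lat", "pred", "var", "area")
    if (!all(req %in% names(object@grid)))
      return(paste("grid must have columns", paste(req, collapse = ", ")))
    if (any(object@grid$area <= 0)) return("cell areas must be > 0")
    TRUE
  })

#' SyntheticTruth: configuration of the synthetic-survey generator
#'
#' Ground-truth scene description from which [genSurvey()] forward-models a
#' two-frequency echogram pair, [genNetSamples()] draws depth-stratified net
#' catches and [genZooscanTable()] draws a plankton-scanner measurement table.
#' Everything downstream is reproducible from `seed`.
#'
#' @slot seed integer random seed.
#' @slot config named list of scene parameters (see [syntheticTruth()]).
#' @seealso [syntheticTruth()], [genSurvey()]
#' @export
setClass("SyntheticTruth",
  slots = c(seed = "integer", config = "list"),
  validity = function(object) {
    if (length(object@seed) != 1L || is.na(object@seed))
      return("seed must be a single integer")
    TRUE
  })
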