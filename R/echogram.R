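#' Construct a single-frequency Sv grid
#'
#' @param frequency frequency in kHz.
#' @param sv n_pings x n_bins matrix of linear volume backscattering
#'   coefficients (m^-1); `NA` marks missing samples. Supply `svDb` instead to
#'   pass dB values.
#' @param depthEdges strictly increasing bin edges in m (positive down),
#'   length `ncol(sv) + 1`.
#' @param pings data.frame with `ping_index`, `time_utc` (POSIXct UTC),
#'   `lat`, `lon`; times strictly increasing.
#' @param svDb optional dB matrix, converted with [dbToLinear()].
#' @return an [SvGrid-class].
#' @examples
#' pings <- data.frame(ping_index = 1:2,
#'   time_utc = as.POSIXct(c("2014-03-05 10:00:00", "2014-03-05 10:00:02"),
#'                         tz = "UTC"),
#'   lat = c(14.5, 14.5), lon = c(-17.5, -17.5001))
#' svGrid(38, svDb = matrix(-70, 2, 3), depthEdges = 10:13, pings = pings)
#' @export
svGrid <- function(frequency, sv = NULL, depthEdges, pings, svDb = NULL) {
  if (is.null(sv)) {
    if (is.null(svDb)) stop("supply sv (linear) or svDb (dB)")
    sv <- dbToLinear(svDb)
  }
  new("SvGrid", frequency = as.numeric(frequency), sv = sv,
      depthEdges = as.numeric(depthEdges), pings = pings)
}

#' @rdname zoosonde-accessors
setMethod("frequency", "SvGrid", function(object) object@frequency)
#' @rdname zoosonde-accessors
setMethod("svMatrix", "SvGrid", function(object) object@sv)
#' @rdname zoosonde-accessors
setMethod("mvbs", "SvGrid", function(object) linearToDb(object@sv))
#' @rdname zoosonde-accessors
setMethod("depthEdges", "SvGrid", function(object) object@depthEdges)
#' @rdname zoosonde-accessors
setMethod("depthMidpoints", "SvGrid", function(object) {
  e <- object@depthEdges
  (e[-1] + e[-length(e)]) / 2
})
#' @rdname zoosonde-accessors
setMethod("pingInfo", "SvGrid", function(object) object@pings)
#' @rdname zoosonde-accessors
setMethod("nPings", "SvGrid", function(object) nrow(object@sv))
#' @rdname zoosonde-accessors
setMethod("nBins", "SvGrid", function(object) ncol(object@sv))

setMethod("show", "SvGrid", function(object) {
  cat(sprintf("SvGrid: %g kHz, %d pings x %d depth bins [%g, %g] m, %.1f%% missing\n",
              object@frequency, nrow(object@sv), ncol(object@sv),
              min(object@depthEdges), max(object@depthEdges),
              100 * mean(is.na(object@sv))))
})

#' Resample a raw-resolution Sv grid into echo-integration cells
#'
#' Averages member samples in the linear domain over blocks of
#' `pingsPerCell` pings by `metersPerCell` m, applying the integration floor
#' `lowerThresholdDb` per raw sample: samples below the floor (or missing)
#' do not contribute, and a cell with no qualifying sample is missing. The
#' cell lattice is anchored at the first ping and at the analysis ceiling
#' `depthRange[1]`; trailing partial cells are dropped.
#'
#' @param grid an [SvGrid-class] at raw resolution.
#' @param pingsPerCell integer >= 1 (3 in the reference configuration).
#' @param metersPerCell vertical cell size, m (> 0; 1 in the reference
#'   configuration).
#' @param lowerThresholdDb integration floor in dB (classically -80 dB; set
#'   well below the expected signal of the weakest channel when inverting
#'   weak scatterers).
#' @param depthRange analysis depth window, m (default c(10, 200)).
#' @return an [SvGrid-class] at cell resolution; cell ping geometry is the
#'   mean time/position of member pings.
#' @examples
#' # two samples at -70 and -60 dB average to -62.62 dB in the linear domain
#' linearToDb(mean(dbToLinear(c(-70, -60))))
#' @export
resampleToCells <- function(grid, pingsPerCell = 3L, metersPerCell = 1,
                            lowerThresholdDb = -80, depthRange = c(10, 200)) {
  stopifnot(is(grid, "SvGrid"))
  if (pingsPerCell < 1L) stop("pingsPerCell must be >= 1")
  if (metersPerCell <= 0) stop("metersPerCell must be > 0")
  sv <- grid@sv
  if (nrow(sv) == 0L || ncol(sv) == 0L) stop("empty grid")

  nBlocks <- nrow(sv) %/% pingsPerCell
  if (nBlocks < 1L) stop("fewer pings than pingsPerCell")
  mid <- depthMidpoints(grid)
  top <- max(depthRange[1], grid@depthEdges[1])
  bottom <- min(depthRange[2], grid@depthEdges[length(grid@depthEdges)])
  nCells <- floor((bottom - top) / metersPerCell)
  if (nCells < 1L) stop("no depth cells inside depthRange")
  cellEdges <- top + metersPerCell * (0:nCells)

  thrLin <- dbToLinear(lowerThresholdDb)
  svq <- sv
  svq[!is.na(svq) & svq < thrLin] <- NA  # below integration floor

  blockOf <- rep(seq_len(nBlocks), each = pingsPerCell)
  rowsUsed <- seq_len(nBlocks * pingsPerCell)
  cellOf <- floor((mid - top) / metersPerCell) + 1
  cellOf[mid < top | cellOf > nCells] <- NA

  out <- matrix(NA_real_, nBlocks, nCells)
  for (j in seq_len(nCells)) {
    cols <- which(!is.na(cellOf) & cellOf == j)
    if (!length(cols)) next
    sub <- svq[rowsUsed, cols, drop = FALSE]
    sums <- rowsum(rowSums(sub, na.rm = TRUE), blockOf)
    cnts <- rowsum(rowSums(!is.na(sub)), blockOf)
    v <- as.vector(sums / cnts)
    v[as.vector(cnts) == 0] <- NA
    out[, j] <- v
  }

  p <- grid@pings[rowsUsed, ]
  cellPings <- data.frame(
    ping_index = seq_len(nBlocks),
    time_utc = as.POSIXct(as.vector(rowsum(as.numeric(p$time_utc), blockOf)) /
                            pingsPerCell, origin = "1970-01-01", tz = "UTC"),
    lat = as.vector(rowsum(p$lat, blockOf)) / pingsPerCell,
    lon = as.vector(rowsum(p$lon, blockOf)) / pingsPerCell)

  new("SvGrid", frequency = grid@frequency, sv = out,
      depthEdges = cellEdges, pings = cellPings)
}

#' Co-register two single-frequency cell grids
#'
#' Pairs the 38 and 120 kHz cell lattices into a [BiFreqCellGrid-class].
#' Cells missing in either channel are excluded; \eqn{\Sigma}MVBS and
#' \eqn{\Delta}MVBS are derived from the channels on access.
#'
#' @param grid38,grid120 [SvGrid-class] objects on an identical cell lattice
#'   (same ping blocks, same depth bins).
#' @return a [BiFreqCellGrid-class].
#' @export
alignBifreq <- function(grid38, grid120) {
  stopifnot(is(grid38, "SvGrid"), is(grid120, "SvGrid"))
  if (nrow(grid38@sv) != nrow(grid120@sv))
    stop("mismatched lattice geometry: ping axis differs (",
         nrow(grid38@sv), " vs ", nrow(grid120@sv), " blocks)")
  if (!isTRUE(all.equal(grid38@depthEdges, grid120@depthEdges)))
    stop("mismatched lattice geometry: depth axis differs")
  if (grid120@frequency <= grid38@frequency)
    stop("grid120 must be the higher frequency")
  m38 <- linearToDb(grid38@sv)
  m120 <- linearToDb(grid120@sv)
  drop <- is.na(m38) | is.na(m120)
  m38[drop] <- NA
  m120[drop] <- NA
  new("BiFreqCellGrid", mvbs38 = m38, mvbs120 = m120,
      fLow = grid38@frequency, fHigh = grid120@frequency,
      depthEdges = grid38@depthEdges, pings = grid38@pings)
}

#' @rdname zoosonde-accessors
setMethod("mvbs38", "BiFreqCellGrid", function(object) object@mvbs38)
#' @rdname zoosonde-accessors
setMethod("mvbs120", "BiFreqCellGrid", function(object) object@mvbs120)
#' @rdname zoosonde-accessors
setMethod("sumMvbs", "BiFreqCellGrid", function(object) object@mvbs120 + object@mvbs38)
#' @rdname zoosonde-accessors
setMethod("deltaMvbs", "BiFreqCellGrid", function(object) object@mvbs120 - object@mvbs38)
#' @rdname zoosonde-accessors
setMethod("excludedMask", "BiFreqCellGrid", function(object) is.na(object@mvbs38))
#' @rdname zoosonde-accessors
setMethod("depthEdges", "BiFreqCellGrid", function(object) object@depthEdges)
#' @rdname zoosonde-accessors
setMethod("depthMidpoints", "BiFreqCellGrid", function(object) {
  e <- object@depthEdges
  (e[-1] + e[-length(e)]) / 2
})
#' @rdname zoosonde-accessors
setMethod("pingInfo", "BiFreqCellGrid", function(object) object@pings)
#' @rdname zoosonde-accessors
setMethod("nPings", "BiFreqCellGrid", function(object) nrow(object@mvbs38))
#' @rdname zoosonde-accessors
setMethod("nBins", "BiFreqCellGrid", function(object) ncol(object@mvbs38))

setMethod("show", "BiFreqCellGrid", function(object) {
  cat(sprintf("BiFreqCellGrid: %g/%g kHz, %d ping blocks x %d depth cells, %.1f%% excluded\n",
              object@fLow, object@fHigh, nrow(object@mvbs38),
              ncol(object@mvbs38), 100 * mean(excludedMask(object))))
})

#' @rdname zoosonde-accessors
setMethod("maskLabels", "ClassMask", function(object) object@labels)
#' @rdname zoosonde-accessors
setMethod("maskProvenance", "ClassMask", function(object) object@provenance)

setMethod("show", "ClassMask", function(object) {
  tab <- table(factor(object@labels, levels = .MASK_LEVELS))
  cat("ClassMask:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
})

#' @rdname zoosonde-accessors
setMethod("densityField", "DensityGrid", function(object) object@nf)
#' @rdname zoosonde-accessors
setMethod("esrField", "DensityGrid", function(object) object@esr)
#' @rdname zoosonde-accessors
setMethod("depthEdges", "DensityGrid", function(object) object@depthEdges)
#' @rdname zoosonde-accessors
setMethod("pingInfo", "DensityGrid", function(object) object@pings)

setMethod("show", "DensityGrid", function(object) {
  nv <- sum(object@valid)
  cat(sprintf("DensityGrid: %d x %d cells, %d inverted (%.1f%%), inversion at %g kHz\n",
              nrow(object@nf), ncol(object@nf), nv,
              100 * nv / length(object@nf), object@inversionFrequency))
})
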