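#' Pipeline configuration
#'
#' Assembles and validates every stage's settings. Defaults are the
#' reference configuration: 3 pings x 1 m cells, -80 dB integration floor,
#' -119 dB fish gate, 2/7/25 dB windows, -65 dB upper threshold, g = 1.02,
#' h = 1.058, c = 1508 m s^-1, 120 kHz inversion on the 7.0-19.7 dB band,
#' 0.001 nmi ESUs, DM_m = 217 ug, 0.05 degree kriging grid, +/-18 degree
#' diel band. Note the -80 dB floor suits strong-scatterer integration;
#' when inverting weak scatterers set `svThresholdDb` below the weak
#' channel's expected signal (the bundled synthetic scenarios use -140 dB).
#'
#' @param pingsPerCell,metersPerCell,svThresholdDb,depthRange
#'   echo-integration settings.
#' @param classifier a [classifierConfig()].
#' @param fitFishThreshold logical; refit the fish gate from the data's
#'   \eqn{\Sigma}MVBS distribution instead of using the configured value.
#' @param scattering a [FluidSphereParams-class].
#' @param bandDeltaDb dB edges (low, high) of the size-inversion band.
#' @param inversionFrequencyKhz 38 or 120.
#' @param esuLengthNmi,dmMeanUg,dielBandDeg ESU integration settings;
#'   `dmMeanUg` is overridden when a scanner table is supplied to
#'   [runPipeline()].
#' @param gridStepDeg,variogramModel,nNeighbors,krigeMinPoints kriging
#'   settings.
#' @param seed integer seed for any stochastic stage.
#' @return validated list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(pingsPerCell = 3L, metersPerCell = 1,
                           svThresholdDb = -80, depthRange = c(10, 200),
                           classifier = classifierConfig(),
                           fitFishThreshold = FALSE,
                           scattering = fluidSphereParams(),
                           bandDeltaDb = c(7.0, 19.7),
                           inversionFrequencyKhz = 120,
                           esuLengthNmi = 0.001, dmMeanUg = 217,
                           dielBandDeg = 18,
                           gridStepDeg = 0.05,
                           variogramModel = "spherical",
                           nNeighbors = 16L, krigeMinPoints = 10L,
                           seed = 1L) {
  stopifnot(inherits(classifier, "ClassifierConfig"),
            is(scattering, "FluidSphereParams"))
  if (pingsPerCell < 1 || metersPerCell <= 0)
    stop("invalid cell resolution")
  if (length(bandDeltaDb) != 2 || bandDeltaDb[1] >= bandDeltaDb[2])
    stop("bandDeltaDb must be increasing (low, high)")
  if (!inversionFrequencyKhz %in% c(scattering@fLow, scattering@fHigh))
    stop("inversionFrequencyKhz must match the scattering frequency pair")
  if (esuLengthNmi <= 0 || dmMeanUg <= 0) stop("invalid ESU settings")
  if (!variogramModel %in% c("spherical", "exponential"))
    stop("unknown variogram model")
  structure(as.list(environment()), class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Flat YAML keys mirror [pipelineConfig()] arguments; classifier and
#' scattering settings are nested under `classifier:` and `scattering:`
#' (keys `g`, `h`, `sound_speed` or `temperature`/`salinity`/`depth`,
#' `f_low_khz`, `f_high_khz`).
#'
#' @param path YAML file.
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  flat <- c("pingsPerCell", "metersPerCell", "svThresholdDb",
            "fitFishThreshold", "inversionFrequencyKhz", "esuLengthNmi",
            "dmMeanUg", "dielBandDeg", "gridStepDeg", "variogramModel",
            "nNeighbors", "krigeMinPoints", "seed")
  for (k in flat) if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  if (!is.null(y$depthRange)) args$depthRange <- as.numeric(y$depthRange)
  if (!is.null(y$bandDeltaDb)) args$bandDeltaDb <- as.numeric(y$bandDeltaDb)
  if (!is.null(y$classifier))
    args$classifier <- do.call(classifierConfig, y$classifier)
  if (!is.null(y$scattering)) {
    s <- y$scattering
    args$scattering <- fluidSphereParams(
      g = s$g %||% 1.02, h = s$h %||% 1.058,
      soundSpeed = s$sound_speed %||% 1508,
      fLow = s$f_low_khz %||% 38, fHigh = s$f_high_khz %||% 120,
      temperature = s$temperature, salinity = s$salinity %||% 35,
      depth = s$depth %||% 50)
  }
  do.call(pipelineConfig, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full bi-frequency pipeline
#'
#' Fixed stage order: resample both channels to analysis cells, co-register,
#' (optionally refit the fish gate), classify with rescue pass, invert
#' copepod cells to size and density, integrate to ESUs with diel labels,
#' summarize day/night, fit a variogram and krige areal biomass on the
#' lon/lat grid, aggregate total biomass with CV, and screen spatial
#' autocorrelation with Moran's I. Kriging uses the non-transition ESUs.
#'
#' @param survey `list(sv38 =, sv120 =)` of raw [SvGrid-class] objects, or a
#'   path readable by [readSurvey()].
#' @param config a [pipelineConfig()].
#' @param zooscan optional scanner table (data.frame or path); when given,
#'   the mean individual dry mass is recomputed from it (ESR > 0.5 mm,
#'   copepods only) and replaces `config$dmMeanUg`.
#' @param dialect survey dialect when `survey` is a path.
#' @param verbose log stage progress with `message()`.
#' @return list with `esu`, `diel`, `variogram`, `kriged`, `totals`,
#'   `moransI`, `mask`, `density`, `grid` and a `report` list (stage counts,
#'   thresholds and DM_m actually used).
#' @export
runPipeline <- function(survey, config = pipelineConfig(), zooscan = NULL,
                        dialect = "csv", verbose = TRUE) {
  stopifnot(inherits(config, "PipelineConfig"))
  say <- function(...) if (verbose) message("[zoosonde] ", sprintf(...))
  set.seed(config$seed)
  if (is.character(survey)) survey <- readSurvey(survey, dialect)

  say("resampling to %d pings x %g m cells (floor %g dB)",
      config$pingsPerCell, config$metersPerCell, config$svThresholdDb)
  r38 <- resampleToCells(survey$sv38, config$pingsPerCell,
                         config$metersPerCell, config$svThresholdDb,
                         config$depthRange)
  r120 <- resampleToCells(survey$sv120, config$pingsPerCell,
                          config$metersPerCell, config$svThresholdDb,
                          config$depthRange)
  grid <- alignBifreq(r38, r120)
  say("grid: %d blocks x %d cells, %.1f%% excluded", nPings(grid),
      nBins(grid), 100 * mean(excludedMask(grid)))

  cls <- config$classifier
  if (isTRUE(config$fitFishThreshold)) {
    s <- sumMvbs(grid)
    cls$fishSumThreshold <- fitFishThreshold(s[is.finite(s)], cls)
    say("fitted fish gate at %.2f dB", cls$fishSumThreshold)
  }
  mask <- rescueFluidInFish(classifyCells(grid, cls), grid, cls)
  counts <- table(factor(maskLabels(mask), levels = .MASK_LEVELS))
  say("labels: %s", paste(names(counts), counts, sep = "=", collapse = " "))

  band <- sizeBand(config$scattering, config$bandDeltaDb[1],
                   config$bandDeltaDb[2])
  density <- gridDensity(grid, mask, config$scattering, band,
                         config$inversionFrequencyKhz)

  dmUsed <- config$dmMeanUg
  if (!is.null(zooscan)) {
    if (is.character(zooscan)) zooscan <- readZooscanTable(zooscan)
    S <- pxToMm2(zooscan$area_px)
    keep <- esrFromArea(S) > 0.5 & zooscan$taxon == "Copepoda"
    dmUsed <- sum(dryMass(S[keep]) * zooscan$split_factor[keep]) /
      sum(zooscan$split_factor[keep])
    say("mean individual dry mass from scanner table: %.1f ug", dmUsed)
  }

  esu <- integrateEsu(density, grid, config$esuLengthNmi, config$depthRange,
                      dmUsed, config$dielBandDeg)
  say("%d ESUs (%s)", nrow(esu),
      paste(levels(esu$diel), table(esu$diel), sep = "=", collapse = " "))
  diel <- dielAggregate(esu)

  pts <- esu[esu$diel != "transition" & is.finite(esu$B_mg_m2), ]
  vgm <- kriged <- totals <- NULL
  mi <- NA_real_
  if (nrow(pts) >= config$krigeMinPoints && stats::sd(pts$B_mg_m2) > 0) {
    emp <- empiricalVariogram(pts$lon, pts$lat, pts$B_mg_m2)
    vgm <- suppressWarnings(fitVariogram(emp, config$variogramModel))
    kriged <- ordinaryKrige(pts$lon, pts$lat, pts$B_mg_m2, vgm,
                            config$gridStepDeg, config$nNeighbors)
    totals <- suppressMessages(totalBiomass(kriged))
    say("kriged %d nodes; B_t = %.1f t (CV %.1f%%)", nrow(kriged@grid),
        totals$Bt_tons, totals$cv_percent)
    mi <- moransI(pts$B_mg_m2, pts$lon, pts$lat)
    say("Moran's I on ESU biomass: %.3f", mi)
  } else say("too few ESUs for kriging; skipped")

  list(esu = esu, diel = diel, variogram = vgm, kriged = kriged,
       totals = totals, moransI = mi, mask = mask, density = density,
       grid = grid,
       report = list(cellCounts = as.list(counts),
                     fishThresholdDb = cls$fishSumThreshold,
                     dmMeanUg = dmUsed,
                     band = c(esrMin = band@esrMin, esrMax = band@esrMax),
                     Bt_tons = if (!is.null(totals)) totals$Bt_tons else NA,
                     cv_percent = if (!is.null(totals)) totals$cv_percent
                                  else NA,
                     moransI = mi))
}

#' Write the ESU table as CSV
#'
#' @param esu ESU table from [integrateEsu()].
#' @param path output CSV.
#' @export
writeEsuTable <- function(esu, path) {
  out <- esu
  out$time_utc <- format(out$time_utc, "%Y-%m-%dT%H:%M:%OS3", tz = "UTC")
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
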