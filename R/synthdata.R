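#' Describe a synthetic survey scene
#'
#' Fixes the ground truth from which [genSurvey()], [genNetSamples()] and
#' [genZooscanTable()] draw: a patchy epipelagic copepod layer (log-Gaussian
#' along-track density, log-normal sizes), krill patches whose model
#' \eqn{\Delta}TS falls in the 2-7 dB window, fish schools with high
#' \eqn{\Sigma}MVBS and non-positive \eqn{\Delta}MVBS, a x7 night:day diel
#' factor, dB-domain noise, and a net catch efficiency linking acoustic and
#' net scales. Everything is reproducible from `seed`.
#'
#' @param seed integer seed.
#' @param nPings number of raw pings (timestamps span the full diel cycle).
#' @param pingsPerBlock raw pings per analysis ping-block (default 3).
#' @param depthTop,depthBottom,binM analysis depth window and raw bin
#'   height, m.
#' @param startLon,startLat,lonStepDeg,nTransects,transectLatStepDeg track
#'   geometry: zigzag transects stepped in latitude.
#' @param startTime POSIXct survey start (UTC).
#' @param pingIntervalS seconds between pings.
#' @param copepodDensity mean daytime copepod density in the layer,
#'   ind m^-3 (acoustic scale). The default 10, with the x7 diel factor and
#'   the ~75 m effective layer, puts areal dry-mass biomass in the
#'   ~120-1100 mg m^-2 range typical of productive upwelling surveys.
#' @param densitySdLog along-track log-Gaussian patchiness (sd of log).
#' @param densityCorrBlocks patch correlation length, ping blocks.
#' @param esrMedianMm,esrSdLog copepod size distribution (log-normal).
#' @param layerCenterM,layerSdM Gaussian vertical layer shape.
#' @param nKrillPatches,krillDensity,krillEsrMm krill patch settings.
#' @param nFishSchools,fishSv38Db,fishDeltaRange fish school settings
#'   (\eqn{\Delta}MVBS drawn uniformly in `fishDeltaRange`, <= 0).
#' @param dielFactor night:day density multiplier (default 7).
#' @param noiseSdDb per-sample, per-channel Gaussian dB noise sd.
#' @param netEfficiency net catch efficiency q in (0, 1]; q = 0.1 reproduces
#'   a tenfold acoustic:net discrepancy.
#' @param scattering a [FluidSphereParams-class] used by the forward model.
#' @return a [SyntheticTruth-class].
#' @export
syntheticTruth <- function(seed = 1L, nPings = 600L, pingsPerBlock = 3L,
                           depthTop = 10, depthBottom = 200, binM = 1,
                           startLon = -17.8, startLat = 14.3,
                           lonStepDeg = 0.005, nTransects = 4L,
                           transectLatStepDeg = 0.08,
                           startTime = as.POSIXct("2014-03-05 00:00:00",
                                                  tz = "UTC"),
                           pingIntervalS = 144,
                           copepodDensity = 10, densitySdLog = 0.5,
                           densityCorrBlocks = 10,
                           esrMedianMm = 0.9, esrSdLog = 0.15,
                           layerCenterM = 50, layerSdM = 30,
                           nKrillPatches = 2L, krillDensity = 20,
                           krillEsrMm = 3.5,
                           nFishSchools = 3L, fishSv38Db = -58,
                           fishDeltaRange = c(-3, 0),
                           dielFactor = 7, noiseSdDb = 1,
                           netEfficiency = 0.1,
                           scattering = fluidSphereParams()) {
  if (copepodDensity < 0 || krillDensity < 0) stop("densities must be >= 0")
  if (netEfficiency <= 0 || netEfficiency > 1)
    stop("netEfficiency must be in (0, 1]")
  if (any(fishDeltaRange > 0)) stop("fish deltaMVBS draw must be <= 0")
  if (nPings < pingsPerBlock) stop("empty domain")
  cfg <- as.list(environment())
  cfg$seed <- NULL
  new("SyntheticTruth", seed = as.integer(seed), config = cfg)
}

setMethod("show", "SyntheticTruth", function(object) {
  c <- object@config
  cat(sprintf(paste0("SyntheticTruth: seed=%d, %d pings, copepod %g ind/m3 ",
                     "(ESR median %g mm), diel x%g, noise %g dB\n"),
              object@seed, c$nPings, c$copepodDensity, c$esrMedianMm,
              c$dielFactor, c$noiseSdDb))
})

## Scene realization shared by the generators: block-level density/size
## fields, labels, and track geometry. Deterministic given the seed.
.realizeScene <- function(truth) {
  c <- truth@config
  set.seed(truth@seed)
  nBlocks <- c$nPings %/% c$pingsPerBlock
  edges <- seq(c$depthTop, c$depthBottom, by = c$binM)
  nBins <- length(edges) - 1L
  mid <- (edges[-1] + edges[-length(edges)]) / 2

  # track: zigzag transects
  perT <- ceiling(c$nPings / c$nTransects)
  tIdx <- rep(seq_len(c$nTransects), each = perT)[seq_len(c$nPings)]
  within <- sequence(rle(tIdx)$lengths) - 1L
  lon <- ifelse(tIdx %% 2L == 1L,
                c$startLon + within * c$lonStepDeg,
                c$startLon + (perT - 1 - within) * c$lonStepDeg)
  lat <- c$startLat + (tIdx - 1L) * c$transectLatStepDeg
  times <- c$startTime + (seq_len(c$nPings) - 1L) * c$pingIntervalS
  pings <- data.frame(ping_index = seq_len(c$nPings), time_utc = times,
                      lat = lat, lon = lon)

  # along-track log-Gaussian density (AR(1) in log, stationary sd densitySdLog)
  phi <- exp(-1 / c$densityCorrBlocks)
  x <- numeric(nBlocks)
  x[1] <- rnorm(1, 0, c$densitySdLog)
  if (nBlocks > 1)
    for (i in 2:nBlocks)
      x[i] <- phi * x[i - 1] + rnorm(1, 0, c$densitySdLog * sqrt(1 - phi^2))
  nBlock <- c$copepodDensity * exp(x - c$densitySdLog^2 / 2)
  esrBlock <- rlnorm(nBlocks, log(c$esrMedianMm), c$esrSdLog)

  # diel factor from solar altitude at the block mid-time
  bt <- times[seq(1, nBlocks * c$pingsPerBlock, by = c$pingsPerBlock)] +
    (c$pingsPerBlock - 1) * c$pingIntervalS / 2
  bi <- seq(1, nBlocks * c$pingsPerBlock, by = c$pingsPerBlock)
  alt <- solarAltitude(bt, lat[bi], lon[bi])
  dielBlock <- as.character(dielLabel(alt))
  factorBlock <- ifelse(dielBlock == "night", c$dielFactor, 1)

  profile <- exp(-(mid - c$layerCenterM)^2 / (2 * c$layerSdM^2))
  density <- outer(nBlock * factorBlock, profile)   # nBlocks x nBins
  labels <- matrix("copepod", nBlocks, nBins)

  rspan <- function(len, max) {
    s <- sample.int(max(1L, max - len), 1L)
    s:min(max, s + len - 1L)
  }
  krill <- vector("list", c$nKrillPatches)
  if (c$nKrillPatches > 0) for (p in seq_len(c$nKrillPatches)) {
    rb <- rspan(10L, nBlocks); rz <- rspan(30L, nBins)
    labels[rb, rz] <- "krill"
    density[rb, rz] <- c$krillDensity
    krill[[p]] <- list(blocks = rb, bins = rz)
  }
  fish <- vector("list", c$nFishSchools)
  if (c$nFishSchools > 0) for (p in seq_len(c$nFishSchools)) {
    rb <- rspan(4L, nBlocks); rz <- rspan(15L, nBins)
    dd <- runif(1, c$fishDeltaRange[1], c$fishDeltaRange[2])
    labels[rb, rz] <- "fish"
    density[rb, rz] <- 0
    fish[[p]] <- list(blocks = rb, bins = rz, deltaDb = dd)
  }

  list(cfg = c, nBlocks = nBlocks, nBins = nBins, edges = edges, mid = mid,
       pings = pings, nBlock = nBlock, esrBlock = esrBlock,
       dielBlock = dielBlock, factorBlock = factorBlock,
       density = density, labels = labels, krill = krill, fish = fish)
}

#' Forward-model a two-frequency synthetic survey
#'
#' Builds raw-resolution 38 and 120 kHz Sv grids from the scene:
#' `sv_f = N sigma_bs(ESR, f)` for copepod and krill cells (so a noise-free
#' copepod cell's \eqn{\Delta}MVBS equals the model \eqn{\Delta}TS of its
#' size exactly), fish schools override both channels with a high 38 kHz
#' level and a drawn non-positive \eqn{\Delta}MVBS, and Gaussian dB noise is
#' added per sample and channel. Zero-density samples are missing.
#'
#' @param truth a [SyntheticTruth-class].
#' @return list with `sv38`, `sv120` ([SvGrid-class] at raw resolution) and
#'   `truth`: the realized scene (block-level density/ESR/label matrices,
#'   diel factors, per-block areal copepod abundance `arealN` in ind m^-2,
#'   track geometry).
#' @export
genSurvey <- function(truth) {
  stopifnot(is(truth, "SyntheticTruth"))
  sc <- .realizeScene(truth)
  c <- sc$cfg
  pars <- c$scattering

  s38block <- matrix(0, sc$nBlocks, sc$nBins)
  s120block <- matrix(0, sc$nBlocks, sc$nBins)
  cop <- sc$labels == "copepod"
  sig38 <- sigmaBs(sc$esrBlock, pars@fLow, pars)
  sig120 <- sigmaBs(sc$esrBlock, pars@fHigh, pars)
  s38block[cop] <- (sc$density * matrix(sig38, sc$nBlocks, sc$nBins))[cop]
  s120block[cop] <- (sc$density * matrix(sig120, sc$nBlocks, sc$nBins))[cop]
  kr <- sc$labels == "krill"
  s38block[kr] <- sc$density[kr] * sigmaBs(c$krillEsrMm, pars@fLow, pars)
  s120block[kr] <- sc$density[kr] * sigmaBs(c$krillEsrMm, pars@fHigh, pars)
  for (f in sc$fish) {
    s38block[f$blocks, f$bins] <- dbToLinear(c$fishSv38Db)
    s120block[f$blocks, f$bins] <- dbToLinear(c$fishSv38Db + f$deltaDb)
  }

  expand <- function(m) m[rep(seq_len(sc$nBlocks), each = c$pingsPerBlock), ,
                          drop = FALSE]
  nUsed <- sc$nBlocks * c$pingsPerBlock
  s38 <- expand(s38block); s120 <- expand(s120block)
  if (nUsed < c$nPings) {   # trailing pings beyond full blocks: repeat last
    extra <- c$nPings - nUsed
    s38 <- rbind(s38, s38[rep(nUsed, extra), , drop = FALSE])
    s120 <- rbind(s120, s120[rep(nUsed, extra), , drop = FALSE])
  }
  toDb <- function(m) {
    db <- suppressWarnings(linearToDb(m))
    db[!is.finite(db)] <- NA
    db
  }
  db38 <- toDb(s38); db120 <- toDb(s120)
  if (c$noiseSdDb > 0) {
    db38 <- db38 + matrix(rnorm(length(db38), 0, c$noiseSdDb), nrow(db38))
    db120 <- db120 + matrix(rnorm(length(db120), 0, c$noiseSdDb), nrow(db120))
  }

  arealN <- as.vector((sc$density * cop) %*% rep(c$binM, sc$nBins))
  list(
    sv38 = new("SvGrid", frequency = pars@fLow, sv = dbToLinear(db38),
               depthEdges = sc$edges, pings = sc$pings),
    sv120 = new("SvGrid", frequency = pars@fHigh, sv = dbToLinear(db120),
                depthEdges = sc$edges, pings = sc$pings),
    truth = list(density = sc$density, esrBlock = sc$esrBlock,
                 labels = sc$labels, diel = sc$dielBlock,
                 dielFactor = sc$factorBlock, arealN = arealN,
                 pings = sc$pings, depthEdges = sc$edges,
                 krill = sc$krill, fish = sc$fish, nBlock = sc$nBlock))
}

.DEFAULT_STRATA <- data.frame(top = c(10, 25, 50, 75, 100),
                              bottom = c(25, 50, 75, 100, 200))

#' Draw depth-stratified net samples from the truth
#'
#' Expected catch per stratum is `mean(N) x volume x q` with
#' `volume = mouth area x stratum height x towFactor` (oblique tow);
#' realized counts are Poisson. The net-scale abundance estimate
#' `count / volume` is therefore `q` times the acoustic-scale truth on
#' average.
#'
#' @param truth a [SyntheticTruth-class].
#' @param survey output of [genSurvey()] for the same truth.
#' @param nStations number of stations, placed at fixed track fractions.
#' @param strata data.frame with `top` and `bottom` (m).
#' @param mouthArea net mouth area, m^2 (default 0.25).
#' @param towFactor tow length as a multiple of stratum height (default 5).
#' @return list with `stations` and `samples` data.frames; `samples` has
#'   the truth mean density, expected and realized counts, filtered volume
#'   and the net abundance estimate per station x stratum.
#' @export
genNetSamples <- function(truth, survey, nStations = 4L,
                          strata = .DEFAULT_STRATA, mouthArea = 0.25,
                          towFactor = 5) {
  stopifnot(is(truth, "SyntheticTruth"))
  if (any(strata$bottom <= strata$top)) stop("bad strata")
  tr <- survey$truth
  c <- truth@config
  set.seed(truth@seed + 7919L)
  nBlocks <- nrow(tr$density)
  at <- pmax(1L, pmin(nBlocks, round(nBlocks *
                                       seq(0.125, 0.875, length.out = nStations))))
  mid <- (tr$depthEdges[-1] + tr$depthEdges[-length(tr$depthEdges)]) / 2
  bi <- (at - 1L) * c$pingsPerBlock + 1L
  stations <- data.frame(station = seq_len(nStations), block = at,
                         lon = tr$pings$lon[bi], lat = tr$pings$lat[bi],
                         time_utc = tr$pings$time_utc[bi],
                         diel = tr$diel[at])
  rows <- list()
  for (s in seq_len(nStations)) {
    for (k in seq_len(nrow(strata))) {
      inz <- mid >= strata$top[k] & mid < strata$bottom[k]
      dens <- tr$density[at[s], inz]
      isCop <- tr$labels[at[s], inz] == "copepod"
      meanN <- mean(ifelse(isCop, dens, 0))
      height <- strata$bottom[k] - strata$top[k]
      vol <- mouthArea * height * towFactor
      if (vol <= 0) stop("zero filtered volume")
      expected <- meanN * vol * c$netEfficiency
      count <- rpois(1, expected)
      rows[[length(rows) + 1L]] <- data.frame(
        station = s, stratum_top_m = strata$top[k],
        stratum_bottom_m = strata$bottom[k], volume_m3 = vol,
        true_mean_n = meanN, expected = expected, count = count,
        abundance_ind_m3 = count / vol)
    }
  }
  list(stations = stations, samples = do.call(rbind, rows))
}

#' Draw a synthetic plankton-scanner measurement table
#'
#' Sizes come from the truth's copepod size distribution (plus a small
#' euphausiid fraction); pixel areas invert the area chain
#' `ESR -> S = pi ESR^2 -> px = S / 0.0106^2` with multiplicative
#' log-normal measurement noise.
#'
#' @param truth a [SyntheticTruth-class].
#' @param nItems number of objects (>= 1).
#' @param measurementNoiseSd sd of the log-normal pixel-area noise
#'   (0 = exact inverse chain).
#' @param krillFraction fraction of euphausiid objects.
#' @param strata strata recycled over items.
#' @return data.frame in the scanner-table schema (see
#'   [readZooscanTable()]).
#' @export
genZooscanTable <- function(truth, nItems = 2000L, measurementNoiseSd = 0.05,
                            krillFraction = 0.05, strata = .DEFAULT_STRATA) {
  stopifnot(is(truth, "SyntheticTruth"))
  if (nItems < 1) stop("nItems must be >= 1")
  c <- truth@config
  set.seed(truth@seed + 104729L)
  isKrill <- runif(nItems) < krillFraction
  esr <- ifelse(isKrill,
                rlnorm(nItems, log(c$krillEsrMm), 0.1),
                rlnorm(nItems, log(c$esrMedianMm), c$esrSdLog))
  areaMm2 <- pi * esr^2
  noise <- if (measurementNoiseSd > 0)
    exp(rnorm(nItems, 0, measurementNoiseSd)) else 1
  px <- pmax(1, round(areaMm2 * noise / 0.0106^2))
  k <- nrow(strata)
  idx <- ((seq_len(nItems) - 1L) %% k) + 1L
  data.frame(station = ((seq_len(nItems) - 1L) %/% (nItems / 4)) %% 4L + 1L,
             net = idx,
             stratum_top_m = strata$top[idx],
             stratum_bottom_m = strata$bottom[idx],
             taxon = ifelse(isKrill, "Euphausiacea", "Copepoda"),
             area_px = px,
             split_factor = sample(c(1, 2, 4), nItems, replace = TRUE,
                                   prob = c(0.8, 0.15, 0.05)))
}
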