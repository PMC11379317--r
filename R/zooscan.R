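#' Convert scanner object area from pixels to mm^2
#'
#' `S = px * 0.0106^2`: the flatbed-scanner pixel pitch is 0.0106 mm
#' (10.6 um) at 2400 dpi.
#'
#' @param objectAreaPx object area in pixels (> 0).
#' @return body area in mm^2.
#' @export
pxToMm2 <- function(objectAreaPx) {
  if (any(objectAreaPx <= 0)) stop("object area must be > 0 px")
  objectAreaPx * 0.0106^2
}

#' Equivalent spherical radius from 2-D body area
#'
#' `ESR = sqrt(S / pi)`: the radius of the circle with the scanned body's
#' area.
#'
#' @param areaMm2 body area, mm^2 (> 0).
#' @return ESR in mm.
#' @export
esrFromArea <- function(areaMm2) {
  if (any(areaMm2 <= 0)) stop("area must be > 0")
  sqrt(areaMm2 / pi)
}

#' Allometric area-to-dry-mass model
#'
#' `DM = intercept * S^exponent` with DM in micrograms and S in mm^2. The
#' coefficients are not universal: the defaults (45.25, 1.59) are
#' literature values for subtropical mesozooplankton and are configuration,
#' not measurements — results scale with them accordingly.
#'
#' @param intercept ug mm^-2b (> 0).
#' @param exponent dimensionless slope (> 0).
#' @return list of class `AllometricModel`.
#' @export
allometricModel <- function(intercept = 45.25, exponent = 1.59) {
  if (intercept <= 0 || exponent <= 0)
    stop("allometric coefficients must be > 0")
  structure(list(intercept = intercept, exponent = exponent),
            class = "AllometricModel")
}

#' Individual dry mass from body area
#'
#' @param areaMm2 body area, mm^2 (> 0; vectorized).
#' @param model an [allometricModel()].
#' @return dry mass in micrograms.
#' @examples
#' dryMass(2)  # 45.25 * 2^1.59
#' @export
dryMass <- function(areaMm2, model = allometricModel()) {
  if (any(areaMm2 <= 0)) stop("area must be > 0")
  model$intercept * areaMm2^model$exponent
}

#' Describe a net station
#'
#' @param station station identifier.
#' @param lat,lon position, decimal degrees.
#' @param time deployment time (POSIXct, UTC).
#' @param volumes data.frame with columns `net` and `volume_m3` (> 0), the
#'   flowmeter-filtered volume per net/stratum.
#' @param mouthArea net mouth opening, m^2 (default 0.25).
#' @return list of class `NetStation`.
#' @export
netStation <- function(station, lat, lon, time, volumes, mouthArea = 0.25) {
  stopifnot(is.data.frame(volumes), all(c("net", "volume_m3") %in% names(volumes)))
  if (any(volumes$volume_m3 <= 0)) stop("filtered volumes must be > 0")
  structure(list(station = station, lat = lat, lon = lon, time = time,
                 volumes = volumes, mouthArea = mouthArea),
            class = "NetStation")
}

#' Read a scanner measurement table
#'
#' Flat EcoTaxa-export-like table with columns `station`, `net`,
#' `stratum_top_m`, `stratum_bottom_m`, `taxon`, `area_px`, `split_factor`.
#' Comma- or tab-separated by file extension.
#'
#' @param path CSV/TSV path.
#' @return validated data.frame.
#' @export
readZooscanTable <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- read.csv(path, sep = sep)
  req <- c("station", "net", "stratum_top_m", "stratum_bottom_m", "taxon",
           "area_px", "split_factor")
  if (!all(req %in% names(df)))
    stop("zooscan table must have columns ", paste(req, collapse = ", "))
  if (any(df$area_px <= 0)) stop("area_px must be > 0")
  if (any(df$split_factor < 1)) stop("split_factor must be >= 1")
  if (any(df$stratum_top_m >= df$stratum_bottom_m))
    stop("stratum top must be above bottom")
  df
}

#' Per-stratum abundance, biomass and mean dry mass at one station
#'
#' Filters scanned objects to `ESR > esrMin`, then per net/stratum:
#' abundance `= sum(split_factor) / volume` (ind m^-3) and biomass
#' `= sum(DM * split_factor) / volume` (ug m^-3). The station mean
#' individual dry mass is the count-weighted mean DM over retained objects.
#'
#' @param items scanner table rows for this station (see
#'   [readZooscanTable()]).
#' @param station a [netStation()] providing per-net filtered volumes.
#' @param model an [allometricModel()].
#' @param esrMin retention threshold, mm (default 0.5).
#' @param taxa optional taxon filter (e.g. "Copepoda").
#' @return list with `strata` (data.frame: net, stratum_top_m,
#'   stratum_bottom_m, count, abundance_ind_m3, biomass_ug_m3) and `meanDm`
#'   (ug).
#' @export
stationSummary <- function(items, station, model = allometricModel(),
                           esrMin = 0.5, taxa = NULL) {
  stopifnot(inherits(station, "NetStation"))
  if (!is.null(taxa)) items <- items[items$taxon %in% taxa, , drop = FALSE]
  S <- pxToMm2(items$area_px)
  keep <- esrFromArea(S) > esrMin
  items <- items[keep, , drop = FALSE]
  S <- S[keep]
  dm <- dryMass(S, model)
  sp <- items$split_factor

  nets <- unique(items[, c("net", "stratum_top_m", "stratum_bottom_m")])
  vol <- station$volumes$volume_m3[match(nets$net, station$volumes$net)]
  if (any(is.na(vol)))
    stop("missing filtered volume for net(s): ",
         paste(nets$net[is.na(vol)], collapse = ", "))
  count <- abundance <- biomass <- numeric(nrow(nets))
  for (i in seq_len(nrow(nets))) {
    sel <- items$net == nets$net[i]
    count[i] <- sum(sp[sel])
    abundance[i] <- sum(sp[sel]) / vol[i]
    biomass[i] <- sum(dm[sel] * sp[sel]) / vol[i]
  }
  meanDm <- if (sum(sp) > 0) sum(dm * sp) / sum(sp) else NA_real_
  list(strata = data.frame(nets, volume_m3 = vol, count = count,
                           abundance_ind_m3 = abundance,
                           biomass_ug_m3 = biomass),
       meanDm = meanDm)
}

#' Spearman comparison of paired acoustic and net estimates
#'
#' Spearman's rho with mid-rank ties; two-sided p-value from the
#' t-approximation `t = rho sqrt((n-2)/(1-rho^2))` on n-2 degrees of
#' freedom (p = 0 at |rho| = 1).
#'
#' @param acoustic,net paired estimates (same length, n >= 5).
#' @return list with `rho`, `p_value`, `n`.
#' @export
spearmanCompare <- function(acoustic, net) {
  ok <- is.finite(acoustic) & is.finite(net)
  x <- acoustic[ok]; y <- net[ok]
  n <- length(x)
  if (n < 5) stop("need >= 5 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rho undefined for a constant vector")
  rho <- stats::cor(x, y, method = "spearman")
  p <- if (abs(rho) >= 1) 0 else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(t), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}
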