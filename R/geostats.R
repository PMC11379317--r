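#' Empirical (Matheron) semivariogram
#'
#' Classical estimator `gamma(h) = mean(0.5 (z_i - z_j)^2)` over great-circle
#' distance bins.
#'
#' @param lon,lat coordinates, decimal degrees (>= 10 points).
#' @param value observed values.
#' @param nBins number of equal-width distance bins (default 12).
#' @param maxDist maximum pair distance, km (default half the largest pair
#'   distance).
#' @return data.frame of class `EmpiricalVariogram` with `h` (mean pair
#'   distance, km), `gamma`, `np` (pair count); empty bins dropped.
#' @export
empiricalVariogram <- function(lon, lat, value, nBins = 12, maxDist = NULL) {
  n <- length(value)
  if (n < 10) stop("need >= 10 points")
  D <- .gcDistMatrixKm(lon, lat)
  if (max(D) == 0) stop("all points coincident")
  if (is.null(maxDist)) maxDist <- max(D) / 2
  iu <- which(upper.tri(D), arr.ind = TRUE)
  h <- D[iu]
  g <- 0.5 * (value[iu[, 1]] - value[iu[, 2]])^2
  keep <- h > 0 & h <= maxDist
  h <- h[keep]; g <- g[keep]
  bin <- pmin(nBins, floor(h / (maxDist / nBins)) + 1L)
  out <- data.frame(
    h = as.vector(tapply(h, bin, mean)),
    gamma = as.vector(tapply(g, bin, mean)),
    np = as.vector(tapply(g, bin, length)))
  out <- out[order(out$h), ]
  rownames(out) <- NULL
  structure(out, class = c("EmpiricalVariogram", "data.frame"),
            maxDist = maxDist)
}

## semivariance of a fitted model; gamma(0) = 0 by convention so kriging is
## exact at data locations
.vgmValue <- function(vgm, h) {
  g <- ifelse(h < vgm@range,
              vgm@nugget + vgm@psill *
                (1.5 * h / vgm@range - 0.5 * (h / vgm@range)^3),
              vgm@nugget + vgm@psill)
  if (vgm@model == "exponential")
    g <- vgm@nugget + vgm@psill * (1 - exp(-3 * h / vgm@range))
  g[h == 0] <- 0
  g
}

#' Fit a variogram model by weighted least squares
#'
#' Minimizes `sum(np/h^2 (gamma - model(h))^2)` over nugget, partial sill
#' and range, from a deterministic grid of starting values. A fit whose
#' range collapses to the minimum bound is flagged `flat` (no spatial
#' structure) with a warning.
#'
#' @param emp an [empiricalVariogram()] result (>= 4 non-empty bins,
#'   non-negative semivariances).
#' @param model "spherical" (default) or "exponential".
#' @return a [VariogramModel-class] (range in km).
#' @export
fitVariogram <- function(emp, model = c("spherical", "exponential")) {
  model <- match.arg(model)
  if (nrow(emp) < 4) stop("need >= 4 non-empty bins")
  if (any(emp$gamma < 0)) stop("negative semivariances rejected")
  h <- emp$h; g <- emp$gamma; w <- emp$np / pmax(h, 1e-6)^2
  hmax <- max(h); gmax <- max(g)
  if (gmax == 0) stop("flat zero variogram: no variability to fit")
  rmin <- hmax * 1e-3

  obj <- function(p) {
    vg <- new("VariogramModel", model = model, nugget = p[1],
              psill = max(p[2], 1e-12), range = max(p[3], rmin), flat = FALSE)
    sum(w * (g - .vgmValue(vg, h))^2)
  }
  starts <- expand.grid(nugget = c(0, min(g)),
                        psill = c(gmax, gmax / 2),
                        range = c(hmax / 4, hmax / 2, hmax))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(as.numeric(starts[i, ]), obj, method = "L-BFGS-B",
            lower = c(0, 1e-10, rmin),
            upper = c(2 * gmax, 10 * gmax, 10 * hmax)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("variogram fit did not converge")
  p <- best$par
  # a range at or below the first lag (or a vanishing partial sill) means no
  # structure is resolvable at the observed distances
  flat <- p[3] <= min(h) * 1.001 || p[2] <= 1e-6 * gmax
  if (flat) warning("variogram range collapsed toward minimum: ",
                    "no resolvable spatial structure")
  new("VariogramModel", model = model, nugget = p[1],
      psill = max(p[2], 1e-10), range = max(p[3], rmin), flat = flat)
}

setMethod("show", "VariogramModel", function(object) {
  cat(sprintf("VariogramModel (%s): nugget=%.4g psill=%.4g range=%.4g km%s\n",
              object@model, object@nugget, object@psill, object@range,
              if (object@flat) " [flat]" else ""))
})

## ray-casting point-in-polygon (polygon closed implicitly)
.inPolygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Ordinary kriging on a regular lon/lat grid
#'
#' Solves the standard ordinary-kriging system (semivariance form, weights
#' summing to one) per grid node using the nearest `nNeighbors` data points
#' by great-circle distance. With a zero nugget the predictor is exact at
#' data locations. Nodes outside the survey polygon (default the data's
#' convex hull) are skipped; cell areas are spherical-geometry areas and
#' shrink with cos(latitude).
#'
#' @param lon,lat,value data points (n >= 1).
#' @param vgm a [VariogramModel-class].
#' @param gridStep grid spacing, decimal degrees (default 0.05).
#' @param nNeighbors kriging neighbourhood size (default 16).
#' @param polygon optional data.frame/matrix with columns lon, lat defining
#'   the interpolation region; default convex hull of the data.
#' @return a [KrigedField-class].
#' @export
ordinaryKrige <- function(lon, lat, value, vgm, gridStep = 0.05,
                          nNeighbors = 16, polygon = NULL) {
  stopifnot(is(vgm, "VariogramModel"))
  n <- length(value)
  if (n < 1) stop("need at least one data point")
  gx <- seq(min(lon), max(lon) + gridStep / 2, by = gridStep)
  gy <- seq(min(lat), max(lat) + gridStep / 2, by = gridStep)
  nodes <- expand.grid(lon = gx, lat = gy)
  if (is.null(polygon) && n >= 3) {
    hull <- grDevices::chull(lon, lat)
    polygon <- cbind(lon = lon[hull], lat = lat[hull])
  }
  if (!is.null(polygon) && nrow(polygon) >= 3) {
    keep <- .inPolygon(nodes$lon, nodes$lat, polygon[, 1], polygon[, 2])
    # always keep nodes nearest the data so tiny surveys still map
    if (!any(keep)) keep <- rep(TRUE, nrow(nodes))
    nodes <- nodes[keep, , drop = FALSE]
  }
  k <- min(nNeighbors, n)

  pred <- vr <- numeric(nrow(nodes))
  negw <- integer(nrow(nodes))
  sill <- vgm@nugget + vgm@psill   # scale the system: weights are invariant
  for (q in seq_len(nrow(nodes))) {
    d0 <- .gcDistKm(lon, lat, nodes$lon[q], nodes$lat[q])
    sel <- order(d0)[seq_len(k)]
    Dk <- .gcDistMatrixKm(lon[sel], lat[sel])
    G <- .vgmValue(vgm, Dk) / sill
    A <- rbind(cbind(G, 1), c(rep(1, k), 0))
    g0 <- .vgmValue(vgm, d0[sel]) / sill
    b <- c(g0, 1)
    sol <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(sol)) {
      diag(A) <- diag(A) + c(rep(1e-9, k), 0)  # jitter retry once
      sol <- tryCatch(solve(A, b), error = function(e)
        stop("singular kriging system at node ", q))
    }
    lam <- sol[seq_len(k)]
    pred[q] <- sum(lam * value[sel])
    vr[q] <- max(0, (sum(lam * g0) + sol[k + 1]) * sill)
    negw[q] <- sum(lam < -1e-10)
  }

  stepRad <- gridStep * pi / 180
  area <- .EARTH_RADIUS_M^2 * stepRad *
    (sin((nodes$lat + gridStep / 2) * pi / 180) -
       sin((nodes$lat - gridStep / 2) * pi / 180))
  new("KrigedField",
      grid = data.frame(lon = nodes$lon, lat = nodes$lat, pred = pred,
                        var = vr, area = area, negWeights = negw),
      gridStep = gridStep, vgm = vgm)
}

setMethod("show", "KrigedField", function(object) {
  cat(sprintf("KrigedField: %d nodes at %.3g deg, pred in [%.4g, %.4g]\n",
              nrow(object@grid), object@gridStep,
              min(object@grid$pred), max(object@grid$pred)))
})

#' Total biomass and its coefficient of variation from a kriged field
#'
#' `B_t = sum(B_i A_i)` converted mg to metric tons. The CV aggregates the
#' per-cell kriging variances under cell independence:
#' `CV = 100 sqrt(sum(var_i A_i^2)) / sum(B_i A_i)` — an approximation, since
#' kriging errors are spatially correlated. Negative predictions are clipped
#' to zero and counted.
#'
#' @param field a [KrigedField-class] with predictions in mg m^-2.
#' @return list with `Bt_tons`, `cv_percent`, `nClipped`.
#' @export
totalBiomass <- function(field) {
  stopifnot(is(field, "KrigedField"))
  g <- field@grid
  nClip <- sum(g$pred < 0)
  if (nClip) message(nClip, " negative kriging prediction(s) clipped to 0")
  b <- pmax(g$pred, 0)
  btMg <- sum(b * g$area)
  cv <- if (btMg > 0) 100 * sqrt(sum(g$var * g$area^2)) / btMg else NA_real_
  list(Bt_tons = btMg / 1e9, cv_percent = cv, nClipped = nClip)
}

#' Global Moran's I spatial autocorrelation
#'
#' `I = (n / S0) * sum_ij w_ij (z_i - zbar)(z_j - zbar) / sum_i (z_i - zbar)^2`
#' with row-standardized weights; by default inverse great-circle distance.
#' Values near 0 indicate negligible autocorrelation; the permutation-null
#' expectation is `-1/(n-1)`.
#'
#' @param value observed values (n >= 4, non-constant).
#' @param lon,lat coordinates (used for the default weights).
#' @param weights optional n x n weight matrix (zero diagonal); it is
#'   row-standardized internally.
#' @return Moran's I (dimensionless).
#' @export
moransI <- function(value, lon = NULL, lat = NULL, weights = NULL) {
  n <- length(value)
  if (n < 4) stop("need >= 4 locations")
  if (stats::sd(value) == 0) stop("Moran's I undefined for constant values")
  if (is.null(weights)) {
    D <- .gcDistMatrixKm(lon, lat)
    if (any(D[upper.tri(D)] == 0)) stop("coincident points: supply weights")
    weights <- 1 / D
    diag(weights) <- 0
  }
  if (!identical(dim(weights), c(n, n))) stop("weights must be n x n")
  diag(weights) <- 0
  rs <- rowSums(weights)
  if (any(rs == 0)) stop("weight matrix has an isolated location")
  W <- weights / rs
  z <- value - mean(value)
  (n / sum(W)) * as.numeric(t(z) %*% W %*% z) / sum(z^2)
}
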