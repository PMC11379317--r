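#' Classifier configuration
#'
#' Thresholds of the discrimination cascade. Defaults are the reference
#' settings: fish gate at \eqn{\Sigma}MVBS > -119 dB, fluid-like windows
#' \eqn{\Delta}MVBS in 2-7 dB (krill, half-open) and 7-25 dB (copepod, ties at
#' 7 dB going to copepod), upper 120 kHz MVBS threshold -65 dB, 3x3 rescue
#' neighbourhood.
#'
#' @param fishSumThreshold dB; cells with \eqn{\Sigma}MVBS above it are FISH.
#' @param deltaOtherMax dB; \eqn{\Delta}MVBS below it is OTHER.
#' @param deltaKrillMax dB; krill window is deltaOtherMax <= delta < deltaKrillMax.
#' @param deltaCopepodMax dB; copepod window is
#'   deltaKrillMax <= delta <= deltaCopepodMax.
#' @param upperMvbsThreshold dB; non-fish cells with 120 kHz MVBS above it
#'   are reclassified OTHER.
#' @param rescueWindow odd window size (cells) of the fluid-in-fish rescue.
#' @return a validated list of class `ClassifierConfig`.
#' @export
classifierConfig <- function(fishSumThreshold = -119, deltaOtherMax = 2,
                             deltaKrillMax = 7, deltaCopepodMax = 25,
                             upperMvbsThreshold = -65, rescueWindow = 3L) {
  cfg <- list(fishSumThreshold = fishSumThreshold,
              deltaOtherMax = deltaOtherMax,
              deltaKrillMax = deltaKrillMax,
              deltaCopepodMax = deltaCopepodMax,
              upperMvbsThreshold = upperMvbsThreshold,
              rescueWindow = as.integer(rescueWindow))
  if (!all(vapply(cfg, is.finite, logical(1))))
    stop("classifier thresholds must be finite")
  if (!(cfg$deltaOtherMax < cfg$deltaKrillMax &&
        cfg$deltaKrillMax < cfg$deltaCopepodMax))
    stop("need deltaOtherMax < deltaKrillMax < deltaCopepodMax")
  if (cfg$rescueWindow < 1L || cfg$rescueWindow %% 2L == 0L)
    stop("rescueWindow must be odd and >= 1")
  structure(cfg, class = "ClassifierConfig")
}

## Two-component univariate Gaussian mixture by EM with deterministic
## restarts: initial partitions at the decile split points, best final
## log-likelihood wins. No RNG involved, so results are reproducible by
## construction.
.em2gauss <- function(x, nRestarts = 10, maxIter = 300, tol = 1e-9) {
  n <- length(x)
  splits <- stats::quantile(x, seq_len(nRestarts) / (nRestarts + 1),
                            names = FALSE)
  best <- NULL
  for (s in splits) {
    grp <- x > s
    if (!any(grp) || all(grp)) next
    w <- c(mean(!grp), mean(grp))
    mu <- c(mean(x[!grp]), mean(x[grp]))
    sg <- pmax(c(stats::sd(x[!grp]), stats::sd(x[grp])), 1e-3)
    sg[is.na(sg)] <- 1e-3
    ll0 <- -Inf
    for (it in seq_len(maxIter)) {
      d1 <- w[1] * dnorm(x, mu[1], sg[1])
      d2 <- w[2] * dnorm(x, mu[2], sg[2])
      tot <- d1 + d2
      tot[tot == 0] <- .Machine$double.xmin
      ll <- sum(log(tot))
      r <- d2 / tot
      w <- c(1 - mean(r), mean(r))
      mu <- c(sum((1 - r) * x) / sum(1 - r), sum(r * x) / sum(r))
      sg <- sqrt(c(sum((1 - r) * (x - mu[1])^2) / sum(1 - r),
                   sum(r * (x - mu[2])^2) / sum(r)))
      sg <- pmax(sg, 1e-3)
      if (is.finite(ll) && abs(ll - ll0) < tol * (abs(ll0) + 1)) break
      ll0 <- ll
    }
    if (is.null(best) || ll > best$ll)
      best <- list(ll = ll, w = w, mu = mu, sg = sg)
  }
  if (is.null(best)) stop("mixture fit failed")
  best
}

#' Fit the fish gate threshold from the \eqn{\Sigma}MVBS distribution
#'
#' Fits a two-component univariate Gaussian mixture by EM (unequal
#' variances, 10 deterministic decile-split restarts) and returns the
#' decision boundary where the two weighted component densities are equal,
#' restricted to the interval between the component means. If the components
#' overlap to within 1 dB of means, the configured default is returned with
#' a warning.
#'
#' @param sumMvbsValues finite \eqn{\Sigma}MVBS values (at least 200,
#'   spanning at least 10 dB).
#' @param cfg a [classifierConfig()]; supplies the fallback threshold.
#' @return threshold in dB.
#' @export
fitFishThreshold <- function(sumMvbsValues, cfg = classifierConfig()) {
  x <- sumMvbsValues[is.finite(sumMvbsValues)]
  if (stats::sd(x) == 0 || length(unique(x)) == 1L)
    stop("degenerate input: constant values")
  if (length(x) < 200) stop("need >= 200 finite values")
  if (diff(range(x)) < 10) stop("values must span >= 10 dB")

  fit <- .em2gauss(x)
  mu <- fit$mu; sg <- fit$sg; w <- fit$w
  o <- order(mu)
  mu <- mu[o]; sg <- sg[o]; w <- w[o]
  if (diff(mu) < 1) {
    warning("mixture components overlap; falling back to configured threshold")
    return(cfg$fishSumThreshold)
  }
  f <- function(z) w[1] * dnorm(z, mu[1], sg[1]) - w[2] * dnorm(z, mu[2], sg[2])
  out <- tryCatch(uniroot(f, lower = mu[1], upper = mu[2])$root,
                  error = function(e) NA_real_)
  if (is.na(out)) {
    warning("no equal-density point between means; falling back to default")
    return(cfg$fishSumThreshold)
  }
  out
}

#' Classify analysis cells into fish / krill / copepod / other
#'
#' Applies the discrimination cascade in fixed order: (1) the
#' \eqn{\Sigma}MVBS fish gate; (2) \eqn{\Delta}MVBS below the fluid window is
#' OTHER; (3) krill window 2-7 dB (half-open); (4) copepod window 7-25 dB (closed); (5)
#' above the copepod window is OTHER; (6) any non-fish cell whose 120 kHz
#' MVBS exceeds the upper threshold is reclassified OTHER (provenance
#' `clamped`). Missing cells are EXCLUDED.
#'
#' @param grid a [BiFreqCellGrid-class].
#' @param cfg a [classifierConfig()].
#' @return a [ClassMask-class].
#' @export
classifyCells <- function(grid, cfg = classifierConfig()) {
  stopifnot(is(grid, "BiFreqCellGrid"))
  s <- sumMvbs(grid); d <- deltaMvbs(grid); m120 <- mvbs120(grid)
  lab <- matrix("EXCLUDED", nrow(s), ncol(s))
  prov <- matrix("primary", nrow(s), ncol(s))
  ok <- !is.na(s)
  fish <- ok & s > cfg$fishSumThreshold
  lab[fish] <- "FISH"
  rest <- ok & !fish
  lab[rest & d < cfg$deltaOtherMax] <- "OTHER"
  lab[rest & d >= cfg$deltaOtherMax & d < cfg$deltaKrillMax] <- "KRILL"
  lab[rest & d >= cfg$deltaKrillMax & d <= cfg$deltaCopepodMax] <- "COPEPOD"
  lab[rest & d > cfg$deltaCopepodMax] <- "OTHER"
  hot <- ok & lab != "FISH" & lab != "OTHER" & m120 > cfg$upperMvbsThreshold
  lab[hot] <- "OTHER"
  prov[hot] <- "clamped"
  new("ClassMask", labels = lab, provenance = prov)
}

#' Rescue fluid-like echoes inside fish regions
#'
#' Single deterministic pass (ping-major scan over the pre-pass mask): a FISH
#' cell whose \eqn{\Delta}MVBS lies in the krill or copepod window and whose
#' `rescueWindow` neighbourhood holds a majority of fluid-like labels is
#' relabelled to the class matching its own dB window, provenance `rescued`.
#'
#' @param mask a [ClassMask-class] from [classifyCells()].
#' @param grid the matching [BiFreqCellGrid-class].
#' @param cfg a [classifierConfig()].
#' @return a [ClassMask-class].
#' @export
rescueFluidInFish <- function(mask, grid, cfg = classifierConfig()) {
  stopifnot(is(mask, "ClassMask"), is(grid, "BiFreqCellGrid"))
  lab0 <- mask@labels
  if (!identical(dim(lab0), dim(mvbs38(grid))))
    stop("mask and grid are not congruent")
  lab <- lab0; prov <- mask@provenance
  d <- deltaMvbs(grid)
  r <- (cfg$rescueWindow - 1L) %/% 2L
  nr <- nrow(lab0); nc <- ncol(lab0)
  fishIdx <- which(lab0 == "FISH", arr.ind = TRUE)
  if (nrow(fishIdx)) fishIdx <- fishIdx[order(fishIdx[, 1], fishIdx[, 2]), ,
                                        drop = FALSE]
  for (k in seq_len(nrow(fishIdx))) {
    i <- fishIdx[k, 1]; j <- fishIdx[k, 2]
    dd <- d[i, j]
    if (is.na(dd) || dd < cfg$deltaOtherMax || dd > cfg$deltaCopepodMax) next
    ri <- max(1L, i - r):min(nr, i + r)
    rj <- max(1L, j - r):min(nc, j + r)
    nb <- lab0[ri, rj]
    nb <- nb[-(which(ri == i) + (which(rj == j) - 1L) * length(ri))]
    if (sum(nb %in% c("KRILL", "COPEPOD")) > length(nb) / 2) {
      lab[i, j] <- if (dd >= cfg$deltaKrillMax) "COPEPOD" else "KRILL"
      prov[i, j] <- "rescued"
    }
  }
  new("ClassMask", labels = lab, provenance = prov)
}
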