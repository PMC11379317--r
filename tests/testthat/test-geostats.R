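ptsGrid <- function(n = 12, seed = 1, spread = 0.5) {
  set.seed(seed)
  list(lon = -17.5 + runif(n, 0, spread), lat = 14.3 + runif(n, 0, spread))
}

test_that("the empirical variogram matches a brute-force Matheron estimate", {
  p <- ptsGrid(12, seed = 3)
  set.seed(3)
  z <- rnorm(12)
  D <- geosphere::distm(cbind(p$lon, p$lat),
                        fun = geosphere::distHaversine) / 1000
  # brute force: all pairs, one bin
  iu <- which(upper.tri(D), arr.ind = TRUE)
  gBrute <- mean(0.5 * (z[iu[, 1]] - z[iu[, 2]])^2)
  emp <- empiricalVariogram(p$lon, p$lat, z, nBins = 1, maxDist = max(D))
  expect_equal(emp$gamma, gBrute)
  expect_equal(emp$np, nrow(iu))
})

test_that("constant and white-noise fields have the expected variograms", {
  p <- ptsGrid(30, seed = 5)
  empC <- empiricalVariogram(p$lon, p$lat, rep(5, 30), nBins = 4)
  expect_true(all(empC$gamma == 0))

  set.seed(6)
  z <- rnorm(400)
  p2 <- ptsGrid(400, seed = 6)
  empN <- empiricalVariogram(p2$lon, p2$lat, z, nBins = 6)
  # flat at the field variance, within sampling error
  expect_true(all(abs(empN$gamma - var(z)) < 0.35))

  expect_error(empiricalVariogram(rep(0, 10), rep(0, 10), rnorm(10)),
               "coincident")
  expect_error(empiricalVariogram(1:5 / 10, 1:5 / 10, rnorm(5)), ">= 10")
})

test_that("WLS fitting recovers a known spherical structure", {
  # simulate a Gaussian random field from the model by Cholesky, on a
  # domain much wider than the range so the empirical sill is unbiased
  trueVgm <- new("VariogramModel", model = "spherical", nugget = 0.1,
                 psill = 1, range = 55, flat = FALSE)   # ~0.5 deg in km
  p <- ptsGrid(200, seed = 11, spread = 5)
  D <- geosphere::distm(cbind(p$lon, p$lat),
                        fun = geosphere::distHaversine) / 1000
  C <- (trueVgm@nugget + trueVgm@psill) - zoosonde:::.vgmValue(trueVgm, D)
  diag(C) <- trueVgm@nugget + trueVgm@psill
  set.seed(12)
  z <- as.vector(t(chol(C + diag(1e-8, 200))) %*% rnorm(200))
  emp <- empiricalVariogram(p$lon, p$lat, z, nBins = 20, maxDist = 250)
  fit <- fitVariogram(emp, "spherical")
  expect_equal(fit@nugget + fit@psill, 1.1, tolerance = 0.25)
  expect_equal(fit@range, 55, tolerance = 0.25)
  expect_false(fit@flat)
})

test_that("structureless and invalid empirical variograms are handled", {
  emp <- data.frame(h = c(5, 10, 15, 20), gamma = rep(1, 4), np = 50)
  expect_warning(fit <- fitVariogram(emp), "structure")
  expect_true(fit@flat)
  bad <- data.frame(h = 1:4, gamma = c(-0.1, 1, 1, 1), np = 10)
  expect_error(fitVariogram(bad), "negative")
  expect_error(fitVariogram(emp[1:3, ]), "bins")
})

test_that("ordinary kriging is exact at data points with zero nugget", {
  vgm <- new("VariogramModel", model = "spherical", nugget = 0, psill = 4,
             range = 30, flat = FALSE)
  p <- ptsGrid(15, seed = 7)
  set.seed(7)
  z <- 100 + rnorm(15, 0, 2)
  # snap data onto grid nodes so nodes coincide with observations
  lon <- round(p$lon / 0.05) * 0.05
  lat <- round(p$lat / 0.05) * 0.05
  dup <- duplicated(cbind(lon, lat))
  lon <- lon[!dup]; lat <- lat[!dup]; z <- z[!dup]
  kf <- ordinaryKrige(lon, lat, z, vgm, gridStep = 0.05, polygon = NULL)
  g <- kf@grid
  for (i in seq_along(z)) {
    hit <- which(abs(g$lon - lon[i]) < 1e-9 & abs(g$lat - lat[i]) < 1e-9)
    if (length(hit)) {
      expect_lt(abs(g$pred[hit] - z[i]), 1e-6)
      expect_lt(g$var[hit], 1e-6)
    }
  }
})

test_that("kriging weights sum to one (translation equivariance)", {
  vgm <- new("VariogramModel", model = "exponential", nugget = 0.5,
             psill = 2, range = 20, flat = FALSE)
  p <- ptsGrid(25, seed = 9)
  set.seed(9)
  z <- rnorm(25, 50, 5)
  k1 <- ordinaryKrige(p$lon, p$lat, z, vgm, gridStep = 0.1)
  k2 <- ordinaryKrige(p$lon, p$lat, z + 1000, vgm, gridStep = 0.1)
  expect_equal(k2@grid$pred, k1@grid$pred + 1000, tolerance = 1e-8)
})

test_that("degenerate kriging inputs give flat surfaces", {
  vgm <- new("VariogramModel", model = "spherical", nugget = 0, psill = 1,
             range = 10, flat = FALSE)
  k1 <- ordinaryKrige(-17.5, 14.3, 42, vgm, gridStep = 0.05)
  expect_true(all(k1@grid$pred == 42))
  k2 <- ordinaryKrige(c(-17.5, -17.4), c(14.3, 14.35), c(7, 7), vgm)
  expect_equal(k2@grid$pred, rep(7, nrow(k2@grid)), tolerance = 1e-9)
})

test_that("total biomass aggregates cell-by-cell and is order invariant", {
  mk <- function(pred, area, vr = 0) {
    vgm <- new("VariogramModel", model = "spherical", nugget = 0, psill = 1,
               range = 10, flat = FALSE)
    new("KrigedField",
        grid = data.frame(lon = seq_along(pred), lat = 0, pred = pred,
                          var = vr, area = area, negWeights = 0L),
        gridStep = 0.05, vgm = vgm)
  }
  # uniform 100 mg/m2 over 1e9 m2 = 1e11 mg = 100 t
  expect_equal(totalBiomass(mk(rep(100, 4), rep(2.5e8, 4)))$Bt_tons, 100)
  expect_equal(totalBiomass(mk(rep(0, 4), rep(2.5e8, 4)))$Bt_tons, 0)
  expect_equal(totalBiomass(mk(rep(100, 4), rep(5e8, 4)))$Bt_tons, 200)
  set.seed(1)
  pr <- runif(10, 0, 50); ar <- runif(10, 1e7, 1e8)
  o <- sample(10)
  expect_equal(totalBiomass(mk(pr, ar))$Bt_tons,
               totalBiomass(mk(pr[o], ar[o]))$Bt_tons)
  # negative predictions are clipped and counted
  expect_message(out <- totalBiomass(mk(c(-5, 10), rep(1e9, 2))), "clipped")
  expect_equal(out$nClipped, 1L)
  expect_equal(out$Bt_tons, 10)
})

test_that("Moran's I matches brute force on the rook checkerboard", {
  # 2x2 lattice, values 1,0,0,1, rook adjacency
  z <- c(1, 0, 0, 1)
  W <- matrix(c(0, 1, 1, 0,
                1, 0, 0, 1,
                1, 0, 0, 1,
                0, 1, 1, 0), 4, 4, byrow = TRUE)
  # brute-force evaluation of the definition over the 4 sites
  Wr <- W / rowSums(W)
  zc <- z - mean(z)
  bruteI <- (4 / sum(Wr)) *
    sum(outer(zc, zc) * Wr) / sum(zc^2)
  expect_equal(bruteI, -1)
  expect_equal(moransI(z, weights = W), -1)
})

test_that("Moran's I sign and null expectation behave as expected", {
  # clustered gradient: strong positive autocorrelation
  lon <- seq(-18, -17, length.out = 20)
  lat <- rep(14.3, 20) + seq(0, 0.1, length.out = 20)
  grad <- seq(0, 10, length.out = 20)
  expect_gt(moransI(grad, lon, lat), 0)
  # permutation null: E[I] = -1/(n-1)
  set.seed(13)
  perms <- replicate(300, moransI(sample(grad), lon, lat))
  expect_equal(mean(perms), -1 / 19, tolerance = 0.02)
  expect_error(moransI(rep(1, 10), lon[1:10], lat[1:10]), "constant")
  expect_error(moransI(1:3, lon[1:3], lat[1:3]), ">= 4")
})

test_that("Moran's I agrees with an independent implementation", {
  skip_if_not_installed("ape")
  set.seed(14)
  lon <- -17.5 + runif(15, 0, 0.5); lat <- 14.3 + runif(15, 0, 0.5)
  z <- rnorm(15)
  D <- geosphere::distm(cbind(lon, lat), fun = geosphere::distHaversine) / 1000
  W <- 1 / D; diag(W) <- 0
  Wr <- W / rowSums(W)
  ref <- ape::Moran.I(z, Wr, scaled = FALSE)
  expect_equal(moransI(z, lon, lat), ref$observed, tolerance = 1e-10)
})
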