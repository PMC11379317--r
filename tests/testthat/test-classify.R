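test_that("the cascade applies the fish gate before the dB windows", {
  # one row of cells: (sum, delta) pairs
  g <- makeCellGrid(matrix(c(-110, -160, -160, -160, -160, NA), 1, 6),
                    matrix(c(10,   10,    4,   -3,   30, NA), 1, 6))
  lab <- maskLabels(classifyCells(g))
  expect_equal(as.vector(lab),
               c("FISH", "COPEPOD", "KRILL", "OTHER", "OTHER", "EXCLUDED"))
})

test_that("window edges are half-open with ties at 7 dB going to copepod", {
  g <- makeCellGrid(matrix(-160, 1, 4), matrix(c(2, 6.999, 7, 25), 1, 4))
  expect_equal(as.vector(maskLabels(classifyCells(g))),
               c("KRILL", "KRILL", "COPEPOD", "COPEPOD"))
})

test_that("the upper MVBS threshold reclassifies hot fluid cells", {
  # sum = -130, delta = 10 puts the 120 kHz channel at -60 dB > -65
  g <- makeCellGrid(matrix(c(-130, -160), 1, 2), matrix(c(10, 10), 1, 2))
  m <- classifyCells(g)
  expect_equal(as.vector(maskLabels(m)), c("OTHER", "COPEPOD"))
  expect_equal(as.vector(maskProvenance(m)), c("clamped", "primary"))
})

test_that("every non-missing cell gets exactly one label", {
  set.seed(21)
  g <- makeCellGrid(matrix(runif(60, -200, -100), 6, 10),
                    matrix(runif(60, -10, 30), 6, 10))
  lab <- maskLabels(classifyCells(g))
  expect_true(all(lab %in% c("FISH", "KRILL", "COPEPOD", "OTHER")))
  expect_equal(sum(table(lab)), 60L)
})

test_that("raising the fish gate never increases the fish count", {
  set.seed(22)
  g <- makeCellGrid(matrix(runif(200, -200, -100), 10, 20),
                    matrix(runif(200, -5, 25), 10, 20))
  nFish <- function(thr) sum(maskLabels(classifyCells(
    g, classifierConfig(fishSumThreshold = thr))) == "FISH")
  counts <- vapply(seq(-160, -100, by = 10), nFish, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("mixture threshold recovery is within 1.5 dB of the analytic point", {
  # two-component mixture: N(-140, 5^2) w=0.8 and N(-100, 6^2) w=0.2
  analytic <- uniroot(function(z)
    0.8 * dnorm(z, -140, 5) - 0.2 * dnorm(z, -100, 6),
    lower = -140, upper = -100)$root
  set.seed(1)
  x <- c(rnorm(4000, -140, 5), rnorm(1000, -100, 6))
  expect_lt(abs(fitFishThreshold(x) - analytic), 1.5)

  # stability across seeds
  errs <- vapply(1:20, function(s) {
    set.seed(s)
    x <- c(rnorm(1600, -140, 5), rnorm(400, -100, 6))
    abs(fitFishThreshold(x) - analytic)
  }, numeric(1))
  expect_true(all(errs < 1.5))
})

test_that("threshold fitting handles separation and degeneracy", {
  set.seed(3)
  x <- c(rnorm(500, -140, 0.5), rnorm(500, -100, 0.5))
  thr <- fitFishThreshold(x)
  expect_gt(thr, -140); expect_lt(thr, -100)
  expect_error(fitFishThreshold(rep(-120, 500)), "constant")
  expect_error(fitFishThreshold(rnorm(100, -120, 6)), "200")
  expect_error(fitFishThreshold(rnorm(500, -120, 1)), "span")
})

test_that("fluid echoes inside fish regions are rescued by majority vote", {
  mkMask <- function(centerDelta, ring) {
    s <- matrix(-160, 3, 3); s[2, 2] <- -110   # center gated FISH
    d <- matrix(12, 3, 3); d[2, 2] <- centerDelta
    if (ring == "FISH") s[] <- -110
    if (ring == "KRILL") d[-5] <- 4
    g <- makeCellGrid(s, d)
    list(g = g, m = classifyCells(g))
  }
  x <- mkMask(12, "COPEPOD")
  r <- rescueFluidInFish(x$m, x$g)
  expect_equal(maskLabels(r)[2, 2], "COPEPOD")
  expect_equal(maskProvenance(r)[2, 2], "rescued")

  # own window decides the rescued class
  x2 <- mkMask(4, "KRILL")
  expect_equal(maskLabels(rescueFluidInFish(x2$m, x2$g))[2, 2], "KRILL")

  # delta outside the fluid windows: stays fish
  x3 <- mkMask(-5, "COPEPOD")
  expect_equal(maskLabels(rescueFluidInFish(x3$m, x3$g))[2, 2], "FISH")

  # no fluid majority: stays fish
  x4 <- mkMask(12, "FISH")
  expect_equal(maskLabels(rescueFluidInFish(x4$m, x4$g))[2, 2], "FISH")
})

test_that("noise-free copepod scenes classify 100% copepod in-band", {
  sim <- genSurvey(syntheticTruth(seed = 5, nPings = 150, noiseSdDb = 0,
                                  esrSdLog = 0, nKrillPatches = 0L,
                                  nFishSchools = 0L))
  r38 <- resampleToCells(sim$sv38, 3, 1, -140)
  r120 <- resampleToCells(sim$sv120, 3, 1, -140)
  g <- alignBifreq(r38, r120)
  lab <- maskLabels(classifyCells(g))
  expect_true(all(lab %in% c("COPEPOD", "EXCLUDED")))
  # every in-band (non-missing) cell classifies copepod
  expect_true(all(lab[lab != "EXCLUDED"] == "COPEPOD"))
  expect_gt(mean(lab == "COPEPOD"), 0.8)
})

test_that("classifier configuration is validated up front", {
  expect_error(classifierConfig(deltaKrillMax = 30), "deltaOtherMax <")
  expect_error(classifierConfig(rescueWindow = 2), "odd")
  expect_error(classifierConfig(fishSumThreshold = Inf), "finite")
})

test_that("the EM gate agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  set.seed(17)
  x <- c(rnorm(3000, -150, 4), rnorm(800, -105, 5))
  ref <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  mu <- ref$parameters$mean
  sg <- sqrt(ref$parameters$variance$sigmasq)
  w <- ref$parameters$pro
  o <- order(mu)
  refBoundary <- uniroot(function(z)
    w[o[1]] * dnorm(z, mu[o[1]], sg[o[1]]) -
      w[o[2]] * dnorm(z, mu[o[2]], sg[o[2]]),
    lower = mu[o[1]], upper = mu[o[2]])$root
  expect_lt(abs(fitFishThreshold(x) - refBoundary), 1)
})
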