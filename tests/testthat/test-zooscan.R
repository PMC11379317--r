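test_that("pixel area converts at the 10.6 um pitch and stays linear", {
  expect_equal(pxToMm2(10000), 1.1236)
  expect_equal(pxToMm2(1), 1.1236e-4)
  expect_equal(pxToMm2(300), 300 * pxToMm2(1))
  expect_error(pxToMm2(0), "> 0")
})

test_that("ESR is the area-equivalent circle radius", {
  expect_equal(esrFromArea(pi * 0.25), 0.5)
  expect_equal(esrFromArea(pi), 1)
  s <- seq(0.1, 5, by = 0.1)
  expect_true(all(diff(esrFromArea(s)) > 0))
})

test_that("allometric dry mass is a power law in body area", {
  m <- allometricModel()       # literature defaults 45.25, 1.59
  expect_equal(dryMass(1, m), 45.25)
  expect_equal(dryMass(2, m), 45.25 * 2^1.59)
  expect_equal(round(dryMass(2, m), 1), 136.2)
  # log-linear: log DM affine in log S
  s <- c(0.5, 1, 2, 4, 8)
  fit <- lm(log(dryMass(s, m)) ~ log(s))
  expect_equal(unname(coef(fit)[2]), 1.59, tolerance = 1e-10)
  expect_error(allometricModel(intercept = -1), "> 0")
})

test_that("station summaries filter, scale by volume and weight by splits", {
  m <- allometricModel()
  sUnit <- (100 / m$intercept)^(1 / m$exponent)  # area with DM = 100 ug
  px <- round(sUnit / 0.0106^2)
  items <- data.frame(station = 1, net = 1, stratum_top_m = 10,
                      stratum_bottom_m = 25, taxon = "Copepoda",
                      area_px = rep(px, 10), split_factor = 1)
  st <- netStation(1, 14.5, -17.5, Sys.time(),
                   data.frame(net = 1, volume_m3 = 50))
  out <- stationSummary(items, st, m)
  expect_equal(out$strata$abundance_ind_m3, 0.2)
  expect_equal(out$strata$biomass_ug_m3, 20, tolerance = 1e-3)
  expect_equal(out$meanDm, 100, tolerance = 1e-3)

  # an object with ESR = 0.4 mm is excluded at the 0.5 mm cut
  small <- items[1, ]; small$area_px <- round(pi * 0.4^2 / 0.0106^2)
  out2 <- stationSummary(rbind(items, small), st, m, esrMin = 0.5)
  expect_equal(out2$strata$count, 10)

  # a split factor of 4 counts as 4 individuals
  items$split_factor[1] <- 4
  out3 <- stationSummary(items, st, m)
  expect_equal(out3$strata$count, 13)
  expect_equal(out3$strata$abundance_ind_m3, 13 / 50)

  # filtering is idempotent: pre-filtered input gives the same summary
  keep <- esrFromArea(pxToMm2(items$area_px)) > 0.5
  expect_equal(stationSummary(items[keep, ], st, m), out3)

  expect_error(stationSummary(transform(items, net = 2), st, m),
               "missing filtered volume")
})

test_that("abundance scales inversely with filtered volume", {
  m <- allometricModel()
  items <- data.frame(station = 1, net = 1, stratum_top_m = 0,
                      stratum_bottom_m = 50, taxon = "Copepoda",
                      area_px = rep(30000, 8), split_factor = 1)
  ab <- vapply(c(25, 50, 100), function(v) {
    st <- netStation(1, 0, 0, Sys.time(), data.frame(net = 1, volume_m3 = v))
    stationSummary(items, st, m)$strata$abundance_ind_m3
  }, numeric(1))
  expect_equal(ab[1] / ab[2], 2)
  expect_equal(ab[2] / ab[3], 2)
})

test_that("zooscan tables round-trip through the readers with validation", {
  tab <- genZooscanTable(syntheticTruth(seed = 2), nItems = 50)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  back <- readZooscanTable(path)
  expect_equal(back$area_px, tab$area_px)
  bad <- tab; bad$area_px[1] <- 0
  p2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(bad, p2, row.names = FALSE)
  expect_error(readZooscanTable(p2), "area_px")
})

test_that("Spearman comparison matches the brute-force rank formula", {
  x <- 1:6
  # permutation with two adjacent swaps: ranks (2, 1, 4, 3, 5, 6)
  y <- c(2, 1, 4, 3, 5, 6)
  d2 <- sum((rank(x) - rank(y))^2)
  rhoBrute <- 1 - 6 * d2 / (6 * (36 - 1))
  out <- spearmanCompare(x, y)
  expect_equal(out$rho, rhoBrute)        # = 0.8857 for d2 = 4
  expect_equal(round(out$rho, 4), 0.8857)

  expect_equal(spearmanCompare(1:8, (1:8)^2)$rho, 1)   # identical rankings
  expect_equal(spearmanCompare(1:8, 8:1)$rho, -1)      # reversed

  # p-value agrees with the t-approximation used by cor.test
  set.seed(4)
  a <- rnorm(12); b <- a + rnorm(12)
  ref <- suppressWarnings(cor.test(a, b, method = "spearman", exact = FALSE))
  out2 <- spearmanCompare(a, b)
  expect_equal(out2$rho, unname(ref$estimate))
  expect_equal(out2$p_value, ref$p.value, tolerance = 1e-6)

  expect_error(spearmanCompare(rep(1, 6), 1:6), "constant")
  expect_error(spearmanCompare(1:4, 4:1), "pairs")
})
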