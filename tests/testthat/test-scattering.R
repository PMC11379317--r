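p0 <- fluidSphereParams()   # g=1.02, h=1.058, c=1508, 38/120 kHz

test_that("Mackenzie sound speed reproduces reference values", {
  # hand-evaluated polynomial at the survey hydrography
  expect_equal(round(soundSpeed(14.9, 35.7, 50), 1), 1508.0)
  c0 <- soundSpeed(0, 35, 0)
  expect_gt(c0, 1440); expect_lt(c0, 1460)
  # leading temperature term dominates: monotone over the oceanic range
  for (T in seq(0, 19)) {
    expect_gt(soundSpeed(T + 1, 35, 50), soundSpeed(T, 35, 50))
  }
  expect_error(soundSpeed(40, 35, 0), "temperature")
  expect_error(soundSpeed(10, 50, 0), "salinity")
  expect_error(soundSpeed(10, 35, -5), "depth")
})

test_that("reflection coefficient and contrast term match hand arithmetic", {
  # R = (1.02*1.058 - 1)/(1.02*1.058 + 1)
  expect_equal(reflectionCoefficient(p0), 0.0380731, tolerance = 1e-5)
  pn <- fluidSphereParams(g = 1, h = 1)
  expect_equal(reflectionCoefficient(pn), 0)
  expect_equal(alphaPis(pn), 0)
  # sign of R follows sign of gh - 1
  expect_lt(reflectionCoefficient(fluidSphereParams(g = 0.95, h = 1)), 0)
  # term-by-term: (1 - gh^2)/(3gh^2) + (1 - g)/(1 + 2g)
  expect_equal(alphaPis(p0), -0.0479631, tolerance = 1e-5)
  # smooth and monotone in h near the operating point
  a <- vapply(c(1.05, 1.058, 1.066),
              function(h) alphaPis(fluidSphereParams(h = h)), numeric(1))
  expect_true(all(diff(a) < 0))
})

test_that("sigma_bs has the Rayleigh limit and the high-pass plateau", {
  alpha <- alphaPis(p0); R <- reflectionCoefficient(p0)
  k <- function(f) 2 * pi * f * 1000 / 1508
  rayleigh <- function(esr, f) {
    a <- esr * 1e-3
    a^2 * (k(f) * a)^4 * alpha^2
  }
  # ka << 1: matches the pure Rayleigh form
  for (esr in c(0.005, 0.01, 0.05)) {
    expect_equal(sigmaBs(esr, 120, p0) / rayleigh(esr, 120), 1,
                 tolerance = 1e-3)
  }
  # near-Rayleigh f^4 scaling between the two channels
  expect_equal(sigmaBs(0.5, 120, p0) / sigmaBs(0.5, 38, p0),
               (120 / 38)^4, tolerance = 0.03)
  # ka >> 1: plateau at a^2 R^2 / 4 (the geometric limit of the model)
  for (esr in c(130, 200)) {
    a <- esr * 1e-3
    expect_equal(sigmaBs(esr, 38, p0) / (a^2 * R^2 / 4), 1, tolerance = 0.02)
  }
  # strictly increasing in size at fixed frequency
  s <- sigmaBs(seq(0.1, 5, by = 0.1), 120, p0)
  expect_true(all(diff(s) > 0))
  expect_error(sigmaBs(-1, 120, p0), "esr")
})

test_that("target strength is the dB cross-section with a^6 Rayleigh slope", {
  expect_equal(targetStrength(0.9, 120, p0),
               10 * log10(sigmaBs(0.9, 120, p0)))
  # deep Rayleigh: doubling size adds 10 log10(2^6) = 18.06 dB
  expect_equal(targetStrength(0.02, 38, p0) - targetStrength(0.01, 38, p0),
               10 * log10(2^6), tolerance = 0.01)
  ts <- targetStrength(seq(0.2, 3, by = 0.2), 120, p0)
  expect_true(all(diff(ts) > 0))
})

test_that("deltaTS has the Rayleigh ceiling and decreases with size", {
  # closed-form limit 40 log10(f_high/f_low)
  expect_equal(deltaTS(0.01, p0), 40 * log10(120 / 38), tolerance = 0.05)
  d <- deltaTS(seq(0.2, 3.0, by = 0.1), p0)
  expect_true(all(diff(d) < 0))
})

test_that("ka uses the geometric-mean frequency and is linear in size", {
  fm <- sqrt(38 * 120)
  expect_equal(fm, 67.528, tolerance = 1e-3)
  expect_equal(kaValue(0.5, p0), 2 * pi * fm * 1000 * 5e-4 / 1508,
               tolerance = 1e-12)
  expect_equal(round(kaValue(0.5, p0), 2), 0.14)
  expect_equal(kaValue(1.0, p0), 2 * kaValue(0.5, p0))
})

test_that("size inversion round-trips the forward curve on the band", {
  b <- sizeBand(p0)
  expect_equal(b@deltaDbAtMin, 19.7)
  expect_equal(b@deltaDbAtMax, 7.0)
  # band edges sit where the forward curve crosses the stated dB values
  expect_equal(deltaTS(b@esrMin, p0), 19.7, tolerance = 1e-4)
  expect_equal(deltaTS(b@esrMax, p0), 7.0, tolerance = 1e-4)
  for (esr in seq(0.7, 2.6, by = 0.3)) {
    inv <- invertSize(deltaTS(esr, p0), p0, b)
    expect_equal(inv$esr, esr, tolerance = 1e-3)
    expect_false(inv$clamped)
  }
})

test_that("out-of-band dB differences clamp to the band edges with a flag", {
  b <- sizeBand(p0)
  expect_warning(inv <- invertSize(21, p0, b), "clamped")
  expect_equal(inv$esr, b@esrMin)
  expect_true(inv$clamped)
  expect_warning(inv2 <- invertSize(5, p0, b), "clamped")
  expect_equal(inv2$esr, b@esrMax)
  # NA propagates
  out <- suppressWarnings(invertSize(c(NA, 10), p0, b))
  expect_true(is.na(out$esr[1]))
})

test_that("degenerate band configurations are rejected", {
  expect_error(sizeBand(p0, 19.7, 7.0), "deltaDbLow")
  expect_error(new("SizeBand", esrMin = 2, esrMax = 1, deltaDbAtMin = 19.7,
                   deltaDbAtMax = 7, kaMin = 0.5, kaMax = 0.2))
})
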