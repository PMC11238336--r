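# Power-law scaling, shear thinning, yield stress, LVE region, ratios.

test_that("noiseless power laws are recovered exactly", {
  x <- c(1, 2, 4, 8)
  f <- powerLawFit(x, 3 * x^2)
  expect_equal(f@exponent, 2, tolerance = 1e-10)
  expect_equal(f@prefactor, 3, tolerance = 1e-10)
  expect_equal(f@rSquared, 1)
  # two points: exact interpolation
  f2 <- powerLawFit(c(2, 5), c(10, 40))
  expect_equal(f2@rSquared, 1)
  expect_equal(f2@prefactor * 2^f2@exponent, 10, tolerance = 1e-12)
})

test_that("power-law fit is exactly unit-covariant in x", {
  set.seed(41)
  x <- 10^runif(8, 0, 2)
  y <- 2.5 * x^1.7 * exp(rnorm(8, 0, 0.1))
  f1 <- powerLawFit(x, y)
  k <- 3.3
  f2 <- powerLawFit(k * x, y)
  expect_equal(f2@exponent, f1@exponent, tolerance = 1e-12)
  expect_equal(f2@prefactor, f1@prefactor * k^(-f1@exponent),
               tolerance = 1e-10)
})

test_that("power-law fit rejects bad domains and honours windows", {
  expect_error(powerLawFit(c(1, -2, 3), c(1, 2, 3)), "domain error")
  expect_error(powerLawFit(1, 1), "equal length|insufficient")
  expect_error(powerLawFit(c(1, 2), c(1, 2), window = c(5, 6)),
               "insufficient data")
  x <- c(1, 2, 4, 8, 100)
  y <- 3 * x^2; y[5] <- 1  # an outlier outside the window
  f <- powerLawFit(x, y, window = c(1, 10))
  expect_equal(f@exponent, 2, tolerance = 1e-10)
  expect_equal(f@nUsed, 4L)
})

test_that("recovered exponent is unbiased under lognormal noise", {
  set.seed(42)
  doses <- c(10, 20, 60, 100, 140)
  exps <- replicate(300, {
    y <- 0.01 * doses^2.2 * exp(rnorm(5, 0, sqrt(log(1 + 0.1^2))))
    powerLawFit(doses, y)@exponent
  })
  expect_lt(abs(mean(exps) - 2.2), 0.05)
})

test_that("shear-thinning exponents match the generator algebra", {
  gd <- 10^seq(-1, 3, length.out = 25)
  # eta = 100 * gd^-0.25
  c1 <- FlowCurve(gd, 100 * gd^(-0.25))
  f1 <- shearThinningExponent(c1, window = range(gd))
  expect_equal(attr(f1, "thinningExponent"), 0.25, tolerance = 1e-10)
  # Newtonian
  c2 <- FlowCurve(gd, rep(2, 25))
  expect_equal(attr(shearThinningExponent(c2, range(gd)),
                    "thinningExponent"), 0, tolerance = 1e-12)
  # strong thinning, exponent 0.93
  c3 <- FlowCurve(gd, 5 * gd^(-0.93))
  expect_equal(attr(shearThinningExponent(c3, range(gd)),
                    "thinningExponent"), 0.93, tolerance = 1e-10)
  # Herschel-Bulkley generator: eta ~ gd^(n-1) when sigmaY = 0
  c4 <- generateFlowCurve(sigmaY = 0, n = 0.75, noiseCv = 0, seed = 1)$curve
  f4 <- shearThinningExponent(c4, window = c(0.1, 1000))
  expect_equal(attr(f4, "thinningExponent"), 0.25, tolerance = 1e-10)
  expect_error(shearThinningExponent(c4), "window")
})

test_that("Herschel-Bulkley yield stress is recovered on synthetic curves", {
  g <- generateFlowCurve(sigmaY = 0.001, K = 0.3, n = 0.75,
                         shearRateRange = c(1e-6, 1000), nPoints = 40,
                         noiseCv = 0, seed = 1)
  y <- yieldStressEstimate(g$curve)
  expect_lt(abs(y@sigmaY - 0.001) / 0.001, 0.1)
  expect_false(y@noPlateau)
  expect_equal(y@method, "herschel-bulkley")
})

test_that("a pure power-law fluid is flagged as having no plateau", {
  g <- generateFlowCurve(sigmaY = 0, K = 0.3, n = 0.75,
                         shearRateRange = c(1e-6, 1000), nPoints = 40,
                         noiseCv = 0, seed = 2)
  y <- yieldStressEstimate(g$curve)
  expect_true(y@noPlateau)
  expect_lt(y@sigmaY, 1e-5)
})

test_that("a constant-stress plug gives sigma_y = sigma0 and K ~ 0", {
  gd <- 10^seq(-3, 1, length.out = 20)
  curve <- FlowCurve(gd, 0.05 / gd)   # sigma = 0.05 everywhere
  y <- yieldStressEstimate(curve)
  expect_equal(y@sigmaY, 0.05, tolerance = 1e-4)
  expect_lt(y@K * max(y@window)^y@n, 0.05 * 1e-3)
  # the plateau-median alternative agrees
  y2 <- yieldStressEstimate(curve, method = "stress-plateau")
  expect_equal(y2@sigmaY, 0.05, tolerance = 1e-10)
})

test_that("curves narrower than two decades are refused", {
  gd <- seq(1, 9, length.out = 10)
  expect_error(yieldStressEstimate(FlowCurve(gd, 1 / gd)), "decades")
})

test_that("LVE critical strain is located on a step construction", {
  g <- generateAmplitudeSweep(criticalStrain = 0.05, decayExponent = 1,
                              noiseCv = 0, seed = 1)
  crit <- lveRegion(g$sweep, tolerance = 0.10)
  strains <- strainValues(g$sweep)
  # first point beyond the true critical strain where decay passed 10%
  expected <- min(strains[strains > 0.05 &
                          (strains / 0.05)^(-1) < 0.9])
  expect_equal(as.numeric(crit), expected)
  expect_false(attr(crit, "noDeparture"))
})

test_that("flat and monotone amplitude sweeps are flagged", {
  flat <- AmplitudeSweep(10^seq(-4, 0, length.out = 10), rep(2, 10),
                         rep(4, 10))
  crit <- lveRegion(flat)
  expect_equal(as.numeric(crit), 1)
  expect_true(attr(crit, "noDeparture"))
  dec <- AmplitudeSweep(10^seq(-4, 0, length.out = 10),
                        2 * 10^seq(0, -2, length.out = 10), rep(1, 10))
  crit2 <- lveRegion(dec)
  expect_true(attr(crit2, "lowConfidence"))
  expect_error(lveRegion(AmplitudeSweep(c(1, 2, 3) / 100, 1:3, 1:3)),
               "insufficient")
})

test_that("LVE detection is invariant to uniform modulus rescaling", {
  g <- generateAmplitudeSweep(noiseCv = 0.02, seed = 5)
  s <- g$sweep
  s2 <- AmplitudeSweep(strainValues(s), gPrime(s) * 1e3,
                       gDoublePrime(s) * 1e3)
  expect_equal(as.numeric(lveRegion(s)), as.numeric(lveRegion(s2)))
})

test_that("sweep ratios behave on identical, scaled and model sweeps", {
  a <- make_sweep()
  r <- sweepRatios(a, a)
  expect_true(all(abs(r$ratio_gPrime - 1) < 1e-12))
  b <- OscillatorySweep(omega(a), gPrime(a) / 1.5, gDoublePrime(a) / 1.5)
  r2 <- sweepRatios(a, b)
  expect_equal(r2$ratio_gPrime, rep(1.5, nrow(r2)), tolerance = 1e-12)
  expect_equal(unname(attr(r2, "summary")["max"]), 1.5, tolerance = 1e-12)
  # G'/G'' grows without bound as omega -> 0 when G > 0
  w <- 10^seq(-6, 1, length.out = 40)
  m <- fkvmModuli(FKVMParams(2, 1.5, 0.7), w)
  sw <- OscillatorySweep(w, m$gPrime, m$gDoublePrime)
  rr <- sweepRatios(sw, sw)$ratio_a
  expect_true(all(diff(rr) < 0))      # decreasing with omega
  expect_gt(rr[1], 1e3)
  # disjoint ranges
  hi <- make_sweep(lo = 1000, hi = 5000)
  expect_error(sweepRatios(make_sweep(lo = 0.3, hi = 45), hi),
               "alignment error")
})

test_that("interpolated grids agree with closed-form log-log interpolation", {
  p <- FKVMParams(2, 1.5, 0.7)
  wa <- 10^seq(-1, 2, length.out = 31)
  wb <- 10^seq(-1, 2, length.out = 61)
  ma <- fkvmModuli(p, wa); mb <- fkvmModuli(p, wb)
  a <- OscillatorySweep(wa, ma$gPrime, ma$gDoublePrime)
  b <- OscillatorySweep(wb, mb$gPrime, mb$gDoublePrime)
  r <- sweepRatios(a, b)
  # a power-law-ish spectrum interpolates nearly exactly in ln-ln space
  expect_true(all(abs(r$ratio_gDoublePrime - 1) < 1e-3))
})

test_that("scalingReport fits all three responses of a series", {
  gen <- generateConcentrationSeries(noiseCv = 0, seed = 1)
  rep <- scalingReport(gen$series)
  expect_equal(rep$exponent[rep$response == "gPrime"], 2.0,
               tolerance = 1e-10)
  expect_equal(rep$exponent[rep$response == "viscosity"], 2.2,
               tolerance = 1e-10)
})
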