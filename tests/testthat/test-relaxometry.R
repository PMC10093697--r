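test_that("log-ratio conversion matches hand-evaluated values", {
  base <- rep(100, 8)
  gre <- array(c(base, 100, 90, 100), dim = c(1, 1, 1, 11))
  ser <- DualEchoSeries(gre, gre, tr = 1.5, teGre = 0.0186, teSe = 0.069,
                        injectionIndex = 9L)
  cu <- toRelaxation(ser, estimateBaseline(ser))
  # S(t) = S(0): dR2* = 0
  expect_equal(cu@r2star[1, 1, 1, 9], 0)
  # S/S0 = 0.9 at TE = 18.6 ms: -ln(0.9)/0.0186
  expect_equal(cu@r2star[1, 1, 1, 10], -log(0.9) / 0.0186, tolerance = 1e-12)
  expect_equal(cu@r2star[1, 1, 1, 10], 5.665, tolerance = 1e-4)
  # spin-echo curve uses TE(SE)
  expect_equal(cu@r2[1, 1, 1, 10], -log(0.9) / 0.069, tolerance = 1e-12)
})

test_that("conversion inverts the exponential forward model to machine precision", {
  set.seed(2)
  x <- matrix(abs(rnorm(5 * 30, sd = 10)), 5, 30)   # injected curves, 1/s
  ser <- seriesFromCurves(r2star = x, r2 = 0.3 * x, baseline = 250)
  cu <- toRelaxation(ser, estimateBaseline(ser))
  rec <- matrix(cu@r2star[, 1, 1, -(1:8)], 5, 30)
  expect_lt(max(abs(rec - x) / pmax(abs(x), 1e-12)), 1e-10)
  recSe <- matrix(cu@r2[, 1, 1, -(1:8)], 5, 30)
  expect_lt(max(abs(recSe - 0.3 * x) / pmax(abs(0.3 * x), 1e-12)), 1e-10)
})

test_that("nonpositive signal ratios invalidate the voxel rather than clamp", {
  base <- rep(100, 8)
  gre <- array(c(base, 100, 0, 100,     # voxel 1 hits zero
                 base, 100, 50, 100),   # voxel 2 fine
               dim = c(11, 2))
  gre <- aperm(gre, c(2, 1)); dim(gre) <- c(2, 1, 1, 11)
  ser <- DualEchoSeries(gre, abs(gre) + 1, tr = 1.5, teGre = 0.0186,
                        teSe = 0.069, injectionIndex = 9L)
  cu <- toRelaxation(ser, estimateBaseline(ser))
  expect_false(validVoxels(cu)[1, 1, 1])
  expect_true(validVoxels(cu)[2, 1, 1])
  expect_true(all(is.na(cu@r2star[1, 1, 1, ])))
  expect_match(cu@validity@reason[1, 1, 1], "nonpositive-signal")
})

test_that("relaxation curves are invariant under a global signal gain", {
  ph <- tinyPhantom(gridShape = c(6L, 4L, 2L))
  s <- trimInitial(ph@series, 4L)
  cu1 <- toRelaxation(s, estimateBaseline(s))
  s2 <- DualEchoSeries(greSignal(s) * 7, seSignal(s) * 7, tr = 1.5,
                       teGre = 0.0186, teSe = 0.069,
                       injectionIndex = injectionIndex(s))
  cu2 <- toRelaxation(s2, estimateBaseline(s2))
  expect_equal(cu1@r2star, cu2@r2star, tolerance = 1e-12)
})

test_that("bolus window detection reproduces the hand-solved triangular case", {
  # mean curve 0,0,1,2,1,0,0 over frames 1..7: any threshold below the
  # smallest nonzero value selects frames 3..5
  tri <- c(0, 0, 1, 2, 1, 0, 0)
  ser <- seriesFromCurves(r2star = tri, r2 = tri, nBaseline = 8L)
  cu <- toRelaxation(ser, estimateBaseline(ser))
  # curves live on frames 9..15 of the padded series
  w <- detectBolusWindow(cu)
  expect_equal(w@t0, 8L + 3L)
  expect_equal(w@t1, 8L + 5L)
})

test_that("a flat curve yields no bolus window", {
  ser <- seriesFromCurves(r2star = rep(0, 6), r2 = rep(0, 6))
  cu <- toRelaxation(ser, estimateBaseline(ser))
  expect_error(detectBolusWindow(cu), "flat|threshold")
})

test_that("the detected window captures nearly all of the analytic bolus mass", {
  ph <- tinyPhantom(gridShape = c(10L, 6L, 3L))
  pc <- phantomCurves(ph)
  b <- bolusModel()
  tFine <- seq(0, 1000, by = 1e-3)
  total <- sum(gammaVariate(tFine, b)) * 1e-3
  # window frames are indices into the trimmed series (offset 4)
  lo <- pc$window@t0 + 4L; hi <- pc$window@t1 + 4L
  inWin <- sum(gammaVariate(tFine[tFine >= lo & tFine <= hi], b)) * 1e-3
  expect_gt(inWin / total, 0.99)
})

test_that("trapezoidal integration matches hand-computed integrals", {
  tri <- c(0, 1, 2, 1, 0)
  ser <- seriesFromCurves(r2star = tri, r2 = tri, tr = 1)
  cu <- toRelaxation(ser, estimateBaseline(ser))
  w <- new("BolusWindow", t0 = 9L, t1 = 13L)
  expect_equal(as.numeric(integrateCbv(cu, w)), 4, tolerance = 1e-10)
  # constant c over a window of L frames: c * (L - 1) * TR
  con <- rep(3, 6)
  ser2 <- seriesFromCurves(r2star = con, r2 = con, tr = 1.5)
  cu2 <- toRelaxation(ser2, estimateBaseline(ser2))
  w2 <- new("BolusWindow", t0 = 9L, t1 = 14L)
  expect_equal(as.numeric(integrateCbv(cu2, w2)), 3 * 5 * 1.5, tolerance = 1e-10)
  expect_error(integrateCbv(cu2, new("BolusWindow", t0 = 3L, t1 = 40L)),
               "time axis")
})

test_that("phantom CBV integral matches the closed-form gamma-variate integral", {
  ph <- tinyPhantom(gridShape = c(10L, 6L, 3L))
  pc <- phantomCurves(ph)
  raw <- integrateCbv(pc$curves, pc$window)
  b <- bolusModel()
  m <- ph@nawmMask
  expected <- b$amplitude * 0.025 * gammaVariateIntegral(b, tr = 1.5)
  expect_lt(abs(mean(raw[m]) - expected) / expected, 0.02)
})

test_that("integration and peaks are linear in the curve scale", {
  ph <- tinyPhantom(gridShape = c(6L, 4L, 2L))
  pc <- phantomCurves(ph)
  cuK <- new("RelaxationCurves", r2star = 3 * pc$curves@r2star,
             r2 = 3 * pc$curves@r2, timeAxis = pc$curves@timeAxis,
             injectionIndex = pc$curves@injectionIndex,
             validity = pc$curves@validity)
  expect_equal(integrateCbv(cuK, pc$window), 3 * integrateCbv(pc$curves, pc$window),
               tolerance = 1e-12)
  pk1 <- peakRates(pc$curves, pc$window); pkK <- peakRates(cuK, pc$window)
  expect_equal(pkK@r2starMax, 3 * pk1@r2starMax, tolerance = 1e-12)
})

test_that("peak rates respect the window and match injected amplitudes", {
  tri <- c(0, 1, 2, 1, 0, 9)     # global max outside the window
  ser <- seriesFromCurves(r2star = tri, r2 = tri, tr = 1)
  cu <- toRelaxation(ser, estimateBaseline(ser))
  pk <- peakRates(cu, new("BolusWindow", t0 = 9L, t1 = 13L))
  expect_equal(as.numeric(pk@r2starMax), 2, tolerance = 1e-10)

  ph <- tinyPhantom(gridShape = c(10L, 6L, 3L))
  pc <- phantomCurves(ph)
  pk2 <- peakRates(pc$curves, pc$window)
  m <- ph@nawmMask
  expect_equal(mean(pk2@r2starMax[m]), bolusModel()$amplitude * 0.025,
               tolerance = 1e-6)
})

test_that("normalized phantom CBV regresses on truth through the origin with R2 > 0.99", {
  ph <- simulateDsc(gridShape = c(32L, 16L, 6L), noiseSd = 800 / 50, seed = 9L)
  pc <- phantomCurves(ph)
  raw <- integrateCbv(pc$curves, pc$window)
  ok <- validVoxels(pc$validity)
  fit <- lm(raw[ok] ~ 0 + ph@truthCbv[ok])
  expect_gt(summary(fit)$r.squared, 0.99)
})
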