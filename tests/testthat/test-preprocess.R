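test_that("trimming removes exactly the leading frames and shifts the injection index", {
  ph <- tinyPhantom(gridShape = c(5L, 2L, 2L))
  expect_equal(nFrames(ph@series), 120L)
  trimmed <- trimInitial(ph@series, 4L)
  expect_equal(nFrames(trimmed), 116L)
  expect_equal(injectionIndex(trimmed), injectionIndex(ph@series) - 4L)
  expect_identical(greSignal(trimmed), greSignal(ph@series)[, , , 5:120])
  # n = 0 is the identity
  expect_identical(trimInitial(ph@series, 0L), ph@series)
})

test_that("trimming rejects degenerate frame counts", {
  ph <- tinyPhantom(gridShape = c(5L, 2L, 2L))
  expect_error(trimInitial(ph@series, 120L), "frame count")
  expect_error(trimInitial(ph@series, 121L), "frame count")
  # trimming past the bolus arrival leaves no baseline
  expect_error(trimInitial(ph@series, 20L), "baseline")
})

test_that("baseline mean and SD match hand-computed values", {
  # constant baseline: mean = value, SD = 0
  s <- seriesFromCurves(r2star = c(1, 2, 1), r2 = c(1, 2, 1), baseline = 100,
                        nBaseline = 8L)
  b <- estimateBaseline(s)
  expect_equal(as.numeric(b@greMean), 100)
  expect_equal(as.numeric(b@greSd), 0)

  # baseline samples {98, 100, 102}: mean 100, sample SD (n-1 divisor) = 2
  gre <- array(c(98, 100, 102, rep(90, 9)), dim = c(1, 1, 1, 12))
  ser <- DualEchoSeries(gre, gre, tr = 1.5, teGre = 0.0186, teSe = 0.069,
                        injectionIndex = 4L)
  b2 <- estimateBaseline(ser, minFrames = 3L)
  expect_equal(as.numeric(b2@greMean), 100)
  expect_equal(as.numeric(b2@greSd), 2)
})

test_that("baseline estimation needs enough pre-bolus frames", {
  s <- seriesFromCurves(r2star = c(1, 2), r2 = c(1, 2), nBaseline = 4L)
  expect_error(estimateBaseline(s), "pre-bolus")
})

test_that("baseline mean of a noisy series stays within the standard-error bound", {
  # Gaussian(100, 5) over 16 frames: SE = 5/4, so |mean - 100| < 4 (3.2 SE)
  # for at least 95% of voxels
  set.seed(11)
  nv <- 2000L
  gre <- array(100 + rnorm(nv * 20, sd = 5), dim = c(nv, 1, 1, 20))
  ser <- DualEchoSeries(gre, gre, tr = 1.5, teGre = 0.0186, teSe = 0.069,
                        injectionIndex = 17L)
  b <- estimateBaseline(ser)
  expect_gt(mean(abs(b@greMean - 100) < 4), 0.95)
})

test_that("the 2-SD drop rule excludes and includes constructed voxels", {
  # two voxels, baseline mean 100 / SD 5 on both echoes:
  #   voxel 1 post-bolus minimum 92 (drop 8 < 10)  -> excluded
  #   voxel 2 post-bolus minimum 80 (drop 20 >= 10) -> included
  base <- rep(c(98, 100, 102), 4)                 # mean 100
  mk <- function(minimum) c(base, 100, minimum, 100)
  gre <- aperm(array(c(mk(92), mk(80)), dim = c(15, 2)), c(2, 1))
  dim(gre) <- c(2, 1, 1, 15)
  ser <- DualEchoSeries(gre, gre, tr = 1.5, teGre = 0.0186, teSe = 0.069,
                        injectionIndex = 13L)
  b <- estimateBaseline(ser)
  sd0 <- sd(base)
  v <- qcFilter(ser, b, sdThreshold = 2 * 5 / sd0)  # rule in units of SD=5
  expect_false(validVoxels(v)[1, 1, 1])
  expect_true(validVoxels(v)[2, 1, 1])
  expect_match(reasonCodes(v)[1, 1, 1], "insufficient-drop")
})

test_that("a zero-SD baseline includes any nonnegative drop", {
  s <- seriesFromCurves(r2star = c(0, 0, 0), r2 = c(0, 0, 0), baseline = 100)
  b <- estimateBaseline(s)
  v <- qcFilter(s, b)
  expect_true(all(validVoxels(v)))
})

test_that("failing on one echo is enough for exclusion", {
  base <- rep(c(98, 100, 102), 4)
  gre <- array(c(base, 100, 60, 100), dim = c(1, 1, 1, 15))   # big drop
  se <- array(c(base, 100, 99, 100), dim = c(1, 1, 1, 15))    # tiny drop
  ser <- DualEchoSeries(gre, se, tr = 1.5, teGre = 0.0186, teSe = 0.069,
                        injectionIndex = 13L)
  v <- qcFilter(ser, estimateBaseline(ser))
  expect_false(validVoxels(v)[1, 1, 1])
  expect_identical(reasonCodes(v)[1, 1, 1], "insufficient-drop-se")
})

test_that("voxels with nonpositive bolus-window signal are invalid", {
  base <- rep(c(98, 100, 102), 4)
  gre <- array(c(base, 100, -5, 100), dim = c(1, 1, 1, 15))
  ser <- DualEchoSeries(gre, gre, tr = 1.5, teGre = 0.0186, teSe = 0.069,
                        injectionIndex = 13L)
  v <- qcFilter(ser, estimateBaseline(ser))
  expect_false(validVoxels(v)[1, 1, 1])
  expect_match(reasonCodes(v)[1, 1, 1], "nonpositive-signal")
})

test_that("the quality filter is order-independent and idempotent in effect", {
  ph <- tinyPhantom(gridShape = c(8L, 4L, 2L), noiseSd = 10, seed = 3L)
  s <- trimInitial(ph@series, 4L)
  b <- estimateBaseline(s)
  v1 <- qcFilter(s, b)
  v2 <- qcFilter(s, b)
  expect_identical(validVoxels(v1), validVoxels(v2))
  # permute voxels along x, filter, unpermute: same decision per voxel
  perm <- rev(seq_len(dim(greSignal(s))[1]))
  sp <- DualEchoSeries(greSignal(s)[perm, , , , drop = FALSE],
                       seSignal(s)[perm, , , , drop = FALSE],
                       tr = 1.5, teGre = 0.0186, teSe = 0.069,
                       injectionIndex = injectionIndex(s))
  vp <- qcFilter(sp, estimateBaseline(sp))
  expect_identical(validVoxels(vp)[perm, , , drop = FALSE], validVoxels(v1))
})

test_that("noiseless bolus voxels all pass; pure-noise voxels mostly fail", {
  ph <- tinyPhantom(gridShape = c(10L, 6L, 3L), noiseSd = 0)
  pc <- phantomCurves(ph)
  expect_true(all(validVoxels(pc$validity)))

  # with no bolus the drop is pure noise; over a short post-injection
  # window it rarely reaches 2 baseline SDs on both echoes (the expected
  # extreme of a handful of Gaussian draws is well under 2 SD)
  phN <- simulateDsc(bolus = bolusModel(amplitude = 0),
                     gridShape = c(12L, 10L, 4L), nTimepoints = 26L,
                     noiseSd = 5, seed = 5L)
  sN <- trimInitial(phN@series, 4L)
  vN <- qcFilter(sN, estimateBaseline(sN))
  expect_gt(mean(!validVoxels(vN)), 0.95)
})
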