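# Shared in-code fixtures: small phantoms and rasterized shapes.

# small default phantom; noiseless unless asked otherwise
tinyPhantom <- function(gridShape = c(20L, 10L, 4L), noiseSd = 0, seed = 1L,
                        bolus = bolusModel(), classes = defaultTissueClasses(bolus)) {
  simulateDsc(classes = classes, bolus = bolus, gridShape = gridShape,
              noiseSd = noiseSd, seed = seed)
}

# run the phantom through preprocessing + relaxometry, returning the pieces
phantomCurves <- function(ph, nDiscard = 4L) {
  s <- trimInitial(ph@series, nDiscard)
  b <- estimateBaseline(s)
  v <- qcFilter(s, b)
  curves <- toRelaxation(s, b, v)
  window <- detectBolusWindow(curves, mask = ph@tumorMask | ph@nawmMask)
  list(series = s, baseline = b, validity = v, curves = curves, window = window)
}

# rasterize a filled ellipse as a logical matrix (pixel-centre rule)
rasterEllipse <- function(a, b = a, theta = 0, pad = 10L) {
  nr <- as.integer(2 * max(a, b) + 2 * pad + 1)
  cx <- (nr + 1) / 2
  xs <- row(matrix(0, nr, nr)); ys <- col(matrix(0, nr, nr))
  dx <- xs - cx; dy <- ys - cx
  u <- dx * cos(theta) + dy * sin(theta)
  w <- -dx * sin(theta) + dy * cos(theta)
  (u / a)^2 + (w / b)^2 <= 1
}

# Ramanujan's ellipse perimeter approximation (independent oracle)
ramanujanPerimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

# tiny synthetic single-echo-pair series built directly from given per-voxel
# curves; grid 1x1x1 unless the curve is a matrix (voxels x frames)
seriesFromCurves <- function(r2star, r2, baseline = 100, tr = 1.5,
                             teGre = 0.0186, teSe = 0.069,
                             injectionIndex, nBaseline = 8L) {
  if (is.vector(r2star)) r2star <- matrix(r2star, nrow = 1L)
  if (is.vector(r2)) r2 <- matrix(r2, nrow = 1L)
  nv <- nrow(r2star); nt <- ncol(r2star) + nBaseline
  gre <- cbind(matrix(0, nv, nBaseline), r2star)
  se <- cbind(matrix(0, nv, nBaseline), r2)
  gre <- baseline * exp(-teGre * gre)
  se <- baseline * exp(-teSe * se)
  dim(gre) <- c(nv, 1L, 1L, nt); dim(se) <- c(nv, 1L, 1L, nt)
  DualEchoSeries(gre, se, tr = tr, teGre = teGre, teSe = teSe,
                 injectionIndex = if (missing(injectionIndex)) nBaseline + 1L
                                  else injectionIndex)
}
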