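#' Tissue-class specification for the digital phantom
#'
#' Bundles the ground-truth parameters of one tissue class: blood-volume
#' fraction (drives the gradient-echo response), microvascular blood-volume
#' fraction (drives the spin-echo response), vessel size, ADC, and baseline
#' signal level.
#'
#' @param label class name, e.g. `"NAWM"`, `"GM"`, `"tumor-A"`.
#' @param cbv true blood-volume fraction, in (0, 0.2].
#' @param ucbv true microvascular fraction, `0 < ucbv <= cbv`.
#' @param vesselSize true mean vessel size in micrometres, or `NA` to derive
#'   it self-consistently from the forward model (see [impliedVesselSize()]).
#' @param adc apparent diffusion coefficient, um^2/s.
#' @param baseline pre-contrast signal level, arbitrary units.
#' @return A `"TissueClass"` list.
#' @export
tissueClass <- function(label, cbv, ucbv, vesselSize = NA_real_, adc, baseline) {
  stopifnot(is.character(label), length(label) == 1L)
  if (!(cbv > 0 && cbv <= 0.2))
    stop("cbv must be a blood-volume fraction in (0, 0.2]: got ", cbv)
  if (!(ucbv > 0 && ucbv <= cbv))
    stop("ucbv must satisfy 0 < ucbv <= cbv")
  if (!is.na(vesselSize) && vesselSize <= 0) stop("vesselSize must be positive")
  if (adc <= 0) stop("adc must be positive")
  if (baseline <= 0) stop("baseline must be positive")
  structure(list(label = label, cbv = cbv, ucbv = ucbv,
                 vesselSize = vesselSize, adc = adc, baseline = baseline),
            class = "TissueClass")
}

#' Gamma-variate contrast bolus model
#'
#' First-pass bolus shape \eqn{C(t) = ((t - t_a)/\beta)^\alpha
#' \exp(\alpha - (t - t_a)/\beta)}, normalized to unit peak (attained at
#' \eqn{t - t_a = \alpha\beta}), with optional recirculation as a delayed,
#' scaled copy. Time is measured in frames.
#'
#' @param arrivalIndex bolus arrival in frames after acquisition start; the
#'   first post-arrival frame is `arrivalIndex + 1`.
#' @param amplitude peak relaxation-rate change per unit blood-volume
#'   fraction, 1/s.
#' @param shapeAlpha gamma-variate shape (unitless, > 0).
#' @param scaleBeta gamma-variate scale, frames (> 0).
#' @param recirculationFraction amplitude fraction of a recirculation bolus
#'   delayed by `recirculationDelay` frames; 0 disables it.
#' @param recirculationDelay delay of the recirculation bolus, frames.
#' @return A `"BolusModel"` list.
#' @export
bolusModel <- function(arrivalIndex = 20L, amplitude = 400,
                       shapeAlpha = 3, scaleBeta = 3,
                       recirculationFraction = 0, recirculationDelay = 24) {
  if (amplitude < 0) stop("amplitude must be nonnegative")
  if (shapeAlpha <= 0 || scaleBeta <= 0) stop("shapeAlpha and scaleBeta must be positive")
  if (recirculationFraction < 0 || recirculationFraction >= 1)
    stop("recirculationFraction must be in [0, 1)")
  structure(list(arrivalIndex = as.integer(arrivalIndex), amplitude = amplitude,
                 shapeAlpha = shapeAlpha, scaleBeta = scaleBeta,
                 recirculationFraction = recirculationFraction,
                 recirculationDelay = recirculationDelay),
            class = "BolusModel")
}

#' Evaluate the unit-peak gamma-variate bolus curve
#'
#' @param t time in frames from acquisition start (numeric vector).
#' @param bolus a [bolusModel()].
#' @return `C(t)`, unitless, peak value 1 (before recirculation is added).
#' @export
gammaVariate <- function(t, bolus) {
  a <- bolus$shapeAlpha; b <- bolus$scaleBeta
  # peak of u^a exp(-u/b) sits at u = a*b; dividing by a^a makes the peak 1
  shape <- function(u) ifelse(u > 0, (u / (a * b))^a * exp(a - u / b), 0)
  tt <- t - bolus$arrivalIndex
  main <- shape(tt)
  if (bolus$recirculationFraction > 0)
    main <- main + bolus$recirculationFraction * shape(tt - bolus$recirculationDelay)
  main
}

#' Closed-form time integral of the gamma-variate bolus
#'
#' Integral of the unit-peak gamma-variate over all time,
#' \eqn{e^\alpha \beta \Gamma(\alpha + 1) / \alpha^\alpha} (frames), scaled
#' to seconds by `tr`, including the recirculation copy if present.
#'
#' @param bolus a [bolusModel()].
#' @param tr frame duration in seconds (default 1: integral in frame units).
#' @return Numeric, the analytic integral.
#' @export
gammaVariateIntegral <- function(bolus, tr = 1) {
  base <- exp(bolus$shapeAlpha) * bolus$scaleBeta * gamma(bolus$shapeAlpha + 1) /
    bolus$shapeAlpha^bolus$shapeAlpha
  base * (1 + bolus$recirculationFraction) * tr
}

#' Default tissue classes of the phantom
#'
#' Five blocks: normal-appearing white matter (the normalization reference),
#' grey matter, and three tumor classes loosely spanning low/high blood
#' volume and vessel size. True vessel sizes are derived self-consistently
#' from the forward model via [impliedVesselSize()] so that the ranking of
#' class-mean vessel size in a recovered map matches the truth by
#' construction.
#'
#' @param bolus the bolus model the phantom will use (needed to derive
#'   vessel-size truth); defaults to [bolusModel()].
#' @return List of `"TissueClass"` objects.
#' @export
defaultTissueClasses <- function(bolus = bolusModel()) {
  cls <- list(
    tissueClass("NAWM",    cbv = 0.025, ucbv = 0.005, adc = 700,  baseline = 800),
    tissueClass("GM",      cbv = 0.055, ucbv = 0.013, adc = 800,  baseline = 900),
    tissueClass("tumor-A", cbv = 0.060, ucbv = 0.016, adc = 1100, baseline = 850),
    tissueClass("tumor-B", cbv = 0.045, ucbv = 0.009, adc = 1200, baseline = 850),
    tissueClass("tumor-C", cbv = 0.050, ucbv = 0.018, adc = 1300, baseline = 850)
  )
  nawmCbv <- cls[[1L]]$cbv
  lapply(cls, function(cl) {
    cl$vesselSize <- impliedVesselSize(cl, bolus, nawmCbv)
    cl
  })
}

#' Vessel size implied by the phantom forward model
#'
#' Pushes a tissue class through the Kiselev vessel-size formula using the
#' analytic peak relaxation-rate changes of the forward model
#' (`amplitude * fraction` at unit bolus peak) and the CBV-scaling
#' convention (class CBV fraction rescaled so the NAWM class sits at
#' 0.032). This is the vessel size a noiseless analysis of the phantom
#' converges to.
#'
#' @param class a [tissueClass()].
#' @param bolus a [bolusModel()].
#' @param nawmCbv blood-volume fraction of the NAWM reference class.
#' @return Vessel size in micrometres.
#' @export
impliedVesselSize <- function(class, bolus, nawmCbv) {
  cbvFraction <- 0.032 * class$cbv / nawmCbv
  r2sMax <- bolus$amplitude * class$cbv
  r2Max <- bolus$amplitude * class$ucbv
  0.867 * sqrt(cbvFraction * class$adc) * r2sMax / r2Max^1.5
}

#' Simulate a dual-echo DSC acquisition with known ground truth
#'
#' Builds a block-wise digital phantom: tissue classes occupy equal-width
#' slabs along x across all slices. Per voxel, the forward model sets
#' \eqn{\Delta R_2^*(t) = A \cdot \mathrm{cbv} \cdot C(t)} and
#' \eqn{\Delta R_2(t) = A \cdot \mathrm{ucbv} \cdot C(t)} with `A` the bolus
#' amplitude and `C(t)` the unit-peak gamma-variate, then generates signals
#' \eqn{S(t) = S(0) \exp(-\mathrm{TE} \cdot \Delta R(t))} per echo and adds
#' noise. With `noiseSd = 0` the relaxometry equations invert the forward
#' model exactly.
#'
#' @param classes list of [tissueClass()] objects; a class labelled
#'   `"NAWM"` becomes the NAWM mask, classes labelled `"tumor*"` the tumor
#'   mask.
#' @param bolus a [bolusModel()]; `arrivalIndex` must leave at least one
#'   baseline frame and lie on the time axis.
#' @param gridShape 3D grid dimensions `c(nx, ny, nz)`.
#' @param nTimepoints number of frames acquired.
#' @param noiseSd additive noise SD in signal units (>= 0).
#' @param noiseModel `"gaussian"` (additive on magnitude; default) or
#'   `"rician"`.
#' @param tr repetition time, s.
#' @param teGre,teSe echo times, s.
#' @param seed integer RNG seed; the simulation is bit-reproducible for a
#'   fixed seed.
#' @return A [PhantomOutput-class].
#' @export
simulateDsc <- function(classes = defaultTissueClasses(bolus),
                        bolus = bolusModel(),
                        gridShape = c(64L, 64L, 15L),
                        nTimepoints = 120L,
                        noiseSd = 0,
                        noiseModel = c("gaussian", "rician"),
                        tr = 1.5, teGre = 0.0186, teSe = 0.069,
                        seed = 1L) {
  noiseModel <- match.arg(noiseModel)
  stopifnot(length(gridShape) == 3L, all(gridShape >= 1L), noiseSd >= 0)
  if (!all(vapply(classes, inherits, logical(1L), "TissueClass")))
    stop("classes must be a list of tissueClass() objects")
  if (bolus$arrivalIndex < 1L || bolus$arrivalIndex >= nTimepoints)
    stop("bolus arrivalIndex must lie within the time axis with >= 1 baseline frame")
  nc <- length(classes)
  if (gridShape[1L] < nc) stop("gridShape[1] must be >= the number of classes")
  set.seed(as.integer(seed))

  nx <- gridShape[1L]; ny <- gridShape[2L]; nz <- gridShape[3L]
  nt <- as.integer(nTimepoints)
  # equal-width slabs along x
  slab <- if (nc == 1L) rep(1L, nx)
          else as.integer(cut(seq_len(nx), breaks = nc, labels = FALSE))
  labels <- vapply(classes, `[[`, character(1L), "label")
  classIdx <- array(rep(slab, times = ny * nz), dim = c(nx, ny, nz))
  classLabel <- array(labels[classIdx], dim = c(nx, ny, nz))

  pick <- function(field) {
    v <- vapply(classes, `[[`, numeric(1L), field)
    array(v[classIdx], dim = c(nx, ny, nz))
  }
  truthCbv <- pick("cbv"); truthUcbv <- pick("ucbv")
  truthVs <- pick("vesselSize"); adc <- pick("adc"); base <- pick("baseline")

  ct <- gammaVariate(seq_len(nt), bolus)           # length nt, unit peak
  nvox <- nx * ny * nz
  # outer(voxel, frame): dR2*(v,t) = A * cbv_v * C(t)
  r2star <- outer(as.vector(truthCbv) * bolus$amplitude, ct)
  r2 <- outer(as.vector(truthUcbv) * bolus$amplitude, ct)
  gre <- as.vector(base) * exp(-teGre * r2star)
  se <- as.vector(base) * exp(-teSe * r2)
  if (noiseSd > 0) {
    if (noiseModel == "gaussian") {
      gre <- gre + stats::rnorm(nvox * nt, sd = noiseSd)
      se <- se + stats::rnorm(nvox * nt, sd = noiseSd)
    } else {
      gre <- sqrt((gre + stats::rnorm(nvox * nt, sd = noiseSd))^2 +
                    stats::rnorm(nvox * nt, sd = noiseSd)^2)
      se <- sqrt((se + stats::rnorm(nvox * nt, sd = noiseSd))^2 +
                   stats::rnorm(nvox * nt, sd = noiseSd)^2)
    }
  }
  dim(gre) <- c(nx, ny, nz, nt); dim(se) <- c(nx, ny, nz, nt)

  series <- DualEchoSeries(gre, se, tr = tr, teGre = teGre, teSe = teSe,
                           injectionIndex = bolus$arrivalIndex + 1L)
  classDf <- data.frame(
    label = labels,
    cbv = vapply(classes, `[[`, numeric(1L), "cbv"),
    ucbv = vapply(classes, `[[`, numeric(1L), "ucbv"),
    vesselSize = vapply(classes, `[[`, numeric(1L), "vesselSize"),
    adc = vapply(classes, `[[`, numeric(1L), "adc"),
    baseline = vapply(classes, `[[`, numeric(1L), "baseline")
  )
  new("PhantomOutput", series = series, adc = adc,
      tumorMask = array(startsWith(classLabel, "tumor"), dim = c(nx, ny, nz)),
      nawmMask = array(classLabel == "NAWM", dim = c(nx, ny, nz)),
      truthCbv = truthCbv, truthUcbv = truthUcbv, truthVesselSize = truthVs,
      classLabel = classLabel, classes = classDf, seed = as.integer(seed))
}

#' Simulate a stained-slide image of elliptical vessel profiles
#'
#' Rasterizes non-overlapping filled ellipses (vessel lumina as a CD31-like
#' stain would show them) on a noisy background and returns both the
#' intensity image and a per-object truth table for oracle comparisons.
#' Intensities are in [0, 1]: background around `backgroundLevel`, vessels
#' at `foregroundLevel`.
#'
#' @param vessels data.frame with columns `cx`, `cy` (centre, px), `a`, `b`
#'   (semi-axes, px) and optionally `theta` (orientation, radians,
#'   default 0).
#' @param imageShape `c(nrow, ncol)` in pixels.
#' @param backgroundNoise Gaussian noise SD added to the whole image.
#' @param backgroundLevel,foregroundLevel base intensities.
#' @param seed RNG seed for the noise.
#' @return List with `image` (numeric matrix, clamped to [0, 1]) and
#'   `truth` (data.frame: id, cx, cy, a, b, theta, areaPx — the exact
#'   rasterized pixel count).
#' @export
simulateSlide <- function(vessels, imageShape = c(256L, 256L),
                          backgroundNoise = 0.02,
                          backgroundLevel = 0.15, foregroundLevel = 0.85,
                          seed = 1L) {
  stopifnot(length(imageShape) == 2L, backgroundNoise >= 0)
  set.seed(as.integer(seed))
  nr <- imageShape[1L]; ncol_ <- imageShape[2L]
  img <- matrix(backgroundLevel, nr, ncol_)
  owner <- matrix(0L, nr, ncol_)
  nV <- if (is.null(vessels) || nrow(vessels) == 0L) 0L else nrow(vessels)
  areas <- integer(nV)
  if (nV > 0L) {
    if (is.null(vessels$theta)) vessels$theta <- 0
    xs <- row(img); ys <- col(img)
    for (i in seq_len(nV)) {
      v <- vessels[i, ]
      if (v$a <= 0 || v$b <= 0) stop("semi-axes must be positive")
      ext <- max(v$a, v$b)
      if (v$cx - ext < 1 || v$cx + ext > nr || v$cy - ext < 1 || v$cy + ext > ncol_)
        stop("vessel ", i, " extends outside the image bounds")
      dx <- xs - v$cx; dy <- ys - v$cy
      u <- dx * cos(v$theta) + dy * sin(v$theta)
      w <- -dx * sin(v$theta) + dy * cos(v$theta)
      inside <- (u / v$a)^2 + (w / v$b)^2 <= 1
      if (any(owner[inside] != 0L))
        stop("vessel ", i, " overlaps vessel ", owner[inside][owner[inside] != 0L][1L])
      owner[inside] <- i
      img[inside] <- foregroundLevel
      areas[i] <- sum(inside)
    }
  }
  if (backgroundNoise > 0)
    img <- img + matrix(stats::rnorm(nr * ncol_, sd = backgroundNoise), nr, ncol_)
  img[img < 0] <- 0; img[img > 1] <- 1
  truth <- if (nV > 0L) {
    data.frame(id = seq_len(nV), cx = vessels$cx, cy = vessels$cy,
               a = vessels$a, b = vessels$b, theta = vessels$theta,
               areaPx = areas)
  } else {
    data.frame(id = integer(), cx = numeric(), cy = numeric(),
               a = numeric(), b = numeric(), theta = numeric(),
               areaPx = integer())
  }
  list(image = img, truth = truth)
}
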