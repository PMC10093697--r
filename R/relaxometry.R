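#' Convert dual-echo signals to relaxation-rate changes
#'
#' Applies the log-ratio conversion per voxel and frame:
#' \deqn{\Delta R_2^*(t) = -\frac{1}{TE_{GRE}} \ln\frac{S_{GRE}(t)}{S_{GRE}(0)},
#'       \qquad
#'       \Delta R_2(t) = -\frac{1}{TE_{SE}} \ln\frac{S_{SE}(t)}{S_{SE}(0)},}
#' with \eqn{S(0)} the baseline mean. Voxels with a nonpositive signal
#' ratio at any frame are marked invalid (reason `"nonpositive-signal"`)
#' rather than clamped; their curves are set to `NA`.
#'
#' @param series a trimmed [DualEchoSeries-class].
#' @param baseline the matching [BaselineEstimate-class].
#' @param validity optional [ValidityMask-class] from [qcFilter()]; the
#'   returned object carries it, updated for nonpositive ratios.
#' @return A [RelaxationCurves-class] with curves in 1/s and a time axis in
#'   seconds.
#' @export
toRelaxation <- function(series, baseline, validity = NULL) {
  d <- dim(series@gre)
  if (!identical(dim(baseline@greMean), d[1:3]))
    stop("baseline grid does not match the series grid")
  if (is.null(validity))
    validity <- new("ValidityMask", valid = array(TRUE, d[1:3]),
                    reason = array("", d[1:3]))
  ratioG <- series@gre / as.vector(baseline@greMean)
  ratioS <- series@se / as.vector(baseline@seMean)
  nvox <- prod(d[1:3])
  rowAny4 <- function(r) {
    m <- matrix(r <= 0 | !is.finite(r), nrow = nvox, ncol = d[4L])
    array(rowSums(m) > 0L, d[1:3])
  }
  badVox <- rowAny4(ratioG) | rowAny4(ratioS)
  r2star <- -log(pmax(ratioG, .Machine$double.xmin)) / series@teGre
  r2 <- -log(pmax(ratioS, .Machine$double.xmin)) / series@teSe
  if (any(badVox)) {
    idx <- which(badVox)
    nvox <- prod(d[1:3])
    full <- as.vector(outer(idx, (seq_len(d[4L]) - 1L) * nvox, `+`))
    r2star[full] <- NA_real_
    r2[full] <- NA_real_
    newlyBad <- badVox & validity@valid
    valid <- validity@valid & !badVox
    reason <- validity@reason
    reason[newlyBad] <- ifelse(reason[newlyBad] == "", "nonpositive-signal",
                               paste(reason[newlyBad], "nonpositive-signal", sep = ";"))
    validity <- new("ValidityMask", valid = valid, reason = reason)
  }
  new("RelaxationCurves", r2star = r2star, r2 = r2,
      timeAxis = (seq_len(d[4L]) - 1L) * series@tr,
      injectionIndex = series@injectionIndex, validity = validity)
}

#' Detect the first-pass bolus window
#'
#' Averages \eqn{\Delta R_2^*(t)} over the masked valid voxels, locates the
#' global peak of the mean curve, and walks outward from the peak to the
#' last frames still at or above `threshold` times the peak value. One
#' shared window (entrance `t0` to exit `t1`) is returned for all voxels.
#' The default threshold of 1% of peak keeps over 99% of a gamma-variate
#' first pass inside the window; looser thresholds (e.g. 10%) clip several
#' percent of the bolus mass from the CBV integral.
#'
#' @param curves a [RelaxationCurves-class].
#' @param mask 3D logical array of voxels to average (e.g. tumor + NAWM);
#'   default: all valid voxels.
#' @param threshold fraction of the peak defining entrance/exit (default
#'   0.01).
#' @return A [BolusWindow-class].
#' @export
detectBolusWindow <- function(curves, mask = NULL, threshold = 0.01) {
  valid <- curves@validity@valid
  use <- if (is.null(mask)) valid else (mask & valid)
  if (!any(use)) stop("no valid voxels to average")
  d <- dim(curves@r2star)
  m <- matrix(curves@r2star, nrow = prod(d[1:3]), ncol = d[4L])
  meanCurve <- colMeans(m[as.vector(use), , drop = FALSE])
  peak <- max(meanCurve)
  if (!is.finite(peak) || peak <= 0)
    stop("flat or nonpositive mean curve: no bolus detected")
  thr <- threshold * peak
  ipk <- which.max(meanCurve)
  if (meanCurve[ipk] < thr) stop("no frame exceeds the detection threshold")
  t0 <- ipk
  while (t0 > 1L && meanCurve[t0 - 1L] >= thr) t0 <- t0 - 1L
  t1 <- ipk
  nt <- length(meanCurve)
  while (t1 < nt && meanCurve[t1 + 1L] >= thr) t1 <- t1 + 1L
  if (t0 == t1) stop("degenerate bolus window (single frame)")
  new("BolusWindow", t0 = as.integer(t0), t1 = as.integer(t1))
}

# trapezoidal rule over frames [t0, t1] with spacing dt, vectorised over voxels
.trapzWindow <- function(arr4, t0, t1, dt) {
  d <- dim(arr4)
  m <- matrix(arr4, nrow = prod(d[1:3]), ncol = d[4L])[, t0:t1, drop = FALSE]
  k <- ncol(m)
  out <- (rowSums(m) - 0.5 * (m[, 1L] + m[, k])) * dt
  array(out, dim = d[1:3])
}

#' Integrate relaxation-rate curves to raw CBV
#'
#' Trapezoidal integration of \eqn{\Delta R_2^*(t)} over the bolus window
#' \eqn{[t_0, t_1]} with the repetition time as the time step. The result
#' is the raw (unnormalized) cerebral blood volume in 1/s x s; negative
#' curve values are integrated as-is.
#'
#' @param curves a [RelaxationCurves-class].
#' @param window a [BolusWindow-class].
#' @return 3D array of raw CBV values (`NA` on invalid voxels).
#' @export
integrateCbv <- function(curves, window) {
  .checkWindow(curves, window)
  dt <- curves@timeAxis[2L] - curves@timeAxis[1L]
  out <- .trapzWindow(curves@r2star, window@t0, window@t1, dt)
  out[!curves@validity@valid] <- NA_real_
  out
}

#' Integrate spin-echo curves to raw microvascular CBV
#'
#' As [integrateCbv()] but on \eqn{\Delta R_2(t)}, whose spin-echo origin
#' weights the capillary-scale vasculature.
#'
#' @inheritParams integrateCbv
#' @return 3D array of raw microvascular CBV values.
#' @export
integrateUcbv <- function(curves, window) {
  .checkWindow(curves, window)
  dt <- curves@timeAxis[2L] - curves@timeAxis[1L]
  out <- .trapzWindow(curves@r2, window@t0, window@t1, dt)
  out[!curves@validity@valid] <- NA_real_
  out
}

.checkWindow <- function(curves, window) {
  nt <- dim(curves@r2star)[4L]
  if (window@t1 <= window@t0) stop("bolus window must satisfy t0 < t1")
  if (window@t0 < 1L || window@t1 > nt) stop("bolus window outside the time axis")
  invisible(TRUE)
}

#' Peak relaxation-rate changes within the bolus window
#'
#' Per-voxel maxima of \eqn{\Delta R_2^*(t)} and \eqn{\Delta R_2(t)}
#' restricted to `[t0, t1]` — the quantities entering the Kiselev
#' vessel-size formula.
#'
#' @inheritParams integrateCbv
#' @return A [PeakRates-class].
#' @export
peakRates <- function(curves, window) {
  .checkWindow(curves, window)
  d <- dim(curves@r2star)
  sel <- function(a) {
    m <- matrix(a, nrow = prod(d[1:3]), ncol = d[4L])[, window@t0:window@t1, drop = FALSE]
    out <- do.call(pmax, c(as.data.frame(m), na.rm = FALSE))
    array(out, dim = d[1:3])
  }
  new("PeakRates", r2starMax = sel(curves@r2star), r2Max = sel(curves@r2))
}
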