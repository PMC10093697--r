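#' Normalize a map to the NAWM mean
#'
#' Divides every voxel by the mean of the map over valid voxels of the
#' normal-appearing white matter mask (contralateral to the tumor), so the
#' NAWM mean of the output is exactly 1.
#'
#' @param rawMap 3D numeric array.
#' @param nawmMask 3D logical array; should contain at least 50 valid
#'   voxels for a stable reference (a warning is raised below that).
#' @param validity optional [ValidityMask-class]; invalid voxels are
#'   excluded from the reference mean and set to `NA` in the output.
#' @return The normalized 3D array (unitless).
#' @export
normalizeToNawm <- function(rawMap, nawmMask, validity = NULL) {
  use <- .refVoxels(rawMap, nawmMask, validity)
  ref <- mean(rawMap[use])
  if (!is.finite(ref) || ref == 0) stop("NAWM reference mean is zero or undefined")
  out <- rawMap / ref
  if (!is.null(validity)) out[!validity@valid] <- NA_real_
  out
}

#' Scale CBV so its NAWM median equals a literature blood-volume percentage
#'
#' Multiplies the raw CBV map by `targetPercent / median(NAWM)` so that the
#' median scaled CBV over valid NAWM voxels equals `targetPercent` (default
#' 3.2, the literature white-matter blood volume in percent). The scaled
#' map is the CBV input of the Kiselev vessel-size formula.
#'
#' @inheritParams normalizeToNawm
#' @param rawCbv 3D raw CBV array.
#' @param targetPercent target NAWM median, percent blood volume.
#' @return 3D array of scaled CBV in percent.
#' @export
scaleToNawmMedian <- function(rawCbv, nawmMask, targetPercent = 3.2,
                              validity = NULL) {
  use <- .refVoxels(rawCbv, nawmMask, validity)
  ref <- stats::median(rawCbv[use])
  if (!is.finite(ref) || ref <= 0) stop("NAWM median must be positive for scaling")
  if (targetPercent == 0) warning("targetPercent = 0 produces an all-zero map")
  out <- rawCbv * (targetPercent / ref)
  if (!is.null(validity)) out[!validity@valid] <- NA_real_
  out
}

.refVoxels <- function(map, nawmMask, validity) {
  stopifnot(identical(dim(map), dim(nawmMask)))
  use <- nawmMask & is.finite(map)
  if (!is.null(validity)) use <- use & validity@valid
  n <- sum(use)
  if (n == 0L) stop("NAWM mask is empty or contains no valid voxels")
  if (n < 50L) warning("only ", n, " valid NAWM voxels; reference may be unstable")
  use
}

#' Kiselev-model vessel-size map
#'
#' Mean vessel size per voxel from the ratio of gradient-echo to spin-echo
#' susceptibility responses:
#' \deqn{VS = 0.867 \sqrt{CBV \cdot ADC}\;
#'       \frac{\Delta R_2^{*\max}}{(\Delta R_2^{\max})^{3/2}},}
#' with CBV the scaled blood volume expressed as a unitless fraction
#' (3.2\% enters as 0.032), ADC in um^2/s and the peak rates in 1/s,
#' yielding micrometres. Voxels with \eqn{\Delta R_2^{\max} \le 0} or a
#' negative \eqn{CBV \cdot ADC} product are invalidated (reason
#' `"nonphysical-vsi-input"`), not clamped.
#'
#' @param cbvFraction 3D array, scaled CBV as a unitless fraction.
#' @param adc 3D ADC array, um^2/s.
#' @param peaks a [PeakRates-class].
#' @param validity optional [ValidityMask-class] to start from.
#' @return List with `vesselSize` (3D array, um, `NA` where invalid) and
#'   `validity` (updated [ValidityMask-class]).
#' @export
vesselSizeMap <- function(cbvFraction, adc, peaks, validity = NULL) {
  stopifnot(identical(dim(cbvFraction), dim(adc)))
  d <- dim(cbvFraction)
  if (is.null(validity))
    validity <- new("ValidityMask", valid = array(TRUE, d), reason = array("", d))
  prod_ <- cbvFraction * adc
  bad <- (!is.na(prod_) & prod_ < 0) |
    (!is.na(peaks@r2Max) & peaks@r2Max <= 0)
  vs <- 0.867 * sqrt(pmax(prod_, 0)) * peaks@r2starMax / peaks@r2Max^1.5
  vs[bad | !validity@valid] <- NA_real_
  newlyBad <- bad & validity@valid
  if (any(newlyBad, na.rm = TRUE)) {
    valid <- validity@valid & !bad
    reason <- validity@reason
    reason[newlyBad] <- ifelse(reason[newlyBad] == "", "nonphysical-vsi-input",
                               paste(reason[newlyBad], "nonphysical-vsi-input", sep = ";"))
    validity <- new("ValidityMask", valid = valid, reason = reason)
  }
  list(vesselSize = vs, validity = validity)
}

#' Compute all parameter maps from relaxation curves
#'
#' Convenience composition of the map stage: integrates CBV and
#' microvascular CBV over the bolus window, normalizes both to the NAWM
#' mean, scales CBV to the NAWM median target, extracts peak rates and
#' applies the Kiselev vessel-size formula.
#'
#' @param curves a [RelaxationCurves-class].
#' @param window a [BolusWindow-class].
#' @param adc 3D ADC map, um^2/s.
#' @param nawmMask 3D logical NAWM mask.
#' @param targetPercent NAWM median target for scaled CBV, percent.
#' @return A [ParamMaps-class].
#' @export
computeParamMaps <- function(curves, window, adc, nawmMask,
                             targetPercent = 3.2) {
  validity <- curves@validity
  rawCbv <- integrateCbv(curves, window)
  rawUcbv <- integrateUcbv(curves, window)
  cbvN <- normalizeToNawm(rawCbv, nawmMask, validity)
  ucbvN <- normalizeToNawm(rawUcbv, nawmMask, validity)
  cbvS <- scaleToNawmMedian(rawCbv, nawmMask, targetPercent, validity)
  pk <- peakRates(curves, window)
  vs <- vesselSizeMap(cbvS / 100, adc, pk, validity)
  new("ParamMaps", cbvNorm = cbvN, ucbvNorm = ucbvN, cbvScaled = cbvS,
      vesselSize = vs$vesselSize, adc = adc, validity = vs$validity)
}
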