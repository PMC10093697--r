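#' @import methods
NULL

#' Dual-echo DSC-MRI time series
#'
#' Container for simultaneously acquired gradient-echo (GRE) and spin-echo
#' (SE) dynamic susceptibility contrast series on a common voxel grid, plus
#' the timing parameters needed to convert signals to relaxation rates.
#'
#' @slot gre 4D numeric array (x, y, z, t): GRE signal, arbitrary units.
#' @slot se 4D numeric array, same dimensions: SE signal.
#' @slot tr repetition time in seconds.
#' @slot teGre gradient-echo echo time in seconds.
#' @slot teSe spin-echo echo time in seconds.
#' @slot injectionIndex 1-based index of the first frame at or after
#'   contrast-bolus arrival; frames `1:(injectionIndex - 1)` are baseline.
#'
#' @export
setClass("DualEchoSeries",
  slots = c(
    gre = "array", se = "array",
    tr = "numeric", teGre = "numeric", teSe = "numeric",
    injectionIndex = "integer"
  )
)

setValidity("DualEchoSeries", function(object) {
  msg <- character()
  if (length(dim(object@gre)) != 4L) msg <- c(msg, "gre must be a 4D array (x, y, z, t)")
  if (!identical(dim(object@gre), dim(object@se)))
    msg <- c(msg, "gre and se must share dimensions")
  if (object@tr <= 0) msg <- c(msg, "tr must be positive")
  if (object@teGre <= 0 || object@teSe <= 0) msg <- c(msg, "echo times must be positive")
  if (object@teGre >= object@teSe) msg <- c(msg, "teGre must be smaller than teSe")
  nt <- dim(object@gre)[4L]
  if (object@injectionIndex < 2L || object@injectionIndex > nt)
    msg <- c(msg, "injectionIndex must lie within the time axis and leave >= 1 baseline frame")
  if (length(msg)) msg else TRUE
})

#' Construct a DualEchoSeries
#'
#' @param gre,se 4D signal arrays (x, y, z, t), identical dimensions.
#' @param tr repetition time (s).
#' @param teGre,teSe echo times (s); `teGre < teSe`.
#' @param injectionIndex 1-based index of the first post-arrival frame.
#' @return A [DualEchoSeries-class] object.
#' @export
DualEchoSeries <- function(gre, se, tr, teGre, teSe, injectionIndex) {
  new("DualEchoSeries", gre = gre, se = se, tr = tr, teGre = teGre,
      teSe = teSe, injectionIndex = as.integer(injectionIndex))
}

#' Per-voxel baseline signal estimate
#'
#' Mean and standard deviation of the pre-bolus signal, per voxel and per
#' echo, over a stated frame window.
#'
#' @slot greMean,greSd 3D arrays: GRE baseline mean / sample SD.
#' @slot seMean,seSd 3D arrays: SE baseline mean / sample SD.
#' @slot window integer of length 2, the (inclusive) frame range used.
#' @export
setClass("BaselineEstimate",
  slots = c(greMean = "array", greSd = "array",
            seMean = "array", seSd = "array", window = "integer")
)

setValidity("BaselineEstimate", function(object) {
  if (any(object@greSd < 0, na.rm = TRUE) || any(object@seSd < 0, na.rm = TRUE))
    return("baseline SD must be nonnegative")
  if (length(object@window) != 2L || object@window[1L] > object@window[2L])
    return("window must be an increasing pair of frame indices")
  TRUE
})

#' Voxel validity mask with reason codes
#'
#' Boolean volume marking voxels that pass the quality filter, with a reason
#' code for each excluded voxel. A voxel is valid only if it passes on both
#' echoes.
#'
#' @slot valid 3D logical array.
#' @slot reason 3D character array; `""` for valid voxels, otherwise one or
#'   more of `"insufficient-drop-gre"`, `"insufficient-drop-se"`,
#'   `"nonpositive-signal"` joined by `";"`.
#' @export
setClass("ValidityMask",
  slots = c(valid = "array", reason = "array")
)

setValidity("ValidityMask", function(object) {
  if (!is.logical(object@valid)) return("valid must be logical")
  if (!identical(dim(object@valid), dim(object@reason)))
    return("valid and reason must share dimensions")
  if (any(object@valid & object@reason != "")) return("valid voxels cannot carry a reason code")
  TRUE
})

#' Per-voxel relaxation-rate time curves
#'
#' Changes in transverse relaxation rates derived from the GRE and SE
#' signals: \eqn{\Delta R_2^*(t)} from the gradient echo and
#' \eqn{\Delta R_2(t)} from the spin echo, both in 1/s.
#'
#' @slot r2star 4D array, \eqn{\Delta R_2^*(t)} (1/s).
#' @slot r2 4D array, \eqn{\Delta R_2(t)} (1/s).
#' @slot timeAxis frame times in seconds (frame index x TR).
#' @slot injectionIndex first post-arrival frame (1-based).
#' @slot validity a [ValidityMask-class], updated for nonpositive ratios.
#' @export
setClass("RelaxationCurves",
  slots = c(r2star = "array", r2 = "array", timeAxis = "numeric",
            injectionIndex = "integer", validity = "ValidityMask")
)

setValidity("RelaxationCurves", function(object) {
  if (!identical(dim(object@r2star), dim(object@r2)))
    return("r2star and r2 must share dimensions")
  if (length(object@timeAxis) != dim(object@r2star)[4L])
    return("timeAxis length must equal the number of frames")
  TRUE
})

#' First-pass bolus window
#'
#' Frame range (inclusive, 1-based) from bolus entrance `t0` to exit `t1`,
#' shared by all voxels.
#'
#' @slot t0,t1 integer frame indices, `t0 < t1`.
#' @export
setClass("BolusWindow", slots = c(t0 = "integer", t1 = "integer"))

setValidity("BolusWindow", function(object) {
  if (object@t0 >= object@t1) return("t0 must precede t1")
  TRUE
})

#' Peak relaxation-rate changes
#'
#' Per-voxel maxima of the relaxation-rate curves restricted to the bolus
#' window.
#'
#' @slot r2starMax,r2Max 3D arrays (1/s).
#' @export
setClass("PeakRates", slots = c(r2starMax = "array", r2Max = "array"))

#' Quantitative parameter maps
#'
#' The per-voxel end products of the pipeline, sharing one grid: NAWM-
#' normalized CBV and microvascular CBV (unitless), CBV scaled so its
#' NAWM median is a stated blood-volume percentage, the Kiselev-model
#' vessel-size map (micrometres), the ADC map, and the validity mask.
#' Invalid voxels hold `NA`.
#'
#' @slot cbvNorm,ucbvNorm 3D arrays, NAWM-relative (unitless).
#' @slot cbvScaled 3D array, percent blood volume.
#' @slot vesselSize 3D array, micrometres.
#' @slot adc 3D array, square micrometres per second.
#' @slot validity a [ValidityMask-class].
#' @export
setClass("ParamMaps",
  slots = c(cbvNorm = "array", ucbvNorm = "array", cbvScaled = "array",
            vesselSize = "array", adc = "array", validity = "ValidityMask")
)

setValidity("ParamMaps", function(object) {
  d <- dim(object@cbvNorm)
  same <- identical(dim(object@ucbvNorm), d) && identical(dim(object@cbvScaled), d) &&
    identical(dim(object@vesselSize), d) && identical(dim(object@adc), d) &&
    identical(dim(object@validity@valid), d)
  if (!same) return("all maps must share one grid")
  if (any(object@vesselSize < 0 & object@validity@valid, na.rm = TRUE))
    return("vessel size must be nonnegative on valid voxels")
  TRUE
})

#' Digital phantom output
#'
#' A synthetic dual-echo DSC acquisition with known per-class ground truth:
#' the simulated series, ADC map, tumor and NAWM masks, truth maps for CBV
#' fraction, microvascular CBV fraction and vessel size, and the tissue-
#' class label volume.
#'
#' @slot series a [DualEchoSeries-class].
#' @slot adc 3D ADC map (square micrometres per second).
#' @slot tumorMask,nawmMask 3D logical masks (disjoint).
#' @slot truthCbv,truthUcbv 3D arrays of true blood-volume fractions.
#' @slot truthVesselSize 3D array of true vessel size (micrometres).
#' @slot classLabel 3D character array of tissue-class names ("" = empty).
#' @slot classes data.frame of the tissue-class specifications used.
#' @slot seed integer RNG seed used.
#' @export
setClass("PhantomOutput",
  slots = c(series = "DualEchoSeries", adc = "array",
            tumorMask = "array", nawmMask = "array",
            truthCbv = "array", truthUcbv = "array", truthVesselSize = "array",
            classLabel = "array", classes = "data.frame", seed = "integer")
)

setValidity("PhantomOutput", function(object) {
  if (any(object@tumorMask & object@nawmMask))
    return("tumor and NAWM masks must be disjoint")
  TRUE
})

#' Three-group statistical comparison result
#'
#' Outcome of the normality-gated decision tree on one parameter: per-group
#' Shapiro-Wilk p-values, the omnibus test chosen (one-way ANOVA when every
#' group is consistent with normality, Kruskal-Wallis otherwise), and the
#' post hoc pairwise table (Tukey HSD or Dunn-Bonferroni) when the omnibus
#' test is significant at `alpha`.
#'
#' @slot parameter character, name of the compared quantity.
#' @slot groups named list of per-subject numeric values.
#' @slot normalityP named numeric, Shapiro-Wilk p per group (NA if the test
#'   was inapplicable, e.g. a constant-valued group).
#' @slot test `"anova"` or `"kruskal"`.
#' @slot statistic omnibus F or H statistic.
#' @slot p omnibus p-value.
#' @slot posthoc data.frame with columns pair, statistic, p_adj, method;
#'   zero rows when the omnibus test is not significant.
#' @slot alpha significance level.
#' @export
setClass("GroupComparison",
  slots = c(parameter = "character", groups = "list", normalityP = "numeric",
            test = "character", statistic = "numeric", p = "numeric",
            posthoc = "data.frame", alpha = "numeric")
)

setValidity("GroupComparison", function(object) {
  if (!object@test %in% c("anova", "kruskal")) return("test must be 'anova' or 'kruskal'")
  if (nrow(object@posthoc) > 0 && !is.na(object@p) && object@p > object@alpha)
    return("post hoc results may be present only when the omnibus test is significant")
  if (nrow(object@posthoc) > 0 && any(object@posthoc$p_adj < 0 | object@posthoc$p_adj > 1))
    return("adjusted p-values must lie in [0, 1]")
  TRUE
})
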