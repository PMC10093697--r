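#' Read a study configuration file
#'
#' Loads a YAML (or JSON-compatible YAML) study description: per-subject
#' paths to the GRE/SE series, ADC map and tumor / NAWM masks, a subtype
#' label per subject, and the pipeline constants. Missing constants take
#' the defaults used throughout: `nDiscard = 4`, `qcSdThreshold = 2`,
#' `nawmCbvTarget = 3.2` (percent), `hotspotPercentile = 90`,
#' `alpha = 0.05`, `tr = 1.5`, `teGre = 0.0186`, `teSe = 0.069`,
#' `injectionIndex = 21`, `adcUnits = "um2_per_s"`.
#'
#' @param path path to the YAML file.
#' @return A list with elements `subjects` (named list) and `constants`.
#' @export
readStudyConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(nDiscard = 4L, qcSdThreshold = 2, nawmCbvTarget = 3.2,
                   hotspotPercentile = 90, alpha = 0.05,
                   tr = 1.5, teGre = 0.0186, teSe = 0.069,
                   injectionIndex = 21L, adcUnits = "um2_per_s", seed = 1L)
  constants <- utils::modifyList(defaults, cfg$constants %||% list())
  if (any(unlist(constants[c("nDiscard", "qcSdThreshold", "nawmCbvTarget",
                             "hotspotPercentile", "alpha")]) < 0))
    stop("pipeline constants must be nonnegative")
  subjects <- cfg$subjects
  if (is.null(names(subjects)))
    names(subjects) <- vapply(subjects, `[[`, character(1L), "id")
  allowed <- c("Oligo", "Astro", "GBM")
  subtype <- vapply(subjects, `[[`, character(1L), "subtype")
  if (!all(subtype %in% allowed))
    stop("subtype labels must be one of: ", paste(allowed, collapse = ", "))
  list(subjects = subjects, constants = constants)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a phantom to disk in standard formats
#'
#' Writes the GRE and SE series as 4D NIfTI, ADC and truth maps as 3D
#' NIfTI, masks as uint8 NIfTI, and the tissue-class truth table as CSV.
#'
#' @param phantom a [PhantomOutput-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of files written.
#' @export
writePhantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- phantom@series
  f <- c(gre = "gre.nii.gz", se = "se.nii.gz", adc = "adc.nii.gz",
         tumorMask = "tumor_mask.nii.gz", nawmMask = "nawm_mask.nii.gz",
         truthCbv = "truth_cbv.nii.gz", truthUcbv = "truth_ucbv.nii.gz",
         truthVesselSize = "truth_vesselsize.nii.gz",
         classes = "truth_classes.csv")
  f <- vapply(f, function(x) file.path(dir, x), character(1L))
  RNifti::writeNifti(RNifti::asNifti(s@gre), f[["gre"]])
  RNifti::writeNifti(RNifti::asNifti(s@se), f[["se"]])
  RNifti::writeNifti(RNifti::asNifti(phantom@adc), f[["adc"]])
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(phantom@tumorMask),
                                           dim(phantom@tumorMask)), datatype = "uint8"),
                     f[["tumorMask"]])
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(phantom@nawmMask),
                                           dim(phantom@nawmMask)), datatype = "uint8"),
                     f[["nawmMask"]])
  RNifti::writeNifti(RNifti::asNifti(phantom@truthCbv), f[["truthCbv"]])
  RNifti::writeNifti(RNifti::asNifti(phantom@truthUcbv), f[["truthUcbv"]])
  RNifti::writeNifti(RNifti::asNifti(phantom@truthVesselSize), f[["truthVesselSize"]])
  utils::write.csv(phantom@classes, f[["classes"]], row.names = FALSE)
  invisible(f)
}

#' Write a simulated slide as an 8-bit grayscale TIFF plus truth CSV
#'
#' @param slide result of [simulateSlide()].
#' @param dir output directory.
#' @param name base file name (default "slide").
#' @return Invisibly, the files written.
#' @export
writeSlide <- function(slide, dir, name = "slide") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fImg <- file.path(dir, paste0(name, ".tif"))
  fCsv <- file.path(dir, paste0(name, "_truth.csv"))
  tiff::writeTIFF(slide$image, fImg, bits.per.sample = 8L)
  utils::write.csv(slide$truth, fCsv, row.names = FALSE)
  invisible(c(image = fImg, truth = fCsv))
}

.readVolume <- function(path) {
  v <- RNifti::readNifti(path)
  array(as.numeric(v), dim = dim(v))
}

#' Run the map pipeline for one subject
#'
#' End-to-end per-subject analysis: load the dual-echo series, ADC and
#' masks; trim the initial frames; estimate baselines; apply the
#' 2-SD quality filter; convert to relaxation rates; detect the bolus
#' window on the tumor+NAWM-averaged curve; integrate CBV and
#' microvascular CBV; normalize and scale to NAWM; map vessel size; and
#' summarize the three maps over the tumor ROI. Maps are written as NIfTI
#' and the summary as one CSV row per parameter. Deterministic given its
#' inputs; all volumes must share one grid.
#'
#' @param config list from [readStudyConfig()] (or of the same shape).
#' @param subjectId name of the subject entry to run.
#' @param outDir output directory; default `subject$outDir` or
#'   `file.path("vsimri_out", subjectId)`.
#' @return Invisibly, a list with `maps` (a [ParamMaps-class]) and
#'   `summary` (data.frame, one row per parameter).
#' @export
runSubject <- function(config, subjectId, outDir = NULL) {
  sub <- config$subjects[[subjectId]]
  if (is.null(sub)) stop("unknown subject: ", subjectId)
  k <- config$constants
  gre <- .readVolume(sub$gre)
  se <- .readVolume(sub$se)
  adc <- .readVolume(sub$adc)
  tumor <- .readVolume(sub$tumorMask) > 0
  nawm <- .readVolume(sub$nawmMask) > 0
  grids <- list(dim(gre)[1:3], dim(se)[1:3], dim(adc), dim(tumor), dim(nawm))
  if (!all(vapply(grids, identical, logical(1L), grids[[1L]])))
    stop("input volumes are not on one voxel grid; no output written")

  series <- DualEchoSeries(gre, se, tr = k$tr, teGre = k$teGre, teSe = k$teSe,
                           injectionIndex = sub$injectionIndex %||% k$injectionIndex)
  series <- trimInitial(series, k$nDiscard)
  baseline <- estimateBaseline(series)
  validity <- qcFilter(series, baseline, sdThreshold = k$qcSdThreshold)
  curves <- toRelaxation(series, baseline, validity)
  window <- detectBolusWindow(curves, mask = tumor | nawm)
  maps <- computeParamMaps(curves, window, adc, nawm,
                           targetPercent = k$nawmCbvTarget)

  summary <- do.call(rbind, list(
    summarizeRoi(cbvNorm(maps), tumor, maps@validity,
                 percentile = k$hotspotPercentile, parameter = "CBV"),
    summarizeRoi(ucbvNorm(maps), tumor, maps@validity,
                 percentile = k$hotspotPercentile, parameter = "uCBV"),
    summarizeRoi(vesselSize(maps), tumor, maps@validity,
                 percentile = k$hotspotPercentile, parameter = "VesselSize")
  ))
  summary <- cbind(subject = subjectId,
                   subtype = sub$subtype %||% NA_character_, summary)

  if (is.null(outDir)) outDir <- sub$outDir %||% file.path("vsimri_out", subjectId)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(RNifti::asNifti(cbvNorm(maps)), file.path(outDir, "cbv_norm.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(ucbvNorm(maps)), file.path(outDir, "ucbv_norm.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(cbvScaled(maps)), file.path(outDir, "cbv_scaled.nii.gz"))
  vsOut <- vesselSize(maps); vsOut[is.na(vsOut)] <- -1   # sentinel for NIfTI
  RNifti::writeNifti(RNifti::asNifti(vsOut), file.path(outDir, "vessel_size.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(validVoxels(maps)),
                                           dim(tumor)), datatype = "uint8"),
                     file.path(outDir, "validity_mask.nii.gz"))
  utils::write.csv(summary, file.path(outDir, "roi_summary.csv"), row.names = FALSE)
  message(sprintf("[%s] %d/%d voxels valid; bolus window frames %d-%d",
                  subjectId, sum(validVoxels(maps)), length(validVoxels(maps)),
                  window@t0, window@t1))
  invisible(list(maps = maps, summary = summary))
}

#' Run the full study: all subjects plus group statistics
#'
#' Runs [runSubject()] for every configured subject, assembles the
#' per-subject ROI summaries, and compares each parameter and summary
#' statistic (mean, median, hot spot) across the three glioma subtypes
#' with [compareGroups()]. Statistics for a parameter are skipped with a
#' warning when any subtype has fewer than 3 subjects.
#'
#' @param config list from [readStudyConfig()].
#' @param outDir study-level output directory (default "vsimri_out").
#' @return Invisibly, a list with `summaries` (data.frame of all subject
#'   rows), `comparisons` (list of [GroupComparison-class]) and the path
#'   of the written report CSV.
#' @export
runStudy <- function(config, outDir = "vsimri_out") {
  rows <- lapply(names(config$subjects), function(id)
    runSubject(config, id, outDir = file.path(outDir, id))$summary)
  summaries <- do.call(rbind, rows)
  utils::write.csv(summaries, file.path(outDir, "subject_summaries.csv"),
                   row.names = FALSE)

  comparisons <- list()
  report <- list()
  for (param in unique(summaries$parameter)) {
    for (statName in c("mean", "median", "hotspot")) {
      sel <- summaries[summaries$parameter == param, ]
      groups <- split(sel[[statName]], sel$subtype)
      if (length(groups) < 3L || any(lengths(groups) < 3L)) {
        warning("skipping ", param, "/", statName,
                ": need >= 3 subjects in each of 3 subtypes")
        next
      }
      cmpName <- paste(param, statName, sep = ".")
      gc <- compareGroups(groups, alpha = config$constants$alpha,
                          parameter = cmpName)
      comparisons[[cmpName]] <- gc
      report[[cmpName]] <- data.frame(
        parameter = param, statistic = statName, test = gc@test,
        omnibus = gc@statistic, p = gc@p,
        significantPairs = if (nrow(gc@posthoc))
          paste(gc@posthoc$pair[gc@posthoc$p_adj <= gc@alpha], collapse = "; ")
        else ""
      )
    }
  }
  reportDf <- if (length(report)) do.call(rbind, c(report, make.row.names = FALSE))
              else data.frame()
  reportPath <- file.path(outDir, "group_comparison.csv")
  utils::write.csv(reportDf, reportPath, row.names = FALSE)
  invisible(list(summaries = summaries, comparisons = comparisons,
                 report = reportPath))
}
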