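#' @rdname DualEchoSeries-class
#' @param object,x a package object.
#' @export
setGeneric("greSignal", function(x) standardGeneric("greSignal"))

#' @rdname DualEchoSeries-class
#' @export
setGeneric("seSignal", function(x) standardGeneric("seSignal"))

#' @rdname DualEchoSeries-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname DualEchoSeries-class
#' @export
setGeneric("injectionIndex", function(x) standardGeneric("injectionIndex"))

#' @rdname ValidityMask-class
#' @export
setGeneric("validVoxels", function(x) standardGeneric("validVoxels"))

#' @rdname ValidityMask-class
#' @export
setGeneric("reasonCodes", function(x) standardGeneric("reasonCodes"))

#' @rdname ParamMaps-class
#' @export
setGeneric("cbvNorm", function(x) standardGeneric("cbvNorm"))

#' @rdname ParamMaps-class
#' @export
setGeneric("ucbvNorm", function(x) standardGeneric("ucbvNorm"))

#' @rdname ParamMaps-class
#' @export
setGeneric("cbvScaled", function(x) standardGeneric("cbvScaled"))

#' @rdname ParamMaps-class
#' @export
setGeneric("vesselSize", function(x) standardGeneric("vesselSize"))

#' @aliases greSignal,DualEchoSeries-method seSignal,DualEchoSeries-method
#'   nFrames,DualEchoSeries-method injectionIndex,DualEchoSeries-method
#' @rdname DualEchoSeries-class
setMethod("greSignal", "DualEchoSeries", function(x) x@gre)
setMethod("seSignal", "DualEchoSeries", function(x) x@se)
setMethod("nFrames", "DualEchoSeries", function(x) dim(x@gre)[4L])
setMethod("injectionIndex", "DualEchoSeries", function(x) x@injectionIndex)

setMethod("validVoxels", "ValidityMask", function(x) x@valid)
setMethod("reasonCodes", "ValidityMask", function(x) x@reason)
setMethod("validVoxels", "RelaxationCurves", function(x) x@validity@valid)
setMethod("validVoxels", "ParamMaps", function(x) x@validity@valid)

setMethod("cbvNorm", "ParamMaps", function(x) x@cbvNorm)
setMethod("ucbvNorm", "ParamMaps", function(x) x@ucbvNorm)
setMethod("cbvScaled", "ParamMaps", function(x) x@cbvScaled)
setMethod("vesselSize", "ParamMaps", function(x) x@vesselSize)

setMethod("show", "DualEchoSeries", function(object) {
  d <- dim(object@gre)
  cat("DualEchoSeries:", paste(d[1:3], collapse = " x "), "voxels,",
      d[4L], "frames\n")
  cat("  TR", object@tr, "s; TE(GRE)/TE(SE)",
      object@teGre * 1000, "/", object@teSe * 1000, "ms\n")
  cat("  bolus arrival at frame", object@injectionIndex,
      sprintf("(%d baseline frames)\n", object@injectionIndex - 1L))
})

setMethod("show", "ValidityMask", function(object) {
  cat("ValidityMask:", sum(object@valid), "of", length(object@valid),
      "voxels valid\n")
  bad <- table(object@reason[object@reason != ""])
  if (length(bad)) {
    for (i in seq_along(bad)) cat("  ", names(bad)[i], ":", bad[i], "\n")
  }
})

setMethod("show", "RelaxationCurves", function(object) {
  d <- dim(object@r2star)
  cat("RelaxationCurves: dR2*(t), dR2(t) on", paste(d[1:3], collapse = " x "),
      "voxels,", d[4L], "frames\n")
})

setMethod("show", "ParamMaps", function(object) {
  d <- dim(object@cbvNorm)
  cat("ParamMaps on a", paste(d, collapse = " x "), "grid\n")
  v <- object@validity@valid
  cat("  valid voxels:", sum(v), "/", length(v), "\n")
  if (any(v))
    cat("  vessel size (valid): median",
        round(stats::median(object@vesselSize[v], na.rm = TRUE), 2), "um\n")
})

setMethod("show", "PhantomOutput", function(object) {
  cat("PhantomOutput (seed", paste0(object@seed, "):"),
      nrow(object@classes), "tissue classes\n")
  print(object@classes[, c("label", "cbv", "ucbv", "vesselSize", "adc")],
        row.names = FALSE)
})

setMethod("show", "GroupComparison", function(object) {
  cat("GroupComparison:", object@parameter, "\n")
  cat("  groups:", paste(sprintf("%s (n=%d)", names(object@groups),
                                 lengths(object@groups)), collapse = ", "), "\n")
  cat("  omnibus:", if (object@test == "anova") "one-way ANOVA F =" else
    "Kruskal-Wallis H =", signif(object@statistic, 4),
    ", p =", signif(object@p, 3), "\n")
  if (nrow(object@posthoc)) {
    cat("  post hoc (", object@posthoc$method[1L], "):\n", sep = "")
    print(object@posthoc, row.names = FALSE)
  } else {
    cat("  no post hoc (omnibus p >", object@alpha, "or not requested)\n")
  }
})
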