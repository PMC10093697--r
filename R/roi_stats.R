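#' Summarize a parameter map over the tumor ROI
#'
#' Computes the mean and median of a map over valid tumor voxels, plus the
#' hot-spot value: the mean of all voxels at or above the 90th percentile
#' of the valid tumor distribution, pooled across all supra-threshold
#' clusters together. The percentile uses linear interpolation between
#' order statistics (R quantile type 7). The number of supra-threshold
#' clusters (26-connectivity connected components in 3D) is reported but
#' does not affect the hot-spot value.
#'
#' @param map 3D numeric array.
#' @param tumorMask 3D logical array.
#' @param validity optional [ValidityMask-class]; invalid voxels are
#'   excluded (as are `NA`s).
#' @param percentile hot-spot percentile (default 90).
#' @param minVoxels minimum number of valid tumor voxels (default 10).
#' @param parameter name recorded in the output.
#' @return One-row data.frame: parameter, mean, median, hotspot,
#'   nValidVoxels, nHotspotVoxels, nClusters.
#' @export
summarizeRoi <- function(map, tumorMask, validity = NULL, percentile = 90,
                         minVoxels = 10L, parameter = "parameter") {
  stopifnot(identical(dim(map), dim(tumorMask)))
  use <- tumorMask & is.finite(map)
  if (!is.null(validity)) use <- use & validity@valid
  vals <- map[use]
  if (length(vals) < minVoxels)
    stop("tumor ROI has only ", length(vals), " valid voxels; need >= ", minVoxels)
  thr <- stats::quantile(vals, probs = percentile / 100, type = 7, names = FALSE)
  hotMask <- use & map >= thr
  hotMask[is.na(hotMask)] <- FALSE
  hotVals <- map[hotMask]
  data.frame(
    parameter = parameter,
    mean = mean(vals),
    median = stats::median(vals),
    hotspot = mean(hotVals),
    nValidVoxels = length(vals),
    nHotspotVoxels = length(hotVals),
    nClusters = countClusters3d(hotMask)
  )
}

#' Count 26-connectivity connected components in a 3D mask
#'
#' Two voxels are connected when they differ by at most one step in each
#' of the three axes (faces, edges and corners all count).
#'
#' @param mask 3D logical array.
#' @return Integer number of components.
#' @export
countClusters3d <- function(mask) {
  max(labelClusters3d(mask))
}

#' Label 26-connectivity connected components in a 3D mask
#'
#' @param mask 3D logical array.
#' @return 3D integer array of component labels (0 = background).
#' @export
labelClusters3d <- function(mask) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  d <- dim(mask)
  lab <- array(0L, d)
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  # linear-index offsets of the 26 neighbours
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- off[!(off$dx == 0 & off$dy == 0 & off$dz == 0), ]
  coords <- arrayInd(idx, d)
  inMask <- array(FALSE, d); inMask[idx] <- TRUE
  cur <- 0L
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      vc <- arrayInd(v, d)
      nx <- vc[1L] + off$dx; ny <- vc[2L] + off$dy; nz <- vc[3L] + off$dz
      ok <- nx >= 1L & nx <= d[1L] & ny >= 1L & ny <= d[2L] & nz >= 1L & nz <= d[3L]
      if (!any(ok)) next
      lin <- (nz[ok] - 1L) * d[1L] * d[2L] + (ny[ok] - 1L) * d[1L] + nx[ok]
      new_ <- lin[inMask[lin] & lab[lin] == 0L]
      if (length(new_)) {
        lab[new_] <- cur
        queue <- c(queue, new_)
      }
    }
  }
  lab
}
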