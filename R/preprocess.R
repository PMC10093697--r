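#' Discard leading non-steady-state frames
#'
#' Removes the first `nDiscard` volumes of both echoes so the signal has
#' reached a steady state, shifting the injection index accordingly.
#'
#' @param series a [DualEchoSeries-class].
#' @param nDiscard number of leading frames to drop (default 4).
#' @return A [DualEchoSeries-class] with `nDiscard` fewer frames.
#' @export
trimInitial <- function(series, nDiscard = 4L) {
  nDiscard <- as.integer(nDiscard)
  stopifnot(nDiscard >= 0L)
  nt <- nFrames(series)
  if (nDiscard >= nt) stop("nDiscard (", nDiscard, ") must be below the frame count (", nt, ")")
  if (series@injectionIndex - nDiscard < 2L)
    stop("trimming ", nDiscard, " frames leaves no baseline before the bolus arrival")
  if (nDiscard == 0L) return(series)
  keep <- (nDiscard + 1L):nt
  DualEchoSeries(series@gre[, , , keep, drop = FALSE],
                 series@se[, , , keep, drop = FALSE],
                 tr = series@tr, teGre = series@teGre, teSe = series@teSe,
                 injectionIndex = series@injectionIndex - nDiscard)
}

#' Estimate per-voxel baseline signal
#'
#' Mean and sample standard deviation (n - 1 divisor) of each voxel's
#' signal over the pre-bolus frames `1:(injectionIndex - 1)`, per echo.
#'
#' @param series a [DualEchoSeries-class] (already trimmed).
#' @param minFrames minimum number of pre-bolus frames required.
#' @return A [BaselineEstimate-class].
#' @export
estimateBaseline <- function(series, minFrames = 5L) {
  nb <- series@injectionIndex - 1L
  if (nb < minFrames)
    stop("only ", nb, " pre-bolus frames; need at least ", minFrames)
  w <- seq_len(nb)
  d <- dim(series@gre)[1:3]
  stat2 <- function(x) {
    m <- rowMeans(x, dims = 3L)
    s <- sqrt(rowSums((x - as.vector(m))^2, dims = 3L) / (nb - 1L))
    list(mean = m, sd = s)
  }
  g <- stat2(series@gre[, , , w, drop = FALSE])
  s <- stat2(series@se[, , , w, drop = FALSE])
  new("BaselineEstimate", greMean = g$mean, greSd = g$sd,
      seMean = s$mean, seSd = s$sd, window = c(1L, nb))
}

#' Voxel quality filter: the 2-standard-deviation drop rule
#'
#' A voxel is kept only if the contrast passage produces a signal drop of
#' at least `sdThreshold` baseline standard deviations on BOTH echoes,
#' where the drop is the baseline mean minus the post-injection signal
#' minimum. Voxels whose signal is nonpositive anywhere in the post-
#' injection window (log-ratio undefined) or whose baseline mean is
#' nonpositive are also excluded. Excluded voxels carry reason codes.
#'
#' @param series a trimmed [DualEchoSeries-class].
#' @param baseline the matching [BaselineEstimate-class].
#' @param sdThreshold required drop in units of baseline SD (default 2).
#' @return A [ValidityMask-class].
#' @export
qcFilter <- function(series, baseline, sdThreshold = 2) {
  d <- dim(series@gre)
  if (!identical(dim(baseline@greMean), d[1:3]))
    stop("baseline grid does not match the series grid")
  post <- series@injectionIndex:d[4L]
  rowMin4 <- function(a) {
    m <- matrix(a, nrow = prod(d[1:3]), ncol = length(post))
    array(do.call(pmin, as.data.frame(m)), d[1:3])
  }
  minG <- rowMin4(series@gre[, , , post, drop = FALSE])
  minS <- rowMin4(series@se[, , , post, drop = FALSE])
  dropG <- baseline@greMean - minG
  dropS <- baseline@seMean - minS
  okG <- dropG >= sdThreshold * baseline@greSd
  okS <- dropS >= sdThreshold * baseline@seSd
  pos <- minG > 0 & minS > 0 & baseline@greMean > 0 & baseline@seMean > 0
  valid <- okG & okS & pos
  reason <- array("", dim = d[1:3])
  add <- function(reason, which, code) {
    reason[which] <- ifelse(reason[which] == "", code,
                            paste(reason[which], code, sep = ";"))
    reason
  }
  reason <- add(reason, !okG, "insufficient-drop-gre")
  reason <- add(reason, !okS, "insufficient-drop-se")
  reason <- add(reason, !pos, "nonpositive-signal")
  new("ValidityMask", valid = valid, reason = reason)
}
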