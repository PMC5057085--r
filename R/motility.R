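# Downstream behavioural quantification: centroid-speed profiles and
# active/inactive population subgrouping.

#' Interpolate short gaps in a trail's centroid series
#'
#' Places the trail on its uniform frame grid. Missing sections shorter than
#' `maxGapS` (time between the flanking observations, strict) are filled by
#' linear interpolation; longer sections are marked invalid and excluded
#' from analysis. Observed samples are never altered.
#'
#' @param trail a [Trail-class].
#' @param fps frames per second.
#' @param maxGapS gap duration cap in seconds (default 1).
#' @return data.frame with columns frame, time, x, y, valid.
#' @export
interpolateGaps <- function(trail, fps, maxGapS = 1) {
  bl <- blobs(trail)
  f0 <- bl$frame[1L]; f1 <- bl$frame[nrow(bl)]
  grid <- f0:f1
  out <- data.frame(frame = grid, time = grid / fps,
                    x = NA_real_, y = NA_real_, valid = FALSE)
  idx <- match(bl$frame, grid)
  out$x[idx] <- bl$x; out$y[idx] <- bl$y; out$valid[idx] <- TRUE
  miss <- which(!out$valid)
  if (length(miss)) {
    # contiguous missing runs; fill when flanking observation gap < maxGapS
    runs <- split(miss, cumsum(c(1L, diff(miss) != 1L)))
    for (r in runs) {
      lo <- r[1L] - 1L; hi <- r[length(r)] + 1L
      gapS <- (out$frame[hi] - out$frame[lo]) / fps
      if (gapS < maxGapS) {
        w <- (out$frame[r] - out$frame[lo]) / (out$frame[hi] - out$frame[lo])
        out$x[r] <- out$x[lo] + w * (out$x[hi] - out$x[lo])
        out$y[r] <- out$y[lo] + w * (out$y[hi] - out$y[lo])
        out$valid[r] <- TRUE
      }
    }
  }
  out
}

# Centered running mean over a window of `halfwidth` frames each side,
# ignoring invalid samples; a window containing invalid frames shrinks to
# its valid portion. Returns NA where no valid sample falls in the window.
.runmeanValid <- function(v, valid, halfwidth) {
  x <- ifelse(valid, v, 0)
  cnt <- as.numeric(valid)
  cx <- c(0, cumsum(x)); cc <- c(0, cumsum(cnt))
  n <- length(v)
  i <- seq_len(n)
  lo <- pmax(i - halfwidth, 1L); hi <- pmin(i + halfwidth, n)
  s <- cx[hi + 1L] - cx[lo]
  k <- cc[hi + 1L] - cc[lo]
  ifelse(k > 0, s / k, NA_real_)
}

#' Smooth a centroid series and derive its speed profile
#'
#' Positions are smoothed with a centered running average over `posWindowS`
#' (window shrinkage at the series ends); speed is the per-frame
#' displacement times fps; speeds are then smoothed with a centered running
#' average over `speedWindowS`. Invalid regions propagate: a speed sample
#' needs two consecutive valid positions, and smoothing windows use only
#' their valid portion.
#'
#' @param series data.frame from [interpolateGaps()] (columns frame, time,
#'   x, y, valid).
#' @param fps frames per second.
#' @param posWindowS position smoothing window, seconds (default 1).
#' @param speedWindowS speed smoothing window, seconds (default 60).
#' @param id profile identifier.
#' @return A [SpeedProfile-class].
#' @export
smoothAndSpeed <- function(series, fps, posWindowS = 1, speedWindowS = 60,
                           id = "trail") {
  n <- nrow(series)
  if (n < 2L)
    return(new("SpeedProfile", id = id, times = numeric(0),
               speeds = numeric(0), valid = logical(0),
               binned = numeric(0), fps = fps))
  hPos <- max(floor(posWindowS * fps / 2), 0L)
  sx <- .runmeanValid(series$x, series$valid, hPos)
  sy <- .runmeanValid(series$y, series$valid, hPos)
  sx[!series$valid] <- NA_real_; sy[!series$valid] <- NA_real_
  sp <- c(NA_real_, sqrt(diff(sx)^2 + diff(sy)^2) * fps)
  spValid <- !is.na(sp)
  hSp <- max(floor(speedWindowS * fps / 2), 0L)
  sm <- .runmeanValid(ifelse(spValid, sp, 0), spValid, hSp)
  sm[!spValid] <- NA_real_
  dur <- series$time[n] - series$time[1L]
  nbin <- max(ceiling(dur / 60), 1L)
  binIdx <- pmin(floor((series$time - series$time[1L]) / 60) + 1L, nbin)
  binned <- vapply(seq_len(nbin), function(b) {
    v <- sm[binIdx == b & spValid]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  new("SpeedProfile", id = id, times = series$time, speeds = sm,
      valid = spValid, binned = binned, fps = fps)
}

#' Trail to speed profile
#'
#' Convenience wrapper: gap interpolation followed by smoothing.
#'
#' @param trail a [Trail-class].
#' @param fps frames per second.
#' @param maxGapS gap cap for interpolation, seconds.
#' @param posWindowS,speedWindowS smoothing windows, seconds.
#' @return A [SpeedProfile-class].
#' @export
speedProfile <- function(trail, fps, maxGapS = 1, posWindowS = 1,
                         speedWindowS = 60) {
  smoothAndSpeed(interpolateGaps(trail, fps, maxGapS), fps, posWindowS,
                 speedWindowS, id = trailId(trail))
}

#' Pool speed profiles into a population profile
#'
#' Per-bin mean over all valid samples of all worms, sharing a common time
#' origin. Trails shorter than `minTrailS` are excluded (the conventional
#' sub-minute noise filter). Bins with no valid sample are reported as NA.
#'
#' @param profiles list of [SpeedProfile-class] objects.
#' @param binS bin width in seconds (default 60).
#' @param minTrailS minimum trail duration in seconds (default 60).
#' @return data.frame with columns timeBinMin, meanSpeedPxS, nWorms,
#'   nSamples.
#' @export
binSpeeds <- function(profiles, binS = 60, minTrailS = 60) {
  keep <- vapply(profiles, function(p) {
    length(p@times) >= 2L &&
      (p@times[length(p@times)] - p@times[1L]) >= minTrailS
  }, logical(1))
  profiles <- profiles[keep]
  if (!length(profiles))
    return(data.frame(timeBinMin = numeric(0), meanSpeedPxS = numeric(0),
                      nWorms = integer(0), nSamples = integer(0)))
  tmax <- max(vapply(profiles, function(p) max(p@times), numeric(1)))
  nbin <- ceiling((tmax + 1e-9) / binS)
  sums <- numeric(nbin); cnts <- integer(nbin); wrm <- matrix(
    FALSE, nbin, length(profiles))
  for (j in seq_along(profiles)) {
    p <- profiles[[j]]
    ok <- p@valid & !is.na(p@speeds)
    b <- pmin(floor(p@times[ok] / binS) + 1L, nbin)
    if (!length(b)) next
    agg <- tapply(p@speeds[ok], b, sum)
    ib <- as.integer(names(agg))
    sums[ib] <- sums[ib] + as.numeric(agg)
    cnt <- tapply(rep(1L, length(b)), b, sum)
    cnts[ib] <- cnts[ib] + as.integer(cnt)
    wrm[ib, j] <- TRUE
  }
  data.frame(timeBinMin = (seq_len(nbin) - 0.5) * binS / 60,
             meanSpeedPxS = ifelse(cnts > 0, sums / pmax(cnts, 1L), NA_real_),
             nWorms = rowSums(wrm), nSamples = cnts)
}

#' Classify a worm as active or inactive per observation window
#'
#' Active movement is time spent with smoothed speed above
#' `activeSpeedThreshold`; a worm is active in a window when it accumulates
#' strictly more than `activeMinThreshold` minutes of active movement there.
#' Default windows are the first 30 minutes, minutes 30-90 and minutes
#' 90-180. Partially covered windows are scored on observed time.
#'
#' @param profile a [SpeedProfile-class].
#' @param windows list of c(start, end) minute ranges.
#' @param activeMinThreshold active-minutes cutoff (default 5).
#' @param activeSpeedThreshold speed cutoff in px/s (default 1, i.e. 0.02
#'   body lengths per second at a 50 px body).
#' @return data.frame with columns windowStartMin, windowEndMin,
#'   activeMinutes, active.
#' @export
classifyActivity <- function(profile,
                             windows = list(c(0, 30), c(30, 90), c(90, 180)),
                             activeMinThreshold = 5,
                             activeSpeedThreshold = 1) {
  dt <- 1 / profile@fps
  tmin <- profile@times / 60
  act <- profile@valid & !is.na(profile@speeds) &
    profile@speeds > activeSpeedThreshold
  rows <- lapply(windows, function(w) {
    inw <- tmin >= w[1L] & tmin < w[2L]
    am <- sum(act & inw) * dt / 60
    data.frame(windowStartMin = w[1L], windowEndMin = w[2L],
               activeMinutes = am, active = am > activeMinThreshold)
  })
  do.call(rbind, rows)
}
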