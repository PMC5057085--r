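# Synthetic multi-worm recordings with ground-truth identities.
#
# Worms move by a persistent random walk reflected at the arena walls (the
# copper-frame boundary) and are rendered per frame as a capsule mask of one
# body length. An emulated segmenter then produces exactly the kind of
# fragmented output a real-time tracker would: a new node id after any
# discontinuity, parent/child links across splits, rejoins and collision
# merges, and no links across dropouts (the false negatives that gap
# inference must repair).

#' Build simulator parameters
#'
#' Presets fix the study condition; any field can be overridden.
#' \describe{
#'   \item{default}{10 worms, 120 s at 5 fps in a 1250 x 750 px arena
#'     (a 2.5 x 1.5 cm frame at 50 px/mm), all corruption processes on at
#'     rates giving a realistic disruption load.}
#'   \item{collisions}{two worms steered to cross near the arena centre,
#'     corruption off; used to generate collision cases in bulk.}
#'   \item{gaps}{dropouts only (no splits, no merging).}
#'   \item{splits}{split episodes only.}
#' }
#'
#' @param preset one of "default", "collisions", "gaps", "splits".
#' @param seed RNG seed.
#' @param ... overrides for any [SimParams-class] slot.
#' @return A [SimParams-class].
#' @export
simParams <- function(preset = c("default", "collisions", "gaps", "splits"),
                      seed = 0L, ...) {
  preset <- match.arg(preset)
  p <- list(nWorms = 10L, durationS = 120, fps = 5, arenaW = 1250L,
            arenaH = 750L, bodyLengthPx = 50, bodyWidthPx = 5,
            speedMeanPxS = 3, speedShape = 4, headingPersistence = 0.9,
            pSplit = 0.004, splitMeanS = 1.0, pDropout = 0.002,
            dropoutMeanS = 2.0, collisionHandling = TRUE,
            placement = "random")
  if (preset == "collisions") {
    p$nWorms <- 2L; p$durationS <- 40; p$arenaW <- 400L; p$arenaH <- 400L
    p$headingPersistence <- 0.995; p$speedShape <- 3
    p$pSplit <- 0; p$pDropout <- 0
  } else if (preset == "gaps") {
    p$pSplit <- 0; p$pDropout <- 0.01; p$collisionHandling <- FALSE
  } else if (preset == "splits") {
    p$pDropout <- 0; p$pSplit <- 0.01; p$collisionHandling <- FALSE
  }
  ov <- list(...)
  unknown <- setdiff(names(ov), names(p))
  if (length(unknown))
    stop("unknown SimParams field: ", paste(unknown, collapse = ", "))
  p[names(ov)] <- ov
  new("SimParams", nWorms = as.integer(p$nWorms), durationS = p$durationS,
      fps = p$fps, arenaW = as.integer(p$arenaW),
      arenaH = as.integer(p$arenaH), bodyLengthPx = p$bodyLengthPx,
      bodyWidthPx = p$bodyWidthPx, speedMeanPxS = p$speedMeanPxS,
      speedShape = p$speedShape, headingPersistence = p$headingPersistence,
      pSplit = p$pSplit, splitMeanS = p$splitMeanS, pDropout = p$pDropout,
      dropoutMeanS = p$dropoutMeanS,
      collisionHandling = isTRUE(p$collisionHandling),
      placement = match.arg(p$placement, c("random", "grid")),
      preset = preset, seed = as.integer(seed))
}

.sampleDurFrames <- function(meanS, fps) {
  max(1L, as.integer(round(stats::rexp(1, 1 / (meanS * fps)))))
}

#' Simulate a recording
#'
#' Runs the motion model and the segmenter emulator. Corruption is applied
#' in order: collision merging (masks touching within a 1-px dilation are
#' emitted as one blob carrying both identities), splitting (a worm emitted
#' as two separated fragments), dropouts (a worm unobserved, with no link
#' across the gap). Identical seed and parameters give identical output.
#'
#' @param params a [SimParams-class].
#' @return list with `nodes` (named list of [TrackNode-class]), `links`
#'   ([LinkTable-class]), `meta` ([RecordingMeta-class]), `truth`
#'   ([GroundTruth-class]) and `params`.
#' @export
simulateRecording <- function(params) {
  stopifnot(is(params, "SimParams"))
  validObject(params)
  set.seed(params@seed)
  n <- params@nWorms
  fps <- params@fps
  FR <- as.integer(round(params@durationS * fps))
  W <- params@arenaW; H <- params@arenaH
  len <- params@bodyLengthPx; wid <- params@bodyWidthPx
  margin <- len / 2 + 5
  sigma <- sqrt(-2 * log(params@headingPersistence))
  worms <- paste0("w", seq_len(n))
  speeds <- stats::rgamma(n, shape = params@speedShape,
                          rate = params@speedShape / params@speedMeanPxS)
  if (params@preset == "collisions" && n == 2L) {
    meet <- c(W / 2, H / 2) + stats::runif(2, -10, 10)
    tMeet <- params@durationS / 2
    phi1 <- stats::runif(1, 0, 2 * pi)
    phi2 <- phi1 + sample(c(-1, 1), 1) * stats::runif(1, 40, 140) * pi / 180
    b <- stats::runif(1, -8, 8)
    theta <- c(phi1, phi2)
    px <- c(meet[1] - cos(phi1) * speeds[1] * tMeet,
            meet[1] - cos(phi2) * speeds[2] * tMeet - sin(phi2) * b)
    py <- c(meet[2] - sin(phi1) * speeds[1] * tMeet,
            meet[2] - sin(phi2) * speeds[2] * tMeet + cos(phi2) * b)
    px <- pmin(pmax(px, margin), W - margin)
    py <- pmin(pmax(py, margin), H - margin)
  } else if (params@placement == "grid") {
    nx <- ceiling(sqrt(n * W / H))
    ny <- ceiling(n / nx)
    gx <- (seq_len(nx) - 0.5) * W / nx
    gy <- (seq_len(ny) - 0.5) * H / ny
    px <- rep(gx, times = ny)[seq_len(n)]
    py <- rep(gy, each = nx)[seq_len(n)]
    theta <- stats::runif(n, 0, 2 * pi)
  } else {
    px <- stats::runif(n, margin, W - margin)
    py <- stats::runif(n, margin, H - margin)
    theta <- stats::runif(n, 0, 2 * pi)
  }

  # segmenter-emulator state
  counter <- 0L
  newId <- function() { counter <<- counter + 1L; as.character(counter) }
  prevSig <- character(0)            # signature -> nodeId at previous frame
  prevNodesOfWorm <- stats::setNames(vector("list", n), worms)
  prevWhole <- stats::setNames(rep(FALSE, n), worms)
  dropped <- stats::setNames(rep(FALSE, n), worms)
  episode <- stats::setNames(rep("none", n), worms)
  episodeEnd <- stats::setNames(rep(-1L, n), worms)
  dropPre <- stats::setNames(rep(NA_character_, n), worms)
  dropPreEnd <- stats::setNames(rep(NA_integer_, n), worms)
  dropPreX <- stats::setNames(rep(NA_real_, n), worms)
  dropPreY <- stats::setNames(rep(NA_real_, n), worms)
  prevBlobXY <- stats::setNames(vector("list", n), worms)

  cap <- FR * (2L * n + 4L)
  bNode <- character(cap); bFrame <- integer(cap); bTime <- numeric(cap)
  bX <- numeric(cap); bY <- numeric(cap); bMask <- vector("list", cap)
  nb <- 0L
  linkP <- character(0); linkC <- character(0)
  asgN <- list(); asgF <- list(); asgW <- list(); na <- 0L
  drops <- list()
  trajX <- matrix(NA_real_, FR, n); trajY <- matrix(NA_real_, FR, n)

  for (f in seq_len(FR) - 1L) {
    if (f > 0L) {
      theta <- theta + stats::rnorm(n, 0, sigma)
      px <- px + cos(theta) * speeds / fps
      py <- py + sin(theta) * speeds / fps
      fx <- px < margin | px > W - margin
      theta[fx] <- pi - theta[fx]
      px <- pmin(pmax(px, margin), W - margin)
      fy <- py < margin | py > H - margin
      theta[fy] <- -theta[fy]
      py <- pmin(pmax(py, margin), H - margin)
    }
    trajX[f + 1L, ] <- px; trajY[f + 1L, ] <- py
    tNow <- f / fps

    capsules <- lapply(seq_len(n), function(i)
      renderCapsule(px[i], py[i], theta[i], len, wid, W, H))

    # contact groups (collision merging)
    groupOf <- seq_len(n)
    if (params@collisionHandling && n > 1L) {
      reach <- len + wid + 3
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        if (abs(px[i] - px[j]) > reach || abs(py[i] - py[j]) > reach) next
        if (maskTouch(capsules[[i]], capsules[[j]])) {
          gi <- groupOf[i]; gj <- groupOf[j]
          if (gi != gj) groupOf[groupOf == gj] <- gi
        }
      }
    }
    merged <- groupOf %in% groupOf[duplicated(groupOf)]

    # episode management (frame 0 establishes initial nodes first)
    for (i in seq_len(n)) {
      w <- worms[i]
      if (merged[i]) { episode[w] <- "none"; episodeEnd[w] <- -1L; next }
      if (episode[w] != "none" && f > episodeEnd[w]) {
        episode[w] <- "none"
      }
      if (episode[w] == "none" && f > 0L) {
        u <- stats::runif(1)
        if (u < params@pDropout && prevWhole[w]) {
          episode[w] <- "dropout"
          episodeEnd[w] <- f + .sampleDurFrames(params@dropoutMeanS, fps) - 1L
          dropPre[w] <- prevNodesOfWorm[[w]][1L]
          dropPreEnd[w] <- f - 1L
          dropPreX[w] <- prevBlobXY[[w]][1L]
          dropPreY[w] <- prevBlobXY[[w]][2L]
        } else if (u < params@pDropout + params@pSplit && prevWhole[w]) {
          iso <- all(abs(px[-i] - px[i]) > 2 * len |
                     abs(py[-i] - py[i]) > 2 * len)
          if (iso) {
            episode[w] <- "split"
            episodeEnd[w] <- f + .sampleDurFrames(params@splitMeanS, fps) - 1L
          }
        }
      }
    }

    # emission units for this frame
    units <- list()
    doneGroup <- integer(0)
    for (i in seq_len(n)) {
      w <- worms[i]
      if (merged[i]) {
        g <- groupOf[i]
        if (g %in% doneGroup) next
        doneGroup <- c(doneGroup, g)
        members <- which(groupOf == g)
        units[[length(units) + 1L]] <- list(
          sig = paste0("M:", paste(sort(worms[members]), collapse = "+")),
          mask = maskUnion(capsules[members]), worms = worms[members])
        next
      }
      if (episode[w] == "dropout") next
      if (episode[w] == "split") {
        off <- len / 4 + 2
        flen <- len / 2 - 4
        for (half in c(-1, 1)) {
          m <- renderCapsule(px[i] + half * off * cos(theta[i]),
                             py[i] + half * off * sin(theta[i]),
                             theta[i], flen, wid, W, H)
          units[[length(units) + 1L]] <- list(
            sig = paste0(w, ":F", if (half < 0) "1" else "2"),
            mask = m, worms = w)
        }
      } else {
        units[[length(units) + 1L]] <- list(sig = paste0(w, ":W"),
                                            mask = capsules[[i]], worms = w)
      }
    }

    # node continuity, links, dropout bookkeeping
    curSig <- character(0)
    curNodesOfWorm <- stats::setNames(vector("list", n), worms)
    curWhole <- stats::setNames(rep(FALSE, n), worms)
    curBlobXY <- stats::setNames(vector("list", n), worms)
    for (u in units) {
      if (nrow(u$mask) == 0L) next   # fully clipped (cannot happen mid-arena)
      cen <- maskCentroid(u$mask)
      if (!is.na(id <- unname(prevSig[u$sig]))) {
        # continue the existing node
      } else {
        id <- newId()
        for (w in u$worms) {
          if (dropped[w]) {
            dd <- sqrt((cen[["x"]] - dropPreX[w])^2 +
                       (cen[["y"]] - dropPreY[w])^2)
            drops[[length(drops) + 1L]] <- list(
              wormId = w, preNode = dropPre[w], postNode = id,
              dtFrames = f - dropPreEnd[w], ddPx = dd)
          } else {
            for (pn in prevNodesOfWorm[[w]]) {
              linkP <- c(linkP, pn); linkC <- c(linkC, id)
            }
          }
        }
      }
      nb <- nb + 1L
      bNode[nb] <- id; bFrame[nb] <- f; bTime[nb] <- tNow
      bX[nb] <- cen[["x"]]; bY[nb] <- cen[["y"]]; bMask[[nb]] <- u$mask
      for (w in u$worms) {
        na <- na + 1L
        asgN[[na]] <- id; asgF[[na]] <- f; asgW[[na]] <- w
        curNodesOfWorm[[w]] <- c(curNodesOfWorm[[w]], id)
        curBlobXY[[w]] <- c(cen[["x"]], cen[["y"]])
        if (identical(u$sig, paste0(w, ":W"))) curWhole[w] <- TRUE
      }
      curSig[u$sig] <- id
    }
    prevSig <- curSig
    prevNodesOfWorm <- curNodesOfWorm
    prevWhole <- curWhole
    prevBlobXY <- curBlobXY
    dropped <- stats::setNames(episode == "dropout", worms)
  }

  # assemble TrackNodes (frames are emitted in order within each node)
  sel <- seq_len(nb)
  bNode <- bNode[sel]; bFrame <- bFrame[sel]; bTime <- bTime[sel]
  bX <- bX[sel]; bY <- bY[sel]; bMask <- bMask[sel]
  nodes <- list()
  for (id in unique(bNode)) {
    sel <- which(bNode == id)
    masks <- bMask[sel]
    nodes[[id]] <- new(
      "TrackNode", nodeId = id, frames = bFrame[sel], times = bTime[sel],
      x = bX[sel], y = bY[sel], masks = masks,
      areas = as.numeric(vapply(masks, nrow, integer(1))))
  }
  links <- linkTable(linkP, linkC)
  meta <- recordingMeta(fps = fps, imageWidth = W, imageHeight = H,
                        bodyLengthPx = len, duration = params@durationS)
  assignment <- data.frame(nodeId = unlist(asgN), frame = unlist(asgF),
                           wormId = unlist(asgW), stringsAsFactors = FALSE)
  if (!nrow(assignment))
    assignment <- data.frame(nodeId = character(0), frame = integer(0),
                             wormId = character(0))
  traj <- lapply(seq_len(n), function(i)
    data.frame(frame = seq_len(FR) - 1L, time = (seq_len(FR) - 1L) / fps,
               x = trajX[, i], y = trajY[, i]))
  names(traj) <- worms
  dropDf <- if (length(drops)) {
    data.frame(wormId = vapply(drops, `[[`, character(1), "wormId"),
               preNode = vapply(drops, `[[`, character(1), "preNode"),
               postNode = vapply(drops, `[[`, character(1), "postNode"),
               dtFrames = vapply(drops, `[[`, numeric(1), "dtFrames"),
               ddPx = vapply(drops, `[[`, numeric(1), "ddPx"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(wormId = character(0), preNode = character(0),
               postNode = character(0), dtFrames = numeric(0),
               ddPx = numeric(0))
  }
  truth <- new("GroundTruth", assignment = assignment, trajectories = traj,
               dropouts = dropDf)
  list(nodes = nodes, links = links, meta = meta, truth = truth,
       params = params)
}
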