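# Accessor generics and methods; slot access stays internal to the package.

#' @rdname TrackNode-class
#' @param object,x a package object.
#' @export
setGeneric("nodeId", function(x) standardGeneric("nodeId"))
#' @rdname TrackNode-class
#' @export
setGeneric("nBlobs", function(x) standardGeneric("nBlobs"))
#' @rdname TrackNode-class
#' @export
setGeneric("startFrame", function(x) standardGeneric("startFrame"))
#' @rdname TrackNode-class
#' @export
setGeneric("endFrame", function(x) standardGeneric("endFrame"))
#' @rdname TrackNode-class
#' @export
setGeneric("startTime", function(x) standardGeneric("startTime"))
#' @rdname TrackNode-class
#' @export
setGeneric("endTime", function(x) standardGeneric("endTime"))
#' @rdname TrackNode-class
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))
#' @rdname TrackNode-class
#' @export
setGeneric("firstCentroid", function(x) standardGeneric("firstCentroid"))
#' @rdname TrackNode-class
#' @export
setGeneric("lastCentroid", function(x) standardGeneric("lastCentroid"))
#' @rdname TrackNode-class
#' @export
setGeneric("firstMask", function(x) standardGeneric("firstMask"))
#' @rdname TrackNode-class
#' @export
setGeneric("lastMask", function(x) standardGeneric("lastMask"))
#' @rdname TrackNode-class
#' @export
setGeneric("pathLength", function(x) standardGeneric("pathLength"))
#' @rdname TrackNode-class
#' @export
setGeneric("blobs", function(x) standardGeneric("blobs"))

setMethod("nodeId", "TrackNode", function(x) x@nodeId)
setMethod("nBlobs", "TrackNode", function(x) length(x@frames))
setMethod("startFrame", "TrackNode", function(x) x@frames[1L])
setMethod("endFrame", "TrackNode", function(x) x@frames[length(x@frames)])
setMethod("startTime", "TrackNode", function(x) x@times[1L])
setMethod("endTime", "TrackNode", function(x) x@times[length(x@times)])
setMethod("duration", "TrackNode",
          function(x) endTime(x) - startTime(x))
setMethod("firstCentroid", "TrackNode", function(x) c(x = x@x[1L], y = x@y[1L]))
setMethod("lastCentroid", "TrackNode",
          function(x) { n <- length(x@x); c(x = x@x[n], y = x@y[n]) })
setMethod("firstMask", "TrackNode", function(x) x@masks[[1L]])
setMethod("lastMask", "TrackNode", function(x) x@masks[[length(x@masks)]])

# Summed per-frame centroid displacement: travelled path, not net displacement.
setMethod("pathLength", "TrackNode", function(x) {
  if (length(x@x) < 2L) return(0)
  sum(sqrt(diff(x@x)^2 + diff(x@y)^2))
})

setMethod("blobs", "TrackNode", function(x)
  data.frame(frame = x@frames, time = x@times, x = x@x, y = x@y,
             area = x@areas, nodeId = x@nodeId))

setMethod("show", "TrackNode", function(object) {
  cat(sprintf("TrackNode %s: %d blobs, frames %d..%d (%.2f..%.2f s)\n",
              object@nodeId, nBlobs(object), startFrame(object),
              endFrame(object), startTime(object), endTime(object)))
})

#' @rdname TrackGraph-class
#' @param x,object a [TrackGraph-class].
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))
#' @rdname TrackGraph-class
#' @export
setGeneric("graphArcs", function(x) standardGeneric("graphArcs"))
#' @rdname TrackGraph-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname TrackGraph-class
#' @export
setGeneric("prunedNodes", function(x) standardGeneric("prunedNodes"))
#' @rdname TrackGraph-class
#' @export
setGeneric("inferredArcs", function(x) standardGeneric("inferredArcs"))

setMethod("graphNodes", "TrackGraph", function(x) x@nodes)
setMethod("graphArcs", "TrackGraph", function(x) x@arcs)
setMethod("provenance", "TrackGraph", function(x) x@provenance)
setMethod("prunedNodes", "TrackGraph", function(x) x@pruned)
setMethod("inferredArcs", "TrackGraph",
          function(x) x@arcs[x@inferred, , drop = FALSE])

setMethod("show", "TrackGraph", function(object) {
  cat(sprintf(
    "TrackGraph: %d nodes, %d arcs (%d inferred), %d pruned\n",
    length(object@nodes), nrow(object@arcs), sum(object@inferred),
    length(object@pruned)))
})

#' @rdname Trail-class
#' @param x,object a [Trail-class].
#' @export
setGeneric("trailId", function(x) standardGeneric("trailId"))
#' @rdname Trail-class
#' @export
setGeneric("trailNodeIds", function(x) standardGeneric("trailNodeIds"))
#' @rdname Trail-class
#' @export
setGeneric("coverage", function(x) standardGeneric("coverage"))

setMethod("trailId", "Trail", function(x) x@trailId)
setMethod("trailNodeIds", "Trail", function(x) x@nodeIds)
setMethod("coverage", "Trail", function(x) x@coverage)
setMethod("blobs", "Trail", function(x) x@blobs)
setMethod("provenance", "Trail", function(x) x@provenance)
setMethod("startTime", "Trail", function(x) x@blobs$time[1L])
setMethod("endTime", "Trail",
          function(x) x@blobs$time[nrow(x@blobs)])
setMethod("duration", "Trail", function(x) endTime(x) - startTime(x))

setMethod("show", "Trail", function(object) {
  cat(sprintf("Trail %s: %d nodes, %d blobs, coverage %.3f\n",
              object@trailId, length(object@nodeIds), nrow(object@blobs),
              object@coverage))
})

setMethod("show", "SimParams", function(object) {
  cat(sprintf(
    "SimParams [%s]: %d worms, %.0f s @ %g fps, arena %dx%d px, seed %d\n",
    object@preset, object@nWorms, object@durationS, object@fps,
    object@arenaW, object@arenaH, object@seed))
  cat(sprintf("  speed %.2g px/s, pSplit %.3g, pDropout %.3g, collisions %s\n",
              object@speedMeanPxS, object@pSplit, object@pDropout,
              if (object@collisionHandling) "on" else "off"))
})

setMethod("show", "CollisionOutcome", function(object) {
  cat(sprintf("CollisionOutcome: %s (scores %.0f vs %.0f)%s\n",
              object@decision, object@score1, object@score2,
              if (nzchar(object@reason)) paste0(" [", object@reason, "]")
              else ""))
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport\n")
  cat(sprintf("  trails scored:                %d\n", object@nTrails))
  cat(sprintf("  id-switch fraction:           %.4f\n",
              object@idSwitchFraction))
  cat(sprintf("  undetected-collision fraction: %.4f\n",
              object@undetectedCollisionFraction))
  cat(sprintf("  collision-trail fraction:     %.4f\n",
              object@collisionTrailFraction))
  cat(sprintf("  collision resolution accuracy: %s\n",
              ifelse(is.na(object@collisionResolutionAccuracy), "NA",
                     sprintf("%.4f", object@collisionResolutionAccuracy))))
  cat(sprintf("  gap recall:                   %s\n",
              ifelse(is.na(object@gapRecall), "NA",
                     sprintf("%.4f", object@gapRecall))))
})
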