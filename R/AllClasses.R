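#' @import methods
NULL

emptyArcs <- function() {
  matrix(character(0), ncol = 2L, dimnames = list(NULL, c("parent", "child")))
}

#' RecordingMeta: acquisition metadata for one recording
#'
#' Frame rate, image geometry, the expected adult body length in pixels (the
#' spatial scale used by the gap and collision heuristics) and the recording
#' duration in seconds. Coordinates are 0-based, x rightward, y downward;
#' frames are 0-based.
#'
#' @slot fps frames per second (> 0).
#' @slot imageWidth,imageHeight image size in pixels.
#' @slot bodyLengthPx expected adult body length in pixels (default 50).
#' @slot duration recording duration in seconds.
#' @exportClass RecordingMeta
setClass("RecordingMeta",
  representation(fps = "numeric", imageWidth = "integer",
                 imageHeight = "integer", bodyLengthPx = "numeric",
                 duration = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@fps) != 1L || !is.finite(object@fps) || object@fps <= 0)
      msg <- c(msg, "fps must be a single positive number")
    if (object@bodyLengthPx <= 0)
      msg <- c(msg, "bodyLengthPx must be positive")
    if (object@imageWidth <= 0L || object@imageHeight <= 0L)
      msg <- c(msg, "image dimensions must be positive")
    if (object@duration < 0)
      msg <- c(msg, "duration must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' Construct recording metadata
#'
#' @param fps frames per second; the default of 5 is the conventional
#'   multi-worm acquisition rate at which 50 frames correspond to 10 seconds.
#' @param imageWidth,imageHeight image size in pixels.
#' @param bodyLengthPx expected adult body length in pixels.
#' @param duration recording duration in seconds.
#' @return A [RecordingMeta-class] object.
#' @export
recordingMeta <- function(fps = 5, imageWidth = 1250L, imageHeight = 750L,
                          bodyLengthPx = 50, duration = 0) {
  new("RecordingMeta", fps = as.numeric(fps),
      imageWidth = as.integer(imageWidth),
      imageHeight = as.integer(imageHeight),
      bodyLengthPx = as.numeric(bodyLengthPx),
      duration = as.numeric(duration))
}

#' TrackNode: one tracker-assigned run of blob observations
#'
#' A time-ordered sequence of blob observations sharing one tracker id: the
#' atomic unit ("track") that the network stitches into trails. Blobs are
#' stored as parallel vectors plus an optional pixel mask per blob (a 2-column
#' integer matrix of (x, y) pixel coordinates).
#'
#' @slot nodeId opaque identifier.
#' @slot frames integer frame indices, strictly increasing.
#' @slot times seconds since recording start, strictly increasing.
#' @slot x,y centroid coordinates in pixels.
#' @slot masks list of 2-column integer matrices (or NULL where only the
#'   centroid is known).
#' @slot areas pixel count per blob; equals nrow(mask) whenever the mask is
#'   present.
#' @exportClass TrackNode
setClass("TrackNode",
  representation(nodeId = "character", frames = "integer", times = "numeric",
                 x = "numeric", y = "numeric", masks = "list",
                 areas = "numeric"),
  validity = function(object) {
    n <- length(object@frames)
    msg <- character(0)
    if (n == 0L) msg <- c(msg, "a track must contain at least one blob")
    if (length(object@times) != n || length(object@x) != n ||
        length(object@y) != n || length(object@masks) != n ||
        length(object@areas) != n)
      msg <- c(msg, "blob fields must have equal length")
    if (n > 1L) {
      if (any(diff(object@frames) <= 0L))
        msg <- c(msg, "frames must be strictly increasing")
      if (any(diff(object@times) <= 0))
        msg <- c(msg, "time must strictly increase with frame")
    }
    has <- !vapply(object@masks, is.null, logical(1))
    if (any(has)) {
      sz <- vapply(object@masks[has], nrow, integer(1))
      if (any(abs(object@areas[has] - sz) > 0))
        msg <- c(msg, "area must equal the mask pixel count when the mask is present")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a track node
#'
#' Blobs may be given in any order; they are sorted by frame. Duplicate frames
#' within one node are an integrity error.
#'
#' @param nodeId identifier (coerced to character).
#' @param frames integer frame indices.
#' @param times seconds; defaults to `frames / fps` when `fps` is given.
#' @param x,y centroid coordinates in pixels.
#' @param masks optional list of 2-column integer matrices, one per blob.
#' @param areas optional pixel counts; derived from masks when present.
#' @param fps used only to derive `times` when omitted.
#' @return A [TrackNode-class] object.
#' @export
trackNode <- function(nodeId, frames, x, y, times = NULL, masks = NULL,
                      areas = NULL, fps = 5) {
  frames <- as.integer(frames)
  if (anyDuplicated(frames))
    stop("integrity error: duplicate frame within node ", nodeId)
  if (is.null(times)) times <- frames / fps
  if (is.null(masks)) masks <- vector("list", length(frames))
  if (is.null(areas))
    areas <- vapply(masks, function(m) if (is.null(m)) NA_real_ else nrow(m),
                    numeric(1))
  o <- order(frames)
  new("TrackNode", nodeId = as.character(nodeId), frames = frames[o],
      times = as.numeric(times)[o], x = as.numeric(x)[o],
      y = as.numeric(y)[o], masks = masks[o], areas = as.numeric(areas)[o])
}

#' LinkTable: succession evidence reported by the upstream tracker
#'
#' Ordered (parent, child) node-id pairs emitted when a blob splits, merges,
#' or is re-identified. Carrier for the evidence from which network arcs are
#' built.
#'
#' @slot links 2-column character matrix with columns parent, child.
#' @exportClass LinkTable
setClass("LinkTable",
  representation(links = "matrix"),
  validity = function(object) {
    L <- object@links
    if (!is.character(L) || ncol(L) != 2L)
      return("links must be a 2-column character matrix")
    if (nrow(L) && any(L[, 1L] == L[, 2L])) return("self-links are not allowed")
    TRUE
  })

#' Construct a link table
#' @param parent,child character vectors of equal length (may be empty).
#' @return A [LinkTable-class] object.
#' @export
linkTable <- function(parent = character(0), child = character(0)) {
  L <- cbind(parent = as.character(parent), child = as.character(child))
  if (nrow(L)) L <- unique(L)
  colnames(L) <- c("parent", "child")
  new("LinkTable", links = L)
}

#' TrackGraph: the directed acyclic track network
#'
#' Nodes are tracks; an arc (u, v) states that v could follow u in time and
#' space, i.e. that the two tracks could belong to the same animal. The graph
#' is acyclic at all times. Provenance maps every current node to the set of
#' original node ids merged into it; nodes removed by pruning are retained in
#' a side table so no observation is ever discarded.
#'
#' @slot nodes named list of [TrackNode-class] objects.
#' @slot arcs 2-column character matrix (parent, child).
#' @slot inferred logical, one flag per arc: TRUE for arcs added by gap
#'   inference rather than reported by the tracker.
#' @slot provenance named list: current node id -> character vector of
#'   original node ids.
#' @slot pruned named list of removed [TrackNode-class] objects.
#' @slot prunedProvenance named list mirroring `provenance` for pruned nodes.
#' @exportClass TrackGraph
setClass("TrackGraph",
  representation(nodes = "list", arcs = "matrix", inferred = "logical",
                 provenance = "list", pruned = "list",
                 prunedProvenance = "list"),
  validity = function(object) {
    msg <- character(0)
    ids <- names(object@nodes)
    if (length(object@nodes) && is.null(ids))
      return("nodes must be a named list")
    A <- object@arcs
    if (ncol(A) != 2L) msg <- c(msg, "arcs must have two columns")
    if (nrow(A)) {
      if (any(A[, 1L] == A[, 2L])) msg <- c(msg, "self-arcs are not allowed")
      if (!all(c(A) %in% ids))
        msg <- c(msg, "arc endpoints must be known nodes")
    }
    if (length(object@inferred) != nrow(A))
      msg <- c(msg, "one inferred flag per arc required")
    if (!setequal(names(object@provenance), ids))
      msg <- c(msg, "provenance must cover exactly the current nodes")
    if (length(msg)) msg else TRUE
  })

#' Trail: a stitched per-animal trajectory
#'
#' The end product of network simplification: an ordered chain of nodes
#' believed to belong to one animal, with its concatenated blob observations
#' and the fraction of the recording it covers.
#'
#' @slot trailId identifier.
#' @slot nodeIds ordered ids of the graph nodes forming the chain.
#' @slot provenance original node ids contributing to the trail.
#' @slot blobs data.frame with columns frame, time, x, y, nodeId, strictly
#'   increasing in time.
#' @slot coverage fraction of recording frames with an observation, in
#'   \[0, 1\].
#' @exportClass Trail
setClass("Trail",
  representation(trailId = "character", nodeIds = "character",
                 provenance = "character", blobs = "data.frame",
                 coverage = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (object@coverage < 0 || object@coverage > 1)
      msg <- c(msg, "coverage must lie in [0, 1]")
    tt <- object@blobs$time
    if (length(tt) > 1L && any(diff(tt) <= 0))
      msg <- c(msg, "blob times must be strictly increasing")
    if (length(msg)) msg else TRUE
  })

#' SimParams: synthetic recording parameters
#'
#' Controls the simulator: population size, arena, a persistent-random-walk
#' speed model, and the corruption processes that emulate the segmenter's
#' failure modes (split-worm fragments, frame dropouts, two-worm collision
#' merges). See the methods vignette for the rationale behind each default.
#'
#' @slot nWorms number of animals.
#' @slot durationS recording length in seconds.
#' @slot fps frames per second.
#' @slot arenaW,arenaH arena size in pixels (the copper-frame field of view).
#' @slot bodyLengthPx rendered worm length in pixels.
#' @slot bodyWidthPx rendered worm width in pixels.
#' @slot speedMeanPxS mean crawling speed, px/s.
#' @slot speedShape gamma shape for across-worm speed variation.
#' @slot headingPersistence per-frame directional correlation in (0, 1).
#' @slot pSplit per-frame probability a free worm starts a split episode.
#' @slot splitMeanS mean split episode duration, seconds (exponential).
#' @slot pDropout per-frame probability a free worm starts a dropout.
#' @slot dropoutMeanS mean dropout duration, seconds (exponential).
#' @slot collisionHandling merge touching worms into one blob when TRUE.
#' @slot placement "random" initial positions, or "grid" for evenly spaced
#'   non-interacting starts.
#' @slot preset name of the preset used to build the object.
#' @slot seed RNG seed; identical seed and parameters give identical output.
#' @exportClass SimParams
setClass("SimParams",
  representation(nWorms = "integer", durationS = "numeric", fps = "numeric",
                 arenaW = "integer", arenaH = "integer",
                 bodyLengthPx = "numeric", bodyWidthPx = "numeric",
                 speedMeanPxS = "numeric", speedShape = "numeric",
                 headingPersistence = "numeric", pSplit = "numeric",
                 splitMeanS = "numeric", pDropout = "numeric",
                 dropoutMeanS = "numeric", collisionHandling = "logical",
                 placement = "character", preset = "character",
                 seed = "integer"),
  validity = function(object) {
    msg <- character(0)
    p <- c(object@pSplit, object@pDropout)
    if (any(p < 0 | p > 1)) msg <- c(msg, "probabilities must lie in [0, 1]")
    if (object@splitMeanS <= 0 || object@dropoutMeanS <= 0 ||
        object@durationS <= 0)
      msg <- c(msg, "durations must be positive")
    if (object@headingPersistence <= 0 || object@headingPersistence >= 1)
      msg <- c(msg, "headingPersistence must lie in (0, 1)")
    if (object@nWorms < 1L) msg <- c(msg, "need at least one worm")
    need <- 2.5 * object@bodyLengthPx * sqrt(object@nWorms)
    if (object@arenaW < need && object@arenaH < need)
      msg <- c(msg, "arena too small for the requested number of worms")
    if (length(msg)) msg else TRUE
  })

#' GroundTruth: simulator-only identity oracle
#'
#' Maps every emitted blob observation to the true animal id(s) that produced
#' it (a merged collision blob maps to all participating worms), carries the
#' true per-worm trajectories, and records every dropout event with its
#' flanking nodes so gap-inference recall can be scored.
#'
#' @slot assignment data.frame(nodeId, frame, wormId); one row per
#'   (observation, worm) pair.
#' @slot trajectories named list: worm id -> data.frame(frame, time, x, y).
#' @slot dropouts data.frame(wormId, preNode, postNode, dtFrames, ddPx).
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(assignment = "data.frame", trajectories = "list",
                 dropouts = "data.frame"))

#' CollisionCase: a two-worm collision motif ready for resolution
#'
#' The 5-node subgraph created when two animals touch and are segmented as a
#' single blob: two pre-collision parents (a, b), the merged collision node c,
#' and two post-collision children (d, e), together with the four pixel-overlap
#' counts between the parents' last masks and the children's first masks.
#'
#' @slot node id of the collision node c.
#' @slot pre ids of the two parents (a, b), temporal order.
#' @slot post ids of the two children (d, e), temporal order.
#' @slot overlaps named numeric of length 4: ad, ae, bd, be (NA when a
#'   boundary mask is missing).
#' @exportClass CollisionCase
setClass("CollisionCase",
  representation(node = "character", pre = "character", post = "character",
                 overlaps = "numeric"),
  validity = function(object) {
    if (length(object@pre) != 2L || length(object@post) != 2L)
      return("exactly two parents and two children required")
    if (!identical(names(object@overlaps), c("ad", "ae", "bd", "be")))
      return("overlaps must be named ad, ae, bd, be")
    if (any(object@overlaps < 0, na.rm = TRUE))
      return("overlap counts must be non-negative")
    TRUE
  })

#' CollisionOutcome: the result of pixel-overlap voting
#'
#' `decision` is "straight" (a continues as d, b as e), "crossed" (a as e, b
#' as d), or "unresolved". A decision is made only when the winning pairing's
#' summed overlap beats the alternative by at least the overlap threshold.
#'
#' @slot decision one of "straight", "crossed", "unresolved".
#' @slot score1 O(a,d) + O(b,e).
#' @slot score2 O(a,e) + O(b,d).
#' @slot reason reason code when unresolved ("ambiguous", "missing-mask",
#'   "cycle-risk", or "" when resolved).
#' @exportClass CollisionOutcome
setClass("CollisionOutcome",
  representation(decision = "character", score1 = "numeric",
                 score2 = "numeric", reason = "character"))

#' EvalReport: scoring of stitched trails against simulator ground truth
#'
#' @slot idSwitchFraction fraction of trails containing blobs from two or
#'   more worms outside collision intervals.
#' @slot undetectedCollisionFraction fraction of trails containing merged
#'   multi-worm observations that no collision case ever covered.
#' @slot collisionTrailFraction fraction of trails that are mostly merged
#'   multi-worm observations.
#' @slot collisionResolutionAccuracy correct / decided collision decisions
#'   (NA when nothing was decided).
#' @slot gapRecall fraction of in-cap dropout gaps bridged into one trail
#'   (NA when no eligible dropout exists).
#' @slot coverage data.frame of coverage summary (see [coverageStats()]).
#' @slot nTrails number of trails scored.
#' @exportClass EvalReport
setClass("EvalReport",
  representation(idSwitchFraction = "numeric",
                 undetectedCollisionFraction = "numeric",
                 collisionTrailFraction = "numeric",
                 collisionResolutionAccuracy = "numeric",
                 gapRecall = "numeric", coverage = "data.frame",
                 nTrails = "integer"))

#' SpeedProfile: smoothed centroid-speed series for one trail
#'
#' @slot id trail/worm identifier.
#' @slot times seconds on the uniform frame grid.
#' @slot speeds smoothed speeds, px/s (NA where invalid).
#' @slot valid logical mask; FALSE inside excluded gap regions.
#' @slot binned per-minute mean speeds (length ceil(duration / 60)).
#' @slot fps frame rate of the grid.
#' @exportClass SpeedProfile
setClass("SpeedProfile",
  representation(id = "character", times = "numeric", speeds = "numeric",
                 valid = "logical", binned = "numeric", fps = "numeric"),
  validity = function(object) {
    if (any(object@speeds[object@valid] < 0, na.rm = TRUE))
      return("speeds must be non-negative")
    TRUE
  })
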