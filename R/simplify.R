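# The correction pipeline: prune, consolidate, infer missing arcs, and the
# fixed phase ordering that drives the graph to a simplified form.

#' Prune transient orphan fragments
#'
#' Removes every parentless or childless node tracked for less than
#' `maxDurationS` (strict), iterating until no removable node remains (a
#' removal can orphan a neighbour). Removed nodes are retained in the
#' graph's pruned side table, never deleted.
#'
#' @param graph a [TrackGraph-class].
#' @param maxDurationS duration cap in seconds (default 1).
#' @return The updated [TrackGraph-class].
#' @export
pruneGraph <- function(graph, maxDurationS = 1) {
  stopifnot(maxDurationS > 0)
  repeat {
    indeg <- inDegree(graph)
    outdeg <- outDegree(graph)
    dur <- vapply(graph@nodes, duration, numeric(1))
    rm <- names(which((indeg == 0L | outdeg == 0L) & dur < maxDurationS))
    if (!length(rm)) break
    graph <- .dropNodes(graph, rm)
  }
  graph
}

.dropNodes <- function(graph, ids) {
  keepArc <- !(graph@arcs[, 1L] %in% ids | graph@arcs[, 2L] %in% ids)
  pruned <- c(graph@pruned, graph@nodes[ids])
  prunedProv <- c(graph@prunedProvenance, graph@provenance[ids])
  .newGraph(graph@nodes[setdiff(names(graph@nodes), ids)],
            arcs = graph@arcs[keepArc, , drop = FALSE],
            inferred = graph@inferred[keepArc],
            provenance = graph@provenance[setdiff(names(graph@provenance),
                                                  ids)],
            pruned = pruned, prunedProvenance = prunedProv)
}

#' Consolidate split-rejoin motifs
#'
#' Merges every split-rejoin motif spanning less than `maxSpanS` seconds
#' (see [findSplitRejoinMotifs()]) into a single node, strictly one motif at
#' a time in temporal order with a full re-scan after each merge, until no
#' motif remains -- a merge can expose a nested motif, and earliest-first
#' keeps overlapping motifs deterministic.
#'
#' @param graph a [TrackGraph-class].
#' @param maxSpanS span cap in seconds (default 3).
#' @param span span convention, passed to [findSplitRejoinMotifs()].
#' @return list with elements `graph` and `merged` (number of motifs merged).
#' @export
consolidateGraph <- function(graph, maxSpanS = 3, span = "intermediaries") {
  merged <- 0L
  repeat {
    motifs <- findSplitRejoinMotifs(graph, maxSpanS, span = span)
    if (!length(motifs)) break
    graph <- mergeNodes(graph, motifs[[1L]]$members)
    merged <- merged + 1L
  }
  list(graph = graph, merged = merged)
}

# All candidate sink/source pairings within the caps, as a data.frame.
.gapCandidates <- function(graph, maxDtFrames, maxDdPx) {
  ss <- findSourcesSinks(graph)
  sinks <- ss$sinks; sources <- ss$sources
  if (!length(sinks) || !length(sources)) return(NULL)
  sEnd <- vapply(graph@nodes[sinks], endFrame, integer(1))
  sX <- vapply(graph@nodes[sinks], function(n) lastCentroid(n)[["x"]],
               numeric(1))
  sY <- vapply(graph@nodes[sinks], function(n) lastCentroid(n)[["y"]],
               numeric(1))
  tStart <- vapply(graph@nodes[sources], startFrame, integer(1))
  tX <- vapply(graph@nodes[sources], function(n) firstCentroid(n)[["x"]],
               numeric(1))
  tY <- vapply(graph@nodes[sources], function(n) firstCentroid(n)[["y"]],
               numeric(1))
  dt <- outer(sEnd, tStart, function(a, b) b - a)
  ok <- dt > 0L & dt < maxDtFrames
  if (!any(ok)) return(NULL)
  idx <- which(ok, arr.ind = TRUE)
  dd <- sqrt((sX[idx[, 1L]] - tX[idx[, 2L]])^2 +
             (sY[idx[, 1L]] - tY[idx[, 2L]])^2)
  keep <- dd < maxDdPx
  if (!any(keep)) return(NULL)
  idx <- idx[keep, , drop = FALSE]; dd <- dd[keep]
  data.frame(sink = sinks[idx[, 1L]], source = sources[idx[, 2L]],
             dtFrames = dt[ok][keep], ddPx = dd,
             score = dt[ok][keep] * dd, stringsAsFactors = FALSE)
}

#' Infer missing arcs between sinks and sources
#'
#' For every (sink, source) pair with time gap strictly inside
#' `maxDtFrames` frames and distance gap strictly inside `maxDdPx` pixels, a
#' candidate is scored as dt x dd (frames x pixels). Candidates are accepted
#' greedily in ascending score (ties broken by smaller dt, then sink id,
#' then source id) under the constraint that each sink gains at most one
#' inferred outgoing arc and each source at most one inferred incoming arc.
#' Accepted arcs are added and marked inferred.
#'
#' @param graph a [TrackGraph-class].
#' @param maxDtFrames time cap in frames (strict; default 50).
#' @param maxDdPx distance cap in pixels (strict; default 50).
#' @return list with elements `graph` and `added` (number of arcs added).
#' @export
inferGaps <- function(graph, maxDtFrames = 50L, maxDdPx = 50) {
  cand <- .gapCandidates(graph, maxDtFrames, maxDdPx)
  if (is.null(cand) || !nrow(cand))
    return(list(graph = graph, added = 0L))
  cand <- cand[cand$sink != cand$source, , drop = FALSE]
  cand <- cand[order(cand$score, cand$dtFrames, cand$sink, cand$source), ,
               drop = FALSE]
  usedSink <- character(0); usedSource <- character(0)
  addP <- character(0); addC <- character(0)
  for (i in seq_len(nrow(cand))) {
    s <- cand$sink[i]; t <- cand$source[i]
    if (s %in% usedSink || t %in% usedSource) next
    usedSink <- c(usedSink, s); usedSource <- c(usedSource, t)
    addP <- c(addP, s); addC <- c(addC, t)
  }
  if (!length(addP)) return(list(graph = graph, added = 0L))
  A <- rbind(graph@arcs, cbind(parent = addP, child = addC))
  inf <- c(graph@inferred, rep(TRUE, length(addP)))
  # sink -> later source arcs cannot create a cycle, but guard anyway
  if (!.isAcyclic(A)) stop("internal error: gap inference produced a cycle")
  g <- .newGraph(graph@nodes, arcs = A, inferred = inf,
                 provenance = graph@provenance, pruned = graph@pruned,
                 prunedProvenance = graph@prunedProvenance)
  list(graph = g, added = length(addP))
}

#' Parameters for network simplification
#'
#' All thresholds of the correction pipeline with their conventional
#' defaults: a 100-pixel overlap margin for collision resolution, 50-frame /
#' 50-pixel caps for gap inference, 1 s pruning, 3 s consolidation, 50 px
#' body length, and at most 10 passes of the phase sequence.
#'
#' @param overlapThreshold collision score margin, pixels.
#' @param maxGapFrames gap-inference time cap, frames (strict).
#' @param maxGapPx gap-inference distance cap, pixels (strict).
#' @param pruneMaxS pruning duration cap, seconds (strict).
#' @param consolidateMaxS consolidation span cap, seconds (strict).
#' @param bodyLengthPx body length, pixels.
#' @param maxPasses maximum number of full phase sequences.
#' @param motifSpan span convention for consolidation.
#' @return named list of class `stitchParams`.
#' @export
stitchParams <- function(overlapThreshold = 100, maxGapFrames = 50L,
                         maxGapPx = 50, pruneMaxS = 1, consolidateMaxS = 3,
                         bodyLengthPx = 50, maxPasses = 10L,
                         motifSpan = "intermediaries") {
  p <- list(overlapThreshold = overlapThreshold,
            maxGapFrames = as.integer(maxGapFrames), maxGapPx = maxGapPx,
            pruneMaxS = pruneMaxS, consolidateMaxS = consolidateMaxS,
            bodyLengthPx = bodyLengthPx, maxPasses = as.integer(maxPasses),
            motifSpan = motifSpan)
  stopifnot(p$maxGapFrames > 0L, p$maxGapPx > 0, p$pruneMaxS > 0,
            p$consolidateMaxS > 0, p$bodyLengthPx > 0, p$maxPasses >= 1L,
            p$overlapThreshold > 0)
  class(p) <- "stitchParams"
  p
}

#' Simplify a track network
#'
#' Applies the four correction phases in the fixed order (i) identify and
#' untangle collision nodes, (ii) infer missing arcs, (iii) prune, (iv)
#' consolidate, repeating the full sequence until a pass makes zero changes
#' or `maxPasses` is reached. Non-convergence is reported with a warning
#' flag in the returned report, never as an error.
#'
#' @param graph a [TrackGraph-class].
#' @param params a [stitchParams()] list.
#' @return list with elements `graph` (the simplified network) and `report`
#'   (per-pass operation counts, collision audit, convergence flag).
#' @export
simplifyRecording <- function(graph, params = stitchParams()) {
  passes <- list()
  audit <- list()
  converged <- FALSE
  for (pass in seq_len(params$maxPasses)) {
    uc <- untangleCollisions(graph, bodyLengthPx = params$bodyLengthPx,
                             overlapThreshold = params$overlapThreshold)
    graph <- uc$graph
    audit <- c(audit, uc$audit)
    ig <- inferGaps(graph, params$maxGapFrames, params$maxGapPx)
    graph <- ig$graph
    nBefore <- length(graph@nodes)
    graph <- pruneGraph(graph, params$pruneMaxS)
    nPruned <- nBefore - length(graph@nodes)
    cg <- consolidateGraph(graph, params$consolidateMaxS,
                           span = params$motifSpan)
    graph <- cg$graph
    counts <- c(collisionsResolved = uc$applied, arcsInferred = ig$added,
                pruned = nPruned, consolidated = cg$merged)
    passes[[pass]] <- counts
    if (sum(counts) == 0L) { converged <- TRUE; break }
  }
  total <- Reduce(`+`, passes)
  unresolved <- Filter(function(a) identical(a$decision, "unresolved"), audit)
  list(graph = graph,
       report = list(passes = passes, total = total, audit = audit,
                     unresolved = unresolved, converged = converged,
                     nPasses = length(passes)))
}

#' Extract trails from a simplified graph
#'
#' Each maximal chain -- a path whose internal arcs connect an out-degree-1
#' parent to an in-degree-1 child -- becomes one trail; branching remnants
#' (e.g. an unresolved collision node) terminate trails, and such a node
#' forms its own trail. Coverage is the fraction of recording frames with an
#' observation.
#'
#' @param graph a [TrackGraph-class].
#' @param meta a [RecordingMeta-class] (for duration and fps).
#' @return list of [Trail-class] objects, ordered by start time.
#' @export
extractTrails <- function(graph, meta) {
  if (!length(graph@nodes)) return(list())
  indeg <- inDegree(graph)
  outdeg <- outDegree(graph)
  A <- graph@arcs
  chain <- if (nrow(A)) outdeg[A[, 1L]] == 1L & indeg[A[, 2L]] == 1L
           else logical(0)
  nxt <- stats::setNames(A[chain, 2L], A[chain, 1L])
  heads <- setdiff(names(graph@nodes), unname(nxt))
  totalFrames <- max(round(meta@duration * meta@fps), 1)
  trails <- list()
  for (h in heads) {
    ids <- h
    repeat {
      nx <- if (length(nxt)) nxt[ids[length(ids)]] else NA_character_
      if (is.na(nx)) break
      ids <- c(ids, unname(nx))
    }
    bl <- do.call(rbind, lapply(graph@nodes[ids], blobs))
    bl <- bl[order(bl$frame), , drop = FALSE]
    bl <- bl[!duplicated(bl$frame), , drop = FALSE]
    rownames(bl) <- NULL
    cov <- min(length(unique(bl$frame)) / totalFrames, 1)
    trails[[length(trails) + 1L]] <- new(
      "Trail", trailId = h, nodeIds = ids,
      provenance = sort(unique(unlist(graph@provenance[ids]))),
      blobs = bl[, c("frame", "time", "x", "y", "nodeId")], coverage = cov)
  }
  trails[order(vapply(trails, startTime, numeric(1)),
               vapply(trails, trailId, character(1)))]
}

#' Coverage summary over a set of trails
#'
#' Fractions of trails whose coverage exceeds each threshold, plus the count
#' of trails shorter than one minute (the conventional noise filter for
#' downstream analysis).
#'
#' @param trails list of [Trail-class] objects.
#' @param meta a [RecordingMeta-class].
#' @param thresholds coverage thresholds (defaults 0.5, 0.9, 0.99).
#' @return list with `fractions` (data.frame threshold/fraction), `nTrails`,
#'   and `nShorterThan1min`.
#' @export
coverageStats <- function(trails, meta, thresholds = c(0.5, 0.9, 0.99)) {
  covs <- vapply(trails, coverage, numeric(1))
  durs <- vapply(trails, duration, numeric(1))
  frac <- vapply(thresholds, function(th) {
    if (!length(covs)) NA_real_ else mean(covs > th)
  }, numeric(1))
  list(fractions = data.frame(threshold = thresholds, fraction = frac),
       nTrails = length(trails),
       nShorterThan1min = sum(durs < 60))
}

#' Check blob conservation through the pipeline
#'
#' Every (original node, frame) observation of the input must survive in at
#' least one current or pruned node whose provenance contains that original
#' id, and no current node may carry frames outside the union of its
#' provenance members' frames. Multiplicity greater than one arises only
#' from collision-node duplication, which intentionally shares the merged
#' blobs between both untangled copies.
#'
#' @param graph a [TrackGraph-class] after any amount of simplification.
#' @param originalNodes the node list the graph was built from.
#' @return TRUE, or a character vector of violations.
#' @export
blobConservation <- function(graph, originalNodes) {
  ids <- vapply(originalNodes, nodeId, character(1))
  names(originalNodes) <- ids
  origFrames <- lapply(originalNodes, function(n) n@frames)
  allNodes <- c(graph@nodes, graph@pruned)
  allProv <- c(graph@provenance, graph@prunedProvenance)
  msg <- character(0)
  seen <- stats::setNames(vector("list", length(ids)), ids)
  for (k in seq_along(allNodes)) {
    nid <- names(allNodes)[k]
    pv <- allProv[[nid]]
    fr <- allNodes[[k]]@frames
    extra <- setdiff(fr, unlist(origFrames[pv]))
    if (length(extra))
      msg <- c(msg, paste0("node ", nid, " carries frames outside its ",
                           "provenance"))
    for (o in pv) seen[[o]] <- union(seen[[o]], fr)
  }
  for (o in ids) {
    missing <- setdiff(origFrames[[o]], seen[[o]])
    if (length(missing))
      msg <- c(msg, paste0("lost ", length(missing), " blobs of node ", o))
  }
  if (length(msg)) msg else TRUE
}
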