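# The directed acyclic track network: construction, degree/motif queries and
# node contraction. All correction operations work through these primitives.

.newGraph <- function(nodes, arcs = emptyArcs(),
                      inferred = logical(nrow(arcs)),
                      provenance = NULL, pruned = list(),
                      prunedProvenance = list()) {
  if (is.null(provenance))
    provenance <- stats::setNames(as.list(names(nodes)), names(nodes))
  new("TrackGraph", nodes = nodes, arcs = arcs, inferred = inferred,
      provenance = provenance, pruned = pruned,
      prunedProvenance = prunedProvenance)
}

.isAcyclic <- function(arcs) {
  if (nrow(arcs) == 0L) return(TRUE)
  igraph::is_dag(igraph::graph_from_edgelist(arcs, directed = TRUE))
}

.degrees <- function(g, col) {
  d <- stats::setNames(integer(length(g@nodes)), names(g@nodes))
  if (nrow(g@arcs)) {
    t <- table(g@arcs[, col])
    d[names(t)] <- as.integer(t)
  }
  d
}

#' @rdname TrackGraph-class
#' @export
setGeneric("inDegree", function(x) standardGeneric("inDegree"))
#' @rdname TrackGraph-class
#' @export
setGeneric("outDegree", function(x) standardGeneric("outDegree"))
setMethod("inDegree", "TrackGraph", function(x) .degrees(x, "child"))
setMethod("outDegree", "TrackGraph", function(x) .degrees(x, "parent"))

parentsOf <- function(g, id) g@arcs[g@arcs[, "child"] == id, "parent"]
childrenOf <- function(g, id) g@arcs[g@arcs[, "parent"] == id, "child"]

#' Build the track network from tracks and tracker links
#'
#' One graph node per track; one arc per link, oriented parent to child.
#' Provenance starts as singletons. A cycle among the links indicates
#' corrupted upstream output and is an error.
#'
#' @param nodes list of [TrackNode-class] objects (named or not; names are
#'   taken from the node ids).
#' @param links a [LinkTable-class]; endpoints must exist among `nodes`.
#' @return A [TrackGraph-class].
#' @export
buildGraph <- function(nodes, links = linkTable()) {
  ids <- vapply(nodes, nodeId, character(1))
  if (anyDuplicated(ids)) stop("integrity error: duplicate node ids")
  names(nodes) <- ids
  A <- links@links
  unknown <- setdiff(c(A), ids)
  if (length(unknown))
    stop("integrity error: link references unknown node ",
         paste(unknown, collapse = ", "))
  if (!.isAcyclic(A))
    stop("integrity error: cycle in link table")
  .newGraph(nodes, arcs = A)
}

#' Find source, sink and isolated nodes
#'
#' Sources have in-degree 0, sinks out-degree 0; isolated nodes appear in
#' both sets. These are the points where animal identity is lost or begins,
#' and the anchors for gap inference.
#'
#' @param graph a [TrackGraph-class].
#' @return list with character vectors `sources` and `sinks`.
#' @export
findSourcesSinks <- function(graph) {
  list(sources = names(which(inDegree(graph) == 0L)),
       sinks = names(which(outDegree(graph) == 0L)))
}

#' Find split-rejoin motifs
#'
#' A split-rejoin motif is a parent node connected to two or more
#' intermediary nodes that all reconnect to a single child: the signature of
#' one animal transiently segmented as multiple blobs. Intermediaries must
#' have the parent as their sole parent and the child as their sole child.
#' The motif span is measured over the intermediary window (earliest
#' intermediary start to latest intermediary end) by default -- the interval
#' the error physically occupies -- or parent start to child end with
#' `span = "parent-child"`. Overlapping motifs are resolved greedily in
#' temporal order (earliest parent start first, then parent id), keeping
#' motifs node-disjoint.
#'
#' @param graph a [TrackGraph-class].
#' @param maxSpanS maximum span in seconds (strict).
#' @param span either "intermediaries" (default) or "parent-child".
#' @return list of motifs, each a list with elements `parent`,
#'   `intermediaries`, `child`, `span`, `members`.
#' @export
findSplitRejoinMotifs <- function(graph, maxSpanS = 3,
                                  span = c("intermediaries", "parent-child")) {
  span <- match.arg(span)
  stopifnot(maxSpanS > 0)
  indeg <- inDegree(graph)
  outdeg <- outDegree(graph)
  found <- list()
  for (p in names(which(outdeg >= 2L))) {
    ch <- unique(childrenOf(graph, p))
    # intermediary candidates: sole parent p, exactly one child
    ok <- ch[indeg[ch] == 1L & outdeg[ch] == 1L]
    if (length(ok) < 2L) next
    cc <- vapply(ok, function(i) unname(childrenOf(graph, i)[1L]),
                 character(1))
    for (cid in unique(cc)) {
      if (cid == p) next
      I <- ok[cc == cid]
      if (length(I) < 2L) next
      s <- if (span == "intermediaries") {
        max(vapply(graph@nodes[I], endTime, numeric(1))) -
          min(vapply(graph@nodes[I], startTime, numeric(1)))
      } else {
        endTime(graph@nodes[[cid]]) - startTime(graph@nodes[[p]])
      }
      if (s < maxSpanS)
        found[[length(found) + 1L]] <- list(
          parent = p, intermediaries = sort(I), child = cid, span = s,
          members = c(p, sort(I), cid))
    }
  }
  if (!length(found)) return(found)
  ord <- order(vapply(found, function(m) startTime(graph@nodes[[m$parent]]),
                      numeric(1)),
               vapply(found, function(m) m$parent, character(1)))
  used <- character(0)
  keep <- list()
  for (m in found[ord]) {
    if (!any(m$members %in% used)) {
      keep[[length(keep) + 1L]] <- m
      used <- c(used, m$members)
    }
  }
  keep
}

# Combine member blobs frame by frame; same-frame duplicates are mask-unioned
# with the centroid recomputed as the pixel-mass centroid (the fragments are
# one animal's body). Maskless duplicates fall back to an area-weighted mean.
.combineBlobs <- function(members) {
  frames <- sort(unique(unlist(lapply(members, function(n) n@frames))))
  nf <- length(frames)
  tms <- numeric(nf); xs <- numeric(nf); ys <- numeric(nf)
  areas <- numeric(nf); masks <- vector("list", nf)
  for (k in seq_len(nf)) {
    f <- frames[k]
    hits <- list()
    for (nd in members) {
      i <- match(f, nd@frames)
      if (!is.na(i))
        hits[[length(hits) + 1L]] <- list(
          time = nd@times[i], x = nd@x[i], y = nd@y[i],
          mask = nd@masks[[i]], area = nd@areas[i])
    }
    tms[k] <- min(vapply(hits, `[[`, numeric(1), "time"))
    if (length(hits) == 1L) {
      xs[k] <- hits[[1L]]$x; ys[k] <- hits[[1L]]$y
      masks[k] <- list(hits[[1L]]$mask); areas[k] <- hits[[1L]]$area
    } else {
      ms <- lapply(hits, `[[`, "mask")
      if (!any(vapply(ms, is.null, logical(1)))) {
        u <- maskUnion(ms)
        cen <- maskCentroid(u)
        xs[k] <- cen[["x"]]; ys[k] <- cen[["y"]]
        masks[[k]] <- u; areas[k] <- nrow(u)
      } else {
        w <- vapply(hits, function(h) {
          if (is.na(h$area)) 1 else h$area
        }, numeric(1))
        xs[k] <- sum(w * vapply(hits, `[[`, numeric(1), "x")) / sum(w)
        ys[k] <- sum(w * vapply(hits, `[[`, numeric(1), "y")) / sum(w)
        areas[k] <- sum(vapply(hits, `[[`, numeric(1), "area"))
        masks[k] <- list(NULL)
      }
    }
  }
  list(frames = frames, times = tms, x = xs, y = ys, masks = masks,
       areas = areas)
}

#' Merge a connected set of nodes into one
#'
#' Realizes consolidation: the members' blob sequences are unioned
#' frame-by-frame (same-frame fragments are mask-unioned), arcs are rewired
#' to the merged node, and provenance sets are unioned. The merged node takes
#' the id of the temporally earliest member. Contraction that would create a
#' cycle is refused.
#'
#' @param graph a [TrackGraph-class].
#' @param ids node ids to merge; must induce a weakly connected subgraph.
#' @return The updated [TrackGraph-class].
#' @export
mergeNodes <- function(graph, ids) {
  ids <- unique(as.character(ids))
  stopifnot(length(ids) >= 2L)
  if (!all(ids %in% names(graph@nodes)))
    stop("unknown node id in merge set")
  sub <- graph@arcs[graph@arcs[, 1L] %in% ids & graph@arcs[, 2L] %in% ids, ,
                    drop = FALSE]
  gsub <- igraph::graph_from_data_frame(
    as.data.frame(sub, stringsAsFactors = FALSE), directed = FALSE,
    vertices = ids)
  if (igraph::count_components(gsub) != 1L)
    stop("merge refused: ids do not induce a connected subgraph")
  members <- graph@nodes[ids]
  starts <- vapply(members, startTime, numeric(1))
  newId <- ids[order(starts, ids)][1L]
  cb <- .combineBlobs(members)
  merged <- new("TrackNode", nodeId = newId, frames = cb$frames,
                times = cb$times, x = cb$x, y = cb$y, masks = cb$masks,
                areas = cb$areas)
  A <- graph@arcs
  inf <- graph@inferred
  inside <- A[, 1L] %in% ids & A[, 2L] %in% ids
  A <- A[!inside, , drop = FALSE]; inf <- inf[!inside]
  A[A[, 1L] %in% ids, 1L] <- newId
  A[A[, 2L] %in% ids, 2L] <- newId
  loop <- A[, 1L] == A[, 2L]
  A <- A[!loop, , drop = FALSE]; inf <- inf[!loop]
  if (nrow(A)) {
    key <- paste(A[, 1L], A[, 2L], sep = "\r")
    inf <- as.logical(tapply(inf, key, any)[unique(key)])
    A <- A[!duplicated(key), , drop = FALSE]
  }
  if (!.isAcyclic(A))
    stop("merge refused: contraction would create a cycle")
  nodes <- graph@nodes[setdiff(names(graph@nodes), ids)]
  nodes[[newId]] <- merged
  prov <- graph@provenance
  newProv <- sort(unique(unlist(prov[ids])))
  prov <- prov[setdiff(names(prov), ids)]
  prov[[newId]] <- newProv
  .newGraph(nodes, arcs = A, inferred = inf, provenance = prov,
            pruned = graph@pruned, prunedProvenance = graph@prunedProvenance)
}
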