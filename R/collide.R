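# Two-worm collision detection and identity untangling by pixel-overlap
# voting between the parents' last masks and the children's first masks.

#' Flag collision candidate nodes
#'
#' The collision motif (two parents, one merged node, two children) is not
#' unique to collisions, so candidates are filtered by movement: a node in
#' the merged position is flagged only if at least one of its parents or
#' children crawls a travelled path longer than one body length. Nodes with
#' more than two parents or children (multi-worm pileups) are still returned
#' here but are never auto-resolved downstream.
#'
#' @param graph a [TrackGraph-class].
#' @param bodyLengthPx body length in pixels (default 50).
#' @return character vector of flagged node ids, in temporal order.
#' @export
flagCollisionCandidates <- function(graph, bodyLengthPx = 50) {
  stopifnot(bodyLengthPx > 0)
  indeg <- inDegree(graph)
  outdeg <- outDegree(graph)
  cand <- names(which(indeg >= 2L & outdeg >= 2L))
  keep <- vapply(cand, function(id) {
    nb <- unique(c(parentsOf(graph, id), childrenOf(graph, id)))
    any(vapply(graph@nodes[nb], pathLength, numeric(1)) > bodyLengthPx)
  }, logical(1))
  cand <- cand[keep]
  cand[order(vapply(graph@nodes[cand], startTime, numeric(1)), cand)]
}

#' Build a collision case for a flagged node
#'
#' Requires exactly two parents and two children. Parents and children are
#' ordered temporally (start time, then id) to fix the (a, b) / (d, e)
#' labels; the four boundary-mask overlaps are computed here.
#'
#' @param graph a [TrackGraph-class].
#' @param id the collision node.
#' @return A [CollisionCase-class], or NULL if the node does not have
#'   exactly two parents and two children.
#' @export
collisionCase <- function(graph, id) {
  pre <- unique(parentsOf(graph, id))
  post <- unique(childrenOf(graph, id))
  if (length(pre) != 2L || length(post) != 2L) return(NULL)
  pre <- pre[order(vapply(graph@nodes[pre], startTime, numeric(1)), pre)]
  post <- post[order(vapply(graph@nodes[post], startTime, numeric(1)), post)]
  ov <- function(p, q) {
    mp <- lastMask(graph@nodes[[p]])
    mq <- firstMask(graph@nodes[[q]])
    if (is.null(mp) || is.null(mq)) NA_real_ else as.numeric(maskOverlap(mp, mq))
  }
  new("CollisionCase", node = id, pre = pre, post = post,
      overlaps = c(ad = ov(pre[1L], post[1L]), ae = ov(pre[1L], post[2L]),
                   bd = ov(pre[2L], post[1L]), be = ov(pre[2L], post[2L])))
}

#' Resolve a collision by pixel-overlap voting
#'
#' Sums the overlaps for the two possible pairings: score1 = O(a,d) + O(b,e)
#' ("straight") and score2 = O(a,e) + O(b,d) ("crossed"). A pairing is
#' selected only if it beats the other by at least `overlapThreshold` pixels;
#' otherwise (including when both outcomes have nearly equal overlap, or a
#' boundary mask is missing) the case is unresolved and no guess is made.
#'
#' @param case a [CollisionCase-class].
#' @param overlapThreshold required score margin in pixels (default 100).
#' @return A [CollisionOutcome-class].
#' @export
resolveCollision <- function(case, overlapThreshold = 100) {
  o <- case@overlaps
  if (anyNA(o))
    return(new("CollisionOutcome", decision = "unresolved",
               score1 = NA_real_, score2 = NA_real_, reason = "missing-mask"))
  s1 <- o[["ad"]] + o[["be"]]
  s2 <- o[["ae"]] + o[["bd"]]
  decision <- if (abs(s1 - s2) >= overlapThreshold) {
    if (s1 > s2) "straight" else "crossed"
  } else "unresolved"
  new("CollisionOutcome", decision = decision, score1 = s1, score2 = s2,
      reason = if (decision == "unresolved") "ambiguous" else "")
}

#' Apply a resolved collision to the graph
#'
#' The collision node c is duplicated into two copies carrying the same
#' (merged) blob masks -- the combined shape is the accepted imprecision
#' during contact -- and the arcs are rewired into two disjoint chains
#' according to the decision: a -> c1 -> d, b -> c2 -> e for "straight", or
#' a -> c1 -> e, b -> c2 -> d for "crossed". Both copies reference c in
#' their provenance. If the rewiring would create a cycle it is refused and
#' the graph is returned unchanged.
#'
#' @param graph a [TrackGraph-class].
#' @param case a [CollisionCase-class].
#' @param outcome a [CollisionOutcome-class]; an unresolved outcome leaves
#'   the graph unchanged.
#' @return list with elements `graph` (possibly updated), `applied`
#'   (logical) and `reason` ("" when applied).
#' @export
applyResolution <- function(graph, case, outcome) {
  if (outcome@decision == "unresolved")
    return(list(graph = graph, applied = FALSE, reason = "unresolved"))
  cid <- case@node
  if (!cid %in% names(graph@nodes))
    return(list(graph = graph, applied = FALSE, reason = "node-gone"))
  a <- case@pre[1L]; b <- case@pre[2L]
  d <- case@post[1L]; e <- case@post[2L]
  if (outcome@decision == "crossed") { tmp <- d; d <- e; e <- tmp }
  c1 <- paste0(cid, ".1"); c2 <- paste0(cid, ".2")
  while (any(c(c1, c2) %in% names(graph@nodes))) {
    c1 <- paste0(c1, "'"); c2 <- paste0(c2, "'")
  }
  cnode <- graph@nodes[[cid]]
  n1 <- cnode; n1@nodeId <- c1
  n2 <- cnode; n2@nodeId <- c2
  touches <- graph@arcs[, 1L] == cid | graph@arcs[, 2L] == cid
  A <- graph@arcs[!touches, , drop = FALSE]
  inf <- graph@inferred[!touches]
  A <- rbind(A, cbind(parent = c(a, c1, b, c2), child = c(c1, d, c2, e)))
  inf <- c(inf, rep(FALSE, 4L))
  if (!.isAcyclic(A))
    return(list(graph = graph, applied = FALSE, reason = "cycle-risk"))
  nodes <- graph@nodes[setdiff(names(graph@nodes), cid)]
  nodes[[c1]] <- n1
  nodes[[c2]] <- n2
  prov <- graph@provenance
  cp <- prov[[cid]]
  prov <- prov[setdiff(names(prov), cid)]
  prov[[c1]] <- cp
  prov[[c2]] <- cp
  g <- .newGraph(nodes, arcs = A, inferred = inf, provenance = prov,
                 pruned = graph@pruned,
                 prunedProvenance = graph@prunedProvenance)
  list(graph = g, applied = TRUE, reason = "")
}

# One collision-untangling sweep: flag candidates, resolve the clean
# two-in/two-out cases, apply the decided ones. Returns the updated graph,
# the number applied, and an audit list (one record per case: ids, overlaps,
# scores, decision, reason, provenance of the collision node).
untangleCollisions <- function(graph, bodyLengthPx = 50,
                               overlapThreshold = 100) {
  audit <- list()
  applied <- 0L
  for (id in flagCollisionCandidates(graph, bodyLengthPx)) {
    if (!id %in% names(graph@nodes)) next
    case <- collisionCase(graph, id)
    if (is.null(case)) {
      audit[[length(audit) + 1L]] <- list(
        node = id, decision = "unresolved", reason = "multi-worm",
        provenance = graph@provenance[[id]])
      next
    }
    out <- resolveCollision(case, overlapThreshold)
    res <- list(graph = graph, applied = FALSE, reason = out@reason)
    if (out@decision != "unresolved") {
      res <- applyResolution(graph, case, out)
      if (!res$applied) out@decision <- "unresolved"
    }
    audit[[length(audit) + 1L]] <- list(
      node = id, pre = case@pre, post = case@post,
      overlaps = case@overlaps, score1 = out@score1, score2 = out@score2,
      decision = out@decision,
      reason = if (res$applied) "" else res$reason,
      provenance = graph@provenance[[id]])
    if (res$applied) {
      graph <- res$graph
      applied <- applied + 1L
    }
  }
  list(graph = graph, applied = applied, audit = audit)
}
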