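# Fixture builders and independent brute-force oracles shared by the tests.
# Oracles are deliberately naive re-implementations working only from the
# arc list and node fields, so they stay independent of the package's
# algorithmic shortcuts.

mkNode <- function(id, frames, x, y, masks = NULL, fps = 5) {
  trackNode(id, frames = frames, x = x, y = y, masks = masks, fps = fps)
}

# a stationary node: `k` blobs at one spot
stillNode <- function(id, from, k, x, y, fps = 5, masks = NULL) {
  mkNode(id, from + seq_len(k) - 1L, rep(x, k), rep(y, k), masks = masks,
         fps = fps)
}

squareMask <- function(x0, y0, w, h = w) {
  as.matrix(expand.grid(x = as.integer(x0 + 0:(w - 1)),
                        y = as.integer(y0 + 0:(h - 1))))
}

graphFromEdges <- function(nodes, edges = NULL) {
  if (is.null(edges) || !length(edges)) return(buildGraph(nodes))
  buildGraph(nodes, linkTable(vapply(edges, `[`, character(1), 1L),
                              vapply(edges, `[`, character(1), 2L)))
}

# random DAG on nodes ordered by start frame; optionally embeds an explicit
# split-rejoin motif so motif-bearing graphs are common
randomDag <- function(nNodes = 10L, pArc = 0.18, embedMotif = FALSE,
                      fps = 5) {
  starts <- sort(sample.int(200L, nNodes))
  durs <- sample(1:20, nNodes, replace = TRUE)
  nodes <- lapply(seq_len(nNodes), function(i) {
    k <- durs[i]
    mkNode(paste0("n", i), starts[i] + seq_len(k) - 1L,
           x = runif(1, 0, 500) + seq_len(k) * runif(1, -2, 2),
           y = runif(1, 0, 500) + seq_len(k) * runif(1, -2, 2), fps = fps)
  })
  edges <- list()
  for (i in seq_len(nNodes - 1L)) for (j in (i + 1L):nNodes) {
    if (runif(1) < pArc && starts[j] >= starts[i])
      edges[[length(edges) + 1L]] <- c(paste0("n", i), paste0("n", j))
  }
  if (embedMotif && nNodes >= 4L) {
    ids <- paste0("n", 1:4)
    edges <- c(edges, list(c(ids[1], ids[2]), c(ids[1], ids[3]),
                           c(ids[2], ids[4]), c(ids[3], ids[4])))
  }
  # drop duplicates
  key <- vapply(edges, paste, character(1), collapse = ">")
  graphFromEdges(nodes, edges[!duplicated(key)])
}

# nested split-rejoin: merging (p, {i1,i2}, c) turns P -> {merged, k} -> Q
# into a second motif
splitRejoinNested <- function(fps = 5) {
  graphFromEdges(
    list(mkNode("P", 0:2, rep(500, 3), rep(500, 3), fps = fps),
         mkNode("p", 3:4, rep(500, 2), rep(500, 2), fps = fps),
         mkNode("i1", 5:6, rep(498, 2), rep(500, 2), fps = fps),
         mkNode("i2", 5:6, rep(502, 2), rep(500, 2), fps = fps),
         mkNode("c", 7:8, rep(500, 2), rep(500, 2), fps = fps),
         mkNode("k", 3:8, rep(505, 6), rep(505, 6), fps = fps),
         mkNode("Q", 9:12, rep(500, 4), rep(500, 4), fps = fps)),
    list(c("P", "p"), c("P", "k"), c("p", "i1"), c("p", "i2"),
         c("i1", "c"), c("i2", "c"), c("c", "Q"), c("k", "Q")))
}

# ---- oracles ---------------------------------------------------------------

# exhaustive split-rejoin motif enumeration straight from the arc matrix
oracleMotifs <- function(graph, maxSpanS = 3) {
  A <- graphArcs(graph)
  nodes <- graphNodes(graph)
  ids <- names(nodes)
  par <- lapply(ids, function(v) unique(A[A[, 2] == v, 1]))
  chl <- lapply(ids, function(v) unique(A[A[, 1] == v, 2]))
  names(par) <- ids; names(chl) <- ids
  out <- list()
  for (p in ids) for (cc in ids) {
    if (p == cc) next
    I <- ids[vapply(ids, function(i)
      identical(par[[i]], p) && identical(chl[[i]], cc), logical(1))]
    if (length(I) < 2L) next
    span <- max(vapply(nodes[I], endTime, numeric(1))) -
      min(vapply(nodes[I], startTime, numeric(1)))
    if (span < maxSpanS)
      out[[length(out) + 1L]] <- list(parent = p, intermediaries = sort(I),
                                      child = cc, span = span)
  }
  out
}

# prune to fixpoint by exhaustive single-removal re-scan
oraclePruneIds <- function(graph, maxDurationS = 1) {
  A <- graphArcs(graph)
  alive <- names(graphNodes(graph))
  dur <- vapply(graphNodes(graph), duration, numeric(1))
  repeat {
    removed <- FALSE
    for (v in alive) {
      Ain <- A[A[, 1] %in% alive & A[, 2] %in% alive, , drop = FALSE]
      indeg <- sum(Ain[, 2] == v)
      outdeg <- sum(Ain[, 1] == v)
      if ((indeg == 0L || outdeg == 0L) && dur[v] < maxDurationS) {
        alive <- setdiff(alive, v)
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }
  alive
}

# canonical form of a graph: provenance partition plus arcs mapped onto the
# smallest original id of each side
canonicalGraph <- function(graph) {
  prov <- lapply(provenance(graph), sort)
  repOf <- character(0)
  for (nid in names(prov)) repOf[prov[[nid]]] <- prov[[nid]][1L]
  A <- graphArcs(graph)
  arcs <- if (nrow(A)) {
    m <- cbind(repOf[vapply(provenance(graph)[A[, 1]], `[`, character(1), 1L)],
               repOf[vapply(provenance(graph)[A[, 2]], `[`, character(1), 1L)])
    m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
    unname(m)
  } else matrix(character(0), ncol = 2)
  list(partition = unname(prov[order(vapply(prov, `[`, character(1), 1L))]),
       arcs = arcs)
}

# consolidation to fixpoint using the exhaustive motif oracle, merging one
# motif at a time (earliest parent start, then parent id)
oracleConsolidate <- function(graph, maxSpanS = 3) {
  repeat {
    ms <- oracleMotifs(graph, maxSpanS)
    if (!length(ms)) return(graph)
    st <- vapply(ms, function(m)
      startTime(graphNodes(graph)[[m$parent]]), numeric(1))
    pid <- vapply(ms, `[[`, character(1), "parent")
    m <- ms[[order(st, pid)[1L]]]
    graph <- mergeNodes(graph, c(m$parent, m$intermediaries, m$child))
  }
}

# exhaustive re-scan greedy gap selection: at each step recompute every
# remaining candidate and take the global minimum score (ties: dt, sink id,
# source id)
oracleGapSelect <- function(cand) {
  if (is.null(cand)) return(NULL)
  sel <- list()
  repeat {
    if (!nrow(cand)) break
    o <- order(cand$score, cand$dtFrames, cand$sink, cand$source)
    best <- cand[o[1L], ]
    sel[[length(sel) + 1L]] <- best
    cand <- cand[cand$sink != best$sink & cand$source != best$source, ,
                 drop = FALSE]
  }
  if (!length(sel)) return(NULL)
  do.call(rbind, sel)
}

# brute-force capsule rasterization over the full bounding box
bruteCapsule <- function(cx, cy, theta, len = 50, width = 5) {
  r <- width / 2; hl <- max((len - width) / 2, 0)
  ux <- cos(theta); uy <- sin(theta)
  ax <- cx - hl * ux; ay <- cy - hl * uy
  bx <- cx + hl * ux; by <- cy + hl * uy
  xs <- floor(min(ax, bx) - r):ceiling(max(ax, bx) + r)
  ys <- floor(min(ay, by) - r):ceiling(max(ay, by) + r)
  px <- rep(xs, times = length(ys)); py <- rep(ys, each = length(xs))
  dx <- bx - ax; dy <- by - ay; L2 <- dx * dx + dy * dy
  if (L2 == 0) d2 <- (px - ax)^2 + (py - ay)^2 else {
    t <- pmin(pmax(((px - ax) * dx + (py - ay) * dy) / L2, 0), 1)
    d2 <- (px - (ax + t * dx))^2 + (py - (ay + t * dy))^2
  }
  m <- cbind(x = as.integer(px[d2 <= r * r]), y = as.integer(py[d2 <= r * r]))
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

sortMask <- function(m) unname(m[order(m[, 1], m[, 2]), , drop = FALSE])

# the standard collision fixture: a travels 80 px then meets stationary b;
# boundary masks are 15x15 squares giving unambiguous overlap votes
collisionFixture <- function(fps = 5) {
  sqA <- squareMask(100, 100, 15)
  sqB <- squareMask(140, 100, 15)
  a <- trackNode("a", frames = 0:10, x = 20 + 8 * (0:10), y = rep(107, 11),
                 masks = c(rep(list(NULL), 10), list(sqA)), fps = fps)
  b <- trackNode("b", frames = 0:10, x = rep(147, 11), y = rep(107, 11),
                 masks = c(rep(list(NULL), 10), list(sqB)), fps = fps)
  cc <- trackNode("c", frames = 11:15, x = rep(127, 5), y = rep(107, 5),
                  masks = c(list(maskUnion(list(sqA, sqB))),
                            rep(list(NULL), 4)), fps = fps)
  d <- trackNode("d", frames = 16:20, x = rep(107, 5), y = rep(107, 5),
                 masks = c(list(sqA), rep(list(NULL), 4)), fps = fps)
  e <- trackNode("e", frames = 16:20, x = rep(147, 5), y = rep(107, 5),
                 masks = c(list(sqB), rep(list(NULL), 4)), fps = fps)
  graphFromEdges(list(a, b, cc, d, e),
                 list(c("a", "c"), c("b", "c"), c("c", "d"), c("c", "e")))
}
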