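test_that("pruning removes sub-second orphans to a fixpoint", {
  # isolated 0.5 s node: removed
  g <- buildGraph(list(mkNode("x", 0:2, 0:2, rep(0, 3))))   # 0.4 s
  g2 <- pruneGraph(g, 1)
  expect_length(graphNodes(g2), 0L)
  expect_identical(names(prunedNodes(g2)), "x")

  # parentless 2 s node: kept
  g <- buildGraph(list(mkNode("x", 0:10, 0:10, rep(0, 11))))
  expect_length(graphNodes(pruneGraph(g, 1)), 1L)

  # chain of two 0.5 s nodes: the second becomes removable on iteration 2
  g <- graphFromEdges(
    list(mkNode("1", 0:2, 0:2, rep(0, 3)), mkNode("2", 3:5, 3:5, rep(0, 3))),
    list(c("1", "2")))
  g2 <- pruneGraph(g, 1)
  expect_length(graphNodes(g2), 0L)
  expect_setequal(names(prunedNodes(g2)), c("1", "2"))
})

test_that("pruning agrees with the exhaustive re-scan oracle", {
  set.seed(61)
  for (i in 1:120) {
    g <- randomDag(sample(3:12, 1), pArc = runif(1, 0.05, 0.4))
    g2 <- pruneGraph(g, 1)
    expect_setequal(names(graphNodes(g2)), oraclePruneIds(g, 1))
  }
})

test_that("consolidation merges nested motifs to a fixpoint", {
  g <- splitRejoinNested()
  res <- consolidateGraph(g, 3)
  expect_gte(res$merged, 2L)
  expect_identical(canonicalGraph(res$graph),
                   canonicalGraph(oracleConsolidate(g, 3)))

  # a 4 s motif is untouched
  g4 <- graphFromEdges(
    list(mkNode("p", 0:10, 0:10, rep(0, 11)),
         mkNode("i1", 11:31, 11:31, rep(-2, 21)),
         mkNode("i2", 11:31, 11:31, rep(2, 21)),
         mkNode("c", 32:35, 32:35, rep(0, 4))),
    list(c("p", "i1"), c("p", "i2"), c("i1", "c"), c("i2", "c")))
  res <- consolidateGraph(g4, 3)
  expect_identical(res$merged, 0L)
  expect_length(graphNodes(res$graph), 4L)
})

test_that("consolidation agrees with the exhaustive oracle on random graphs", {
  set.seed(71)
  for (i in 1:120) {
    g <- randomDag(sample(4:12, 1), pArc = runif(1, 0.05, 0.35),
                   embedMotif = i %% 3 != 0)
    res <- consolidateGraph(g, 3)
    expect_identical(canonicalGraph(res$graph),
                     canonicalGraph(oracleConsolidate(g, 3)))
  }
})

test_that("gap inference respects both caps strictly", {
  mkGap <- function(dtFrames, ddPx) {
    graphFromEdges(list(
      mkNode("s", 0:200, c(rep(100, 200), 100), rep(100, 201)),
      mkNode("t", (200 + dtFrames):(200 + dtFrames + 200),
             rep(100 + ddPx, 201), rep(100, 201))))
  }
  # dt 10 frames, dd 20 px: inside both caps
  res <- inferGaps(mkGap(10L, 20))
  expect_identical(res$added, 1L)
  expect_identical(unname(inferredArcs(res$graph)), cbind("s", "t"))

  # dd 60 px: no arc regardless of dt
  expect_identical(inferGaps(mkGap(5L, 60))$added, 0L)

  # exhaustive boundary grid at 49 / 50 / 51
  for (dt in c(49L, 50L, 51L)) for (dd in c(49, 50, 51)) {
    added <- inferGaps(mkGap(dt, dd))$added
    expect_identical(added, if (dt < 50L && dd < 50) 1L else 0L,
                     info = sprintf("dt=%d dd=%g", dt, dd))
  }
})

test_that("among multiple options only the smallest dt x dd is selected", {
  g <- graphFromEdges(list(
    mkNode("s", 0:100, rep(100, 101), rep(100, 101)),
    mkNode("t1", 111:150, rep(120, 40), rep(100, 40)),   # dt 10, dd 20: 200
    mkNode("t2", 104:150, rep(130, 47), rep(122.5, 47)))) # dt 3, dd 30: 90
  res <- inferGaps(g)
  A <- inferredArcs(res$graph)
  expect_identical(res$added, 1L)
  expect_identical(unname(A), cbind("s", "t2"))
})

test_that("greedy gap matching equals the exhaustive re-scan selection", {
  set.seed(81)
  for (i in 1:150) {
    nS <- sample(1:6, 1); nT <- sample(1:6, 1)
    sinks <- lapply(seq_len(nS), function(k)
      mkNode(paste0("s", k), 0:10, rep(runif(1, 0, 120), 11),
             rep(runif(1, 0, 120), 11)))
    sources <- lapply(seq_len(nT), function(k)
      mkNode(paste0("t", k), sample(12:59, 1) + 0:10,
             rep(runif(1, 0, 120), 11), rep(runif(1, 0, 120), 11)))
    g <- buildGraph(c(sinks, sources))
    cand <- wormtrails:::.gapCandidates(g, 50L, 50)
    res <- inferGaps(g)
    A <- inferredArcs(res$graph)
    want <- oracleGapSelect(cand)
    if (is.null(want)) {
      expect_identical(nrow(A), 0L)
    } else {
      expect_identical(res$added, nrow(want))
      expect_setequal(paste(A[, 1], A[, 2]),
                      paste(want$sink, want$source))
    }
    # accepted arcs never violate the caps or temporal order
    for (j in seq_len(nrow(A))) {
      sk <- graphNodes(g)[[A[j, 1]]]; so <- graphNodes(g)[[A[j, 2]]]
      dt <- startFrame(so) - endFrame(sk)
      dd <- sqrt(sum((lastCentroid(sk) - firstCentroid(so))^2))
      expect_true(dt > 0 && dt < 50 && dd < 50)
    }
  }
})

test_that("prune, consolidate and infer_gaps are idempotent", {
  set.seed(91)
  for (i in 1:15) {
    g <- randomDag(sample(5:10, 1), pArc = 0.2, embedMotif = TRUE)
    p1 <- pruneGraph(g, 1)
    expect_identical(names(graphNodes(pruneGraph(p1, 1))),
                     names(graphNodes(p1)))
    c1 <- consolidateGraph(g, 3)$graph
    expect_identical(consolidateGraph(c1, 3)$merged, 0L)
    i1 <- inferGaps(g)$graph
    expect_identical(inferGaps(i1)$added, 0L)
  }
})

oneOfEachGraph <- function() {
  sqA <- squareMask(100, 100, 15)
  sqB <- squareMask(140, 100, 15)
  nodes <- list(
    # collision: a travels 80 px into stationary b
    trackNode("a", 0:10, x = 20 + 8 * (0:10), y = rep(107, 11),
              masks = c(rep(list(NULL), 10), list(sqA))),
    trackNode("b", 0:10, x = rep(147, 11), y = rep(107, 11),
              masks = c(rep(list(NULL), 10), list(sqB))),
    trackNode("c", 11:15, x = rep(127, 5), y = rep(107, 5),
              masks = c(list(maskUnion(list(sqA, sqB))),
                        rep(list(NULL), 4))),
    trackNode("d", 16:40, x = rep(107, 25), y = rep(107, 25),
              masks = c(list(sqA), rep(list(NULL), 24))),
    trackNode("e", 16:40, x = rep(147, 25), y = rep(107, 25),
              masks = c(list(sqB), rep(list(NULL), 24))),
    # gap: g1 ends f10 at (300,300); g2 starts f21 at (310,300)
    mkNode("g1", 0:10, rep(300, 11), rep(300, 11)),
    mkNode("g2", 21:40, rep(310, 20), rep(300, 20)),
    # orphan: isolated 0.6 s fragment far away
    mkNode("o", 100:102, rep(700, 3), rep(100, 3)),
    # split-rejoin: p -> {i1,i2} -> q at (500,500)
    mkNode("p", 0:10, rep(500, 11), rep(500, 11)),
    mkNode("i1", 11:13, rep(498, 3), rep(500, 3)),
    mkNode("i2", 11:13, rep(502, 3), rep(500, 3)),
    mkNode("q", 14:40, rep(500, 27), rep(500, 27)))
  graphFromEdges(nodes, list(c("a", "c"), c("b", "c"), c("c", "d"),
                             c("c", "e"), c("p", "i1"), c("p", "i2"),
                             c("i1", "q"), c("i2", "q")))
}

test_that("one disruption of each class yields one operation of each type", {
  g <- oneOfEachGraph()
  res <- simplifyRecording(g)
  expect_true(res$report$converged)
  expect_identical(unname(res$report$total),
                   c(1L, 1L, 1L, 1L))
  expect_identical(names(res$report$total),
                   c("collisionsResolved", "arcsInferred", "pruned",
                     "consolidated"))
  expect_true(isTRUE(blobConservation(res$graph, graphNodes(g))))
  meta <- recordingMeta(duration = 41 / 5, imageWidth = 1000L,
                        imageHeight = 1000L)
  trails <- extractTrails(res$graph, meta)
  expect_length(trails, 4L)
})

test_that("an already-simplified graph is a fixpoint", {
  g <- buildGraph(list(mkNode("x", 0:100, rep(1, 101), rep(1, 101))))
  res <- simplifyRecording(g)
  expect_true(res$report$converged)
  expect_identical(res$report$nPasses, 1L)
  expect_identical(sum(res$report$total), 0L)
})

test_that("trail extraction walks maximal chains", {
  meta <- recordingMeta(fps = 5, duration = 2)
  # single isolated node spanning the whole recording
  g <- buildGraph(list(mkNode("x", 0:9, 0:9, rep(0, 10))))
  tr <- extractTrails(g, meta)
  expect_length(tr, 1L)
  expect_equal(coverage(tr[[1]]), 1)

  # an unresolved collision node keeps five separate trails
  g <- collisionFixture()
  tr <- extractTrails(g, recordingMeta(duration = 4.2))
  expect_length(tr, 5L)
  expect_setequal(vapply(tr, trailId, character(1)),
                  c("a", "b", "c", "d", "e"))

  # empty graph
  expect_length(extractTrails(buildGraph(list()), meta), 0L)

  # a resolved collision yields two trails through the duplicated node
  case <- collisionCase(g, "c")
  res <- applyResolution(g, case, resolveCollision(case, 100))
  tr <- extractTrails(res$graph, recordingMeta(duration = 4.2))
  expect_length(tr, 2L)
  expect_true(all(vapply(tr, function(t) "c" %in% provenance(t),
                         logical(1))))
})

test_that("coverage statistics summarise trail durations", {
  meta <- recordingMeta(fps = 5, duration = 20)
  mkTrail <- function(id, cov) new("Trail", trailId = id, nodeIds = id,
                                   provenance = id,
                                   blobs = data.frame(
                                     frame = 0:9, time = (0:9) / 5,
                                     x = 1:10, y = 1:10, nodeId = id),
                                   coverage = cov)
  cs <- coverageStats(list(mkTrail("t1", 1)), meta)
  expect_true(all(cs$fractions$fraction == 1))
  cs <- coverageStats(list(mkTrail("t1", 0.95), mkTrail("t2", 0.3)), meta)
  expect_equal(cs$fractions$fraction[cs$fractions$threshold == 0.9], 0.5)
  expect_identical(cs$nShorterThan1min, 2L)
})
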