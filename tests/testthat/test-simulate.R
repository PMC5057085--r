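smallParams <- function(seed, ...) {
  simParams("default", seed = seed, nWorms = 4L, durationS = 20,
            arenaW = 500L, arenaH = 400L, ...)
}

test_that("identical seed and parameters give identical recordings", {
  a <- simulateRecording(smallParams(3))
  b <- simulateRecording(smallParams(3))
  expect_identical(a$nodes, b$nodes)
  expect_identical(a$links@links, b$links@links)
  expect_identical(a$truth@assignment, b$truth@assignment)
  d <- simulateRecording(smallParams(4))
  expect_false(identical(a$nodes, d$nodes))
})

test_that("without corruption or contacts each worm is one full-span node", {
  p <- simParams("default", seed = 5, nWorms = 6L, durationS = 30,
                 arenaW = 2400L, arenaH = 1200L, pSplit = 0, pDropout = 0,
                 placement = "grid")
  sim <- simulateRecording(p)
  expect_length(sim$nodes, 6L)
  expect_identical(nrow(sim$links@links), 0L)
  for (nd in sim$nodes) {
    expect_identical(startFrame(nd), 0L)
    expect_identical(endFrame(nd), 149L)
  }
  # no multi-worm blobs in the truth
  counts <- table(paste(sim$truth@assignment$nodeId,
                        sim$truth@assignment$frame))
  expect_true(all(counts == 1L))
})

test_that("split fragments form motifs that consolidation recovers", {
  p <- simParams("splits", seed = 6, nWorms = 4L, durationS = 30,
                 arenaW = 1200L, arenaH = 900L, pSplit = 0.03,
                 splitMeanS = 0.8, placement = "grid")
  sim <- simulateRecording(p)
  expect_gt(length(sim$nodes), 4L)   # fragmentation happened
  g <- buildGraph(sim$nodes, sim$links)
  res <- simplifyRecording(g)
  expect_gte(unname(res$report$total["consolidated"]), 1L)
  trails <- extractTrails(res$graph, sim$meta)
  rep <- scoreAgainstTruth(trails, sim$truth, sim$meta,
                           audit = res$report$audit)
  expect_identical(rep@idSwitchFraction, 0)
  expect_true(isTRUE(blobConservation(res$graph, sim$nodes)))
})

test_that("a steered crossing produces the two-in/two-out collision motif", {
  found <- FALSE
  for (seed in 1:30) {
    sim <- simulateRecording(simParams("collisions", seed = seed))
    g <- buildGraph(sim$nodes, sim$links)
    flagged <- flagCollisionCandidates(g, 50)
    for (id in flagged) {
      if (!is.null(collisionCase(g, id))) { found <- TRUE; break }
    }
    if (found) break
  }
  expect_true(found)
  # the flagged node carries both identities in the truth
  ws <- unique(sim$truth@assignment$wormId[
    sim$truth@assignment$nodeId == id])
  expect_setequal(ws, c("w1", "w2"))
})

test_that("dropouts inside the caps are recovered by gap inference", {
  p <- simParams("gaps", seed = 7, nWorms = 4L, durationS = 60,
                 arenaW = 2000L, arenaH = 1000L, pDropout = 0.01,
                 dropoutMeanS = 2, placement = "grid")
  sim <- simulateRecording(p)
  expect_gt(nrow(sim$truth@dropouts), 0L)
  g <- buildGraph(sim$nodes, sim$links)
  res <- simplifyRecording(g)
  trails <- extractTrails(res$graph, sim$meta)
  rep <- scoreAgainstTruth(trails, sim$truth, sim$meta,
                           audit = res$report$audit)
  # worms are far apart: every in-cap dropout has a unique best candidate
  expect_identical(rep@gapRecall, 1)
  expect_identical(rep@idSwitchFraction, 0)
  # inferred arcs never bridge out-of-cap dropouts
  A <- inferredArcs(res$graph)
  gd <- sim$truth@dropouts
  far <- gd[!(gd$dtFrames < 50 & gd$ddPx < 50), ]
  for (j in seq_len(nrow(far)))
    expect_false(any(A[, 1] == far$preNode[j] &
                     A[, 2] == far$postNode[j]))
})

test_that("raw fragmentation grows with the corruption rates", {
  frag <- function(pS) {
    mean(vapply(1:20, function(s) {
      sim <- simulateRecording(simParams(
        "splits", seed = 1000 + s, nWorms = 3L, durationS = 15,
        arenaW = 1000L, arenaH = 800L, pSplit = pS, placement = "grid"))
      length(sim$nodes)
    }, numeric(1)))
  }
  expect_gt(frag(0.03), frag(0.003))
  dropFrag <- function(pD) {
    mean(vapply(1:20, function(s) {
      sim <- simulateRecording(simParams(
        "gaps", seed = 2000 + s, nWorms = 3L, durationS = 15,
        arenaW = 1000L, arenaH = 800L, pDropout = pD, placement = "grid"))
      length(sim$nodes)
    }, numeric(1)))
  }
  expect_gt(dropFrag(0.03), dropFrag(0.003))
})

test_that("truth scoring flags deliberately spliced trails", {
  p <- simParams("default", seed = 8, nWorms = 2L, durationS = 20,
                 arenaW = 1500L, arenaH = 500L, pSplit = 0, pDropout = 0,
                 placement = "grid")
  sim <- simulateRecording(p)
  g <- buildGraph(sim$nodes, sim$links)
  trails <- extractTrails(g, sim$meta)
  rep <- scoreAgainstTruth(trails, sim$truth, sim$meta)
  expect_identical(rep@idSwitchFraction, 0)
  expect_true(is.na(rep@collisionResolutionAccuracy))

  # splice both worms into one trail: 1 of 1 trails id-switched
  ids <- names(sim$nodes)
  spliced <- new("Trail", trailId = "x", nodeIds = ids, provenance = ids,
                 blobs = data.frame(frame = 0:1, time = c(0, 0.2),
                                    x = c(0, 1), y = c(0, 1),
                                    nodeId = ids),
                 coverage = 0.5)
  rep <- scoreAgainstTruth(list(spliced), sim$truth, sim$meta)
  expect_identical(rep@idSwitchFraction, 1)

  expect_error(
    scoreAgainstTruth(list(new("Trail", trailId = "x", nodeIds = "zz",
                               provenance = "zz",
                               blobs = data.frame(frame = 0, time = 0,
                                                  x = 0, y = 0,
                                                  nodeId = "zz"),
                               coverage = 0.1)),
                      sim$truth, sim$meta),
    "unknown node")
})

test_that("an all-unresolved audit yields an undefined accuracy", {
  audit <- list(list(node = "c", pre = c("a", "b"), post = c("d", "e"),
                     decision = "unresolved"))
  truth <- new("GroundTruth",
               assignment = data.frame(nodeId = c("a", "b", "d", "e"),
                                       frame = 0L,
                                       wormId = c("w1", "w2", "w1", "w2")),
               trajectories = list(),
               dropouts = data.frame(wormId = character(0),
                                     preNode = character(0),
                                     postNode = character(0),
                                     dtFrames = numeric(0),
                                     ddPx = numeric(0)))
  res <- scoreCollisionAudit(audit, truth)
  expect_identical(res$nDecided, 0L)
  expect_true(is.na(res$accuracy))
})
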