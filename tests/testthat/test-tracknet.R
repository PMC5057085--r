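mk3 <- function() {
  list(mkNode("1", 0:4, 0:4, rep(0, 5)),
       mkNode("2", 5:9, 5:9, rep(0, 5)),
       mkNode("3", 5:9, 5:9, rep(5, 5)))
}

test_that("buildGraph wires one node per track and one arc per link", {
  g <- graphFromEdges(mk3(), list(c("1", "2"), c("1", "3")))
  expect_length(graphNodes(g), 3L)
  expect_identical(nrow(graphArcs(g)), 2L)
  expect_identical(unname(outDegree(g)["1"]), 2L)

  g0 <- buildGraph(mk3())
  ss <- findSourcesSinks(g0)
  expect_setequal(ss$sources, c("1", "2", "3"))
  expect_setequal(ss$sinks, c("1", "2", "3"))

  expect_error(graphFromEdges(mk3(), list(c("1", "2"), c("2", "1"))),
               "cycle")
  expect_error(graphFromEdges(mk3(), list(c("1", "9"))), "unknown")
})

test_that("sources and sinks bracket the identity-loss points", {
  nodes <- lapply(1:5, function(i) mkNode(paste0("n", i), 0:1, c(0, 1),
                                          c(i, i)))
  g <- buildGraph(nodes)
  ss <- findSourcesSinks(g)
  expect_length(ss$sources, 5L)
  expect_length(ss$sinks, 5L)

  chain <- graphFromEdges(
    list(mkNode("1", 0:1, c(0, 1), c(0, 0)), mkNode("2", 2:3, c(2, 3),
                                                    c(0, 0)),
         mkNode("3", 4:5, c(4, 5), c(0, 0))),
    list(c("1", "2"), c("2", "3")))
  ss <- findSourcesSinks(chain)
  expect_identical(ss$sources, "1")
  expect_identical(ss$sinks, "3")

  # the two-animal contact subgraph: two parents into c, two children out
  g <- collisionFixture()
  ss <- findSourcesSinks(g)
  expect_setequal(ss$sources, c("a", "b"))
  expect_setequal(ss$sinks, c("d", "e"))
})

splitRejoin <- function(spanFrames = 10L, fps = 5) {
  # p ends f10; i1,i2 cover f11..(11+spanFrames-1); c follows
  iEnd <- 10L + spanFrames
  graphFromEdges(
    list(mkNode("p", 0:10, 0:10, rep(0, 11), fps = fps),
         mkNode("i1", 11:iEnd, 11:iEnd, rep(-2, spanFrames), fps = fps),
         mkNode("i2", 11:iEnd, 11:iEnd, rep(2, spanFrames), fps = fps),
         mkNode("c", (iEnd + 1):(iEnd + 5), (iEnd + 1):(iEnd + 5),
                rep(0, 5), fps = fps)),
    list(c("p", "i1"), c("p", "i2"), c("i1", "c"), c("i2", "c")))
}

test_that("split-rejoin motifs respect the span cap", {
  # intermediary window 2 s at 5 fps
  g <- splitRejoin(spanFrames = 11L)     # 10 frame span = 2 s
  ms <- findSplitRejoinMotifs(g, maxSpanS = 3)
  expect_length(ms, 1L)
  expect_identical(ms[[1]]$parent, "p")
  expect_setequal(ms[[1]]$intermediaries, c("i1", "i2"))
  expect_identical(ms[[1]]$child, "c")
  expect_equal(ms[[1]]$span, 2)

  g5 <- splitRejoin(spanFrames = 26L)    # 25 frame span = 5 s
  expect_length(findSplitRejoinMotifs(g5, maxSpanS = 3), 0L)
})

test_that("an intermediary with an extra child disqualifies the motif", {
  g <- graphFromEdges(
    list(mkNode("p", 0:2, 0:2, rep(0, 3)),
         mkNode("i1", 3:4, 3:4, rep(-2, 2)),
         mkNode("i2", 3:4, 3:4, rep(2, 2)),
         mkNode("c", 5:6, 5:6, rep(0, 2)),
         mkNode("d", 5:6, 5:6, rep(9, 2))),
    list(c("p", "i1"), c("p", "i2"), c("i2", "c"), c("i1", "c"),
         c("i1", "d")))
  got <- findSplitRejoinMotifs(g, maxSpanS = 3)
  expect_length(got, 0L)
  expect_length(oracleMotifs(g, 3), 0L)
})

test_that("motif finding agrees with exhaustive enumeration on random graphs", {
  set.seed(31)
  for (i in 1:120) {
    g <- randomDag(nNodes = sample(4:12, 1), embedMotif = i %% 2 == 0)
    got <- findSplitRejoinMotifs(g, maxSpanS = 3)
    want <- oracleMotifs(g, 3)
    # compare as (parent, child, intermediary-set) triples; the implementation
    # additionally makes overlapping motifs disjoint, so it returns a subset
    key <- function(m) paste(m$parent, m$child,
                             paste(sort(m$intermediaries), collapse = "+"))
    expect_true(all(vapply(got, key, character(1)) %in%
                    vapply(want, key, character(1))))
    # and every oracle motif not returned must overlap a returned one
    if (length(want) > length(got)) {
      usedIds <- unlist(lapply(got, function(m)
        c(m$parent, m$intermediaries, m$child)))
      for (m in want) {
        if (!key(m) %in% vapply(got, key, character(1)))
          expect_true(any(c(m$parent, m$intermediaries, m$child) %in%
                          usedIds))
      }
    } else {
      expect_identical(sort(vapply(got, key, character(1))),
                       sort(vapply(want, key, character(1))))
    }
  }
})

test_that("merging a chain concatenates its blobs", {
  g <- graphFromEdges(
    list(mkNode("1", 0:2, 0:2, rep(0, 3)), mkNode("2", 3:5, 3:5, rep(0, 3))),
    list(c("1", "2")))
  g2 <- mergeNodes(g, c("1", "2"))
  expect_length(graphNodes(g2), 1L)
  nd <- graphNodes(g2)[[1]]
  expect_identical(nd@frames, 0:5)
  expect_setequal(provenance(g2)[[nodeId(nd)]], c("1", "2"))
})

test_that("same-frame blobs merge by pixel-set union with mass centroid", {
  mA <- squareMask(0, 0, 4)        # 16 px
  mB <- squareMask(2, 0, 4)        # overlaps by 8 px
  g <- graphFromEdges(
    list(trackNode("p", 0, x = 0, y = 0),
         trackNode("i1", 1, x = 1.5, y = 1.5, masks = list(mA)),
         trackNode("i2", 1, x = 3.5, y = 1.5, masks = list(mB)),
         trackNode("c", 2, x = 2, y = 2)),
    list(c("p", "i1"), c("p", "i2"), c("i1", "c"), c("i2", "c")))
  g2 <- mergeNodes(g, c("p", "i1", "i2", "c"))
  nd <- graphNodes(g2)[[1]]
  expect_identical(nd@frames, 0:2)
  i <- match(1L, nd@frames)
  expect_equal(nd@areas[i], 24)    # union, not sum
  u <- maskUnion(list(mA, mB))
  expect_equal(nd@x[i], mean(u[, 1]))
  expect_equal(nd@y[i], mean(u[, 2]))
})

test_that("merging conserves blobs over member frames on random motifs", {
  set.seed(41)
  for (i in 1:20) {
    g <- randomDag(sample(5:10, 1), pArc = 0.3, embedMotif = TRUE)
    ids <- c("n1", "n2", "n3", "n4")   # the embedded split-rejoin motif
    g2 <- tryCatch(mergeNodes(g, ids), error = function(e) NULL)
    if (is.null(g2)) next              # contraction refused (cycle): fine
    mid <- names(which(vapply(provenance(g2), setequal, logical(1), ids)))
    merged <- graphNodes(g2)[[mid[1]]]
    expect_identical(
      sort(unique(unlist(lapply(graphNodes(g)[ids], function(n) n@frames)))),
      as.integer(merged@frames))
    expect_setequal(provenance(g2)[[mid[1]]], ids)
  }
})

test_that("merging two parallel parents of a shared child stays acyclic", {
  g <- graphFromEdges(
    list(mkNode("a", 0:2, 0:2, rep(0, 3)), mkNode("b", 0:2, 0:2, rep(5, 3)),
         mkNode("c", 3:4, 3:4, rep(0, 2))),
    list(c("a", "c"), c("b", "c")))
  expect_error(mergeNodes(g, c("a", "b")), "connected")
  g2 <- mergeNodes(g, c("a", "b", "c"))
  expect_length(graphNodes(g2), 1L)
})

test_that("contraction that would close a cycle is refused", {
  # a -> b -> c and a -> c; merging {a, c} would leave b in a 2-cycle
  g <- graphFromEdges(
    list(mkNode("a", 0:1, 0:1, c(0, 0)), mkNode("b", 2:3, 2:3, c(0, 0)),
         mkNode("c", 4:5, 4:5, c(0, 0))),
    list(c("a", "b"), c("b", "c"), c("a", "c")))
  expect_error(mergeNodes(g, c("a", "c")), "cycle")
})
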