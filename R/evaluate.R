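# Scoring stitched trails against simulator ground truth, replacing the
# manual validation screen: id-switches, undetected collisions, collision
# trails, collision-resolution accuracy and gap-inference recall.

#' Score stitched trails against ground truth
#'
#' A trail is id-switched when it contains single-worm observations from two
#' or more different worms (merged multi-worm observations -- honest
#' collision intervals -- are excluded from this accounting). A trail whose
#' observations are mostly multi-worm is a collision trail; a trail with
#' some multi-worm observations that no collision case ever covered contains
#' an undetected collision. Collision-resolution accuracy is correct /
#' decided over the audit log, and gap recall is the fraction of dropout
#' gaps inside the inference caps whose flanking nodes were stitched into
#' one trail.
#'
#' @param trails list of [Trail-class] objects.
#' @param truth a [GroundTruth-class] from the same recording.
#' @param meta the recording's [RecordingMeta-class].
#' @param audit collision audit list from [simplifyRecording()]'s report
#'   (optional).
#' @param maxGapFrames,maxGapPx the gap-inference caps used, for recall
#'   eligibility (strict, defaults 50 / 50).
#' @return An [EvalReport-class].
#' @export
scoreAgainstTruth <- function(trails, truth, meta, audit = NULL,
                              maxGapFrames = 50L, maxGapPx = 50) {
  asg <- truth@assignment
  wormsOfNode <- split(asg$wormId, asg$nodeId)
  wormsOfNode <- lapply(wormsOfNode, unique)
  framesOfNode <- split(asg$frame, asg$nodeId)
  framesOfNode <- lapply(framesOfNode, unique)
  multiNode <- names(which(vapply(wormsOfNode, length, integer(1)) >= 2L))
  handled <- unique(unlist(lapply(audit, `[[`, "provenance")))

  nT <- length(trails)
  idSwitch <- logical(nT); collTrail <- logical(nT); undet <- logical(nT)
  for (k in seq_len(nT)) {
    pv <- provenance(trails[[k]])
    unknown <- setdiff(pv, names(wormsOfNode))
    if (length(unknown))
      stop("integrity error: trail references unknown node ",
           paste(unknown, collapse = ", "))
    isMulti <- pv %in% multiNode
    singleWorms <- unique(unlist(wormsOfNode[pv[!isMulti]]))
    idSwitch[k] <- length(singleWorms) >= 2L
    nFrMulti <- length(unique(unlist(framesOfNode[pv[isMulti]])))
    nFrAll <- length(unique(unlist(framesOfNode[pv])))
    collTrail[k] <- nFrAll > 0L && nFrMulti > nFrAll / 2
    undet[k] <- !collTrail[k] &&
      length(setdiff(pv[isMulti], handled)) > 0L
  }

  acc <- scoreCollisionAudit(audit, truth)

  gd <- truth@dropouts
  gapRecall <- NA_real_
  if (nrow(gd)) {
    elig <- gd$dtFrames > 0 & gd$dtFrames < maxGapFrames & gd$ddPx < maxGapPx
    if (any(elig)) {
      pvs <- lapply(trails, provenance)
      bridged <- vapply(which(elig), function(i) {
        any(vapply(pvs, function(pv)
          gd$preNode[i] %in% pv && gd$postNode[i] %in% pv, logical(1)))
      }, logical(1))
      gapRecall <- mean(bridged)
    }
  }

  cs <- coverageStats(trails, meta)
  new("EvalReport",
      idSwitchFraction = if (nT) mean(idSwitch) else NA_real_,
      undetectedCollisionFraction = if (nT) mean(undet) else NA_real_,
      collisionTrailFraction = if (nT) mean(collTrail) else NA_real_,
      collisionResolutionAccuracy = acc$accuracy,
      gapRecall = gapRecall, coverage = cs$fractions, nTrails = nT)
}

#' Score a collision audit log against ground truth
#'
#' For every decided case, the chosen pre/post pairing is compared with the
#' true worm identities of the four neighbour nodes. Cases whose truth is
#' ambiguous (a neighbour is itself a multi-worm blob, or the worm sets do
#' not match across the collision) are excluded from the denominator and
#' counted separately.
#'
#' @param audit collision audit list (records with `pre`, `post`,
#'   `decision`).
#' @param truth a [GroundTruth-class].
#' @return list with `nDecided`, `nCorrect`, `nUnscorable`, `accuracy`
#'   (NA when nothing was decided and scorable).
#' @export
scoreCollisionAudit <- function(audit, truth) {
  asg <- truth@assignment
  wormsOfNode <- lapply(split(asg$wormId, asg$nodeId), unique)
  nDecided <- 0L; nCorrect <- 0L; nUnscorable <- 0L
  for (rec in audit) {
    if (is.null(rec$decision) || rec$decision == "unresolved") next
    ws <- lapply(c(rec$pre, rec$post), function(id) wormsOfNode[[id]])
    if (any(vapply(ws, function(w) length(w) != 1L, logical(1))) ||
        !setequal(c(ws[[1L]], ws[[2L]]), c(ws[[3L]], ws[[4L]])) ||
        ws[[1L]] == ws[[2L]]) {
      nUnscorable <- nUnscorable + 1L
      next
    }
    nDecided <- nDecided + 1L
    straight <- identical(ws[[1L]], ws[[3L]])
    if ((rec$decision == "straight") == straight)
      nCorrect <- nCorrect + 1L
  }
  list(nDecided = nDecided, nCorrect = nCorrect, nUnscorable = nUnscorable,
       accuracy = if (nDecided) nCorrect / nDecided else NA_real_)
}

#' Bulk collision-resolution accuracy experiment
#'
#' Generates two-worm crossing recordings with the "collisions" preset,
#' flags collision candidates, resolves each clean two-in/two-out case by
#' pixel-overlap voting, and scores every decision against ground truth.
#' Recordings in which no collision motif is flagged (the worms missed each
#' other) are discarded; generation continues until `casesPerSeed` flagged
#' recordings per seed stream or the attempt cap is reached.
#'
#' @param seeds integer vector of seed streams.
#' @param casesPerSeed flagged collision recordings to collect per seed.
#' @param overlapThreshold collision score margin, pixels.
#' @param bodyLengthPx body length, pixels.
#' @param maxAttemptsFactor attempt cap as a multiple of `casesPerSeed`.
#' @return list with `nCases` (flagged collision cases), `nDecided`,
#'   `nCorrect`, `nUnresolved`, `nUnscorable`, `accuracy` (fraction) and
#'   `accuracyPct`.
#' @export
collisionAccuracyExperiment <- function(seeds = 0:9, casesPerSeed = 100L,
                                        overlapThreshold = 100,
                                        bodyLengthPx = 50,
                                        maxAttemptsFactor = 8L) {
  nCases <- 0L; nDecided <- 0L; nCorrect <- 0L
  nUnresolved <- 0L; nUnscorable <- 0L
  for (s in seeds) {
    got <- 0L; attempt <- 0L
    while (got < casesPerSeed && attempt < maxAttemptsFactor * casesPerSeed) {
      attempt <- attempt + 1L
      sd <- s * 10000L + attempt
      sim <- simulateRecording(simParams("collisions", seed = sd))
      g <- buildGraph(sim$nodes, sim$links)
      flagged <- flagCollisionCandidates(g, bodyLengthPx)
      audit <- list()
      for (id in flagged) {
        case <- collisionCase(g, id)
        if (is.null(case)) next
        out <- resolveCollision(case, overlapThreshold)
        audit[[length(audit) + 1L]] <- list(
          node = id, pre = case@pre, post = case@post,
          decision = out@decision)
      }
      if (!length(audit)) next
      got <- got + 1L
      nCases <- nCases + length(audit)
      res <- scoreCollisionAudit(audit, sim$truth)
      nDecided <- nDecided + res$nDecided
      nCorrect <- nCorrect + res$nCorrect
      nUnscorable <- nUnscorable + res$nUnscorable
      nUnresolved <- nUnresolved +
        sum(vapply(audit, function(a) a$decision == "unresolved",
                   logical(1)))
    }
  }
  acc <- if (nDecided) nCorrect / nDecided else NA_real_
  list(nCases = nCases, nDecided = nDecided, nCorrect = nCorrect,
       nUnresolved = nUnresolved, nUnscorable = nUnscorable,
       accuracy = acc, accuracyPct = 100 * acc)
}
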