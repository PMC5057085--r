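# Unified configuration and the chained simulate -> simplify -> evaluate ->
# motility pipeline. Precedence for the command-line tool is flags > config
# file > defaults; every run stamps a provenance block (config, seed,
# package version) into its output headers.

#' Default pipeline configuration
#'
#' All tunables of every stage with their conventional defaults: 50-frame /
#' 50-pixel gap caps, 100-pixel collision overlap margin, 1 s pruning, 3 s
#' consolidation, 50 px body length, 5 fps.
#'
#' @return named list of class `wormtrailsConfig`.
#' @export
defaultConfig <- function() {
  cfg <- list(
    preset = "default", seed = 0L,
    nWorms = 10L, durationS = 120, fps = 5,
    arenaW = 1250L, arenaH = 750L, bodyLengthPx = 50,
    maxGapFrames = 50L, maxGapPx = 50, overlapThreshold = 100,
    pruneMaxS = 1, consolidateMaxS = 3, maxPasses = 10L,
    maxInterpGapS = 1, posWindowS = 1, speedWindowS = 60,
    binS = 60, minTrailS = 60,
    activeMinThreshold = 5, activeSpeedThreshold = 1,
    windows = "0-30,30-90,90-180")
  class(cfg) <- "wormtrailsConfig"
  cfg
}

#' Validate a pipeline configuration
#'
#' Unknown keys are rejected; numeric constraints are checked before any
#' computation.
#'
#' @param config a named list (e.g. from [defaultConfig()] or
#'   [readConfig()]).
#' @return The validated config (invisibly usable), or an error.
#' @export
validateConfig <- function(config) {
  ref <- defaultConfig()
  unknown <- setdiff(names(config), names(ref))
  if (length(unknown))
    stop("unknown config key: ", paste(unknown, collapse = ", "))
  full <- ref
  full[names(config)] <- config
  with(full, {
    stopifnot(maxGapFrames > 0, maxGapPx > 0, overlapThreshold > 0,
              pruneMaxS > 0, consolidateMaxS > 0, bodyLengthPx > 0,
              fps > 0, maxPasses >= 1, nWorms >= 1, durationS > 0)
  })
  class(full) <- "wormtrailsConfig"
  full
}

#' Read / write a configuration file (YAML)
#'
#' @param path file path.
#' @return For `readConfig`, the validated config list.
#' @export
readConfig <- function(path) {
  validateConfig(yaml::read_yaml(path))
}

#' @rdname readConfig
#' @param config a config list.
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.parseWindows <- function(s) {
  lapply(strsplit(strsplit(s, ",")[[1L]], "-"),
         function(p) as.numeric(p))
}

#' Write / read ground truth (JSON lines)
#'
#' Simulator-only identity oracle serialization: per-(node, worm) frame
#' arrays, true per-worm trajectories, and dropout events.
#'
#' @param truth a [GroundTruth-class].
#' @param path file path.
#' @export
writeGroundTruth <- function(truth, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  wl <- function(x) writeLines(.jsonLine(x), con, useBytes = TRUE)
  wl(list(type = "truth", worms = names(truth@trajectories)))
  asg <- truth@assignment
  key <- paste(asg$nodeId, asg$wormId, sep = "\r")
  for (k in unique(key)) {
    rows <- asg[key == k, ]
    wl(list(type = "assign", node = rows$nodeId[1L], worm = rows$wormId[1L],
            frames = rows$frame))
  }
  for (w in names(truth@trajectories)) {
    tr <- truth@trajectories[[w]]
    wl(list(type = "traj", worm = w, frame = tr$frame, x = tr$x, y = tr$y,
            time = tr$time))
  }
  d <- truth@dropouts
  for (i in seq_len(nrow(d)))
    wl(list(type = "dropout", worm = d$wormId[i], pre = d$preNode[i],
            post = d$postNode[i], dt = d$dtFrames[i], dd = d$ddPx[i]))
  invisible(path)
}

#' @rdname writeGroundTruth
#' @return For `readGroundTruth`, a [GroundTruth-class].
#' @export
readGroundTruth <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  recs <- lapply(lines[nzchar(lines)], jsonlite::fromJSON)
  types <- vapply(recs, `[[`, character(1), "type")
  a <- recs[types == "assign"]
  assignment <- if (length(a)) {
    do.call(rbind, lapply(a, function(r)
      data.frame(nodeId = r$node, frame = as.integer(r$frames),
                 wormId = r$worm, stringsAsFactors = FALSE)))
  } else {
    data.frame(nodeId = character(0), frame = integer(0),
               wormId = character(0))
  }
  tj <- recs[types == "traj"]
  traj <- lapply(tj, function(r)
    data.frame(frame = as.integer(r$frame), time = as.numeric(r$time),
               x = as.numeric(r$x), y = as.numeric(r$y)))
  names(traj) <- vapply(tj, `[[`, character(1), "worm")
  dr <- recs[types == "dropout"]
  dropouts <- if (length(dr)) {
    do.call(rbind, lapply(dr, function(r)
      data.frame(wormId = r$worm, preNode = r$pre, postNode = r$post,
                 dtFrames = as.numeric(r$dt), ddPx = as.numeric(r$dd),
                 stringsAsFactors = FALSE)))
  } else {
    data.frame(wormId = character(0), preNode = character(0),
               postNode = character(0), dtFrames = numeric(0),
               ddPx = numeric(0))
  }
  new("GroundTruth", assignment = assignment, trajectories = traj,
      dropouts = dropouts)
}

#' Run the chained pipeline
#'
#' Executes the requested stages in order on one configuration: simulate a
#' recording, simplify it into trails, evaluate against ground truth, and
#' compute motility profiles. Every output carries a provenance block
#' (config, seed, package version). Identical config and seed give
#' identical outputs.
#'
#' @param config a config list (see [defaultConfig()]); validated first.
#' @param outDir output directory (created if needed).
#' @param stages subset of c("simulate", "simplify", "evaluate",
#'   "motility"), in pipeline order.
#' @param recordingPath input recording when the simulate stage is skipped.
#' @param truthPath input ground truth when the simulate stage is skipped.
#' @return Invisibly, a list with the in-memory stage results and the paths
#'   of all written artifacts.
#' @export
runPipeline <- function(config = defaultConfig(), outDir = ".",
                        stages = c("simulate", "simplify", "evaluate",
                                   "motility"),
                        recordingPath = NULL, truthPath = NULL) {
  config <- validateConfig(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  prov <- list(package = "wormtrails",
               version = as.character(utils::packageVersion("wormtrails")),
               seed = config$seed, config = unclass(config))
  paths <- list()
  rec <- NULL; truth <- NULL
  if ("simulate" %in% stages) {
    params <- simParams(config$preset, seed = config$seed,
                        nWorms = config$nWorms, durationS = config$durationS,
                        fps = config$fps, arenaW = config$arenaW,
                        arenaH = config$arenaH,
                        bodyLengthPx = config$bodyLengthPx)
    sim <- simulateRecording(params)
    rec <- sim; truth <- sim$truth
    paths$recording <- file.path(outDir, "rec.jsonl")
    writeRecording(sim$nodes, sim$links, sim$meta, paths$recording,
                   provenance = prov)
    paths$truth <- file.path(outDir, "truth.jsonl")
    writeGroundTruth(truth, paths$truth)
  } else if (!is.null(recordingPath)) {
    r <- readRecording(recordingPath)
    rec <- list(nodes = r$nodes, links = r$links, meta = r$meta)
    if (!is.null(truthPath)) truth <- readGroundTruth(truthPath)
  }
  simp <- NULL; trails <- NULL
  if ("simplify" %in% stages) {
    if (is.null(rec)) stop("simplify stage needs a recording")
    g <- buildGraph(rec$nodes, rec$links)
    simp <- simplifyRecording(g, stitchParams(
      overlapThreshold = config$overlapThreshold,
      maxGapFrames = config$maxGapFrames, maxGapPx = config$maxGapPx,
      pruneMaxS = config$pruneMaxS,
      consolidateMaxS = config$consolidateMaxS,
      bodyLengthPx = config$bodyLengthPx, maxPasses = config$maxPasses))
    trails <- extractTrails(simp$graph, rec$meta)
    paths$trails <- file.path(outDir, "trails.jsonl")
    writeRecording(graphNodes(simp$graph), linkTable(), rec$meta,
                   paths$trails, trails = trails, provenance = prov)
    paths$report <- file.path(outDir, "report.json")
    cs <- coverageStats(trails, rec$meta)
    jsonlite::write_json(
      list(passes = lapply(simp$report$passes, as.list),
           total = as.list(simp$report$total),
           converged = simp$report$converged,
           unresolvedCollisions = vapply(simp$report$unresolved,
                                         `[[`, character(1), "node"),
           coverage = cs$fractions,
           nTrails = cs$nTrails,
           nShorterThan1min = cs$nShorterThan1min,
           provenance = prov),
      paths$report, auto_unbox = TRUE, digits = NA)
  }
  evalRep <- NULL
  if ("evaluate" %in% stages && !is.null(truth) && !is.null(trails)) {
    evalRep <- scoreAgainstTruth(trails, truth, rec$meta,
                                 audit = simp$report$audit,
                                 maxGapFrames = config$maxGapFrames,
                                 maxGapPx = config$maxGapPx)
    paths$eval <- file.path(outDir, "eval.json")
    jsonlite::write_json(
      list(idSwitchFraction = evalRep@idSwitchFraction,
           undetectedCollisionFraction = evalRep@undetectedCollisionFraction,
           collisionTrailFraction = evalRep@collisionTrailFraction,
           collisionResolutionAccuracy = evalRep@collisionResolutionAccuracy,
           gapRecall = evalRep@gapRecall,
           nTrails = evalRep@nTrails,
           coverage = evalRep@coverage,
           provenance = prov),
      paths$eval, auto_unbox = TRUE, digits = NA, na = "null")
  }
  profile <- NULL
  if ("motility" %in% stages && !is.null(trails)) {
    profs <- lapply(trails, speedProfile, fps = config$fps,
                    maxGapS = config$maxInterpGapS,
                    posWindowS = config$posWindowS,
                    speedWindowS = config$speedWindowS)
    profile <- binSpeeds(profs, binS = config$binS,
                         minTrailS = config$minTrailS)
    paths$profile <- file.path(outDir, "profile.csv")
    utils::write.csv(profile, paths$profile, row.names = FALSE)
    cls <- do.call(rbind, lapply(profs, function(p) {
      d <- classifyActivity(p, windows = .parseWindows(config$windows),
                            activeMinThreshold = config$activeMinThreshold,
                            activeSpeedThreshold =
                              config$activeSpeedThreshold)
      cbind(trailId = p@id, d)
    }))
    paths$classification <- file.path(outDir, "classification.tsv")
    utils::write.table(cls, paths$classification, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(list(recording = rec, simplified = simp, trails = trails,
                 evaluation = evalRep, profile = profile, paths = paths))
}
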