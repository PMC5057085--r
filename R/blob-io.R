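# Reader/writer for the canonical recording format: UTF-8 JSON lines.
# Line 1 is a meta header; then one object per blob, then link records, and
# optionally trail records. This dialect is the single supported input;
# native tracker output is converted externally.

.jsonLine <- function(x) {
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
}

#' Write a recording to the canonical JSON-lines format
#'
#' @param nodes list of [TrackNode-class] objects.
#' @param links a [LinkTable-class].
#' @param meta a [RecordingMeta-class].
#' @param path output file path.
#' @param trails optional list of [Trail-class] objects appended as trail
#'   records.
#' @param provenance optional named list recorded verbatim in the header
#'   (e.g. config hash, seed, package version).
#' @return `path`, invisibly.
#' @export
writeRecording <- function(nodes, links, meta, path, trails = NULL,
                           provenance = NULL) {
  stopifnot(is(meta, "RecordingMeta"), is(links, "LinkTable"))
  header <- list(type = "meta", fps = meta@fps,
                 image_width = meta@imageWidth,
                 image_height = meta@imageHeight,
                 body_length_px = meta@bodyLengthPx,
                 duration = meta@duration)
  if (!is.null(provenance)) header$provenance <- provenance
  con <- file(path, open = "wb")
  on.exit(close(con))
  wl <- function(s) writeLines(s, con, useBytes = TRUE)
  wl(.jsonLine(header))
  for (nd in nodes) {
    validObject(nd)
    for (i in seq_len(nBlobs(nd))) {
      rec <- list(type = "blob", node_id = nd@nodeId,
                  frame = nd@frames[i], time = nd@times[i],
                  x = nd@x[i], y = nd@y[i])
      if (!is.null(nd@masks[[i]])) {
        rec$mask <- unname(nd@masks[[i]])
      } else if (!is.na(nd@areas[i])) {
        rec$area <- nd@areas[i]
      }
      wl(.jsonLine(rec))
    }
  }
  L <- links@links
  for (i in seq_len(nrow(L)))
    wl(.jsonLine(list(type = "link", parent = L[i, 1L], child = L[i, 2L])))
  for (tr in trails)
    wl(.jsonLine(list(type = "trail", trail_id = tr@trailId,
                      node_ids = tr@nodeIds, coverage = tr@coverage)))
  invisible(path)
}

#' Read a recording from the canonical JSON-lines format
#'
#' Every blob record becomes exactly one observation attached to its track
#' node; nodes are frame-sorted. Malformed lines raise a parse error naming
#' the line number; duplicate (node, frame) pairs and links referencing
#' unknown nodes raise integrity errors.
#'
#' @param path file path.
#' @return A list with elements `nodes` (named list of [TrackNode-class]),
#'   `links` ([LinkTable-class]), `meta` ([RecordingMeta-class]) and
#'   `trails` (list of trail records, usually empty).
#' @export
readRecording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("parse error at line 1: empty file")
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    recs[[i]] <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
      error = function(e)
        stop("parse error at line ", i, ": ", conditionMessage(e),
             call. = FALSE))
  }
  if (!identical(recs[[1L]]$type, "meta"))
    stop("parse error at line 1: first record must be the meta header")
  h <- recs[[1L]]
  meta <- recordingMeta(fps = h$fps, imageWidth = h$image_width,
                        imageHeight = h$image_height,
                        bodyLengthPx = h$body_length_px,
                        duration = h$duration)
  types <- vapply(recs, function(r) r$type %||% "", character(1))
  bl <- recs[types == "blob"]
  ids <- vapply(bl, function(r) as.character(r$node_id), character(1))
  nodes <- list()
  for (id in unique(ids)) {
    rs <- bl[ids == id]
    frames <- vapply(rs, function(r) as.integer(r$frame), integer(1))
    if (anyDuplicated(frames))
      stop("integrity error: duplicate (node_id, frame) for node ", id)
    masks <- lapply(rs, function(r) {
      if (is.null(r$mask)) return(NULL)
      m <- r$mask
      if (!is.matrix(m)) m <- matrix(as.integer(m), ncol = 2L, byrow = TRUE)
      storage.mode(m) <- "integer"
      colnames(m) <- c("x", "y")
      m
    })
    areas <- vapply(rs, function(r) {
      if (!is.null(r$mask)) NA_real_ else (r$area %||% NA_real_)
    }, numeric(1))
    hasMask <- !vapply(masks, is.null, logical(1))
    areas[hasMask] <- vapply(masks[hasMask], nrow, integer(1))
    nodes[[id]] <- trackNode(
      nodeId = id, frames = frames,
      times = vapply(rs, function(r) as.numeric(r$time), numeric(1)),
      x = vapply(rs, function(r) as.numeric(r$x), numeric(1)),
      y = vapply(rs, function(r) as.numeric(r$y), numeric(1)),
      masks = masks, areas = areas)
  }
  lk <- recs[types == "link"]
  parent <- vapply(lk, function(r) as.character(r$parent), character(1))
  child <- vapply(lk, function(r) as.character(r$child), character(1))
  unknown <- setdiff(c(parent, child), names(nodes))
  if (length(unknown))
    stop("integrity error: link references unknown node ",
         paste(unknown, collapse = ", "))
  list(nodes = nodes, links = linkTable(parent, child), meta = meta,
       trails = recs[types == "trail"])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
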