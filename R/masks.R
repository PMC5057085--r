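# Pixel-mask primitives. Masks are 2-column integer matrices of (x, y)
# coordinates, 0-based, treated as sets (duplicates ignored).

# Coordinates are bounded by image sizes well under 2^15, so a pixel packs
# into one integer key.
.maskKey <- function(m) m[, 1L] * 32768L + m[, 2L]

#' Count overlapping pixels between two masks
#'
#' The core collision-resolution primitive: the number of pixels shared by
#' two blob masks, an exact set intersection. Symmetric, and never larger
#' than the smaller mask.
#'
#' @param a,b 2-column integer matrices of (x, y) pixel coordinates; either
#'   may be empty or NULL.
#' @return Integer pixel count `|a intersect b|`.
#' @examples
#' sq <- as.matrix(expand.grid(x = 0:9, y = 0:9))
#' maskOverlap(sq, sq)                      # 100
#' maskOverlap(sq, cbind(sq[, 1] + 5, sq[, 2]))  # 50
#' @export
maskOverlap <- function(a, b) {
  if (is.null(a) || is.null(b) || nrow(a) == 0L || nrow(b) == 0L)
    return(0L)
  length(intersect(unique(.maskKey(a)), unique(.maskKey(b))))
}

# TRUE when the two masks touch within a 1-pixel (Chebyshev) dilation:
# the segmenter-contact criterion for merging worms into one blob.
maskTouch <- function(a, b) {
  if (is.null(a) || is.null(b) || nrow(a) == 0L || nrow(b) == 0L)
    return(FALSE)
  if (min(a[, 1L]) > max(b[, 1L]) + 1L || min(b[, 1L]) > max(a[, 1L]) + 1L ||
      min(a[, 2L]) > max(b[, 2L]) + 1L || min(b[, 2L]) > max(a[, 2L]) + 1L)
    return(FALSE)
  ka <- .maskKey(a)
  kb <- .maskKey(b)
  sh <- as.integer(outer(c(-1L, 0L, 1L) * 32768L, c(-1L, 0L, 1L), `+`))
  any(outer(kb, sh, `+`) %in% ka)
}

maskUnion <- function(masks) {
  masks <- masks[!vapply(masks, is.null, logical(1))]
  if (!length(masks)) return(NULL)
  m <- do.call(rbind, masks)
  m[!duplicated(.maskKey(m)), , drop = FALSE]
}

maskCentroid <- function(m) c(x = mean(m[, 1L]), y = mean(m[, 2L]))

# Render a capsule (a segment of total extent `len` thickened to `width`)
# as the set of integer pixels within width/2 of the segment, clipped to the
# image. The simplest body shape that supports exact overlap voting; the
# per-pixel distance scan lives in src/render.cpp.
renderCapsule <- function(cx, cy, theta, len = 50, width = 5,
                          imageW = NULL, imageH = NULL) {
  .renderCapsuleCpp(cx, cy, theta, len, width,
                    if (is.null(imageW)) 0 else imageW,
                    if (is.null(imageH)) 0 else imageH,
                    !is.null(imageW))
}
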