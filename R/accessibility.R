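#' Flag and exclude stream segments overlapping glacier ice
#'
#' A present-day DEM represents the ice surface, not terrain, wherever a
#' glacier sits; stream segments with at least one path cell inside any
#' glacier footprint are therefore flagged `overlapsIce` and excluded from
#' the present-day network (they remain in the table so the drainage
#' topology stays intact for tracing).
#'
#' @param segments a segment table (see [segmentReaches()]).
#' @param glaciers a [GlacierSet-class] on the same grid.
#' @return The segment table with `overlapsIce` set.
#' @export
removeIceOverlap <- function(segments, glaciers) {
  stopifnot(is(glaciers, "GlacierSet"))
  if (nrow(segments) == 0 || nrow(glacierTable(glaciers)) == 0)
    return(segments)
  dims <- gridDim(glaciers)
  ice <- logical(prod(dims))
  ice[unlist(glacierFootprints(glaciers), use.names = FALSE)] <- TRUE
  nr <- dims[1]
  segments$overlapsIce <- vapply(segments$path, function(p)
    any(ice[.linIndex(p[, 1], p[, 2], nr)]), logical(1))
  segments
}

#' Trace the salmon-accessible network under a gradient threshold
#'
#' A segment is accessible when its own gradient is strictly below the
#' threshold and every segment on its unique path to the outlet is also
#' below the threshold (contiguous tracing from the river mouth toward the
#' headwaters; a single steeper segment is a barrier for everything
#' upstream). Ties at exactly the threshold are barriers. Segments flagged
#' `overlapsIce` or invalid are not traversable.
#'
#' @param segments a segment table with gradients attributed.
#' @param threshold migration gradient threshold as a fraction in (0, 1)
#'   (0.10 conservative, 0.15 inclusive).
#' @param keep logical vector of traversable segments; defaults to valid,
#'   ice-free segments.
#' @return A list with `accessible` (segment ids) and `limits` (ids of the
#'   most-upstream accessible segment on each headwater path: the upper
#'   limits of salmon migration).
#' @examples
#' # a mouth-to-head chain with gradients 2%, 8%, 12%, 3% has two
#' # accessible segments at the 10% threshold (the 12% barrier blocks the
#' # 3% segment) and four at 15%
#' @export
traceAccessible <- function(segments, threshold,
                            keep = segments$valid & !segments$overlapsIce) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must be a fraction in (0, 1)")
  n <- nrow(segments)
  if (n == 0) return(list(accessible = integer(0), limits = integer(0)))
  down <- match(segments$downSeg, segments$segId)
  orphan <- !is.na(segments$downSeg) & is.na(down)
  if (any(orphan))
    stop("disconnected segment(s): ",
         paste(segments$segId[orphan], collapse = ", "))
  passes <- keep & !is.na(segments$gradient) &
    segments$gradient < threshold
  acc <- logical(n)
  children <- split(seq_len(n), factor(down, levels = seq_len(n)))
  roots <- which(is.na(down))
  acc[roots] <- passes[roots]
  queue <- roots[acc[roots]]
  while (length(queue) > 0) {
    i <- queue[1]; queue <- queue[-1]
    kids <- children[[i]]
    if (length(kids) > 0) {
      ok <- kids[passes[kids]]
      acc[ok] <- TRUE
      queue <- c(queue, ok)
    }
  }
  hasAccUp <- logical(n)
  up <- down[acc[seq_len(n)] & !is.na(down)]
  hasAccUp[up] <- TRUE
  list(accessible = segments$segId[acc],
       limits = segments$segId[acc & !hasAccUp])
}

# contact points where the accessible network is truncated by ice: the
# shared endpoint cell between an accessible ice-free segment and the
# ice-overlapping segment immediately upstream of it
.truncationTips <- function(segments, accessibleIds) {
  nrGrid <- NULL
  accSet <- segments$segId %in% accessibleIds
  downPos <- match(segments$downSeg, segments$segId)
  tips <- integer(0)
  for (i in which(segments$overlapsIce)) {
    d <- downPos[i]
    if (!is.na(d) && accSet[d]) {
      p <- segments$path[[i]]
      tips <- c(tips, c(r = p[nrow(p), 1], c = p[nrow(p), 2]))
    }
  }
  if (length(tips) == 0) return(matrix(integer(0), ncol = 2))
  matrix(tips, ncol = 2, byrow = TRUE, dimnames = list(NULL, c("r", "c")))
}

#' Identify salmon-accessible glaciers
#'
#' A glacier is accessible when the gradient-constrained present-day network
#' reaches its ice ("butted against" the migration-constrained network).
#' Because ice removal happens at whole-segment granularity, the truncated
#' segment straddling the ice margin can extend a segment length beyond the
#' outline, so contact is assessed along the drainage: a glacier is
#' accessible when a segment overlapping its footprint drains directly into
#' a kept, accessible segment. A secondary geometric test also accepts a
#' glacier whose footprint boundary lies within `adjacencyRadius` of a
#' truncation tip (the kept endpoint of the accessible network), covering
#' ice abutting the network without overlapping any segment. A glacier
#' reachable via several tributaries is counted once.
#'
#' @param segments a segment table with `overlapsIce` set (see
#'   [removeIceOverlap()]).
#' @param accessibleIds accessible segment ids from [traceAccessible()].
#' @param glaciers a [GlacierSet-class].
#' @param adjacencyRadius contact tolerance in metres between a truncated
#'   network tip and the glacier footprint boundary; default 60 m (2 cells
#'   at 30 m resolution).
#' @return Character vector of accessible glacier ids.
#' @export
findAccessibleGlaciers <- function(segments, accessibleIds, glaciers,
                                   adjacencyRadius = 60) {
  stopifnot(is(glaciers, "GlacierSet"))
  tb <- glacierTable(glaciers)
  if (nrow(tb) == 0 || nrow(segments) == 0) return(character(0))
  dims <- gridDim(glaciers)
  cs <- cellSize(glaciers)
  nr <- dims[1]
  fp <- glacierFootprints(glaciers)
  accSet <- segments$segId %in% accessibleIds
  downPos <- match(segments$downSeg, segments$segId)
  kept <- segments$valid & !segments$overlapsIce
  tips <- .truncationTips(segments, accessibleIds)
  ice <- logical(prod(dims))
  for (cells in fp) ice[cells] <- TRUE
  out <- character(0)
  for (g in seq_len(nrow(tb))) {
    cells <- fp[[g]]
    inG <- logical(prod(dims)); inG[cells] <- TRUE
    # drainage contact: an overlapping segment whose downstream segment is
    # kept and accessible
    reached <- FALSE
    for (i in which(segments$overlapsIce)) {
      p <- segments$path[[i]]
      if (!any(inG[.linIndex(p[, 1], p[, 2], nr)])) next
      d <- downPos[i]
      if (!is.na(d) && kept[d] && accSet[d]) { reached <- TRUE; break }
    }
    # geometric contact: truncation tip within adjacencyRadius of the
    # footprint boundary
    if (!reached && nrow(tips) > 0) {
      r <- .rowOf(cells, nr); c <- .colOf(cells, nr)
      onBoundary <- logical(length(cells))
      for (k in 1:8) {
        rr <- r + .d8offsets[k, 1]; cc <- c + .d8offsets[k, 2]
        inside <- rr >= 1 & rr <= dims[1] & cc <= dims[2] & cc >= 1
        nb <- rep(FALSE, length(cells))
        nb[inside] <- !ice[.linIndex(rr[inside], cc[inside], nr)]
        onBoundary <- onBoundary | !inside | nb
      }
      br <- r[onBoundary]; bc <- c[onBoundary]
      for (t in seq_len(nrow(tips))) {
        d2 <- (br - tips[t, 1])^2 + (bc - tips[t, 2])^2
        if (min(d2) * cs^2 <= adjacencyRadius^2 + 1e-9) {
          reached <- TRUE
          break
        }
      }
    }
    if (reached) out <- c(out, tb$id[g])
  }
  out
}

#' Compare accessibility between gradient thresholds
#'
#' Evaluates the accessible network and the accessible-glacier set at each
#' threshold on one landscape. Counts and areas are monotone in the
#' threshold: the 15% set always contains the 10% set.
#'
#' @param segments a segment table with gradients and `overlapsIce` set.
#' @param glaciers a [GlacierSet-class].
#' @param thresholds gradient thresholds to compare (fractions); default the
#'   conservative/inclusive pair `c(0.10, 0.15)`.
#' @param adjacencyRadius see [findAccessibleGlaciers()].
#' @return data.frame with one row per threshold: `threshold`, `nGlaciers`,
#'   `glacierAreaKm2`, `accessibleKm`.
#' @export
thresholdComparison <- function(segments, glaciers,
                                thresholds = c(0.10, 0.15),
                                adjacencyRadius = 60) {
  tb <- glacierTable(glaciers)
  rows <- lapply(thresholds, function(th) {
    tr <- traceAccessible(segments, th)
    gl <- findAccessibleGlaciers(segments, tr$accessible, glaciers,
                                 adjacencyRadius)
    data.frame(threshold = th, nGlaciers = length(gl),
               glacierAreaKm2 = sum(tb$areaKm2[tb$id %in% gl]),
               accessibleKm = sum(segments$length_m[
                 segments$segId %in% tr$accessible]) / 1000)
  })
  do.call(rbind, rows)
}
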