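#' Assign Strahler orders to a stream network
#'
#' Headwater reaches have order 1. At a junction the downstream reach takes
#' the maximum of the inflowing orders, incremented by one when that maximum
#' is attained by two or more inflows. Orders are therefore non-decreasing
#' downstream.
#'
#' @param net a [StreamNetwork-class] (acyclic, as produced by
#'   [extractStreams()]).
#' @return The network with the `order` column of [reaches()] filled in.
#' @export
strahlerOrder <- function(net) {
  stopifnot(is(net, "StreamNetwork"))
  rt <- reaches(net)
  n <- nrow(rt)
  if (n == 0) return(net)
  ord <- rep(NA_integer_, n)
  inflows <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- rt$toReach[i]
    if (!is.na(tr)) inflows[[tr]] <- c(inflows[[tr]], i)
  }
  nIn <- lengths(inflows)
  pending <- nIn
  queue <- which(pending == 0L)
  done <- 0L
  while (length(queue) > 0) {
    i <- queue[1]; queue <- queue[-1]
    ins <- inflows[[i]]
    if (length(ins) == 0) {
      ord[i] <- 1L
    } else {
      o <- ord[ins]
      m <- max(o)
      ord[i] <- m + as.integer(sum(o == m) >= 2L)
    }
    done <- done + 1L
    tr <- rt$toReach[i]
    if (!is.na(tr)) {
      pending[tr] <- pending[tr] - 1L
      if (pending[tr] == 0L) queue <- c(queue, tr)
    }
  }
  if (done != n) stop("cycle detected in stream network; cannot order")
  rt$order <- ord
  initialize(net, reaches = rt)
}

#' Break network reaches into ~equal-length segments
#'
#' Reaches are cut at junctions first (a segment never spans a junction) and
#' each reach is then subdivided into `ceiling(length / targetLength)` pieces
#' of near-equal along-path length, with cut points snapped to cell
#' boundaries. A reach shorter than the target yields a single segment, so
#' segment lengths tile each reach exactly: the summed segment length equals
#' the summed reach length at every target length.
#'
#' @param net an ordered [StreamNetwork-class] (see [strahlerOrder()]).
#' @param targetLength target segment length in metres (default 500 m, the
#'   nominal gradient-analysis scale); must be at least `2 * cellSize`.
#' @return A segment table (`data.frame`) with one row per segment:
#'   `segId`, `reachId`, `downSeg` (segment immediately downstream, `NA` at
#'   the outlet), `order`, `length_m`, and a `path` list column of (row, col)
#'   cell paths (upstream to downstream, endpoints shared with neighboring
#'   segments). Gradient columns are filled by [attributeGradient()].
#' @export
segmentReaches <- function(net, targetLength = 500) {
  stopifnot(is(net, "StreamNetwork"))
  if (!is.numeric(targetLength) || targetLength <= 0)
    stop("targetLength must be positive")
  cs <- cellSize(net)
  if (targetLength < 2 * cs)
    stop("targetLength must be at least 2 * cellSize (", 2 * cs, " m)")
  rt <- reaches(net)
  paths <- reachPaths(net)
  segRows <- vector("list", nrow(rt))
  firstSegOf <- integer(nrow(rt))
  segCount <- 0L
  for (i in seq_len(nrow(rt))) {
    p <- paths[[i]]
    steps <- .stepLengths(p, cs)
    L <- sum(steps)
    nSeg <- max(1L, as.integer(ceiling(L / targetLength - 1e-9)))
    nSteps <- length(steps)
    nSeg <- min(nSeg, nSteps)  # cannot cut finer than one step per segment
    cuts <- integer(0)
    if (nSeg > 1) {
      cum <- cumsum(steps)
      target <- L * seq_len(nSeg - 1) / nSeg
      cuts <- vapply(target, function(b) which.min(abs(cum - b)), integer(1))
      # enforce strictly increasing interior cuts (>= 1 step per segment)
      for (k in seq_along(cuts))
        cuts[k] <- max(cuts[k], if (k == 1) 1L else cuts[k - 1] + 1L)
      for (k in rev(seq_along(cuts)))
        cuts[k] <- min(cuts[k], nSteps - (length(cuts) - k) - 1L)
      cuts <- as.integer(cuts)
    }
    bounds <- c(0L, cuts, nSteps)
    firstSegOf[i] <- segCount + 1L
    rows <- vector("list", nSeg)
    for (j in seq_len(nSeg)) {
      cellsIdx <- (bounds[j] + 1L):(bounds[j + 1] + 1L)
      sp <- p[cellsIdx, , drop = FALSE]
      rows[[j]] <- data.frame(
        reachId = rt$id[i], idxInReach = j, nInReach = nSeg,
        order = rt$order[i], length_m = sum(steps[(bounds[j] + 1L):
                                                    bounds[j + 1]]))
      attr(rows[[j]], "path") <- sp
    }
    segRows[[i]] <- rows
    segCount <- segCount + nSeg
  }
  flat <- unlist(segRows, recursive = FALSE)
  seg <- do.call(rbind, flat)
  if (is.null(seg)) {
    seg <- data.frame(reachId = integer(0), idxInReach = integer(0),
                      nInReach = integer(0), order = integer(0),
                      length_m = numeric(0))
    seg$path <- list()
    seg$segId <- integer(0)
    seg$downSeg <- integer(0)
    return(seg)
  }
  seg$path <- I(lapply(flat, attr, "path"))
  seg$segId <- seq_len(nrow(seg))
  # downstream linkage: next segment in reach, else first segment of the
  # downstream reach
  toReach <- rt$toReach[match(seg$reachId, rt$id)]
  lastInReach <- seg$idxInReach == seg$nInReach
  seg$downSeg <- ifelse(lastInReach,
                        ifelse(is.na(toReach), NA_integer_,
                               firstSegOf[match(toReach, rt$id)]),
                        seg$segId + 1L)
  seg$elevUp <- NA_real_
  seg$elevDown <- NA_real_
  seg$gradient <- NA_real_
  seg$valid <- TRUE
  seg$overlapsIce <- FALSE
  seg$provenance <- "present"
  rownames(seg) <- NULL
  seg[c("segId", "reachId", "idxInReach", "nInReach", "downSeg", "order",
        "length_m", "elevUp", "elevDown", "gradient", "valid", "overlapsIce",
        "provenance", "path")]
}

#' Attribute segments with endpoint-elevation gradients
#'
#' The gradient of a segment is the absolute elevation difference between its
#' two endpoint cells divided by its along-path length, stored as a
#' dimensionless fraction (0.05 = 5%). The absolute difference makes the
#' gradient invariant to the stored direction of the segment; it matters for
#' bedrock-derived segments, which need not be monotone. A segment with a
#' nodata endpoint is flagged invalid (`valid = FALSE`, gradient `NA`) and
#' excluded from all totals.
#'
#' @param segments a segment table from [segmentReaches()].
#' @param dem the [ElevationGrid-class] to read endpoint elevations from (the
#'   ice-surface DEM for present-day segments, the reconstructed bedrock for
#'   future segments).
#' @return The segment table with `elevUp`, `elevDown`, `gradient` and
#'   `valid` filled in.
#' @examples
#' # endpoints 100 m and 75 m over 500 m give gradient 0.05 (5%)
#' @export
attributeGradient <- function(segments, dem) {
  stopifnot(is(dem, "ElevationGrid"))
  if (nrow(segments) == 0) return(segments)
  v <- gridValues(dem)
  nr <- nrow(v)
  up <- vapply(segments$path, function(p)
    v[.linIndex(p[1, 1], p[1, 2], nr)], numeric(1))
  dn <- vapply(segments$path, function(p)
    v[.linIndex(p[nrow(p), 1], p[nrow(p), 2], nr)], numeric(1))
  segments$elevUp <- up
  segments$elevDown <- dn
  bad <- is.na(up) | is.na(dn) | segments$length_m <= 0
  segments$valid <- !bad
  segments$gradient <- ifelse(bad, NA_real_,
                              abs(up - dn) / segments$length_m)
  if (any(bad))
    warning(sum(bad), " segment(s) with nodata endpoints flagged invalid ",
            "and excluded from totals")
  segments
}

#' Maximum gradient on the outlet path of every segment
#'
#' For each segment, the maximum of its own gradient and the gradients of all
#' segments on its unique path to the outlet. This is the statistic used for
#' fish-presence threshold verification and it is monotone non-decreasing in
#' the upstream direction along any path.
#'
#' @param segments an attributed segment table (see [attributeGradient()]).
#' @return Numeric vector aligned with `segments$segId`.
#' @export
pathMaxGradient <- function(segments) {
  n <- nrow(segments)
  out <- rep(NA_real_, n)
  if (n == 0) return(out)
  down <- match(segments$downSeg, segments$segId)
  children <- split(seq_len(n), factor(down, levels = seq_len(n)))
  roots <- which(is.na(down))
  queue <- roots
  out[roots] <- segments$gradient[roots]
  while (length(queue) > 0) {
    i <- queue[1]; queue <- queue[-1]
    kids <- children[[i]]
    if (length(kids) > 0) {
      out[kids] <- pmax(segments$gradient[kids], out[i], na.rm = FALSE)
      queue <- c(queue, kids)
    }
  }
  out
}
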