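.salmonSpecies <- c("chinook", "chum", "coho", "pink", "sockeye")

.checkSpecies <- function(species) {
  bad <- setdiff(unique(species), .salmonSpecies)
  if (length(bad) > 0)
    stop("unknown species: ", paste(bad, collapse = ", "),
         " (expected one of ", paste(.salmonSpecies, collapse = ", "), ")")
  invisible(TRUE)
}

#' Snap observation points to the stream network
#'
#' Attaches each fish-presence point to the nearest segment (by distance to
#' the segment's cell centres) within the snap tolerance; points farther
#' than the tolerance from any stream are counted and excluded.
#'
#' @param points data.frame with columns `species`, `x`, `y` (map metres).
#'   Species labels outside the five Pacific salmon are rejected.
#' @param segments a segment table.
#' @param dims grid dimensions; `cellSize`, `origin` its georeferencing.
#' @param tolerance maximum snap distance (m), default 100.
#' @param cellSize,origin grid georeferencing.
#' @return The points with `snappedSeg` and `snapDist` columns, snapped rows
#'   only; the number of excluded points is in attribute `"nUnsnapped"`.
#' @export
snapToNetwork <- function(points, segments, dims, cellSize = 30,
                          origin = c(0, 0), tolerance = 100) {
  stopifnot(tolerance > 0, all(c("species", "x", "y") %in% names(points)))
  .checkSpecies(points$species)
  keep <- segments$valid & !segments$overlapsIce
  segIdx <- rep(segments$segId[keep],
                vapply(segments$path[keep], nrow, integer(1)))
  cellsAll <- do.call(rbind, segments$path[keep])
  xy <- .cellXY(cellsAll[, 1], cellsAll[, 2], dims, cellSize, origin)
  snapped <- integer(nrow(points))
  dist <- numeric(nrow(points))
  for (i in seq_len(nrow(points))) {
    d2 <- (xy[, 1] - points$x[i])^2 + (xy[, 2] - points$y[i])^2
    j <- which.min(d2)
    snapped[i] <- segIdx[j]
    dist[i] <- sqrt(d2[j])
  }
  ok <- dist <= tolerance
  out <- points[ok, , drop = FALSE]
  out$snappedSeg <- snapped[ok]
  out$snapDist <- dist[ok]
  attr(out, "nUnsnapped") <- sum(!ok)
  if (any(!ok))
    warning(sum(!ok), " point(s) beyond the ", tolerance,
            " m snap tolerance excluded")
  out
}

#' Maximum stream gradient crossed from outlet to observation
#'
#' For each snapped observation, the steepest segment gradient on the unique
#' network path from the river outlet to the snapped segment, inclusive --
#' the statistic used to verify migration gradient thresholds against
#' presence records. It is monotone along a path: a point upstream of
#' another sees at least the downstream point's value.
#'
#' @param points snapped observations (see [snapToNetwork()]).
#' @param segments the segment table the points were snapped to.
#' @return The points with a `maxGradient` column.
#' @export
maxGradientCrossed <- function(points, segments) {
  stopifnot("snappedSeg" %in% names(points))
  mg <- pathMaxGradient(segments)
  idx <- match(points$snappedSeg, segments$segId)
  if (any(is.na(idx)))
    stop("snapped segment not on the network for point(s) ",
         paste(utils::head(which(is.na(idx)), 5), collapse = ", "))
  points$maxGradient <- mg[idx]
  if (any(is.na(points$maxGradient)))
    stop("no path to outlet for segment(s) ",
         paste(unique(points$snappedSeg[is.na(points$maxGradient)]),
               collapse = ", "))
  points
}

#' Per-species summary of the maximum-gradient-crossed statistic
#'
#' Quartiles (sort-based, inverse-ECDF definition) of the statistic per
#' species plus the fractions of observations whose statistic is below the
#' 10% and 15% migration thresholds. Because the wording "cross a maximum
#' stream gradient threshold of at least X" can be read in either direction,
#' both tail fractions are reported (`fracBelow*` and `fracAtLeast10`).
#'
#' @param points observations with `maxGradient` (see
#'   [maxGradientCrossed()]).
#' @return data.frame per species: `n`, `q25`, `q50`, `q75`, `fracBelow10`,
#'   `fracBelow15`, `fracAtLeast10`. Species with no observations are
#'   omitted with a warning.
#' @export
speciesSummary <- function(points) {
  stopifnot("maxGradient" %in% names(points))
  .checkSpecies(points$species)
  listed <- intersect(.salmonSpecies, unique(points$species))
  usable <- vapply(listed, function(sp)
    sum(!is.na(points$maxGradient[points$species == sp])) > 0, logical(1))
  if (any(!usable))
    warning("species without usable observations omitted: ",
            paste(listed[!usable], collapse = ", "))
  rows <- lapply(listed[usable], function(sp) {
    g <- points$maxGradient[points$species == sp]
    g <- g[!is.na(g)]
    q <- stats::quantile(g, c(0.25, 0.5, 0.75), type = 1, names = FALSE)
    data.frame(species = sp, n = length(g), q25 = q[1], q50 = q[2],
               q75 = q[3], fracBelow10 = mean(g < 0.10),
               fracBelow15 = mean(g < 0.15),
               fracAtLeast10 = mean(g >= 0.10))
  })
  do.call(rbind, rows)
}
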