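#' Fill depressions in an elevation grid
#'
#' Priority-flood filling to spill elevation: every closed depression is
#' raised to the lowest elevation over which it drains, so that from every
#' drained cell a non-ascending 8-neighbor path reaches the grid boundary.
#' Cells that already drain are returned unchanged, and the result is minimal
#' (lowering any raised cell would re-create a pit) and idempotent.
#'
#' Nodata cells are barriers. Non-nodata cells completely enclosed by nodata
#' cannot drain to the boundary; they are left at their input elevation and
#' recorded in the `"nExcluded"` attribute (downstream steps exclude them).
#'
#' @param dem an [ElevationGrid-class]; at least one non-nodata cell must lie
#'   on the grid boundary.
#' @return A filled [ElevationGrid-class] with attribute `nExcluded`.
#' @examples
#' z <- matrix(10, 3, 3); z[2, 2] <- 5
#' gridValues(fillDepressions(elevationGrid(z)))[2, 2]  # raised to 10
#' @seealso [d8FlowDirection()], [flowAccumulation()]
#' @export
fillDepressions <- function(dem) {
  stopifnot(is(dem, "ElevationGrid"))
  v <- gridValues(dem)
  if (all(is.na(v))) stop("invalid input: all-nodata grid")
  edge <- c(v[1, ], v[nrow(v), ], v[, 1], v[, ncol(v)])
  if (all(is.na(edge)))
    stop("invalid input: no non-nodata cell on the grid boundary")
  res <- .fillDepressionsC(v)
  filled <- res$filled
  filled[!res$drained] <- v[!res$drained]
  out <- elevationGrid(filled, cellSize(dem), gridOrigin(dem), gridCRS(dem))
  attr(out, "nExcluded") <- sum(!res$drained & !is.na(v))
  out
}

#' D8 flow directions on a filled elevation grid
#'
#' Each drained cell points to its steepest-descent 8-neighbor, with slope
#' measured as drop over centre-to-centre distance (diagonal distance
#' `cellSize * sqrt(2)`). Slope ties break to the first neighbor in the fixed
#' scan order E, SE, S, SW, W, NW, N, NE. Cells on a filled flat, which have
#' no strictly lower neighbor, are resolved toward the nearest drained
#' neighbor by following the breadth-first order in which the priority flood
#' conquered the flat, which guarantees an acyclic field. Boundary cells with
#' no lower drained neighbor are outlets (code 0).
#'
#' @param dem a depression-filled [ElevationGrid-class] (see
#'   [fillDepressions()]). An interior pit raises an internal-consistency
#'   error.
#' @return A [FlowField-class] with directions and flow accumulation.
#' @export
d8FlowDirection <- function(dem) {
  stopifnot(is(dem, "ElevationGrid"))
  v <- gridValues(dem)
  if (all(is.na(v))) stop("invalid input: all-nodata grid")
  res <- .fillDepressionsC(v)
  raised <- res$drained & (res$filled > v + 1e-9)
  if (any(raised))
    stop("internal-consistency error: unfilled pit encountered (",
         sum(raised), " cell(s) below spill level); run fillDepressions()")
  dir <- .d8DirectionsC(res$filled, res$parent, res$drained, cellSize(dem))
  acc <- .flowAccumulationC(dir)
  new("FlowField", direction = dir, accumulation = acc,
      cellSize = cellSize(dem), origin = gridOrigin(dem), crs = gridCRS(dem),
      nExcluded = sum(!res$drained & !is.na(v)))
}

#' Flow accumulation from a D8 direction field
#'
#' The accumulation of a cell is the number of cells whose directed flow path
#' passes through it, including the cell itself, so
#' `acc(c) = 1 + sum(acc(upstream neighbors of c))`.
#'
#' @param flow a [FlowField-class], or an integer matrix of D8 direction
#'   codes. A cyclic direction field is an error.
#' @return Integer matrix of per-cell counts (`NA` where undrained).
#' @export
flowAccumulation <- function(flow) {
  dir <- if (is(flow, "FlowField")) flowDirection(flow) else flow
  storage.mode(dir) <- "integer"
  .flowAccumulationC(dir)
}

#' Catchment delineation
#'
#' Labels every drained cell with the linear (column-major, 1-based) index of
#' the outlet cell its flow path terminates at.
#'
#' @param flow a [FlowField-class].
#' @return Integer matrix of basin labels (`NA` where undrained).
#' @export
catchments <- function(flow) {
  stopifnot(is(flow, "FlowField"))
  .basinsC(flowDirection(flow))
}

#' Extract a stream network from a flow field
#'
#' Stream cells are cells whose flow accumulation meets the support
#' threshold; they form a sub-network of the D8 field that is split into
#' reaches at confluences. Each reach runs from a source or junction cell to
#' the next junction or outlet cell (endpoints inclusive; the shared junction
#' cell contributes its between-cell steps to exactly one reach, so reach
#' lengths tile the network).
#'
#' @param flow a [FlowField-class].
#' @param supportThreshold minimum accumulation (in cells) for a cell to
#'   carry a stream; default 50 cells. A threshold above the maximum
#'   accumulation yields an empty network, flagged via [isEmptyNetwork()]
#'   rather than an error.
#' @return A [StreamNetwork-class] (Strahler orders unset; see
#'   [strahlerOrder()]).
#' @export
extractStreams <- function(flow, supportThreshold = 50) {
  stopifnot(is(flow, "FlowField"), supportThreshold >= 1)
  dir <- flowDirection(flow)
  acc <- flowAccum(flow)
  nr <- nrow(dir)
  dims <- c(nr, ncol(dir))
  cs <- cellSize(flow)
  emptyNet <- function() new("StreamNetwork",
    reaches = data.frame(id = integer(0), toReach = integer(0),
                         length_m = numeric(0), accTop = integer(0),
                         accBottom = integer(0), order = integer(0)),
    paths = list(), dim = as.integer(dims), cellSize = cs,
    origin = gridOrigin(flow), crs = gridCRS(flow), outlets = integer(0),
    empty = TRUE)

  idx <- which(!is.na(acc) & acc >= supportThreshold)
  if (length(idx) == 0) return(emptyNet())

  r <- .rowOf(idx, nr); c <- .colOf(idx, nr)
  d <- dir[idx]
  ds <- rep(NA_integer_, length(idx))
  has <- d >= 1L
  ds[has] <- .linIndex(r[has] + .d8offsets[d[has], 1L],
                       c[has] + .d8offsets[d[has], 2L], nr)
  # position lookup: linear cell index -> position in idx
  pos <- integer(prod(dims)); pos[idx] <- seq_along(idx)
  dsPos <- ifelse(is.na(ds), NA_integer_, pos[ifelse(is.na(ds), 1L, ds)])
  if (any(!is.na(ds) & dsPos == 0L))
    stop("internal: stream cell drains to a non-stream cell")
  inflow <- tabulate(dsPos[!is.na(dsPos)], nbins = length(idx))

  isJunction <- inflow >= 2L
  isSource <- inflow == 0L
  isOutlet <- is.na(dsPos)
  starts <- which((isSource | isJunction) & !isOutlet)
  # isolated single cells (source and outlet at once) carry no length
  paths <- vector("list", length(starts))
  endPos <- integer(length(starts))
  for (i in seq_along(starts)) {
    p <- starts[i]
    cells <- p
    repeat {
      nxt <- dsPos[p]
      cells <- c(cells, nxt)
      if (isJunction[nxt] || is.na(dsPos[nxt])) break
      p <- nxt
    }
    paths[[i]] <- cells
    endPos[i] <- cells[length(cells)]
  }
  if (length(starts) == 0) return(emptyNet())

  startOf <- integer(length(idx)); startOf[starts] <- seq_along(starts)
  toReach <- ifelse(isOutlet[endPos], NA_integer_, startOf[endPos])
  toReach[!is.na(toReach) & toReach == 0L] <- NA_integer_
  pathMats <- lapply(paths, function(pp)
    cbind(r = r[pp], c = c[pp]))
  lens <- vapply(pathMats, .pathLength, numeric(1), cellSize = cs)
  rt <- data.frame(id = seq_along(starts), toReach = as.integer(toReach),
                   length_m = lens, accTop = acc[idx[starts]],
                   accBottom = acc[idx[endPos]],
                   order = NA_integer_)
  outCells <- unique(idx[endPos[isOutlet[endPos]]])
  # also count isolated source+outlet cells as outlets
  iso <- which(isSource & isOutlet)
  outCells <- unique(c(outCells, idx[iso]))
  new("StreamNetwork", reaches = rt, paths = pathMats,
      dim = as.integer(dims), cellSize = cs, origin = gridOrigin(flow),
      crs = gridCRS(flow), outlets = as.integer(outCells), empty = FALSE)
}
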