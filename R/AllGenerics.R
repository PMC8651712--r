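#' @include AllClasses.R
NULL

#' Accessors for grid-like objects
#'
#' `gridValues()` returns the value matrix, `cellSize()` the cell edge length
#' in metres, `gridDim()` the (rows, cols) dimensions, `gridOrigin()` the
#' lower-left corner and `gridCRS()` the CRS tag. `nodataMask()` returns a
#' logical matrix, TRUE where the cell is nodata.
#'
#' @param x an [ElevationGrid-class], [FlowField-class],
#'   [StreamNetwork-class] or [GlacierSet-class] object.
#' @return See the individual descriptions.
#' @name grid-accessors
#' @aliases gridValues cellSize gridDim gridOrigin gridCRS nodataMask
#' @examples
#' g <- elevationGrid(matrix(0, 2, 2))
#' gridDim(g)
NULL

#' @rdname grid-accessors
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))
#' @rdname grid-accessors
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))
#' @rdname grid-accessors
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))
#' @rdname grid-accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
#' @rdname grid-accessors
#' @export
setGeneric("gridCRS", function(x) standardGeneric("gridCRS"))
#' @rdname grid-accessors
#' @export
setGeneric("nodataMask", function(x) standardGeneric("nodataMask"))

setMethod("gridValues", "ElevationGrid", function(x) x@values)
setMethod("cellSize", "ElevationGrid", function(x) x@cellSize)
setMethod("gridDim", "ElevationGrid", function(x) dim(x@values))
setMethod("gridOrigin", "ElevationGrid", function(x) x@origin)
setMethod("gridCRS", "ElevationGrid", function(x) x@crs)
setMethod("nodataMask", "ElevationGrid", function(x) is.na(x@values))

setMethod("cellSize", "FlowField", function(x) x@cellSize)
setMethod("gridDim", "FlowField", function(x) dim(x@direction))
setMethod("gridOrigin", "FlowField", function(x) x@origin)
setMethod("gridCRS", "FlowField", function(x) x@crs)

setMethod("cellSize", "StreamNetwork", function(x) x@cellSize)
setMethod("gridDim", "StreamNetwork", function(x) x@dim)
setMethod("gridOrigin", "StreamNetwork", function(x) x@origin)
setMethod("gridCRS", "StreamNetwork", function(x) x@crs)

setMethod("cellSize", "GlacierSet", function(x) x@cellSize)
setMethod("gridDim", "GlacierSet", function(x) x@dim)
setMethod("gridOrigin", "GlacierSet", function(x) x@origin)
setMethod("gridCRS", "GlacierSet", function(x) x@crs)

#' Flow-field accessors
#'
#' @param x a [FlowField-class].
#' @return `flowDirection()`: integer matrix of D8 codes (1-8 in scan order
#'   E, SE, S, SW, W, NW, N, NE; 0 = outlet; NA = nodata/excluded).
#'   `flowAccum()`: integer matrix of inclusive drainage counts.
#' @name flowfield-accessors
#' @aliases flowDirection flowAccum
NULL

#' @rdname flowfield-accessors
#' @export
setGeneric("flowDirection", function(x) standardGeneric("flowDirection"))
#' @rdname flowfield-accessors
#' @export
setGeneric("flowAccum", function(x) standardGeneric("flowAccum"))
setMethod("flowDirection", "FlowField", function(x) x@direction)
setMethod("flowAccum", "FlowField", function(x) x@accumulation)

#' Stream-network accessors
#'
#' @param x a [StreamNetwork-class].
#' @return `reaches()`: the reach attribute table. `reachPaths()`: list of
#'   (row, col) cell-path matrices. `outletCells()`: linear indices of outlet
#'   cells. `isEmptyNetwork()`: TRUE for the flagged empty-extraction result.
#'   `networkLength()`: total reach length in metres.
#' @name network-accessors
#' @aliases reaches reachPaths outletCells isEmptyNetwork networkLength
NULL

#' @rdname network-accessors
#' @export
setGeneric("reaches", function(x) standardGeneric("reaches"))
#' @rdname network-accessors
#' @export
setGeneric("reachPaths", function(x) standardGeneric("reachPaths"))
#' @rdname network-accessors
#' @export
setGeneric("outletCells", function(x) standardGeneric("outletCells"))
#' @rdname network-accessors
#' @export
setGeneric("isEmptyNetwork", function(x) standardGeneric("isEmptyNetwork"))
#' @rdname network-accessors
#' @export
setGeneric("networkLength", function(x) standardGeneric("networkLength"))
setMethod("reaches", "StreamNetwork", function(x) x@reaches)
setMethod("reachPaths", "StreamNetwork", function(x) x@paths)
setMethod("outletCells", "StreamNetwork", function(x) x@outlets)
setMethod("isEmptyNetwork", "StreamNetwork", function(x) x@empty)
setMethod("networkLength", "StreamNetwork",
          function(x) sum(x@reaches$length_m))

#' Glacier-set accessors
#'
#' @param x a [GlacierSet-class].
#' @return `glacierTable()`: data.frame of glacier records.
#'   `glacierFootprints()`: named list of footprint cell-index vectors.
#' @name glacier-accessors
#' @aliases glacierTable glacierFootprints
NULL

#' @rdname glacier-accessors
#' @export
setGeneric("glacierTable", function(x) standardGeneric("glacierTable"))
#' @rdname glacier-accessors
#' @export
setGeneric("glacierFootprints",
           function(x) standardGeneric("glacierFootprints"))
setMethod("glacierTable", "GlacierSet", function(x) x@table)
setMethod("glacierFootprints", "GlacierSet", function(x) x@footprints)

#' Ice-extent mask of a retreat schedule at a given year
#'
#' A footprint cell is covered in year `y` when its melt-out year is later
#' than `y` (or beyond the horizon).
#'
#' @param x a [RetreatSchedule-class].
#' @param year calendar year within the schedule horizon.
#' @return Integer vector of covered cell indices (subset of the footprint).
#' @export
setGeneric("extentMask", function(x, year) standardGeneric("extentMask"))
setMethod("extentMask", "RetreatSchedule", function(x, year) {
  if (year < x@startYear || year > x@endYear)
    stop("year outside schedule horizon [", x@startYear, ", ", x@endYear, "]")
  x@cells[is.na(x@meltYear) | x@meltYear > year]
})

setMethod("show", "ElevationGrid", function(object) {
  d <- dim(object@values)
  rng <- range(object@values, na.rm = TRUE)
  cat(sprintf(
    "ElevationGrid: %d x %d cells @ %.0f m (%.1f-%.1f m, %d nodata)\n",
    d[1], d[2], object@cellSize, rng[1], rng[2], sum(is.na(object@values))))
})

setMethod("show", "FlowField", function(object) {
  d <- dim(object@direction)
  cat(sprintf(
    "FlowField: %d x %d cells @ %.0f m, %d drained, max accumulation %d\n",
    d[1], d[2], object@cellSize, sum(!is.na(object@direction)),
    suppressWarnings(max(object@accumulation, na.rm = TRUE))))
})

setMethod("show", "StreamNetwork", function(object) {
  if (object@empty) {
    cat("StreamNetwork: empty (no cell above the support threshold)\n")
    return(invisible(NULL))
  }
  cat(sprintf(
    "StreamNetwork: %d reaches, %.3f km, %d outlet(s), max order %s\n",
    nrow(object@reaches), networkLength(object) / 1000,
    length(object@outlets),
    if (all(is.na(object@reaches$order))) "unset"
    else max(object@reaches$order, na.rm = TRUE)))
})

setMethod("show", "GlacierSet", function(object) {
  cat(sprintf("GlacierSet: %d glacier(s), %.2f km2 total\n",
              nrow(object@table), sum(object@table$areaKm2)))
})

setMethod("show", "RetreatSchedule", function(object) {
  cat(sprintf(
    "RetreatSchedule: glacier %s, member %s, scenario %s, %d-%d, %d cells\n",
    object@glacierId, object@member, object@scenario, object@startYear,
    object@endYear, length(object@cells)))
})
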