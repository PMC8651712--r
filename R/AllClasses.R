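#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib glacierStreams, .registration = TRUE
NULL

#' ElevationGrid: a regular single-band raster
#'
#' Holds gridded elevation (or ice thickness) on a regular metric grid.
#' Values are stored as a numeric matrix in map orientation: row 1 is the
#' northern edge, column 1 the western edge. Nodata cells are `NA`. The cell
#' centre of cell (r, c) is at
#' `x = xll + (c - 0.5) * cellSize`, `y = yll + (nrow - r + 0.5) * cellSize`.
#'
#' @slot values numeric matrix of elevations (m); `NA` = nodata.
#' @slot cellSize cell edge length (m), > 0.
#' @slot origin numeric(2), (xll, yll) of the lower-left grid corner (m).
#' @slot crs free-form CRS tag carried through all outputs.
#' @exportClass ElevationGrid
setClass("ElevationGrid",
  representation(values = "matrix", cellSize = "numeric",
                 origin = "numeric", crs = "character"),
  prototype(cellSize = 30, origin = c(0, 0), crs = "local-metric"))

setValidity("ElevationGrid", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be a numeric matrix")
  if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
      object@cellSize <= 0) return("cellSize must be a single positive number")
  if (length(object@origin) != 2L || any(!is.finite(object@origin)))
    return("origin must be numeric(2)")
  if (any(!is.finite(v[!is.na(v)]))) return("non-nodata values must be finite")
  TRUE
})

#' Construct an ElevationGrid
#'
#' @param values numeric matrix, row 1 = north; `NA` marks nodata.
#' @param cellSize cell edge length in metres.
#' @param origin (xll, yll) of the lower-left corner in metres.
#' @param crs coordinate reference tag (free-form).
#' @return An [ElevationGrid-class] object.
#' @examples
#' dem <- elevationGrid(matrix(1:12, 3, 4), cellSize = 30)
#' cellSize(dem)
#' @export
elevationGrid <- function(values, cellSize = 30, origin = c(0, 0),
                          crs = "local-metric") {
  storage.mode(values) <- "double"
  new("ElevationGrid", values = values, cellSize = as.numeric(cellSize),
      origin = as.numeric(origin), crs = as.character(crs))
}

#' FlowField: D8 directions and flow accumulation
#'
#' Direction codes follow the fixed neighbor scan order
#' E, SE, S, SW, W, NW, N, NE (codes 1-8); 0 marks an outlet cell whose flow
#' leaves the grid; `NA` marks nodata or cells excluded because they drain
#' only to nodata.
#'
#' @slot direction integer matrix of D8 codes.
#' @slot accumulation integer matrix; cells draining through each cell,
#'   inclusive of itself.
#' @slot cellSize,origin,crs grid georeferencing, as in
#'   [ElevationGrid-class].
#' @slot nExcluded number of non-nodata cells excluded because they are
#'   enclosed by nodata and cannot drain to the grid boundary.
#' @exportClass FlowField
setClass("FlowField",
  representation(direction = "matrix", accumulation = "matrix",
                 cellSize = "numeric", origin = "numeric", crs = "character",
                 nExcluded = "integer"))

setValidity("FlowField", function(object) {
  d <- object@direction
  a <- object@accumulation
  if (!identical(dim(d), dim(a)))
    return("direction and accumulation must share dimensions")
  ok <- is.na(d) | (d >= 0 & d <= 8)
  if (!all(ok)) return("direction codes must be 0-8 or NA")
  if (any(!is.na(a) & a < 1)) return("accumulation must be >= 1 where drained")
  TRUE
})

#' StreamNetwork: reaches of a drainage network
#'
#' A directed acyclic graph of stream reaches extracted from a
#' [FlowField-class]. Each reach is a cell path (upstream to downstream,
#' endpoints inclusive) between two network nodes (source, junction or
#' outlet); consecutive reaches share their junction cell but every
#' between-cell step belongs to exactly one reach, so path lengths tile the
#' network without double counting.
#'
#' @slot reaches data.frame with columns `id`, `toReach` (downstream reach id,
#'   `NA` at an outlet), `length_m`, `accTop`, `accBottom`, `order`
#'   (Strahler, `NA` until [strahlerOrder()] is run).
#' @slot paths list of 2-column integer matrices (row, col), one per reach.
#' @slot dim,cellSize,origin,crs grid geometry the cell paths refer to.
#' @slot outlets integer vector of 1-based linear cell indices of outlet
#'   cells.
#' @slot empty TRUE when extraction found no cell above the support
#'   threshold (flagged rather than an error).
#' @exportClass StreamNetwork
setClass("StreamNetwork",
  representation(reaches = "data.frame", paths = "list", dim = "integer",
                 cellSize = "numeric", origin = "numeric", crs = "character",
                 outlets = "integer", empty = "logical"),
  prototype(empty = FALSE))

setValidity("StreamNetwork", function(object) {
  rt <- object@reaches
  if (nrow(rt) != length(object@paths))
    return("one path per reach required")
  if (nrow(rt) > 0) {
    bad <- !is.na(rt$toReach) & !(rt$toReach %in% rt$id)
    if (any(bad)) return("toReach must reference an existing reach or be NA")
    if (anyDuplicated(rt$id)) return("reach ids must be unique")
  }
  TRUE
})

#' GlacierSet: glacier records on a grid
#'
#' Footprints are stored as 1-based linear cell indices (column-major, the R
#' matrix convention) into the grid the set was built on.
#'
#' @slot table data.frame with columns `id`, `areaKm2`, `terminusCell`
#'   (linear index of the lowest footprint cell), `style`.
#' @slot footprints named list of integer vectors of footprint cell indices.
#' @slot dim,cellSize,origin,crs grid geometry.
#' @exportClass GlacierSet
setClass("GlacierSet",
  representation(table = "data.frame", footprints = "list", dim = "integer",
                 cellSize = "numeric", origin = "numeric", crs = "character"))

setValidity("GlacierSet", function(object) {
  tb <- object@table
  if (nrow(tb) != length(object@footprints))
    return("one footprint per glacier record required")
  if (nrow(tb) > 0) {
    if (any(lengths(object@footprints) == 0))
      return("glacier footprints must be non-empty")
    if (any(tb$areaKm2 <= 0)) return("glacier area must be > 0")
  }
  TRUE
})

#' RetreatSchedule: annual ice extent for one glacier and ensemble member
#'
#' Extent is encoded per footprint cell as the melt-out year: the first year
#' in which the cell is ice-free. The extent mask for year `y` is the set of
#' cells with melt year > `y` (`NA` melt year = not ice-free within the
#' horizon). The schedule is monotone by construction: extent can only
#' shrink. At `startYear` the extent equals the full footprint.
#'
#' @slot glacierId glacier identifier the schedule belongs to.
#' @slot member ensemble member tag (emulating a GCM forcing).
#' @slot scenario emissions-scenario tag ("moderate" or "fast").
#' @slot startYear,endYear simulation horizon (inclusive).
#' @slot cells integer footprint cell indices (1-based linear).
#' @slot meltYear numeric, first ice-free year per cell; `NA` = never within
#'   the horizon.
#' @exportClass RetreatSchedule
setClass("RetreatSchedule",
  representation(glacierId = "character", member = "character",
                 scenario = "character", startYear = "numeric",
                 endYear = "numeric", cells = "integer", meltYear = "numeric"))

setValidity("RetreatSchedule", function(object) {
  if (length(object@cells) != length(object@meltYear))
    return("cells and meltYear must align")
  if (length(object@cells) == 0) return("footprint must be non-empty")
  my <- object@meltYear[!is.na(object@meltYear)]
  if (any(my <= object@startYear))
    return("extent at startYear must equal the full footprint")
  if (any(my > object@endYear + 1))
    return("finite melt years must lie within the horizon")
  TRUE
})
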