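#' Raster I/O: ESRI ASCII grid
#'
#' Plain-text single-band raster exchange format (`ncols`/`nrows`/
#' `xllcorner`/`yllcorner`/`cellsize`/`NODATA_value` header followed by the
#' value matrix, first row = northern edge). Grid geometry round-trips
#' exactly; values round-trip within float precision of the `%.9g` encoding.
#'
#' @param grid an [ElevationGrid-class].
#' @param path file path (conventionally `.asc`).
#' @return `writeAsciiGrid()` the path, invisibly; `readAsciiGrid()` an
#'   [ElevationGrid-class].
#' @name ascii-grid
NULL

#' @rdname ascii-grid
#' @export
writeAsciiGrid <- function(grid, path) {
  stopifnot(is(grid, "ElevationGrid"))
  v <- gridValues(grid)
  nodata <- -9999
  if (any(!is.na(v) & v == nodata)) nodata <- min(v, na.rm = TRUE) - 1e6
  hdr <- c(paste("ncols", ncol(v)), paste("nrows", nrow(v)),
           paste("xllcorner", formatC(gridOrigin(grid)[1], format = "g",
                                      digits = 12)),
           paste("yllcorner", formatC(gridOrigin(grid)[2], format = "g",
                                      digits = 12)),
           paste("cellsize", formatC(cellSize(grid), format = "g",
                                     digits = 12)),
           paste("NODATA_value", nodata))
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(v, trim = TRUE, digits = 9, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname ascii-grid
#' @export
readAsciiGrid <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, character(1), 1))
  vals <- as.numeric(vapply(kv, `[`, character(1), 2))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% keys)) stop("malformed ASCII grid header in ", path)
  m <- matrix(scan(path, skip = 6, quiet = TRUE),
              nrow = vals["nrows"], ncol = vals["ncols"], byrow = TRUE)
  m[m == vals["nodata_value"]] <- NA_real_
  elevationGrid(m, vals["cellsize"],
                c(vals["xllcorner"], vals["yllcorner"]))
}

#' Vector I/O: segments as GeoJSON
#'
#' Writes the segment table as a GeoJSON FeatureCollection of LineString
#' features (cell-centre vertices in map coordinates) with the attribute
#' columns as properties, and reads it back to an attribute table.
#' Geometry coordinates round-trip exactly at the encoded precision.
#'
#' @param segments a segment table.
#' @param path output file path.
#' @param dims grid dimensions; `cellSize`, `origin` its georeferencing.
#' @param cellSize,origin grid georeferencing.
#' @return `writeSegmentsGeoJSON()` the path, invisibly;
#'   `readSegmentsGeoJSON()` a data.frame of properties with a
#'   `coordinates` list column.
#' @name segments-geojson
NULL

#' @rdname segments-geojson
#' @export
writeSegmentsGeoJSON <- function(segments, path, dims, cellSize = 30,
                                 origin = c(0, 0)) {
  cols <- intersect(c("segId", "reachId", "downSeg", "order", "length_m",
                      "gradient", "valid", "overlapsIce", "provenance",
                      "accessible", "habitat", "exposureYear"),
                    names(segments))
  feats <- lapply(seq_len(nrow(segments)), function(i) {
    p <- segments$path[[i]]
    xy <- .cellXY(p[, 1], p[, 2], dims, cellSize, origin)
    props <- as.list(segments[i, cols, drop = FALSE])
    props <- lapply(props, function(x) if (is.na(x)) NULL else x)
    list(type = "Feature",
         properties = props[!vapply(props, is.null, logical(1))],
         geometry = list(type = "LineString",
                         coordinates = unname(
                           lapply(seq_len(nrow(xy)),
                                  function(j) c(xy[j, 1], xy[j, 2])))))
  })
  obj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' @rdname segments-geojson
#' @export
readSegmentsGeoJSON <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$type, "FeatureCollection"))
    stop("not a GeoJSON FeatureCollection: ", path)
  rows <- lapply(obj$features, function(f) {
    props <- lapply(f$properties, function(x) if (is.null(x)) NA else x)
    as.data.frame(props, stringsAsFactors = FALSE)
  })
  allNames <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (nm in setdiff(allNames, names(r))) r[[nm]] <- NA
    r[allNames]
  })
  out <- do.call(rbind, rows)
  out$coordinates <- I(lapply(obj$features, function(f) {
    m <- do.call(rbind, lapply(f$geometry$coordinates, unlist))
    colnames(m) <- c("x", "y")
    m
  }))
  out
}

#' Read a fish-presence observation table
#'
#' CSV with columns `species`, `x`, `y`. Species labels are validated
#' against the five Pacific salmon; a malformed row is reported by number.
#'
#' @param path CSV file path.
#' @return data.frame with `species`, `x`, `y`.
#' @export
readObservations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species", "x", "y") %in% names(df)))
    stop("observation CSV must have columns species, x, y: ", path)
  badNum <- which(is.na(suppressWarnings(as.numeric(df$x))) |
                    is.na(suppressWarnings(as.numeric(df$y))))
  if (length(badNum) > 0)
    stop("malformed coordinates in row(s) ",
         paste(utils::head(badNum, 5), collapse = ", "), " of ", path)
  badSp <- which(!(df$species %in% .salmonSpecies))
  if (length(badSp) > 0)
    stop("unknown species in row(s) ",
         paste(utils::head(badSp, 5), collapse = ", "), " of ", path)
  df$x <- as.numeric(df$x)
  df$y <- as.numeric(df$y)
  df
}

#' Write a summary or budget table as CSV
#'
#' Plain CSV export with a provenance comment header carrying the
#' configuration hash so outputs are traceable to their run.
#'
#' @param table a data.frame (e.g. from [summarizeKm()] or
#'   [uncertaintyBudget()]).
#' @param path output path.
#' @param config optional [pipelineConfig()] echoed as a hash comment.
#' @return The path, invisibly.
#' @export
writeSummaryCSV <- function(table, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config)) {
    h <- sum(utf8ToInt(paste(deparse(unclass(config)), collapse = "")))
    writeLines(paste0("# config-hash: ", h), con)
  }
  utils::write.csv(table, con, row.names = FALSE)
  invisible(path)
}
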