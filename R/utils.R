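# Shared low-level helpers: D8 geometry, cell indexing, coordinates.

# Fixed neighbor scan order (E, SE, S, SW, W, NW, N, NE); row = code.
.d8offsets <- matrix(c(0L, 1L,   1L, 1L,   1L, 0L,   1L, -1L,
                       0L, -1L, -1L, -1L, -1L, 0L,  -1L, 1L),
                     ncol = 2, byrow = TRUE,
                     dimnames = list(NULL, c("dr", "dc")))

# step length multiplier per code (1 cardinal, sqrt(2) diagonal)
.d8steps <- c(1, sqrt(2), 1, sqrt(2), 1, sqrt(2), 1, sqrt(2))

.linIndex <- function(r, c, nr) r + (c - 1L) * nr

.rowOf <- function(idx, nr) ((idx - 1L) %% nr) + 1L
.colOf <- function(idx, nr) ((idx - 1L) %/% nr) + 1L

# cell centre coordinates in map units (row 1 = northern edge)
.cellXY <- function(r, c, dims, cellSize, origin = c(0, 0)) {
  cbind(x = origin[1] + (c - 0.5) * cellSize,
        y = origin[2] + (dims[1] - r + 0.5) * cellSize)
}

# nearest cell containing a map coordinate
.xyCell <- function(x, y, dims, cellSize, origin = c(0, 0)) {
  c0 <- pmin(pmax(ceiling((x - origin[1]) / cellSize), 1L), dims[2])
  r0 <- pmin(pmax(dims[1] - floor((y - origin[2]) / cellSize), 1L), dims[1])
  cbind(r = as.integer(r0), c = as.integer(c0))
}

# along-path length (m) of a (row, col) cell path: sum of
# centre-to-centre steps, diagonals cellSize * sqrt(2)
.pathLength <- function(path, cellSize) {
  if (nrow(path) < 2) return(0)
  dr <- abs(diff(path[, 1])); dc <- abs(diff(path[, 2]))
  sum(ifelse(dr + dc == 2L, sqrt(2), 1)) * cellSize
}

# per-step lengths of a cell path (n - 1 values)
.stepLengths <- function(path, cellSize) {
  if (nrow(path) < 2) return(numeric(0))
  dr <- abs(diff(path[, 1])); dc <- abs(diff(path[, 2]))
  ifelse(dr + dc == 2L, sqrt(2), 1) * cellSize
}

.sameGeometry <- function(a, b) {
  identical(gridDim(a), gridDim(b)) &&
    isTRUE(all.equal(cellSize(a), cellSize(b))) &&
    isTRUE(all.equal(gridOrigin(a), gridOrigin(b)))
}
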