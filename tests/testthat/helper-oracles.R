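# Brute-force oracles and fixture builders, independent of the package's
# C++ / graph implementations.

OFF <- matrix(c(0, 1, 1, 1, 1, 0, 1, -1, 0, -1, -1, -1, -1, 0, -1, 1),
              ncol = 2, byrow = TRUE)

randGrid <- function(n = 12, seed = 1, nodata = 0) {
  set.seed(seed)
  z <- matrix(stats::runif(n * n, 0, 100), n, n)
  if (nodata > 0) z[sample(seq_along(z), nodata)] <- NA
  z
}

# TRUE iff every non-nodata cell has a non-ascending 8-neighbor path to the
# grid boundary (exhaustive fixpoint search)
oracleDrains <- function(z, tol = 1e-9) {
  nr <- nrow(z); nc <- ncol(z)
  can <- matrix(FALSE, nr, nc)
  can[1, ] <- TRUE; can[nr, ] <- TRUE; can[, 1] <- TRUE; can[, nc] <- TRUE
  can[is.na(z)] <- FALSE
  repeat {
    changed <- FALSE
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      if (is.na(z[r, c]) || can[r, c]) next
      for (k in 1:8) {
        rr <- r + OFF[k, 1]; cc <- c + OFF[k, 2]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            !is.na(z[rr, cc]) && can[rr, cc] &&
            z[rr, cc] <= z[r, c] + tol) {
          can[r, c] <- TRUE; changed <- TRUE; break
        }
      }
    }
    if (!changed) break
  }
  all(can | is.na(z))
}

# per-cell accumulation by following the direction field from every cell
oracleAccum <- function(dir) {
  nr <- nrow(dir); nc <- ncol(dir)
  acc <- matrix(0L, nr, nc)
  acc[is.na(dir)] <- NA_integer_
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (is.na(dir[r0, c0])) next
    r <- r0; c <- c0; steps <- 0
    repeat {
      acc[r, c] <- acc[r, c] + 1L
      d <- dir[r, c]
      if (d == 0) break
      r2 <- r + OFF[d, 1]; c2 <- c + OFF[d, 2]
      r <- r2; c <- c2
      steps <- steps + 1
      if (steps > nr * nc) stop("cycle in direction field")
    }
  }
  acc
}

# outlet label per cell by following the direction field
oracleBasins <- function(dir) {
  nr <- nrow(dir); nc <- ncol(dir)
  lab <- matrix(NA_integer_, nr, nc)
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (is.na(dir[r0, c0])) next
    r <- r0; c <- c0
    while (dir[r, c] != 0) {
      d <- dir[r, c]
      r2 <- r + OFF[d, 1]; c2 <- c + OFF[d, 2]
      r <- r2; c <- c2
    }
    lab[r0, c0] <- r + (c - 1L) * nr
  }
  lab
}

# recursive-definition Strahler oracle on a reach table (id, toReach)
oracleStrahler <- function(rt) {
  children <- split(rt$id, factor(rt$toReach, levels = rt$id))
  rec <- function(id) {
    kids <- children[[as.character(id)]]
    if (is.null(kids) || length(kids) == 0) return(1L)
    o <- vapply(kids, rec, integer(1))
    m <- max(o)
    m + as.integer(sum(o == m) >= 2L)
  }
  vapply(rt$id, rec, integer(1))
}

# random reach tree wrapped in a minimal StreamNetwork
randomReachTree <- function(nReach, seed) {
  set.seed(seed)
  toReach <- c(NA_integer_,
               vapply(seq_len(nReach - 1) + 1L,
                      function(i) sample.int(i - 1L, 1), integer(1)))
  rt <- data.frame(id = seq_len(nReach), toReach = toReach,
                   length_m = stats::runif(nReach, 100, 2000),
                   accTop = 1L, accBottom = 1L, order = NA_integer_)
  paths <- lapply(seq_len(nReach), function(i)
    cbind(r = c(1L, 2L), c = c(i, i)))
  new("StreamNetwork", reaches = rt, paths = paths,
      dim = as.integer(c(2L, nReach)),
      cellSize = 30, origin = c(0, 0), crs = "x", outlets = 1L,
      empty = FALSE)
}

# a mouth-to-head chain of segments with prescribed gradients
chainSegments <- function(gradients, length_m = 500) {
  n <- length(gradients)
  if (n == 0) {
    out <- data.frame(segId = integer(0), reachId = integer(0),
                      idxInReach = integer(0), nInReach = integer(0),
                      downSeg = integer(0), order = integer(0),
                      length_m = numeric(0), elevUp = numeric(0),
                      elevDown = numeric(0), gradient = numeric(0),
                      valid = logical(0), overlapsIce = logical(0),
                      provenance = character(0))
    out$path <- list()
    return(out)
  }
  data.frame(segId = seq_len(n),
             reachId = 1L, idxInReach = seq_len(n), nInReach = n,
             downSeg = c(NA_integer_, seq_len(n - 1)),
             order = 1L, length_m = length_m,
             elevUp = NA_real_, elevDown = NA_real_,
             gradient = gradients, valid = TRUE, overlapsIce = FALSE,
             provenance = "present",
             path = I(lapply(seq_len(n), function(i)
               cbind(r = c(i, i + 1L), c = c(1L, 1L)))))
}

# symmetric V-valley with an axial channel of exact constant slope
vValleyDEM <- function(nr = 200, nc = 61, cellSize = 30,
                       channelSlope = 0.03, hillslope = 0.3) {
  mid <- (nc + 1) %/% 2
  axis <- channelSlope * cellSize * (nr - seq_len(nr))
  z <- outer(axis, abs(seq_len(nc) - mid) * cellSize * hillslope, "+")
  elevationGrid(z, cellSize)
}

# memoized default landscapes so expensive fixtures build once per run
.fixtures <- new.env(parent = emptyenv())

knownLandscape <- function() {
  if (is.null(.fixtures$known)) {
    spec <- landscapeSpec(seed = 1, roughnessAmp = 0)
    .fixtures$known <- simulateLandscape(spec)
  }
  .fixtures$known
}

knownScenario <- function(which = c("conservative", "inclusive")) {
  which <- match.arg(which)
  key <- paste0("scen_", which)
  if (is.null(.fixtures[[key]])) {
    ls <- knownLandscape()
    cfg <- pipelineConfig()
    cr <- habitatCriteria(cfg$accessThresholds[[which]],
                          cfg$habitatGradientMax[[which]])
    .fixtures[[key]] <- runScenario(ls$surface, ls$ice, ls$glaciers, cr,
                                    cfg)
  }
  .fixtures[[key]]
}

smallLandscape <- function(seed) {
  spec <- landscapeSpec(nrow = 140, ncol = 140, seed = seed)
  simulateLandscape(spec)
}
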