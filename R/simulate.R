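#' Specification of a synthetic glacierized landscape
#'
#' Describes a valley-forming terrain draining to a single outlet on the
#' southern grid edge: a main stem with diagonal tributaries and
#' sub-tributaries carved as V-shaped valleys (the terrain is the lower
#' envelope of cones rising from the planted channel profiles at the
#' cross-valley hillslope), correlated power-law roughness, a watershed
#' mask (cells beyond `maskRadius` of any channel are nodata, as when a DEM
#' is clipped to a basin boundary), and headwater glaciers with smooth
#' thickness fields. Glacier bedrock styles: `"gentle"` (uniform valley
#' slope under the ice), `"icefall"` (a ~25% bedrock ramp mid-glacier),
#' `"hanging"` (a ~30% headwall below the terminus, blocking salmon at both
#' thresholds) and `"gate"` (a ~12% approach ramp, blocking at 10% but not
#' at 15%). Ramp slopes are capped below the hillslope because the terrain,
#' as a lower envelope of hillslope cones, cannot contain anything steeper.
#'
#' All geometry scales with the grid, so smaller grids give faster,
#' structurally identical landscapes. Channel slopes are exact construction
#' parameters: 1.5% main stem, 3% tributaries, 4% sub-tributaries, 2%
#' branches beneath glaciers.
#'
#' @param nrow,ncol grid dimensions (default 400 x 400).
#' @param cellSize cell edge (m, default 30).
#' @param mainSlope,tribSlope,subTribSlope,branchSlope along-channel
#'   gradients (fractions).
#' @param hillslope cross-valley gradient (fraction).
#' @param roughnessAmp roughness standard deviation (m); 0 gives the
#'   analytically controlled landscape used for ground-truth recovery.
#' @param roughnessBeta spectral exponent of the power-law roughness.
#' @param maskRadius watershed half-width (m): terrain farther than this
#'   from every channel is nodata.
#' @param glacierWidth glacier half-width (m).
#' @param glacierStyles named character vector of bedrock styles for the
#'   four glaciers G1 (main-stem head), G2 (tributary T2), G3 (tributary
#'   T3), G4 (tributary T4).
#' @param glacierMaxThickness named numeric vector of maximum ice
#'   thicknesses (m); must be positive.
#' @param rampLength bedrock ramp length (m) for the stepped styles.
#' @param startYear,endYear retreat-schedule horizon.
#' @param rateModerate,rateFast terminus retreat rates (m/yr) for the
#'   moderate and fast emissions scenarios; fast must exceed moderate.
#' @param nMembers ensemble size (default 5, emulating a 5-GCM ensemble).
#' @param memberSpread fractional spread of member retreat-rate
#'   multipliers.
#' @param seed integer seed (mandatory); all stochastic components draw
#'   from sub-seeds derived from it.
#' @return A list of class `"landscapeSpec"`.
#' @export
landscapeSpec <- function(nrow = 400, ncol = 400, cellSize = 30,
                          mainSlope = 0.015, tribSlope = 0.03,
                          subTribSlope = 0.04, branchSlope = 0.02,
                          hillslope = 0.35, roughnessAmp = 3,
                          roughnessBeta = 1.6, maskRadius = 1080,
                          glacierWidth = 360,
                          glacierStyles = c(G1 = "gentle", G2 = "icefall",
                                            G3 = "hanging", G4 = "gate"),
                          glacierMaxThickness = c(G1 = 250, G2 = 180,
                                                  G3 = 200, G4 = 200),
                          rampLength = 900,
                          startYear = 2020, endYear = 2200,
                          rateModerate = 25, rateFast = 50,
                          nMembers = 5, memberSpread = 0.2, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (mainSlope <= 0 || tribSlope <= 0 || hillslope <= 0)
    stop("a landscape with non-positive slopes cannot drain; rejected")
  stopifnot(nrow >= 100, ncol >= 100, cellSize > 0, maskRadius > 0,
            glacierWidth > 0, rateFast > rateModerate, rateModerate > 0,
            nMembers >= 2, memberSpread >= 0, memberSpread < 1,
            all(glacierStyles %in% c("gentle", "icefall", "hanging",
                                     "gate")),
            all(glacierMaxThickness > 0),
            identical(names(glacierStyles), names(glacierMaxThickness)))
  spec <- as.list(environment())
  spec$seed <- as.integer(seed)
  class(spec) <- "landscapeSpec"
  spec
}

# Planted channel plan. Fractions are relative to the main-stem step count
# (base) or to the parent channel's step count (parentFrac). Directions are
# up-channel; flow runs toward vertex 0 (the junction with the parent).
.channelPlan <- function(spec) {
  base <- round(0.85 * spec$nrow)
  ch <- function(parent, parentFrac, dir, stepsFrac, slope)
    list(parent = parent, parentFrac = parentFrac, dir = dir,
         steps = max(6L, round(stepsFrac * base)), slope = slope)
  list(
    M   = ch(NA, NA, "N", 1.00, spec$mainSlope),
    S1  = ch("M", 0.088, "E", 0.250, spec$tribSlope),
    S2  = ch("M", 0.147, "W", 0.250, spec$tribSlope),
    T1  = ch("M", 0.294, "NE", 0.265, spec$tribSlope),
    T1a = ch("T1", 0.555, "N", 0.147, spec$subTribSlope),
    T1b = ch("T1", 0.833, "E", 0.176, spec$subTribSlope),
    T2  = ch("M", 0.441, "NW", 0.265, spec$tribSlope),
    T2a = ch("T2", 0.400, "W", 0.176, spec$subTribSlope),
    T2b = ch("T2", 0.720, "N", 0.147, spec$subTribSlope),
    # small gullies anchor a junction at each bedrock-ramp base, where
    # the valley side slopes converge anyway, so reach splits (and hence
    # segment cut points) are deterministic around the ramps
    T2g = ch("T2", 0.578, "W", 0.070, spec$subTribSlope),
    T3  = ch("M", 0.588, "NE", 0.294, spec$tribSlope),
    T3a = ch("T3", 0.620, "N", 0.080, spec$subTribSlope),
    T3g = ch("T3", 0.300, "E", 0.070, spec$subTribSlope),
    T4  = ch("M", 0.735, "NW", 0.294, spec$tribSlope),
    T4a = ch("T4", 0.750, "N", 0.088, spec$branchSlope),
    T4g = ch("T4", 0.300, "W", 0.070, spec$subTribSlope),
    M1  = ch("M", 0.853, "NE", 0.118, spec$branchSlope),
    M2  = ch("M", 0.912, "NW", 0.103, spec$branchSlope))
}

# Glacier plan: ice occupies the channel from spanFrac of its length to the
# head, plus the listed branch channels. Ramps realize the bedrock styles.
.glacierPlan <- function(spec) {
  styles <- spec$glacierStyles
  hmax <- spec$glacierMaxThickness
  list(
    G1 = list(id = "G1", channel = "M", spanFrac = 0.794,
              branches = c("M1", "M2"), style = styles[["G1"]],
              maxThickness = hmax[["G1"]]),
    G2 = list(id = "G2", channel = "T2", spanFrac = 0.50,
              branches = "T2b", style = styles[["G2"]],
              maxThickness = hmax[["G2"]]),
    G3 = list(id = "G3", channel = "T3", spanFrac = 0.52,
              branches = "T3a", style = styles[["G3"]],
              maxThickness = hmax[["G3"]]),
    G4 = list(id = "G4", channel = "T4", spanFrac = 0.52,
              branches = "T4a", style = styles[["G4"]],
              maxThickness = hmax[["G4"]]))
}

.dirStep <- function(dir) {
  switch(dir,
         N = c(-1L, 0L), S = c(1L, 0L), E = c(0L, 1L), W = c(0L, -1L),
         NE = c(-1L, 1L), NW = c(-1L, -1L), SE = c(1L, 1L),
         SW = c(1L, -1L), stop("unknown direction ", dir))
}

# Build channel geometry and elevation profiles (ramps applied), parents
# first. Returns a named list of channels with cells, z, stepLen, and the
# per-edge slope vector.
.buildChannels <- function(spec) {
  plan <- .channelPlan(spec)
  glaciers <- .glacierPlan(spec)
  # ramps keyed by channel: edge interval [lo+1 .. hi] and slope
  ramps <- list()
  for (g in glaciers) {
    n <- plan[[g$channel]]$steps
    k0 <- round(g$spanFrac * n)
    stepLen <- spec$cellSize *
      (if (plan[[g$channel]]$dir %in% c("NE", "NW", "SE", "SW")) sqrt(2)
       else 1)
    rampSteps <- min(ceiling(spec$rampLength / stepLen), k0 - 2L)
    # ramp slopes stay below the cross-valley hillslope: the terrain is a
    # lower envelope of hillslope cones, so a steeper planted profile
    # would be undercut and the DEM could never contain it
    if (g$style %in% c("hanging", "gate")) {
      ramps[[g$channel]] <- list(lo = k0 - rampSteps, hi = k0,
        slope = if (g$style == "hanging") min(0.30, 0.85 * spec$hillslope)
                else 0.12)
    } else if (g$style == "icefall") {
      off <- max(2L, round(0.15 * (n - k0)))
      ramps[[g$channel]] <- list(lo = k0 + off,
        hi = min(n - 2L, k0 + off + rampSteps),
        slope = min(0.25, 0.7 * spec$hillslope))
    }
  }
  channels <- list()
  for (nm in names(plan)) {
    p <- plan[[nm]]
    step <- .dirStep(p$dir)
    stepLen <- spec$cellSize * if (all(step != 0L)) sqrt(2) else 1
    if (is.na(p$parent)) {
      startCell <- c(spec$nrow, round(spec$ncol / 2))
      z0 <- 10
    } else {
      par <- channels[[p$parent]]
      kj <- round(p$parentFrac * plan[[p$parent]]$steps)
      startCell <- par$cells[kj + 1L, ]
      z0 <- par$z[kj + 1L]
      channels[[p$parent]]$junctions <-
        rbind(channels[[p$parent]]$junctions,
              data.frame(child = nm, k = kj))
    }
    n <- p$steps
    cells <- cbind(startCell[1] + step[1] * (0:n),
                   startCell[2] + step[2] * (0:n))
    if (any(cells < 1L) || any(cells[, 1] > spec$nrow) ||
        any(cells[, 2] > spec$ncol))
      stop("channel ", nm, " leaves the grid; enlarge the grid")
    edgeSlope <- rep(p$slope, n)
    rp <- ramps[[nm]]
    if (!is.null(rp)) {
      idx <- seq(rp$lo + 1L, rp$hi)
      edgeSlope[idx] <- rp$slope
    }
    z <- z0 + c(0, cumsum(edgeSlope * stepLen))
    channels[[nm]] <- list(name = nm, parent = p$parent,
                           parentK = if (is.na(p$parent)) NA_integer_ else
                             kj,
                           dir = p$dir, n = n, stepLen = stepLen,
                           cells = cells, z = z, edgeSlope = edgeSlope,
                           slope = p$slope,
                           junctions = data.frame(child = character(0),
                                                  k = integer(0)))
  }
  attr(channels, "ramps") <- ramps
  attr(channels, "glaciers") <- glaciers
  channels
}

# correlated roughness with a power-law spectrum, tapered at the grid edge
.roughnessField <- function(nr, nc, amp, beta, seed) {
  if (amp <= 0) return(matrix(0, nr, nc))
  set.seed(seed)
  w <- matrix(stats::rnorm(nr * nc), nr, nc)
  fr <- c(seq(0, floor(nr / 2)), seq(-(ceiling(nr / 2) - 1), -1)) / nr
  fc <- c(seq(0, floor(nc / 2)), seq(-(ceiling(nc / 2) - 1), -1)) / nc
  f <- sqrt(outer(fr^2, fc^2, "+"))
  flt <- f
  flt[f > 0] <- f[f > 0]^(-beta / 2)
  flt[1, 1] <- 0
  z <- Re(stats::fft(stats::fft(w) * flt, inverse = TRUE)) / (nr * nc)
  z <- z / stats::sd(z) * amp
  edge <- pmin(outer(pmin(seq_len(nr) - 1, nr - seq_len(nr)),
                     pmin(seq_len(nc) - 1, nc - seq_len(nc)), pmin) / 6, 1)
  z * edge
}

#' Generate synthetic valley terrain
#'
#' Builds the ice-free (bedrock) terrain of a [landscapeSpec()]: the lower
#' envelope of cones rising at the cross-valley hillslope from the planted
#' channel elevation profiles, plus power-law roughness, clipped to nodata
#' beyond the watershed mask. Deterministic for a given spec and seed. After
#' depression filling the terrain drains to the single planted outlet on the
#' southern edge.
#'
#' @param spec a [landscapeSpec()].
#' @return An [ElevationGrid-class] with attributes `channels` (planted
#'   channel geometry), `nearest` (per-cell index of the nearest channel
#'   vertex) and `coneDist` (per-cell distance to the channel network, m),
#'   used by [placeGlaciers()] and the ground-truth manifest.
#' @export
generateTerrain <- function(spec) {
  stopifnot(inherits(spec, "landscapeSpec"))
  channels <- .buildChannels(spec)
  # vertex registry: skip duplicated junction vertices (k = 0 of children)
  pr <- pc <- pz <- numeric(0)
  vch <- character(0); vk <- integer(0)
  for (ch in channels) {
    k0 <- if (is.na(ch$parent)) 0L else 1L
    ks <- seq(k0, ch$n)
    pr <- c(pr, ch$cells[ks + 1L, 1])
    pc <- c(pc, ch$cells[ks + 1L, 2])
    pz <- c(pz, ch$z[ks + 1L])
    vch <- c(vch, rep(ch$name, length(ks)))
    vk <- c(vk, ks)
  }
  cone <- .minConeC(spec$nrow, spec$ncol, pr, pc, pz, spec$hillslope,
                    spec$cellSize)
  z <- cone$z
  nearest <- cone$nearest
  coneDist <- (z - matrix(pz[nearest], spec$nrow, spec$ncol)) /
    spec$hillslope
  z <- z + .roughnessField(spec$nrow, spec$ncol, spec$roughnessAmp,
                           spec$roughnessBeta, spec$seed + 101L)
  # watershed mask: full half-width along the channels, tapering to a
  # narrow collar at every channel head (the cirque headwall) so headwater
  # drainage enters from the side slopes, not from a converging cap
  floorR <- 1.5 * spec$cellSize
  allowed <- numeric(length(pz))
  for (ch in channels) {
    own <- vch == ch$name
    fromHead <- (ch$n - vk[own]) * ch$stepLen
    allowed[own] <- pmin(spec$maskRadius, floorR + fromHead)
  }
  kept <- coneDist <= matrix(allowed[nearest], spec$nrow, spec$ncol)
  z[!kept] <- NA_real_
  out <- elevationGrid(z, spec$cellSize, c(0, 0), "synthetic-metric")
  attr(out, "kept") <- kept
  attr(out, "channels") <- channels
  attr(out, "vertexChannel") <- vch
  attr(out, "vertexK") <- vk
  attr(out, "nearest") <- nearest
  attr(out, "coneDist") <- coneDist
  out
}

#' Place glaciers and build the ice-thickness field
#'
#' Glacier footprints occupy the headwater valleys of their assigned
#' channels (all cells draining to the iced channel span, out to the glacier
#' half-width). Thickness is smooth, zero at the lateral and terminus
#' margins and maximal in the interior: the product of a parabolic
#' cross-valley taper and a parabolic along-flow taper scaled to the
#' glacier's maximum thickness. The ice-surface DEM is the bedrock terrain
#' plus thickness.
#'
#' @param spec a [landscapeSpec()].
#' @param terrain output of [generateTerrain()] (bedrock, with planted
#'   channel attributes).
#' @return A list: `glaciers` ([GlacierSet-class]), `thickness`
#'   ([ElevationGrid-class], m of ice), `surface` (ice-surface
#'   [ElevationGrid-class] = terrain + thickness).
#' @export
placeGlaciers <- function(spec, terrain) {
  stopifnot(inherits(spec, "landscapeSpec"), is(terrain, "ElevationGrid"))
  channels <- attr(terrain, "channels")
  vch <- attr(terrain, "vertexChannel")
  vk <- attr(terrain, "vertexK")
  nearest <- attr(terrain, "nearest")
  coneDist <- attr(terrain, "coneDist")
  if (is.null(channels)) stop("terrain lacks planted channel attributes")
  glaciers <- attr(channels, "glaciers")
  nr <- spec$nrow
  bed <- gridValues(terrain)
  H <- matrix(0, spec$nrow, spec$ncol)
  fp <- list(); tabRows <- list()
  taken <- logical(spec$nrow * spec$ncol)
  for (g in glaciers) {
    main <- channels[[g$channel]]
    k0 <- round(g$spanFrac * main$n)
    inSpan <- (vch == g$channel & vk >= k0) | (vch %in% g$branches)
    cellsIdx <- which(inSpan[nearest] & coneDist <= spec$glacierWidth &
                        !is.na(bed))
    if (length(cellsIdx) == 0)
      stop("glacier ", g$id, " has an empty footprint; rejected")
    if (any(taken[cellsIdx]))
      stop("glacier ", g$id, " overlaps an earlier placement; rejected")
    taken[cellsIdx] <- TRUE
    # along-flow coordinate: distance of the nearest iced vertex from the
    # terminus vertex, through the branch junction where applicable
    vAlong <- rep(NA_real_, length(vch))
    termPos <- k0 * main$stepLen
    vAlong[vch == g$channel & vk >= k0] <-
      (vk[vch == g$channel & vk >= k0] - k0) * main$stepLen
    for (b in g$branches) {
      bc <- channels[[b]]
      base <- (bc$parentK - k0) * channels[[bc$parent]]$stepLen
      vAlong[vch == b] <- base + vk[vch == b] * bc$stepLen
    }
    sAll <- vAlong[nearest[cellsIdx]]
    sn <- sAll / max(sAll)
    cross <- 1 - (coneDist[cellsIdx] / spec$glacierWidth)^2
    H[cellsIdx] <- g$maxThickness * pmax(0, cross) *
      pmax(0, 4 * sn * (1 - sn))
    areaKm2 <- length(cellsIdx) * spec$cellSize^2 / 1e6
    fp[[g$id]] <- as.integer(cellsIdx)
    tabRows[[g$id]] <- data.frame(id = g$id, areaKm2 = areaKm2,
                                  terminusCell = NA_integer_,
                                  style = g$style)
  }
  surf <- bed + H
  for (gid in names(fp)) {
    cells <- fp[[gid]]
    tabRows[[gid]]$terminusCell <- cells[which.min(bed[cells])]
  }
  gl <- new("GlacierSet", table = do.call(rbind, tabRows), footprints = fp,
            dim = as.integer(c(spec$nrow, spec$ncol)),
            cellSize = spec$cellSize, origin = gridOrigin(terrain),
            crs = gridCRS(terrain))
  rownames(gl@table) <- NULL
  thick <- elevationGrid(H, spec$cellSize, gridOrigin(terrain),
                         gridCRS(terrain))
  surface <- elevationGrid(surf, spec$cellSize, gridOrigin(terrain),
                           gridCRS(terrain))
  list(glaciers = gl, thickness = thick, surface = surface)
}

#' Build ensemble retreat schedules
#'
#' Each glacier retreats terminus-upward: a cell melts out
#' `max(1, ceiling(d / r))` years after the start year, where `d` is its
#' distance from the initial terminus cell and `r` the member's retreat
#' rate. Member rates are the scenario base rate times a seed-derived
#' multiplier shared across glaciers and scenarios (a member emulates one
#' GCM forcing), so the fast scenario retreats strictly faster than the
#' moderate one for every member, year and glacier, and all schedules are
#' monotone with the full footprint at the start year.
#'
#' @param spec a [landscapeSpec()].
#' @param glaciers the [GlacierSet-class] from [placeGlaciers()].
#' @return Nested list `schedules[[scenario]][[member]]`: a list of
#'   [RetreatSchedule-class] objects, one per glacier. Member rate
#'   multipliers are attached as attribute `"memberRates"`.
#' @export
makeRetreatSchedules <- function(spec, glaciers) {
  stopifnot(inherits(spec, "landscapeSpec"), is(glaciers, "GlacierSet"))
  set.seed(spec$seed + 202L)
  mult <- stats::runif(spec$nMembers, 1 - spec$memberSpread,
                       1 + spec$memberSpread)
  members <- paste0("m", seq_len(spec$nMembers))
  names(mult) <- members
  rates <- list(moderate = spec$rateModerate, fast = spec$rateFast)
  nr <- gridDim(glaciers)[1]
  tb <- glacierTable(glaciers)
  fp <- glacierFootprints(glaciers)
  out <- list()
  for (scen in names(rates)) {
    out[[scen]] <- list()
    for (m in seq_along(members)) {
      r <- rates[[scen]] * mult[m]
      if (r <= 0) stop("non-positive retreat rate")
      scheds <- lapply(seq_len(nrow(tb)), function(g) {
        cells <- fp[[g]]
        tc <- tb$terminusCell[g]
        d <- sqrt((.rowOf(cells, nr) - .rowOf(tc, nr))^2 +
                    (.colOf(cells, nr) - .colOf(tc, nr))^2) *
          cellSize(glaciers)
        melt <- spec$startYear + pmax(1, ceiling(d / r))
        melt[melt > spec$endYear] <- NA_real_
        retreatSchedule(tb$id[g], members[m], scen, spec$startYear,
                        spec$endYear, cells, melt)
      })
      names(scheds) <- tb$id
      out[[scen]][[members[m]]] <- scheds
    }
  }
  attr(out, "memberRates") <- mult
  out
}

#' Sample fish-presence observation points with known truth
#'
#' Emulates presence records: for each species, points are placed uniformly
#' (length-weighted) on valid, ice-free segments whose outlet-path maximum
#' gradient is below the species' tolerance, then jittered off-line by at
#' most `jitter` metres. The source segment and its true outlet-path
#' maximum gradient are stored for oracle tests.
#'
#' @param segments an attributed present-day segment table.
#' @param dims grid dimensions.
#' @param cellSize,origin grid georeferencing.
#' @param tolerances named vector of per-species maximum-gradient
#'   tolerances; names must be among the five Pacific salmon.
#' @param nPerSpecies points per species (default 200).
#' @param jitter maximum off-line displacement (m, default 50).
#' @param seed integer seed.
#' @return data.frame: `species`, `x`, `y`, `truthSegId`,
#'   `truthMaxGradient`.
#' @export
sampleObservations <- function(segments, dims, cellSize = 30,
                               origin = c(0, 0),
                               tolerances = c(chinook = 0.15, chum = 0.10,
                                              coho = 0.10, pink = 0.10,
                                              sockeye = 0.12),
                               nPerSpecies = 200, jitter = 50, seed) {
  if (missing(seed)) stop("seed is mandatory")
  .checkSpecies(names(tolerances))
  set.seed(as.integer(seed))
  maxg <- pathMaxGradient(segments)
  rows <- list()
  for (sp in names(tolerances)) {
    ok <- which(segments$valid & !segments$overlapsIce &
                  !is.na(maxg) & maxg < tolerances[[sp]])
    if (length(ok) == 0)
      stop("no eligible segments for species ", sp)
    pick <- sample(ok, nPerSpecies, replace = TRUE,
                   prob = segments$length_m[ok])
    for (i in pick) {
      p <- segments$path[[i]]
      # sample interior cells so points do not sit on the endpoint cell
      # shared with the neighboring segment
      cand <- if (nrow(p) > 2) 2:(nrow(p) - 1) else seq_len(nrow(p))
      v <- p[if (length(cand) > 1) sample(cand, 1) else cand, ]
      xy <- .cellXY(v[1], v[2], dims, cellSize, origin)
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- stats::runif(1, 0, jitter)
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, x = xy[1] + rad * cos(ang), y = xy[2] + rad * sin(ang),
        truthSegId = segments$segId[i], truthMaxGradient = maxg[i])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a complete landscape with ground truth
#'
#' Runs [generateTerrain()], [placeGlaciers()] and [makeRetreatSchedules()]
#' and computes the planted-truth manifest: present and future accessible /
#' habitat stream kilometres and the accessible-glacier sets per gradient
#' threshold, derived purely from the planted channel geometry (a 1-D
#' emulation of reach splitting, segmentation and contiguous threshold
#' tracing on the known profiles; the raster pipeline never feeds into it).
#' With `roughnessAmp = 0` the manifest is exact up to cell quantization.
#'
#' @param spec a [landscapeSpec()].
#' @param config a [pipelineConfig()]; its support threshold, target length
#'   and scenario thresholds parameterize the manifest.
#' @return A list: `surface`, `ice`, `terrain` (bedrock truth), `glaciers`,
#'   `schedules`, `manifest` (see [plantedTruth()]), `spec`.
#' @export
simulateLandscape <- function(spec, config = pipelineConfig()) {
  terrain <- generateTerrain(spec)
  pg <- placeGlaciers(spec, terrain)
  schedules <- makeRetreatSchedules(spec, pg$glaciers)
  manifest <- plantedTruth(spec, terrain, config)
  list(surface = pg$surface, ice = pg$thickness, terrain = terrain,
       glaciers = pg$glaciers, schedules = schedules, manifest = manifest,
       spec = spec)
}

#' Ground-truth manifest from planted geometry
#'
#' Computes, independently of the raster pipeline, the stream kilometres the
#' analysis should recover on a synthetic landscape: the planted channels
#' are split into reaches at their junctions, head reaches are trimmed to
#' the stream-initiation point implied by the support threshold (from the
#' cone-geometry drainage counts), reaches are segmented at the target
#' length, and segments are classified with the same contiguous-threshold,
#' order and gradient rules -- all on the 1-D planted profiles.
#'
#' @param spec a [landscapeSpec()].
#' @param terrain output of [generateTerrain()] for that spec.
#' @param config a [pipelineConfig()].
#' @return A list with `presentAccessibleKm`, `futureAccessibleKm`,
#'   `futureHabitatKm` (named per criteria), `accessibleGlaciers` (list per
#'   criteria), `plantedNetworkKm`, and the 1-D `segments` table.
#' @export
plantedTruth <- function(spec, terrain, config = pipelineConfig()) {
  channels <- attr(terrain, "channels")
  vch <- attr(terrain, "vertexChannel")
  vk <- attr(terrain, "vertexK")
  nearest <- attr(terrain, "nearest")
  coneDist <- attr(terrain, "coneDist")
  glaciers <- attr(channels, "glaciers")
  maskOK <- attr(terrain, "kept")
  if (is.null(maskOK)) maskOK <- coneDist <= spec$maskRadius
  # drainage-count proxy per vertex (cells whose nearest vertex is v)
  cnt <- tabulate(nearest[maskOK], nbins = length(vch))

  # iced interval per channel: k >= k0 on the glacier's channel, whole
  # branches; record the glacier id
  icedFrom <- list(); icedBy <- list()
  for (g in glaciers) {
    k0 <- round(g$spanFrac * channels[[g$channel]]$n)
    icedFrom[[g$channel]] <- k0; icedBy[[g$channel]] <- g$id
    for (b in g$branches) { icedFrom[[b]] <- 0L; icedBy[[b]] <- g$id }
  }

  # reaches: split channels at junctions; trim head reaches to the
  # initiation point
  reachRows <- list()
  for (ch in channels) {
    cuts <- sort(unique(ch$junctions$k))
    cuts <- cuts[cuts > 0 & cuts < ch$n]
    bounds <- c(0L, cuts, ch$n)
    for (j in seq_len(length(bounds) - 1L)) {
      kLo <- bounds[j]; kHi <- bounds[j + 1L]
      if (j == length(bounds) - 1L) {
        # head reach: initiation where the cumulative drainage count
        # (from the head down) reaches the support threshold
        own <- vch == ch$name
        cumAt <- function(k) sum(cnt[own & vk >= k])
        kInit <- kHi
        while (kInit > kLo + 1L && cumAt(kInit) < config$supportThreshold)
          kInit <- kInit - 1L
        kHi <- kInit
      }
      if (kHi <= kLo) next
      reachRows[[length(reachRows) + 1L]] <- list(
        channel = ch$name, kLo = kLo, kHi = kHi,
        len = (kHi - kLo) * ch$stepLen)
    }
  }
  nR <- length(reachRows)
  rch <- vapply(reachRows, function(x) x$channel, character(1))
  rLo <- vapply(reachRows, function(x) x$kLo, numeric(1))
  rHi <- vapply(reachRows, function(x) x$kHi, numeric(1))
  rLen <- vapply(reachRows, function(x) x$len, numeric(1))
  # downstream reach: same channel with kHi == kLo, else parent reach with
  # kHi == parentK
  downR <- rep(NA_integer_, nR)
  for (i in seq_len(nR)) {
    if (rLo[i] > 0) {
      downR[i] <- which(rch == rch[i] & rHi == rLo[i])[1]
    } else {
      par <- channels[[rch[i]]]$parent
      if (!is.na(par))
        downR[i] <- which(rch == par &
                            rHi == channels[[rch[i]]]$parentK)[1]
    }
  }
  # Strahler orders on the reach tree
  ordR <- rep(NA_integer_, nR)
  pending <- tabulate(downR[!is.na(downR)], nbins = nR)
  queue <- which(pending == 0L)
  inOrd <- vector("list", nR)
  while (length(queue) > 0) {
    i <- queue[1]; queue <- queue[-1]
    o <- inOrd[[i]]
    ordR[i] <- if (length(o) == 0) 1L else
      max(o) + as.integer(sum(o == max(o)) >= 2L)
    d <- downR[i]
    if (!is.na(d)) {
      inOrd[[d]] <- c(inOrd[[d]], ordR[i])
      pending[d] <- pending[d] - 1L
      if (pending[d] == 0L) queue <- c(queue, d)
    }
  }

  # 1-D segmentation and attributes
  segRows <- list()
  for (i in seq_len(nR)) {
    ch <- channels[[rch[i]]]
    L <- rLen[i]
    nSeg <- max(1L, ceiling(L / config$targetLength - 1e-9))
    sb <- seq(0, L, length.out = nSeg + 1L)  # from downstream end
    kAt <- rLo[i] + sb / ch$stepLen
    zAt <- stats::approx(seq(0, ch$n), ch$z, xout = kAt)$y
    iFrom <- icedFrom[[rch[i]]]
    for (j in seq_len(nSeg)) {
      kA <- kAt[j]; kB <- kAt[j + 1L]
      segRows[[length(segRows) + 1L]] <- data.frame(
        reach = i, channel = rch[i], order = ordR[i],
        len = sb[j + 1L] - sb[j],
        gradient = abs(zAt[j + 1L] - zAt[j]) / (sb[j + 1L] - sb[j]),
        iced = !is.null(iFrom) && kB >= iFrom,
        glacier = if (!is.null(iFrom) && kB >= iFrom)
          icedBy[[rch[i]]] else NA_character_,
        posInReach = j, nInReach = nSeg)
    }
  }
  seg <- do.call(rbind, segRows)
  # downstream segment pointers (seg rows are grouped by reach, ascending)
  lastSegOfReach <- nrow(seg) - match(seq_len(nR), rev(seg$reach)) + 1L
  segDown <- rep(NA_integer_, nrow(seg))
  for (s in seq_len(nrow(seg))) {
    if (seg$posInReach[s] > 1L) {
      segDown[s] <- s - 1L
    } else {
      d <- downR[seg$reach[s]]
      if (!is.na(d)) segDown[s] <- lastSegOfReach[d]
    }
  }
  trace <- function(passes) {
    nS <- nrow(seg)
    acc <- logical(nS)
    children <- split(seq_len(nS), factor(segDown, levels = seq_len(nS)))
    roots <- which(is.na(segDown))
    acc[roots] <- passes[roots]
    queue <- roots[acc[roots]]
    while (length(queue) > 0) {
      i <- queue[1]; queue <- queue[-1]
      kids <- children[[i]]
      ok <- kids[passes[kids]]
      acc[ok] <- TRUE
      queue <- c(queue, ok)
    }
    acc
  }
  criteria <- .criteriaFromConfig(config)
  presentKm <- futureKm <- habitatKm <- numeric(0)
  accGl <- list()
  for (nm in names(criteria)) {
    th <- criteria[[nm]]$accessThreshold
    hb <- criteria[[nm]]$habitatGradientMax
    passPresent <- !seg$iced & seg$gradient < th
    accPresent <- trace(passPresent)
    presentKm[nm] <- sum(seg$len[accPresent]) / 1000
    # accessible glaciers: first non-iced segment below the ice is
    # present-accessible
    gAcc <- character(0)
    for (g in glaciers) {
      lowIced <- which(seg$iced & !is.na(seg$glacier) &
                         seg$glacier == g$id & seg$channel == g$channel)
      if (length(lowIced) == 0) next
      s <- lowIced[1]
      # walk down to the first ice-free segment
      d <- segDown[s]
      while (!is.na(d) && seg$iced[d]) d <- segDown[d]
      if (!is.na(d) && accPresent[d]) gAcc <- c(gAcc, g$id)
    }
    accGl[[nm]] <- gAcc
    passCombined <- seg$gradient < th &
      (!seg$iced | seg$glacier %in% gAcc)
    accComb <- trace(passCombined)
    isFut <- seg$iced & seg$glacier %in% gAcc
    futureKm[nm] <- sum(seg$len[accComb & isFut]) / 1000
    habitatKm[nm] <- sum(seg$len[accComb & isFut & seg$order >= 2 &
                                   seg$gradient <= hb]) / 1000
  }
  list(presentAccessibleKm = presentKm, futureAccessibleKm = futureKm,
       futureHabitatKm = habitatKm, accessibleGlaciers = accGl,
       plantedNetworkKm = sum(seg$len) / 1000, segments = seg)
}
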