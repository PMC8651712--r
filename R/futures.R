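#' Habitat criteria for a projection scenario
#'
#' Bundles the adult-migration gradient threshold with the spawning/rearing
#' habitat gradient ceiling and the minimum Strahler order. The two standard
#' scenarios are conservative (access < 10%, habitat 0-2%) and inclusive
#' (access < 15%, habitat 0-4%), both with order >= 2 (habitat spans second-
#' to fourth-order streams; first-order streams are accessible but are not
#' counted as spawning/rearing habitat).
#'
#' @param accessThreshold migration gradient threshold, fraction in (0, 1).
#' @param habitatGradientMax habitat gradient ceiling, inclusive bound
#'   (0-2% read as gradient <= 0.02); must be below `accessThreshold`.
#' @param minOrder minimum Strahler order for habitat; >= 2.
#' @return A list of class `"habitatCriteria"`.
#' @export
habitatCriteria <- function(accessThreshold, habitatGradientMax,
                            minOrder = 2L) {
  stopifnot(accessThreshold > 0, accessThreshold < 1,
            habitatGradientMax > 0,
            habitatGradientMax < accessThreshold, minOrder >= 2)
  structure(list(accessThreshold = accessThreshold,
                 habitatGradientMax = habitatGradientMax,
                 minOrder = as.integer(minOrder)),
            class = "habitatCriteria")
}

#' Reconstruct deglaciated bedrock beneath the ice
#'
#' Bedrock elevation is the ice-surface elevation minus (optionally scaled)
#' ice thickness; cells with zero thickness are unchanged. The scale factor
#' implements the ice-thickness sensitivity analysis: 1.259 and 0.741
#' systematically thicken/thin all ice by 25.9%, bracketing the stated
#' uncertainty of modeled ice thickness.
#'
#' @param surface ice-surface [ElevationGrid-class].
#' @param ice ice-thickness [ElevationGrid-class] on the same geometry
#'   (metres; zero or `NA` outside glacier footprints).
#' @param scale positive thickness multiplier (default 1).
#' @return Bedrock [ElevationGrid-class].
#' @export
reconstructBedrock <- function(surface, ice, scale = 1) {
  stopifnot(is(surface, "ElevationGrid"), is(ice, "ElevationGrid"),
            scale > 0)
  if (!.sameGeometry(surface, ice))
    stop("surface and ice thickness grids must share geometry")
  h <- gridValues(ice)
  h[is.na(h)] <- 0
  if (any(h < 0)) stop("ice thickness must be >= 0")
  elevationGrid(gridValues(surface) - scale * h, cellSize(surface),
                gridOrigin(surface), gridCRS(surface))
}

#' Derive the combined present + future stream network
#'
#' Subtracts (scaled) ice thickness over the accessible glaciers only --
#' terrain outside their footprints, including inaccessible glaciers, is
#' frozen -- and re-runs the full hydrology chain (fill, D8, accumulation,
#' extraction, Strahler ordering, segmentation, gradient attribution) on the
#' resulting surface. Future reaches thereby join the present network
#' exactly where the ice-truncated network ended, and Strahler orders are
#' computed on the combined drainage so a future trunk continuing a large
#' present river keeps its order. Segments with path cells beneath a
#' formerly accessible glacier carry provenance `"future:<glacierId>"`;
#' segments overlapping a remaining (inaccessible) glacier are flagged
#' `overlapsIce` and excluded as in the present-day analysis.
#'
#' @param surface present-day ice-surface [ElevationGrid-class].
#' @param ice ice-thickness [ElevationGrid-class].
#' @param glaciers [GlacierSet-class] of all glaciers.
#' @param accessibleIds ids of accessible glaciers (see
#'   [findAccessibleGlaciers()]); an empty set returns an empty future
#'   network (present segments only).
#' @param supportThreshold stream-initiation accumulation threshold (cells),
#'   as used for the present-day network so stream density is comparable.
#' @param targetLength segment target length (m).
#' @param thicknessScale thickness multiplier for sensitivity runs.
#' @return A list: `segments` (combined segment table with provenance),
#'   `network` (the ordered [StreamNetwork-class]), `bedrock` (the surface
#'   hydrology ran on), `internallyDraining` (ids of accessible glaciers that
#'   produced no future segments).
#' @export
deriveFutureNetwork <- function(surface, ice, glaciers, accessibleIds,
                                supportThreshold = 50, targetLength = 500,
                                thicknessScale = 1) {
  stopifnot(is(surface, "ElevationGrid"), is(glaciers, "GlacierSet"))
  v <- gridValues(surface)
  h <- gridValues(ice)
  h[is.na(h)] <- 0
  fp <- glacierFootprints(glaciers)
  tb <- glacierTable(glaciers)
  accFp <- fp[tb$id %in% accessibleIds]
  bed <- v
  accCells <- unlist(accFp, use.names = FALSE)
  bed[accCells] <- v[accCells] - thicknessScale * h[accCells]
  bedrock <- elevationGrid(bed, cellSize(surface), gridOrigin(surface),
                           gridCRS(surface))
  flow <- d8FlowDirection(fillDepressions(bedrock))
  net <- strahlerOrder(extractStreams(flow, supportThreshold))
  seg <- attributeGradient(segmentReaches(net, targetLength), bedrock)
  # provenance: majority accessible-glacier footprint along the path
  nrG <- gridDim(surface)[1]
  glOf <- character(prod(gridDim(surface)))
  for (gid in tb$id[tb$id %in% accessibleIds])
    glOf[fp[[match(gid, tb$id)]]] <- gid
  if (nrow(seg) > 0) {
    prov <- vapply(seg$path, function(p) {
      g <- glOf[.linIndex(p[, 1], p[, 2], nrG)]
      g <- g[nzchar(g)]
      if (length(g) == 0) "" else names(sort(table(g), decreasing = TRUE))[1]
    }, character(1))
    seg$provenance <- ifelse(nzchar(prov), paste0("future:", prov),
                             "present")
    seg$glacierId <- ifelse(nzchar(prov), prov, NA_character_)
  } else {
    seg$glacierId <- character(0)
  }
  remaining <- tb$id[!(tb$id %in% accessibleIds)]
  if (length(remaining) > 0) {
    rem <- new("GlacierSet",
               table = tb[tb$id %in% remaining, , drop = FALSE],
               footprints = fp[match(remaining, tb$id)],
               dim = glaciers@dim, cellSize = glaciers@cellSize,
               origin = glaciers@origin, crs = glaciers@crs)
    seg <- removeIceOverlap(seg, rem)
  }
  produced <- unique(seg$glacierId[!is.na(seg$glacierId)])
  list(segments = seg, network = net, bedrock = bedrock,
       internallyDraining = setdiff(accessibleIds, produced))
}

#' Classify segments as salmon-accessible and as spawning/rearing habitat
#'
#' A segment is accessible when the contiguous below-threshold condition
#' holds along its whole path to the outlet (through the present network and
#' into the future network); it is habitat when it is accessible, its
#' Strahler order meets the scenario minimum (>= 2), and its gradient is at
#' or below the habitat ceiling (closed interval: 0-2% means
#' gradient <= 0.02).
#'
#' @param segments a combined segment table (see [deriveFutureNetwork()]).
#' @param criteria a [habitatCriteria()] scenario.
#' @return The segment table with logical columns `accessible` and
#'   `habitat`.
#' @export
classifySegments <- function(segments, criteria) {
  stopifnot(inherits(criteria, "habitatCriteria"))
  tr <- traceAccessible(segments, criteria$accessThreshold)
  segments$accessible <- segments$segId %in% tr$accessible
  segments$habitat <- segments$accessible &
    !is.na(segments$order) & segments$order >= criteria$minOrder &
    !is.na(segments$gradient) &
    segments$gradient <= criteria$habitatGradientMax
  segments
}
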