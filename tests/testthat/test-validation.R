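presentSegments <- function() {
  if (is.null(.fixtures$presentSeg)) {
    ls <- knownLandscape()
    flow <- d8FlowDirection(fillDepressions(ls$surface))
    net <- strahlerOrder(extractStreams(flow, 50))
    .fixtures$presentSeg <- removeIceOverlap(
      attributeGradient(segmentReaches(net, 500), ls$surface), ls$glaciers)
  }
  .fixtures$presentSeg
}

test_that("snapping attaches points to their source segments within tolerance", {
  ls <- knownLandscape()
  seg <- presentSegments()
  dims <- gridDim(ls$surface)
  # a point exactly on a segment vertex snaps at distance zero
  p <- seg$path[[5]][1, ]
  x <- (p[2] - 0.5) * 30; y <- (dims[1] - p[1] + 0.5) * 30
  pt <- data.frame(species = "coho", x = x, y = y)
  sn <- snapToNetwork(pt, seg, dims)
  expect_equal(sn$snapDist, 0)
  # a far point is excluded
  far <- data.frame(species = "coho", x = 1e7, y = 1e7)
  expect_warning(snF <- snapToNetwork(far, seg, dims), "excluded")
  expect_equal(nrow(snF), 0)
  expect_equal(attr(snF, "nUnsnapped"), 1L)
  # unknown species rejected at parse time
  expect_error(snapToNetwork(data.frame(species = "trout", x = 0, y = 0),
                             seg, dims), "unknown species")
  # generator-jittered points (jitter <= tolerance/2) all snap back to
  # their source segments
  obs <- sampleObservations(seg, dims, tolerances = c(coho = 0.10),
                            nPerSpecies = 200, seed = 11)
  snO <- snapToNetwork(obs, seg, dims)
  expect_equal(nrow(snO), 200)
  # identity recovered except where channels run within a jitter radius
  # of each other near confluences
  expect_gte(mean(snO$snappedSeg == snO$truthSegId), 0.97)
  # and the statistic itself agrees even when the neighbor wins the snap
  mg <- pathMaxGradient(seg)
  snapStat <- mg[match(snO$snappedSeg, seg$segId)]
  expect_gte(mean(abs(snapStat - snO$truthMaxGradient) < 1e-12), 0.98)
})

test_that("max gradient crossed equals the outlet-path maximum and is path-monotone", {
  ls <- knownLandscape()
  seg <- presentSegments()
  dims <- gridDim(ls$surface)
  # the most-downstream segment sees only its own gradient
  outletSeg <- seg[is.na(seg$downSeg), ][1, ]
  p <- outletSeg$path[[1]][1, ]
  pt <- data.frame(species = "pink",
                   x = (p[2] - 0.5) * 30, y = (dims[1] - p[1] + 0.5) * 30)
  mg <- maxGradientCrossed(snapToNetwork(pt, seg, dims), seg)
  expect_equal(mg$maxGradient, outletSeg$gradient)
  # two points on the same segment get identical values
  p2 <- seg$path[[8]]
  pts <- data.frame(species = c("chum", "chum"),
                    x = (p2[c(1, nrow(p2) - 1), 2] - 0.5) * 30,
                    y = (dims[1] - p2[c(1, nrow(p2) - 1), 1] + 0.5) * 30)
  snapped <- snapToNetwork(pts, seg, dims)
  snapped <- snapped[snapped$snappedSeg == seg$segId[8], ]
  if (nrow(snapped) == 2) {
    mg2 <- maxGradientCrossed(snapped, seg)
    expect_equal(mg2$maxGradient[1], mg2$maxGradient[2])
  }
  # a point above a planted barrier carries the barrier gradient
  mgAll <- pathMaxGradient(seg)
  barrier <- which(seg$gradient > 0.10 & seg$valid & !seg$overlapsIce)
  up <- which(seg$downSeg %in% seg$segId[barrier] & seg$gradient < 0.05)
  if (length(up) > 0)
    expect_gte(mgAll[up[1]], 0.10)
  # monotone along every path
  down <- match(seg$downSeg, seg$segId)
  ok <- is.na(down) | mgAll >= mgAll[down] - 1e-12 | is.na(mgAll)
  expect_true(all(ok, na.rm = TRUE))
})

test_that("species summaries separate planted tolerances and match a sort oracle", {
  ls <- knownLandscape()
  seg <- presentSegments()
  dims <- gridDim(ls$surface)
  obs <- sampleObservations(seg, dims,
                            tolerances = c(chinook = 0.15, pink = 0.10),
                            nPerSpecies = 200, seed = 21)
  pts <- maxGradientCrossed(snapToNetwork(obs, seg, dims), seg)
  su <- speciesSummary(pts)
  # planted tolerance 10%: at least 95% of statistics below 0.10
  expect_gte(su$fracBelow10[su$species == "pink"], 0.95)
  expect_gte(su$fracBelow15[su$species == "chinook"], 0.97)
  # the 15% fraction dominates the 10% fraction for every species
  expect_true(all(su$fracBelow15 >= su$fracBelow10))
  expect_equal(su$fracAtLeast10, 1 - su$fracBelow10)
  # quartiles match an independent sort-based oracle
  for (sp in su$species) {
    g <- sort(pts$maxGradient[pts$species == sp])
    n <- length(g)
    expect_equal(su$q25[su$species == sp], g[ceiling(0.25 * n)])
    expect_equal(su$q50[su$species == sp], g[ceiling(0.50 * n)])
    expect_equal(su$q75[su$species == sp], g[ceiling(0.75 * n)])
  }
  # truth statistics stored by the generator respect the tolerance
  expect_true(all(obs$truthMaxGradient[obs$species == "pink"] < 0.10))
})
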