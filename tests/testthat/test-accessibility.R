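test_that("contiguous tracing applies the barrier rule on the reference chain", {
  seg <- chainSegments(c(0.02, 0.08, 0.12, 0.03))
  # conservative 10% threshold: the 12% barrier blocks the 3% segment
  tr10 <- traceAccessible(seg, 0.10)
  expect_setequal(tr10$accessible, c(1L, 2L))
  expect_equal(tr10$limits, 2L)
  # inclusive 15% threshold: all four accessible
  tr15 <- traceAccessible(seg, 0.15)
  expect_setequal(tr15$accessible, 1:4)
  expect_equal(tr15$limits, 4L)
  # ties at exactly the threshold are barriers
  trTie <- traceAccessible(chainSegments(c(0.02, 0.10, 0.03)), 0.10)
  expect_equal(trTie$accessible, 1L)
  # empty network
  empty <- chainSegments(numeric(0))
  expect_length(traceAccessible(empty, 0.10)$accessible, 0)
  # disconnected segment named in the error
  bad <- chainSegments(c(0.02, 0.05))
  bad$downSeg[2] <- 99L
  expect_error(traceAccessible(bad, 0.10), "disconnected.*2")
  expect_error(traceAccessible(seg, 1.2), "fraction")
})

test_that("accessibility is downward-closed and monotone in the threshold", {
  for (s in 1:4) {
    ls <- smallLandscape(seed = 300 + s)
    flow <- d8FlowDirection(fillDepressions(ls$surface))
    net <- strahlerOrder(extractStreams(flow, 50))
    seg <- removeIceOverlap(attributeGradient(segmentReaches(net, 500),
                                              ls$surface), ls$glaciers)
    down <- match(seg$downSeg, seg$segId)
    a10 <- traceAccessible(seg, 0.10)$accessible
    a15 <- traceAccessible(seg, 0.15)$accessible
    expect_true(all(a10 %in% a15))
    for (acc in list(a10, a15)) {
      up <- down[seg$segId %in% acc]
      up <- up[!is.na(up)]
      expect_true(all(seg$segId[up] %in% acc))
    }
  }
})

test_that("ice-overlapping segments are flagged exactly (point-in-footprint oracle)", {
  ls <- knownLandscape()
  flow <- d8FlowDirection(fillDepressions(ls$surface))
  net <- strahlerOrder(extractStreams(flow, 50))
  seg <- attributeGradient(segmentReaches(net, 500), ls$surface)
  # no glaciers: identity
  emptyGl <- new("GlacierSet",
                 table = glacierTable(ls$glaciers)[0, ],
                 footprints = list(), dim = ls$glaciers@dim,
                 cellSize = 30, origin = c(0, 0), crs = "x")
  expect_equal(removeIceOverlap(seg, emptyGl)$overlapsIce,
               rep(FALSE, nrow(seg)))
  seg <- removeIceOverlap(seg, ls$glaciers)
  # oracle: per-cell membership test
  ice <- logical(prod(gridDim(ls$glaciers)))
  ice[unlist(glacierFootprints(ls$glaciers))] <- TRUE
  nr <- gridDim(ls$glaciers)[1]
  oracle <- vapply(seg$path, function(p)
    any(ice[p[, 1] + (p[, 2] - 1L) * nr]), logical(1))
  expect_equal(seg$overlapsIce, oracle)
  expect_gt(sum(oracle), 0)
  # a segment fully inside a footprint is removed
  inner <- which(vapply(seg$path, function(p)
    all(ice[p[, 1] + (p[, 2] - 1L) * nr]), logical(1)))
  expect_true(all(seg$overlapsIce[inner]))
})

test_that("glacier accessibility reflects planted barriers and the threshold contrast", {
  ls <- knownLandscape()
  res10 <- knownScenario("conservative")
  res15 <- knownScenario("inclusive")
  truth <- ls$manifest$accessibleGlaciers
  expect_setequal(res10$accessibleGlaciers, truth$conservative)
  expect_setequal(res15$accessibleGlaciers, truth$inclusive)
  # the hanging glacier (headwall below its terminus) is never accessible
  hang <- glacierTable(ls$glaciers)$id[
    glacierTable(ls$glaciers)$style == "hanging"]
  expect_false(hang %in% res15$accessibleGlaciers)
  # the gate glacier (~12% approach) is gained only at the 15% threshold
  gate <- glacierTable(ls$glaciers)$id[
    glacierTable(ls$glaciers)$style == "gate"]
  expect_false(gate %in% res10$accessibleGlaciers)
  expect_true(gate %in% res15$accessibleGlaciers)
})

test_that("threshold comparison is monotone in count, area and kilometres", {
  ls <- knownLandscape()
  flow <- d8FlowDirection(fillDepressions(ls$surface))
  net <- strahlerOrder(extractStreams(flow, 50))
  seg <- removeIceOverlap(attributeGradient(segmentReaches(net, 500),
                                            ls$surface), ls$glaciers)
  cmp <- thresholdComparison(seg, ls$glaciers)
  expect_equal(cmp$threshold, c(0.10, 0.15))
  expect_true(cmp$nGlaciers[2] >= cmp$nGlaciers[1])
  expect_true(cmp$glacierAreaKm2[2] >= cmp$glacierAreaKm2[1])
  expect_true(cmp$accessibleKm[2] >= cmp$accessibleKm[1])
  # the known landscape's gate glacier makes the counts differ by exactly 1
  expect_equal(cmp$nGlaciers[2] - cmp$nGlaciers[1], 1L)
})
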