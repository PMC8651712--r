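test_that("depression filling leaves drained terrain unchanged and raises pits to spill level", {
  plane <- elevationGrid(outer(rep(0, 6), seq(60, 10, length.out = 6), "+"))
  expect_equal(gridValues(fillDepressions(plane)), gridValues(plane))

  z <- matrix(10, 3, 3); z[2, 2] <- 5
  filled <- fillDepressions(elevationGrid(z))
  expect_equal(gridValues(filled)[2, 2], 10)

  expect_error(fillDepressions(elevationGrid(matrix(NA_real_, 3, 3))),
               "nodata")
})

test_that("filling is minimal, idempotent and drains every cell (random grids)", {
  for (s in 1:25) {
    z <- randGrid(12, seed = s, nodata = if (s %% 5 == 0) 6 else 0)
    # carve a depression so filling has work to do
    z[5:7, 5:7] <- z[5:7, 5:7] - 60
    dem <- elevationGrid(z)
    filled <- gridValues(fillDepressions(dem))
    expect_true(all(filled >= z | is.na(z)))
    expect_true(oracleDrains(filled))
    # idempotence
    expect_equal(gridValues(fillDepressions(elevationGrid(filled))), filled)
    # minimality: lowering any raised interior cell re-creates a pit
    raised <- which(filled > z + 1e-6, arr.ind = TRUE)
    raised <- raised[raised[, 1] > 1 & raised[, 1] < 12 &
                       raised[, 2] > 1 & raised[, 2] < 12, , drop = FALSE]
    for (i in seq_len(min(3, nrow(raised)))) {
      z2 <- filled
      z2[raised[i, 1], raised[i, 2]] <- z2[raised[i, 1], raised[i, 2]] - 0.5
      expect_false(oracleDrains(z2))
    }
  }
})

test_that("D8 directions follow steepest descent and geometry forces known patterns", {
  # plane tilted purely west -> east: every interior cell points east
  plane <- elevationGrid(outer(rep(0, 6), seq(60, 10, length.out = 6), "+"))
  ff <- d8FlowDirection(plane)
  d <- flowDirection(ff)
  expect_true(all(d[, 1:5] == 1L))
  expect_true(all(d[, 6] == 0L))

  # V-valley with axial tilt: hillslopes point to the axis, axis down-valley
  dem <- vValleyDEM(nr = 20, nc = 11)
  d <- flowDirection(d8FlowDirection(dem))
  expect_true(all(d[1:19, 1:5] == 1L))   # west flank points east
  expect_true(all(d[1:19, 7:11] == 5L))  # east flank points west
  expect_true(all(d[1:19, 6] == 3L))     # axis points south (down-valley)
  expect_identical(d[20, 6], 0L)         # outlet
})

test_that("directions are acyclic and accumulation matches graph reachability", {
  for (s in 1:25) {
    z <- randGrid(12, seed = 100 + s, nodata = if (s %% 4 == 0) 8 else 0)
    filled <- fillDepressions(elevationGrid(z))
    ff <- d8FlowDirection(filled)
    # oracleAccum errors on a cycle, so completing is the acyclicity check
    acc <- oracleAccum(flowDirection(ff))
    expect_equal(flowAccum(ff), acc)
    expect_equal(flowAccumulation(ff), acc)
    # basin membership equals brute-force path following
    expect_equal(catchments(ff), oracleBasins(flowDirection(ff)))
    # conservation: outlet accumulations sum to the drained cell count
    outlets <- which(flowDirection(ff) == 0L)
    expect_equal(sum(flowAccum(ff)[outlets]),
                 sum(!is.na(flowDirection(ff))))
  }
})

test_that("accumulation on a draining column counts cells from the top", {
  # single column: accumulation k at the k-th cell from the top
  zc <- matrix(rev(seq_len(8)), 8, 1)
  ffc <- d8FlowDirection(elevationGrid(zc))
  expect_equal(flowAccum(ffc)[, 1], seq_len(8))
  # flanked column: each flank cell adds one at its row
  z <- cbind(zc + 100, zc, zc + 100)
  ff <- d8FlowDirection(fillDepressions(elevationGrid(z)))
  expect_equal(flowAccum(ff)[, 2], seq_len(8) * 3)
})

test_that("stream extraction thresholds behave as closed forms predict", {
  plane <- elevationGrid(outer(rep(0, 8), seq(80, 10, length.out = 8), "+"))
  ff <- d8FlowDirection(plane)
  # threshold 1: every drained cell is a stream cell
  net1 <- extractStreams(ff, 1)
  cells1 <- unique(do.call(rbind, reachPaths(net1)))
  expect_equal(nrow(cells1), 64)
  # threshold t: parallel channels begin exactly t cells from the divide
  t <- 4
  net <- extractStreams(ff, t)
  cells <- do.call(rbind, reachPaths(net))
  expect_true(all(cells[, 2] >= t))
  expect_equal(sum(!duplicated(cells)), 8 * (8 - t + 1))

  # V-valley: a single main-stem reach along the axis
  dem <- vValleyDEM(nr = 30, nc = 11)
  ffv <- d8FlowDirection(dem)
  netv <- extractStreams(ffv, 40)
  expect_equal(nrow(reaches(netv)), 1L)
  expect_true(all(do.call(rbind, reachPaths(netv))[, 2] == 6))

  # threshold beyond the maximum accumulation: flagged empty result
  empty <- extractStreams(ffv, 1e6)
  expect_true(isEmptyNetwork(empty))
  expect_equal(nrow(reaches(empty)), 0L)
})

test_that("flow accumulation rejects cyclic direction fields", {
  d <- matrix(NA_integer_, 2, 2)
  d[1, 1] <- 1L; d[1, 2] <- 3L; d[2, 2] <- 5L; d[2, 1] <- 7L
  expect_error(flowAccumulation(d), "cycle")
})
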