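test_that("Strahler ordering follows the junction rule", {
  # single unbranched path: order 1 everywhere
  chain <- randomReachTree(1, seed = 1)
  expect_equal(reaches(strahlerOrder(chain))$order, 1L)

  # two order-1 tributaries joining give order 2; adding an order-1 inflow
  # to an order-2 reach leaves it at 2
  net <- randomReachTree(5, seed = 1)
  net@reaches$toReach <- c(NA, 1L, 1L, 2L, 2L)
  ord <- reaches(strahlerOrder(net))$order
  expect_equal(ord[4], 1L)  # headwater
  expect_equal(ord[2], 2L)  # two order-1 inflows (4 and 5)
  expect_equal(ord[1], 2L)  # order-2 joined by order-1 (reach 3) stays 2
})

test_that("Strahler orders equal the recursive-definition oracle on random trees", {
  for (s in 1:50) {
    n <- sample(5:60, 1)
    net <- randomReachTree(n, seed = 1000 + s)
    ord <- reaches(strahlerOrder(net))$order
    expect_equal(ord, oracleStrahler(reaches(net)))
    # orders are non-decreasing downstream
    rt <- reaches(net)
    down <- rt$toReach
    ok <- is.na(down) | ord[down] >= ord
    expect_true(all(ok))
  }
})

test_that("segmentation cuts reaches into near-equal pieces with the short-reach rule", {
  dem <- vValleyDEM(nr = 60, nc = 11)
  net <- strahlerOrder(extractStreams(d8FlowDirection(dem), 100))
  total <- networkLength(net)  # single 1500 m axis reach
  expect_equal(total, 1500)
  seg <- segmentReaches(net, 500)
  # ceiling(1500/500) = 3 near-equal pieces
  expect_equal(nrow(seg), 3L)
  expect_true(all(abs(seg$length_m - mean(seg$length_m)) <= 30))
  expect_equal(sum(seg$length_m), total)

  # a reach shorter than the target yields exactly one segment
  demS <- vValleyDEM(nr = 14, nc = 11)
  netS <- strahlerOrder(extractStreams(d8FlowDirection(demS), 40))
  segS <- segmentReaches(netS, 500)
  expect_equal(nrow(segS), 1L)
  expect_equal(segS$length_m, networkLength(netS))

  expect_error(segmentReaches(net, -5), "positive")
  expect_error(segmentReaches(net, 40), "cellSize")
})

test_that("segment lengths tile the network exactly at every target length", {
  ls <- knownLandscape()
  flow <- d8FlowDirection(fillDepressions(ls$surface))
  net <- strahlerOrder(extractStreams(flow, 50))
  total <- networkLength(net)
  for (L in c(250, 400, 500, 600, 750)) {
    seg <- segmentReaches(net, L)
    expect_equal(sum(seg$length_m), total, tolerance = 1e-9)
    # target-length compliance (short-reach exemption)
    long <- seg$nInReach > 1
    expect_true(all(seg$length_m[long] >= 0.5 * L - 45))
    expect_true(all(seg$length_m[long] <= 1.5 * L + 45))
    # segments of a reach tile it without gaps: shared endpoint cells
    byReach <- split(seq_len(nrow(seg)), seg$reachId)
    for (idx in utils::head(byReach[lengths(byReach) > 1], 3)) {
      for (j in seq_len(length(idx) - 1)) {
        a <- seg$path[[idx[j]]]; b <- seg$path[[idx[j + 1]]]
        expect_equal(unname(a[nrow(a), ]), unname(b[1, ]))
      }
    }
  }
})

test_that("gradient is |elevation difference| / along-path length, flagged on nodata", {
  path <- cbind(r = 1:18, c = rep(1L, 18))  # 17 steps of 30 m = 510 m
  z <- matrix(0, 18, 2)
  z[1, 1] <- 125.5; z[18, 1] <- 100
  seg <- data.frame(segId = 1L, length_m = 510)
  seg$path <- I(list(path))
  out <- attributeGradient(seg, elevationGrid(z))
  expect_equal(out$gradient, 25.5 / 510)  # 5%
  expect_true(out$valid)

  # equal endpoint elevations give gradient zero
  z[1, 1] <- 100
  expect_equal(attributeGradient(seg, elevationGrid(z))$gradient, 0)

  # direction reversal leaves the gradient unchanged
  z[1, 1] <- 125.5
  segRev <- seg
  segRev$path <- I(list(path[18:1, ]))
  expect_equal(attributeGradient(segRev, elevationGrid(z))$gradient,
               25.5 / 510)

  # nodata endpoint: invalid, excluded, warned
  z[18, 1] <- NA
  expect_warning(out2 <- attributeGradient(seg, elevationGrid(z)),
                 "invalid")
  expect_false(out2$valid)
  expect_true(is.na(out2$gradient))
})

test_that("constant-slope channel recovers the construction gradient at every segment length", {
  dem <- vValleyDEM(nr = 200, nc = 21, channelSlope = 0.03)
  net <- strahlerOrder(extractStreams(d8FlowDirection(dem), 300))
  for (L in c(250, 400, 500, 600, 750)) {
    seg <- attributeGradient(segmentReaches(net, L), dem)
    expect_true(all(abs(seg$gradient - 0.03) < 1e-9))
  }
})

test_that("outlet-path maximum gradient is monotone upstream", {
  seg <- chainSegments(c(0.02, 0.08, 0.12, 0.03))
  mg <- pathMaxGradient(seg)
  expect_equal(mg, c(0.02, 0.08, 0.12, 0.12))
  expect_true(all(diff(mg) >= 0))
})
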