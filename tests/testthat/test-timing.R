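mkSched <- function(cells, meltYear, start = 2020, end = 2200,
                    member = "m1", scenario = "moderate") {
  retreatSchedule("G", member, scenario, start, end, cells, meltYear)
}

test_that("benchmark extent implements the per-cell decadal majority rule", {
  # static ice (never melts within horizon): benchmark mask = full mask
  s <- mkSched(1:10, rep(NA_real_, 10))
  b <- benchmarkExtent(s, 2100)
  expect_setequal(b$coveredCells, 1:10)
  # cell deglaciated the year before the center is covered 4 of 10 window
  # years, hence ice-free in the benchmark; at the center year it is
  # covered 5 of 10 and stays ice-covered
  s2 <- mkSched(1:2, c(2099, 2100))
  b2 <- benchmarkExtent(s2, 2100)
  expect_false(1 %in% b2$coveredCells)
  expect_true(2 %in% b2$coveredCells)
  # complete deglaciation benchmark: empty mask
  expect_length(benchmarkExtent(s, "complete")$coveredCells, 0)
  # window outside the horizon is an error
  expect_error(benchmarkExtent(s, 2200), "horizon")
  # extent masks are monotone under retreat
  s3 <- mkSched(1:6, 2020 + (1:6) * 10)
  prev <- extentMask(s3, 2020)
  expect_setequal(prev, 1:6)
  for (y in seq(2030, 2080, 10)) {
    cur <- extentMask(s3, y)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("segment exposure requires the whole path to be ice-free", {
  seg <- chainSegments(c(0.01, 0.01, 0.01))
  dims <- c(4L, 1L)  # paths cover rows 1:4 of a single column
  # melt years by row: 2030, 2040, 2050, never
  sched <- mkSched(1:4, c(2030, 2040, 2050, NA))
  ey <- exposureYear(seg, list(sched), dims)
  # segment 1 spans rows 1:2 (melt 2030/2040) -> whole path free in 2040
  expect_equal(ey, c(2040, 2050, Inf))
  # a segment fully outside the footprint is exposed at the start year
  sched2 <- mkSched(1L, 2050)
  expect_equal(exposureYear(seg, list(sched2), dims)[3], 2020)
  # static schedule: never exposed
  schedStatic <- mkSched(1:4, rep(NA_real_, 4))
  expect_true(all(is.infinite(exposureYear(seg, list(schedStatic), dims))))
})

test_that("linear retreat exposes segments at start + ceiling(d / r) exactly", {
  ls <- knownLandscape()
  res <- knownScenario("conservative")
  seg <- res$combined
  isFut <- startsWith(seg$provenance, "future")
  scheds <- ls$schedules$moderate$m1
  rate <- ls$spec$rateModerate * attr(ls$schedules, "memberRates")[["m1"]]
  dims <- gridDim(ls$surface)
  nr <- dims[1]
  ey <- exposureYear(seg, scheds, dims)
  tb <- glacierTable(ls$glaciers)
  checked <- 0
  for (i in which(isFut & is.finite(ey))) {
    gid <- seg$glacierId[i]
    sch <- scheds[[gid]]
    tc <- tb$terminusCell[tb$id == gid]
    p <- seg$path[[i]]
    cellIdx <- p[, 1] + (p[, 2] - 1L) * nr
    inFp <- cellIdx %in% sch@cells
    if (!any(inFp)) next
    d <- sqrt((p[inFp, 1] - ((tc - 1) %% nr + 1))^2 +
                (p[inFp, 2] - ((tc - 1) %/% nr + 1))^2) * 30
    expect_equal(ey[i], ls$spec$startYear + max(1, ceiling(max(d) / rate)))
    checked <- checked + 1
  }
  expect_gt(checked, 10)
})

test_that("kilometre summaries count planted exposure correctly", {
  # 12 future segments of 500 m: 7 exposed by 2050, 11 by 2100, all at
  # complete deglaciation -> 3.5 / 5.5 / 6.0 km
  seg <- chainSegments(rep(0.01, 12))
  seg$provenance <- "future:G"
  seg$order <- 2L
  dims <- c(13L, 1L)
  melt <- c(rep(2040, 7), rep(2090, 4), 2150)
  # cell k is the upstream endpoint of segment k (rows k, k+1 per path)
  sched <- function(m) mkSched(2:13, melt, member = m)
  schedules <- list(moderate = list(m1 = list(G = sched("m1")),
                                    m2 = list(G = sched("m2"))))
  crit <- list(conservative = habitatCriteria(0.10, 0.02))
  out <- summarizeKm(seg, schedules, crit, dims)
  km <- function(b, m) out$km[out$benchmark == b & out$class ==
                                "accessible" & out$member == m]
  expect_equal(km("2050", "m1"), 3.5)
  expect_equal(km("2100", "m1"), 5.5)
  expect_equal(km("complete", "m1"), 6.0)
  # identical members produce identical rows
  expect_equal(km("2050", "m1"), km("2050", "m2"))
  # habitat km <= accessible km in every row pairing
  hab <- out$km[out$class == "habitat"]
  acc <- out$km[out$class == "accessible"]
  expect_true(all(hab <= acc + 1e-12))
  # an empty future set still yields a complete, all-zero table
  segNone <- seg
  segNone$provenance <- "present"
  out0 <- summarizeKm(segNone, schedules, crit, dims)
  expect_equal(nrow(out0), nrow(out))
  expect_true(all(out0$km == 0))
})

test_that("temporal monotonicity holds per member under monotone schedules", {
  ls <- knownLandscape()
  out <- runPipeline(ls, pipelineConfig(), uncertainty = FALSE)
  s <- out$summary
  for (key in split(s, list(s$scenario, s$member, s$criteria, s$class))) {
    k <- setNames(key$km, key$benchmark)
    expect_lte(k[["2050"]], k[["2100"]] + 1e-12)
    expect_lte(k[["2100"]], k[["complete"]] + 1e-12)
  }
})

test_that("relative increase is the future-to-present percentage", {
  su <- data.frame(region = "all", scenario = "moderate",
                   member = rep(c("m1", "m2"), each = 2),
                   criteria = "conservative",
                   benchmark = "2100", class = "accessible",
                   km = c(26, 27, 28, 27))
  su <- su[c(1, 3), ]
  pres <- data.frame(region = "all", criteria = "conservative", km = 100)
  out <- relativeIncrease(su, pres)
  expect_equal(out$percent, 27)  # future 27 km on present 100 km
  # halving the present kilometres doubles the percentage
  pres2 <- pres; pres2$km <- 50
  expect_equal(relativeIncrease(su, pres2)$percent, 54)
  # zero future km gives 0%
  su0 <- su; su0$km <- 0
  expect_equal(relativeIncrease(su0, pres)$percent, 0)
  # zero present km is reported as not applicable
  pres0 <- pres; pres0$km <- 0
  expect_true(is.na(relativeIncrease(su, pres0)$percent))
})
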