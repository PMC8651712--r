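test_that("root-sum-of-squares combination and its bounds", {
  expect_equal(combineRSS(c(3, 4, 0)), 5)
  expect_equal(combineRSS(c(0, 0, 0)), 0)
  expect_equal(combineRSS(c(7, 0, 0)), 7)
  expect_error(combineRSS(c(1, -2, 0)), "non-negative")
  set.seed(42)
  for (i in 1:20) {
    x <- stats::runif(3, 0, 10)
    total <- combineRSS(x)
    expect_gte(total, max(x))
    expect_lte(total, sum(x))
  }
})

test_that("ensemble statistics are the sample mean and n-1 standard deviation", {
  su <- expand.grid(region = "all", scenario = "moderate",
                    criteria = "conservative", benchmark = "2100",
                    class = "accessible", member = c("m1", "m2", "m3"),
                    stringsAsFactors = FALSE)
  su$km <- c(10, 12, 14)
  es <- ensembleStats(su)
  expect_equal(es$meanKm, 12)
  expect_equal(es$sdKm, 2)
  expect_equal(es$nMembers, 3L)
  # identical members give sd 0
  su0 <- su; su0$km <- 11
  expect_equal(ensembleStats(su0)$sdKm, 0)
  # a single member is an error
  expect_error(ensembleStats(su[su$member == "m1", ]), "single member")
})

test_that("ensemble summary matches recomputation from the raw member tables", {
  ls <- knownLandscape()
  out <- runPipeline(ls, pipelineConfig(), uncertainty = FALSE)
  es <- out$ensemble
  for (i in sample(nrow(es), 6)) {
    rows <- out$summary[out$summary$region == es$region[i] &
                          out$summary$scenario == es$scenario[i] &
                          out$summary$criteria == es$criteria[i] &
                          out$summary$benchmark == es$benchmark[i] &
                          out$summary$class == es$class[i], ]
    expect_equal(es$meanKm[i], mean(rows$km))
    expect_equal(es$sdKm[i], stats::sd(rows$km))
  }
})

test_that("thickness sensitivity re-runs equal independent from-scratch runs", {
  ls <- knownLandscape()
  cfg <- pipelineConfig()
  ts <- .fixtures$thickSens
  if (is.null(ts)) {
    ts <- thicknessSensitivity(ls$surface, ls$ice, ls$glaciers, cfg)
    .fixtures$thickSens <- ts
  }
  expect_true(all(ts$relSigma >= 0))
  expect_equal(ts$relSigma,
               (abs(ts$deltaPlus) + abs(ts$deltaMinus)) / 2)
  # oracle: a fresh pipeline run at the scaled thickness, from scratch
  cr <- habitatCriteria(cfg$accessThresholds[["conservative"]],
                        cfg$habitatGradientMax[["conservative"]])
  fresh <- runScenario(ls$surface, ls$ice, ls$glaciers, cr, cfg,
                       thicknessScale = 1.259)
  row <- ts[ts$criteria == "conservative" & ts$class == "accessible", ]
  expect_equal(row$kmPlus, fresh$futureAccessibleKm)
  # zero ice thickness: both deltas vanish
  zeroIce <- elevationGrid(matrix(0, 140, 140), 30)
  lsz <- smallLandscape(seed = 777)
  z0 <- thicknessSensitivity(lsz$surface,
                             elevationGrid(matrix(0, 140, 140), 30),
                             lsz$glaciers, cfg)
  expect_true(all(abs(z0$deltaPlus) < 1e-12 & abs(z0$deltaMinus) < 1e-12))
})

test_that("segment-length sensitivity conserves network length and spans the extremes", {
  ls <- knownLandscape()
  cfg <- pipelineConfig()
  sl <- .fixtures$segSens
  if (is.null(sl)) {
    sl <- segmentLengthSensitivity(ls$surface, ls$ice, ls$glaciers, cfg)
    .fixtures$segSens <- sl
  }
  per <- sl$perLength
  # totals at every length conserve the summed network length
  for (nm in unique(per$criteria)) {
    tot <- per$totalNetworkKm[per$criteria == nm]
    expect_true(all(abs(tot - tot[1]) < 1e-9))
  }
  expect_setequal(unique(per$targetLength), c(250, 400, 500, 600, 750))
  # sigma built from the extreme lengths against the 500 m baseline
  s <- sl$sigma[sl$sigma$criteria == "conservative" &
                  sl$sigma$class == "accessible", ]
  base <- per[per$criteria == "conservative" & per$targetLength == 500, ]
  expect_equal(s$km0, base$futureAccessibleKm)
  expect_equal(s$relSigma,
               mean(c(abs(s$kmLow - s$km0), abs(s$kmHigh - s$km0))) /
                 s$km0)
  # lengths below 2 * cellSize are skipped with a warning
  expect_warning(
    segmentLengthSensitivity(vValleyDEM(40, 11),
                             elevationGrid(matrix(0, 40, 11), 30),
                             new("GlacierSet",
                                 table = data.frame(id = character(0),
                                                    areaKm2 = numeric(0),
                                                    terminusCell = integer(0),
                                                    style = character(0)),
                                 footprints = list(), dim = c(40L, 11L),
                                 cellSize = 30, origin = c(0, 0),
                                 crs = "x"),
                             cfg, lengths = c(45, 400)),
    "skipping")
})

test_that("the combined budget is the RSS of its three components", {
  ls <- knownLandscape()
  out <- .fixtures$pipelineFull
  if (is.null(out)) {
    out <- runPipeline(ls, pipelineConfig(), uncertainty = TRUE)
    .fixtures$pipelineFull <- out
  }
  b <- out$budget
  expect_true(all(b$sigmaTotal >= pmax(b$sigmaMember, b$sigmaThickness,
                                       b$sigmaSegment) - 1e-12))
  expect_equal(b$sigmaTotal,
               sqrt(b$sigmaMember^2 + b$sigmaThickness^2 +
                      b$sigmaSegment^2))
})
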