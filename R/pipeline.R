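#' Pipeline configuration
#'
#' Collects every tunable parameter of the projection pipeline with its
#' default. Defaults mirror the standard analysis: migration thresholds 10%
#' and 15%; habitat scenarios (10%, 0-2%) and (15%, 0-4%) at order >= 2;
#' ~500 m segments with sensitivity lengths 250/400/600/750 m; +/-25.9%
#' ice-thickness perturbation; decadal benchmark windows centered on 2050
#' and 2100.
#'
#' @param accessThresholds migration gradient thresholds (fractions).
#' @param habitatGradientMax habitat ceilings paired with the thresholds.
#' @param minOrder minimum Strahler order for habitat.
#' @param targetLength segment target length (m).
#' @param sensitivityLengths alternative segment lengths (m) for the
#'   segment-length sensitivity analysis.
#' @param thicknessPerturbation fractional ice-thickness perturbation for
#'   the sensitivity analysis (0.259 = +/-25.9%).
#' @param benchmarkYears benchmark center years.
#' @param benchmarkWindow averaging window (years).
#' @param supportThreshold stream-initiation flow-accumulation threshold
#'   (cells).
#' @param adjacencyRadius glacier-contact tolerance (m).
#' @param snapTolerance observation snap tolerance (m).
#' @param seed integer seed for stochastic stages.
#' @return A list of class `"pipelineConfig"`.
#' @export
pipelineConfig <- function(accessThresholds = c(0.10, 0.15),
                           habitatGradientMax = c(0.02, 0.04),
                           minOrder = 2L,
                           targetLength = 500,
                           sensitivityLengths = c(250, 400, 600, 750),
                           thicknessPerturbation = 0.259,
                           benchmarkYears = c(2050, 2100),
                           benchmarkWindow = 10,
                           supportThreshold = 50,
                           adjacencyRadius = 60,
                           snapTolerance = 100,
                           seed = 1L) {
  stopifnot(length(accessThresholds) == length(habitatGradientMax),
            all(habitatGradientMax < accessThresholds),
            targetLength > 0, supportThreshold >= 1,
            thicknessPerturbation > 0, thicknessPerturbation < 1)
  cfg <- list(accessThresholds = accessThresholds,
              habitatGradientMax = habitatGradientMax,
              minOrder = as.integer(minOrder),
              targetLength = targetLength,
              sensitivityLengths = sensitivityLengths,
              thicknessPerturbation = thicknessPerturbation,
              benchmarkYears = benchmarkYears,
              benchmarkWindow = benchmarkWindow,
              supportThreshold = supportThreshold,
              adjacencyRadius = adjacencyRadius,
              snapTolerance = snapTolerance,
              seed = as.integer(seed))
  names(cfg$accessThresholds) <-
    names(cfg$habitatGradientMax) <-
    ifelse(seq_along(accessThresholds) == 1, "conservative", "inclusive")
  class(cfg) <- "pipelineConfig"
  cfg
}

.criteriaFromConfig <- function(config) {
  out <- lapply(seq_along(config$accessThresholds), function(i)
    habitatCriteria(config$accessThresholds[i],
                    config$habitatGradientMax[i], config$minOrder))
  names(out) <- names(config$accessThresholds)
  out
}

#' Run one accessibility scenario end to end (no retreat timing)
#'
#' Builds the present-day network from the ice-surface DEM, removes
#' ice-overlapping segments, traces accessibility at the scenario threshold,
#' identifies accessible glaciers, reconstructs bedrock beneath them, and
#' derives the classified combined present + future network.
#'
#' @param surface ice-surface [ElevationGrid-class].
#' @param ice ice-thickness [ElevationGrid-class].
#' @param glaciers [GlacierSet-class].
#' @param criteria a [habitatCriteria()] scenario.
#' @param config a [pipelineConfig()].
#' @param thicknessScale thickness multiplier (sensitivity runs).
#' @param targetLength segment target length override (m).
#' @return List: `present` (present-day segment table), `accessibleGlaciers`
#'   (ids), `combined` (classified combined segment table), `network`
#'   (combined [StreamNetwork-class]), and scalar summaries
#'   `presentAccessibleKm`, `futureAccessibleKm`, `futureHabitatKm`.
#' @export
runScenario <- function(surface, ice, glaciers, criteria,
                        config = pipelineConfig(),
                        thicknessScale = 1,
                        targetLength = config$targetLength) {
  flow <- d8FlowDirection(fillDepressions(surface))
  net <- strahlerOrder(extractStreams(flow, config$supportThreshold))
  seg <- attributeGradient(segmentReaches(net, targetLength), surface)
  seg <- removeIceOverlap(seg, glaciers)
  tr <- traceAccessible(seg, criteria$accessThreshold)
  accGl <- findAccessibleGlaciers(seg, tr$accessible, glaciers,
                                  config$adjacencyRadius)
  fut <- deriveFutureNetwork(surface, ice, glaciers, accGl,
                             supportThreshold = config$supportThreshold,
                             targetLength = targetLength,
                             thicknessScale = thicknessScale)
  combined <- classifySegments(fut$segments, criteria)
  isFut <- startsWith(combined$provenance, "future")
  list(present = seg,
       accessibleSegments = tr$accessible,
       migrationLimits = tr$limits,
       accessibleGlaciers = accGl,
       combined = combined,
       network = fut$network,
       bedrock = fut$bedrock,
       presentAccessibleKm = sum(seg$length_m[seg$segId %in%
                                                tr$accessible]) / 1000,
       futureAccessibleKm = sum(combined$length_m[isFut &
                                                    combined$accessible]) /
         1000,
       futureHabitatKm = sum(combined$length_m[isFut &
                                                 combined$habitat]) / 1000)
}

#' Run the full projection pipeline on a landscape
#'
#' Orchestrates hydrology, segmentation, accessibility, future-network
#' derivation, retreat timing and the uncertainty budget for every habitat
#' scenario in the configuration. Deterministic: identical inputs and
#' configuration give identical outputs.
#'
#' @param landscape a list with elements `surface`, `ice`
#'   ([ElevationGrid-class]), `glaciers` ([GlacierSet-class]) and
#'   `schedules` (nested list `schedules[[scenario]][[member]]` of
#'   per-glacier [RetreatSchedule-class] objects), as produced by
#'   [simulateLandscape()].
#' @param config a [pipelineConfig()].
#' @param uncertainty logical; run the thickness and segment-length
#'   sensitivity re-runs and assemble the combined budget (slower).
#' @return List with elements `scenarios` (per-criteria [runScenario()]
#'   results), `summary` (tidy km table from [summarizeKm()]), `ensemble`
#'   ([ensembleStats()] of the summary), `relative`
#'   ([relativeIncrease()] per region), `budget` (uncertainty budget or
#'   NULL), `presentKm`, and `config`.
#' @export
runPipeline <- function(landscape, config = pipelineConfig(),
                        uncertainty = TRUE) {
  criteria <- .criteriaFromConfig(config)
  dims <- gridDim(landscape$surface)
  scenarios <- lapply(criteria, function(cr)
    runScenario(landscape$surface, landscape$ice, landscape$glaciers, cr,
                config))
  summaries <- lapply(names(criteria), function(nm) {
    res <- scenarios[[nm]]
    summarizeKm(res$combined, landscape$schedules,
                criteria[nm], dims,
                benchmarks = config$benchmarkYears)
  })
  summary <- do.call(rbind, summaries)
  presentKm <- do.call(rbind, lapply(names(criteria), function(nm)
    data.frame(region = "all", criteria = nm,
               km = scenarios[[nm]]$presentAccessibleKm)))
  ensemble <- ensembleStats(summary)
  relative <- relativeIncrease(summary, presentKm)
  budget <- NULL
  if (uncertainty) {
    thick <- thicknessSensitivity(landscape$surface, landscape$ice,
                                  landscape$glaciers, config)
    segs <- segmentLengthSensitivity(landscape$surface, landscape$ice,
                                     landscape$glaciers, config)
    budget <- uncertaintyBudget(summary, thick, segs)
  }
  list(scenarios = scenarios, summary = summary, ensemble = ensemble,
       relative = relative, budget = budget, presentKm = presentKm,
       config = config)
}
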