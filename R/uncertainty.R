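#' Ensemble mean and spread of a km summary
#'
#' Collapses the per-member rows of a [summarizeKm()] table to the ensemble
#' mean and sample (n-1) standard deviation across members, per region,
#' emissions scenario, habitat-criteria scenario, benchmark and class --
#' the "ensemble mean +/- one standard deviation" presentation of the GCM
#' spread.
#'
#' @param summary output of [summarizeKm()] (>= 2 members required).
#' @return data.frame with `meanKm`, `sdKm` and `nMembers` per group.
#' @examples
#' # member values 10, 12, 14 km give mean 12, sd 2
#' @export
ensembleStats <- function(summary) {
  if (length(unique(summary$member)) < 2)
    stop("ensemble standard deviation undefined with a single member")
  agg <- stats::aggregate(
    km ~ region + scenario + criteria + benchmark + class, data = summary,
    FUN = function(x) c(mean = mean(x), sd = stats::sd(x), n = length(x)))
  out <- cbind(agg[setdiff(names(agg), "km")],
               meanKm = agg$km[, "mean"], sdKm = agg$km[, "sd"],
               nMembers = as.integer(agg$km[, "n"]))
  out
}

#' Ice-thickness sensitivity of projected stream kilometres
#'
#' Re-runs the whole scenario pipeline with all ice thicknesses
#' systematically increased and decreased by the configured perturbation
#' (default 25.9%), recomputing bedrock topography and repeating the segment
#' analysis from scratch. Reports, per habitat scenario and class, the
#' relative change of future accessible and habitat kilometres against the
#' unperturbed baseline; the one-sided deltas are collapsed to a single
#' relative sigma as the mean of their absolute values. A baseline of zero
#' kilometres reports the deltas as absolute km (flagged).
#'
#' @param surface,ice,glaciers landscape inputs as in [runScenario()].
#' @param config a [pipelineConfig()].
#' @return data.frame: `criteria`, `class`, `km0`, `kmPlus`, `kmMinus`,
#'   `deltaPlus`, `deltaMinus`, `relSigma`, `absolute`.
#' @export
thicknessSensitivity <- function(surface, ice, glaciers,
                                 config = pipelineConfig()) {
  p <- config$thicknessPerturbation
  criteria <- .criteriaFromConfig(config)
  rows <- list()
  for (nm in names(criteria)) {
    base <- runScenario(surface, ice, glaciers, criteria[[nm]], config)
    plus <- runScenario(surface, ice, glaciers, criteria[[nm]], config,
                        thicknessScale = 1 + p)
    minus <- runScenario(surface, ice, glaciers, criteria[[nm]], config,
                         thicknessScale = 1 - p)
    for (cls in c("accessible", "habitat")) {
      fld <- if (cls == "accessible") "futureAccessibleKm" else
        "futureHabitatKm"
      k0 <- base[[fld]]; kp <- plus[[fld]]; km <- minus[[fld]]
      absolute <- k0 == 0
      dP <- if (absolute) kp - k0 else (kp - k0) / k0
      dM <- if (absolute) km - k0 else (km - k0) / k0
      rows[[length(rows) + 1L]] <- data.frame(
        criteria = nm, class = cls, km0 = k0, kmPlus = kp, kmMinus = km,
        deltaPlus = dP, deltaMinus = dM,
        relSigma = mean(c(abs(dP), abs(dM))), absolute = absolute)
    }
  }
  do.call(rbind, rows)
}

#' Segment-length sensitivity of the accessibility analysis
#'
#' Re-runs the scenario pipeline at alternative segment target lengths
#' (default 250, 400, 600 and 750 m against the 500 m baseline), reporting
#' the accessible-glacier count, present accessible kilometres and future
#' accessible/habitat kilometres at every length, plus the total network
#' length (which segmentation must conserve). The sensitivity sigma is the
#' mean absolute relative delta of the two extreme lengths against the
#' baseline. Lengths below `2 * cellSize` are skipped with a warning.
#'
#' @param surface,ice,glaciers landscape inputs as in [runScenario()].
#' @param config a [pipelineConfig()].
#' @param lengths alternative target lengths (m).
#' @return List: `perLength` (one row per criteria x length, baseline
#'   included) and `sigma` (`criteria`, `class`, `km0`, `kmLow`, `kmHigh`,
#'   `relSigma`).
#' @export
segmentLengthSensitivity <- function(surface, ice, glaciers,
                                     config = pipelineConfig(),
                                     lengths = config$sensitivityLengths) {
  cs <- cellSize(surface)
  bad <- lengths < 2 * cs
  if (any(bad)) {
    warning("skipping segment length(s) below 2 * cellSize: ",
            paste(lengths[bad], collapse = ", "))
    lengths <- lengths[!bad]
  }
  criteria <- .criteriaFromConfig(config)
  allLengths <- sort(unique(c(config$targetLength, lengths)))
  perLength <- list()
  runs <- list()
  for (nm in names(criteria)) {
    for (L in allLengths) {
      res <- runScenario(surface, ice, glaciers, criteria[[nm]], config,
                         targetLength = L)
      runs[[paste(nm, L)]] <- res
      perLength[[length(perLength) + 1L]] <- data.frame(
        criteria = nm, targetLength = L,
        nGlaciers = length(res$accessibleGlaciers),
        presentAccessibleKm = res$presentAccessibleKm,
        futureAccessibleKm = res$futureAccessibleKm,
        futureHabitatKm = res$futureHabitatKm,
        totalNetworkKm = sum(res$present$length_m) / 1000)
    }
  }
  perLength <- do.call(rbind, perLength)
  sig <- list()
  lo <- min(lengths); hi <- max(lengths)
  for (nm in names(criteria)) {
    for (cls in c("accessible", "habitat")) {
      fld <- if (cls == "accessible") "futureAccessibleKm" else
        "futureHabitatKm"
      k0 <- runs[[paste(nm, config$targetLength)]][[fld]]
      kL <- runs[[paste(nm, lo)]][[fld]]
      kH <- runs[[paste(nm, hi)]][[fld]]
      rel <- if (k0 == 0) 0 else
        mean(c(abs(kL - k0), abs(kH - k0))) / k0
      sig[[length(sig) + 1L]] <- data.frame(
        criteria = nm, class = cls, km0 = k0, kmLow = kL, kmHigh = kH,
        relSigma = rel)
    }
  }
  list(perLength = perLength, sigma = do.call(rbind, sig))
}

#' Root-sum-of-squares combination of uncertainty components
#'
#' @param components non-negative uncertainty components (same units).
#' @return `sqrt(sum(components^2))`; at least the largest component and at
#'   most the plain sum.
#' @examples
#' combineRSS(c(3, 4, 0))  # 5
#' @export
combineRSS <- function(components) {
  if (any(is.na(components)) || any(components < 0))
    stop("uncertainty components must be non-negative")
  sqrt(sum(components^2))
}

#' Assemble the three-component uncertainty budget
#'
#' Per region, scenario, habitat-criteria scenario, benchmark and class:
#' the ensemble spread (sample sd across members), the ice-thickness
#' sensitivity and the segment-length sensitivity -- the latter two as the
#' relative sigmas from the sensitivity re-runs applied to the ensemble-mean
#' kilometres -- combined by root sum of squares into the total sigma used
#' for the symmetric mean +/- sigma error bars.
#'
#' @param summary output of [summarizeKm()].
#' @param thickness output of [thicknessSensitivity()].
#' @param segLength output of [segmentLengthSensitivity()].
#' @return data.frame with columns `sigmaMember`, `sigmaThickness`,
#'   `sigmaSegment`, `sigmaTotal` (km) appended to the ensemble means.
#' @export
uncertaintyBudget <- function(summary, thickness, segLength) {
  ens <- ensembleStats(summary)
  key <- paste(ens$criteria, ens$class)
  relT <- thickness$relSigma[match(key, paste(thickness$criteria,
                                              thickness$class))]
  sl <- segLength$sigma
  relS <- sl$relSigma[match(key, paste(sl$criteria, sl$class))]
  relT[is.na(relT)] <- 0
  relS[is.na(relS)] <- 0
  ens$sigmaMember <- ens$sdKm
  ens$sigmaThickness <- relT * ens$meanKm
  ens$sigmaSegment <- relS * ens$meanKm
  ens$sigmaTotal <- mapply(function(a, b, c) combineRSS(c(a, b, c)),
                           ens$sigmaMember, ens$sigmaThickness,
                           ens$sigmaSegment)
  ens
}
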