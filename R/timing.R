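#' Construct a retreat schedule
#'
#' @param glacierId,member,scenario identifying tags (glacier, ensemble
#'   member emulating a GCM forcing, emissions scenario).
#' @param startYear,endYear horizon (inclusive); extent at `startYear` is the
#'   full footprint.
#' @param cells footprint cell indices (1-based, column-major).
#' @param meltYear first ice-free year per cell (`NA` = never within the
#'   horizon); must be > `startYear`.
#' @return A [RetreatSchedule-class].
#' @export
retreatSchedule <- function(glacierId, member, scenario, startYear, endYear,
                            cells, meltYear) {
  new("RetreatSchedule", glacierId = as.character(glacierId),
      member = as.character(member), scenario = as.character(scenario),
      startYear = as.numeric(startYear), endYear = as.numeric(endYear),
      cells = as.integer(cells), meltYear = as.numeric(meltYear))
}

#' Decadal-mean benchmark extent of a retreat schedule
#'
#' The benchmark extent around a center year is the per-cell majority of the
#' annual extent masks over a window of `window` years
#' (`[center - window/2, center + window/2 - 1]`): a cell is ice-covered in
#' the benchmark when it is covered in at least 50% of the window's annual
#' masks. This operationalizes a "10-year average" of a set-valued extent.
#' The `"complete"` benchmark is the empty mask (full deglaciation).
#'
#' @param sched a [RetreatSchedule-class].
#' @param center benchmark center year (e.g. 2050 or 2100), or `"complete"`.
#' @param window averaging window in years (default 10); the window must lie
#'   within the schedule horizon.
#' @return A list of class `"benchmarkExtent"` with elements `center`,
#'   `window` and `coveredCells` (integer cell indices).
#' @export
benchmarkExtent <- function(sched, center, window = 10) {
  stopifnot(is(sched, "RetreatSchedule"), window >= 1)
  if (identical(center, "complete"))
    return(structure(list(center = "complete", window = window,
                          coveredCells = integer(0)),
                     class = "benchmarkExtent"))
  lo <- center - window / 2
  hi <- center + window / 2 - 1
  if (lo < sched@startYear || hi > sched@endYear)
    stop("benchmark window [", lo, ", ", hi, "] outside schedule horizon")
  years <- seq(lo, hi)
  m <- sched@meltYear
  # covered in year y iff meltYear > y; count covered years in the window
  count <- ifelse(is.na(m), length(years),
                  pmin(pmax(m - lo, 0), length(years)))
  structure(list(center = center, window = window,
                 coveredCells = sched@cells[count >= length(years) / 2]),
            class = "benchmarkExtent")
}

#' Exposure year of segments under a set of retreat schedules
#'
#' The exposure year of a segment is the first year in which every cell of
#' its path is outside the annual ice mask. Partial exposure does not count:
#' a segment becomes available only as a whole. Segments fully outside all
#' initial footprints are exposed at the start year; segments containing a
#' cell that never deglaciates within the horizon get `Inf` (never).
#'
#' @param segments a segment table.
#' @param schedules list of [RetreatSchedule-class] objects for one ensemble
#'   member and scenario (one schedule per glacier).
#' @param dims grid dimensions `(rows, cols)` the cell indices refer to.
#' @return Numeric vector of exposure years aligned with the segment table.
#' @export
exposureYear <- function(segments, schedules, dims) {
  if (length(schedules) == 0)
    return(rep(if (nrow(segments)) NA_real_ else numeric(0),
               nrow(segments)))
  start <- schedules[[1]]@startYear
  melt <- rep(-Inf, prod(dims))
  for (s in schedules) {
    stopifnot(is(s, "RetreatSchedule"))
    my <- s@meltYear
    my[is.na(my)] <- Inf
    melt[s@cells] <- pmax(melt[s@cells], my)
  }
  nr <- dims[1]
  vapply(segments$path, function(p)
    max(start, melt[.linIndex(p[, 1], p[, 2], nr)]), numeric(1))
}

#' Summarize exposed stream kilometres by benchmark
#'
#' For every emissions scenario, ensemble member, habitat-criteria scenario,
#' benchmark and class, sums the length of future segments that are exposed
#' by the benchmark year and carry the class flag. A future segment counts
#' toward a benchmark when its whole path is ice-free in the decadal-mean
#' benchmark extent, which for monotone schedules is exactly
#' `exposureYear < center`; the `"complete"` benchmark counts every future
#' segment. Under monotone schedules the totals are non-decreasing:
#' km(2050) <= km(2100) <= km(complete) within each member.
#'
#' @param segments combined segment table (present + future provenance).
#' @param schedulesByRun nested list: `schedulesByRun[[scenario]][[member]]`
#'   is a list of per-glacier [RetreatSchedule-class] objects.
#' @param criteriaList named list of [habitatCriteria()] scenarios (e.g.
#'   conservative, inclusive).
#' @param dims grid dimensions.
#' @param benchmarks numeric benchmark center years (default 2050, 2100);
#'   `"complete"` is always included.
#' @param regions character vector assigning each segment to a sub-region
#'   (default a single region `"all"`); a future segment without an
#'   assignment is an error.
#' @return Tidy data.frame: `region`, `scenario`, `member`, `criteria`,
#'   `benchmark`, `class`, `km`.
#' @export
summarizeKm <- function(segments, schedulesByRun, criteriaList, dims,
                        benchmarks = c(2050, 2100),
                        regions = rep("all", nrow(segments))) {
  stopifnot(length(regions) == nrow(segments))
  isFuture <- startsWith(segments$provenance, "future")
  if (any(isFuture & is.na(regions)))
    stop("segment without region assignment: ",
         paste(utils::head(segments$segId[isFuture & is.na(regions)], 5),
               collapse = ", "))
  classed <- lapply(criteriaList, function(cr) {
    s <- classifySegments(segments, cr)
    list(accessible = s$accessible, habitat = s$habitat)
  })
  out <- list()
  benchLabels <- c(as.character(benchmarks), "complete")
  regionLevels <- sort(unique(regions[isFuture]))
  if (length(regionLevels) == 0) regionLevels <- "all"
  for (scen in names(schedulesByRun)) {
    members <- schedulesByRun[[scen]]
    for (mem in names(members)) {
      expo <- exposureYear(segments, members[[mem]], dims)
      for (crName in names(classed)) {
        fl <- classed[[crName]]
        for (cls in c("accessible", "habitat")) {
          inClass <- isFuture & fl[[cls]]
          for (b in seq_along(benchLabels)) {
            lim <- if (benchLabels[b] == "complete") Inf else benchmarks[b]
            hit <- inClass & (is.infinite(lim) | expo < lim)
            km <- tapply(segments$length_m[hit], factor(regions[hit],
                         levels = regionLevels), sum)
            km[is.na(km)] <- 0
            out[[length(out) + 1L]] <- data.frame(
              region = regionLevels, scenario = scen, member = mem,
              criteria = crName, benchmark = benchLabels[b], class = cls,
              km = as.numeric(km) / 1000, row.names = NULL)
          }
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Relative increase in salmon-accessible stream kilometres
#'
#' Percent gain per region: 100 times the projected future accessible
#' kilometres at the 2100 benchmark (ensemble mean over members) divided by
#' the present-day accessible kilometres under the same gradient threshold.
#' Regions with zero present-day accessible kilometres are reported as `NA`
#' (not applicable).
#'
#' @param summary output of [summarizeKm()].
#' @param presentKm data.frame with columns `region`, `criteria`, `km`
#'   giving present-day accessible stream kilometres.
#' @param benchmark benchmark label to evaluate (default `"2100"`).
#' @param class class to evaluate (default `"accessible"`).
#' @return data.frame: `region`, `scenario`, `criteria`, `futureKm`,
#'   `presentKm`, `percent`.
#' @export
relativeIncrease <- function(summary, presentKm, benchmark = "2100",
                             class = "accessible") {
  s <- summary[summary$benchmark == benchmark & summary$class == class, ]
  agg <- stats::aggregate(km ~ region + scenario + criteria, data = s,
                          FUN = mean)
  names(agg)[names(agg) == "km"] <- "futureKm"
  m <- merge(agg, presentKm, by = c("region", "criteria"), all.x = TRUE)
  names(m)[names(m) == "km"] <- "presentKm"
  m$percent <- ifelse(!is.na(m$presentKm) & m$presentKm > 0,
                      100 * m$futureKm / m$presentKm, NA_real_)
  m
}
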