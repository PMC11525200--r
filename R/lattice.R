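#' Run a lattice simulation of multicolor clonal labeling
#'
#' Simulates a confluent basal layer as a lattice of cells evolving by
#' continuous-time division-stratification events: at total rate
#' \eqn{N\lambda} a cell is chosen uniformly to divide, and a second cell —
#' a uniform von Neumann neighbor in \code{"neighbor"} mode, a uniform
#' lattice site in \code{"mean_field"} mode — stratifies (leaves the basal
#' layer) and is replaced by the daughter, which inherits the mother's
#' color. Occupancy is therefore conserved exactly at every event, and the
#' labeled fraction of every color is a martingale (neutral drift). In
#' mean-field mode small clones behave as the critical birth-death process
#' with \eqn{\kappa = \lambda}, enabling exact comparison with the closed
#' forms of [survivalProbability()] and [meanSurvivingSize()].
#'
#' @param config a [LatticeConfig]. The RNG is seeded from
#'   \code{config@seed}; identical configs give identical traces.
#' @param recordComponents if \code{FALSE}, skip connected-component
#'   extraction (the \code{scaRecords} slot is left empty); the per-color
#'   label fractions are always recorded.
#' @return a [SimTrace].
#' @examples
#' cfg <- LatticeConfig(16, 16, DriftParams(kappa = 0.5, r = 0.5,
#'                      lambdaDiv = 1), colors = 4, duration = 4, seed = 7)
#' tr <- runLattice(cfg)
#' head(scaRecords(tr))
#' @export
runLattice <- function(config, recordComponents = TRUE) {
    stopifnot(is(config, "LatticeConfig"))
    validObject(config)
    old <- .save_seed()
    on.exit(.restore_seed(old), add = TRUE)
    set.seed(config@seed)
    N <- config@width * config@height
    grid0 <- integer(N)
    lab <- runif(N) < config@labeledFraction
    grid0[lab] <- sample.int(config@colors, sum(lab), replace = TRUE)
    res <- cpp_run_lattice(grid0, config@width, config@height,
                           config@boundary == "periodic",
                           config@mode == "mean_field",
                           config@params@lambdaDiv, config@duration,
                           config@sampleInterval)
    times <- res$times
    snaps <- res$snapshots
    lf <- matrix(0, length(times), config@colors,
                 dimnames = list(NULL, paste0("color", seq_len(config@colors))))
    recs <- vector("list", length(times))
    for (i in seq_along(times)) {
        g <- snaps[[i]]
        stopifnot(length(g) == N)  # occupancy conservation
        lf[i, ] <- tabulate(g[g > 0], nbins = config@colors) / N
        if (recordComponents) {
            comp <- cpp_label_components(g, config@width, config@height, 4L)
            if (length(comp$size)) {
                recs[[i]] <- data.frame(
                    time_weeks = times[i],
                    color = comp$color,
                    component_id = seq_along(comp$size),
                    area_mm2 = comp$size * config@areaPerCell)
            }
        }
    }
    recs <- recs[!vapply(recs, is.null, TRUE)]
    sca <- if (length(recs)) do.call(rbind, recs) else
        data.frame(time_weeks = numeric(), color = integer(),
                   component_id = integer(), area_mm2 = numeric())
    new("SimTrace", sampleTimes = times, scaRecords = sca,
        labelFraction = lf, config = config)
}

#' Extract single-colored areas from a color field
#'
#' Same-color connected components of a labeled lattice: an SCA is a
#' maximal connected region of identically colored labeled sites (merged
#' same-color neighboring clones count as one SCA). Unlabeled sites
#' (value 0) are excluded.
#'
#' @param grid integer matrix; 0 = unlabeled, positive integers = colors.
#' @param connectivity 4 (von Neumann, default) or 8 (Moore).
#' @param areaPerCell mm^2 per site (default 1: areas in site units).
#' @return data.frame with columns \code{component_id}, \code{color},
#'   \code{area} (site count times \code{areaPerCell}).
#' @export
labelComponents <- function(grid, connectivity = 4, areaPerCell = 1) {
    if (!is.matrix(grid)) stop("'grid' must be a matrix")
    if (!connectivity %in% c(4, 8))
        stop("'connectivity' must be 4 or 8")
    # column-major matrix maps to width = nrow when traversed by column;
    # treat rows as x so adjacency matches the matrix layout
    comp <- cpp_label_components(as.integer(grid), nrow(grid), ncol(grid),
                                 as.integer(connectivity))
    data.frame(component_id = seq_along(comp$size), color = comp$color,
               area = comp$size * areaPerCell)
}

#' Summarise a simulation trace into drift curves
#'
#' Applies the imaging detection limit to the per-time SCA records of a
#' [SimTrace]: components with area below the threshold are treated as
#' indistinguishable from background (count 0, area 0). Sample times where
#' no component passes the threshold get count 0 and missing (NA) mean
#' area.
#'
#' @param trace a [SimTrace].
#' @param detectionThreshold mm^2, >= 0.
#' @return a [DriftCurve] over the trace's sample times.
#' @export
traceToSummary <- function(trace, detectionThreshold = 0) {
    stopifnot(is(trace, "SimTrace"))
    if (detectionThreshold < 0)
        stop("'detectionThreshold' must be >= 0")
    if (!length(trace@sampleTimes)) stop("empty trace")
    times <- trace@sampleTimes
    rec <- trace@scaRecords
    meanA <- totA <- cnt <- numeric(length(times))
    for (i in seq_along(times)) {
        a <- rec$area_mm2[rec$time_weeks == times[i]]
        a <- a[a >= detectionThreshold & a > 0]
        cnt[i] <- length(a)
        totA[i] <- sum(a)
        meanA[i] <- if (length(a)) mean(a) else NA_real_
    }
    DriftCurve(times = times, meanArea = meanA, count = cnt,
               totalArea = totA)
}
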