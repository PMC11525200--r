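#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats mad median optimize p.adjust quantile rbinom rlnorm
#'   rnbinom runif sd wilcox.test rgeom lm coef
#' @importFrom utils head read.delim write.table
#' @importFrom Rcpp sourceCpp
#' @useDynLib epidrift, .registration = TRUE
NULL

.rel_tol <- 1e-9

#' Single-progenitor drift parameters
#'
#' Container for the parameters of the single-progenitor (SP) neutral-drift
#' model. The one parameter that governs all analytic predictions is the
#' composite drift rate \eqn{\kappa = r\lambda} (per week), the product of the
#' symmetric-division probability \eqn{r} and the division rate \eqn{\lambda}.
#' \eqn{r} and \eqn{\lambda} are optional (they are not separately
#' identifiable from neutral summary curves); the basal-layer density
#' \eqn{\rho} (cells per mm^2) converts cell counts to areas.
#'
#' @slot kappa numeric(1), drift rate per week, > 0.
#' @slot r numeric(1), symmetric-division probability in (0, 0.5], or NA.
#' @slot lambdaDiv numeric(1), division rate per week > 0, or NA.
#' @slot rho numeric(1), basal cell density (cells/mm^2) > 0, or NA.
#'
#' @examples
#' dp <- DriftParams(kappa = 0.25, rho = 50)
#' kappa(dp)
#' @export
setClass("DriftParams", representation(
    kappa = "numeric", r = "numeric", lambdaDiv = "numeric", rho = "numeric"
))

setValidity("DriftParams", function(object) {
    msg <- character()
    k <- object@kappa
    if (length(k) != 1L || !is.finite(k) || k <= 0)
        msg <- c(msg, "'kappa' must be a single positive finite number")
    if (!is.na(object@r) && (object@r <= 0 || object@r > 0.5))
        msg <- c(msg, "'r' must lie in (0, 0.5]")
    if (!is.na(object@lambdaDiv) && object@lambdaDiv < 0)
        msg <- c(msg, "'lambdaDiv' must be >= 0")  # 0 = frozen dynamics
    if (!is.na(object@rho) && object@rho <= 0)
        msg <- c(msg, "'rho' must be > 0")
    if (!is.na(object@r) && !is.na(object@lambdaDiv) && length(k) == 1L &&
        is.finite(k) && abs(object@r * object@lambdaDiv - k) > .rel_tol * k)
        msg <- c(msg, "kappa must equal r * lambdaDiv")
    if (length(msg)) msg else TRUE
})

#' @param kappa drift rate per week (rate of clone-size variance growth);
#'   if missing it is computed as \code{r * lambdaDiv}.
#' @param r optional symmetric-division probability.
#' @param lambdaDiv optional division rate per week.
#' @param rho optional basal density, cells per mm^2.
#' @rdname DriftParams-class
#' @export
DriftParams <- function(kappa = NULL, r = NA_real_, lambdaDiv = NA_real_,
                        rho = NA_real_) {
    if (is.null(kappa)) {
        if (is.na(r) || is.na(lambdaDiv))
            stop("supply 'kappa', or both 'r' and 'lambdaDiv'")
        kappa <- r * lambdaDiv
    }
    new("DriftParams", kappa = as.numeric(kappa), r = as.numeric(r),
        lambdaDiv = as.numeric(lambdaDiv), rho = as.numeric(rho))
}

#' Cohort summary curves of clone dynamics
#'
#' Per-time summaries of a cohort of labeled clones: mean area of surviving
#' single-colored areas (SCA), number of surviving SCA, and total labeled
#' area. This is both the target of the analytic single-parameter fit and the
#' output of the lattice simulation and of observed-cohort summarisation.
#' Times with no surviving clone carry \code{NA} mean area (flagged missing,
#' not zero).
#'
#' @slot times numeric, weeks, strictly increasing.
#' @slot meanArea numeric, mean surviving SCA area (mm^2); NA where count 0.
#' @slot count numeric, number of surviving SCA (>= 0).
#' @slot totalArea numeric, summed surviving SCA area (mm^2).
#'
#' @export
setClass("DriftCurve", representation(
    times = "numeric", meanArea = "numeric", count = "numeric",
    totalArea = "numeric"
))

setValidity("DriftCurve", function(object) {
    msg <- character()
    n <- length(object@times)
    if (length(object@meanArea) != n || length(object@count) != n ||
        length(object@totalArea) != n)
        msg <- c(msg, "all slots must have equal length")
    if (n > 1 && any(diff(object@times) <= 0))
        msg <- c(msg, "'times' must be strictly increasing")
    if (any(object@count < 0, na.rm = TRUE))
        msg <- c(msg, "'count' must be >= 0")
    if (any(object@totalArea < -.rel_tol, na.rm = TRUE) ||
        any(object@meanArea < -.rel_tol, na.rm = TRUE))
        msg <- c(msg, "areas must be >= 0")
    pos <- which(object@count > 0 & is.finite(object@meanArea))
    if (length(pos)) {
        expect <- object@meanArea[pos] * object@count[pos]
        bad <- abs(object@totalArea[pos] - expect) >
            .rel_tol * pmax(1, abs(expect))
        if (any(bad))
            msg <- c(msg, "totalArea must equal meanArea * count where count > 0")
    }
    if (length(msg)) msg else TRUE
})

#' @param times,meanArea,count,totalArea numeric vectors of equal length;
#'   \code{totalArea} defaults to \code{meanArea * count}.
#' @rdname DriftCurve-class
#' @export
DriftCurve <- function(times, meanArea, count,
                       totalArea = ifelse(count > 0, meanArea * count, 0)) {
    new("DriftCurve", times = as.numeric(times),
        meanArea = as.numeric(meanArea), count = as.numeric(count),
        totalArea = as.numeric(totalArea))
}

#' Result of the single-parameter drift fit
#'
#' @slot kappaHat numeric(1), fitted drift rate per week.
#' @slot kappaCI numeric(2), bootstrap percentile interval (low, high).
#' @slot objective numeric(1), final sum of squared relative residuals.
#' @slot nPoints integer(1), number of fitted observations.
#' @slot t0 numeric(1), labeling time origin (weeks).
#' @slot warnings character, diagnostic flags (e.g. "increasing_counts").
#'
#' @export
setClass("FitResult", representation(
    kappaHat = "numeric", kappaCI = "numeric", objective = "numeric",
    nPoints = "integer", t0 = "numeric", warnings = "character"
))

setValidity("FitResult", function(object) {
    msg <- character()
    if (object@kappaHat <= 0)
        msg <- c(msg, "'kappaHat' must be > 0")
    if (length(object@kappaCI) != 2L)
        msg <- c(msg, "'kappaCI' must have length 2")
    else if (all(is.finite(object@kappaCI)) &&
             (object@kappaCI[1] > object@kappaHat ||
              object@kappaCI[2] < object@kappaHat))
        msg <- c(msg, "'kappaCI' must bracket 'kappaHat'")
    if (object@objective < 0)
        msg <- c(msg, "'objective' must be >= 0")
    if (length(msg)) msg else TRUE
})

#' One clone's weekly area trajectory
#'
#' The unit record of SCA lineage tracing: a clone's measured area per
#' observation week. A recorded 0 means the clone was below the detection
#' limit that week (indistinguishable from background); a missing week means
#' no observation.
#'
#' @slot scaId character(1) clone identifier.
#' @slot cultureId character(1) culture identifier.
#' @slot areas named numeric, names are integer weeks, values areas (mm^2,
#'   >= 0).
#'
#' @export
setClass("SCATrajectory", representation(
    scaId = "character", cultureId = "character", areas = "numeric"
))

setValidity("SCATrajectory", function(object) {
    msg <- character()
    a <- object@areas
    if (is.null(names(a)) || anyNA(suppressWarnings(as.integer(names(a)))))
        msg <- c(msg, "'areas' must be named by integer weeks")
    if (any(a < 0, na.rm = TRUE))
        msg <- c(msg, "areas must be >= 0")
    if (length(msg)) msg else TRUE
})

#' @param scaId,cultureId identifiers.
#' @param areas named numeric vector of areas (mm^2), names = weeks.
#' @rdname SCATrajectory-class
#' @export
SCATrajectory <- function(scaId, cultureId, areas) {
    new("SCATrajectory", scaId = as.character(scaId),
        cultureId = as.character(cultureId), areas = areas)
}

#' Lattice simulation configuration
#'
#' Specification of a stochastic voter-model simulation of multicolor clonal
#' labeling in a confluent basal layer. Each division-stratification event
#' replaces one stratifying cell with the daughter of a dividing cell, so the
#' layer stays confluent.
#'
#' @slot width,height integer lattice dimensions (sites = cells).
#' @slot boundary "periodic" or "reflecting".
#' @slot colors integer, number of label colors (plus an implicit unlabeled
#'   state 0).
#' @slot labeledFraction numeric in [0,1], probability a site is labeled at
#'   time 0 (labeled sites draw a color uniformly).
#' @slot params a [DriftParams]; \code{lambdaDiv} is the per-cell division
#'   rate (per week).
#' @slot mode "neighbor" (von Neumann voter rule) or "mean_field" (the
#'   stratifying cell is drawn uniformly from the whole lattice).
#' @slot duration,sampleInterval weeks.
#' @slot areaPerCell mm^2 per lattice site.
#' @slot seed integer RNG seed.
#'
#' @export
setClass("LatticeConfig", representation(
    width = "integer", height = "integer", boundary = "character",
    colors = "integer", labeledFraction = "numeric", params = "DriftParams",
    mode = "character", duration = "numeric", sampleInterval = "numeric",
    areaPerCell = "numeric", seed = "integer"
))

setValidity("LatticeConfig", function(object) {
    msg <- character()
    if (object@width * object@height < 4)
        msg <- c(msg, "lattice must have >= 4 sites")
    if (object@labeledFraction < 0 || object@labeledFraction > 1)
        msg <- c(msg, "'labeledFraction' must be in [0, 1]")
    if (object@duration <= 0) msg <- c(msg, "'duration' must be > 0")
    if (object@sampleInterval <= 0)
        msg <- c(msg, "'sampleInterval' must be > 0")
    if (object@areaPerCell <= 0) msg <- c(msg, "'areaPerCell' must be > 0")
    if (!object@boundary %in% c("periodic", "reflecting"))
        msg <- c(msg, "'boundary' must be 'periodic' or 'reflecting'")
    if (!object@mode %in% c("neighbor", "mean_field"))
        msg <- c(msg, "'mode' must be 'neighbor' or 'mean_field'")
    if (object@colors < 1) msg <- c(msg, "'colors' must be >= 1")
    if (is.na(object@params@lambdaDiv))
        msg <- c(msg, "'params@lambdaDiv' must be set for lattice simulation")
    if (length(msg)) msg else TRUE
})

#' @param width,height lattice dimensions.
#' @param boundary "periodic" (default) or "reflecting".
#' @param colors number of label colors.
#' @param labeledFraction initial labeling probability per site.
#' @param params a [DriftParams] with \code{lambdaDiv} set.
#' @param mode "neighbor" (default) or "mean_field".
#' @param duration simulated weeks.
#' @param sampleInterval weeks between snapshots.
#' @param areaPerCell mm^2 per site; defaults to \code{1/rho} when
#'   \code{params@rho} is set, else 1.
#' @param seed integer RNG seed.
#' @rdname LatticeConfig-class
#' @export
LatticeConfig <- function(width, height, params, colors = 4L,
                          labeledFraction = 1, boundary = "periodic",
                          mode = "neighbor", duration = 12,
                          sampleInterval = 1, areaPerCell = NULL,
                          seed = 1L) {
    if (is.null(areaPerCell))
        areaPerCell <- if (!is.na(params@rho)) 1 / params@rho else 1
    new("LatticeConfig", width = as.integer(width),
        height = as.integer(height), boundary = boundary,
        colors = as.integer(colors),
        labeledFraction = as.numeric(labeledFraction), params = params,
        mode = mode, duration = as.numeric(duration),
        sampleInterval = as.numeric(sampleInterval),
        areaPerCell = as.numeric(areaPerCell), seed = as.integer(seed))
}

#' Output trace of a lattice simulation
#'
#' @slot sampleTimes numeric, weeks at which the lattice was sampled.
#' @slot scaRecords data.frame with columns \code{time_weeks}, \code{color},
#'   \code{component_id}, \code{area_mm2}: every same-color connected
#'   component (SCA) at every sample time.
#' @slot labelFraction numeric matrix, sample times x colors; fraction of
#'   sites carrying each color.
#' @slot config the generating [LatticeConfig].
#'
#' @export
setClass("SimTrace", representation(
    sampleTimes = "numeric", scaRecords = "data.frame",
    labelFraction = "matrix", config = "LatticeConfig"
))

setValidity("SimTrace", function(object) {
    msg <- character()
    cfg <- object@config
    cap <- cfg@width * cfg@height * cfg@areaPerCell
    if (nrow(object@scaRecords)) {
        tot <- tapply(object@scaRecords$area_mm2,
                      object@scaRecords$time_weeks, sum)
        if (any(tot > cap * (1 + 1e-9)))
            msg <- c(msg, "summed SCA area exceeds lattice area")
        mult <- object@scaRecords$area_mm2 / cfg@areaPerCell
        if (any(abs(mult - round(mult)) > 1e-6) || any(mult < 0.5))
            msg <- c(msg, "component areas must be positive multiples of areaPerCell")
    }
    if (nrow(object@labelFraction) != length(object@sampleTimes))
        msg <- c(msg, "labelFraction rows must match sampleTimes")
    if (length(msg)) msg else TRUE
})

#' Two-population competition time series
#'
#' Proportion of a focal subpopulation over time in a mixed culture, as read
#' out by cell sampling (e.g. flow cytometry).
#'
#' @slot times numeric weeks, strictly increasing.
#' @slot proportion numeric in (0, 1].
#' @slot focalLabel character(1), name of the focal population.
#' @slot nCellsSampled numeric, cells sampled per time (NA if unknown).
#'
#' @export
setClass("CompetitionSeries", representation(
    times = "numeric", proportion = "numeric", focalLabel = "character",
    nCellsSampled = "numeric"
))

setValidity("CompetitionSeries", function(object) {
    msg <- character()
    if (length(object@times) != length(object@proportion))
        msg <- c(msg, "'times' and 'proportion' must have equal length")
    if (length(object@times) > 1 && any(diff(object@times) <= 0))
        msg <- c(msg, "'times' must be strictly increasing")
    if (any(object@proportion <= 0 | object@proportion > 1))
        msg <- c(msg, "'proportion' must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' @param times,proportion numeric vectors.
#' @param focalLabel name of the focal population.
#' @param nCellsSampled optional cells sampled per time point.
#' @rdname CompetitionSeries-class
#' @export
CompetitionSeries <- function(times, proportion, focalLabel = "focal",
                              nCellsSampled = rep(NA_real_, length(times))) {
    new("CompetitionSeries", times = as.numeric(times),
        proportion = as.numeric(proportion), focalLabel = focalLabel,
        nCellsSampled = as.numeric(nCellsSampled))
}

#' Guide RNA count table for a pooled fitness screen
#'
#' A \linkS4class{SummarizedExperiment} subclass. Rows are gRNAs with
#' \code{rowData} columns \code{guide_id}, \code{gene} (NA for nontargeting
#' guides) and \code{category} (one of \code{driver},
#' \code{cancer_candidate}, \code{essential}, \code{NT}); columns are samples
#' with \code{colData} columns \code{replicate} and \code{timepoint}
#' (\code{week0} or \code{week3}); the \code{counts} assay holds nonnegative
#' integer read counts.
#'
#' @export
setClass("GuideTable", contains = "SummarizedExperiment")

.guide_categories <- c("driver", "cancer_candidate", "essential", "NT")

setValidity("GuideTable", function(object) {
    msg <- character()
    rd <- SummarizedExperiment::rowData(object)
    cd <- SummarizedExperiment::colData(object)
    need_rd <- c("guide_id", "gene", "category")
    if (!all(need_rd %in% colnames(rd)))
        return(paste("rowData must have columns:",
                     paste(need_rd, collapse = ", ")))
    if (!all(c("replicate", "timepoint") %in% colnames(cd)))
        return("colData must have columns: replicate, timepoint")
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("assay 'counts' is required")
    if (!all(rd$category %in% .guide_categories))
        msg <- c(msg, paste("category must be one of:",
                            paste(.guide_categories, collapse = ", ")))
    if (!all(cd$timepoint %in% c("week0", "week3")))
        msg <- c(msg, "timepoint must be 'week0' or 'week3'")
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(cts < 0) || any(cts != round(cts)))
        msg <- c(msg, "counts must be nonnegative integers")
    if (any(rd$category == "NT" & !is.na(rd$gene)))
        msg <- c(msg, "NT guides must have gene = NA")
    both <- all(c("week0", "week3") %in% cd$timepoint)
    if (!both)
        msg <- c(msg, "both timepoints week0 and week3 must be present")
    if (length(msg)) msg else TRUE
})

#' @param counts integer matrix, guides x samples.
#' @param guide_id,gene,category per-guide annotation vectors.
#' @param replicate,timepoint per-sample annotation vectors.
#' @rdname GuideTable-class
#' @export
GuideTable <- function(counts, guide_id, gene, category, replicate,
                       timepoint) {
    rownames(counts) <- guide_id
    colnames(counts) <- paste(replicate, timepoint, sep = "_")
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        rowData = S4Vectors::DataFrame(guide_id = guide_id, gene = gene,
                                       category = category),
        colData = S4Vectors::DataFrame(replicate = replicate,
                                       timepoint = timepoint))
    new("GuideTable", se)
}
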