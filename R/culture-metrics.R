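#' Relative fitness from a competition series
#'
#' Fold increase of the focal subpopulation's proportion at time \code{t}
#' versus its proportion at the initial time point. 1 means neutral
#' competition; values above 1 mean the focal population outcompetes its
#' neighbors.
#'
#' @param series a [CompetitionSeries].
#' @param t week; must be one of the series' time points.
#' @param log2 if TRUE return log2 of the fold change (convenience; the
#'   plain fold is the primary statistic).
#' @return fold change (or its log2).
#' @export
relativeFitness <- function(series, t, log2 = FALSE) {
    stopifnot(is(series, "CompetitionSeries"))
    validObject(series)
    i <- match(t, series@times)
    if (is.na(i)) stop("time ", t, " not present in series")
    p0 <- series@proportion[1]
    if (p0 <= 0) stop("initial proportion is 0; fitness undefined")
    f <- series@proportion[i] / p0
    if (log2) base::log2(f) else f
}

#' Suprabasal-to-basal stratification ratio
#'
#' @param nSuprabasal,nBasal cell counts (e.g. ITGA6-negative and
#'   ITGA6-positive populations from flow cytometry).
#' @return \code{nSuprabasal / nBasal}.
#' @export
stratificationRatio <- function(nSuprabasal, nBasal) {
    if (any(nBasal <= 0)) stop("'nBasal' must be > 0")
    if (any(nSuprabasal < 0)) stop("'nSuprabasal' must be >= 0")
    nSuprabasal / nBasal
}

#' Barrier permeability percentage
#'
#' Percentage of blank-subtracted fluorescence leaked through a cultured
#' barrier relative to the blank-subtracted 100% (no-cell) control:
#' \code{100 * (fSample - fBlank) / (fMax - fBlank)}. Values outside
#' [0, 100] can arise from assay noise and are returned unclipped with an
#' \code{out_of_range} attribute.
#'
#' @param fSample,fBlank,fMax fluorescence readings (sample well, blank,
#'   100% leakage control).
#' @return percent, with attribute \code{out_of_range} (logical).
#' @export
permeabilityPercent <- function(fSample, fBlank, fMax) {
    if (any(fMax <= fBlank)) stop("'fMax' must exceed 'fBlank'")
    pct <- 100 * (fSample - fBlank) / (fMax - fBlank)
    attr(pct, "out_of_range") <- pct < 0 | pct > 100
    pct
}

#' Wound closure fractions and rate
#'
#' Fraction of the initial wound closed per imaging day,
#' \code{(A(0) - A(d)) / A(0)}, and the overall closure rate as the
#' ordinary least-squares slope of that fraction against day.
#'
#' @param areas named numeric: names are days (day 0 required), values
#'   wound areas (mm^2, >= 0).
#' @return list with \code{fraction_closed} (named numeric per day) and
#'   \code{rate_per_day} (slope).
#' @examples
#' a <- c("0" = 10, "5" = 10 * (1 - 5 / 15), "10" = 10 * (1 - 10 / 15))
#' woundClosureRate(a)$rate_per_day  # 1/15
#' @export
woundClosureRate <- function(areas) {
    if (any(areas < 0)) stop("wound areas must be >= 0")
    days <- as.numeric(names(areas))
    if (anyNA(days)) stop("'areas' must be named by day")
    o <- order(days)
    days <- days[o]; areas <- areas[o]
    if (days[1] != 0) stop("a day-0 area is required")
    if (areas[1] <= 0) stop("day-0 area must be > 0")
    frac <- (areas[1] - areas) / areas[1]
    names(frac) <- days
    slope <- unname(coef(lm(frac ~ days))[2])
    list(fraction_closed = frac, rate_per_day = slope)
}

#' Projected expansion fold under repeated punch passaging
#'
#' Each passage round cuts a confluent membrane into \code{splitFactor}
#' pieces, each regrowing to confluence, so the projected amplification
#' after \code{rounds} passages is
#' \code{initialFold * splitFactor^rounds}. With the observed 57-fold
#' initial amplification, 16 pieces per membrane and 4 rounds this gives
#' about 3.7e6-fold.
#'
#' @param initialFold amplification of the starting culture (> 0).
#' @param splitFactor pieces per passage (>= 1).
#' @param rounds number of passage rounds (integer >= 0).
#' @param signif significant figures for the reported value (default NULL:
#'   exact).
#' @return projected fold expansion.
#' @examples
#' expansionProjection(57, 16, 4)             # 3735552
#' expansionProjection(57, 16, 4, signif = 2) # 3.7e6
#' @export
expansionProjection <- function(initialFold, splitFactor, rounds,
                                signif = NULL) {
    if (initialFold <= 0) stop("'initialFold' must be > 0")
    if (splitFactor < 1) stop("'splitFactor' must be >= 1")
    if (rounds < 0 || rounds != round(rounds))
        stop("'rounds' must be a nonnegative integer")
    out <- initialFold * splitFactor^rounds
    if (!is.null(signif)) out <- base::signif(out, signif)
    out
}

#' Harvest amplification fold
#'
#' Ratio of harvested to initial cell number, e.g. cells counted at
#' confluence versus the estimated basal cells in the plated explant.
#'
#' @param harvestedCells,initialCells cell counts.
#' @return \code{harvestedCells / initialCells}.
#' @examples
#' harvestFold(2.0e6, 3.6e4)  # about 55.6
#' @export
harvestFold <- function(harvestedCells, initialCells) {
    if (any(initialCells <= 0)) stop("'initialCells' must be > 0")
    harvestedCells / initialCells
}
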