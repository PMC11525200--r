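.windows <- list(A4_8 = 4:8, A10_13 = 10:13, A15_19 = 15:19)

#' Window means of an SCA trajectory
#'
#' Arithmetic means of the available weekly areas in the three inclusive
#' classification windows: weeks 4-8 (A4_8), 10-13 (A10_13) and 15-19
#' (A15_19). Recorded zeros (below detection) enter the means; missing
#' weeks are simply absent. A window with no observed week at all makes the
#' trajectory ineligible for classification.
#'
#' @param traj an [SCATrajectory].
#' @return named numeric of length 3: \code{A4_8}, \code{A10_13},
#'   \code{A15_19}.
#' @export
windowMeans <- function(traj) {
    stopifnot(is(traj, "SCATrajectory"))
    validObject(traj)
    wk <- as.integer(names(traj@areas))
    out <- vapply(names(.windows), function(w) {
        sel <- wk %in% .windows[[w]] & !is.na(traj@areas)
        if (!any(sel))
            stop("SCA '", traj@scaId, "' has no observation in window ", w,
                 "; ineligible for classification")
        mean(traj@areas[sel])
    }, numeric(1))
    out
}

.classes <- c("Decay1", "Decay2", "Decay3", "Biphasic", "Growing", "Steady")

#' Classify an SCA trajectory
#'
#' Applies the windowed decision rules in order: \code{Decay1} if
#' A10_13 = 0 and A15_19 = 0; \code{Decay2} if A10_13 > 0 and A15_19 = 0;
#' \code{Decay3} if A4_8 > A10_13 > A15_19; \code{Biphasic} if
#' A4_8 < A10_13 > A15_19; \code{Growing} if A4_8 < A10_13 < A15_19;
#' everything else is \code{Steady}. Inequalities are strict; equality
#' cases fall through to the \code{Steady} catch-all. The classification is
#' invariant to rescaling all areas by a positive constant.
#'
#' @param traj an [SCATrajectory], or a numeric vector of the three window
#'   means \code{(A4_8, A10_13, A15_19)}.
#' @return a factor level among Decay1, Decay2, Decay3, Biphasic, Growing,
#'   Steady.
#' @examples
#' classifyTrajectory(c(3, 0, 0))  # Decay1
#' classifyTrajectory(c(1, 4, 2))  # Biphasic
#' @export
classifyTrajectory <- function(traj) {
    w <- if (is.numeric(traj) && length(traj) == 3) traj else windowMeans(traj)
    a1 <- w[[1]]; a2 <- w[[2]]; a3 <- w[[3]]
    cls <-
        if (a2 == 0 && a3 == 0) "Decay1"
        else if (a2 > 0 && a3 == 0) "Decay2"
        else if (a1 > a2 && a2 > a3) "Decay3"
        else if (a1 < a2 && a2 > a3) "Biphasic"
        else if (a1 < a2 && a2 < a3) "Growing"
        else "Steady"
    factor(cls, levels = .classes)
}

#' Classify a cohort of SCA trajectories
#'
#' @param trajs list of [SCATrajectory].
#' @return list with \code{class} (named factor per eligible SCA),
#'   \code{counts} and \code{proportions} (per class, over eligible SCA
#'   only), and \code{ineligible} (character vector of excluded SCA ids).
#' @export
classifyCohort <- function(trajs) {
    if (!length(trajs)) stop("empty cohort")
    stopifnot(all(vapply(trajs, is, TRUE, "SCATrajectory")))
    cls <- character(0)
    inel <- character(0)
    for (tr in trajs) {
        res <- tryCatch(as.character(classifyTrajectory(tr)),
                        error = function(e) NA_character_)
        if (is.na(res)) inel <- c(inel, tr@scaId)
        else { cls[tr@scaId] <- res }
    }
    if (!length(cls)) stop("no eligible trajectory in cohort")
    fac <- factor(cls, levels = .classes)
    counts <- table(fac)
    list(class = fac, counts = counts,
         proportions = counts / sum(counts), ineligible = inel)
}

#' Weekly cohort summary curves
#'
#' Per observation week across a trajectory cohort: number of surviving SCA
#' (area strictly greater than the detection threshold), their mean area,
#' and their total area. Weeks with no survivor get count 0 and missing
#' (NA) mean area. The default threshold is 0: the detection limit is
#' already encoded upstream as recorded zeros.
#'
#' @param trajs list of [SCATrajectory].
#' @param detectionThreshold mm^2 (default 0).
#' @return a [DriftCurve] over the union of observed weeks.
#' @export
cohortSummary <- function(trajs, detectionThreshold = 0) {
    if (!length(trajs)) stop("empty cohort")
    stopifnot(all(vapply(trajs, is, TRUE, "SCATrajectory")))
    wk <- sort(unique(unlist(lapply(trajs, function(t)
        as.integer(names(t@areas))))))
    cnt <- tot <- numeric(length(wk))
    mn <- rep(NA_real_, length(wk))
    for (i in seq_along(wk)) {
        a <- unlist(lapply(trajs, function(t) {
            v <- t@areas[names(t@areas) == as.character(wk[i])]
            v[!is.na(v)]
        }))
        surv <- a[a > detectionThreshold]
        cnt[i] <- length(surv)
        tot[i] <- sum(surv)
        if (length(surv)) mn[i] <- mean(surv)
    }
    DriftCurve(times = wk, meanArea = mn, count = cnt, totalArea = tot)
}

#' Matched-pairs Wilcoxon signed-rank test
#'
#' Two-sided Wilcoxon signed-rank test on paired area measurements (e.g.
#' the same SCA at two weeks). Zero differences are dropped; the null
#' distribution is exact for up to 25 informative pairs without ties in the
#' absolute differences, and a tie-corrected normal approximation with
#' continuity correction otherwise. If every difference is zero the test is
#' uninformative: p = 1 with a warning.
#'
#' @param x,y paired numeric vectors (same clones, two time points).
#' @return list with \code{statistic} (V, sum of positive-difference
#'   ranks), \code{p_value}, \code{n} (informative pairs) and
#'   \code{method}.
#' @examples
#' pairedSignedRank(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))$p_value  # 0.0625
#' @export
pairedSignedRank <- function(x, y) {
    if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
    d <- x - y
    d <- d[!is.na(d)]
    nz <- d[d != 0]
    if (!length(nz)) {
        warning("all differences are zero; test is uninformative")
        return(list(statistic = NA_real_, p_value = 1, n = 0L,
                    method = "degenerate"))
    }
    n <- length(nz)
    ties <- any(duplicated(abs(nz)))
    exact <- n <= 25 && !ties
    wt <- suppressWarnings(
        wilcox.test(nz, alternative = "two.sided", mu = 0, exact = exact,
                    correct = TRUE))
    list(statistic = unname(wt$statistic), p_value = wt$p.value, n = n,
         method = if (exact) "exact" else "normal approximation")
}

#' Convert lattice SCA records to trajectories
#'
#' Reshapes the per-time component records of a [SimTrace] into
#' [SCATrajectory] objects by following component identity per color across
#' sample times. Identity across frames is only well defined when each
#' color has at most one component per frame (sparse labeling), so this
#' helper tracks the summed area per color; with unique founder colors this
#' is exactly the clone trajectory.
#'
#' @param trace a [SimTrace].
#' @param cultureId culture label for the resulting trajectories.
#' @return list of [SCATrajectory], one per color present at time 0.
#' @export
traceToTrajectories <- function(trace, cultureId = "sim") {
    stopifnot(is(trace, "SimTrace"))
    lf <- trace@labelFraction
    cfg <- trace@config
    siteArea <- cfg@areaPerCell * cfg@width * cfg@height
    present <- which(lf[1, ] > 0)
    lapply(present, function(col) {
        a <- lf[, col] * siteArea
        names(a) <- as.character(trace@sampleTimes)
        SCATrajectory(scaId = paste0("color", col), cultureId = cultureId,
                      areas = a)
    })
}
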