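#' Clone survival probability under neutral drift
#'
#' In the single-progenitor model, clone sizes follow a critical birth-death
#' process with per-cell gain and loss rate \eqn{\kappa = r\lambda}. The
#' probability that a clone founded by one progenitor at time 0 still
#' contains progenitors after \code{elapsed} weeks is
#' \deqn{P_{surv}(t) = \frac{1}{1 + \kappa t}.}
#'
#' @param elapsed time since labeling, weeks (>= 0); vectorised.
#' @param params a [DriftParams].
#' @return survival probabilities in (0, 1].
#' @seealso [meanSurvivingSize()], [cloneSizePmf()]
#' @examples
#' survivalProbability(3, DriftParams(kappa = 1))  # 0.25
#' @export
survivalProbability <- function(elapsed, params) {
    .check_drift_args(elapsed, params)
    1 / (1 + params@kappa * elapsed)
}

#' Mean size of surviving clones
#'
#' Expected progenitor number of a clone conditional on survival:
#' \eqn{E[n \mid n > 0] = 1 + \kappa t}. Together with
#' [survivalProbability()] this conserves the expected labeled cell number
#' per founder: \eqn{P_{surv}(t)\,(1 + \kappa t) = 1} for all \eqn{t}.
#'
#' @inheritParams survivalProbability
#' @return expected cell counts (>= 1).
#' @export
meanSurvivingSize <- function(elapsed, params) {
    .check_drift_args(elapsed, params)
    1 + params@kappa * elapsed
}

.check_drift_args <- function(elapsed, params) {
    stopifnot(is(params, "DriftParams"))
    validObject(params)
    if (any(elapsed < 0))
        stop("'elapsed' must be >= 0")
    invisible(TRUE)
}

#' Clone-size distribution conditional on survival
#'
#' Surviving clones of the critical birth-death process have geometrically
#' distributed sizes:
#' \deqn{P(n \mid n > 0) = \frac{1}{1+\kappa t}
#'   \left(\frac{\kappa t}{1+\kappa t}\right)^{n-1}, \quad n \ge 1.}
#'
#' @param n integer cell counts (>= 1); vectorised.
#' @param elapsed time since labeling, weeks (> 0).
#' @param params a [DriftParams].
#' @return probabilities summing to 1 over \code{n >= 1}.
#' @export
cloneSizePmf <- function(n, elapsed, params) {
    stopifnot(is(params, "DriftParams"))
    validObject(params)
    if (any(n < 1) || any(n != round(n)))
        stop("'n' must be integer >= 1")
    if (any(elapsed <= 0))
        stop("'elapsed' must be > 0")
    kt <- params@kappa * elapsed
    (1 / (1 + kt)) * (kt / (1 + kt))^(n - 1)
}

#' Predicted neutral-drift summary curves
#'
#' Deterministic expectations for a cohort of \code{n0} clones labeled at
#' \code{t0} with mean area \code{a0}: the surviving-clone count falls as
#' \eqn{n_0 / (1 + \kappa(t - t_0))}, the mean surviving area grows as
#' \eqn{a_0 (1 + \kappa(t - t_0))}, and the total labeled area stays constant
#' at \eqn{n_0 a_0} — the hallmark of neutral drift.
#'
#' @param params a [DriftParams].
#' @param tGrid times (weeks), all >= \code{t0}.
#' @param n0 clone count at \code{t0} (> 0).
#' @param t0 labeling time origin (weeks).
#' @param a0 mean clone area at \code{t0} (mm^2, > 0).
#' @return a [DriftCurve].
#' @export
predictDriftCurves <- function(params, tGrid, n0, t0 = 0, a0) {
    stopifnot(is(params, "DriftParams"))
    validObject(params)
    if (!length(tGrid)) stop("'tGrid' must be nonempty")
    if (any(tGrid < t0)) stop("'tGrid' must be >= t0")
    if (n0 <= 0 || a0 <= 0) stop("'n0' and 'a0' must be > 0")
    g <- 1 + params@kappa * (tGrid - t0)
    DriftCurve(times = tGrid, meanArea = a0 * g, count = n0 / g,
               totalArea = rep(n0 * a0, length(tGrid)))
}

#' Fit the drift rate kappa to observed summary curves
#'
#' Single-parameter least-squares fit of the neutral-drift rate
#' \eqn{\kappa} to an observed [DriftCurve]. The model amplitudes are
#' anchored at the first observed time point \eqn{t_1} (the fit is therefore
#' genuinely single-parameter): predictions are
#' \eqn{\bar a(t) = \bar a(t_1) \frac{1+\kappa(t-t_0)}{1+\kappa(t_1-t_0)}}
#' and \eqn{N(t) = N(t_1) \frac{1+\kappa(t_1-t_0)}{1+\kappa(t-t_0)}},
#' and the objective is the sum of squared relative residuals of the
#' surviving-clone count curve. The count channel is used because it is the
#' statistically efficient one: surviving clone areas are geometrically
#' dispersed (CV near 1), so the cohort mean-area summary is much noisier
#' than the survival counts, and the total area is determined by the other
#' two curves. The fitted \eqn{\kappa} fixes all three predicted curves
#' through the anchor. Confidence intervals are percentile
#' bootstrap: over time points for a summary-level fit, over clones when a
#' trajectory cohort is supplied.
#'
#' @param observed a [DriftCurve], or a list of [SCATrajectory] (in which
#'   case the cohort summary is formed internally and clones are resampled
#'   for the bootstrap).
#' @param t0 labeling time origin in weeks (default 0, the induction time).
#' @param nBoot bootstrap resamples for the CI (default 1000; 0 disables).
#' @param seed RNG seed for the bootstrap.
#' @param detectionThreshold survival threshold passed to [cohortSummary()]
#'   when \code{observed} is a trajectory cohort.
#' @return a [FitResult]. A count series that never decreases (incompatible
#'   with neutral decay) sets the \code{"increasing_counts"} warning flag.
#' @examples
#' truth <- predictDriftCurves(DriftParams(kappa = 0.3), 4:19,
#'                             n0 = 351, a0 = 0.05)
#' fitDriftKappa(truth, nBoot = 0)
#' @export
fitDriftKappa <- function(observed, t0 = 0, nBoot = 1000, seed = 1,
                          detectionThreshold = 0) {
    if (is.list(observed) && all(vapply(observed, is, TRUE, "SCATrajectory")))
        return(.fit_kappa_cohort(observed, t0, nBoot, seed,
                                 detectionThreshold))
    stopifnot(is(observed, "DriftCurve"))
    validObject(observed)
    ok <- observed@count > 0 & is.finite(observed@meanArea)
    if (sum(ok) < 3)
        stop("need >= 3 time points with count > 0")
    tt <- observed@times[ok]
    ma <- observed@meanArea[ok]
    ct <- observed@count[ok]
    if (any(tt < t0)) stop("observed times must be >= t0")

    fit <- .kappa_ls(tt, ma, ct, t0)
    warn <- character()
    if (all(diff(ct) >= 0) && length(ct) > 1)
        warn <- c(warn, "increasing_counts")

    ci <- c(NA_real_, NA_real_)
    if (nBoot > 0) {
        old <- .save_seed()
        on.exit(.restore_seed(old), add = TRUE)
        set.seed(seed)
        n <- length(tt)
        kb <- vapply(seq_len(nBoot), function(b) {
            idx <- sort(unique(sample.int(n, n, replace = TRUE)))
            if (length(idx) < 3) return(NA_real_)
            .kappa_ls(tt[idx], ma[idx], ct[idx], t0)$kappa
        }, numeric(1))
        kb <- kb[is.finite(kb)]
        if (length(kb)) ci <- unname(quantile(kb, c(0.025, 0.975)))
        ci[1] <- min(ci[1], fit$kappa)
        ci[2] <- max(ci[2], fit$kappa)
    }
    new("FitResult", kappaHat = fit$kappa, kappaCI = ci,
        objective = fit$objective, nPoints = length(tt), t0 = t0,
        warnings = warn)
}

# least-squares in kappa for anchored relative residuals of the
# surviving-clone count curve. The mean-area summary is deliberately left
# out of the loss: surviving clone sizes are geometrically distributed
# (coefficient of variation near 1), so cohort mean areas are far noisier
# than survival counts and, being anchored to a noisy first-week mean,
# their errors are shared across the whole curve. Counts are the
# statistically efficient channel; the fitted kappa still determines the
# mean-area and total-area curves through the same anchor.
.kappa_objective <- function(kappa, tt, ma, ct, t0) {
    g <- 1 + kappa * (tt - t0)
    pc <- ct[1] * g[1] / g
    sum((ct / pc - 1)^2)
}

.kappa_ls <- function(tt, ma, ct, t0) {
    f <- function(logk) .kappa_objective(exp(logk), tt, ma, ct, t0)
    opt <- optimize(f, interval = log(c(1e-6, 1e3)), tol = 1e-12)
    list(kappa = exp(opt$minimum), objective = opt$objective)
}

.fit_kappa_cohort <- function(trajs, t0, nBoot, seed, threshold) {
    curve <- cohortSummary(trajs, detectionThreshold = threshold)
    fit <- fitDriftKappa(curve, t0 = t0, nBoot = 0)
    ci <- c(NA_real_, NA_real_)
    if (nBoot > 0) {
        old <- .save_seed()
        on.exit(.restore_seed(old), add = TRUE)
        set.seed(seed)
        n <- length(trajs)
        kb <- vapply(seq_len(nBoot), function(b) {
            res <- trajs[sample.int(n, n, replace = TRUE)]
            cv <- cohortSummary(res, detectionThreshold = threshold)
            ok <- cv@count > 0 & is.finite(cv@meanArea)
            if (sum(ok) < 3) return(NA_real_)
            .kappa_ls(cv@times[ok], cv@meanArea[ok], cv@count[ok], t0)$kappa
        }, numeric(1))
        kb <- kb[is.finite(kb)]
        if (length(kb)) ci <- unname(quantile(kb, c(0.025, 0.975)))
        ci[1] <- min(ci[1], fit@kappaHat)
        ci[2] <- max(ci[2], fit@kappaHat)
    }
    new("FitResult", kappaHat = fit@kappaHat, kappaCI = ci,
        objective = fit@objective, nPoints = fit@nPoints, t0 = t0,
        warnings = fit@warnings)
}

# preserve the caller's RNG state around seeded internals
.save_seed <- function() {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv())
    else NULL
}

.restore_seed <- function(old) {
    if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
    invisible(NULL)
}

#' Simulate critical birth-death clone trajectories
#'
#' Exact Gillespie simulation of the critical (birth rate = death rate =
#' \eqn{\kappa} per cell) birth-death process that underlies the neutral
#' single-progenitor model. Used by the synthetic cohort generator and as a
#' stochastic cross-check of the closed forms.
#'
#' @param n0 integer vector of founder sizes (one clone per element).
#' @param kappa per-cell event rate, per week.
#' @param times sample times (weeks, nondecreasing, >= 0).
#' @return integer matrix, clones x times, of clone sizes (0 = extinct).
#' @examples
#' set.seed(1)
#' sizes <- simBirthDeath(rep(1L, 1000), kappa = 0.5, times = c(2, 4))
#' mean(sizes[, 2] > 0)  # close to 1/(1 + 0.5*4) = 1/3
#' @export
simBirthDeath <- function(n0, kappa, times) {
    if (kappa <= 0) stop("'kappa' must be > 0")
    if (any(times < 0) || is.unsorted(times))
        stop("'times' must be nondecreasing and >= 0")
    if (any(n0 < 0)) stop("'n0' must be >= 0")
    m <- cpp_bd_trajectories(as.integer(n0), as.numeric(kappa),
                             as.numeric(times))
    colnames(m) <- as.character(times)
    m
}
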