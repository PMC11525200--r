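test_that("window means average the observed weeks", {
    expect_equal(windowMeans(make_traj("a", rep(2, 16))),
                 c(A4_8 = 2, A10_13 = 2, A15_19 = 2))
    areas <- c(1, 2, 3, 4, 5, 9, 0, 0, 0, 0, 9, 0, 0, 0, 0, 0)
    expect_equal(windowMeans(make_traj("b", areas)),
                 c(A4_8 = 3, A10_13 = 0, A15_19 = 0))

    # random trajectories with random missing weeks vs per-window means
    set.seed(31)
    for (i in 1:50) {
        wk <- sort(sample(4:19, sample(8:16, 1)))
        a <- runif(length(wk), 0, 3)
        names(a) <- wk
        tr <- SCATrajectory("x", "c", a)
        wm <- tryCatch(windowMeans(tr), error = function(e) NULL)
        ref <- vapply(list(4:8, 10:13, 15:19), function(w) {
            v <- a[as.integer(names(a)) %in% w]
            if (length(v)) mean(v) else NA_real_
        }, numeric(1))
        if (anyNA(ref)) {
            expect_null(wm)
        } else {
            expect_equal(unname(wm), ref)
        }
    }
    # empty-window error names the window
    gap <- c(1, 1, 1, 1, 1, 1, 1, 1)
    names(gap) <- c(4:8, 15:17)
    expect_error(windowMeans(SCATrajectory("g", "c", gap)), "A10_13")
})

test_that("trajectory classes follow the decision rules in order", {
    expect_equal(as.character(classifyTrajectory(c(3, 0, 0))), "Decay1")
    expect_equal(as.character(classifyTrajectory(c(3, 2, 0))), "Decay2")
    expect_equal(as.character(classifyTrajectory(c(5, 3, 1))), "Decay3")
    expect_equal(as.character(classifyTrajectory(c(1, 4, 2))), "Biphasic")
    expect_equal(as.character(classifyTrajectory(c(1, 2, 3))), "Growing")
    expect_equal(as.character(classifyTrajectory(c(2, 2, 2))), "Steady")
    # full window pipeline gives the same answers
    expect_equal(as.character(classifyTrajectory(traj_from_windows(c(5, 3, 1)))),
                 "Decay3")
})

test_that("classification matches the 27-pattern enumeration oracle", {
    pats <- expand.grid(a1 = 0:2, a2 = 0:2, a3 = 0:2)
    for (i in seq_len(nrow(pats))) {
        w <- as.numeric(pats[i, ])
        expect_equal(as.character(classifyTrajectory(w)),
                     oracle_class(w[1], w[2], w[3]),
                     info = paste(w, collapse = ","))
    }
})

test_that("classification is scale invariant and order independent", {
    set.seed(17)
    trajs <- simConfettiCohort(nCultures = 2, scaPerCulture = 20, seed = 17)
    base <- classifyCohort(trajs)
    shuffled <- classifyCohort(trajs[sample(length(trajs))])
    expect_equal(base$counts, shuffled$counts)
    scaled <- lapply(trajs, function(tr)
        SCATrajectory(scaId(tr), cultureId(tr), scaAreas(tr) * 7.3))
    expect_equal(unname(classifyCohort(scaled)$counts), unname(base$counts))
})

test_that("cohort classification reports proportions over eligible SCA", {
    grow <- lapply(1:10, function(i)
        traj_from_windows(c(1, 2, 3), paste0("g", i)))
    res <- classifyCohort(grow)
    expect_equal(as.numeric(res$proportions["Growing"]), 1.0)

    mix <- list(traj_from_windows(c(3, 0, 0), "d"),
                traj_from_windows(c(1, 4, 2), "b"),
                traj_from_windows(c(1, 2, 3), "g"),
                traj_from_windows(c(2, 2, 2), "s"))
    res <- classifyCohort(mix)
    expect_equal(as.numeric(res$proportions[c("Decay1", "Biphasic",
                                               "Growing", "Steady")]),
                 rep(0.25, 4))

    # ineligible trajectories are excluded from the denominator
    bad <- SCATrajectory("bad", "c", c("4" = 1, "5" = 1))
    res2 <- classifyCohort(c(mix, list(bad)))
    expect_equal(res2$ineligible, "bad")
    expect_equal(sum(res2$counts), 4)
})

test_that("weekly cohort summaries count survivors above threshold", {
    one <- make_traj("a", rep(2, 16))
    cv <- cohortSummary(list(one))
    expect_true(all(meanArea(cv) == 2))
    expect_true(all(scaCount(cv) == 1))
    expect_true(all(totalArea(cv) == 2))

    ext <- make_traj("b", c(rep(1, 6), rep(0, 10)))  # extinct from week 10
    cv2 <- cohortSummary(list(one, ext))
    expect_equal(scaCount(cv2), c(rep(2, 6), rep(1, 10)))
    expect_equal(totalArea(cv2), c(rep(3, 6), rep(2, 10)))

    # totals equal the per-week survivor sums exactly on random cohorts
    set.seed(12)
    trajs <- simConfettiCohort(nCultures = 1, scaPerCulture = 25, seed = 12)
    cv3 <- cohortSummary(trajs)
    mat <- do.call(rbind, lapply(trajs, scaAreas))
    expect_equal(totalArea(cv3), unname(colSums(mat)))
    expect_equal(scaCount(cv3), unname(colSums(mat > 0)))
})

test_that("lattice traces and trajectory summaries agree", {
    p <- DriftParams(kappa = 0.5, r = 0.5, lambdaDiv = 1)
    cfg <- LatticeConfig(24, 24, p, colors = 576, labeledFraction = 0.01,
                         duration = 4, sampleInterval = 1, seed = 5)
    tr <- runLattice(cfg)
    cv_trace <- traceToSummary(tr)
    cv_traj <- cohortSummary(traceToTrajectories(tr))
    # per-color totals and component totals are the same labeled mass
    expect_equal(totalArea(cv_traj), totalArea(cv_trace))
    # clones can transiently fragment into several same-color components,
    # so component counts can only exceed surviving-color counts
    expect_true(all(scaCount(cv_trace) >= scaCount(cv_traj)))
})

test_that("signed-rank test is exact for small samples", {
    expect_warning(res <- pairedSignedRank(1:5, 1:5), "uninformative")
    expect_equal(res$p_value, 1.0)

    res <- pairedSignedRank(c(2, 3, 4, 5, 6), rep(1, 5))
    expect_equal(res$p_value, 0.0625)
    expect_equal(res$p_value, enumerate_signed_rank_p(c(1, 2, 3, 4, 5)))

    # random small samples agree with full sign-flip enumeration
    set.seed(77)
    for (i in 1:20) {
        d <- round(rnorm(8, 0.3, 1), 3)
        d <- d[d != 0]
        if (any(duplicated(abs(d))) || length(d) < 3) next
        ours <- pairedSignedRank(d, rep(0, length(d)))
        expect_equal(ours$p_value, enumerate_signed_rank_p(d),
                     tolerance = 1e-12)
    }
})

test_that("large-sample signed-rank p matches a permutation oracle", {
    set.seed(8)
    x <- rnorm(30, 0.4, 1)
    y <- rep(0, 30)
    ours <- pairedSignedRank(x, y)
    expect_equal(ours$method, "normal approximation")
    d <- x - y
    r <- rank(abs(d))
    v_obs <- sum(r[d > 0])
    mu <- sum(r) / 2
    nres <- 1e5
    flips <- matrix(runif(nres * 30) < 0.5, nres, 30)
    v_null <- flips %*% r
    p_perm <- mean(abs(v_null - mu) >= abs(v_obs - mu))
    expect_lt(abs(ours$p_value - p_perm), 0.005)
})
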