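test_that("closed forms and the conservation identity hold", {
    dp <- DriftParams(kappa = 1)
    expect_equal(survivalProbability(0, dp), 1.0)
    expect_equal(survivalProbability(3, dp), 0.25)
    expect_equal(meanSurvivingSize(0, dp), 1.0)
    expect_equal(meanSurvivingSize(3, dp), 4.0)

    set.seed(11)
    for (i in 1:100) {
        k <- runif(1, 0.01, 3)
        t <- runif(1, 0, 30)
        p <- DriftParams(kappa = k)
        expect_equal(survivalProbability(t, p) * meanSurvivingSize(t, p), 1)
        expect_lte(survivalProbability(t, p), 1)
        expect_gt(survivalProbability(t, p), 0)
    }
    # strictly monotone in elapsed time
    tt <- seq(0, 20, by = 0.5)
    expect_true(all(diff(survivalProbability(tt, dp)) < 0))
    expect_true(all(diff(meanSurvivingSize(tt, dp)) > 0))

    expect_error(survivalProbability(-1, dp), "elapsed")
    expect_error(DriftParams(kappa = -2), "kappa")
    expect_error(DriftParams(kappa = 1, r = 0.3, lambdaDiv = 1),
                 "r \\* lambdaDiv")
})

test_that("conditional clone-size distribution is geometric and normalized", {
    dp <- DriftParams(kappa = 1)
    # vanishing drift: all surviving clones still a single cell
    expect_equal(cloneSizePmf(1, 1e-12, dp), 1, tolerance = 1e-9)
    expect_equal(sum(cloneSizePmf(1:10000, 1, dp)), 1, tolerance = 1e-6)
    # truncation at mean + 50 SD also captures essentially all mass
    kt <- 1 * 5
    ntrunc <- ceiling((1 + kt) + 50 * sqrt(kt * (1 + kt)))
    expect_equal(sum(cloneSizePmf(seq_len(ntrunc), 5, dp)), 1,
                 tolerance = 1e-6)
    expect_error(cloneSizePmf(0, 1, dp), "n")
})

test_that("Gillespie clone sizes match the geometric conditional law", {
    set.seed(42)
    n <- 1e5
    sizes <- simBirthDeath(rep(1L, n), kappa = 1, times = 2)[, 1]
    surv <- sizes[sizes > 0]
    dp <- DriftParams(kappa = 1)
    # chi-square against the geometric pmf, pooling the tail
    kmax <- 30
    obs <- tabulate(pmin(surv, kmax + 1), nbins = kmax + 1)
    prob <- cloneSizePmf(1:kmax, 2, dp)
    prob <- c(prob, 1 - sum(prob))
    suppressWarnings(ct <- chisq.test(obs, p = prob))
    expect_gt(ct$p.value, 0.01)
})

test_that("predicted drift curves obey the neutral closed forms", {
    # frozen drift: all three curves constant
    frozen <- predictDriftCurves(DriftParams(kappa = 1e-12), 4:19,
                                 n0 = 100, a0 = 0.1)
    expect_lt(diff(range(meanArea(frozen))), 1e-6)
    expect_lt(diff(range(scaCount(frozen))), 1e-6)

    cv <- predictDriftCurves(DriftParams(kappa = 0.2), c(0, 5), n0 = 351,
                             t0 = 0, a0 = 0.1)
    expect_equal(meanArea(cv)[2], 0.2)
    expect_equal(scaCount(cv)[2], 175.5)
    expect_equal(totalArea(cv), c(35.1, 35.1))
    # total labeled area is time-constant to machine precision
    cv2 <- predictDriftCurves(DriftParams(kappa = 0.7), seq(2, 40, 0.5),
                              n0 = 17, t0 = 2, a0 = 0.3)
    expect_equal(diff(range(totalArea(cv2))), 0)
    expect_error(predictDriftCurves(DriftParams(kappa = 1), numeric(0),
                                    n0 = 1, a0 = 1), "nonempty")
})

test_that("kappa fit is exact on noise-free curves and beats a grid search", {
    truth <- predictDriftCurves(DriftParams(kappa = 0.3), 4:19, n0 = 351,
                                t0 = 0, a0 = 0.05)
    fit <- fitDriftKappa(truth, t0 = 0, nBoot = 0)
    expect_equal(kappa(fit), 0.3, tolerance = 1e-6)
    expect_lt(fit@objective, 1e-12)

    # noisy curve: optimizer attains the brute-force grid minimum
    set.seed(5)
    noisy <- DriftCurve(times = 4:19,
                        meanArea = meanArea(truth) * exp(rnorm(16, 0, 0.1)),
                        count = pmax(1, round(scaCount(truth) *
                                              exp(rnorm(16, 0, 0.1)))))
    fit2 <- fitDriftKappa(noisy, t0 = 0, nBoot = 100, seed = 2)
    grid <- seq(0.01, 2, by = 0.0005)
    objs <- vapply(grid, function(k)
        epidrift:::.kappa_objective(k, curveTimes(noisy), meanArea(noisy),
                                    scaCount(noisy), 0), numeric(1))
    expect_lte(fit2@objective, min(objs) + 1e-6)
    expect_true(kappaCI(fit2)[1] <= kappa(fit2) &&
                kappaCI(fit2)[2] >= kappa(fit2))
})

test_that("fit flags growing cohorts and rejects short series", {
    growing <- DriftCurve(times = 4:10, meanArea = rep(1, 7),
                          count = c(10, 11, 12, 13, 14, 15, 16))
    fit <- fitDriftKappa(growing, nBoot = 0)
    expect_true("increasing_counts" %in% fitWarnings(fit))
    short <- DriftCurve(times = 4:5, meanArea = c(1, 2), count = c(5, 3))
    expect_error(fitDriftKappa(short, nBoot = 0), ">= 3 time points")
})

test_that("compiled Gillespie agrees with a plain-R oracle", {
    kap <- 0.8; tmax <- 2; n <- 3000
    set.seed(9)
    ours <- simBirthDeath(rep(1L, n), kap, tmax)[, 1]
    set.seed(10)
    ref <- replicate(n, r_gillespie_bd(1L, kap, tmax))
    # survival fractions within 3 pooled MC SE
    p1 <- mean(ours > 0); p2 <- mean(ref > 0)
    se <- sqrt(p1 * (1 - p1) / n + p2 * (1 - p2) / n)
    expect_lt(abs(p1 - p2), 3 * se)
    # surviving-size means within 3 pooled SE
    m1 <- mean(ours[ours > 0]); m2 <- mean(ref[ref > 0])
    se_m <- sqrt(var(ours[ours > 0]) / sum(ours > 0) +
                 var(ref[ref > 0]) / sum(ref > 0))
    expect_lt(abs(m1 - m2), 3 * se_m)
})
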