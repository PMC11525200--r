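# small hand-built table: 2 genes x 2 guides + 12 NT, 1 replicate
tiny_table <- function(w0, w3, nt = 12) {
    ng <- length(w0)
    stopifnot(ng > 4)
    gene <- c("geneA", "geneA", "geneB", "geneB", rep(NA, ng - 4))
    cat <- c(rep("driver", 4), rep("NT", ng - 4))
    GuideTable(counts = cbind(w0, w3),
               guide_id = sprintf("g%02d", seq_len(ng)), gene = gene,
               category = cat, replicate = rep("rep1", 2),
               timepoint = c("week0", "week3"))
}

test_that("CPM normalization is scale invariant and sums to 1e6", {
    set.seed(2)
    w0 <- rpois(16, 400)
    tab <- tiny_table(w0, w0 * 3L)  # proportional samples
    cpm <- SummarizedExperiment::assay(normalizeCounts(tab, 0), "cpm")
    expect_equal(cpm[, 1], cpm[, 2])
    expect_equal(unname(colSums(cpm)), c(1e6, 1e6))

    one <- GuideTable(counts = cbind(5L, 9L), guide_id = "g1",
                      gene = NA_character_, category = "NT",
                      replicate = c("r1", "r1"),
                      timepoint = c("week0", "week3"))
    cpm1 <- SummarizedExperiment::assay(normalizeCounts(one), "cpm")
    expect_equal(unname(cpm1[1, ]), c(1e6, 1e6))
})

test_that("guide log2 fold changes follow the count ratios", {
    w0 <- rep(100L, 16)
    st0 <- guideLog2FC(tiny_table(w0, w0))
    expect_equal(st0$log2fc, rep(0, 16))

    # one guide at 4x under equal library size: log2FC = 2 for it
    w3 <- w0
    w3[1] <- 400L
    w3[2] <- 0L   # compensate elsewhere so totals change little
    tab <- tiny_table(w0, w3)
    st <- guideLog2FC(normalizeCounts(tab, pseudocount = 0))
    shift <- st$log2fc[5]  # NT guide absorbs the library-size change
    expect_equal(st$log2fc[1] - shift, 2, tolerance = 1e-12)

    # pipeline is invariant to scaling a sample's counts
    tabx <- tiny_table(w0 * 7L, w3 * 3L)
    stx <- guideLog2FC(normalizeCounts(tabx, pseudocount = 0))
    expect_equal(stx$log2fc, st$log2fc, tolerance = 1e-12)
})

test_that("noiseless generator reproduces the selection closed form", {
    tf <- 0.13; dur <- 3; s_ess <- -2
    tab <- simScreenCounts(nDrivers = 2, nCandidates = 2, nEssentials = 2,
                           guidesPerGene = 3, nNT = 50,
                           s = c(driver = 0, cancer_candidate = 0,
                                 essential = s_ess),
                           targetedFraction = tf, duration = dur,
                           depth = 1e9, dispersion = 0, seed = 6)
    st <- guideLog2FC(tab, pseudocount = 0)
    delta <- mean(st$log2fc[st$category == "essential"]) -
        mean(st$log2fc[st$category == "NT"])
    expect_equal(delta, dur * s_ess * tf / log(2), tolerance = 1e-6)
    # all-neutral screen: every guide identical across timepoints
    null <- simScreenCounts(nEssentials = 0, nDrivers = 3, nCandidates = 0,
                            nNT = 20, depth = 1e9, dispersion = 0, seed = 6)
    stn <- guideLog2FC(null, pseudocount = 0)
    expect_equal(stn$log2fc, rep(0, nrow(stn)), tolerance = 1e-6)
})

test_that("robust z-scores are NT-anchored and location invariant", {
    set.seed(33)
    stats <- data.frame(
        guide_id = sprintf("g%04d", 1:10100),
        gene = c(rep("gA", 100), rep(NA, 10000)),
        category = c(rep("driver", 100), rep("NT", 10000)),
        log2fc = c(rnorm(100, -2), rnorm(10000)))
    z <- guideZScore(stats)
    med_guide <- which.min(abs(stats$log2fc - median(
        stats$log2fc[stats$category == "NT"])))
    expect_lt(abs(z$z[med_guide]), 0.02)
    # location invariance
    stats2 <- stats
    stats2$log2fc <- stats$log2fc + 5.5
    expect_equal(guideZScore(stats2)$z, z$z, tolerance = 1e-12)
    # NT z-scores approximate a standard normal: mean |z| near sqrt(2/pi)
    znt <- z$z[z$category == "NT"]
    se <- sd(abs(znt)) / sqrt(length(znt))
    expect_lt(abs(mean(abs(znt)) - sqrt(2 / pi)), 3 * se)
    expect_error(guideZScore(stats[1:105, ]), ">= 10 NT")
})

test_that("depletion AUC matches step-curve geometry", {
    mk_stats <- function(lfc) data.frame(
        guide_id = sprintf("g%04d", seq_along(lfc)),
        gene = NA_character_, category = "NT", log2fc = lfc)
    # set occupying the first |S| ranks: AUC = 1 - |S|/(2N)
    st <- mk_stats(seq_len(200))
    res <- depletionAUC(st, sprintf("g%04d", 1:40))
    expect_equal(res$auc, 1 - 40 / (2 * 200))
    # set occupying the last |S| ranks: mirrored
    res2 <- depletionAUC(st, sprintf("g%04d", 161:200))
    expect_equal(res2$auc, 40 / (2 * 200))
    # perfectly interleaved set sits at 0.5 (up to 1/N edge effects)
    res3 <- depletionAUC(st, sprintf("g%04d", seq(1, 200, by = 2)))
    expect_equal(res3$auc, 0.5, tolerance = 1 / 200)
    # near-complete set still follows the step-curve formula
    res4 <- depletionAUC(st, sprintf("g%04d", 1:199))
    expect_equal(res4$auc, 1 - 199 / 400)
    # ties broken deterministically by guide id
    tied <- mk_stats(rep(1, 50))
    expect_equal(depletionAUC(tied, sprintf("g%04d", 1:10))$auc,
                 1 - 10 / 100)
    expect_error(depletionAUC(st, st$guide_id), "strict subset")
    expect_error(depletionAUC(st, character(0)), "nonempty")
})

test_that("gene calling finds a strongly depleted gene and keeps direction consistent", {
    tab <- simScreenCounts(nDrivers = 10, nCandidates = 0, nEssentials = 0,
                           nNT = 200, sGene = c(drv1 = -8), seed = 44)
    calls <- callGenes(guideLog2FC(tab), nPerm = 5000, seed = 44)
    hit <- calls[calls$gene == "drv1", ]
    expect_equal(hit$direction, "depleted")
    expect_lt(hit$fdr, 0.1)
    # direction consistency on a random screen
    tab2 <- simScreenCounts(seed = 45)
    calls2 <- callGenes(guideLog2FC(tab2), nPerm = 2000, seed = 45)
    expect_true(all(calls2$median_log2fc[calls2$direction == "enriched"] > 0))
    expect_true(all(calls2$median_log2fc[calls2$direction == "depleted"] < 0))
    # identical seed gives identical p-values
    calls3 <- callGenes(guideLog2FC(tab2), nPerm = 2000, seed = 45)
    expect_identical(calls2$p_value, calls3$p_value)
})

test_that("single-guide genes are called unchanged with a warning", {
    tab <- simScreenCounts(nDrivers = 3, nCandidates = 0, nEssentials = 0,
                           guidesPerGene = 1, nNT = 30, seed = 7)
    expect_warning(calls <- callGenes(guideLog2FC(tab), nPerm = 500),
                   "< 2 guides")
    expect_true(all(calls$direction == "unchanged"))
})

test_that("category summaries reproduce the screen outcome arithmetic", {
    calls <- data.frame(
        gene = c(paste0("d", 1:23), paste0("c", 1:62)),
        direction = c(rep(c("enriched", "depleted", "unchanged"),
                          c(9, 9, 5)),
                      rep(c("enriched", "depleted", "unchanged"),
                          c(5, 44, 13))))
    cats <- setNames(rep(c("driver", "cancer_candidate"), c(23, 62)),
                     calls$gene)
    sm <- summarizeCalls(calls, cats)
    expect_equal(sm$percent_altered[sm$category == "driver"], 78)
    expect_equal(sm$n_altered[sm$category == "cancer_candidate"], 49)
    expect_equal(sum(sm$n_altered), 67)

    # empty category flagged, unknown gene errors
    cats2 <- c(cats, none1 = "essential")
    sm2 <- summarizeCalls(calls, cats2)
    expect_true(sm2$empty[sm2$category == "essential"])
    expect_equal(sm2$n_total[sm2$category == "essential"], 0)
    expect_error(summarizeCalls(calls, cats[-1]), "without category")
})
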