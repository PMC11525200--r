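#' Generate a synthetic confetti SCA cohort
#'
#' Seeded generator of multicolor lineage-tracing trajectories with the
#' statistical structure the drift analyses assume. Each SCA evolves by the
#' critical birth-death process (exact Gillespie) from a week-4 size drawn
#' from the conditional geometric surviving-clone distribution (tracking
#' begins when SCA are recognizable at week 4, not at induction). Measured
#' area = true clonal units / rho, times multiplicative lognormal imaging
#' noise with the given coefficient of variation; areas below the detection
#' threshold are recorded as 0.
#'
#' Defaults mirror a typical long-term tracing cohort: 9 cultures of 39 SCA
#' (351 total), weekly observation over weeks 4-19, drift rate 0.25 per week.
#'
#' @param nCultures number of cultures (default 9).
#' @param scaPerCulture SCA per culture (default 39).
#' @param kappa drift rate per week (default 0.25).
#' @param weeks observation weeks (default 4:19).
#' @param areaNoiseCV lognormal measurement-noise CV (default 0.1).
#' @param detectionThreshold mm^2 below which areas record as 0
#'   (default 0.01).
#' @param rho effective clonal units per mm^2 (default 50), converting
#'   sizes to areas.
#' @param seed integer RNG seed; identical seeds give identical cohorts.
#' @return list of [SCATrajectory].
#' @examples
#' cohort <- simConfettiCohort(nCultures = 2, scaPerCulture = 5, seed = 3)
#' cohortSummary(cohort)
#' @export
simConfettiCohort <- function(nCultures = 9, scaPerCulture = 39,
                              kappa = 0.25, weeks = 4:19,
                              areaNoiseCV = 0.1, detectionThreshold = 0.01,
                              rho = 50, seed = 1) {
    stopifnot(nCultures > 0, scaPerCulture > 0, kappa > 0, rho > 0,
              areaNoiseCV >= 0, detectionThreshold >= 0,
              all(weeks >= 4), all(weeks <= 19))
    weeks <- sort(unique(as.integer(weeks)))
    t_start <- min(weeks)
    old <- .save_seed()
    on.exit(.restore_seed(old), add = TRUE)
    set.seed(seed)
    n <- nCultures * scaPerCulture
    # surviving-clone sizes at first observation: geometric on {1, 2, ...}
    n0 <- 1L + rgeom(n, prob = 1 / (1 + kappa * t_start))
    sizes <- cpp_bd_trajectories(as.integer(n0), kappa,
                                 as.numeric(weeks - t_start))
    sdlog <- sqrt(log(1 + areaNoiseCV^2))
    noise <- matrix(rlnorm(n * length(weeks), meanlog = -sdlog^2 / 2,
                           sdlog = sdlog), n, length(weeks))
    area <- sizes / rho * noise
    area[area < detectionThreshold] <- 0
    culture <- rep(seq_len(nCultures), each = scaPerCulture)
    lapply(seq_len(n), function(i) {
        a <- area[i, ]
        names(a) <- as.character(weeks)
        SCATrajectory(scaId = sprintf("c%02d_sca%03d", culture[i], i),
                      cultureId = sprintf("c%02d", culture[i]), areas = a)
    })
}

#' Generate a synthetic two-population competition series
#'
#' Deterministic replicator dynamics with selection coefficient \code{s}
#' per week, \deqn{p(t) = \frac{p_0 e^{st}}{1 - p_0 + p_0 e^{st}},}
#' observed through binomial sampling of \code{nCellsSampled} cells per
#' time point (skip sampling by leaving it \code{NA}). \code{s = 0} gives a
#' constant expected proportion (neutral competition).
#'
#' @param p0 initial focal proportion in (0, 1).
#' @param s selection coefficient per week.
#' @param times observation weeks (strictly increasing).
#' @param nCellsSampled cells sampled per time point (NA = exact).
#' @param focalLabel name for the focal population.
#' @param seed RNG seed (used only when sampling).
#' @return a [CompetitionSeries].
#' @export
simCompetitionSeries <- function(p0, s, times, nCellsSampled = NA,
                                 focalLabel = "focal", seed = 1) {
    stopifnot(p0 > 0, p0 < 1, length(times) >= 1)
    if (is.unsorted(times, strictly = TRUE))
        stop("'times' must be strictly increasing")
    p <- p0 * exp(s * times) / (1 - p0 + p0 * exp(s * times))
    nvec <- rep_len(nCellsSampled, length(times))
    if (any(!is.na(nvec))) {
        old <- .save_seed()
        on.exit(.restore_seed(old), add = TRUE)
        set.seed(seed)
        for (i in seq_along(p)) {
            if (!is.na(nvec[i])) {
                k <- rbinom(1, nvec[i], p[i])
                # keep observed proportions in (0, 1] for downstream ratios
                p[i] <- max(k, 0.5) / nvec[i]
            }
        }
    }
    CompetitionSeries(times = times, proportion = p,
                      focalLabel = focalLabel, nCellsSampled = nvec)
}

#' Generate synthetic pooled-screen counts
#'
#' Seeded negative-binomial count generator for a pooled CRISPR fitness
#' screen with driver, cancer-candidate, essential and nontargeting (NT)
#' guide sets. Week-0 library abundances are Dirichlet-uniform; the
#' expected week-3 abundance of a guide targeting gene \eqn{g} is
#' proportional to its week-0 abundance times
#' \eqn{e^{T s_g f}}, where \eqn{T} is the screen duration,
#' \eqn{s_g} the gene's fitness effect per week and \eqn{f} the fraction of
#' cells actually gene-targeted (competition against untargeted neighbors
#' attenuates selection multiplicatively). Counts are negative-binomial at
#' the stated depth and dispersion, independently per replicate;
#' \code{dispersion = 0} gives deterministic (rounded expected) counts.
#'
#' @param nDrivers,nCandidates,nEssentials genes per category
#'   (defaults 23, 62, 50).
#' @param guidesPerGene guides per gene (default 4).
#' @param nNT nontargeting guides (default 1000).
#' @param s named numeric of per-category fitness effects per week
#'   (defaults: driver 0, cancer_candidate 0, essential -3).
#' @param sGene optional named numeric of per-gene effects overriding the
#'   category defaults.
#' @param targetedFraction fraction of cells gene-targeted (default 0.13).
#' @param duration screen length in weeks (default 3).
#' @param replicates biological replicates (default 3).
#' @param depth mean reads per guide (default 500).
#' @param dispersion negative-binomial dispersion (default 0.2; 0 =
#'   noiseless).
#' @param seed integer RNG seed.
#' @return a [GuideTable].
#' @export
simScreenCounts <- function(nDrivers = 23, nCandidates = 62,
                            nEssentials = 50, guidesPerGene = 4,
                            nNT = 1000,
                            s = c(driver = 0, cancer_candidate = 0,
                                  essential = -3),
                            sGene = NULL, targetedFraction = 0.13,
                            duration = 3, replicates = 3, depth = 500,
                            dispersion = 0.2, seed = 1) {
    stopifnot(nDrivers >= 0, nCandidates >= 0, nEssentials >= 0,
              guidesPerGene >= 1, nNT >= 1, targetedFraction > 0,
              targetedFraction <= 1, duration > 0, replicates >= 1,
              depth > 0, dispersion >= 0)
    genes <- c(if (nDrivers) paste0("drv", seq_len(nDrivers)),
               if (nCandidates) paste0("cnd", seq_len(nCandidates)),
               if (nEssentials) paste0("ess", seq_len(nEssentials)))
    gcat <- rep(c("driver", "cancer_candidate", "essential"),
                c(nDrivers, nCandidates, nEssentials))
    gene_s <- s[gcat]
    names(gene_s) <- genes
    if (!is.null(sGene)) gene_s[names(sGene)] <- sGene
    guide_gene <- rep(genes, each = guidesPerGene)
    guide_cat <- rep(gcat, each = guidesPerGene)
    guide_id <- c(paste0(guide_gene, "_g",
                         rep(seq_len(guidesPerGene), length(genes))),
                  paste0("NT_g", seq_len(nNT)))
    guide_gene <- c(guide_gene, rep(NA_character_, nNT))
    guide_cat <- c(guide_cat, rep("NT", nNT))
    guide_s <- c(gene_s[guide_gene[seq_len(length(genes) * guidesPerGene)]],
                 rep(0, nNT))
    nG <- length(guide_id)

    old <- .save_seed()
    on.exit(.restore_seed(old), add = TRUE)
    set.seed(seed)
    ab0 <- rexp(nG)                    # Dirichlet(1, ..., 1)
    ab0 <- ab0 / sum(ab0)
    ab3 <- ab0 * exp(duration * guide_s * targetedFraction)
    ab3 <- ab3 / sum(ab3)
    mu <- cbind(week0 = ab0, week3 = ab3) * depth * nG
    draw <- function(m) {
        if (dispersion <= 0) round(m)
        else rnbinom(length(m), mu = m, size = 1 / dispersion)
    }
    counts <- matrix(0, nG, 2 * replicates)
    replicate_id <- rep(paste0("rep", seq_len(replicates)), each = 2)
    timepoint <- rep(c("week0", "week3"), replicates)
    for (j in seq_len(2 * replicates))
        counts[, j] <- draw(mu[, timepoint[j]])
    GuideTable(counts = counts, guide_id = guide_id, gene = guide_gene,
               category = guide_cat, replicate = replicate_id,
               timepoint = timepoint)
}
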