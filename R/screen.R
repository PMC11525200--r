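#' CPM-normalize screen counts
#'
#' Adds a \code{cpm} assay: per sample, \code{1e6 * (count + pseudocount) /
#' sum(count + pseudocount)}. The pseudocount (default 0.5) keeps
#' fold changes finite for guides that drop to zero reads.
#'
#' @param table a [GuideTable].
#' @param pseudocount added to every guide count before scaling.
#' @return the [GuideTable] with a \code{cpm} assay.
#' @export
normalizeCounts <- function(table, pseudocount = 0.5) {
    stopifnot(is(table, "GuideTable"))
    validObject(table)
    cts <- SummarizedExperiment::assay(table, "counts") + pseudocount
    tot <- colSums(cts)
    if (any(tot <= 0)) stop("empty sample: total count is 0")
    SummarizedExperiment::assay(table, "cpm") <-
        sweep(cts, 2, tot, "/") * 1e6
    table
}

#' Per-guide log2 fold change
#'
#' For every replicate with both timepoints, computes
#' \code{log2(cpm_week3 / cpm_week0)} per guide, then averages across
#' replicates.
#'
#' @param table a [GuideTable] (CPM-normalized automatically if needed).
#' @param pseudocount passed to [normalizeCounts()] when needed.
#' @return data.frame with columns \code{guide_id}, \code{gene},
#'   \code{category}, \code{log2fc} (mean across replicates) and
#'   \code{n_replicates}.
#' @export
guideLog2FC <- function(table, pseudocount = 0.5) {
    stopifnot(is(table, "GuideTable"))
    if (!"cpm" %in% SummarizedExperiment::assayNames(table))
        table <- normalizeCounts(table, pseudocount)
    cpm <- SummarizedExperiment::assay(table, "cpm")
    cd <- SummarizedExperiment::colData(table)
    reps <- unique(cd$replicate)
    lfc <- matrix(NA_real_, nrow(table), 0)
    for (r in reps) {
        i0 <- which(cd$replicate == r & cd$timepoint == "week0")
        i3 <- which(cd$replicate == r & cd$timepoint == "week3")
        if (length(i0) != 1L || length(i3) != 1L) next
        lfc <- cbind(lfc, log2(cpm[, i3] / cpm[, i0]))
    }
    if (!ncol(lfc)) stop("no replicate has both timepoints")
    rd <- SummarizedExperiment::rowData(table)
    data.frame(guide_id = rd$guide_id, gene = rd$gene,
               category = rd$category, log2fc = rowMeans(lfc),
               n_replicates = ncol(lfc))
}

#' Robust guide z-scores against nontargeting controls
#'
#' \code{z = (log2fc - median(NT)) / (1.4826 * MAD(NT))}, so the median NT
#' guide scores 0 and the scale is the NT distribution's robust SD. The
#' score is invariant to adding a constant to all log2 fold changes.
#'
#' @param stats data.frame from [guideLog2FC()].
#' @return \code{stats} with a \code{z} column; NT location and scale are
#'   attached as attributes \code{nt_median} and \code{nt_scale}.
#' @export
guideZScore <- function(stats) {
    nt <- stats$log2fc[stats$category == "NT"]
    if (length(nt) < 10) stop("need >= 10 NT guides")
    m <- median(nt)
    s <- mad(nt, center = m)  # 1.4826 * median absolute deviation
    if (s == 0) stop("NT guides have zero spread; z-scores undefined")
    stats$z <- (stats$log2fc - m) / s
    attr(stats, "nt_median") <- m
    attr(stats, "nt_scale") <- s
    stats
}

#' Cumulative-fraction depletion AUC of a guide set
#'
#' Ranks all guides by log2 fold change ascending (most depleted first,
#' ties broken lexically by guide id) and traces the cumulative fraction of
#' the query set recovered against the fraction of the ranked list
#' traversed; the AUC is computed by the trapezoid rule. Under this
#' convention AUC near 1 means strong depletion of the set, near 0.5 no
#' selection, near 0 strong enrichment.
#'
#' @param stats data.frame from [guideLog2FC()].
#' @param setGuides character vector of guide ids (nonempty strict subset
#'   of the table).
#' @param setName label for the result.
#' @return list with \code{set}, \code{auc}, \code{n_set}, \code{n_total}
#'   and \code{convention = "ascending_log2fc"}.
#' @export
depletionAUC <- function(stats, setGuides, setName = "set") {
    setGuides <- unique(setGuides)
    if (!length(setGuides)) stop("'setGuides' must be nonempty")
    if (!all(setGuides %in% stats$guide_id))
        stop("unknown guide ids in 'setGuides'")
    N <- nrow(stats)
    if (length(setGuides) >= N)
        stop("'setGuides' must be a strict subset of the ranked guides")
    o <- order(stats$log2fc, stats$guide_id)
    member <- stats$guide_id[o] %in% setGuides
    y <- c(0, cumsum(member) / sum(member))
    # trapezoid over the uniform grid i/N, i = 0..N
    auc <- sum((y[-1] + y[-length(y)]) / 2) / N
    list(set = setName, auc = auc, n_set = length(setGuides), n_total = N,
         convention = "ascending_log2fc")
}

#' Permutation-based gene fitness calls
#'
#' Per-gene statistic: mean log2 fold change of its guides. The null is the
#' distribution of means of size-matched random draws from the pooled guide
#' log2FC values (targeting and NT alike), with a two-sided permutation p
#' and Benjamini-Hochberg FDR across genes. A gene is called
#' \code{enriched} or \code{depleted} only if its FDR is below
#' \code{fdrThreshold} and the fold change implied by its median guide
#' log2FC differs from 1 by more than \code{fcThreshold}; otherwise it is
#' \code{unchanged}.
#'
#' @param stats data.frame from [guideLog2FC()].
#' @param fdrThreshold FDR cutoff (default 0.1).
#' @param fcThreshold fold-change cutoff (default 0.10, i.e. >10% change).
#' @param nPerm permutations per gene size (default 10000).
#' @param seed RNG seed for the permutation draws.
#' @return data.frame with columns \code{gene}, \code{direction},
#'   \code{p_value}, \code{fdr}, \code{median_log2fc}, \code{n_guides}.
#' @export
callGenes <- function(stats, fdrThreshold = 0.1, fcThreshold = 0.10,
                      nPerm = 10000, seed = 1) {
    targ <- stats[!is.na(stats$gene), , drop = FALSE]
    if (!nrow(targ)) stop("no gene-targeting guides")
    pool <- stats$log2fc
    genes <- unique(targ$gene)
    ng <- vapply(genes, function(g) sum(targ$gene == g), integer(1))
    old <- .save_seed()
    on.exit(.restore_seed(old), add = TRUE)
    set.seed(seed)
    # one null ensemble per distinct guide count
    nulls <- lapply(sort(unique(ng)), function(n) {
        draws <- matrix(sample(pool, n * nPerm, replace = TRUE), nrow = n)
        colMeans(draws)
    })
    names(nulls) <- as.character(sort(unique(ng)))
    few <- character(0)
    res <- lapply(seq_along(genes), function(i) {
        g <- genes[i]
        lfc <- targ$log2fc[targ$gene == g]
        n <- length(lfc)
        med <- median(lfc)
        if (n < 2) {
            few <<- c(few, g)
            return(data.frame(gene = g, direction = "unchanged",
                              p_value = NA_real_, fdr = NA_real_,
                              median_log2fc = med, n_guides = n))
        }
        null <- nulls[[as.character(n)]]
        obs <- mean(lfc)
        p_lo <- (1 + sum(null <= obs)) / (nPerm + 1)
        p_hi <- (1 + sum(null >= obs)) / (nPerm + 1)
        data.frame(gene = g, direction = NA_character_,
                   p_value = min(1, 2 * min(p_lo, p_hi)),
                   fdr = NA_real_, median_log2fc = med, n_guides = n)
    })
    calls <- do.call(rbind, res)
    if (length(few))
        warning("genes with < 2 guides called unchanged: ",
                paste(few, collapse = ", "))
    ok <- !is.na(calls$p_value)
    calls$fdr[ok] <- p.adjust(calls$p_value[ok], method = "BH")
    fc_pass <- abs(2^calls$median_log2fc - 1) > fcThreshold
    sig <- ok & calls$fdr < fdrThreshold & fc_pass
    calls$direction[ok] <- "unchanged"
    calls$direction[sig & calls$median_log2fc > 0] <- "enriched"
    calls$direction[sig & calls$median_log2fc < 0] <- "depleted"
    rownames(calls) <- NULL
    calls
}

#' Per-category summary of gene calls
#'
#' Counts enriched, depleted and unchanged genes per annotation category
#' and the percentage of fitness-altering (enriched or depleted) genes,
#' rounded to the nearest integer.
#'
#' @param calls data.frame from [callGenes()] (or any data.frame with
#'   \code{gene} and \code{direction} columns).
#' @param categories named character vector mapping gene to category; must
#'   cover every called gene.
#' @return data.frame with one row per category: \code{category},
#'   \code{n_enriched}, \code{n_depleted}, \code{n_unchanged},
#'   \code{n_total}, \code{n_altered}, \code{percent_altered},
#'   \code{empty}.
#' @examples
#' calls <- data.frame(
#'     gene = paste0("g", 1:23),
#'     direction = rep(c("enriched", "depleted", "unchanged"), c(9, 9, 5)))
#' cats <- setNames(rep("driver", 23), calls$gene)
#' summarizeCalls(calls, cats)$percent_altered  # 78
#' @export
summarizeCalls <- function(calls, categories) {
    missing <- setdiff(calls$gene, names(categories))
    if (length(missing))
        stop("genes without category annotation: ",
             paste(missing, collapse = ", "))
    cats <- unique(categories)
    out <- lapply(cats, function(cat) {
        g <- names(categories)[categories == cat]
        sub <- calls[calls$gene %in% g, , drop = FALSE]
        ne <- sum(sub$direction == "enriched")
        nd <- sum(sub$direction == "depleted")
        nu <- sum(sub$direction == "unchanged")
        tot <- nrow(sub)
        data.frame(category = cat, n_enriched = ne, n_depleted = nd,
                   n_unchanged = nu, n_total = tot, n_altered = ne + nd,
                   percent_altered = if (tot) round(100 * (ne + nd) / tot)
                                     else 0,
                   empty = tot == 0L)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}
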