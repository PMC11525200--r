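.schemas <- list(
    sca = list(cols = c("sca_id", "culture_id", "week", "area_mm2"),
               numeric = c("week", "area_mm2")),
    drift = list(cols = c("time_weeks", "mean_area_mm2", "sca_count",
                          "total_area_mm2"),
                 numeric = c("time_weeks", "mean_area_mm2", "sca_count",
                             "total_area_mm2")),
    competition = list(cols = c("time_weeks", "proportion_focal",
                                "n_cells"),
                       numeric = c("time_weeks", "proportion_focal",
                                   "n_cells")),
    guide = list(cols = c("guide_id", "gene", "category", "replicate",
                          "timepoint", "count"),
                 numeric = "count"))

#' Read a validated tab-separated table
#'
#' Reads a TSV against one of the package's named schemas, with
#' descriptive errors: missing or unexpected columns are named, and a
#' malformed numeric cell is reported with its row number.
#'
#' @param path file path.
#' @param schema one of \code{"sca"}, \code{"drift"},
#'   \code{"competition"}, \code{"guide"}.
#' @return data.frame with typed columns.
#' @export
readTable <- function(path, schema) {
    sc <- .schemas[[match.arg(schema, names(.schemas))]]
    if (!file.exists(path)) stop("file not found: ", path)
    df <- read.delim(path, sep = "\t", header = TRUE,
                     colClasses = "character", check.names = FALSE,
                     na.strings = "NA")
    miss <- setdiff(sc$cols, colnames(df))
    if (length(miss))
        stop("missing column(s) in ", path, ": ",
             paste(miss, collapse = ", "))
    extra <- setdiff(colnames(df), sc$cols)
    if (length(extra))
        stop("unexpected column(s) in ", path, ": ",
             paste(extra, collapse = ", "))
    for (cn in sc$numeric) {
        v <- suppressWarnings(as.numeric(df[[cn]]))
        bad <- which(is.na(v) & !is.na(df[[cn]]))
        if (length(bad))
            stop("malformed numeric value in column '", cn, "', row ",
                 bad[1], ": '", df[[cn]][bad[1]], "'")
        df[[cn]] <- v
    }
    df
}

#' Write a table in the package's TSV dialect
#'
#' UTF-8, tab-separated, '.' decimal separator, mandatory header, no
#' quoting, no row names — so that write/read round trips are bit-exact.
#'
#' @param df data.frame.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeTable <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
    invisible(path)
}

#' Read/write SCA trajectory tables
#'
#' Long-format TSV with columns \code{sca_id}, \code{culture_id},
#' \code{week}, \code{area_mm2}; one row per observed clone-week.
#'
#' @param path file path.
#' @return \code{readScaTable}: list of [SCATrajectory].
#' @export
readScaTable <- function(path) {
    df <- readTable(path, "sca")
    ids <- unique(df$sca_id)
    lapply(ids, function(id) {
        sub <- df[df$sca_id == id, , drop = FALSE]
        sub <- sub[order(sub$week), , drop = FALSE]
        a <- sub$area_mm2
        names(a) <- as.character(sub$week)
        SCATrajectory(scaId = id, cultureId = sub$culture_id[1], areas = a)
    })
}

#' @param trajs list of [SCATrajectory].
#' @rdname readScaTable
#' @export
writeScaTable <- function(trajs, path) {
    df <- do.call(rbind, lapply(trajs, function(tr)
        data.frame(sca_id = tr@scaId, culture_id = tr@cultureId,
                   week = as.integer(names(tr@areas)),
                   area_mm2 = unname(tr@areas))))
    writeTable(df, path)
}

#' Read/write drift summary curves
#'
#' TSV schema: \code{time_weeks}, \code{mean_area_mm2}, \code{sca_count},
#' \code{total_area_mm2}.
#'
#' @param path file path.
#' @return \code{readDriftCurve}: a [DriftCurve].
#' @export
readDriftCurve <- function(path) {
    df <- readTable(path, "drift")
    DriftCurve(times = df$time_weeks, meanArea = df$mean_area_mm2,
               count = df$sca_count, totalArea = df$total_area_mm2)
}

#' @param curve a [DriftCurve].
#' @rdname readDriftCurve
#' @export
writeDriftCurve <- function(curve, path) {
    writeTable(as.data.frame(curve), path)
}

#' Read/write competition proportion series
#'
#' TSV schema: \code{time_weeks}, \code{proportion_focal}, \code{n_cells}.
#'
#' @param path file path.
#' @param focalLabel label for the focal population on read.
#' @return \code{readCompetitionSeries}: a [CompetitionSeries].
#' @export
readCompetitionSeries <- function(path, focalLabel = "focal") {
    df <- readTable(path, "competition")
    CompetitionSeries(times = df$time_weeks,
                      proportion = df$proportion_focal,
                      focalLabel = focalLabel,
                      nCellsSampled = df$n_cells)
}

#' @param series a [CompetitionSeries].
#' @rdname readCompetitionSeries
#' @export
writeCompetitionSeries <- function(series, path) {
    writeTable(data.frame(time_weeks = series@times,
                          proportion_focal = series@proportion,
                          n_cells = series@nCellsSampled), path)
}

#' Read/write guide count tables
#'
#' Long-format TSV with columns \code{guide_id}, \code{gene},
#' \code{category}, \code{replicate}, \code{timepoint}, \code{count}.
#' Nontargeting guides carry \code{gene = NA}.
#'
#' @param path file path.
#' @return \code{readGuideTable}: a [GuideTable].
#' @export
readGuideTable <- function(path) {
    df <- readTable(path, "guide")
    df$gene[df$gene == ""] <- NA_character_
    samples <- unique(df[, c("replicate", "timepoint")])
    samples <- samples[order(samples$replicate, samples$timepoint), ,
                       drop = FALSE]
    guides <- unique(df[, c("guide_id", "gene", "category")])
    counts <- matrix(0, nrow(guides), nrow(samples))
    key <- paste(df$replicate, df$timepoint)
    skey <- paste(samples$replicate, samples$timepoint)
    gi <- match(df$guide_id, guides$guide_id)
    si <- match(key, skey)
    counts[cbind(gi, si)] <- df$count
    GuideTable(counts = counts, guide_id = guides$guide_id,
               gene = guides$gene, category = guides$category,
               replicate = samples$replicate,
               timepoint = samples$timepoint)
}

#' @param table a [GuideTable].
#' @rdname readGuideTable
#' @export
writeGuideTable <- function(table, path) {
    rd <- SummarizedExperiment::rowData(table)
    cd <- SummarizedExperiment::colData(table)
    cts <- SummarizedExperiment::assay(table, "counts")
    df <- do.call(rbind, lapply(seq_len(ncol(cts)), function(j)
        data.frame(guide_id = rd$guide_id, gene = rd$gene,
                   category = rd$category, replicate = cd$replicate[j],
                   timepoint = cd$timepoint[j], count = cts[, j])))
    writeTable(df, path)
}

#' Serialize a drift fit to JSON
#'
#' Flat key-value JSON with \code{kappa_hat}, \code{ci_low},
#' \code{ci_high}, \code{objective}, \code{n_points}, \code{t0},
#' \code{warnings}.
#'
#' @param fit a [FitResult].
#' @param path output path.
#' @export
writeFitResult <- function(fit, path) {
    jsonlite::write_json(list(
        kappa_hat = fit@kappaHat, ci_low = fit@kappaCI[1],
        ci_high = fit@kappaCI[2], objective = fit@objective,
        n_points = fit@nPoints, t0 = fit@t0,
        warnings = as.list(fit@warnings)),
        path, auto_unbox = TRUE, digits = NA, na = "null")
    invisible(path)
}
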