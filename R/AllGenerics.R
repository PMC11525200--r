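#' @name epidrift-accessors
#' @title Accessors for epidrift classes
#' @description Slot accessors for the core classes. Use these rather than
#'   \code{@} access.
#' @param object an epidrift S4 object.
NULL

#' @rdname epidrift-accessors
#' @export
setGeneric("kappa", function(object) standardGeneric("kappa"))
#' @rdname epidrift-accessors
#' @export
setMethod("kappa", "DriftParams", function(object) object@kappa)
#' @rdname epidrift-accessors
#' @export
setMethod("kappa", "FitResult", function(object) object@kappaHat)

#' @rdname epidrift-accessors
#' @export
setGeneric("curveTimes", function(object) standardGeneric("curveTimes"))
#' @rdname epidrift-accessors
#' @export
setMethod("curveTimes", "DriftCurve", function(object) object@times)

#' @rdname epidrift-accessors
#' @export
setGeneric("meanArea", function(object) standardGeneric("meanArea"))
#' @rdname epidrift-accessors
#' @export
setMethod("meanArea", "DriftCurve", function(object) object@meanArea)

#' @rdname epidrift-accessors
#' @export
setGeneric("scaCount", function(object) standardGeneric("scaCount"))
#' @rdname epidrift-accessors
#' @export
setMethod("scaCount", "DriftCurve", function(object) object@count)

#' @rdname epidrift-accessors
#' @export
setGeneric("totalArea", function(object) standardGeneric("totalArea"))
#' @rdname epidrift-accessors
#' @export
setMethod("totalArea", "DriftCurve", function(object) object@totalArea)

#' @rdname epidrift-accessors
#' @export
setGeneric("kappaCI", function(object) standardGeneric("kappaCI"))
#' @rdname epidrift-accessors
#' @export
setMethod("kappaCI", "FitResult", function(object) object@kappaCI)

#' @rdname epidrift-accessors
#' @export
setGeneric("fitWarnings", function(object) standardGeneric("fitWarnings"))
#' @rdname epidrift-accessors
#' @export
setMethod("fitWarnings", "FitResult", function(object) object@warnings)

#' @rdname epidrift-accessors
#' @export
setGeneric("scaAreas", function(object) standardGeneric("scaAreas"))
#' @rdname epidrift-accessors
#' @export
setMethod("scaAreas", "SCATrajectory", function(object) object@areas)

#' @rdname epidrift-accessors
#' @export
setGeneric("scaId", function(object) standardGeneric("scaId"))
#' @rdname epidrift-accessors
#' @export
setMethod("scaId", "SCATrajectory", function(object) object@scaId)

#' @rdname epidrift-accessors
#' @export
setGeneric("cultureId", function(object) standardGeneric("cultureId"))
#' @rdname epidrift-accessors
#' @export
setMethod("cultureId", "SCATrajectory", function(object) object@cultureId)

#' @rdname epidrift-accessors
#' @export
setGeneric("sampleTimes", function(object) standardGeneric("sampleTimes"))
#' @rdname epidrift-accessors
#' @export
setMethod("sampleTimes", "SimTrace", function(object) object@sampleTimes)

#' @rdname epidrift-accessors
#' @export
setGeneric("scaRecords", function(object) standardGeneric("scaRecords"))
#' @rdname epidrift-accessors
#' @export
setMethod("scaRecords", "SimTrace", function(object) object@scaRecords)

#' @rdname epidrift-accessors
#' @export
setGeneric("labelFraction", function(object) standardGeneric("labelFraction"))
#' @rdname epidrift-accessors
#' @export
setMethod("labelFraction", "SimTrace", function(object) object@labelFraction)

#' Coerce a DriftCurve to a data.frame
#'
#' Columns follow the on-disk schema: \code{time_weeks},
#' \code{mean_area_mm2}, \code{sca_count}, \code{total_area_mm2}.
#'
#' @param x a [DriftCurve].
#' @param row.names,optional,... passed through (unused).
#' @export
as.data.frame.DriftCurve <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
    data.frame(time_weeks = x@times, mean_area_mm2 = x@meanArea,
               sca_count = x@count, total_area_mm2 = x@totalArea)
}

setMethod("show", "DriftParams", function(object) {
    cat("DriftParams: kappa =", format(object@kappa), "per week")
    if (!is.na(object@r)) cat(", r =", format(object@r))
    if (!is.na(object@lambdaDiv)) cat(", lambda =", format(object@lambdaDiv))
    if (!is.na(object@rho)) cat(", rho =", format(object@rho), "cells/mm^2")
    cat("\n")
})

setMethod("show", "DriftCurve", function(object) {
    cat("DriftCurve with", length(object@times), "time points (weeks",
        format(min(object@times)), "to", format(max(object@times)), ")\n")
    print(head(as.data.frame(object), 5))
    if (length(object@times) > 5) cat("...\n")
})

setMethod("show", "FitResult", function(object) {
    cat("Single-parameter neutral-drift fit\n")
    cat("  kappa_hat:", format(object@kappaHat), "per week  [",
        format(object@kappaCI[1]), ",", format(object@kappaCI[2]), "]\n")
    cat("  objective:", format(object@objective), "over", object@nPoints,
        "observations; t0 =", object@t0, "weeks\n")
    if (length(object@warnings))
        cat("  warnings:", paste(object@warnings, collapse = ", "), "\n")
})

setMethod("show", "SCATrajectory", function(object) {
    cat("SCATrajectory", object@scaId, "(culture", object@cultureId, "):",
        length(object@areas), "weeks,",
        sum(object@areas > 0, na.rm = TRUE), "above detection\n")
})

setMethod("show", "SimTrace", function(object) {
    cfg <- object@config
    cat("SimTrace:", cfg@width, "x", cfg@height, cfg@mode,
        "lattice,", length(object@sampleTimes), "samples over",
        cfg@duration, "weeks,", nrow(object@scaRecords),
        "SCA records\n")
})

setMethod("show", "CompetitionSeries", function(object) {
    cat("CompetitionSeries '", object@focalLabel, "': ",
        length(object@times), " time points, p0 = ",
        format(object@proportion[1]), "\n", sep = "")
})
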