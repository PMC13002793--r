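#' Accessors for package classes
#'
#' \code{reportData()} returns the report-level data.frame of a
#' \linkS4class{SafetyReportSet} (or of the set inside an
#' \linkS4class{SrsSimulation}); \code{auditLog()} the processing audit
#' counts; \code{cellCounts()} the named (a,b,c,d) vector of a
#' \linkS4class{ContingencyTable}; \code{signalStats()} and
#' \code{signalFlags()} the estimator values and threshold flags of a
#' \linkS4class{SignalResult}; \code{shapeParam()} the Weibull shape
#' estimate with its confidence interval; \code{groundTruth()} the planted
#' parameter ledger of a simulation; \code{communityMembership()} the
#' PT-to-community map of a \linkS4class{CoocNetwork}.
#'
#' @param x the object.
#' @return See each accessor's description.
#' @name accessors
#' @aliases reportData auditLog cellCounts signalStats signalFlags
#'   shapeParam groundTruth communityMembership
NULL

#' @rdname accessors
#' @export
setGeneric("reportData", function(x) standardGeneric("reportData"))
#' @rdname accessors
#' @export
setGeneric("auditLog", function(x) standardGeneric("auditLog"))
#' @rdname accessors
#' @export
setGeneric("cellCounts", function(x) standardGeneric("cellCounts"))
#' @rdname accessors
#' @export
setGeneric("signalStats", function(x) standardGeneric("signalStats"))
#' @rdname accessors
#' @export
setGeneric("signalFlags", function(x) standardGeneric("signalFlags"))
#' @rdname accessors
#' @export
setGeneric("shapeParam", function(x) standardGeneric("shapeParam"))
#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setGeneric("communityMembership", function(x) standardGeneric("communityMembership"))

#' @rdname accessors
setMethod("reportData", "SafetyReportSet", function(x) x@reports)
#' @rdname accessors
setMethod("reportData", "SrsSimulation", function(x) x@reports@reports)
#' @rdname accessors
setMethod("auditLog", "SafetyReportSet", function(x) x@audit)
#' @rdname accessors
setMethod("cellCounts", "ContingencyTable",
          function(x) c(a = x@a, b = x@b, c = x@c, d = x@d))
#' @rdname accessors
setMethod("signalStats", "SignalResult", function(x) x@stats)
#' @rdname accessors
setMethod("signalFlags", "SignalResult", function(x) x@flags)
#' @rdname accessors
setMethod("shapeParam", "WeibullFit",
          function(x) c(shape = x@shape, lo = x@shape_ci[1], hi = x@shape_ci[2]))
#' @rdname accessors
setMethod("groundTruth", "SrsSimulation", function(x) x@truth)
#' @rdname accessors
setMethod("communityMembership", "CoocNetwork", function(x) x@membership)

#' Number of reports in a SafetyReportSet
#' @param x a \linkS4class{SafetyReportSet}.
#' @export
setMethod("length", "SafetyReportSet", function(x) nrow(x@reports))
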