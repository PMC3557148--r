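#' Accessors for the core containers
#'
#' Small accessor generics so user code never reaches into slots:
#' \code{probeIds}/\code{arrayIds}/\code{intensities}/\code{intensityScale}
#' for [ProbeMatrix-class], \code{annotation} for
#' [ProbeAnnotation-class], \code{sampleInfo} for
#' [SampleMetadata-class], \code{qcTable}/\code{flaggedArrays} for
#' [QCReport-class], \code{svMatrix}/\code{numSV} for
#' [SurrogateVariables-class], and \code{truthClusters}/\code{truthArrays}
#' for [SimulationTruth-class].
#'
#' @param x an object of the documented class.
#' @return the corresponding component (matrix, data.frame or vector).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("probeIds", function(x) standardGeneric("probeIds"))
#' @rdname accessors
#' @export
setGeneric("arrayIds", function(x) standardGeneric("arrayIds"))
#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setGeneric("intensityScale", function(x) standardGeneric("intensityScale"))
#' @rdname accessors
#' @export
setGeneric("annotation", function(x) standardGeneric("annotation"))
#' @rdname accessors
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))
#' @rdname accessors
#' @export
setGeneric("qcTable", function(x) standardGeneric("qcTable"))
#' @rdname accessors
#' @export
setGeneric("flaggedArrays", function(x) standardGeneric("flaggedArrays"))
#' @rdname accessors
#' @export
setGeneric("svMatrix", function(x) standardGeneric("svMatrix"))
#' @rdname accessors
#' @export
setGeneric("numSV", function(x) standardGeneric("numSV"))
#' @rdname accessors
#' @export
setGeneric("truthClusters", function(x) standardGeneric("truthClusters"))
#' @rdname accessors
#' @export
setGeneric("truthArrays", function(x) standardGeneric("truthArrays"))

#' @rdname accessors
setMethod("probeIds", "ProbeMatrix", function(x) rownames(x@values))
#' @rdname accessors
setMethod("arrayIds", "ProbeMatrix", function(x) colnames(x@values))
#' @rdname accessors
setMethod("intensities", "ProbeMatrix", function(x) x@values)
#' @rdname accessors
setMethod("intensityScale", "ProbeMatrix", function(x) x@scale)
#' @rdname accessors
setMethod("annotation", "ProbeAnnotation", function(x) x@ann)
#' @rdname accessors
setMethod("sampleInfo", "SampleMetadata", function(x) x@info)
#' @rdname accessors
setMethod("qcTable", "QCReport", function(x) x@report)
#' @rdname accessors
setMethod("flaggedArrays", "QCReport",
    function(x) x@report$array_id[x@report$flagged])
#' @rdname accessors
setMethod("svMatrix", "SurrogateVariables", function(x) x@sv)
#' @rdname accessors
setMethod("numSV", "SurrogateVariables", function(x) ncol(x@sv))
#' @rdname accessors
setMethod("truthClusters", "SimulationTruth", function(x) x@clusters)
#' @rdname accessors
setMethod("truthArrays", "SimulationTruth", function(x) x@arrays)
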