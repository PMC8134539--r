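#' @rdname FCExperiment-accessors
#' @export
setGeneric("fcMatrix", function(x) standardGeneric("fcMatrix"))

#' @rdname FCExperiment-accessors
#' @export
setGeneric("fcStage", function(x) standardGeneric("fcStage"))

#' @rdname FCExperiment-accessors
#' @export
setGeneric("edgeIndex", function(x) standardGeneric("edgeIndex"))

#' @rdname FCExperiment-accessors
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname FCExperiment-accessors
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' @rdname CCAResult-accessors
#' @export
setGeneric("canonicalCorrelations",
           function(x) standardGeneric("canonicalCorrelations"))

#' @rdname CCAResult-accessors
#' @export
setGeneric("etaSquared", function(x) standardGeneric("etaSquared"))

#' @rdname CCAResult-accessors
#' @export
setGeneric("adjEtaSquared", function(x) standardGeneric("adjEtaSquared"))

#' @rdname CCAResult-accessors
#' @export
setGeneric("subjectScores", function(x) standardGeneric("subjectScores"))

#' @rdname PartitionResult-accessors
#' @export
setGeneric("severityLabels", function(x) standardGeneric("severityLabels"))
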