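#' @import methods
NULL

#' @export
setGeneric("oxyHb", function(x) standardGeneric("oxyHb"))

#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' @export
setGeneric("samplingInterval", function(x) standardGeneric("samplingInterval"))

#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @export
setGeneric("channelIds", function(x) standardGeneric("channelIds"))

#' @export
setGeneric("trials", function(x) standardGeneric("trials"))

#' @export
setGeneric("nSessions", function(x) standardGeneric("nSessions"))

#' @export
setGeneric("xScale", function(x) standardGeneric("xScale"))

#' @export
setGeneric("riskParams", function(x) standardGeneric("riskParams"))

#' @export
setGeneric("catchAccuracy", function(x) standardGeneric("catchAccuracy"))

#' @export
setGeneric("covariates", function(x) standardGeneric("covariates"))

#' @export
setGeneric("choices", function(x) standardGeneric("choices"))

#' @export
setGeneric("behaviorLogs", function(x) standardGeneric("behaviorLogs"))

#' @export
setGeneric("recordings", function(x) standardGeneric("recordings"))

#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
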