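#' @import methods
#' @importFrom stats rbinom rlnorm rmultinom rnorm pt setNames
#' @importFrom utils read.delim write.table
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
NULL

#' @export
setGeneric("targets", function(x) standardGeneric("targets"))

#' @export
setGeneric("decoys", function(x) standardGeneric("decoys"))

#' @export
setGeneric("contaminants", function(x) standardGeneric("contaminants"))

#' @export
setGeneric("decoyPrefix", function(x) standardGeneric("decoyPrefix"))

#' @export
setGeneric("seedIds", function(x) standardGeneric("seedIds"))

#' @export
setGeneric("groupIds", function(x) standardGeneric("groupIds"))

#' @export
setGeneric("memberIds", function(x) standardGeneric("memberIds"))

#' @export
setGeneric("seedLengths", function(x) standardGeneric("seedLengths"))

#' @export
setGeneric("groupTaxa", function(x) standardGeneric("groupTaxa"))

#' @export
setGeneric("identityThreshold", function(x) standardGeneric("identityThreshold"))

#' @export
setGeneric("nspc", function(x) standardGeneric("nspc"))

#' @export
setGeneric("spectralCounts", function(x) standardGeneric("spectralCounts"))

#' @export
setGeneric("quantScale", function(x) standardGeneric("quantScale"))

#' @export
setGeneric("quantUniverse", function(x) standardGeneric("quantUniverse"))

#' @export
setGeneric("truthSamples", function(x) standardGeneric("truthSamples"))

#' @export
setGeneric("truthWeights", function(x) standardGeneric("truthWeights"))

#' @export
setGeneric("familyMap", function(x) standardGeneric("familyMap"))

#' @export
setGeneric("rngSeed", function(x) standardGeneric("rngSeed"))
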