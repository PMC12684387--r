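#' @rdname theta
#' @export
setGeneric("theta", function(x) standardGeneric("theta"))

#' @rdname theta
#' @export
setGeneric("theta<-", function(x, value) standardGeneric("theta<-"))

#' @rdname BppResult-accessors
#' @export
setGeneric("bppMatrix", function(x) standardGeneric("bppMatrix"))

#' @rdname BppResult-accessors
#' @export
setGeneric("mbpp", function(x) standardGeneric("mbpp"))

#' @rdname BppResult-accessors
#' @export
setGeneric("partitionFunction", function(x) standardGeneric("partitionFunction"))

#' @rdname SecondaryStructure-accessors
#' @export
setGeneric("basePairs", function(x) standardGeneric("basePairs"))

#' @rdname SecondaryStructure-accessors
#' @export
setGeneric("dotBracket", function(x) standardGeneric("dotBracket"))

#' @rdname SecondaryStructure-accessors
#' @export
setGeneric("foldEnergy", function(x) standardGeneric("foldEnergy"))

#' @rdname TrainResult-accessors
#' @export
setGeneric("lossHistory", function(x) standardGeneric("lossHistory"))

#' @rdname TrainResult-accessors
#' @export
setGeneric("updateCount", function(x) standardGeneric("updateCount"))

#' @rdname TrainResult-accessors
#' @export
setGeneric("thetaTrajectory", function(x) standardGeneric("thetaTrajectory"))
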