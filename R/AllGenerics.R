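# Accessor generics. Slot access from user code is discouraged; these are the
# supported surface.

#' @rdname QuadratureRule-class
#' @param object,x a package object
#' @export
setGeneric("quadPoints", function(object) standardGeneric("quadPoints"))

#' @rdname QuadratureRule-class
#' @export
setGeneric("quadWeights", function(object) standardGeneric("quadWeights"))

#' @rdname GaussianBelief-class
#' @export
setGeneric("beliefMean", function(object) standardGeneric("beliefMean"))

#' @rdname GaussianBelief-class
#' @export
setGeneric("beliefCov", function(object) standardGeneric("beliefCov"))

#' @rdname FilterTrace-class
#' @param k time index
#' @export
setGeneric("filteredBelief", function(object, k) standardGeneric("filteredBelief"))

#' @rdname FilterTrace-class
#' @export
setGeneric("predictedBelief", function(object, k) standardGeneric("predictedBelief"))

#' @rdname SmoothTrace-class
#' @export
setGeneric("smoothedMeans", function(object) standardGeneric("smoothedMeans"))

#' @rdname SmoothTrace-class
#' @export
setGeneric("smoothedCovs", function(object) standardGeneric("smoothedCovs"))

#' @rdname SmoothTrace-class
#' @export
setGeneric("smootherGains", function(object) standardGeneric("smootherGains"))

#' @rdname GRNFit-class
#' @export
setGeneric("coefMatrix", function(object) standardGeneric("coefMatrix"))

#' @rdname GRNFit-class
#' @export
setGeneric("thetaHat", function(object) standardGeneric("thetaHat"))

#' @rdname GRNFit-class
#' @export
setGeneric("emHistory", function(object) standardGeneric("emHistory"))

#' Run a parameter-estimation method on expression data
#'
#' Generic over the observation container: a plain K x n matrix (rows = time
#' points, columns = genes) or a [SummarizedExperiment::SummarizedExperiment]
#' as produced by [simulateGRN()] (genes x time points).
#'
#' @param Y observations
#' @param model a [StateSpaceModel-class]
#' @param config an [emConfig()] list
#' @param ... passed through
#' @export
setGeneric("runEM", function(Y, model, config, ...) standardGeneric("runEM"))
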