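#' @rdname GenotypeData
#' @param x a `GenotypeData` object.
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' @rdname GenotypeData
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' @rdname GenotypeData
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))

#' @rdname GenotypeData
#' @param value replacement vector (named by sample id, or positional).
#' @export
setGeneric("sampleLabels<-",
           function(x, value) standardGeneric("sampleLabels<-"))

#' @rdname GenotypeData
#' @export
setGeneric("sampleSplits", function(x) standardGeneric("sampleSplits"))

#' @rdname GenotypeData
#' @export
setGeneric("sampleSplits<-",
           function(x, value) standardGeneric("sampleSplits<-"))

#' @rdname Bloc
#' @param x a `Bloc` object.
#' @export
setGeneric("blocSize", function(x) standardGeneric("blocSize"))

#' @rdname Bloc
#' @export
setGeneric("blocMembers", function(x) standardGeneric("blocMembers"))

#' @rdname AlleleNetwork-class
#' @param x an `AlleleNetwork` object.
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
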