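#' @rdname SignatureMatrix-class
#' @param object,x a `SignatureMatrix`
#' @export
setGeneric("signatureStage", function(x) standardGeneric("signatureStage"))

#' @rdname EmbeddingResult-class
#' @export
setGeneric("embeddingCoords", function(x) standardGeneric("embeddingCoords"))

#' @rdname EmbeddingResult-class
#' @export
setGeneric("klTrace", function(x) standardGeneric("klTrace"))

#' @rdname EmbeddingResult-class
#' @export
setGeneric("tsneParams", function(x) standardGeneric("tsneParams"))

#' @rdname MarkerTable-class
#' @export
setGeneric("geneUniverse", function(x) standardGeneric("geneUniverse"))

#' @rdname SyntheticCommunity-class
#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))

#' @rdname SyntheticCommunity-class
#' @export
setGeneric("markerTable", function(x) standardGeneric("markerTable"))

#' @rdname SyntheticCommunity-class
#' @export
setGeneric("truthLabels", function(x) standardGeneric("truthLabels"))
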