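# Accessors, show methods, coercions for the core classes.

#' @rdname SignatureMatrix-class
#' @export
setMethod("signatureStage", "SignatureMatrix", function(x) x@stage)

#' @describeIn SignatureMatrix-class numeric matrix of signature values
#'   (row names are sequence ids, column names the k-mer index).
#' @param ... ignored
#' @export
setMethod("as.matrix", "SignatureMatrix", function(x, ...) {
  m <- x@values
  dimnames(m) <- list(x@ids, x@kmers)
  m
})

#' @rdname SignatureMatrix-class
#' @export
setMethod("dim", "SignatureMatrix", function(x) dim(x@values))

setMethod("show", "SignatureMatrix", function(object) {
  cat(sprintf(
    "SignatureMatrix: %d sequences x %d features (k = %d, stage = %s%s)\n",
    nrow(object@values), ncol(object@values), object@k, object@stage,
    if (object@mergeRevcomp) ", canonical k-mers" else ""
  ))
})

#' Construct Barnes-Hut t-SNE parameters
#'
#' @param perplexity target perplexity; must satisfy
#'   `perplexity < (n - 1) / 3` for `n` input points so that each point
#'   can have `floor(3 * perplexity)` neighbors.
#' @param theta Barnes-Hut accuracy parameter in \[0, 1\]; a quadtree cell
#'   of width `w` at distance `r` is summarized by its center of mass when
#'   `w / r < theta`; `theta = 0` reproduces the exact gradient.
#' @param nIter gradient-descent iterations.
#' @param earlyExaggeration,exaggerationIter affinity exaggeration factor
#'   and the number of initial iterations it is applied for.
#' @param learningRate gradient-descent learning rate.
#' @param momentumStart,momentumFinal,momentumSwitch momentum schedule.
#' @param seed integer RNG seed.
#' @param nThreads threads for the gradient computation.
#' @return a [TsneParams] object.
#' @examples
#' TsneParams(perplexity = 10, seed = 1L)
#' @export
TsneParams <- function(perplexity = 30, theta = 0.5, nIter = 1000L,
                       earlyExaggeration = 12, exaggerationIter = 250L,
                       learningRate = 200, momentumStart = 0.5,
                       momentumFinal = 0.8, momentumSwitch = 250L,
                       seed = 42L, nThreads = 1L) {
  new("TsneParams",
    perplexity = as.numeric(perplexity), theta = as.numeric(theta),
    nIter = as.integer(nIter),
    earlyExaggeration = as.numeric(earlyExaggeration),
    exaggerationIter = as.integer(exaggerationIter),
    learningRate = as.numeric(learningRate),
    momentumStart = as.numeric(momentumStart),
    momentumFinal = as.numeric(momentumFinal),
    momentumSwitch = as.integer(momentumSwitch),
    seed = as.integer(seed), nThreads = as.integer(nThreads)
  )
}

setMethod("show", "TsneParams", function(object) {
  cat(sprintf(
    paste0("TsneParams: perplexity=%g theta=%g nIter=%d ",
           "exaggeration=%g(x%d) eta=%g seed=%d threads=%d\n"),
    object@perplexity, object@theta, object@nIter,
    object@earlyExaggeration, object@exaggerationIter,
    object@learningRate, object@seed, object@nThreads
  ))
})

setMethod("show", "AffinityMatrix", function(object) {
  cat(sprintf(
    "AffinityMatrix (%s): %d points, %d stored pairs, perplexity %g\n",
    object@type, nrow(object@P), length(object@P@x), object@perplexity
  ))
})

#' @rdname EmbeddingResult-class
#' @param x an `EmbeddingResult`
#' @export
setMethod("embeddingCoords", "EmbeddingResult", function(x) {
  m <- x@coords
  rownames(m) <- x@ids
  colnames(m) <- c("x", "y")
  m
})

#' @rdname EmbeddingResult-class
#' @export
setMethod("klTrace", "EmbeddingResult", function(x) x@klTrace)

#' @rdname EmbeddingResult-class
#' @export
setMethod("tsneParams", "EmbeddingResult", function(x) x@params)

setMethod("show", "EmbeddingResult", function(object) {
  lastKl <- if (nrow(object@klTrace)) {
    sprintf(", final KL %.4f", utils::tail(object@klTrace$kl, 1))
  } else ""
  cat(sprintf("EmbeddingResult: %d points in 2-D%s\n",
              nrow(object@coords), lastKl))
})

#' @rdname MarkerTable-class
#' @param x a `MarkerTable`
#' @export
setMethod("geneUniverse", "MarkerTable", function(x) x@geneUniverse)

#' @describeIn MarkerTable-class one row per gene occurrence
#'   (`contigId`, `geneId`).
#' @param row.names,optional,... passed conventions of [as.data.frame()]
#' @export
setMethod("as.data.frame", "MarkerTable",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(contigId = x@contigId, geneId = x@geneId,
               stringsAsFactors = FALSE)
  }
)

setMethod("show", "MarkerTable", function(object) {
  cat(sprintf(
    "MarkerTable: %d gene occurrences on %d contigs (universe: %d genes)\n",
    length(object@geneId), length(unique(object@contigId)),
    length(object@geneUniverse)
  ))
})

#' @rdname SyntheticCommunity-class
#' @param x a `SyntheticCommunity`
#' @export
setMethod("fragments", "SyntheticCommunity", function(x) x@fragments)

#' @rdname SyntheticCommunity-class
#' @export
setMethod("markerTable", "SyntheticCommunity", function(x) x@markers)

#' @rdname SyntheticCommunity-class
#' @export
setMethod("truthLabels", "SyntheticCommunity", function(x) {
  stats::setNames(S4Vectors::mcols(x@fragments)$label, names(x@fragments))
})

setMethod("show", "SyntheticCommunity", function(object) {
  cat(sprintf(
    "SyntheticCommunity: %d fragments from %d populations (seed %d)\n",
    length(object@fragments), nrow(object@populations), object@seed
  ))
})
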