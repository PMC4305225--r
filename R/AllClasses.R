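#' @import methods
#' @importFrom Rcpp sourceCpp
#' @importFrom stats setNames
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom Matrix Matrix
#' @useDynLib binscape, .registration = TRUE
NULL

#' Oligonucleotide signature matrix
#'
#' One row per sequence fragment, one column per k-mer (or principal
#' component after reduction). The `stage` slot records how far along the
#' counts -> frequencies -> CLR -> PCA pipeline the values are.
#'
#' @slot ids character, sequence identifiers (row names of `values`).
#' @slot kmers character, the k-mer index in fixed lexicographic order
#'   (A < C < G < T); for `stage = "pca"` the retained component names.
#' @slot values numeric matrix, n x d.
#' @slot stage one of `"counts"`, `"frequencies"`, `"clr"`, `"pca"`.
#' @slot k integer k-mer length used.
#' @slot mergeRevcomp logical, whether reverse complements were folded onto
#'   canonical k-mers.
#'
#' @exportClass SignatureMatrix
setClass("SignatureMatrix",
  representation(
    ids = "character",
    kmers = "character",
    values = "matrix",
    stage = "character",
    k = "integer",
    mergeRevcomp = "logical"
  )
)

setValidity("SignatureMatrix", function(object) {
  msg <- character()
  if (length(object@stage) != 1L ||
      !object@stage %in% c("counts", "frequencies", "clr", "pca"))
    msg <- c(msg, "stage must be one of counts/frequencies/clr/pca")
  if (nrow(object@values) != length(object@ids))
    msg <- c(msg, "number of ids must equal number of rows")
  if (ncol(object@values) != length(object@kmers))
    msg <- c(msg, "kmer index length must equal number of columns")
  if (anyDuplicated(object@ids))
    msg <- c(msg, "sequence ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Barnes-Hut t-SNE parameters
#'
#' Hyperparameters of the embedding. Defaults follow the reference
#' Barnes-Hut t-SNE implementation: perplexity 30, theta 0.5, 1000
#' iterations, early exaggeration 12 for the first 250 iterations,
#' learning rate 200, momentum 0.5 switching to 0.8 at iteration 250.
#'
#' @slot perplexity target perplexity (effective neighbor count), > 0.
#' @slot theta Barnes-Hut accuracy in \[0, 1\]; 0 is the exact method.
#' @slot nIter number of gradient-descent iterations.
#' @slot earlyExaggeration factor applied to the affinities for the first
#'   `exaggerationIter` iterations.
#' @slot exaggerationIter iterations under early exaggeration.
#' @slot learningRate gradient-descent learning rate (eta).
#' @slot momentumStart,momentumFinal momentum before/after `momentumSwitch`.
#' @slot momentumSwitch iteration at which momentum switches.
#' @slot seed integer RNG seed; with `nThreads = 1` the embedding is
#'   bit-reproducible for a fixed seed.
#' @slot nThreads threads used for the gradient (>= 1).
#'
#' @exportClass TsneParams
setClass("TsneParams",
  representation(
    perplexity = "numeric",
    theta = "numeric",
    nIter = "integer",
    earlyExaggeration = "numeric",
    exaggerationIter = "integer",
    learningRate = "numeric",
    momentumStart = "numeric",
    momentumFinal = "numeric",
    momentumSwitch = "integer",
    seed = "integer",
    nThreads = "integer"
  )
)

setValidity("TsneParams", function(object) {
  msg <- character()
  if (object@perplexity <= 0) msg <- c(msg, "perplexity must be > 0")
  if (object@theta < 0 || object@theta > 1)
    msg <- c(msg, "theta must be in [0, 1]")
  if (object@nIter < 1L) msg <- c(msg, "nIter must be >= 1")
  if (object@earlyExaggeration < 1)
    msg <- c(msg, "earlyExaggeration must be >= 1")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (object@nThreads < 1L) msg <- c(msg, "nThreads must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Neighbor affinity matrix
#'
#' Sparse pairwise affinities used by t-SNE. `type = "conditional"` holds
#' the row-stochastic conditional probabilities p(j|i) over each point's
#' floor(3 * perplexity) exact nearest neighbors; `type = "joint"` holds
#' the symmetrized joint probabilities p_ij = (p(j|i) + p(i|j)) / (2n),
#' which sum to 1 over all stored pairs.
#'
#' @slot P sparse n x n matrix (`Matrix::dgCMatrix`).
#' @slot beta per-point Gaussian precision reached by the perplexity
#'   binary search.
#' @slot perplexity target perplexity used.
#' @slot type `"conditional"` or `"joint"`.
#'
#' @exportClass AffinityMatrix
setClass("AffinityMatrix",
  representation(
    P = "Matrix",
    beta = "numeric",
    perplexity = "numeric",
    type = "character"
  )
)

setValidity("AffinityMatrix", function(object) {
  msg <- character()
  if (!object@type %in% c("conditional", "joint"))
    msg <- c(msg, "type must be 'conditional' or 'joint'")
  if (nrow(object@P) != ncol(object@P))
    msg <- c(msg, "P must be square")
  if (any(object@P@x < 0)) msg <- c(msg, "affinities must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Two-dimensional embedding result
#'
#' @slot ids character, sequence identifiers (one per embedded point).
#' @slot coords n x 2 numeric matrix of embedding coordinates.
#' @slot klTrace data.frame with columns `iteration`, `kl`: the
#'   Kullback-Leibler divergence recorded every 50 iterations.
#' @slot params the [TsneParams] actually used.
#'
#' @exportClass EmbeddingResult
setClass("EmbeddingResult",
  representation(
    ids = "character",
    coords = "matrix",
    klTrace = "data.frame",
    params = "TsneParams"
  )
)

setValidity("EmbeddingResult", function(object) {
  msg <- character()
  if (ncol(object@coords) != 2L) msg <- c(msg, "coords must have 2 columns")
  if (nrow(object@coords) != length(object@ids))
    msg <- c(msg, "one id per embedded point required")
  if (any(!is.finite(object@coords)))
    msg <- c(msg, "coords must be finite")
  if (nrow(object@klTrace) && any(object@klTrace$kl < 0))
    msg <- c(msg, "KL divergence trace must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Contig-to-marker-gene table
#'
#' One row per detected gene occurrence (a gene found twice on one contig
#' contributes two rows), against a fixed universe of single-copy genes
#' whose size is the completeness denominator.
#'
#' @slot contigId character, contig carrying the occurrence.
#' @slot geneId character, gene identifier; must belong to `geneUniverse`.
#' @slot geneUniverse character, the reference list of single-copy genes
#'   (107 by default, see [essentialGeneUniverse()]).
#'
#' @exportClass MarkerTable
setClass("MarkerTable",
  representation(
    contigId = "character",
    geneId = "character",
    geneUniverse = "character"
  )
)

setValidity("MarkerTable", function(object) {
  msg <- character()
  if (length(object@contigId) != length(object@geneId))
    msg <- c(msg, "contigId and geneId must have equal length")
  if (!all(object@geneId %in% object@geneUniverse))
    msg <- c(msg, "every geneId must belong to the gene universe")
  if (anyDuplicated(object@geneUniverse))
    msg <- c(msg, "gene universe must not contain duplicates")
  if (length(msg)) msg else TRUE
})

#' Synthetic mock community
#'
#' Fragments drawn from order-m Markov "genomes" with known population
#' labels, simulated coverage, and planted single-copy marker genes.
#'
#' @slot fragments `Biostrings::DNAStringSet` with `mcols` columns
#'   `label`, `coverage`, `gc`.
#' @slot markers [MarkerTable] of planted gene occurrences.
#' @slot populations data.frame with one row per population: `id`,
#'   `abundance`, `coverage`.
#' @slot seed integer seed the community was generated from.
#'
#' @exportClass SyntheticCommunity
setClass("SyntheticCommunity",
  representation(
    fragments = "DNAStringSet",
    markers = "MarkerTable",
    populations = "data.frame",
    seed = "integer"
  )
)

setValidity("SyntheticCommunity", function(object) {
  md <- S4Vectors::mcols(object@fragments)
  msg <- character()
  if (is.null(md) || !all(c("label", "coverage") %in% colnames(md))) {
    msg <- c(msg, "fragments must carry label and coverage metadata")
  } else {
    if (!all(md$label %in% object@populations$id))
      msg <- c(msg, "every fragment label must name a population")
    if (any(md$coverage <= 0))
      msg <- c(msg, "coverage must be positive")
  }
  if (length(msg)) msg else TRUE
})
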