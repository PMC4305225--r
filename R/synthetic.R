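# Mock metagenomic communities: each population is an order-m Markov
# "genome" with its own transition model, so populations differ in
# oligonucleotide composition exactly the way signature-based binning
# assumes. Fragments, coverage, and planted single-copy marker genes make
# every pipeline stage testable without external data.

.BASES <- c("A", "C", "G", "T")

#' Generate a population-specific Markov sequence model
#'
#' An order-`m` stationary Markov model over A/C/G/T. Each of the 4^m
#' transition rows is a log-normally perturbed uniform composition,
#' `p(base | context) ∝ exp(divergence * sigma0 * z)` with iid standard
#' normal `z` and a fixed perturbation scale `sigma0 = 0.2`, so
#' `divergence = 0` gives exactly uniform rows (populations
#' indistinguishable) and `divergence = 1` gives multiplicative
#' composition biases of about `e^{±0.2}`. The scale is calibrated so
#' that at the default study conditions inter-population compositional
#' distances are comparable to the k-mer count noise of 1,000-nt
#' fragments — the regime in which fragments of about 1,000 nt form
#' separable clusters while clusters overlap as lengths approach 600 nt,
#' matching the documented length dependence of signature-based binning.
#'
#' @param order Markov order `m >= 0` (default 4, so 5-mer signatures are
#'   informative by construction).
#' @param divergence in `[0, 1]`; how far transition rows depart from
#'   uniform.
#' @param seed integer seed; the model is deterministic per seed.
#' @return list with `order`, `divergence`, and the `4^m x 4` row-
#'   stochastic `transitions` matrix (rows named by context).
#' @export
generatePopulationModel <- function(order = 4L, divergence, seed) {
  stopifnot(order >= 0L, divergence >= 0, divergence <= 1)
  set.seed(as.integer(seed))
  nCtx <- 4L^as.integer(order)
  sigma0 <- 0.2
  z <- matrix(stats::rnorm(nCtx * 4L), nCtx, 4L)
  w <- exp(divergence * sigma0 * z)
  trans <- w / rowSums(w)
  rownames(trans) <- if (order > 0L) {
    Biostrings::mkAllStrings(.BASES, as.integer(order))
  } else "."
  colnames(trans) <- .BASES
  list(order = as.integer(order), divergence = divergence,
       transitions = trans)
}

#' Simulate a genome from a population model
#'
#' @param model from [generatePopulationModel()].
#' @param length genome length in nt.
#' @return a single character string over A/C/G/T. Uses the current RNG
#'   state (seed it upstream).
#' @export
simulateGenome <- function(model, length) {
  m <- model$order
  stopifnot(length > m)
  cum <- t(apply(model$transitions, 1, cumsum))
  if (!is.matrix(cum)) cum <- matrix(cum, nrow = 1)
  init <- if (m > 0L) sample.int(4L, m, replace = TRUE) - 1L else integer(0)
  codes <- markov_sequence_cpp(as.integer(length), m, cum, init,
                               stats::runif(length))
  paste(.BASES[codes + 1L], collapse = "")
}

#' Generate a synthetic mock community
#'
#' One Markov genome per population; fragments are cut at uniform random
#' genome positions with lengths `fragMin + Exp(mean = fragMean -
#' fragMin)` (truncated at the genome end), per-population coverage is
#' drawn log-normally (so the opacity channel has realistic structure),
#' and each gene of `markerGenes` is planted exactly once per genome on a
#' random fragment of that population.
#'
#' @param nPops number of populations.
#' @param genomeLength genome length per population, nt.
#' @param fragMin,fragMean minimum and mean fragment length, nt.
#' @param nFragsPerPop fragments sampled per population.
#' @param divergence compositional divergence in `[0, 1]`, see
#'   [generatePopulationModel()].
#' @param seed integer master seed; everything (models, genomes,
#'   fragments, coverage, marker placement) derives from it.
#' @param order Markov order of the population models.
#' @param markerGenes genes to plant once per genome; default the bundled
#'   107-gene universe.
#' @return a [SyntheticCommunity].
#' @examples
#' cm <- generateCommunity(nPops = 2, genomeLength = 20000,
#'                         nFragsPerPop = 20, divergence = 0.8, seed = 1)
#' table(truthLabels(cm))
#' @export
generateCommunity <- function(nPops = 5L, genomeLength = 100000L,
                              fragMin = 1000L, fragMean = 1500L,
                              nFragsPerPop = 200L, divergence = 0.8,
                              seed = 1L, order = 4L,
                              markerGenes = essentialGeneUniverse()) {
  stopifnot(nPops >= 1L, genomeLength >= fragMin, fragMean >= fragMin)
  seed <- as.integer(seed)
  popIds <- sprintf("pop%02d", seq_len(nPops))

  models <- lapply(seq_len(nPops), function(p) {
    generatePopulationModel(order = order, divergence = divergence,
                            seed = seed + 7919L * p)
  })

  set.seed(seed)
  popCoverage <- stats::rlnorm(nPops, meanlog = log(15), sdlog = 0.8)
  abundance <- popCoverage / sum(popCoverage)

  seqs <- character(0)
  ids <- character(0)
  labels <- character(0)
  coverage <- numeric(0)
  mContig <- character(0)
  mGene <- character(0)

  for (p in seq_len(nPops)) {
    set.seed(seed + 104729L * p)
    genome <- simulateGenome(models[[p]], genomeLength)
    lens <- pmin(
      fragMin + round(stats::rexp(nFragsPerPop, 1 / (fragMean - fragMin))),
      genomeLength
    )
    starts <- vapply(lens, function(l) {
      sample.int(genomeLength - l + 1L, 1L)
    }, integer(1))
    frag <- substring(genome, starts, starts + lens - 1L)
    id <- sprintf("%s_frag%04d", popIds[p], seq_len(nFragsPerPop))
    seqs <- c(seqs, frag)
    ids <- c(ids, id)
    labels <- c(labels, rep(popIds[p], nFragsPerPop))
    coverage <- c(coverage,
                  popCoverage[p] * stats::rlnorm(nFragsPerPop, 0, 0.1))
    # plant each marker gene exactly once per genome
    carrier <- sample(id, length(markerGenes), replace = TRUE)
    mContig <- c(mContig, carrier)
    mGene <- c(mGene, markerGenes)
  }

  frags <- Biostrings::DNAStringSet(seqs)
  names(frags) <- ids
  gc <- 100 * as.numeric(
    Biostrings::letterFrequency(frags, "GC", as.prob = TRUE))
  S4Vectors::mcols(frags) <- S4Vectors::DataFrame(
    label = labels, coverage = coverage, gc = gc
  )
  new("SyntheticCommunity",
      fragments = frags,
      markers = MarkerTable(mContig, mGene, universe = markerGenes),
      populations = data.frame(id = popIds, abundance = abundance,
                               coverage = popCoverage),
      seed = seed)
}

#' Materialize a synthetic community as a fixture directory
#'
#' Writes `community.fasta`, `annotations.csv` (length, coverage, gc,
#' label, isMarker — the per-sequence annotation dialect), `markers.csv`
#' (contig_id, gene_id) and `truth.csv` (id, label).
#'
#' @param community a [SyntheticCommunity].
#' @param dir output directory (created if needed).
#' @return (invisibly) named vector of the file paths written.
#' @export
writeCommunity <- function(community, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  frags <- fragments(community)
  md <- S4Vectors::mcols(frags)
  paths <- c(
    fasta = file.path(dir, "community.fasta"),
    annotations = file.path(dir, "annotations.csv"),
    markers = file.path(dir, "markers.csv"),
    truth = file.path(dir, "truth.csv")
  )
  Biostrings::writeXStringSet(frags, paths["fasta"], width = 70L)
  isMarker <- names(frags) %in% community@markers@contigId
  utils::write.csv(
    data.frame(length = Biostrings::width(frags),
               coverage = md$coverage, gc = md$gc, label = md$label,
               isMarker = as.integer(isMarker)),
    paths["annotations"], row.names = FALSE, quote = FALSE
  )
  utils::write.csv(
    data.frame(contig_id = community@markers@contigId,
               gene_id = community@markers@geneId),
    paths["markers"], row.names = FALSE, quote = FALSE
  )
  utils::write.csv(
    data.frame(id = names(frags), label = md$label),
    paths["truth"], row.names = FALSE, quote = FALSE
  )
  invisible(paths)
}

#' k-nearest-neighbor label purity of an embedding
#'
#' Fraction of points whose majority label among their `k` nearest
#' embedded neighbors (Euclidean, ties in distance broken by row index)
#' equals their own label. A tied majority vote is counted as a
#' disagreement (conservative).
#'
#' @param embedding an [EmbeddingResult] or an n x 2 coordinate matrix.
#' @param labels one label per point.
#' @param k neighbors to consult, `k < n`.
#' @return purity in `[0, 1]`.
#' @export
knnLabelPurity <- function(embedding, labels, k = 5L) {
  co <- if (is(embedding, "EmbeddingResult")) embeddingCoords(embedding)
        else as.matrix(embedding)
  n <- nrow(co)
  stopifnot(k < n, length(labels) == n)
  labels <- as.character(labels)
  D2 <- .squaredDistances(co)
  agree <- vapply(seq_len(n), function(i) {
    others <- seq_len(n)[-i]
    nn <- others[order(D2[i, others], others)[seq_len(k)]]
    votes <- table(labels[nn])
    top <- votes[votes == max(votes)]
    length(top) == 1L && names(top) == labels[i]
  }, logical(1))
  mean(agree)
}
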