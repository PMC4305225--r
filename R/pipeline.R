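# End-to-end pipeline: filter -> signatures -> embedding -> optional
# polygon selection -> optional bin assessment, with a JSON run manifest
# that suffices to reproduce the run (single-threaded).

#' Assemble a pipeline configuration
#'
#' All defaults are materialized here so the manifest records the full
#' effective configuration, seed included.
#'
#' @param input path to the input multi-FASTA.
#' @param outputDir directory for all artifacts (created if needed).
#' @param annotations optional annotation CSV (see [readAnnotations()]).
#' @param polygons optional polygon file (see [readPolygons()]); each
#'   named polygon is extracted and exported as `<name>.fasta`.
#' @param markers optional contig-to-marker-gene table (see
#'   [readMarkerTable()]); when given, every selected bin is scored.
#' @param minLength minimum fragment length, nt (inclusive).
#' @param k,mergeRevcomp,pseudocount,pcaDims signature options, see
#'   [computeSignatures()].
#' @param tsne a [TsneParams].
#' @param plot write `embedding.png`?
#' @return a `RunConfig` (named list, class `"RunConfig"`).
#' @export
runConfig <- function(input, outputDir, annotations = NULL,
                      polygons = NULL, markers = NULL,
                      minLength = 1000L, k = 5L, mergeRevcomp = FALSE,
                      pseudocount = 1, pcaDims = 50L,
                      tsne = TsneParams(), plot = TRUE) {
  stopifnot(is(tsne, "TsneParams"))
  structure(list(
    input = input, outputDir = outputDir, annotations = annotations,
    polygons = polygons, markers = markers,
    minLength = as.integer(minLength), k = as.integer(k),
    mergeRevcomp = mergeRevcomp, pseudocount = pseudocount,
    pcaDims = if (is.null(pcaDims)) NULL else as.integer(pcaDims),
    tsne = tsne, plot = plot
  ), class = "RunConfig")
}

.paramsAsList <- function(p) {
  sl <- methods::slotNames(class(p))
  stats::setNames(lapply(sl, methods::slot, object = p), sl)
}

#' Run the full visualization-and-binning pipeline
#'
#' Stages: length filter, CLR k-mer signatures (optionally PCA-reduced),
#' Barnes-Hut t-SNE, optional polygon selection with per-bin FASTA
#' export, optional marker-gene bin assessment. Writes `embedding.csv`,
#' optionally `embedding.png`, one `<polygon>.fasta` per selection, a
#' `bin_stats.csv` report when markers are supplied, and `manifest.json`
#' with versions, parameters, seed, input checksums and per-stage counts.
#'
#' @param config a `RunConfig` from [runConfig()].
#' @param verbose log stage progress?
#' @return (invisibly) the manifest as a list.
#' @export
runPipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "RunConfig"))
  t0 <- Sys.time()
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))

  records <- readFastaRecords(config$input, minLength = config$minLength)
  meta <- S4Vectors::metadata(records)
  say("input: %d records, %d dropped below %d nt, %d retained",
      meta$nInput, meta$nDropped, config$minLength, length(records))

  ann <- NULL
  if (!is.null(config$annotations)) {
    ann <- readAnnotations(config$annotations, records)
    say("annotations: %s", paste(colnames(ann), collapse = ", "))
  }

  sig <- computeSignatures(records, k = config$k,
                           mergeRevcomp = config$mergeRevcomp,
                           pseudocount = config$pseudocount,
                           pcaDims = config$pcaDims)
  say("signatures: %d x %d (stage %s)", nrow(sig), ncol(sig),
      signatureStage(sig))

  emb <- runBhSne(sig, params = config$tsne)
  embPath <- file.path(config$outputDir, "embedding.csv")
  writeEmbedding(emb, embPath)
  say("embedding: %d points, final KL %.4f", length(records),
      utils::tail(klTrace(emb)$kl, 1))

  outputs <- c(embedding = embPath)
  polys <- NULL
  if (!is.null(config$polygons)) polys <- readPolygons(config$polygons)

  if (isTRUE(config$plot)) {
    plotPath <- file.path(config$outputDir, "embedding.png")
    plotEmbedding(emb, lengths = Biostrings::width(records),
                  annotations = ann, polygons = polys, file = plotPath)
    outputs["plot"] <- plotPath
  }

  selections <- list()
  if (!is.null(polys)) {
    for (nm in names(polys)) {
      ids <- selectCluster(emb, polys[[nm]])
      say("selection %s: %d points", nm, length(ids))
      fa <- file.path(config$outputDir, paste0(nm, ".fasta"))
      writeBinFasta(records, ids, fa)
      outputs[paste0("bin_", nm)] <- fa
      selections[[nm]] <- ids
    }
  }

  if (!is.null(config$markers) && length(selections)) {
    markers <- readMarkerTable(config$markers)
    stats <- do.call(rbind, lapply(names(selections), function(nm) {
      cbind(bin = nm, assessBin(selections[[nm]], records, markers))
    }))
    repPath <- file.path(config$outputDir, "bin_stats.csv")
    writeBinReport(stats, repPath)
    outputs["bin_stats"] <- repPath
  }

  manifest <- list(
    package = "binscape",
    version = as.character(utils::packageVersion("binscape")),
    rVersion = R.version.string,
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    input = list(
      path = config$input,
      md5 = unname(tools::md5sum(config$input)),
      annotations = config$annotations,
      polygons = config$polygons,
      markers = config$markers
    ),
    parameters = list(
      minLength = config$minLength, k = config$k,
      mergeRevcomp = config$mergeRevcomp,
      pseudocount = config$pseudocount, pcaDims = config$pcaDims,
      tsne = .paramsAsList(config$tsne)
    ),
    seed = config$tsne@seed,
    counts = list(
      inputRecords = meta$nInput,
      filteredRecords = length(records),
      embeddedPoints = length(records),
      selected = lapply(selections, length)
    ),
    outputs = as.list(outputs)
  )
  jsonlite::write_json(manifest, file.path(config$outputDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Rebuild a pipeline configuration from a run manifest
#'
#' With one thread, re-running the returned configuration reproduces the
#' embedding bit-for-bit.
#'
#' @param path a `manifest.json` written by [runPipeline()].
#' @param outputDir output directory for the rerun (defaults to the
#'   manifest's directory).
#' @return a `RunConfig`.
#' @export
configFromManifest <- function(path, outputDir = dirname(path)) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  ts <- m$parameters$tsne
  orNull <- function(x) if (is.null(x) || length(x) == 0L) NULL else x
  runConfig(
    input = m$input$path, outputDir = outputDir,
    annotations = orNull(m$input$annotations),
    polygons = orNull(m$input$polygons),
    markers = orNull(m$input$markers),
    minLength = m$parameters$minLength, k = m$parameters$k,
    mergeRevcomp = m$parameters$mergeRevcomp,
    pseudocount = m$parameters$pseudocount,
    pcaDims = m$parameters$pcaDims,
    tsne = TsneParams(
      perplexity = ts$perplexity, theta = ts$theta, nIter = ts$nIter,
      earlyExaggeration = ts$earlyExaggeration,
      exaggerationIter = ts$exaggerationIter,
      learningRate = ts$learningRate, momentumStart = ts$momentumStart,
      momentumFinal = ts$momentumFinal, momentumSwitch = ts$momentumSwitch,
      seed = ts$seed, nThreads = ts$nThreads
    )
  )
}
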