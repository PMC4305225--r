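# Bin quality from single-copy essential-gene annotations: completeness
# (fraction of the gene universe recovered) and homogeneity (how few
# genes occur in multiple copies, a contamination signal).

#' The bundled universe of 107 single-copy essential genes
#'
#' Bacterial single-copy marker genes (ribosomal proteins, tRNA
#' synthetases, RNA polymerase subunits, replication and translation
#' factors) are conserved across nearly all sequenced bacteria, so a bin
#' from a single population should carry each at most once: genes present
#' in multiple copies indicate a mixed bin, genes absent reduce
#' completeness. The bundled list
#' (`inst/extdata/essential_genes_synthetic.txt`) is a representative,
#' synthetic stand-in of the conventional 107-gene universe — the names
#' exist only to give completeness a reproducible denominator; analyses of
#' real data should pass the gene identifiers their annotation pipeline
#' emits.
#'
#' @return character vector of 107 gene names.
#' @examples
#' length(essentialGeneUniverse())  # 107
#' @export
essentialGeneUniverse <- function() {
  path <- system.file("extdata", "essential_genes_synthetic.txt",
                      package = "binscape", mustWork = TRUE)
  readLines(path)
}

#' Construct a contig-to-marker-gene table
#'
#' @param contigId,geneId parallel character vectors, one entry per gene
#'   occurrence (a gene detected twice on one contig appears twice).
#' @param universe the single-copy gene universe; defaults to the bundled
#'   107-gene list.
#' @return a [MarkerTable].
#' @export
MarkerTable <- function(contigId = character(), geneId = character(),
                        universe = essentialGeneUniverse()) {
  new("MarkerTable", contigId = as.character(contigId),
      geneId = as.character(geneId), geneUniverse = universe)
}

#' Read a contig-to-marker-gene table from file
#'
#' Tab- or comma-separated, two columns `(contig_id, gene_id)` with one
#' row per gene occurrence; a header row is detected and skipped if its
#' first field is `contig_id` or `contigId`.
#'
#' @param path table path.
#' @inheritParams MarkerTable
#' @return a [MarkerTable].
#' @export
readMarkerTable <- function(path, universe = essentialGeneUniverse()) {
  if (!file.exists(path)) stop("marker table not readable: ", path)
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  header <- grepl("^contig_?[iI]d", first)
  tab <- utils::read.table(path, sep = sep, header = header,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("marker table needs columns (contig_id, gene_id)")
  MarkerTable(tab[[1]], tab[[2]], universe = universe)
}

.geneCopyNumbers <- function(binIds, markers) {
  hit <- markers@contigId %in% binIds
  table(factor(markers@geneId[hit], levels = markers@geneUniverse))
}

#' Score a bin against the single-copy gene universe
#'
#' Aggregates marker-gene multiplicities over the bin's contigs. A gene
#' occurring twice on one contig counts as copy number 2 (occurrences,
#' not contigs — the contamination-sensitive convention). `totalMbp` is
#' the summed contig length in Mbp, rounded half-even to 2 decimals at
#' report time; `completeness` is the fraction of the universe present
#' with at least one copy.
#'
#' @param binIds contig ids of the bin (may be empty); every id must
#'   occur among `records`.
#' @param records `DNAStringSet` of all contigs (lengths are taken from
#'   the sequences).
#' @param markers a [MarkerTable].
#' @return one-row data.frame: `nContigs`, `totalMbp`, `singleCopy`,
#'   `multipleCopies`, `completeness`.
#' @export
assessBin <- function(binIds, records, markers) {
  binIds <- as.character(binIds)
  missing <- setdiff(binIds, names(records))
  if (length(missing))
    stop("bin id(s) absent from records: ",
         paste(utils::head(missing, 5), collapse = ", "))
  copies <- .geneCopyNumbers(binIds, markers)
  nU <- length(markers@geneUniverse)
  data.frame(
    nContigs = length(binIds),
    totalMbp = round(sum(Biostrings::width(records[binIds])) / 1e6, 2),
    singleCopy = sum(copies == 1),
    multipleCopies = sum(copies >= 2),
    completeness = sum(copies >= 1) / nU
  )
}

#' Compare a parent bin against refined subclusters
#'
#' Scores the parent and each subcluster and reports the change in
#' multi-copy gene count and completeness relative to the parent.
#' Subclusters need not partition the parent: re-selection on the
#' embedding can recruit fragments that the original binning placed
#' elsewhere, which is how refinement can *gain* completeness while
#' shedding multi-copy contamination.
#'
#' @param parentIds contig ids of the parent bin.
#' @param subclusters named list of contig-id vectors.
#' @inheritParams assessBin
#' @return data.frame with one row for the parent and one per subcluster,
#'   with columns of [assessBin()] plus `bin`, `deltaMultipleCopies` and
#'   `deltaCompleteness` (subcluster minus parent; `NA` for the parent).
#' @export
comparePartitions <- function(parentIds, subclusters, records, markers) {
  if (is.null(names(subclusters)))
    names(subclusters) <- sprintf("subcluster%03d", seq_along(subclusters))
  parent <- assessBin(parentIds, records, markers)
  rows <- lapply(names(subclusters), function(nm) {
    s <- assessBin(subclusters[[nm]], records, markers)
    cbind(bin = nm, s,
          deltaMultipleCopies = s$multipleCopies - parent$multipleCopies,
          deltaCompleteness = s$completeness - parent$completeness)
  })
  out <- rbind(
    cbind(bin = "parent", parent,
          deltaMultipleCopies = NA_integer_,
          deltaCompleteness = NA_real_),
    do.call(rbind, rows)
  )
  rownames(out) <- NULL
  out
}

#' Write a bin-statistics report as CSV
#'
#' Columns mirror the conventional report: bin name, number of contigs,
#' Mbp, single-copy and multiple-copy gene counts, plus completeness.
#'
#' @param stats data.frame from [assessBin()] (optionally with a `bin`
#'   column) or [comparePartitions()].
#' @param path output CSV path.
#' @return (invisibly) the path.
#' @export
writeBinReport <- function(stats, path) {
  utils::write.csv(stats, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
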