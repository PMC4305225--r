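# FASTA, annotation-file, embedding-file and polygon-file I/O.

IUPAC_DNA <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N", ".", "-") # '-' last: regex class

#' Read contigs from a multi-FASTA file with a minimum-length filter
#'
#' Reads nucleotide sequences, uppercases them, and drops every fragment
#' shorter than `minLength` (the threshold is inclusive: the default keeps
#' fragments of at least 1,000 nt, below which signature-based clusters
#' degrade and eventually overlap). FASTA ids are the header up to the
#' first whitespace; the remainder is kept as a description and re-emitted
#' on export.
#'
#' @param path FASTA file (wrapped or single-line).
#' @param minLength minimum retained fragment length in nt (inclusive),
#'   default 1000.
#' @return a [Biostrings::DNAStringSet] of the retained records in file
#'   order, with `mcols` column `description` and metadata entries
#'   `nInput`, `nDropped` and `keptIndices` (positions of the retained
#'   records in the unfiltered file, used to align annotation rows).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACGTACGT", ">b x", "ACGT"), fa)
#' readFastaRecords(fa, minLength = 5)
#' @export
readFastaRecords <- function(path, minLength = 1000L) {
  if (!is.character(path) || !file.exists(path))
    stop("FASTA file not readable: ", path)
  if (minLength < 1L) stop("minLength must be >= 1")
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("FASTA file contains no records: ", path)

  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(ids))) stop("FASTA record with empty id")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate FASTA ids: ", paste(utils::head(dup, 5), collapse = ", "))
  }

  seqs <- toupper(as.character(raw))
  bad <- !grepl(paste0("^[", paste(IUPAC_DNA, collapse = ""), "]*$"), seqs)
  if (any(bad)) {
    stop("non-IUPAC nucleotide characters in record(s): ",
         paste(utils::head(ids[bad], 5), collapse = ", "))
  }
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence in record(s): ",
         paste(utils::head(ids[nchar(seqs) == 0L], 5), collapse = ", "))
  }

  keep <- nchar(seqs) >= minLength
  out <- Biostrings::DNAStringSet(gsub("U", "T", seqs[keep], fixed = TRUE))
  names(out) <- ids[keep]
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(description = desc[keep])
  S4Vectors::metadata(out) <- list(
    nInput = length(raw),
    nDropped = sum(!keep),
    keptIndices = unname(which(keep)),
    minLength = as.integer(minLength)
  )
  out
}

.parseLogical01 <- function(x, field) {
  v <- tolower(trimws(as.character(x)))
  if (!all(v %in% c("0", "1", "true", "false")))
    stop(field, " values must be in {0, 1, true, false}")
  v %in% c("1", "true")
}

#' Read the per-sequence annotation file
#'
#' A comma-separated file with a header row naming a subset of
#' `{length, coverage, gc, label, isMarker}` and one data row per FASTA
#' record *in FASTA file order* (the format carries no id column; rows are
#' aligned positionally). The rows are then subset to the records retained
#' by the length filter, so annotation row i describes retained record i.
#'
#' @param path annotation CSV.
#' @param records the `DNAStringSet` returned by [readFastaRecords()]
#'   (its metadata records which file positions were retained).
#' @return a [S4Vectors::DataFrame] aligned to `records`, with whichever
#'   of the columns `length`, `coverage`, `gc`, `label`, `isMarker` the
#'   file provided.
#' @export
readAnnotations <- function(path, records) {
  if (!file.exists(path)) stop("annotation file not readable: ", path)
  tab <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                         check.names = FALSE, strip.white = TRUE)
  known <- c("length", "coverage", "gc", "label", "isMarker")
  unknown <- setdiff(colnames(tab), known)
  if (length(unknown))
    stop("unknown annotation field(s): ", paste(unknown, collapse = ", "),
         " (expected a subset of ", paste(known, collapse = ", "), ")")
  if (ncol(tab) == 0L) stop("annotation file has no recognized fields")

  meta <- S4Vectors::metadata(records)
  nInput <- meta$nInput
  if (is.null(nInput)) nInput <- length(records)
  if (nrow(tab) != nInput) {
    stop(sprintf(
      "annotation row count (%d) does not match FASTA record count (%d)",
      nrow(tab), nInput))
  }

  for (fld in c("coverage", "gc", "length")) {
    if (fld %in% colnames(tab)) {
      v <- suppressWarnings(as.numeric(tab[[fld]]))
      if (anyNA(v) && !all(is.na(tab[[fld]]) == is.na(v)))
        stop("non-numeric ", fld, " value in annotation file")
      if (anyNA(v)) stop("non-numeric ", fld, " value in annotation file")
      tab[[fld]] <- v
    }
  }
  if ("coverage" %in% colnames(tab) && any(tab$coverage < 0))
    stop("coverage must be >= 0")
  if ("gc" %in% colnames(tab) && any(tab$gc < 0 | tab$gc > 100))
    stop("gc must lie in [0, 100]")
  if ("isMarker" %in% colnames(tab))
    tab$isMarker <- .parseLogical01(tab$isMarker, "isMarker")

  kept <- meta$keptIndices
  if (is.null(kept)) kept <- seq_len(length(records))
  out <- S4Vectors::DataFrame(tab[kept, , drop = FALSE])
  rownames(out) <- names(records)
  out
}

#' Export selected records as a FASTA bin
#'
#' Writes the records named in `ids`, preserving input order, full
#' sequences and descriptions; lines wrap at 70 columns.
#'
#' @param records a `DNAStringSet` (e.g. from [readFastaRecords()]).
#' @param ids ids to export; every id must occur among `records`.
#' @param path output FASTA path.
#' @return (invisibly) the number of records written.
#' @export
writeBinFasta <- function(records, ids, path) {
  missing <- setdiff(ids, names(records))
  if (length(missing))
    stop("unknown sequence id(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  sel <- records[names(records) %in% ids]
  desc <- S4Vectors::mcols(sel)$description
  out <- sel
  if (!is.null(desc)) {
    hasDesc <- nzchar(desc)
    names(out)[hasDesc] <- paste(names(sel)[hasDesc], desc[hasDesc])
  }
  Biostrings::writeXStringSet(out, path, width = 70L)
  invisible(length(sel))
}

#' Write / read a two-dimensional embedding as CSV
#'
#' The on-disk format is `id,x,y`, one row per embedded sequence, so an
#' embedding can be reloaded for re-selection without recomputation.
#'
#' @param embedding an [EmbeddingResult].
#' @param path CSV path.
#' @return `writeEmbedding`: (invisibly) the path. `readEmbedding`: a
#'   data.frame with columns `id`, `x`, `y`.
#' @export
writeEmbedding <- function(embedding, path) {
  co <- embeddingCoords(embedding)
  df <- data.frame(id = rownames(co), x = co[, 1], y = co[, 2])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeEmbedding
#' @export
readEmbedding <- function(path) {
  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("id", "x", "y") %in% colnames(df)))
    stop("embedding file must have columns id, x, y")
  df$id <- as.character(df$id)
  df
}

#' Read named selection polygons
#'
#' Accepts either a JSON object mapping polygon names to vertex lists
#' (`{"bin1": [[x, y], ...], ...}`) or a CSV with columns
#' `name,x,y` (vertices grouped by name, in row order).
#'
#' @param path polygon file (`.json` or `.csv`).
#' @return a named list of numeric matrices with columns `x`, `y`.
#' @export
readPolygons <- function(path) {
  if (!file.exists(path)) stop("polygon file not readable: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    polys <- lapply(raw, function(v) {
      m <- matrix(as.numeric(unlist(v)), ncol = 2, byrow = !is.matrix(v))
      if (is.matrix(v)) m <- v
      colnames(m) <- c("x", "y")
      m
    })
  } else {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("name", "x", "y") %in% colnames(tab)))
      stop("polygon CSV must have columns name, x, y")
    polys <- lapply(split(tab, factor(tab$name, unique(tab$name))),
                    function(d) {
      m <- cbind(x = d$x, y = d$y)
      m
    })
  }
  bad <- vapply(polys, function(m) nrow(m) < 3 || any(!is.finite(m)),
                logical(1))
  if (any(bad))
    stop("polygon(s) with fewer than 3 vertices or non-finite coordinates: ",
         paste(names(polys)[bad], collapse = ", "))
  polys
}
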