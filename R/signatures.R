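# Oligonucleotide signatures: k-mer counts -> pseudocounted frequencies ->
# centered log-ratio transform -> optional PCA pre-reduction.

#' The fixed k-mer index
#'
#' Lexicographic over A < C < G < T. With `mergeRevcomp = TRUE` only
#' canonical k-mers are kept, where the canonical form of a k-mer is the
#' lexicographically smaller of itself and its reverse complement
#' (512 canonical 5-mers instead of 4^5 = 1024).
#'
#' @param k k-mer length, >= 1.
#' @param mergeRevcomp fold reverse complements onto canonical k-mers?
#' @return character vector of k-mers in index order.
#' @examples
#' kmerIndex(1)            # A C G T
#' length(kmerIndex(5))    # 1024
#' length(kmerIndex(5, mergeRevcomp = TRUE))  # 512
#' @export
kmerIndex <- function(k, mergeRevcomp = FALSE) {
  stopifnot(k >= 1)
  all <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), as.integer(k))
  if (!mergeRevcomp) return(all)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(all)))
  sort(unique(pmin(all, rc)))
}

.canonicalFoldMap <- function(k) {
  all <- kmerIndex(k)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(all)))
  pmin(all, rc)
}

#' Count overlapping k-mers in a nucleotide sequence
#'
#' Every window of length `k` consisting solely of A/C/G/T is counted;
#' windows containing any other symbol (N or other IUPAC ambiguity codes)
#' contribute nothing. With `mergeRevcomp = TRUE` each window increments
#' its canonical k-mer, and the returned vector is indexed by canonical
#' k-mers only. Case-insensitive.
#'
#' @param sequence a character string, `DNAString`, or `DNAStringSet`
#'   (for a set, a count matrix with one row per sequence is returned).
#' @param k k-mer length.
#' @param mergeRevcomp fold reverse complements onto canonical k-mers?
#' @return named integer vector over [kmerIndex()] (or matrix for a set).
#'   A sequence shorter than `k` yields the zero vector with attribute
#'   `tooShort = TRUE`.
#' @examples
#' countKmers("AAAA", k = 2)["AA"]        # 3
#' countKmers("ACGNA", k = 2)[c("AC", "CG")]  # 1 1; GN and NA skipped
#' @export
countKmers <- function(sequence, k = 5L, mergeRevcomp = FALSE) {
  k <- as.integer(k)
  stopifnot(k >= 1L)
  single <- !is(sequence, "DNAStringSet")
  dss <- if (is(sequence, "DNAStringSet")) {
    sequence
  } else if (is(sequence, "DNAString")) {
    Biostrings::DNAStringSet(sequence)
  } else {
    Biostrings::DNAStringSet(toupper(as.character(sequence)))
  }
  counts <- Biostrings::oligonucleotideFrequency(dss, width = k)
  storage.mode(counts) <- "integer"
  if (mergeRevcomp) {
    fold <- .canonicalFoldMap(k)
    counts <- t(rowsum(t(counts), fold))
    counts <- counts[, kmerIndex(k, TRUE), drop = FALSE]
    storage.mode(counts) <- "integer"
  }
  if (single) {
    v <- counts[1L, ]
    if (Biostrings::width(dss)[1L] < k) attr(v, "tooShort") <- TRUE
    v
  } else {
    counts
  }
}

#' Normalize k-mer counts to a strictly positive frequency vector
#'
#' Additive (pseudocount) smoothing before normalization:
#' `(counts_i + pseudocount) / sum_j (counts_j + pseudocount)`. The
#' pseudocount keeps every component strictly positive so the centered
#' log-ratio transform downstream is defined even for absent k-mers.
#'
#' @param counts non-negative count vector or matrix (rows = sequences).
#' @param pseudocount positive smoothing constant, default 1.
#' @return frequency vector/matrix; every row sums to 1.
#' @export
toFrequencies <- function(counts, pseudocount = 1) {
  stopifnot(pseudocount > 0, all(counts >= 0))
  if (is.matrix(counts)) {
    sm <- counts + pseudocount
    sm / rowSums(sm)
  } else {
    sm <- counts + pseudocount
    sm / sum(sm)
  }
}

#' Centered log-ratio (CLR) transform
#'
#' Maps a composition to `ln(x_i) - mean_j ln(x_j)`, i.e. log-ratios to
#' the geometric mean. CLR rows sum to zero, removing the unit-sum
#' constraint of frequency vectors so that Euclidean distances downstream
#' are meaningful for compositional data.
#'
#' @param freqs strictly positive frequency vector or matrix
#'   (rows = compositions). Any non-positive component is an error — it
#'   signals a missing pseudocount upstream.
#' @return transformed vector/matrix; rows sum to 0.
#' @examples
#' clrTransform(rep(1 / 4, 4))   # all zeros
#' @export
clrTransform <- function(freqs) {
  if (any(freqs <= 0))
    stop("CLR requires strictly positive components; ",
         "apply a pseudocount before normalization")
  lg <- log(freqs)
  if (is.matrix(lg)) lg - rowMeans(lg) else lg - mean(lg)
}

#' Compute the CLR signature matrix of a set of sequence fragments
#'
#' Per record: count k-mers, smooth and normalize, CLR-transform. If
#' `pcaDims` is set, the CLR matrix is column-centered and projected onto
#' its top principal components (deterministic sign convention: the
#' largest-magnitude loading of each component is made positive), a
#' standard pre-reduction before Barnes-Hut t-SNE.
#'
#' @param records `DNAStringSet` (e.g. from [readFastaRecords()]), n >= 2.
#' @param k k-mer length, default 5 (1,024 features).
#' @param mergeRevcomp fold reverse complements? Default `FALSE`,
#'   preserving the full 4^k dimensionality.
#' @param pseudocount smoothing constant, default 1.
#' @param pcaDims number of principal components to keep, or `NULL` to
#'   skip PCA. Default 50; must satisfy `pcaDims < n` and `pcaDims <= d`.
#' @return a [SignatureMatrix] with stage `"clr"` or `"pca"`.
#' @export
computeSignatures <- function(records, k = 5L, mergeRevcomp = FALSE,
                              pseudocount = 1, pcaDims = 50L) {
  if (length(records) < 2L) stop("need at least 2 records")
  counts <- countKmers(records, k = k, mergeRevcomp = mergeRevcomp)
  clr <- clrTransform(toFrequencies(counts, pseudocount))
  ids <- names(records)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(clr)))
  idx <- kmerIndex(k, mergeRevcomp)

  if (is.null(pcaDims)) {
    return(new("SignatureMatrix", ids = ids, kmers = idx, values = clr,
               stage = "clr", k = as.integer(k),
               mergeRevcomp = mergeRevcomp))
  }
  pcaDims <- as.integer(pcaDims)
  n <- nrow(clr); d <- ncol(clr)
  if (pcaDims >= n) stop("pcaDims must be < number of records")
  if (pcaDims > d) stop("pcaDims must be <= signature dimensionality")
  pc <- stats::prcomp(clr, center = TRUE, scale. = FALSE, rank. = pcaDims)
  # sign convention: largest-magnitude loading of each component positive
  flip <- vapply(seq_len(pcaDims), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  scores <- sweep(pc$x[, seq_len(pcaDims), drop = FALSE], 2, flip, `*`)
  new("SignatureMatrix", ids = ids,
      kmers = colnames(scores), values = unname(scores),
      stage = "pca", k = as.integer(k), mergeRevcomp = mergeRevcomp)
}

#' Export a signature matrix as CSV
#'
#' One row per sequence (`id` column first, then the k-mer or component
#' columns), for analysis outside R.
#'
#' @param signatures a [SignatureMatrix].
#' @param path output CSV path.
#' @return (invisibly) the path.
#' @export
writeSignatures <- function(signatures, path) {
  m <- as.matrix(signatures)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
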