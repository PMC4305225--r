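# Independent brute-force oracles, deliberately naive and separate from
# the implementation paths they check.

# sliding-window k-mer tally over a character sequence
oracleCountKmers <- function(seq, k, mergeRevcomp = FALSE) {
  seq <- toupper(seq)
  idx <- kmerIndex(k, mergeRevcomp)
  counts <- setNames(integer(length(idx)), idx)
  n <- nchar(seq)
  if (n < k) return(counts)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (s in 1:(n - k + 1)) {
    w <- substr(seq, s, s + k - 1)
    if (!grepl("^[ACGT]+$", w)) next
    if (mergeRevcomp) {
      rc <- paste(rev(comp[strsplit(w, "")[[1]]]), collapse = "")
      w <- min(w, rc)
    }
    counts[w] <- counts[w] + 1L
  }
  counts
}

randomDna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# literal double-loop transcription of the t-SNE gradient
oracleExactGradient <- function(P, Y) {
  P <- as.matrix(P)
  n <- nrow(Y)
  Z <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) Z <- Z + 1 / (1 + sum((Y[i, ] - Y[j, ])^2))
  }
  G <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d2 <- sum((Y[i, ] - Y[j, ])^2)
      w <- 1 / (1 + d2)
      q <- w / Z
      G[i, ] <- G[i, ] + 4 * (P[i, j] - q) * w * (Y[i, ] - Y[j, ])
    }
  }
  G
}

# literal double-loop KL divergence over stored pairs
oracleKl <- function(P, Y) {
  P <- as.matrix(P)
  n <- nrow(Y)
  Z <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) Z <- Z + 1 / (1 + sum((Y[i, ] - Y[j, ])^2))
  }
  kl <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    p <- P[i, j]
    if (p <= 0) next
    q <- (1 / (1 + sum((Y[i, ] - Y[j, ])^2))) / Z
    kl <- kl + p * (log(max(p, 1e-12)) - log(max(q, 1e-12)))
  }
  kl
}

# winding-number point-in-polygon (nonzero rule; agrees with even-odd
# for simple polygons, used off-boundary only)
oracleWindingNumber <- function(pt, poly) {
  m <- nrow(poly)
  wn <- 0
  for (i in seq_len(m)) {
    a <- poly[i, ]
    b <- poly[if (i == m) 1 else i + 1, ]
    isLeft <- (b[1] - a[1]) * (pt[2] - a[2]) - (pt[1] - a[1]) * (b[2] - a[2])
    if (a[2] <= pt[2]) {
      if (b[2] > pt[2] && isLeft > 0) wn <- wn + 1
    } else {
      if (b[2] <= pt[2] && isLeft < 0) wn <- wn - 1
    }
  }
  wn != 0
}

writeTempFasta <- function(ids, seqs, desc = NULL, width = 60) {
  path <- tempfile(fileext = ".fasta")
  con <- file(path, "w")
  for (i in seq_along(ids)) {
    hdr <- if (!is.null(desc) && nzchar(desc[i])) {
      paste(ids[i], desc[i])
    } else ids[i]
    writeLines(paste0(">", hdr), con)
    s <- seqs[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  close(con)
  path
}
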