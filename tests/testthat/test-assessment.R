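makeRecords <- function(ids, len = 1000) {
  set.seed(61)
  r <- Biostrings::DNAStringSet(vapply(rep(len, length(ids)), randomDna,
                                       character(1)))
  names(r) <- ids
  r
}

test_that("bin statistics match hand counts on a constructed fixture", {
  recs <- makeRecords(c("c1", "c2", "c3"), len = 250000)
  mk <- MarkerTable(contigId = c("c1", "c2", "c3"),
                    geneId = c("rplA", "rpoB", "rpoB"))
  st <- assessBin(c("c1", "c2", "c3"), recs, mk)
  expect_identical(st$nContigs, 3L)
  expect_identical(st$singleCopy, 1L)      # rplA
  expect_identical(st$multipleCopies, 1L)  # rpoB on two contigs
  expect_equal(st$completeness, 2 / 107)
  expect_equal(st$totalMbp, 0.75)          # 3 x 0.25 Mbp

  # empty bin
  st0 <- assessBin(character(0), recs, mk)
  expect_identical(st0$nContigs, 0L)
  expect_identical(st0$singleCopy, 0L)
  expect_identical(st0$multipleCopies, 0L)
  expect_equal(st0$completeness, 0)
  expect_equal(st0$totalMbp, 0)

  expect_error(assessBin("nope", recs, mk), "absent")
})

test_that("a gene occurring twice on one contig counts as copy number two", {
  recs <- makeRecords("c1")
  mk <- MarkerTable(contigId = c("c1", "c1"), geneId = c("gyrA", "gyrA"))
  st <- assessBin("c1", recs, mk)
  expect_identical(st$singleCopy, 0L)
  expect_identical(st$multipleCopies, 1L)
})

test_that("random bins match an exhaustive per-gene tally oracle", {
  set.seed(62)
  ids <- sprintf("ctg%02d", 1:50)
  recs <- makeRecords(ids)
  universe <- essentialGeneUniverse()
  occ <- data.frame(
    contig = sample(ids, 400, replace = TRUE),
    gene = sample(universe, 400, replace = TRUE)
  )
  mk <- MarkerTable(occ$contig, occ$gene)
  for (rep in 1:5) {
    bin <- sample(ids, sample(5:40, 1))
    st <- assessBin(bin, recs, mk)
    copies <- vapply(universe, function(g) {
      sum(occ$gene == g & occ$contig %in% bin)
    }, numeric(1))
    expect_identical(st$singleCopy, sum(copies == 1))
    expect_identical(st$multipleCopies, sum(copies >= 2))
    expect_equal(st$completeness, sum(copies >= 1) / 107)
    expect_identical(st$singleCopy + st$multipleCopies,
                     sum(copies >= 1)) # distinct genes present
    expect_true(st$completeness * 107 == round(st$completeness * 107))
  }
})

test_that("assessment is contig-order invariant and merging is monotone", {
  set.seed(63)
  ids <- sprintf("m%02d", 1:20)
  recs <- makeRecords(ids)
  mk <- MarkerTable(sample(ids, 100, replace = TRUE),
                    sample(essentialGeneUniverse(), 100, replace = TRUE))
  bin <- sample(ids, 10)
  expect_identical(assessBin(bin, recs, mk),
                   assessBin(rev(bin), recs, mk))
  # merging two bins never loses a present gene
  a <- ids[1:8]; b <- ids[9:20]
  cu <- binscape:::.geneCopyNumbers(c(a, b), mk)
  ca <- binscape:::.geneCopyNumbers(a, mk)
  cb <- binscape:::.geneCopyNumbers(b, mk)
  expect_true(all(cu >= pmax(ca, cb)))
})

test_that("splitting a merged two-genome bin restores homogeneity", {
  idsA <- sprintf("a%02d", 1:10)
  idsB <- sprintf("b%02d", 1:10)
  recs <- makeRecords(c(idsA, idsB))
  universe <- essentialGeneUniverse()
  set.seed(64)
  # both genomes are marker-complete: every gene once per genome
  mk <- MarkerTable(
    contigId = c(sample(idsA, 107, replace = TRUE),
                 sample(idsB, 107, replace = TRUE)),
    geneId = c(universe, universe)
  )
  rep <- comparePartitions(c(idsA, idsB),
                           list(A = idsA, B = idsB), recs, mk)
  parent <- rep[rep$bin == "parent", ]
  subs <- rep[rep$bin != "parent", ]
  expect_identical(parent$multipleCopies, 107L) # all genes shared
  expect_identical(subs$multipleCopies, c(0L, 0L))
  expect_true(all(subs$deltaMultipleCopies < 0))
  expect_true(any(subs$deltaCompleteness >= 0))
  expect_equal(subs$completeness, c(1, 1))

  # identity comparison: zero deltas
  idrep <- comparePartitions(idsA, list(same = idsA), recs, mk)
  expect_identical(idrep$deltaMultipleCopies[2], 0L)
  expect_equal(idrep$deltaCompleteness[2], 0)
})

test_that("a subcluster recruiting outside contigs can exceed parent completeness", {
  ids <- sprintf("r%02d", 1:12)
  recs <- makeRecords(ids)
  universe <- essentialGeneUniverse()
  mk <- MarkerTable(contigId = ids[1:12],
                    geneId = universe[1:12])
  parent <- ids[1:6] # carries genes 1..6
  sub <- ids[1:9]    # recruits r07..r09, gains genes 7..9
  rep <- comparePartitions(parent, list(s = sub), recs, mk)
  expect_gt(rep$deltaCompleteness[2], 0)
  st <- assessBin(sub, recs, mk)
  expect_identical(st$singleCopy, 9L)
})

test_that("marker tables read from CSV and TSV with or without header", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("contig_id,gene_id", "c1,rplA", "c1,rplB", "c2,rplA"), p)
  mk <- readMarkerTable(p)
  expect_length(mk@geneId, 3L)
  expect_identical(length(geneUniverse(mk)), 107L)

  p2 <- tempfile(fileext = ".tsv")
  writeLines(c("c1\trplA", "c2\tgyrB"), p2)
  mk2 <- readMarkerTable(p2)
  expect_identical(mk2@contigId, c("c1", "c2"))

  expect_error(MarkerTable("c1", "notAGene"), "universe")
})
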